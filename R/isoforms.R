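#' Expressed isoforms per gene per tissue
#'
#' Counts, for every (gene, tissue), how many of the gene's annotated
#' transcripts pass the expression call. Genes with zero expressed isoforms
#' in a tissue are omitted from that tissue's rows, so the per-tissue mean is
#' taken over genes with at least one expressed isoform (the only denominator
#' under which per-gene averages near 1.2 are attainable), and the histogram
#' totals equal the tissue's expressed-gene count. The histogram buckets
#' isoform counts into 1, 2, 3 and a 4+ overflow.
#'
#' @param tx_calls transcript-level `call_set`.
#' @param ann an [annotation_set()] resolving every called transcript.
#' @return An object of class `isoform_table`: list with `counts` (long
#'   data.frame: `gene_id`, `tissue`, `n_isoforms`), `means` (named vector,
#'   mean isoforms per expressed gene per tissue) and `histogram` (tissue x
#'   bucket matrix over `"1"`, `"2"`, `"3"`, `"4+"`).
#' @export
isoform_counts <- function(tx_calls, ann) {
  stopifnot(inherits(tx_calls, "call_set"), inherits(ann, "atlas_annotation"))
  absent <- setdiff(unlist(tx_calls$expressed, use.names = FALSE),
                    ann$transcripts$transcript_id)
  if (length(absent))
    stop("called transcripts with no parent gene in the annotation: ",
         paste(head(absent, 10), collapse = ", "))
  tissues <- names(tx_calls$expressed)
  per_tissue <- lapply(tissues, function(t) {
    ids <- tx_calls$expressed[[t]]
    if (!length(ids))
      return(data.frame(gene_id = character(0), tissue = character(0),
                        n_isoforms = integer(0), stringsAsFactors = FALSE))
    tab <- table(ann$transcripts[ids, "gene_id"])
    data.frame(gene_id = names(tab), tissue = t,
               n_isoforms = as.integer(tab), stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, per_tissue)
  counts <- counts[order(counts$tissue, counts$gene_id), , drop = FALSE]
  rownames(counts) <- NULL
  means <- vapply(stats::setNames(tissues, tissues), function(t) {
    n <- counts$n_isoforms[counts$tissue == t]
    if (!length(n)) NA_real_ else mean(n)
  }, numeric(1))
  buckets <- c("1", "2", "3", "4+")
  histogram <- t(vapply(tissues, function(t) {
    n <- counts$n_isoforms[counts$tissue == t]
    c(sum(n == 1L), sum(n == 2L), sum(n == 3L), sum(n >= 4L))
  }, integer(4)))
  dimnames(histogram) <- list(tissues, buckets)
  structure(list(counts = counts, means = means, histogram = histogram),
            class = "isoform_table")
}

#' @export
print.isoform_table <- function(x, ...) {
  cat("isoform_table over", length(x$means), "tissue(s); mean isoforms per",
      "expressed gene:\n")
  print(round(x$means, 3))
  invisible(x)
}

#' Genes with at least k expressed isoforms in every tissue
#'
#' The intersection across tissues of the genes with `n_isoforms >= k`
#' (a gene missing from a tissue counts 0 there and is excluded), plus each
#' tissue's maximal-isoform-count genes, ordered by count descending then
#' gene id ascending.
#'
#' @param table an [isoform_counts()] result.
#' @param k minimum expressed-isoform count (default 4).
#' @return List with `genes` (sorted character vector of qualifying genes)
#'   and `per_tissue_max` (data.frame: `tissue`, `gene_id`, `n_isoforms`,
#'   the top-count gene(s) of each tissue).
#' @export
high_isoform_genes <- function(table, k = 4) {
  stopifnot(inherits(table, "isoform_table"), k >= 1)
  tissues <- names(table$means)
  cnt <- table$counts
  wide <- matrix(0L, nrow = length(unique(cnt$gene_id)), ncol = length(tissues),
                 dimnames = list(sort(unique(cnt$gene_id)), tissues))
  wide[cbind(cnt$gene_id, cnt$tissue)] <- cnt$n_isoforms
  genes <- rownames(wide)[rowSums(wide >= k) == length(tissues)]
  per_tissue_max <- do.call(rbind, lapply(tissues, function(t) {
    sub <- cnt[cnt$tissue == t, , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(tissue = character(0), gene_id = character(0),
                        n_isoforms = integer(0), stringsAsFactors = FALSE))
    top <- sub[sub$n_isoforms == max(sub$n_isoforms), , drop = FALSE]
    top <- top[order(-top$n_isoforms, top$gene_id), , drop = FALSE]
    data.frame(tissue = t, gene_id = top$gene_id,
               n_isoforms = top$n_isoforms, stringsAsFactors = FALSE)
  }))
  rownames(per_tissue_max) <- NULL
  list(genes = sort(genes), per_tissue_max = per_tissue_max)
}
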