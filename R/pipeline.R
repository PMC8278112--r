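#' Characterize an expression atlas end to end
#'
#' Runs the full characterization: replicate-averaged transcript profiles and
#' expression calls at the TPM threshold, gene-level calls (from a gene-level
#' TPM matrix when supplied, else by projecting transcript calls through the
#' annotation), detection summary and biotype census, tissue-unique feature
#' sets, antisense-overlap and head-to-head pair detection with per-tissue
#' co-/mono-expression status, isoform-per-gene statistics, and
#' tissue-specificity rankings (on replicate-averaged median-of-ratios
#' normalized counts when a count matrix is supplied, else on TPM profiles).
#'
#' @param ann an [annotation_set()] (or a GTF path, parsed on the fly).
#' @param tpm transcript-level [expression_matrix()] in TPM.
#' @param counts optional gene-level [expression_matrix()] in counts, used
#'   for normalization-based specificity and sample similarity.
#' @param gene_tpm optional gene-level TPM [expression_matrix()]; takes
#'   precedence for gene-level calls.
#' @param threshold expression call threshold (default 0.5 TPM).
#' @param h2h_distance maximum head-to-head TSS distance (default 1000 bp).
#' @param top_genes,top_isoforms sizes of the specificity rankings
#'   (defaults 2000 and 500).
#' @return List of class `atlas_characterization` with elements
#'   `tx_profile`, `tx_calls`, `gene_calls`, `detection`, `census`,
#'   `unique_pc`, `unique_lnc`, `antisense`, `h2h`, `pair_status`,
#'   `isoforms`, `gene_specificity`, `isoform_specificity`, `similarity`,
#'   `threshold`.
#' @export
characterize_atlas <- function(ann, tpm, counts = NULL, gene_tpm = NULL,
                               threshold = 0.5, h2h_distance = 1000,
                               top_genes = 2000, top_isoforms = 500) {
  if (is.character(ann)) ann <- parse_gtf(ann)
  stopifnot(inherits(ann, "atlas_annotation"), inherits(tpm, "expr_matrix"))

  tx_profile <- average_replicates(tpm)
  tx_calls <- call_expressed(tx_profile, threshold)
  gene_calls <- if (!is.null(gene_tpm)) {
    call_expressed(average_replicates(gene_tpm), threshold)
  } else {
    gene_calls_from_tx(tx_calls, ann)
  }

  detection <- detection_summary(gene_calls, tx_calls, ann)
  census <- biotype_census(tx_calls, ann)
  unique_pc <- unique_expression(gene_calls, ann, biotype = "protein_coding")
  unique_lnc <- unique_expression(gene_calls, ann, biotype = "lncRNA")

  antisense <- find_antisense_pairs(ann)
  h2h <- find_h2h_pairs(ann, max_distance = h2h_distance)
  pair_status <- pair_expression_status(rbind_pairs(antisense, h2h), gene_calls)

  isoforms <- isoform_counts(tx_calls, ann)

  spec_profile <- if (!is.null(counts)) {
    average_replicates(normalize_counts(counts))
  } else {
    gene_profile_from_tx(tx_profile, ann)
  }
  gene_specificity <- suppressWarnings(
    rank_gene_specificity(spec_profile, top_n = top_genes))
  isoform_specificity <- suppressWarnings(
    rank_isoform_specificity(tx_profile, gene_calls, ann,
                             top_n = top_isoforms, threshold = threshold))
  similarity <- if (!is.null(counts)) sample_similarity(counts)
                else sample_similarity(tpm)

  structure(list(
    tx_profile = tx_profile, tx_calls = tx_calls, gene_calls = gene_calls,
    detection = detection, census = census,
    unique_pc = unique_pc, unique_lnc = unique_lnc,
    antisense = antisense, h2h = h2h, pair_status = pair_status,
    isoforms = isoforms, gene_specificity = gene_specificity,
    isoform_specificity = isoform_specificity, similarity = similarity,
    threshold = threshold
  ), class = "atlas_characterization")
}

# row-bind antisense and h2h pair tables onto a common column set
rbind_pairs <- function(antisense, h2h) {
  cols <- c("gene_a", "gene_b", "relation", "chrom", "biotype_category")
  out <- rbind(antisense[, cols, drop = FALSE], h2h[, cols, drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("gene_pairs", "data.frame")
  out
}

# sum transcript-level profiles into gene-level profiles
gene_profile_from_tx <- function(tx_profile, ann) {
  g <- ann$transcripts[rownames(tx_profile), "gene_id"]
  if (anyNA(g)) stop("profile transcripts absent from annotation")
  rowsum(tx_profile, group = g)
}

#' @export
print.atlas_characterization <- function(x, ...) {
  ov <- x$detection$overall
  cat("atlas_characterization over", nrow(x$detection$per_tissue),
      "tissues at TPM threshold", x$threshold, "\n")
  cat(sprintf("  detected genes: %d / %d (%.1f%%)\n",
              ov$detected[1], ov$annotated[1], ov$percent[1]))
  cat(sprintf("  detected transcripts: %d / %d (%.1f%%)\n",
              ov$detected[2], ov$annotated[2], ov$percent[2]))
  cat("  antisense-overlap pairs:", nrow(x$antisense),
      "| head-to-head pairs:", nrow(x$h2h), "\n")
  cat("  mean isoforms per expressed gene:",
      paste(range(round(x$isoforms$means, 2)), collapse = " - "), "\n")
  invisible(x)
}

#' Write characterization tables to a directory
#'
#' Emits the summary TSVs: detection (per tissue + overall), biotype census
#' counts and percentages, tissue-unique gene lists, pair tables (TSV and
#' BED-like), isoform counts/histogram/high-isoform genes, and the
#' specificity rankings.
#'
#' @param x an [characterize_atlas()] result.
#' @param ann the [annotation_set()] used.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_characterization <- function(x, ann, dir) {
  stopifnot(inherits(x, "atlas_characterization"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, ...) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, ...)
    p
  }
  paths <- c(
    w(x$detection$per_tissue, "detection_per_tissue.tsv"),
    w(x$detection$overall, "detection_overall.tsv"),
    w(data.frame(tissue = rownames(x$census$counts), x$census$counts,
                 check.names = FALSE), "census_counts.tsv"),
    w(data.frame(tissue = rownames(x$census$percentages), x$census$percentages,
                 check.names = FALSE), "census_percentages.tsv"),
    w(stack_unique(x$unique_pc), "unique_protein_coding.tsv"),
    w(stack_unique(x$unique_lnc), "unique_lncRNA.tsv"),
    w(x$antisense, "antisense_pairs.tsv"),
    w(x$h2h, "h2h_pairs.tsv"),
    w(x$pair_status$status, "pair_status.tsv"),
    w(x$isoforms$counts, "isoform_counts.tsv"),
    w(data.frame(tissue = rownames(x$isoforms$histogram),
                 x$isoforms$histogram, check.names = FALSE),
      "isoform_histogram.tsv"),
    w(x$gene_specificity$table, "gene_specificity.tsv"),
    w(x$isoform_specificity$table, "isoform_specificity.tsv"),
    w(data.frame(feature_id = rownames(x$gene_specificity$matrix),
                 x$gene_specificity$matrix, check.names = FALSE),
      "gene_specificity_heatmap.tsv")
  )
  bedp <- file.path(dir, "antisense_pairs.bed")
  write_pairs_bed(x$antisense, ann, bedp)
  bedh <- file.path(dir, "h2h_pairs.bed")
  write_pairs_bed(x$h2h, ann, bedh)
  invisible(c(paths, bedp, bedh))
}

stack_unique <- function(u) {
  data.frame(
    tissue = rep(names(u), lengths(u)),
    feature_id = unlist(u, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
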