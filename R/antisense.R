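#' Classify an opposite-strand gene pair by member biotypes
#'
#' Both protein_coding -> `"PC-PC"`; one protein_coding and one lncRNA ->
#' `"PC-lncRNA"`; both lncRNA -> `"lncRNA-lncRNA"`; any other combination
#' (miRNA, pseudogene, snoRNA, ..., including mixed with protein_coding or
#' lncRNA) -> `"other"`. Order-insensitive. Biotypes outside the recognized
#' vocabulary ([atlas_biotypes]) are an error.
#'
#' @param biotype_a,biotype_b character vectors of member biotypes
#'   (vectorized pairwise).
#' @return Character vector of categories.
#' @export
classify_pair_biotype <- function(biotype_a, biotype_b) {
  bad <- setdiff(c(biotype_a, biotype_b), atlas_biotypes)
  if (length(bad))
    stop("unknown biotype(s): ", paste(unique(bad), collapse = ", "))
  pc_a <- biotype_a == "protein_coding"; pc_b <- biotype_b == "protein_coding"
  ln_a <- biotype_a == "lncRNA";         ln_b <- biotype_b == "lncRNA"
  ifelse(pc_a & pc_b, "PC-PC",
    ifelse((pc_a & ln_b) | (ln_a & pc_b), "PC-lncRNA",
      ifelse(ln_a & ln_b, "lncRNA-lncRNA", "other")))
}

# assemble the canonical gene_pairs data.frame: unordered pairs stored with
# gene_a < gene_b, deduplicated, deterministically sorted
make_gene_pairs <- function(id1, id2, relation, value, ann) {
  swap <- id1 > id2
  a <- ifelse(swap, id2, id1)
  b <- ifelse(swap, id1, id2)
  key <- paste(a, b)
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]; value <- value[!dup]
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]; value <- value[ord]
  df <- data.frame(gene_a = a, gene_b = b,
                   relation = rep(relation, length(a)),
                   stringsAsFactors = FALSE, row.names = NULL)
  if (relation == "antisense_overlap") df$overlap_bp <- as.integer(value)
  else df$tss_distance_bp <- as.integer(value)
  df$chrom <- ann$genes[df$gene_a, "chrom"]
  df$biotype_category <- classify_pair_biotype(ann$genes[df$gene_a, "biotype"],
                                               ann$genes[df$gene_b, "biotype"])
  class(df) <- c("gene_pairs", "data.frame")
  df
}

#' Find overlapping antisense gene pairs
#'
#' Emits every unordered pair of genes on the same chromosome and opposite
#' strands whose spans overlap by at least one base pair (1-based inclusive
#' arithmetic: overlap iff min(end) >= max(start); overlap length =
#' min(end) - max(start) + 1). A gene overlapping several opposite-strand
#' partners yields one pair per partner. The result is deterministic and
#' sorted by (gene_a, gene_b).
#'
#' @param ann an [annotation_set()].
#' @return A `gene_pairs` data.frame with columns `gene_a`, `gene_b`
#'   (lexicographically ordered), `relation` (`"antisense_overlap"`),
#'   `overlap_bp`, `chrom`, `biotype_category`.
#' @export
find_antisense_pairs <- function(ann) {
  stopifnot(inherits(ann, "atlas_annotation"))
  g <- ann$genes
  empty <- make_gene_pairs(character(0), character(0), "antisense_overlap",
                           integer(0), ann)
  if (nrow(g) < 2) return(empty)
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  opp <- g$strand[i] != g$strand[j]
  i <- i[opp]; j <- j[opp]
  if (!length(i)) return(empty)
  ov <- pmin(g$end[i], g$end[j]) - pmax(g$start[i], g$start[j]) + 1L
  make_gene_pairs(g$gene_id[i], g$gene_id[j], "antisense_overlap", ov, ann)
}

#' Find head-to-head (TSS-proximal) gene pairs
#'
#' Emits every unordered pair of genes on the same chromosome and opposite
#' strands whose transcription start sites lie within `max_distance` bp of
#' each other (inclusive: a distance of exactly `max_distance` qualifies).
#' No divergent-orientation requirement is imposed; the orientation
#' (`"divergent"` when the two genes transcribe away from each other, i.e.
#' the +-strand TSS is not left of the --strand TSS, else `"convergent"`) is
#' recorded as a column for downstream filtering. The same unordered pair
#' may also be an antisense-overlap pair; the two relations are kept
#' separately.
#'
#' @param ann an [annotation_set()].
#' @param max_distance maximum TSS-to-TSS distance in bp (default 1000).
#' @return A `gene_pairs` data.frame with columns `gene_a`, `gene_b`,
#'   `relation` (`"head_to_head"`), `tss_distance_bp`, `chrom`,
#'   `biotype_category`, `orientation`.
#' @export
find_h2h_pairs <- function(ann, max_distance = 1000) {
  stopifnot(inherits(ann, "atlas_annotation"), max_distance >= 0)
  g <- ann$genes
  g$tss <- tss_of(g)
  # sorted sweep per chromosome: candidates are TSSs within the window
  ia <- integer(0); ib <- integer(0)
  ord <- order(g$chrom, g$tss)
  gs <- g[ord, , drop = FALSE]
  n <- nrow(gs)
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && gs$chrom[j] == gs$chrom[i] &&
             gs$tss[j] - gs$tss[i] <= max_distance) {
        if (gs$strand[j] != gs$strand[i]) {
          ia <- c(ia, i); ib <- c(ib, j)
        }
        j <- j + 1L
      }
    }
  }
  d <- abs(gs$tss[ib] - gs$tss[ia])
  pairs <- make_gene_pairs(gs$gene_id[ia], gs$gene_id[ib], "head_to_head",
                           d, ann)
  tss <- stats::setNames(g$tss, g$gene_id)
  strand <- stats::setNames(g$strand, g$gene_id)
  plus <- ifelse(strand[pairs$gene_a] == "+", pairs$gene_a, pairs$gene_b)
  minus <- ifelse(strand[pairs$gene_a] == "-", pairs$gene_a, pairs$gene_b)
  pairs$orientation <- ifelse(tss[plus] >= tss[minus], "divergent", "convergent")
  rownames(pairs) <- NULL
  pairs
}

#' Per-tissue co-expression / mono-expression status of gene pairs
#'
#' For each (pair, tissue): `co_expressed` when both members are expressed,
#' `mono_expressed` when exactly one is, `silent` otherwise — a partition, so
#' per tissue co + mono + silent = number of pairs. Also tallies statuses per
#' tissue stratified by relation and biotype category, and extracts pairs
#' unique to a single tissue for each status (a pair is unique to tissue t
#' for a status iff it holds that status in exactly one tissue, namely t).
#' A gene absent from the call set's universe counts as not expressed.
#'
#' @param pairs a `gene_pairs` data.frame (antisense, H2H, or both row-bound).
#' @param calls gene-level `call_set`.
#' @return List with `status` (long data.frame: pair columns + `tissue`,
#'   `status`), `counts` (per tissue x relation x biotype_category tallies of
#'   co/mono/silent), `unique_co` and `unique_mono` (data.frames of pairs
#'   holding the status in exactly one tissue).
#' @export
pair_expression_status <- function(pairs, calls) {
  stopifnot(inherits(pairs, "data.frame"), inherits(calls, "call_set"))
  tissues <- names(calls$expressed)
  n <- nrow(pairs)
  status_mat <- matrix("silent", nrow = n, ncol = length(tissues),
                       dimnames = list(NULL, tissues))
  for (t in tissues) {
    ex <- calls$expressed[[t]]
    ea <- pairs$gene_a %in% ex
    eb <- pairs$gene_b %in% ex
    status_mat[, t] <- ifelse(ea & eb, "co_expressed",
                              ifelse(ea | eb, "mono_expressed", "silent"))
  }
  base_cols <- c("gene_a", "gene_b", "relation", "biotype_category")
  long <- do.call(rbind, lapply(tissues, function(t) {
    cbind(pairs[, base_cols, drop = FALSE],
          data.frame(tissue = rep(t, n), status = status_mat[, t],
                     stringsAsFactors = FALSE))
  }))
  rownames(long) <- NULL
  counts <- as.data.frame(
    table(tissue = long$tissue, relation = long$relation,
          biotype_category = long$biotype_category, status = long$status),
    stringsAsFactors = FALSE, responseName = "n"
  )
  uniq <- function(s) {
    hit <- status_mat == s
    one <- rowSums(hit) == 1L
    if (!any(one)) {
      out <- pairs[integer(0), base_cols, drop = FALSE]
      out$tissue <- character(0)
      return(out)
    }
    out <- pairs[one, base_cols, drop = FALSE]
    out$tissue <- tissues[apply(hit[one, , drop = FALSE], 1, which)]
    rownames(out) <- NULL
    out
  }
  list(status = long, counts = counts,
       unique_co = uniq("co_expressed"), unique_mono = uniq("mono_expressed"))
}

#' Write gene pairs as a BED-like file
#'
#' Six columns — chrom, start-1, end, pair id, overlap or TSS distance, "." —
#' using 0-based half-open coordinates on output only (internally everything
#' is 1-based inclusive). The interval written is the union span of the two
#' member genes.
#'
#' @param pairs a `gene_pairs` data.frame.
#' @param ann the [annotation_set()] the pairs came from.
#' @param path output file path.
#' @return Invisibly, the written data.frame.
#' @export
write_pairs_bed <- function(pairs, ann, path) {
  g <- ann$genes
  val <- if ("overlap_bp" %in% names(pairs)) pairs$overlap_bp else pairs$tss_distance_bp
  bed <- data.frame(
    chrom = pairs$chrom,
    start = pmin(g[pairs$gene_a, "start"], g[pairs$gene_b, "start"]) - 1L,
    end = pmax(g[pairs$gene_a, "end"], g[pairs$gene_b, "end"]),
    name = paste(pairs$gene_a, pairs$gene_b, pairs$relation, sep = "|"),
    score = val,
    strand = ".",
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
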