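#' Round half away from zero
#'
#' Decimal rounding with halves going away from zero (so 73.35 -> 73.4,
#' -0.05 -> -0.1), unlike [round()]'s round-half-to-even. All printed
#' percentages in this package use this rule.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Detection percentage
#'
#' `100 * detected / annotated`, rounded half-away-from-zero to one decimal.
#' This is the arithmetic behind all detected-vs-annotated percentages, e.g.
#' 17,872 of 24,356 annotated genes -> 73.4.
#'
#' @param detected,annotated non-negative integers (vectorized).
#' @param digits decimal places (default 1).
#' @return Numeric percentage(s).
#' @export
detection_percentage <- function(detected, annotated, digits = 1) {
  stopifnot(all(annotated > 0), all(detected >= 0))
  round_half_up(100 * detected / annotated, digits)
}

#' Per-tissue transcript biotype census
#'
#' Counts detected transcripts per biotype for each tissue, with percentages
#' over that tissue's detected total and a low-abundance breakout (every
#' biotype except protein_coding and lncRNA).
#'
#' @param calls a transcript-level [call_expressed()] `call_set`.
#' @param ann an [annotation_set()] covering all called transcripts.
#' @return List with matrices `counts` (tissue x biotype), `percentages`
#'   (one decimal, same shape), `low_abundance` (counts without
#'   protein_coding/lncRNA columns) and vector `totals` (detected transcripts
#'   per tissue).
#' @export
biotype_census <- function(calls, ann) {
  stopifnot(inherits(calls, "call_set"), inherits(ann, "atlas_annotation"))
  called <- unique(unlist(calls$expressed, use.names = FALSE))
  absent <- setdiff(called, ann$transcripts$transcript_id)
  if (length(absent))
    stop("called transcripts absent from annotation: ",
         paste(head(absent, 10), collapse = ", "))
  lev <- union(atlas_biotypes, sort(unique(ann$transcripts$biotype)))
  counts <- t(vapply(calls$expressed, function(ids) {
    as.integer(table(factor(ann$transcripts[ids, "biotype"], levels = lev)))
  }, integer(length(lev))))
  colnames(counts) <- lev
  totals <- rowSums(counts)
  pct <- counts
  pct[] <- 0
  nz <- totals > 0
  pct[nz, ] <- round_half_up(100 * counts[nz, , drop = FALSE] / totals[nz], 1)
  list(counts = counts, percentages = pct,
       low_abundance = counts[, setdiff(lev, c("protein_coding", "lncRNA")),
                              drop = FALSE],
       totals = totals)
}

#' Features expressed in exactly one tissue
#'
#' A feature is unique to tissue t iff it is expressed in t and in no other
#' tissue. Optionally restricted to one biotype (looked up in the annotation
#' at transcript level first, then gene level).
#'
#' @param calls a [call_expressed()] `call_set` (gene or transcript level).
#' @param ann an [annotation_set()]; required when `biotype` is given.
#' @param biotype optional biotype to restrict to, e.g. `"protein_coding"`.
#' @return Named list, tissue -> character vector of unique feature ids.
#' @export
unique_expression <- function(calls, ann = NULL, biotype = NULL) {
  stopifnot(inherits(calls, "call_set"))
  if (length(calls$expressed) < 2)
    stop("unique_expression() needs at least 2 tissues")
  feats <- sort(unique(unlist(calls$expressed, use.names = FALSE)))
  if (!is.null(biotype)) {
    if (is.null(ann)) stop("biotype filtering requires the annotation")
    bt <- ann$transcripts[feats, "biotype"]
    bt[is.na(bt)] <- ann$genes[feats[is.na(bt)], "biotype"]
    if (anyNA(bt))
      stop("features absent from annotation: ",
           paste(head(feats[is.na(bt)], 10), collapse = ", "))
    feats <- feats[bt == biotype]
  }
  memb <- vapply(calls$expressed, function(s) feats %in% s,
                 logical(length(feats)))
  memb <- matrix(memb, nrow = length(feats),
                 dimnames = list(feats, names(calls$expressed)))
  n_tis <- rowSums(memb)
  lapply(stats::setNames(colnames(memb), colnames(memb)),
         function(t) feats[memb[, t] & n_tis == 1L])
}

#' Detection summary against the annotation
#'
#' Overall detected-vs-annotated counts and percentages (union over tissues)
#' at gene and transcript level, plus the per-tissue gene / transcript /
#' lncRNA-gene counts.
#'
#' @param gene_calls gene-level `call_set`.
#' @param tx_calls transcript-level `call_set` over the same tissues.
#' @param ann an [annotation_set()].
#' @return List with data.frames `overall` (`level`, `detected`, `annotated`,
#'   `percent`) and `per_tissue` (`tissue`, `genes`, `transcripts`, `lncRNA`).
#' @export
detection_summary <- function(gene_calls, tx_calls, ann) {
  stopifnot(inherits(gene_calls, "call_set"), inherits(tx_calls, "call_set"),
            inherits(ann, "atlas_annotation"))
  tissues <- names(gene_calls$expressed)
  if (!setequal(tissues, names(tx_calls$expressed)))
    stop("gene and transcript call sets cover different tissues")
  det_g <- unique(unlist(gene_calls$expressed, use.names = FALSE))
  det_t <- unique(unlist(tx_calls$expressed, use.names = FALSE))
  ann_g <- nrow(ann$genes)
  ann_t <- nrow(ann$transcripts)
  overall <- data.frame(
    level = c("gene", "transcript"),
    detected = c(length(det_g), length(det_t)),
    annotated = c(ann_g, ann_t),
    stringsAsFactors = FALSE
  )
  overall$percent <- detection_percentage(overall$detected, overall$annotated)
  lnc <- ann$genes$gene_id[ann$genes$biotype == "lncRNA"]
  per_tissue <- data.frame(
    tissue = tissues,
    genes = unname(lengths(gene_calls$expressed)[tissues]),
    transcripts = unname(lengths(tx_calls$expressed)[tissues]),
    lncRNA = vapply(tissues, function(t)
      sum(gene_calls$expressed[[t]] %in% lnc), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(overall = overall, per_tissue = per_tissue)
}

#' Derive gene-level calls from transcript-level calls
#'
#' A gene is expressed in a tissue iff at least one of its transcripts is.
#'
#' @param tx_calls transcript-level `call_set`.
#' @param ann an [annotation_set()] resolving transcripts to genes.
#' @return Gene-level `call_set` at the same threshold.
#' @export
gene_calls_from_tx <- function(tx_calls, ann) {
  stopifnot(inherits(tx_calls, "call_set"), inherits(ann, "atlas_annotation"))
  absent <- setdiff(unlist(tx_calls$expressed, use.names = FALSE),
                    ann$transcripts$transcript_id)
  if (length(absent))
    stop("called transcripts absent from annotation: ",
         paste(head(absent, 10), collapse = ", "))
  expressed <- lapply(tx_calls$expressed, function(ids)
    sort(unique(ann$transcripts[ids, "gene_id"])))
  structure(list(expressed = expressed, threshold = tx_calls$threshold,
                 features = sort(unique(ann$genes$gene_id))),
            class = "call_set")
}
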