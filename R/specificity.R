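#' Shannon entropy of an expression distribution, in bits
#'
#' The vector is normalized to a probability distribution p over tissues and
#' H = -sum(p_i * log2(p_i)) is returned, with 0*log(0) taken as 0. Entropy
#' is 0 for a point mass (one expressing tissue) and log2(T) for perfectly
#' uniform expression over T tissues; it is invariant to positive rescaling
#' and to permutation of tissues.
#'
#' @param x non-negative numeric vector of expression values over tissues.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop("x must be a non-negative numeric vector")
  s <- sum(x)
  if (s <= 0) stop("all-zero expression vector: entropy undefined; pre-filter")
  p <- x[x > 0] / s
  -sum(p * log2(p)) + 0  # + 0 canonicalizes IEEE -0 at the point mass
}

# entropy per row of a features x tissues matrix; rows must have positive sums
row_entropies <- function(profile) {
  s <- rowSums(profile)
  stopifnot(all(s > 0))
  p <- profile / s
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

# shared ranking core: entropy, specificity score, deterministic ranks
specificity_table <- function(profile, direction = c("most_specific", "least_specific")) {
  direction <- match.arg(direction)
  n_tis <- ncol(profile)
  stopifnot(n_tis >= 2)
  keep <- rowSums(profile) > 0
  profile <- profile[keep, , drop = FALSE]
  h <- row_entropies(profile)
  score <- log2(n_tis) - h
  key <- if (direction == "most_specific") -score else score
  ord <- order(key, rownames(profile))
  data.frame(
    feature_id = rownames(profile)[ord],
    entropy = unname(h[ord]),
    score = unname(score[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Rank genes by tissue specificity
#'
#' Scores every gene with positive total expression by the specificity score
#' log2(T) - H, where H is the Shannon entropy of its cross-tissue profile
#' and T the tissue count. The most specific gene (expressed in a single
#' tissue) scores log2(T); a perfectly uniform gene scores 0. Ties are broken
#' lexicographically by feature id so output is deterministic. The intended
#' input is a replicate-averaged profile of size-factor-normalized counts
#' (TPM profiles are accepted as an alternative).
#'
#' @param profile features x tissues matrix (see [average_replicates()]).
#' @param top_n number of features for the exported heatmap matrix
#'   (default 2000). If larger than the number of scorable features, all are
#'   returned with a warning.
#' @param direction `"most_specific"` (default) ranks the highest scores
#'   first; `"least_specific"` ranks uniform features first.
#' @return List with `table` (data.frame: `feature_id`, `entropy`, `score`,
#'   `rank`) and `matrix` (expression of the `top_n` first-ranked features,
#'   heatmap-ready).
#' @export
rank_gene_specificity <- function(profile, top_n = 2000,
                                  direction = c("most_specific", "least_specific")) {
  tab <- specificity_table(profile, direction)
  if (top_n > nrow(tab)) {
    warning("top_n = ", top_n, " exceeds the ", nrow(tab),
            " scorable features; returning all")
    top_n <- nrow(tab)
  }
  top <- tab$feature_id[seq_len(top_n)]
  list(table = tab, matrix = profile[top, , drop = FALSE])
}

#' Rank isoforms by tissue specificity
#'
#' Isoform-level specificity with two filters applied before scoring: the
#' isoform's parent gene must be expressed in at least `min_gene_tissues`
#' tissues (so single-tissue genes do not trivially dominate the isoform
#' ranking), and the isoform itself must pass the expression call in at
#' least one tissue. Scoring and tie-breaking are as in
#' [rank_gene_specificity()].
#'
#' @param tx_profile transcripts x tissues matrix.
#' @param gene_calls gene-level `call_set` over the same tissues.
#' @param ann an [annotation_set()] resolving transcripts to genes.
#' @param top_n heatmap matrix size (default 500).
#' @param threshold isoform-level expression threshold (default 0.5, matching
#'   the call threshold).
#' @param min_gene_tissues minimum number of tissues the parent gene must be
#'   expressed in (default 2).
#' @param direction as in [rank_gene_specificity()].
#' @return List with `table` and `matrix` as in [rank_gene_specificity()].
#' @export
rank_isoform_specificity <- function(tx_profile, gene_calls, ann, top_n = 500,
                                     threshold = 0.5, min_gene_tissues = 2,
                                     direction = c("most_specific", "least_specific")) {
  stopifnot(inherits(gene_calls, "call_set"), inherits(ann, "atlas_annotation"))
  tx_ids <- rownames(tx_profile)
  parent <- ann$transcripts[tx_ids, "gene_id"]
  if (anyNA(parent))
    stop("transcripts with unresolvable gene: ",
         paste(head(tx_ids[is.na(parent)], 10), collapse = ", "))
  gene_n_tis <- table(unlist(lapply(gene_calls$expressed, unique),
                             use.names = FALSE))
  n_tis_of <- as.integer(gene_n_tis[parent])
  n_tis_of[is.na(n_tis_of)] <- 0L
  keep <- n_tis_of >= min_gene_tissues &
    rowSums(tx_profile > threshold) >= 1L
  if (!any(keep)) stop("no isoform passes the specificity filters")
  rank_gene_specificity(tx_profile[keep, , drop = FALSE], top_n, direction)
}
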