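#' Construct an expression matrix with sample grouping
#'
#' The core expression container: a non-negative numeric matrix (features in
#' rows, samples in columns), a sample-to-tissue grouping, and a units tag
#' distinguishing TPM, raw counts and size-factor-normalized counts.
#'
#' @param values numeric matrix, rownames = feature ids, colnames = sample ids.
#' @param grouping either a named character vector (names = sample ids,
#'   values = tissue labels) or a two-column data.frame (`sample_id`,
#'   `tissue`).
#' @param units one of `"TPM"`, `"counts"`, `"normalized"`.
#' @return An object of class `expr_matrix`: list with `values`, `grouping`
#'   (named character vector aligned to `colnames(values)`) and `units`.
#' @export
expression_matrix <- function(values, grouping, units = c("TPM", "counts", "normalized")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative expression value at (",
         rownames(values)[neg[1, 1]], ", ", colnames(values)[neg[1, 2]], ")")
  if (is.data.frame(grouping)) {
    if (!all(c("sample_id", "tissue") %in% names(grouping)))
      stop("grouping data.frame needs columns sample_id and tissue")
    grouping <- stats::setNames(as.character(grouping$tissue),
                                as.character(grouping$sample_id))
  }
  missing_s <- setdiff(colnames(values), names(grouping))
  if (length(missing_s))
    stop("samples missing from grouping: ", paste(missing_s, collapse = ", "))
  grouping <- grouping[colnames(values)]
  structure(list(values = values, grouping = grouping, units = units),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix [", x$units, "]: ", nrow(x$values), " features x ",
      ncol(x$values), " samples in ", length(unique(x$grouping)),
      " tissue group(s)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' The TSV must have a header row of sample ids and feature ids in the first
#' column. The grouping may be given as a data.frame or as a path to a
#' two-column TSV (`sample_id`, `tissue`).
#'
#' @param path path to the matrix TSV.
#' @param grouping sample-to-tissue grouping (data.frame, named vector, or
#'   TSV path).
#' @param units `"TPM"` or `"counts"`.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, grouping, units = c("TPM", "counts")) {
  units <- match.arg(units)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix TSV needs a feature column plus sample columns")
  feats <- as.character(df[[1]])
  if (anyDuplicated(feats))
    stop("duplicate feature ids: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- feats
  if (is.character(grouping) && length(grouping) == 1 && file.exists(grouping))
    grouping <- read.delim(grouping, stringsAsFactors = FALSE)
  expression_matrix(values, grouping, units)
}

#' Average replicate columns into per-tissue profiles
#'
#' Arithmetic mean of each tissue's replicate columns; a single-replicate
#' tissue passes through unchanged. Raw counts are refused: normalize with
#' [normalize_counts()] first so tissue profiles are comparable.
#'
#' @param m an [expression_matrix()] in TPM or normalized units.
#' @return Numeric matrix, features x tissues (tissue columns sorted), with
#'   a `units` attribute.
#' @export
average_replicates <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$units == "counts")
    stop("average_replicates() expects TPM or normalized values; ",
         "apply normalize_counts() to raw counts first")
  tissues <- sort(unique(unname(m$grouping)))
  prof <- vapply(tissues, function(t) {
    cols <- names(m$grouping)[m$grouping == t]
    if (!length(cols)) stop("empty tissue group: ", t)
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  prof <- matrix(prof, nrow = nrow(m$values),
                 dimnames = list(rownames(m$values), tissues))
  attr(prof, "units") <- m$units
  prof
}

#' Call expressed features per tissue at a TPM threshold
#'
#' A feature is called expressed in a tissue iff its replicate-averaged value
#' is strictly greater than the threshold; a value of exactly 0.5 at the
#' default threshold is not expressed.
#'
#' @param profile features x tissues matrix from [average_replicates()].
#' @param threshold expression threshold (default 0.5 TPM).
#' @return An object of class `call_set`: list with `expressed` (named list,
#'   tissue -> character vector of feature ids), `threshold` and `features`.
#' @export
call_expressed <- function(profile, threshold = 0.5) {
  stopifnot(is.matrix(profile), is.numeric(threshold), threshold >= 0)
  tissues <- colnames(profile)
  expressed <- lapply(stats::setNames(tissues, tissues), function(t) {
    rownames(profile)[profile[, t] > threshold]
  })
  structure(list(expressed = expressed, threshold = threshold,
                 features = rownames(profile)),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat("call_set at threshold", x$threshold, "over", length(x$features),
      "features:\n")
  print(lengths(x$expressed))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' The size factor of sample j is the median, over features with all-positive
#' counts, of the ratio of that feature's count in j to its geometric mean
#' across samples. Features with a zero count in any sample are excluded
#' (their geometric mean is zero). The factors are then scaled to unit
#' geometric mean, which fixes their arbitrary overall scale and makes
#' normalization idempotent: the factors of an already-normalized matrix are
#' exactly 1. Dividing each column by its factor makes samples comparable.
#'
#' @param counts an [expression_matrix()] in counts units, or a bare
#'   non-negative numeric matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  if (inherits(counts, "expr_matrix")) {
    if (counts$units != "counts")
      stop("size factors are defined for raw counts, not ", counts$units)
    counts <- counts$values
  }
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has all-positive counts; a pseudo-reference fallback ",
         "is not provided")
  ref <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(ref)))
  sf <- apply(ref / geo, 2, median)
  if (any(sf <= 0)) stop("non-positive size factor computed")
  sf / exp(mean(log(sf)))
}

#' Normalize a count matrix by median-of-ratios size factors
#'
#' @param m an [expression_matrix()] in counts units.
#' @return An [expression_matrix()] in `"normalized"` units, with the
#'   size factors attached as attribute `size_factors`.
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  sf <- size_factors_median_of_ratios(m)
  out <- expression_matrix(sweep(m$values, 2, sf, "/"), m$grouping, "normalized")
  attr(out, "size_factors") <- sf
  out
}

#' Sample-to-sample Euclidean distance and Pearson correlation
#'
#' Distances and correlations between per-sample feature vectors. Raw counts
#' are size-factor normalized first. A sample with a constant vector has an
#' undefined Pearson correlation; its rows and columns are set to `NA` and a
#' warning names the sample(s).
#'
#' @param m an [expression_matrix()].
#' @return List with symmetric matrices `distance` (zero diagonal) and
#'   `correlation` (unit diagonal where defined).
#' @export
sample_similarity <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 2) stop("sample_similarity() needs at least 2 samples")
  vals <- if (m$units == "counts") normalize_counts(m)$values else m$values
  d <- as.matrix(dist(t(vals)))
  const <- apply(vals, 2, sd) == 0
  rho <- suppressWarnings(cor(vals))
  if (any(const)) {
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
    warning("Pearson correlation undefined for constant sample(s): ",
            paste(colnames(vals)[const], collapse = ", "))
  }
  diag(rho)[!const] <- 1
  list(distance = d, correlation = rho)
}
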