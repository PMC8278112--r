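#' Transcript biotypes of the reference annotation
#'
#' The fifteen transcript biotypes present in the Ensembl chicken (GRCg6a,
#' release 98) annotation that this package's census and pair classification
#' operate over. Annotations may carry additional biotype strings; these are
#' tolerated at parse time but rejected by the strict-vocabulary operations
#' (see [classify_pair_biotype()]).
#'
#' @format A character vector of length 15.
#' @export
atlas_biotypes <- c(
  "protein_coding", "lncRNA", "miRNA", "pseudogene", "misc_RNA",
  "snoRNA", "snRNA", "scaRNA", "rRNA", "processed_pseudogene",
  "IG_V_gene", "Mt_rRNA", "Mt_tRNA", "ribozyme", "sRNA"
)

#' Assemble an annotation set from gene and transcript tables
#'
#' Builds the validated in-memory annotation container used throughout the
#' package. Coordinates are GTF-native: 1-based, inclusive at both ends.
#' All invariants of the annotation model are enforced here: every
#' transcript's `gene_id` resolves, members of a gene share chromosome and
#' strand, the gene span covers every member transcript, and every gene has
#' at least one transcript.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`), `biotype`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `biotype`.
#' @return An object of class `atlas_annotation`: a list with elements
#'   `genes`, `transcripts` (both sorted by id, rownames = ids) and
#'   `biotype_counts` (named integer vector over transcript biotypes).
#' @export
annotation_set <- function(genes, transcripts) {
  req_g <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  req_t <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(req_g %in% names(genes)))
    stop("genes table must have columns: ", paste(req_g, collapse = ", "))
  if (!all(req_t %in% names(transcripts)))
    stop("transcripts table must have columns: ", paste(req_t, collapse = ", "))
  genes <- genes[order(genes$gene_id), req_g, drop = FALSE]
  transcripts <- transcripts[order(transcripts$transcript_id), req_t, drop = FALSE]
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript ids: ",
         paste(unique(transcripts$transcript_id[duplicated(transcripts$transcript_id)]),
               collapse = ", "))
  rownames(genes) <- genes$gene_id
  rownames(transcripts) <- transcripts$transcript_id

  if (!all(genes$strand %in% c("+", "-")) || !all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(genes$start > genes$end) || any(transcripts$start > transcripts$end))
    stop("start > end in annotation records")
  if (any(!nzchar(genes$biotype)) || any(!nzchar(transcripts$biotype)))
    stop("empty biotype in annotation records")

  orphan <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(orphan))
    stop("transcripts reference unknown gene ids: ", paste(orphan, collapse = ", "))
  bare <- setdiff(genes$gene_id, transcripts$gene_id)
  if (length(bare))
    stop("genes without any transcript: ", paste(bare, collapse = ", "))

  idx <- match(transcripts$gene_id, genes$gene_id)
  if (any(transcripts$chrom != genes$chrom[idx]))
    stop("transcript chromosome differs from its gene's chromosome")
  bad_strand <- transcripts$strand != genes$strand[idx]
  if (any(bad_strand))
    stop("gene(s) with transcripts on conflicting strands: ",
         paste(unique(transcripts$gene_id[bad_strand]), collapse = ", "))
  uncovered <- transcripts$start < genes$start[idx] | transcripts$end > genes$end[idx]
  if (any(uncovered))
    stop("gene span does not cover member transcript(s): ",
         paste(unique(transcripts$transcript_id[uncovered]), collapse = ", "))

  bt <- table(transcripts$biotype)
  structure(
    list(genes = genes, transcripts = transcripts,
         biotype_counts = stats::setNames(as.integer(bt), names(bt))),
    class = "atlas_annotation"
  )
}

#' @export
print.atlas_annotation <- function(x, ...) {
  cat("atlas_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  cat("transcript biotypes:\n")
  print(sort(x$biotype_counts, decreasing = TRUE))
  invisible(x)
}

# extract a single attribute value from GTF column-9 strings; NA where absent
gtf_attr <- function(attrs, key) {
  pat <- paste0('(?:^|;)\\s*', key, '\\s+"([^"]*)"')
  m <- regexpr(pat, attrs, perl = TRUE)
  out <- rep(NA_character_, length(attrs))
  hit <- m != -1L
  out[hit] <- sub(pat, "\\1", regmatches(attrs, m), perl = TRUE)
  out
}

#' Parse a GTF annotation file
#'
#' Reads `gene` and `transcript` feature lines from a 9-column GTF (other
#' feature types, including exons, are ignored). Transcript biotype is taken
#' from the `transcript_biotype` attribute, falling back to `gene_biotype`
#' (both Ensembl dialects are common); a transcript line with neither is a
#' parse error. Genes lacking an explicit `gene` line get the union span
#' (min start, max end) of their transcripts. Invalid strand characters,
#' reversed coordinates and missing `gene_id`/`transcript_id` attributes
#' raise errors naming the offending line number.
#'
#' @param path path to a GTF file.
#' @return An [annotation_set()] object.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  raw <- readLines(path)
  ln <- seq_along(raw)
  keep <- !grepl("^\\s*(#|$)", raw)
  raw <- raw[keep]; ln <- ln[keep]
  if (!length(raw)) stop("GTF file has no feature lines: ", path)

  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("line ", ln[which(nf != 9L)[1]], ": expected 9 tab-separated fields")
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  feat <- m[, 3]
  use <- feat %in% c("gene", "transcript")
  m <- m[use, , drop = FALSE]; ln <- ln[use]; feat <- feat[use]

  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("line ", ln[bad[1]], ": non-numeric coordinates")
  bad <- which(start > end)
  if (length(bad)) stop("line ", ln[bad[1]], ": start > end")
  strand <- m[, 7]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("line ", ln[bad[1]], ": invalid strand '", strand[bad[1]], "'")

  attrs <- m[, 9]
  gid <- gtf_attr(attrs, "gene_id")
  bad <- which(is.na(gid))
  if (length(bad)) stop("line ", ln[bad[1]], ": missing gene_id attribute")
  gene_bt <- gtf_attr(attrs, "gene_biotype")

  is_tx <- feat == "transcript"
  tid <- gtf_attr(attrs, "transcript_id")
  bad <- which(is_tx & is.na(tid))
  if (length(bad)) stop("line ", ln[bad[1]], ": missing transcript_id attribute")
  tx_bt <- gtf_attr(attrs, "transcript_biotype")
  bt <- ifelse(is.na(tx_bt), gene_bt, tx_bt)
  bad <- which(is_tx & is.na(bt))
  if (length(bad))
    stop("line ", ln[bad[1]],
         ": transcript has neither transcript_biotype nor gene_biotype attribute")

  transcripts <- data.frame(
    transcript_id = tid[is_tx], gene_id = gid[is_tx], chrom = m[is_tx, 1],
    start = start[is_tx], end = end[is_tx], strand = strand[is_tx],
    biotype = bt[is_tx], stringsAsFactors = FALSE
  )
  if (!nrow(transcripts)) stop("GTF contains no transcript lines: ", path)

  is_g <- feat == "gene"
  genes <- data.frame(
    gene_id = gid[is_g], chrom = m[is_g, 1], start = start[is_g],
    end = end[is_g], strand = strand[is_g],
    biotype = gene_bt[is_g], stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene feature lines for: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))

  # synthesize genes that have transcripts but no explicit gene line
  implied_ids <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(implied_ids)) {
    sub <- transcripts[transcripts$gene_id %in% implied_ids, , drop = FALSE]
    sub <- sub[order(sub$transcript_id), , drop = FALSE]
    sp <- split(sub, sub$gene_id)
    implied <- do.call(rbind, lapply(sp, function(d) {
      if (length(unique(d$strand)) > 1L)
        stop("gene ", d$gene_id[1], " has transcripts on conflicting strands")
      if (length(unique(d$chrom)) > 1L)
        stop("gene ", d$gene_id[1], " has transcripts on multiple chromosomes")
      data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                 start = min(d$start), end = max(d$end), strand = d$strand[1],
                 biotype = d$biotype[1], stringsAsFactors = FALSE)
    }))
    genes <- rbind(genes, implied)
  }
  # genes whose own line lacked gene_biotype inherit their first transcript's
  na_bt <- which(is.na(genes$biotype))
  if (length(na_bt)) {
    tx_sorted <- transcripts[order(transcripts$transcript_id), , drop = FALSE]
    genes$biotype[na_bt] <- tx_sorted$biotype[match(genes$gene_id[na_bt], tx_sorted$gene_id)]
  }
  annotation_set(genes, transcripts)
}

#' Transcription start site of gene records
#'
#' The TSS is the strand-dependent 5' end of the gene span: the span start
#' for `+`-strand genes and the span end for `-`-strand genes.
#'
#' @param gene a data.frame of gene records with columns `start`, `end`,
#'   `strand` (one row per gene), e.g. `ann$genes` or a subset of it.
#' @return Integer vector of TSS positions (bp), named by `gene_id` when the
#'   column is present.
#' @export
tss_of <- function(gene) {
  stopifnot(all(c("start", "end", "strand") %in% names(gene)))
  out <- ifelse(gene$strand == "+", gene$start, gene$end)
  out <- as.integer(out)
  if (!is.null(gene$gene_id)) names(out) <- gene$gene_id
  out
}
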