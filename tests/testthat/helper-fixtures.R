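# shared fixtures and independent oracles, all built in code

# write GTF lines to a temp file, return the path
tmp_gtf <- function(lines) {
  p <- tempfile(fileext = ".gtf")
  writeLines(lines, p)
  p
}

gtf_gene_line <- function(gid, start, end, strand, biotype = "protein_coding",
                          chrom = "chr1") {
  sprintf('%s\tsrc\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
          chrom, start, end, strand, gid, biotype)
}

gtf_tx_line <- function(gid, tid, start, end, strand,
                        biotype = "protein_coding", chrom = "chr1",
                        attr_key = "transcript_biotype") {
  sprintf('%s\tsrc\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; %s "%s";',
          chrom, start, end, strand, gid, tid, attr_key, biotype)
}

# hand-built annotation: genes with given coordinates, one transcript each
ann_from_genes <- function(genes) {
  tx <- genes
  tx$transcript_id <- paste0(genes$gene_id, ".t1")
  annotation_set(genes, tx[, c("transcript_id", "gene_id", "chrom", "start",
                               "end", "strand", "biotype")])
}

# random annotation with arbitrary overlaps for oracle stress tests
random_annotation <- function(n, seed) {
  set.seed(seed)
  chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
  start <- sample.int(30000L, n, replace = TRUE)
  len <- sample(50:3000, n, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("R%04d", seq_len(n)), chrom = chrom,
    start = start, end = start + len - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = sample(atlas_biotypes, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  ann_from_genes(genes)
}

# exhaustive all-pairs antisense-overlap scan (independent of the finders)
brute_antisense <- function(ann) {
  g <- ann$genes
  n <- nrow(g)
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    overlap_bp = integer(0), stringsAsFactors = FALSE)
  if (n >= 2) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- ij[, 1]; j <- ij[, 2]
    ov <- pmin(g$end[i], g$end[j]) - pmax(g$start[i], g$start[j]) + 1L
    keep <- g$chrom[i] == g$chrom[j] & g$strand[i] != g$strand[j] & ov >= 1L
    i <- i[keep]; j <- j[keep]; ov <- ov[keep]
    a <- pmin(g$gene_id[i], g$gene_id[j])
    b <- pmax(g$gene_id[i], g$gene_id[j])
    out <- data.frame(gene_a = a, gene_b = b, overlap_bp = as.integer(ov),
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# exhaustive all-pairs head-to-head scan
brute_h2h <- function(ann, max_distance = 1000) {
  g <- ann$genes
  g$tss <- tss_of(g)
  n <- nrow(g)
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    tss_distance_bp = integer(0), stringsAsFactors = FALSE)
  if (n >= 2) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- ij[, 1]; j <- ij[, 2]
    d <- abs(g$tss[i] - g$tss[j])
    keep <- g$chrom[i] == g$chrom[j] & g$strand[i] != g$strand[j] &
      d <= max_distance
    i <- i[keep]; j <- j[keep]; d <- d[keep]
    a <- pmin(g$gene_id[i], g$gene_id[j])
    b <- pmax(g$gene_id[i], g$gene_id[j])
    out <- data.frame(gene_a = a, gene_b = b, tss_distance_bp = as.integer(d),
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# small expression matrix from a plain numeric matrix
em <- function(values, tissues, units = "TPM") {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  expression_matrix(values, stats::setNames(tissues, colnames(values)), units)
}

# small simulation config used when full defaults would be overkill
small_cfg <- function(seed, ...) {
  generator_config(n_genes = 120, n_antisense_pairs = 5, n_h2h_pairs = 3,
                   n_specific_per_tissue = 1, n_tissues = 4, seed = seed, ...)
}
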