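#' Configuration for the synthetic atlas generator
#'
#' Defaults emulate the study design the package targets: 10 cell/tissue
#' types profiled in duplicate, a mixed-biotype annotation dominated by
#' protein-coding (0.69) and lncRNA (0.23) transcripts, mostly single-isoform
#' genes, planted overlapping-antisense and head-to-head gene pairs, and
#' tissue-specific genes at 100x fold-enrichment over a suppressed baseline,
#' with negative-binomial count noise.
#'
#' @param n_tissues number of tissue groups (default 10; at 10 the study's
#'   tissue names are used, otherwise `tissue01`, ...).
#' @param replicates_per_tissue biological replicates per tissue (default 2).
#' @param n_genes total genes (default 1000).
#' @param biotype_props named proportions over [atlas_biotypes] (must sum
#'   to 1). Default: protein_coding 0.69, lncRNA 0.23, remainder split
#'   evenly over the other 13 biotypes.
#' @param isoform_probs probabilities of 1/2/3/4+ isoforms per gene,
#'   default c(0.8, 0.15, 0.04, 0.01). The 4+ mass is realized by planting
#'   `round(p4 * n_genes)` high-isoform genes (4-6 isoforms each) so their
#'   recovery has exact ground truth.
#' @param n_antisense_pairs planted opposite-strand overlapping pairs
#'   (default 10).
#' @param n_h2h_pairs planted head-to-head pairs (default 5).
#' @param h2h_gap_range inclusive range the planted TSS gaps are drawn from
#'   (default c(1, 1000)).
#' @param n_specific_per_tissue planted single-tissue-specific genes per
#'   tissue (default 3).
#' @param fold_enrichment expression fold-change of a specific gene in its
#'   target tissue (default 100).
#' @param dispersion negative-binomial dispersion (default 0.1; NB size =
#'   1/dispersion).
#' @param base_meanlog,base_sdlog lognormal parameters of background gene
#'   mean counts (default log(50), 1).
#' @param specific_on_mean baseline mean count of a specific gene in its
#'   target tissue before fold-enrichment (default 2; on-tissue mean =
#'   `specific_on_mean * fold_enrichment`).
#' @param specific_off_mean suppressed mean count of a specific gene outside
#'   its target tissue (default 0.001, i.e. almost always zero counts and
#'   average TPM below the 0.5 call threshold).
#' @param high_isoform_mean mean count of planted high-isoform genes in every
#'   tissue (default 100, so all their isoforms clear the call threshold).
#' @param seed integer random seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_tissues = 10, replicates_per_tissue = 2,
                             n_genes = 1000, biotype_props = NULL,
                             isoform_probs = c(0.8, 0.15, 0.04, 0.01),
                             n_antisense_pairs = 10, n_h2h_pairs = 5,
                             h2h_gap_range = c(1, 1000),
                             n_specific_per_tissue = 3, fold_enrichment = 100,
                             dispersion = 0.1, base_meanlog = log(50),
                             base_sdlog = 1, specific_on_mean = 2,
                             specific_off_mean = 0.001,
                             high_isoform_mean = 100, seed = 1) {
  if (is.null(biotype_props)) {
    others <- setdiff(atlas_biotypes, c("protein_coding", "lncRNA"))
    biotype_props <- c(protein_coding = 0.69, lncRNA = 0.23,
                       stats::setNames(rep(0.08 / length(others), length(others)),
                                       others))
  }
  stopifnot(
    n_tissues >= 2, replicates_per_tissue >= 1, n_genes >= 1,
    abs(sum(biotype_props) - 1) < 1e-8,
    all(names(biotype_props) %in% atlas_biotypes),
    length(isoform_probs) == 4, abs(sum(isoform_probs) - 1) < 1e-8,
    n_antisense_pairs >= 0, n_h2h_pairs >= 0,
    length(h2h_gap_range) == 2, h2h_gap_range[1] >= 1,
    h2h_gap_range[2] >= h2h_gap_range[1],
    n_specific_per_tissue >= 0, fold_enrichment > 0, dispersion > 0,
    specific_on_mean > 0, specific_off_mean >= 0, high_isoform_mean > 0
  )
  cfg <- list(
    n_tissues = as.integer(n_tissues),
    replicates_per_tissue = as.integer(replicates_per_tissue),
    n_genes = as.integer(n_genes), biotype_props = biotype_props,
    isoform_probs = isoform_probs,
    n_antisense_pairs = as.integer(n_antisense_pairs),
    n_h2h_pairs = as.integer(n_h2h_pairs),
    h2h_gap_range = as.integer(h2h_gap_range),
    n_specific_per_tissue = as.integer(n_specific_per_tissue),
    fold_enrichment = fold_enrichment, dispersion = dispersion,
    base_meanlog = base_meanlog, base_sdlog = base_sdlog,
    specific_on_mean = specific_on_mean,
    specific_off_mean = specific_off_mean,
    high_isoform_mean = high_isoform_mean,
    n_high_isoform = as.integer(round(isoform_probs[4] * n_genes)),
    seed = as.integer(seed)
  )
  n_pair_genes <- 2L * (cfg$n_antisense_pairs + cfg$n_h2h_pairs)
  n_planted_single <- cfg$n_tissues * cfg$n_specific_per_tissue +
    cfg$n_high_isoform
  if (n_pair_genes + n_planted_single > cfg$n_genes)
    stop("infeasible configuration: ", n_pair_genes, " pair genes + ",
         n_planted_single, " planted single genes exceed n_genes = ",
         cfg$n_genes)
  class(cfg) <- "generator_config"
  cfg
}

sim_tissue_labels <- function(cfg) {
  if (cfg$n_tissues == 10L)
    c("B_cell", "bursa", "ileum", "jejunum", "macrophage", "monocyte",
      "ovary", "proximal_cecum", "spleen_T_cell", "thymus")
  else sprintf("tissue%02d", seq_len(cfg$n_tissues))
}

#' Generate a synthetic annotation with planted gene-pair geometry
#'
#' Lays genes on one synthetic chromosome with inter-unit gaps greater than
#' 1 kb, so no accidental overlaps or TSS adjacencies arise. Planted
#' antisense pairs overlap tail-to-tail by a drawn 1-1000 bp (their TSSs sit
#' at the outer span edges, always more than 1 kb apart); planted
#' head-to-head pairs get opposite strands, zero span overlap and a drawn
#' TSS gap within `h2h_gap_range`. Gene biotypes and isoform numbers are
#' drawn per the configuration; tissue-specific and high-isoform genes are
#' designated among the unpaired background genes. After layout the pair
#' finders are run and the result asserted equal to the planted truth.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @param gtf_path optional path; when given, the annotation is written there
#'   as GTF (byte-identical for identical configurations).
#' @return List with `annotation` (an [annotation_set()]), `gtf_path`
#'   (or `NULL`) and `truth` (planted `antisense_pairs`, `h2h_pairs`,
#'   `specific_genes`, `high_isoform_genes`, `isoforms_per_gene`).
#' @export
generate_annotation <- function(cfg, gtf_path = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n_bg <- cfg$n_genes - 2L * (cfg$n_antisense_pairs + cfg$n_h2h_pairs)
  units <- sample(c(rep("as", cfg$n_antisense_pairs),
                    rep("h2h", cfg$n_h2h_pairs), rep("bg", n_bg)))
  chrom <- "chrS"
  cur <- 1L
  rows <- vector("list", cfg$n_genes)
  gi <- 0L
  next_id <- function() sprintf("G%05d", gi)
  as_pairs <- list(); h2h_pairs <- list()
  for (u in units) {
    if (u == "bg") {
      len <- sample(1500:4000, 1)
      gi <- gi + 1L
      rows[[gi]] <- data.frame(
        gene_id = next_id(), chrom = chrom, start = cur, end = cur + len - 1L,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      unit_end <- cur + len - 1L
    } else if (u == "as") {
      len <- sample(1500:4000, 2, replace = TRUE)
      ov <- sample(1:1000, 1)
      gi <- gi + 1L; id_a <- next_id()
      a <- data.frame(gene_id = id_a, chrom = chrom, start = cur,
                      end = cur + len[1] - 1L, strand = "+",
                      stringsAsFactors = FALSE)
      gi <- gi + 1L; id_b <- next_id()
      b_start <- a$end - ov + 1L
      b <- data.frame(gene_id = id_b, chrom = chrom, start = b_start,
                      end = b_start + len[2] - 1L, strand = "-",
                      stringsAsFactors = FALSE)
      rows[[gi - 1L]] <- a; rows[[gi]] <- b
      as_pairs[[length(as_pairs) + 1L]] <-
        data.frame(gene_a = id_a, gene_b = id_b, overlap_bp = ov,
                   stringsAsFactors = FALSE)
      unit_end <- max(a$end, b$end)
    } else {
      len <- sample(1500:4000, 2, replace = TRUE)
      gap <- sample(cfg$h2h_gap_range[1]:cfg$h2h_gap_range[2], 1)
      gi <- gi + 1L; id_b <- next_id()
      b <- data.frame(gene_id = id_b, chrom = chrom, start = cur,
                      end = cur + len[1] - 1L, strand = "-",
                      stringsAsFactors = FALSE)
      gi <- gi + 1L; id_a <- next_id()
      a_start <- b$end + gap
      a <- data.frame(gene_id = id_a, chrom = chrom, start = a_start,
                      end = a_start + len[2] - 1L, strand = "+",
                      stringsAsFactors = FALSE)
      rows[[gi - 1L]] <- b; rows[[gi]] <- a
      h2h_pairs[[length(h2h_pairs) + 1L]] <-
        data.frame(gene_a = id_b, gene_b = id_a, tss_distance_bp = gap,
                   stringsAsFactors = FALSE)
      unit_end <- a$end
    }
    cur <- unit_end + 1001L + sample(0:500, 1)
  }
  genes <- do.call(rbind, rows)
  genes$biotype <- sample(names(cfg$biotype_props), cfg$n_genes,
                          replace = TRUE, prob = cfg$biotype_props)

  pair_ids <- c(unlist(lapply(as_pairs, function(p) c(p$gene_a, p$gene_b))),
                unlist(lapply(h2h_pairs, function(p) c(p$gene_a, p$gene_b))))
  bg_ids <- setdiff(genes$gene_id, pair_ids)
  hi_ids <- sort(sample(bg_ids, cfg$n_high_isoform))
  tissues <- sim_tissue_labels(cfg)
  spec_ids <- sort(sample(setdiff(bg_ids, hi_ids),
                          cfg$n_tissues * cfg$n_specific_per_tissue))
  specific <- data.frame(
    gene_id = spec_ids,
    tissue = rep(tissues, length.out = length(spec_ids)),
    stringsAsFactors = FALSE)

  p123 <- cfg$isoform_probs[1:3] / sum(cfg$isoform_probs[1:3])
  n_iso <- ifelse(genes$gene_id %in% hi_ids,
                  sample(4:6, cfg$n_genes, replace = TRUE),
                  sample(1:3, cfg$n_genes, replace = TRUE, prob = p123))
  transcripts <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(i) {
    k <- n_iso[i]
    data.frame(
      transcript_id = sprintf("%s.t%d", genes$gene_id[i], seq_len(k)),
      gene_id = genes$gene_id[i], chrom = genes$chrom[i],
      start = genes$start[i], end = genes$end[i], strand = genes$strand[i],
      biotype = genes$biotype[i], stringsAsFactors = FALSE)
  }))
  ann <- annotation_set(genes, transcripts)

  bind_or_empty <- function(lst, cols) {
    if (length(lst)) {
      out <- do.call(rbind, lst)
      out[order(out$gene_a, out$gene_b), , drop = FALSE]
    } else {
      as.data.frame(stats::setNames(
        rep(list(character(0)), length(cols)), cols))
    }
  }
  truth <- list(
    antisense_pairs = bind_or_empty(as_pairs, c("gene_a", "gene_b", "overlap_bp")),
    h2h_pairs = bind_or_empty(h2h_pairs, c("gene_a", "gene_b", "tss_distance_bp")),
    specific_genes = specific,
    high_isoform_genes = hi_ids,
    isoforms_per_gene = stats::setNames(n_iso, genes$gene_id)
  )
  rownames(truth$antisense_pairs) <- rownames(truth$h2h_pairs) <- NULL

  # no-leakage assertion: the finders must see exactly the planted structure
  plain <- function(df) { class(df) <- "data.frame"; df }
  found_as <- find_antisense_pairs(ann)
  found_h2h <- find_h2h_pairs(ann, max_distance = 1000)
  stopifnot(
    identical(plain(found_as[, c("gene_a", "gene_b", "overlap_bp")]),
              truth$antisense_pairs),
    identical(plain(found_h2h[, c("gene_a", "gene_b", "tss_distance_bp")]),
              truth$h2h_pairs)
  )

  if (!is.null(gtf_path)) write_gtf(ann, gtf_path)
  list(annotation = ann, gtf_path = gtf_path, truth = truth)
}

#' Write an annotation set as GTF
#'
#' Emits one `gene` line per gene followed by its `transcript` lines, with
#' `gene_id`/`gene_biotype` and `transcript_id`/`transcript_biotype`
#' attributes, 1-based inclusive coordinates. Output is deterministic
#' (genes in coordinate order, transcripts by id), so identical annotations
#' give byte-identical files.
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(ann, path) {
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start, ann$genes$gene_id), ]
  tx <- ann$transcripts
  lines <- unlist(lapply(seq_len(nrow(g)), function(i) {
    gl <- sprintf('%s\ttxatlas_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
                  g$chrom[i], g$start[i], g$end[i], g$strand[i],
                  g$gene_id[i], g$biotype[i])
    t_i <- tx[tx$gene_id == g$gene_id[i], , drop = FALSE]
    tl <- sprintf('%s\ttxatlas_sim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s"; transcript_biotype "%s";',
                  t_i$chrom, t_i$start, t_i$end, t_i$strand,
                  t_i$gene_id, t_i$transcript_id, t_i$biotype, t_i$biotype)
    c(gl, tl)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Generate synthetic expression matrices with planted structure
#'
#' Gene counts are drawn negative-binomially around per-tissue means:
#' background genes share one lognormal mean across tissues; planted
#' tissue-specific genes get `specific_on_mean * fold_enrichment` in their
#' target tissue and `specific_off_mean` elsewhere; planted high-isoform
#' genes get `high_isoform_mean` everywhere. Transcript TPMs split each
#' gene's counts over its isoforms with a per-gene Dirichlet usage simplex
#' (near-uniform for high-isoform genes) and normalize every sample column
#' to 1e6; transcript lengths are treated as equal, so no length correction
#' applies. Replicates are independent draws. Reproducible from
#' `cfg$seed + 1` (a stream separate from the annotation's).
#'
#' @param sim result of [generate_annotation()].
#' @param cfg the same [generator_config()].
#' @return List with `tpm` (transcript-level [expression_matrix()], TPM),
#'   `counts` (gene-level [expression_matrix()], counts), `grouping`
#'   (data.frame `sample_id`, `tissue`) and `truth` (the annotation truth
#'   extended with `expected_mean_counts`, the gene x tissue NB mean matrix).
#' @export
generate_expression <- function(sim, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  ann <- sim$annotation
  truth <- sim$truth
  set.seed(cfg$seed + 1L)
  tissues <- sim_tissue_labels(cfg)
  grouping <- data.frame(
    sample_id = paste0(rep(tissues, each = cfg$replicates_per_tissue), "_rep",
                       seq_len(cfg$replicates_per_tissue)),
    tissue = rep(tissues, each = cfg$replicates_per_tissue),
    stringsAsFactors = FALSE)

  gene_ids <- ann$genes$gene_id
  n <- length(gene_ids)
  mu <- matrix(rlnorm(n, cfg$base_meanlog, cfg$base_sdlog), nrow = n,
               ncol = cfg$n_tissues, dimnames = list(gene_ids, tissues))
  mu[truth$high_isoform_genes, ] <- cfg$high_isoform_mean
  mu[truth$specific_genes$gene_id, ] <- cfg$specific_off_mean
  mu[cbind(truth$specific_genes$gene_id, truth$specific_genes$tissue)] <-
    cfg$specific_on_mean * cfg$fold_enrichment

  counts <- vapply(seq_len(nrow(grouping)), function(s) {
    rnbinom(n, mu = mu[, grouping$tissue[s]], size = 1 / cfg$dispersion)
  }, numeric(n))
  dimnames(counts) <- list(gene_ids, grouping$sample_id)

  tx <- ann$transcripts
  usage <- unlist(lapply(gene_ids, function(g) {
    k <- sum(tx$gene_id == g)
    alpha <- if (g %in% truth$high_isoform_genes) 10 else 1
    u <- rgamma(k, shape = alpha, rate = 1)
    u / sum(u)
  }))
  # transcripts are sorted by id = gene order with .t1..t6 suffixes, so the
  # per-gene usage concatenation aligns with the transcript table
  stopifnot(length(usage) == nrow(tx))
  abund <- counts[match(tx$gene_id, gene_ids), , drop = FALSE] * usage
  csum <- colSums(abund)
  if (any(csum <= 0)) stop("degenerate sample with zero total abundance")
  tpm <- sweep(abund, 2, csum, "/") * 1e6
  dimnames(tpm) <- list(tx$transcript_id, grouping$sample_id)

  truth$expected_mean_counts <- mu
  list(
    tpm = expression_matrix(tpm, grouping, "TPM"),
    counts = expression_matrix(counts, grouping, "counts"),
    grouping = grouping,
    truth = truth
  )
}

#' Generate a complete synthetic atlas
#'
#' Runs [generate_annotation()] and [generate_expression()]; optionally
#' writes the GTF, TPM/count/grouping TSVs and the truth record (JSON) to a
#' directory.
#'
#' @param cfg a [generator_config()].
#' @param dir optional output directory (created if missing).
#' @return List with `annotation`, `tpm`, `counts`, `grouping`, `truth`, and
#'   the file paths written (`files`, or `NULL`).
#' @export
simulate_atlas <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  gtf_path <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gtf_path <- file.path(dir, "annotation.gtf")
  }
  anng <- generate_annotation(cfg, gtf_path)
  expr <- generate_expression(anng, cfg)
  files <- NULL
  if (!is.null(dir)) {
    write_tsv_matrix <- function(m, path, id_col) {
      df <- data.frame(rownames(m), m, check.names = FALSE,
                       stringsAsFactors = FALSE)
      names(df)[1] <- id_col
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    files <- list(
      gtf = gtf_path,
      tpm = file.path(dir, "transcript_tpm.tsv"),
      counts = file.path(dir, "gene_counts.tsv"),
      groups = file.path(dir, "groups.tsv"),
      truth = file.path(dir, "truth.json")
    )
    write_tsv_matrix(expr$tpm$values, files$tpm, "transcript_id")
    write_tsv_matrix(expr$counts$values, files$counts, "gene_id")
    write.table(expr$grouping, files$groups, sep = "\t", quote = FALSE,
                row.names = FALSE)
    truth_json <- expr$truth
    truth_json$isoforms_per_gene <- as.list(truth_json$isoforms_per_gene)
    truth_json$expected_mean_counts <- NULL  # large; regenerate from seed
    jsonlite::write_json(truth_json, files$truth, auto_unbox = TRUE,
                         digits = NA)
  }
  list(annotation = anng$annotation, tpm = expr$tpm, counts = expr$counts,
       grouping = expr$grouping, truth = expr$truth, files = files)
}
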