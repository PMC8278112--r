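test_that("antisense overlap follows 1-based inclusive interval arithmetic", {
  genes <- data.frame(
    gene_id = c("A", "B"), chrom = "chr1",
    start = c(100, 150), end = c(200, 250), strand = c("+", "-"),
    biotype = "protein_coding", stringsAsFactors = FALSE)
  pairs <- find_antisense_pairs(ann_from_genes(genes))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$overlap_bp, 51L)
  expect_equal(pairs$gene_a, "A")

  adjacent <- genes; adjacent$start[2] <- 201; adjacent$end[2] <- 300
  expect_equal(nrow(find_antisense_pairs(ann_from_genes(adjacent))), 0)

  same <- genes; same$strand[2] <- "+"
  expect_equal(nrow(find_antisense_pairs(ann_from_genes(same))), 0)

  # single-base overlap counts (>= 1 bp rule)
  touch <- genes; touch$start[2] <- 200; touch$end[2] <- 300
  expect_equal(find_antisense_pairs(ann_from_genes(touch))$overlap_bp, 1L)
})

test_that("head-to-head pairs respect strand, TSS distance and the inclusive 1 kb bound", {
  mk <- function(b_end) data.frame(
    gene_id = c("A", "B"), chrom = "chr1",
    start = c(5000, b_end - 800), end = c(6000, b_end),
    strand = c("+", "-"), biotype = "protein_coding", stringsAsFactors = FALSE)
  p <- find_h2h_pairs(ann_from_genes(mk(4900)))   # A TSS 5000, B TSS 4900
  expect_equal(nrow(p), 1)
  expect_equal(p$tss_distance_bp, 100L)
  expect_equal(p$orientation, "divergent")

  # boundary: exactly 1000 is in, 1001 is out
  at_bound <- find_h2h_pairs(ann_from_genes(mk(4000)))
  expect_equal(at_bound$tss_distance_bp, 1000L)
  expect_equal(nrow(find_h2h_pairs(ann_from_genes(mk(3999)))), 0)

  both_plus <- mk(4900); both_plus$strand <- c("+", "+")
  expect_equal(nrow(find_h2h_pairs(ann_from_genes(both_plus))), 0)
})

test_that("biotype pairing categories are order-insensitive with a strict vocabulary", {
  expect_equal(classify_pair_biotype("protein_coding", "protein_coding"), "PC-PC")
  expect_equal(classify_pair_biotype("lncRNA", "protein_coding"), "PC-lncRNA")
  expect_equal(classify_pair_biotype("protein_coding", "lncRNA"), "PC-lncRNA")
  expect_equal(classify_pair_biotype("lncRNA", "lncRNA"), "lncRNA-lncRNA")
  expect_equal(classify_pair_biotype("protein_coding", "miRNA"), "other")
  expect_equal(classify_pair_biotype("miRNA", "snoRNA"), "other")
  expect_error(classify_pair_biotype("protein_coding", "TEC"), "unknown biotype")
})

test_that("finders match the exhaustive all-pairs oracle on random annotations", {
  for (seed in 1:8) {
    ann <- random_annotation(n = sample(20:120, 1), seed = seed)
    fa <- find_antisense_pairs(ann)
    expect_equal(fa[, c("gene_a", "gene_b", "overlap_bp")],
                 brute_antisense(ann), ignore_attr = TRUE)
    maxd <- sample(c(100, 1000, 5000), 1)
    fh <- find_h2h_pairs(ann, max_distance = maxd)
    expect_equal(fh[, c("gene_a", "gene_b", "tss_distance_bp")],
                 brute_h2h(ann, maxd), ignore_attr = TRUE)
  }
})

test_that("pair results are invariant under global strand reversal", {
  ann <- random_annotation(80, seed = 99)
  flip <- ann$genes
  flip$strand <- ifelse(flip$strand == "+", "-", "+")
  ann_flip <- ann_from_genes(flip)
  a1 <- find_antisense_pairs(ann)
  a2 <- find_antisense_pairs(ann_flip)
  expect_equal(a1[, c("gene_a", "gene_b", "overlap_bp")],
               a2[, c("gene_a", "gene_b", "overlap_bp")])
  # H2H pair membership is strand-relative too, but TSSs move with the flip,
  # so compare only the unordered pair identity under a symmetric distance
  h1 <- brute_h2h(ann, 1e9)
  h2 <- brute_h2h(ann_flip, 1e9)
  expect_equal(h1[, c("gene_a", "gene_b")], h2[, c("gene_a", "gene_b")])
})

test_that("H2H pair sets are monotone in the distance bound", {
  ann <- random_annotation(100, seed = 4)
  key <- function(p) paste(p$gene_a, p$gene_b)
  d_prev <- character(0)
  for (d in c(0, 200, 1000, 4000)) {
    k <- key(find_h2h_pairs(ann, d))
    expect_true(all(d_prev %in% k))
    d_prev <- k
  }
})

test_that("pair expression status partitions co/mono/silent per tissue", {
  genes <- data.frame(
    gene_id = c("A", "B", "C", "D"), chrom = "chr1",
    start = c(100, 150, 5000, 5100), end = c(200, 250, 5600, 5700),
    strand = c("+", "-", "+", "-"),
    biotype = c("protein_coding", "lncRNA", "protein_coding", "protein_coding"),
    stringsAsFactors = FALSE)
  ann <- ann_from_genes(genes)
  pairs <- find_antisense_pairs(ann)
  expect_equal(nrow(pairs), 2)
  prof <- matrix(c(1, 1, 1, 0,   # tissue X: A,B,C on
                   1, 0, 0, 0,   # tissue Y: A only
                   0, 0, 0, 0),  # tissue Z: silence
                 nrow = 4, dimnames = list(c("A", "B", "C", "D"),
                                           c("X", "Y", "Z")))
  st <- pair_expression_status(pairs, call_expressed(prof, 0.5))
  get <- function(pa, tis) st$status$status[st$status$gene_a == pa &
                                            st$status$tissue == tis]
  expect_equal(get("A", "X"), "co_expressed")
  expect_equal(get("A", "Y"), "mono_expressed")
  expect_equal(get("A", "Z"), "silent")
  expect_equal(get("C", "X"), "mono_expressed")
  # partition: per tissue, statuses over pairs sum to the number of pairs
  tab <- table(st$status$tissue)
  expect_true(all(tab == nrow(pairs)))
  # uniqueness: held in exactly one tissue
  expect_equal(st$unique_co$gene_a, "A")
  expect_equal(st$unique_co$tissue, "X")
  # A-B is mono in Y only; C-D is mono in X only
  expect_setequal(paste(st$unique_mono$gene_a, st$unique_mono$tissue),
                  c("A Y", "C X"))
})

test_that("raising the call threshold never increases co-expression counts", {
  sim <- simulate_atlas(small_cfg(seed = 12))
  ann <- sim$annotation
  pairs <- find_antisense_pairs(ann)
  prof <- average_replicates(sim$tpm)
  co_at <- function(thr) {
    gc <- gene_calls_from_tx(call_expressed(prof, thr), ann)
    st <- pair_expression_status(pairs, gc)
    tapply(st$status$status == "co_expressed", st$status$tissue, sum)
  }
  lo <- co_at(0.5); hi <- co_at(5); higher <- co_at(50)
  expect_true(all(hi <= lo))
  expect_true(all(higher <= hi))
})
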