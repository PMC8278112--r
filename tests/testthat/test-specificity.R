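test_that("entropy closed forms in bits", {
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2.0)
  expect_equal(shannon_entropy(c(5, 0, 0, 0)), 0.0)
  expect_equal(shannon_entropy(c(2, 1, 1, 0)), 1.5)
  expect_error(shannon_entropy(c(0, 0, 0)), "all-zero")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
})

test_that("entropy extremes are exact and invariances hold on random vectors", {
  for (T in c(2, 5, 10, 16))
    expect_equal(shannon_entropy(rep(3.7, T)), log2(T))
  set.seed(13)
  for (rep in 1:20) {
    x <- rexp(sample(3:12, 1))
    h <- shannon_entropy(x)
    expect_gte(h, 0)
    expect_lte(h, log2(length(x)) + 1e-12)
    c_ <- runif(1, 0.01, 100)
    expect_equal(shannon_entropy(c_ * x), h)
    expect_equal(shannon_entropy(sample(x)), h)
  }
})

test_that("specificity ranking: single-tissue genes first, uniform last, ties by id", {
  prof <- matrix(0, nrow = 4, ncol = 10,
                 dimnames = list(c("uniformZ", "single", "two", "uniformA"),
                                 sprintf("T%02d", 1:10)))
  prof["uniformZ", ] <- 5
  prof["uniformA", ] <- 1
  prof["single", 3] <- 8
  prof["two", c(2, 9)] <- 4
  r <- rank_gene_specificity(prof, top_n = 4)
  expect_equal(r$table$feature_id, c("single", "two", "uniformA", "uniformZ"))
  expect_equal(r$table$score[1], log2(10))
  expect_equal(r$table$score[3:4], c(0, 0))
  expect_equal(r$table$rank, 1:4)
  # descending score ordering equals ascending entropy ordering
  expect_equal(order(-r$table$score, r$table$feature_id),
               order(r$table$entropy, r$table$feature_id))
  # least-specific direction reverses the extremes
  l <- rank_gene_specificity(prof, top_n = 4, direction = "least_specific")
  expect_equal(l$table$feature_id[1:2], c("uniformA", "uniformZ"))
  expect_warning(rank_gene_specificity(prof, top_n = 99), "returning all")
})

test_that("permuting tissue columns leaves entropies unchanged", {
  set.seed(31)
  prof <- matrix(rexp(80), nrow = 8,
                 dimnames = list(sprintf("g%d", 1:8), sprintf("T%d", 1:10)))
  r1 <- rank_gene_specificity(prof, top_n = 8)
  r2 <- rank_gene_specificity(prof[, sample(10)], top_n = 8)
  expect_equal(r1$table, r2$table)
})

test_that("isoform specificity applies the parent-gene and own-expression filters", {
  p <- tmp_gtf(c(
    gtf_tx_line("gOne", "one.t1", 1, 100, "+"),
    gtf_tx_line("gMulti", "multi.t1", 5000, 5100, "+"),
    gtf_tx_line("gMulti", "multi.t2", 5000, 5100, "+")
  ))
  ann <- parse_gtf(p)
  gene_prof <- matrix(c(9, 0, 0,
                        5, 5, 5), nrow = 2, byrow = TRUE,
                      dimnames = list(c("gOne", "gMulti"), c("A", "B", "C")))
  gene_calls <- call_expressed(gene_prof, 0.5)
  tx_prof <- matrix(c(9, 0, 0,
                      5, 0, 0,
                      0.1, 0.1, 0.1), nrow = 3, byrow = TRUE,
                    dimnames = list(c("one.t1", "multi.t1", "multi.t2"),
                                    c("A", "B", "C")))
  r <- suppressWarnings(
    rank_isoform_specificity(tx_prof, gene_calls, ann, top_n = 3))
  # one.t1 excluded: its gene is expressed in a single tissue
  expect_false("one.t1" %in% r$table$feature_id)
  # multi.t2 excluded: never passes the call itself
  expect_false("multi.t2" %in% r$table$feature_id)
  # multi.t1 retained and maximally specific among retained
  expect_equal(r$table$feature_id[1], "multi.t1")
  expect_equal(r$table$score[1], log2(3))

  bad <- tx_prof
  rownames(bad)[1] <- "phantom.t1"
  expect_error(rank_isoform_specificity(bad, gene_calls, ann), "unresolvable")
})

test_that("planted tissue-specific genes and isoforms are recovered in top ranks", {
  sim <- simulate_atlas(small_cfg(seed = 21))
  prof <- average_replicates(normalize_counts(sim$counts))
  k <- nrow(sim$truth$specific_genes)
  r <- rank_gene_specificity(prof, top_n = k)
  expect_setequal(r$table$feature_id[1:k], sim$truth$specific_genes$gene_id)

  tx_prof <- average_replicates(sim$tpm)
  gene_calls <- gene_calls_from_tx(call_expressed(tx_prof), sim$annotation)
  ri <- suppressWarnings(
    rank_isoform_specificity(tx_prof, gene_calls, sim$annotation, top_n = 10))
  # every retained isoform's parent gene is expressed in >= 2 tissues
  parents <- sim$annotation$transcripts[ri$table$feature_id, "gene_id"]
  tis_per_gene <- table(unlist(gene_calls$expressed))
  expect_true(all(tis_per_gene[parents] >= 2))
  expect_equal(ri$table$rank, seq_len(nrow(ri$table)))
})
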