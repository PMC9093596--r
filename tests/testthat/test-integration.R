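test_that("DEG classification applies inclusive fold and p thresholds", {
  d <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                  log2fc = c(1.5, 0.9, -3.0, 1.0, 2.0),
                  p_adj = c(0.01, 0.001, 0.049, 0.05, 0.051),
                  stringsAsFactors = FALSE)
  r <- classify_degs(d)
  expect_equal(r$status, c("up", "ns", "down", "up", "ns"))
  expect_error(classify_degs(d[, 1:2]), "p_adj")
  # idempotent
  expect_equal(classify_degs(r)$status, r$status)
  # threshold-monotone: raising the fold cut never adds up/down calls
  for (fc in c(2, 3, 4, 8)) {
    lo <- classify_degs(d, fc_threshold = fc)
    hi <- classify_degs(d, fc_threshold = fc * 2)
    expect_lte(sum(hi$status != "ns"), sum(lo$status != "ns"))
  }
  # raw p route
  r2 <- classify_degs(transform(d[, 1:2], p = c(0.01, 0.5, 0.01, 0.5, 0.01)),
                      adjust = TRUE)
  expect_true("p_adj" %in% names(r2))
})

test_that("the plumbing DE test reproduces the pseudocount formula", {
  counts <- matrix(c(200L, 50L, 100L, 100L, 0L, 0L), ncol = 2,
                   byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  # equalize library sizes so normalisation is a no-op
  counts["g2", ] <- c(100L, 250L)
  r <- simple_de_test(counts, c("A", "B"))
  expect_equal(r$log2fc[1], log2(201 / 51))
  expect_equal(r$log2fc[3], 0)
  expect_equal(r$p[3], 1)
  ident <- matrix(c(5L, 5L), 1, dimnames = list("g", NULL))
  ri <- simple_de_test(ident, c("A", "B"))
  expect_equal(ri$log2fc, 0)
  expect_equal(ri$p, 1)
})

test_that("strong planted fold changes are nearly always detected", {
  set.seed(10)
  n <- 200
  lfc <- rep(c(2, -2, 0), length.out = n)
  mu_b <- rep(500, n)
  counts <- cbind(A = rnbinom(n, mu = mu_b * 2^lfc, size = 20),
                  B = rnbinom(n, mu = mu_b, size = 20))
  rownames(counts) <- sprintf("g%03d", 1:n)
  r <- simple_de_test(counts, c("A", "B"))
  expect_gte(mean(r$p_adj[lfc != 0] <= 0.05), 0.95)
})

test_that("DMG-DEG intersection fills the four categories from ground truth", {
  degs <- classify_degs(data.frame(gene_id = character(),
                                   log2fc = numeric(), p_adj = numeric(),
                                   stringsAsFactors = FALSE))
  empty <- intersect_dmg_deg(
    data.frame(gene_id = character(), association = character(),
               direction = character(), degree_of_difference = numeric(),
               stringsAsFactors = FALSE), degs)
  expect_equal(nrow(empty$dmegs), 0L)
  expect_equal(empty$venn$n_hyper_down, 0L)

  assoc <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    association = c("promoter", "promoter", "gene_body", "promoter"),
    direction = c("hyper", "hyper", "hypo", "hyper"),
    degree_of_difference = c(2, 3, -2, 1), stringsAsFactors = FALSE)
  degs <- classify_degs(data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    log2fc = c(-2, -2, 2, 0), p_adj = c(0.01, 0.01, 0.01, 0.9),
    stringsAsFactors = FALSE))
  res <- intersect_dmg_deg(assoc, degs)
  expect_equal(res$venn$n_hyper_down, 2L)
  expect_equal(res$venn$n_hypo_up, 1L)
  expect_equal(res$venn$n_hyper_up, 0L)
  sub <- res$by_subgroup
  expect_equal(sub$n_hyper_down[sub$association == "promoter"], 2L)
  expect_equal(sub$n_hypo_up[sub$association == "gene_body"], 1L)
})

test_that("a multi-DMR gene takes the direction of its strongest DMR", {
  assoc <- data.frame(gene_id = "g1", association = "promoter",
                      direction = c("hyper", "hypo"),
                      degree_of_difference = c(1, -4),
                      stringsAsFactors = FALSE)
  degs <- classify_degs(data.frame(gene_id = "g1", log2fc = 2,
                                   p_adj = 0.01, stringsAsFactors = FALSE))
  res <- intersect_dmg_deg(assoc, degs)
  expect_equal(res$dmegs$direction, "hypo")
})

test_that("coupled counts vanish under gene-label permutation", {
  cfg <- sim_config(coupling_fraction = 1, seed = small_cfg$seed,
                    n_chromosomes = 1L, chromosome_length = 60000L,
                    n_genes = 6L, n_dmrs = 4L, n_deg = 0L)
  ex <- simulate_expression(cfg, small_fix$genes, small_fix$sim$truth,
                            mode = "truth")
  degs <- classify_degs(ex$deg_table)
  assoc <- associate_dmrs(small_fix$sim$truth$dmrs,
                          small_fix$genes)$associations
  res <- intersect_dmg_deg(assoc, degs)
  sub <- res$by_subgroup
  observed <- sub$n_hyper_down[sub$association == "promoter"]
  expect_equal(observed, nrow(ex$coupled_pairs))

  # permutation null: relabelling genes leaves only hypergeometric overlap
  n_hyper <- 1L          # promoter-hyper genes in this fixture
  n_down <- sum(degs$status == "down")
  N <- nrow(degs)
  expect_hyper <- n_hyper * n_down / N
  sd_hyper <- sqrt(expect_hyper * (1 - n_down / N) *
                     (N - n_hyper) / max(N - 1, 1))
  set.seed(20)
  perm <- replicate(200, {
    dp <- degs; dp$gene_id <- sample(dp$gene_id)
    intersect_dmg_deg(assoc, dp)$by_subgroup$n_hyper_down[2]
  })
  expect_lte(abs(mean(perm) - expect_hyper), 3 * max(sd_hyper, 0.1))
})

test_that("rank correlation handles perfect and degenerate inputs", {
  j <- function(x, y) data.frame(degree_of_difference = x, log2fc = y)
  expect_equal(methylation_expression_correlation(
    j(1:3, -(1:3)))$rho, -1)
  expect_equal(methylation_expression_correlation(j(1:3, 1:3))$rho, 1)
  r <- methylation_expression_correlation(j(rep(1, 5), 1:5))
  expect_true(is.na(r$rho))
  expect_true(is.na(methylation_expression_correlation(
    j(1:2, 2:1))$rho))                      # fewer than 3 pairs
})

test_that("promoter methylation anticorrelates with expression when coupled", {
  cfg <- sim_config(coupling_fraction = 0.8, seed = small_cfg$seed,
                    n_chromosomes = 1L, chromosome_length = 60000L,
                    n_genes = 6L, n_dmrs = 4L, n_deg = 1L)
  ex <- simulate_expression(cfg, small_fix$genes, small_fix$sim$truth,
                            mode = "truth")
  d <- call_dmrs(small_fix$meth_a, small_fix$meth_b)
  assoc <- associate_dmrs(d, small_fix$genes)$associations
  prom <- unique(assoc[assoc$association == "promoter",
                       c("gene_id", "direction", "degree_of_difference")])
  joined <- merge(prom, ex$deg_table, by = "gene_id")
  r <- methylation_expression_correlation(joined)
  expect_lt(r$rho, 0)
})
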