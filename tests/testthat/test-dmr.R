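test_that("Fisher exact p matches the combinatorial oracle and fisher.test", {
  # exact fraction for the canonical 8/2 vs 2/8 table
  expect_equal(fisher_exact_p(8, 2, 2, 8), 4252 / 184756)
  set.seed(1)
  for (i in 1:200) {
    tab <- rpois(4, sample(3:10, 1))
    mine <- fisher_exact_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(mine, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    expect_equal(mine,
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
  # large pooled counts stay finite and sane
  expect_lt(fisher_exact_p(4000, 1000, 1000, 4000), 1e-10)
  expect_equal(fisher_exact_p(0, 0, 0, 0), 1)
  expect_error(fisher_exact_p(-1, 2, 3, 4), "non-negative")
})

test_that("degree of difference applies the log2 ratio with zero substitution", {
  expect_equal(degree_of_difference(0.8, 0.2), 2)
  expect_equal(degree_of_difference(0.3, 0.3), 0)
  expect_equal(degree_of_difference(0.5, 0), log2(500))
  expect_equal(degree_of_difference(0, 0.5), -log2(500))
  expect_equal(degree_of_difference(0, 0), 0)
  expect_error(degree_of_difference(1.2, 0.5), "\\[0, 1\\]")
  expect_error(degree_of_difference(0.5, -0.1), "\\[0, 1\\]")
})

test_that("window enumeration enforces the joint site minimum", {
  mk <- function(pos, total) make_meth("chr1", pos, "+", "CG",
                                       meth = rep(1L, length(pos)),
                                       total = total)
  pos6 <- c(100L, 200L, 300L, 400L, 500L, 600L)
  a <- mk(pos6, rep(10L, 6))
  # only 4 joint sites -> discarded
  b4 <- mk(pos6, c(10L, 10L, 10L, 10L, 2L, 2L))
  expect_equal(nrow(enumerate_windows(a, b4, "CG", 1000L, 1000L, 5L)), 0L)
  # sample A rich but B covers only 3 -> discarded
  b3 <- mk(pos6, c(10L, 10L, 10L, 2L, 2L, 2L))
  expect_equal(nrow(enumerate_windows(a, b3, "CG", 1000L, 1000L, 5L)), 0L)
  # 5 joint sites qualify and counts pool
  b5 <- mk(pos6, c(10L, 10L, 10L, 10L, 10L, 2L))
  w <- enumerate_windows(a, b5, "CG", 1000L, 1000L, 5L)
  expect_equal(w$n_sites, 5L)
  expect_equal(w$m_a + w$u_a, 50L)
  expect_error(enumerate_windows(a, b5, "CG", 0L, 500L), "positive")
})

test_that("window tests combine the fold and Fisher criteria", {
  w <- data.frame(chrom = "chr1", start = 1L, end = 1000L, context = "CG",
                  n_sites = 5L,
                  m_a = c(8L, 10L, 3000L), u_a = c(2L, 10L, 7000L),
                  m_b = c(2L, 10L, 2000L), u_b = c(8L, 10L, 8000L),
                  stringsAsFactors = FALSE)
  w$ml_a <- w$m_a / (w$m_a + w$u_a)
  w$ml_b <- w$m_b / (w$m_b + w$u_b)
  t <- test_windows(w)
  expect_equal(t$p_value[1], 4252 / 184756)
  expect_equal(t$fold_ratio[1], 4)
  expect_true(t$pass[1])
  expect_equal(t$p_value[2], 1)            # identical counts
  expect_equal(t$fold_ratio[2], 1)
  expect_false(t$pass[2])
  expect_lt(t$p_value[3], 1e-10)           # 0.30 vs 0.20: p tiny but
  expect_false(t$pass[3])                  # fold 1.5 < 2 binds
})

test_that("interdependent windows merge to independent regions", {
  sites <- data.frame(chrom = "chr1",
                      pos = seq(50L, 2950L, by = 100L), strand = "+",
                      m_a = 9L, t_a = 10L, m_b = 1L, t_b = 10L,
                      stringsAsFactors = FALSE)
  mkw <- function(start, end, dir = "hyper") {
    w <- data.frame(chrom = "chr1", start = start, end = end,
                    context = "CG", n_sites = 5L, m_a = 45L, u_a = 5L,
                    m_b = 5L, u_b = 45L, ml_a = 0.9, ml_b = 0.1,
                    stringsAsFactors = FALSE)
    test_windows(w)
  }
  # two overlapping hyper windows -> a single spanning DMR
  d <- merge_interdependent(mkw(c(1L, 501L), c(1000L, 1500L)),
                            sites = sites)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end), c(1L, 1500L))
  expect_equal(d$direction, "hyper")
  expect_gt(d$degree_of_difference, 3)

  # chain of 5 mutually overlapping windows -> 1 DMR, order-invariant,
  # equal to the brute-force transitive closure
  starts <- c(1L, 401L, 801L, 1201L, 1601L)
  ends <- starts + 999L
  w5 <- mkw(starts, ends)
  d5 <- merge_interdependent(w5, sites = sites)
  expect_equal(nrow(d5), 1L)
  set.seed(2)
  perm <- sample(5)
  d5p <- merge_interdependent(w5[perm, ], sites = sites)
  expect_equal(d5p, d5)
  oracle <- merge_oracle(starts, ends)
  expect_equal(c(d5$start, d5$end), c(oracle$start, oracle$end))
})

test_that("direction mismatch blocks merging of adjacent windows", {
  sites <- data.frame(chrom = "chr1",
                      pos = c(seq(50L, 950L, 100L), seq(1050L, 1950L, 100L)),
                      strand = "+",
                      m_a = rep(c(9L, 1L), each = 10L), t_a = 10L,
                      m_b = rep(c(1L, 9L), each = 10L), t_b = 10L,
                      stringsAsFactors = FALSE)
  w <- data.frame(chrom = "chr1", start = c(1L, 1001L),
                  end = c(1000L, 2000L), context = "CG", n_sites = 10L,
                  m_a = c(90L, 10L), u_a = c(10L, 90L),
                  m_b = c(10L, 90L), u_b = c(90L, 10L),
                  ml_a = c(0.9, 0.1), ml_b = c(0.1, 0.9),
                  stringsAsFactors = FALSE)
  d <- merge_interdependent(test_windows(w), sites = sites)
  expect_equal(nrow(d), 2L)
  expect_setequal(d$direction, c("hyper", "hypo"))
})

test_that("swapping the samples flips directions and negates the degree of difference", {
  d_ab <- call_dmrs(small_fix$meth_a, small_fix$meth_b)
  d_ba <- call_dmrs(small_fix$meth_b, small_fix$meth_a)
  expect_gt(nrow(d_ab), 0L)
  key <- function(d) paste(d$chrom, d$start, d$end, d$context)
  expect_setequal(key(d_ab), key(d_ba))
  m <- match(key(d_ab), key(d_ba))
  expect_equal(d_ba$direction[m],
               ifelse(d_ab$direction == "hyper", "hypo", "hyper"))
  expect_equal(d_ba$degree_of_difference[m], -d_ab$degree_of_difference)
  expect_equal(d_ba$p_value[m], d_ab$p_value)
})

test_that("planted DMRs are recovered on the small fixture", {
  d <- call_dmrs(small_fix$meth_a, small_fix$meth_b)
  rec <- dmr_recovery(d, small_fix$sim$truth$dmrs)
  expect_gte(rec$recall, 0.75)     # 4 planted regions, small genome
  expect_gte(rec$precision, 0.75)
})

test_that("chromosome distribution counts group and total correctly", {
  empty <- dmr_chromosome_distribution(
    data.frame(chrom = character(), context = character()),
    chroms = c("chr1", "chr2"))
  expect_true(all(empty$n == 0L))
  d <- data.frame(chrom = rep(c("chr1", "chr2"), c(10, 5)),
                  context = rep(c("CG", "CHG"), c(10, 5)),
                  stringsAsFactors = FALSE)
  tab <- dmr_chromosome_distribution(d)
  expect_equal(sum(tab$n), 15L)
  expect_equal(tab$n[tab$chrom == "chr1" & tab$context == "CG"], 10L)
  expect_equal(tab$n[tab$chrom == "chr2" & tab$context == "CHG"], 5L)
  expect_equal(tab$n[tab$chrom == "chr1" & tab$context == "CHH"], 0L)
})
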