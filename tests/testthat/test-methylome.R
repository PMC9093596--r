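test_that("context classification handles the canonical cases", {
  expect_equal(classify_context("ACGTA", 2, "+"), "CG")
  expect_equal(classify_context("ACAGT", 2, "+"), "CHG")
  expect_equal(classify_context("ACTTG", 2, "+"), "CHH")
  expect_equal(classify_context("TACGT", 4, "-"), "CG")
  expect_equal(classify_context("ACNGT", 2, "+"), NA_character_)
  expect_equal(classify_context("AAACG", 4, "+"), NA_character_) # at end
  expect_error(classify_context("ACGTA", 9, "+"), "out of bounds")
  expect_error(classify_context("ACGTA", 1, "+"), "not a cytosine")
  expect_error(classify_context("ACGTA", 2, "-"), "not a cytosine")
})

test_that("context calls agree with trinucleotide enumeration on both strands", {
  set.seed(99)
  seq <- paste(sample(c("A", "C", "G", "T", "N"), 10000, replace = TRUE,
                      prob = c(0.29, 0.2, 0.2, 0.29, 0.02)),
               collapse = "")
  chars <- strsplit(seq, "")[[1]]
  cy <- genome_cytosines(Biostrings::DNAStringSet(c(chr1 = seq)))
  # every C/G position appears unless undefined
  for (strand in c("+", "-")) {
    base <- if (strand == "+") "C" else "G"
    for (pos in which(chars == base)) {
      want <- context_oracle(seq, pos, strand)
      got <- cy$context[cy$pos == pos & cy$strand == strand]
      if (is.na(want)) {
        expect_length(got, 0)
      } else {
        expect_equal(got, want)
      }
    }
  }
})

test_that("trinucleotides are reported in strand sense", {
  cy <- genome_cytosines(Biostrings::DNAStringSet(c(chr1 = "TACGTT")))
  # C at 3 (+): CGT; G at 4 is a minus-strand C read as CGT on the complement
  expect_equal(cy$trinucleotide[cy$pos == 3], "CGT")
  expect_equal(cy$trinucleotide[cy$pos == 4 & cy$strand == "-"], "CGT")
})

test_that("methylation level is the integer ratio under the coverage filter", {
  m <- make_meth("chr1", c(100L, 200L, 300L), "+", "CG",
                 meth = c(3L, 2L, 0L), total = c(10L, 3L, 10L))
  expect_equal(m$ml, c(0.3, NA, 0))          # 2/3 undefined below cov 4
  expect_equal(m$meth_reads[2], 2L)          # counts retained
  m5 <- make_meth("chr1", 100L, "+", "CG", 2L, 4L, min_coverage = 5L)
  expect_true(is.na(m5$ml))                  # knob: >=5 convention
})

test_that("reference context validation warns and the reference wins", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AACGTA"))
  df <- data.frame(chrom = "chr1", pos = 3L, strand = "+",
                   meth_reads = 1L, total_reads = 5L, context = "CHH",
                   trinucleotide = "CTT", stringsAsFactors = FALSE)
  expect_warning(m <- load_methylome(df, genome = genome), "reference")
  expect_equal(m$context, "CG")
})

test_that("context summary fractions are exact and order-invariant", {
  m <- make_meth("chr1", c(10L, 20L, 30L, 40L), "+",
                 c("CG", "CG", "CHG", "CHH"),
                 meth = c(5L, 5L, 0L, 0L), total = rep(10L, 4))
  s <- summarize_contexts(m)
  expect_equal(s$by_context$fraction_of_mc, c(1, 0, 0))  # only CG meth
  expect_equal(sum(s$by_context$fraction_of_mc), 1)
  s2 <- summarize_contexts(m[c(3, 1, 4, 2), ])
  expect_equal(s2$by_context, s$by_context)
})

test_that("coverage fractions use genomic denominators", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAA"))
  cy <- genome_cytosines(genome)
  m <- load_methylome(data.frame(chrom = cy$chrom, pos = cy$pos,
                                 strand = cy$strand, meth_reads = 1L,
                                 total_reads = 10L, context = cy$context,
                                 trinucleotide = cy$trinucleotide,
                                 stringsAsFactors = FALSE))
  s <- summarize_contexts(m, genome = genome)
  cg <- s$by_context[s$by_context$context == "CG", ]
  expect_equal(cg$coverage, 1)               # all genomic CG covered
  expect_equal(s$genome_coverage, 1)
})

test_that("methylation calls follow the closed-form binomial tail", {
  m <- make_meth("chr1", c(1L, 2L, 3L) * 10L, "+", "CG",
                 meth = c(0L, 20L, 1L), total = c(20L, 20L, 20L))
  called <- call_methylated_sites(m, conversion_rate = 0.995)
  expect_false(called$methylated[1])
  expect_equal(called$p_meth[2], 0.005^20)
  expect_equal(called$p_meth[3], 1 - 0.995^20, tolerance = 1e-12)
  expect_true(called$methylated[2])
  # uncovered sites stay uncalled
  m0 <- make_meth("chr1", 5L, "+", "CG", 0L, 0L)
  expect_true(is.na(call_methylated_sites(m0)$methylated))
})

test_that("conversion-rate estimation is the pooled read ratio", {
  m <- make_meth("chrC", c(1L, 2L), "+", "CG",
                 meth = c(15L, 10L), total = c(2500L, 2500L))
  est <- estimate_conversion_rate(m)
  expect_equal(est$rate, 4975 / 5000)
  expect_equal(est$n_reads, 5000L)
  expect_error(estimate_conversion_rate(m, spike_chrom = "chrX"),
               "spike-in")
})

test_that("simulated conversion rate is recovered on the spike-in", {
  est <- estimate_conversion_rate(small_fix$meth_a)
  expect_gt(est$n_reads, 5000)
  expect_lt(abs(est$rate - small_cfg$conversion_rate), 0.003)
})

test_that("element profiles are flat for uniform methylation and empty for no elements", {
  set.seed(5)
  pos <- sort(sample(1:20000, 3000))
  tot <- rpois(3000, 30)
  m <- make_meth("chr1", pos, "+", "CG", rbinom(3000, tot, 0.5),
                 pmax(tot, 4L))
  els <- data.frame(class = "mRNA", chrom = "chr1",
                    start = c(1000L, 6000L, 11000L),
                    end = c(4000L, 9000L, 14000L), strand = "+",
                    stringsAsFactors = FALSE)
  prof <- profile_elements(m, els)
  expect_true(all(abs(prof$mean_ml - 0.5) < 0.03))
  expect_equal(sort(unique(prof$bin)), 1:20)
  expect_equal(nrow(profile_elements(m, els[0, ])), 0L)
})

test_that("gene-body methylation exceeds flanks in the binned profile", {
  set.seed(6)
  pos <- sort(sample(1:30000, 5000))
  body <- pos >= 10000 & pos <= 20000
  tot <- pmax(rpois(5000, 30), 4L)
  m <- make_meth("chr1", pos, "+", "CG",
                 rbinom(5000, tot, ifelse(body, 0.8, 0.3)), tot)
  els <- rbind(
    data.frame(class = "mRNA", chrom = "chr1", start = 10000L,
               end = 20000L, strand = "+", stringsAsFactors = FALSE),
    data.frame(class = "Up2k", chrom = "chr1", start = 8000L,
               end = 9999L, strand = "+", stringsAsFactors = FALSE))
  prof <- profile_elements(m, els)
  expect_gt(min(prof$mean_ml[prof$class == "mRNA"]),
            max(prof$mean_ml[prof$class == "Up2k"]))
})

test_that("short elements are kept via fractional binning", {
  m <- make_meth("chr1", c(5L, 8L), "+", "CG", c(4L, 0L), c(4L, 4L))
  els <- data.frame(class = "tiny", chrom = "chr1", start = 4L, end = 9L,
                    strand = "+", stringsAsFactors = FALSE)
  prof <- profile_elements(m, els, n_bins = 20L)
  expect_equal(nrow(prof), 2L)               # one bin per covered site
  expect_true(all(prof$bin >= 1 & prof$bin <= 20))
})
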