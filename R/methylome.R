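#' Load a methylome with the coverage filter applied
#'
#' Reads a cytosine report (or accepts one already in memory) and computes
#' the per-site methylation level, ML = methylated reads / total reads, the
#' exact integer ratio. The ML is defined only where
#' \code{total_reads >= min_coverage}; below the filter the counts are
#' retained but \code{ml} is \code{NA}. If a reference genome is supplied,
#' reported contexts are checked against the reference; disagreements are
#' warned about and the reference context wins.
#'
#' @param report Path to a cytosine report (see
#'   \code{\link{read_cytosine_report}}) or an equivalent data.frame.
#' @param min_coverage Minimum read total for a defined ML (default 4).
#' @param genome Optional named \code{DNAStringSet} for context validation.
#' @return The site data.frame with an added \code{ml} column and attribute
#'   \code{min_coverage}.
#' @export
load_methylome <- function(report, min_coverage = 4L, genome = NULL) {
  sites <- if (is.character(report)) read_cytosine_report(report) else
    validate_cx(report)
  if (!is.null(genome)) {
    ref <- genome_cytosines(genome)
    key <- function(d) paste(d$chrom, d$pos, d$strand)
    m <- match(key(sites), key(ref))
    if (anyNA(m))
      stop("sites absent from the reference: e.g. line ",
           which(is.na(m))[1])
    bad <- sites$context != ref$context[m]
    if (any(bad)) {
      warning(sum(bad), " sites disagree with the reference context; ",
              "using the reference")
      sites$context[bad] <- ref$context[m][bad]
      sites$trinucleotide[bad] <- ref$trinucleotide[m][bad]
    }
  }
  sites$ml <- ifelse(sites$total_reads >= min_coverage,
                     sites$meth_reads / sites$total_reads, NA_real_)
  attr(sites, "min_coverage") <- as.integer(min_coverage)
  sites
}

#' Call methylated cytosines against the conversion error rate
#'
#' A covered site is called methylated when its methylated read count is
#' larger than expected from bisulfite conversion failure alone: the
#' one-sided binomial upper-tail p-value of \code{meth_reads} out of
#' \code{total_reads} at error rate \code{1 - conversion_rate} is computed
#' per site and Benjamini-Hochberg adjusted across all covered sites; calls
#' are made at \code{fdr_threshold}. Sites with zero reads are uncalled
#' (\code{NA}).
#'
#' @param methylome A \code{\link{load_methylome}} data.frame.
#' @param conversion_rate Bisulfite conversion rate in (0,1].
#' @param fdr_threshold BH FDR threshold (default 0.05).
#' @return The methylome with added \code{p_meth}, \code{q_meth} and
#'   logical \code{methylated} columns.
#' @export
call_methylated_sites <- function(methylome, conversion_rate = 0.995,
                                  fdr_threshold = 0.05) {
  stopifnot(conversion_rate > 0, conversion_rate <= 1)
  err <- 1 - conversion_rate
  cov <- methylome$total_reads > 0L
  p <- rep(NA_real_, nrow(methylome))
  # P(X >= k) for X ~ Binomial(n, err)
  p[cov] <- pbinom(methylome$meth_reads[cov] - 1L,
                   methylome$total_reads[cov], err, lower.tail = FALSE)
  q <- rep(NA_real_, nrow(methylome))
  q[cov] <- p.adjust(p[cov], method = "BH")
  methylome$p_meth <- p
  methylome$q_meth <- q
  methylome$methylated <- q <= fdr_threshold
  methylome
}

#' Summarise methylation by sequence context
#'
#' Computes, per context, the number of methylated sites, their fraction of
#' all methylated cytosines, and the coverage fraction (covered cytosines of
#' that context over all genomic cytosines of that context, when a genome is
#' supplied), plus the genome-wide cytosine coverage.
#'
#' @param methylome A methylome with a \code{methylated} column (from
#'   \code{\link{call_methylated_sites}}); if absent, covered sites with at
#'   least one methylated read are counted as methylated.
#' @param genome Optional named \code{DNAStringSet}; enables the coverage
#'   denominators.
#' @param min_coverage Coverage threshold defining a "covered" site;
#'   defaults to the methylome's own filter.
#' @return A list with \code{by_context} (data.frame: context, n_methylated,
#'   fraction_of_mc, n_covered, n_genomic, coverage) and scalar
#'   \code{genome_coverage}.
#' @export
summarize_contexts <- function(methylome, genome = NULL,
                               min_coverage = NULL) {
  min_coverage <- min_coverage %||% attr(methylome, "min_coverage") %||% 4L
  contexts <- c("CG", "CHG", "CHH")
  covered <- methylome$total_reads >= min_coverage
  meth <- if ("methylated" %in% names(methylome))
    covered & methylome$methylated %in% TRUE else
      covered & methylome$meth_reads > 0L
  n_meth <- vapply(contexts, function(cx)
    sum(meth & methylome$context == cx), integer(1))
  tot_m <- sum(n_meth)
  frac <- if (tot_m > 0) n_meth / tot_m else {
    warning("no methylated sites; fractions reported as 0")
    rep(0, 3)
  }
  n_cov <- vapply(contexts, function(cx)
    sum(covered & methylome$context == cx), integer(1))
  if (!is.null(genome)) {
    ref <- genome_cytosines(genome)
    n_gen <- vapply(contexts, function(cx)
      sum(ref$context == cx), integer(1))
  } else {
    n_gen <- rep(NA_integer_, 3)
  }
  coverage <- ifelse(!is.na(n_gen) & n_gen > 0, n_cov / n_gen, NA_real_)
  list(by_context = data.frame(context = contexts, n_methylated = n_meth,
                               fraction_of_mc = unname(frac),
                               n_covered = n_cov, n_genomic = n_gen,
                               coverage = unname(coverage),
                               row.names = NULL, stringsAsFactors = FALSE),
       genome_coverage = if (all(is.na(n_gen))) NA_real_ else
         sum(n_cov) / sum(n_gen))
}

#' Estimate the bisulfite conversion rate from an unmethylated control
#'
#' Pools all reads over the cytosines of a sequence known to be fully
#' unmethylated (e.g. a spiked-in lambda/chloroplast chromosome): the
#' conversion rate is the fraction of reads reported unmethylated,
#' converted reads / total reads.
#'
#' @param methylome A methylome data.frame.
#' @param spike_chrom Name of the control chromosome (default "chrC").
#' @return List with \code{rate}, \code{n_reads} and \code{n_sites}.
#' @export
estimate_conversion_rate <- function(methylome, spike_chrom = "chrC") {
  s <- methylome[methylome$chrom == spike_chrom, , drop = FALSE]
  if (nrow(s) == 0L)
    stop("no cytosines found on spike-in chromosome '", spike_chrom, "'")
  tot <- sum(s$total_reads)
  if (tot == 0L) stop("spike-in chromosome has zero read coverage")
  list(rate = (tot - sum(s$meth_reads)) / tot, n_reads = tot,
       n_sites = nrow(s))
}

#' Binned methylation metaprofiles over genomic elements
#'
#' Scales every element instance to \code{n_bins} positions (5'->3' in the
#' element's strand sense) and averages the per-site methylation level per
#' bin and context over all instances of each element class. Elements
#' shorter than \code{n_bins} are handled by fractional binning; empty bins
#' are \code{NA} for that instance and ignored in the average.
#'
#' @param methylome A \code{\link{load_methylome}} data.frame (sites with
#'   undefined ML are excluded).
#' @param elements data.frame with columns \code{class}, \code{chrom},
#'   \code{start}, \code{end} and optionally \code{strand} ("." or absent
#'   means plus orientation); see \code{\link{element_intervals}}.
#' @param n_bins Number of bins per element (default 20).
#' @return data.frame: \code{class}, \code{context}, \code{bin},
#'   \code{mean_ml}, \code{n_sites}. Empty if \code{elements} is empty.
#' @export
profile_elements <- function(methylome, elements, n_bins = 20L) {
  empty <- data.frame(class = character(), context = character(),
                      bin = integer(), mean_ml = numeric(),
                      n_sites = integer(), stringsAsFactors = FALSE)
  if (is.null(elements) || nrow(elements) == 0L) return(empty)
  if (is.null(elements$strand)) elements$strand <- "+"
  elements$strand[!elements$strand %in% c("+", "-")] <- "+"
  sites <- methylome[!is.na(methylome$ml), , drop = FALSE]
  if (nrow(sites) == 0L) return(empty)
  el <- GenomicRanges::GRanges(elements$chrom,
                               IRanges::IRanges(elements$start,
                                                elements$end))
  pt <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(pt, el, ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  si <- S4Vectors::queryHits(hits)
  ei <- S4Vectors::subjectHits(hits)
  len <- elements$end[ei] - elements$start[ei] + 1L
  rel <- ifelse(elements$strand[ei] == "+",
                sites$pos[si] - elements$start[ei],
                elements$end[ei] - sites$pos[si])      # 0-based, 5'->3'
  bin <- pmin(n_bins, floor((rel + 0.5) / len * n_bins) + 1L)
  d <- data.frame(class = elements$class[ei], context = sites$context[si],
                  bin = as.integer(bin), ml = sites$ml[si],
                  stringsAsFactors = FALSE)
  agg <- aggregate(ml ~ class + context + bin, data = d,
                   FUN = function(x) c(mean(x), length(x)))
  data.frame(class = agg$class, context = agg$context, bin = agg$bin,
             mean_ml = agg$ml[, 1], n_sites = as.integer(agg$ml[, 2]),
             stringsAsFactors = FALSE)
}

#' Standard element interval set for metaprofiles
#'
#' Builds the interval table consumed by \code{\link{profile_elements}}:
#' gene spans (mRNA), 2-kb upstream (Up2k) and downstream (Down2k) flanks,
#' detected CpG islands, and optional repeats from a BED file. CDS intervals
#' are included when the gene table carries them.
#'
#' @param genes Gene model data.frame.
#' @param genome Optional genome for CpG-island detection and flank
#'   clipping.
#' @param repeats Optional repeat data.frame (chrom, start, end, 1-based) or
#'   path to a BED file; skipped when absent.
#' @param flank_size Flank size in bp (default 2000).
#' @return data.frame with columns class, chrom, start, end, strand.
#' @export
element_intervals <- function(genes, genome = NULL, repeats = NULL,
                              flank_size = 2000L) {
  chrom_len <- if (!is.null(genome))
    setNames(Biostrings::width(genome), names(genome)) else NULL
  fl <- build_flanks(genes, flank_size = flank_size,
                     chrom_lengths = chrom_len)
  out <- rbind(
    data.frame(class = "mRNA", chrom = genes$chrom, start = genes$start,
               end = genes$end, strand = genes$strand,
               stringsAsFactors = FALSE),
    data.frame(class = "Up2k", chrom = fl$chrom[fl$element == "Up2k"],
               start = fl$start[fl$element == "Up2k"],
               end = fl$end[fl$element == "Up2k"],
               strand = fl$strand[fl$element == "Up2k"],
               stringsAsFactors = FALSE),
    data.frame(class = "Down2k", chrom = fl$chrom[fl$element == "Down2k"],
               start = fl$start[fl$element == "Down2k"],
               end = fl$end[fl$element == "Down2k"],
               strand = fl$strand[fl$element == "Down2k"],
               stringsAsFactors = FALSE))
  if (!is.null(genome)) {
    isl <- detect_cpg_islands(genome)
    if (nrow(isl))
      out <- rbind(out, data.frame(class = "CpG_island", chrom = isl$chrom,
                                   start = isl$start, end = isl$end,
                                   strand = "+", stringsAsFactors = FALSE))
  }
  if (!is.null(repeats)) {
    rp <- if (is.character(repeats)) read_bed(repeats) else repeats
    if (nrow(rp))
      out <- rbind(out, data.frame(class = "repeat", chrom = rp$chrom,
                                   start = rp$start, end = rp$end,
                                   strand = "+", stringsAsFactors = FALSE))
  }
  out
}
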