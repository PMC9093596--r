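#' Two-sided Fisher exact test p-value for 2x2 count tables
#'
#' Conditional exact test on the table \code{[[m_a, u_a], [m_b, u_b]]}
#' (methylated/unmethylated reads in samples A and B). The two-sided p-value
#' sums the hypergeometric probabilities of all tables with the observed
#' margins that are no more probable than the observed one (the same
#' convention as \code{stats::fisher.test}), evaluated via \code{dhyper}
#' over the full support. Vectorised over rows; orders of magnitude faster
#' than \code{fisher.test} for many large-count tables.
#'
#' @param m_a,u_a,m_b,u_b Non-negative integer vectors.
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher_exact_p <- function(m_a, u_a, m_b, u_b) {
  n <- length(m_a)
  stopifnot(length(u_a) == n, length(m_b) == n, length(u_b) == n)
  counts <- cbind(m_a, u_a, m_b, u_b)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  p <- numeric(n)
  for (i in seq_len(n)) {
    M <- m_a[i] + m_b[i]            # methylated margin
    U <- u_a[i] + u_b[i]            # unmethylated margin
    Ta <- m_a[i] + u_a[i]           # sample A reads
    if (M + U == 0L) { p[i] <- 1; next }
    lo <- max(0L, Ta - U)
    hi <- min(Ta, M)
    d <- dhyper(lo:hi, M, U, Ta)
    p[i] <- min(1, sum(d[d <= d[m_a[i] - lo + 1L] * (1 + 1e-7)]))
  }
  p
}

#' Degree of difference between two methylation levels
#'
#' log2 ratio of the two samples' methylation levels, with any zero level
#' replaced by 0.001 before taking the ratio. Positive values mean sample A
#' is hypermethylated relative to sample B.
#'
#' @param ml_a,ml_b Methylation levels in [0, 1]; vectorised.
#' @return \code{log2(ml_a' / ml_b')} with the zero substitution.
#' @examples
#' degree_of_difference(0.8, 0.2)  # 2
#' degree_of_difference(0.5, 0)    # log2(500)
#' @export
degree_of_difference <- function(ml_a, ml_b) {
  if (any(is.na(ml_a)) || any(is.na(ml_b)) ||
      any(ml_a < 0 | ml_a > 1) || any(ml_b < 0 | ml_b > 1))
    stop("methylation levels must lie in [0, 1]")
  log2(ifelse(ml_a > 0, ml_a, 0.001) / ifelse(ml_b > 0, ml_b, 0.001))
}

# joint covered-site table for one context: ML defined in BOTH samples
joint_sites <- function(meth_a, meth_b, context) {
  a <- meth_a[meth_a$context == context & !is.na(meth_a$ml), , drop = FALSE]
  b <- meth_b[meth_b$context == context & !is.na(meth_b$ml), , drop = FALSE]
  key_a <- paste(a$chrom, a$pos, a$strand)
  key_b <- paste(b$chrom, b$pos, b$strand)
  m <- match(key_a, key_b)
  keep <- !is.na(m)
  data.frame(chrom = a$chrom[keep], pos = a$pos[keep],
             strand = a$strand[keep],
             m_a = a$meth_reads[keep], t_a = a$total_reads[keep],
             m_b = b$meth_reads[m[keep]], t_b = b$total_reads[m[keep]],
             stringsAsFactors = FALSE)
}

#' Enumerate candidate windows for DMR testing
#'
#' Slides fixed windows (default 1 kb every 500 bp) along each chromosome
#' and keeps those containing at least \code{min_sites} cytosines of the
#' requested context with a defined methylation level in \emph{both}
#' samples. Read counts of the qualifying sites are pooled per window and
#' sample.
#'
#' @param meth_a,meth_b Methylomes from \code{\link{load_methylome}} on the
#'   same reference.
#' @param context One of "CG", "CHG", "CHH".
#' @param window_size,step Window geometry in bp.
#' @param min_sites Minimum covered sites per window (default 5).
#' @return data.frame: chrom, start, end, context, n_sites, pooled counts
#'   (\code{m_a}, \code{u_a}, \code{m_b}, \code{u_b}) and pooled levels
#'   \code{ml_a}, \code{ml_b}.
#' @export
enumerate_windows <- function(meth_a, meth_b, context,
                              window_size = 1000L, step = 500L,
                              min_sites = 5L) {
  if (window_size < 1L || step < 1L)
    stop("window_size and step must be positive")
  js <- joint_sites(meth_a, meth_b, context)
  out <- NULL
  for (chrom in unique(js$chrom)) {
    s <- js[js$chrom == chrom, , drop = FALSE]
    starts <- seq.int(1L, max(s$pos), by = step)
    win <- IRanges::IRanges(starts, width = window_size)
    hits <- IRanges::findOverlaps(IRanges::IRanges(s$pos, width = 1L), win)
    wi <- S4Vectors::subjectHits(hits)
    si <- S4Vectors::queryHits(hits)
    n_sites <- tabulate(wi, nbins = length(win))
    keep <- which(n_sites >= min_sites)
    if (!length(keep)) next
    sum_by <- function(x) {
      v <- rowsum(x[si], wi)
      out <- integer(length(win)); out[as.integer(rownames(v))] <- v
      out[keep]
    }
    m_a <- sum_by(s$m_a); t_a <- sum_by(s$t_a)
    m_b <- sum_by(s$m_b); t_b <- sum_by(s$t_b)
    out <- rbind(out, data.frame(
      chrom = chrom, start = starts[keep],
      end = starts[keep] + window_size - 1L, context = context,
      n_sites = n_sites[keep], m_a = m_a, u_a = t_a - m_a,
      m_b = m_b, u_b = t_b - m_b,
      ml_a = m_a / t_a, ml_b = m_b / t_b, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      n_sites = integer(), m_a = integer(), u_a = integer(),
                      m_b = integer(), u_b = integer(), ml_a = numeric(),
                      ml_b = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply the DMR criteria to candidate windows
#'
#' Computes the pooled-count Fisher exact p-value and the fold ratio
#' \code{max(ml_a, ml_b) / min(ml_a, ml_b)} (zero levels replaced by 0.001)
#' for each window; a window passes when the fold ratio is at least
#' \code{fold_threshold} and p is at most \code{p_threshold}.
#'
#' @param windows Output of \code{\link{enumerate_windows}}.
#' @param fold_threshold Minimum methylation-level fold change (default 2).
#' @param p_threshold Fisher p-value cutoff (default 0.05).
#' @param bh If \code{TRUE}, apply Benjamini-Hochberg adjustment to the
#'   window p-values before thresholding (off by default: the criterion is
#'   on raw p).
#' @return The windows with added \code{fold_ratio}, \code{p_value},
#'   \code{direction} and logical \code{pass} columns.
#' @export
test_windows <- function(windows, fold_threshold = 2, p_threshold = 0.05,
                         bh = FALSE) {
  if (nrow(windows) == 0L) {
    windows$fold_ratio <- numeric(); windows$p_value <- numeric()
    windows$direction <- character(); windows$pass <- logical()
    return(windows)
  }
  sub <- function(x) ifelse(x > 0, x, 0.001)
  windows$fold_ratio <- pmax(sub(windows$ml_a), sub(windows$ml_b)) /
    pmin(sub(windows$ml_a), sub(windows$ml_b))
  windows$p_value <- fisher_exact_p(windows$m_a, windows$u_a,
                                    windows$m_b, windows$u_b)
  p_use <- if (bh) p.adjust(windows$p_value, "BH") else windows$p_value
  windows$direction <- ifelse(windows$ml_a >= windows$ml_b, "hyper", "hypo")
  zero <- (windows$m_a + windows$u_a == 0L) | (windows$m_b + windows$u_b == 0L)
  windows$pass <- !zero & windows$fold_ratio >= fold_threshold &
    p_use <= p_threshold
  windows
}

#' Iteratively merge interdependent windows into final DMRs
#'
#' Passing windows of the same context and direction that overlap or lie
#' within \code{merge_gap} bp of each other are interdependent and merged
#' into one region. Pooled counts of each merged region are recomputed from
#' the underlying covered sites and both criteria are re-applied; regions
#' failing the re-test are dropped. Merging and re-testing repeat until the
#' surviving regions are mutually independent (a fixpoint).
#'
#' @param windows Tested windows (\code{\link{test_windows}}); only rows
#'   with \code{pass} are used.
#' @param sites Joint site table for the same context (internal form as
#'   produced by the window enumerator); required to recompute pooled
#'   counts. Supply \code{meth_a}/\code{meth_b} instead to have it built.
#' @param meth_a,meth_b Methylomes, used when \code{sites} is NULL.
#' @param fold_threshold,p_threshold Criteria for the re-test.
#' @param merge_gap Maximum gap (bp) still considered interdependent
#'   (default 0: overlapping or book-ended).
#' @return data.frame of DMRs: chrom, start, end, context, direction,
#'   n_sites, n_windows, pooled levels \code{ml_a}/\code{ml_b},
#'   \code{p_value}, \code{fold_ratio}, \code{degree_of_difference}.
#' @export
merge_interdependent <- function(windows, sites = NULL, meth_a = NULL,
                                 meth_b = NULL, fold_threshold = 2,
                                 p_threshold = 0.05, merge_gap = 0L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      direction = character(), n_sites = integer(),
                      n_windows = integer(), ml_a = numeric(),
                      ml_b = numeric(), p_value = numeric(),
                      fold_ratio = numeric(),
                      degree_of_difference = numeric(),
                      stringsAsFactors = FALSE)
  w <- windows[windows$pass %in% TRUE, , drop = FALSE]
  if (nrow(w) == 0L) return(empty)
  context <- unique(w$context)
  if (length(context) != 1L)
    stop("merge_interdependent expects windows from a single context")
  if (is.null(sites)) {
    if (is.null(meth_a) || is.null(meth_b))
      stop("supply either 'sites' or both methylomes")
    sites <- joint_sites(meth_a, meth_b, context)
  }
  regions <- w[, c("chrom", "start", "end", "direction")]
  region_key <- function(r) sort(paste(r$chrom, r$start, r$end, r$direction))
  repeat {
    merged <- NULL
    for (dir in unique(regions$direction)) {
      r <- regions[regions$direction == dir, , drop = FALSE]
      gr <- GenomicRanges::GRanges(r$chrom,
                                   IRanges::IRanges(r$start, r$end))
      red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
      merged <- rbind(merged, data.frame(
        chrom = as.character(GenomicRanges::seqnames(red)),
        start = GenomicRanges::start(red), end = GenomicRanges::end(red),
        direction = dir, stringsAsFactors = FALSE))
    }
    stats <- region_stats(merged, sites)
    sub <- function(x) ifelse(x > 0, x, 0.001)
    fold <- pmax(sub(stats$ml_a), sub(stats$ml_b)) /
      pmin(sub(stats$ml_a), sub(stats$ml_b))
    pval <- fisher_exact_p(stats$m_a, stats$u_a, stats$m_b, stats$u_b)
    ok <- fold >= fold_threshold & pval <= p_threshold &
      ifelse(stats$ml_a >= stats$ml_b, "hyper", "hypo") == merged$direction
    nxt <- merged[ok, , drop = FALSE]
    if (nrow(nxt) == 0L) return(empty)
    if (identical(region_key(nxt), region_key(regions))) {
      stats <- stats[ok, , drop = FALSE]
      fold <- fold[ok]; pval <- pval[ok]
      gr <- GenomicRanges::GRanges(nxt$chrom,
                                   IRanges::IRanges(nxt$start, nxt$end))
      wg <- GenomicRanges::GRanges(w$chrom,
                                   IRanges::IRanges(w$start, w$end))
      nw <- GenomicRanges::countOverlaps(gr, wg)
      out <- data.frame(chrom = nxt$chrom, start = nxt$start,
                        end = nxt$end, context = context,
                        direction = nxt$direction,
                        n_sites = stats$n_sites, n_windows = nw,
                        ml_a = stats$ml_a, ml_b = stats$ml_b,
                        p_value = pval, fold_ratio = fold,
                        degree_of_difference =
                          degree_of_difference(stats$ml_a, stats$ml_b),
                        stringsAsFactors = FALSE)
      out <- out[order(out$chrom, out$start), , drop = FALSE]
      rownames(out) <- NULL
      return(out)
    }
    regions <- nxt
  }
}

# pooled counts of covered sites within each region
region_stats <- function(regions, sites) {
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  pt <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr, pt)
  ri <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  acc <- function(x) {
    out <- numeric(nrow(regions))
    if (length(ri)) {
      v <- rowsum(x[si], ri)
      out[as.integer(rownames(v))] <- v
    }
    out
  }
  m_a <- acc(sites$m_a); t_a <- acc(sites$t_a)
  m_b <- acc(sites$m_b); t_b <- acc(sites$t_b)
  data.frame(n_sites = as.integer(acc(rep(1L, nrow(sites)))),
             m_a = m_a, u_a = t_a - m_a, m_b = m_b, u_b = t_b - m_b,
             ml_a = ifelse(t_a > 0, m_a / t_a, 0),
             ml_b = ifelse(t_b > 0, m_b / t_b, 0))
}

#' Call differentially methylated regions between two methylomes
#'
#' Full caller: for each requested context, enumerate sliding windows with
#' at least \code{min_sites} jointly covered cytosines, test each window
#' (pooled-count Fisher exact test at \code{p_threshold} plus a
#' \code{fold_threshold}-fold methylation-level change), then iteratively
#' merge interdependent passing windows into independent DMRs, re-testing
#' after each merge.
#'
#' @inheritParams enumerate_windows
#' @inheritParams test_windows
#' @inheritParams merge_interdependent
#' @param contexts Contexts to call (default all three).
#' @return data.frame of DMRs across contexts (see
#'   \code{\link{merge_interdependent}}), sorted by chrom, start, context.
#' @export
call_dmrs <- function(meth_a, meth_b, contexts = c("CG", "CHG", "CHH"),
                      window_size = 1000L, step = 500L, min_sites = 5L,
                      fold_threshold = 2, p_threshold = 0.05,
                      merge_gap = 0L, bh = FALSE) {
  res <- lapply(contexts, function(cx) {
    js <- joint_sites(meth_a, meth_b, cx)
    w <- enumerate_windows(meth_a, meth_b, cx, window_size = window_size,
                           step = step, min_sites = min_sites)
    w <- test_windows(w, fold_threshold = fold_threshold,
                      p_threshold = p_threshold, bh = bh)
    merge_interdependent(w, sites = js, fold_threshold = fold_threshold,
                         p_threshold = p_threshold, merge_gap = merge_gap)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$context), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-chromosome, per-context DMR counts
#'
#' @param dmrs DMR data.frame from \code{\link{call_dmrs}}.
#' @param chroms,contexts Optional level sets to force zero rows.
#' @return data.frame chrom, context, n; total equals \code{nrow(dmrs)}.
#' @export
dmr_chromosome_distribution <- function(dmrs, chroms = NULL,
                                        contexts = c("CG", "CHG", "CHH")) {
  chroms <- chroms %||% sort(unique(dmrs$chrom))
  tab <- table(factor(dmrs$chrom, levels = chroms),
               factor(dmrs$context, levels = contexts))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("chrom", "context", "n")
  out$n <- as.integer(out$n)
  out[order(out$chrom, out$context), , drop = FALSE]
}

#' Compare called DMRs with planted truth by reciprocal overlap
#'
#' A called DMR matches a planted interval when their intersection covers at
#' least \code{min_reciprocal} of \emph{both} intervals. Context is ignored
#' (a planted region shifts every context); direction must agree.
#'
#' @param called DMR data.frame (chrom, start, end, direction).
#' @param truth Planted-DMR data.frame (chrom, start, end, direction).
#' @param min_reciprocal Reciprocal overlap fraction (default 0.5).
#' @return List with \code{recall}, \code{precision}, \code{n_called},
#'   \code{n_truth}.
#' @export
dmr_recovery <- function(called, truth, min_reciprocal = 0.5) {
  if (nrow(truth) == 0L)
    return(list(recall = NA_real_, precision = NA_real_,
                n_called = nrow(called), n_truth = 0L))
  if (nrow(called) == 0L)
    return(list(recall = 0, precision = NA_real_, n_called = 0L,
                n_truth = nrow(truth)))
  cg <- GenomicRanges::GRanges(called$chrom,
                               IRanges::IRanges(called$start, called$end))
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start, truth$end))
  hits <- GenomicRanges::findOverlaps(cg, tg)
  ci <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(cg)[ci],
                                           IRanges::ranges(tg)[ti]))
  good <- ov >= min_reciprocal * IRanges::width(IRanges::ranges(cg)[ci]) &
    ov >= min_reciprocal * IRanges::width(IRanges::ranges(tg)[ti]) &
    called$direction[ci] == truth$direction[ti]
  list(recall = length(unique(ti[good])) / nrow(truth),
       precision = length(unique(ci[good])) / nrow(called),
       n_called = nrow(called), n_truth = nrow(truth))
}
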