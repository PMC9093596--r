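# Independent oracles, kept deliberately naive and separate from the
# package's implementations.

# Two-sided Fisher p by explicit combinatorial enumeration (choose(), no
# dhyper): sum of probabilities of all tables with the observed margins
# that are no more probable than the observed table.
fisher_oracle <- function(m_a, u_a, m_b, u_b) {
  M <- m_a + m_b; U <- u_a + u_b; Ta <- m_a + u_a; N <- M + U
  if (N == 0) return(1)
  k <- max(0, Ta - U):min(Ta, M)
  prob <- choose(M, k) * choose(U, Ta - k) / choose(N, Ta)
  p_obs <- prob[k == m_a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Hypergeometric upper tail P(X >= k) by direct summation of the pmf
# written out in factorials.
hyper_tail_oracle <- function(k, n, K, N) {
  if (k <= 0) return(1)
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk) / choose(N, n))
}

# Per-position context calls by literal trinucleotide case analysis on one
# strand; minus strand handled by reverse-complementing the sequence.
context_oracle <- function(seq, pos, strand) {
  rc <- function(x) chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]),
                                                   collapse = ""))
  n <- nchar(seq)
  if (strand == "-") {
    return(context_oracle(rc(seq), n - pos + 1L, "+"))
  }
  if (pos + 2L > n) return(NA_character_)
  tri <- substr(seq, pos, pos + 2L)
  b2 <- substr(tri, 2, 2); b3 <- substr(tri, 3, 3)
  if (b2 == "G") return("CG")
  if (!b2 %in% c("A", "C", "T")) return(NA_character_)
  if (b3 == "G") return("CHG")
  if (b3 %in% c("A", "C", "T")) return("CHH")
  NA_character_
}

# Transitive-closure interval merging by brute force (quadratic), used to
# check the reduce-based window merging.
merge_oracle <- function(start, end, gap = 0L) {
  n <- length(start)
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (group[i] != group[j] &&
          start[j] <= end[i] + gap + 1L && start[i] <= end[j] + gap + 1L) {
        group[group == group[j]] <- group[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(group), function(g)
    data.frame(start = min(start[group == g]),
               end = max(end[group == g]))))
  out[order(out$start), , drop = FALSE]
}
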