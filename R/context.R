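#' Classify the sequence context of a cytosine
#'
#' Assigns the CG / CHG / CHH context of a cytosine from its reference
#' sequence, reading in the strand sense (H is A, C or T). A cytosine on the
#' minus strand appears as G in the plus-strand reference and its context is
#' read leftwards on the complement. Sites with fewer than two downstream
#' bases (strand sense) or an ambiguous base (N) in the trinucleotide are
#' undefined and returned as \code{NA}.
#'
#' @param sequence A single chromosome sequence: a character string or a
#'   \code{Biostrings::DNAString}.
#' @param pos 1-based position(s) of the cytosine on the plus-strand
#'   reference. Vectorised.
#' @param strand \code{"+"} or \code{"-"}, recycled along \code{pos}.
#' @return Character vector of \code{"CG"}, \code{"CHG"}, \code{"CHH"} or
#'   \code{NA} (undefined).
#' @examples
#' classify_context("ACGTA", 2, "+")  # "CG"
#' classify_context("ACAGT", 2, "+")  # "CHG"
#' classify_context("TACGT", 4, "-")  # "CG" read on the minus strand
#' @export
classify_context <- function(sequence, pos, strand) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (any(pos < 1L | pos > n))
    stop("position out of bounds (sequence length ", n, ")")
  strand <- rep_len(strand, length(pos))
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  base <- substring(s, pos, pos)
  expect <- ifelse(strand == "+", "C", "G")
  if (any(base != expect))
    stop("base at position ", pos[which(base != expect)[1]],
         " is not a cytosine on the ", strand[which(base != expect)[1]],
         " strand")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  classify_context_vec(chars, pos, strand)
}

# vectorised worker over a pre-split character vector; no input checks
classify_context_vec <- function(chars, pos, strand) {
  n <- length(chars)
  plus <- strand == "+"
  i1 <- ifelse(plus, pos + 1L, pos - 1L)  # first downstream, strand sense
  i2 <- ifelse(plus, pos + 2L, pos - 2L)
  ok <- ifelse(plus, i2 <= n, i2 >= 1L)
  b1 <- b2 <- rep(NA_character_, length(pos))
  b1[ok] <- chars[i1[ok]]
  b2[ok] <- chars[i2[ok]]
  # on the minus strand a downstream G reads as reference C, H as non-C
  g1 <- ifelse(plus, b1 == "G", b1 == "C")
  g2 <- ifelse(plus, b2 == "G", b2 == "C")
  h1 <- ifelse(plus, b1 %in% c("A", "C", "T"), b1 %in% c("A", "G", "T"))
  h2 <- ifelse(plus, b2 %in% c("A", "C", "T"), b2 %in% c("A", "G", "T"))
  out <- rep(NA_character_, length(pos))
  out[ok & g1] <- "CG"
  out[ok & h1 & g2] <- "CHG"
  out[ok & h1 & h2] <- "CHH"
  out
}

#' Enumerate all cytosines of a genome with context and trinucleotide
#'
#' Scans every chromosome on both strands and returns one row per cytosine
#' whose context is defined. The trinucleotide is reported in the strand
#' sense (so it always starts with C).
#'
#' @param genome A named \code{DNAStringSet} (or named character vector) of
#'   chromosome sequences.
#' @return A \code{data.frame} with columns \code{chrom}, \code{pos}
#'   (1-based, plus-strand coordinates), \code{strand}, \code{context},
#'   \code{trinucleotide}, sorted by chromosome then position.
#' @export
genome_cytosines <- function(genome) {
  seqs <- as.character(genome)
  if (is.null(names(seqs))) stop("genome sequences must be named")
  res <- lapply(names(seqs), function(chrom) {
    chars <- strsplit(toupper(seqs[[chrom]]), "", fixed = TRUE)[[1]]
    pos_p <- which(chars == "C")
    pos_m <- which(chars == "G")
    pos <- c(pos_p, pos_m)
    strand <- rep(c("+", "-"), c(length(pos_p), length(pos_m)))
    ctx <- classify_context_vec(chars, pos, strand)
    keep <- !is.na(ctx)
    pos <- pos[keep]; strand <- strand[keep]; ctx <- ctx[keep]
    tri <- character(length(pos))
    p <- strand == "+"
    tri[p] <- paste0(chars[pos[p]], chars[pos[p] + 1L], chars[pos[p] + 2L])
    tri[!p] <- paste0(comp(chars[pos[!p]]), comp(chars[pos[!p] - 1L]),
                      comp(chars[pos[!p] - 2L]))
    data.frame(chrom = chrom, pos = pos, strand = strand, context = ctx,
               trinucleotide = tri, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

comp <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

revcomp <- function(x) {
  vapply(strsplit(toupper(x), "", fixed = TRUE),
         function(ch) paste(rev(comp(ch)), collapse = ""), character(1))
}
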