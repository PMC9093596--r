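#' Read a cytosine report
#'
#' Parses the 7-column Bismark-CX-style tab-separated dialect: chrom,
#' 1-based position, strand (+/-), methylated count, unmethylated count,
#' context (CG/CHG/CHH), trinucleotide. Gzip input is decoded
#' transparently. Malformed lines (wrong column count, non-integer or
#' negative counts, unknown strand or context) raise an error naming the
#' offending line.
#'
#' @param path File path (.gz allowed).
#' @return data.frame: chrom, pos, strand, meth_reads, total_reads,
#'   context, trinucleotide.
#' @export
read_cytosine_report <- function(path) {
  magic <- readBin(path, "raw", 2L)
  dt <- if (identical(magic, as.raw(c(0x1f, 0x8b)))) {
    utils::read.delim(gzfile(path), header = FALSE, sep = "\t",
                      colClasses = "character")
  } else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = "character", data.table = FALSE)
  }
  if (ncol(dt) != 7L)
    stop("cytosine report must have 7 tab-separated columns, found ",
         ncol(dt))
  names(dt) <- c("chrom", "pos", "strand", "meth", "unmeth", "context",
                 "trinucleotide")
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop("line ", bad[1], ": ", what, " is not a non-negative integer: '",
           dt[[col]][bad[1]], "'")
    as.integer(v)
  }
  pos <- num("pos", "position")
  meth <- num("meth", "methylated count")
  unmeth <- num("unmeth", "unmethylated count")
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop("line ", bad[1], ": unknown strand '", dt$strand[bad[1]], "'")
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad))
    stop("line ", bad[1], ": unknown context '", dt$context[bad[1]], "'")
  validate_cx(data.frame(chrom = dt$chrom, pos = pos, strand = dt$strand,
                         meth_reads = meth, total_reads = meth + unmeth,
                         context = dt$context,
                         trinucleotide = dt$trinucleotide,
                         stringsAsFactors = FALSE))
}

validate_cx <- function(sites) {
  need <- c("chrom", "pos", "strand", "meth_reads", "total_reads",
            "context")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("site table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(sites$meth_reads > sites$total_reads)
  if (length(bad))
    stop("line ", bad[1], ": methylated count exceeds total reads")
  if (is.null(sites$trinucleotide)) sites$trinucleotide <- NA_character_
  sites
}

#' Write a cytosine report
#'
#' Inverse of \code{\link{read_cytosine_report}}; rows are sorted by
#' chromosome and position and positions must be strictly increasing
#' within each chromosome (one row per cytosine; plus- and minus-strand
#' cytosines occupy distinct reference positions).
#'
#' @param sites Site data.frame (internal form, with meth_reads /
#'   total_reads).
#' @param path Output path; a ".gz" suffix compresses.
#' @return Invisibly, \code{path}.
#' @export
write_cytosine_report <- function(sites, path) {
  sites <- validate_cx(sites)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  dup <- stats::ave(sites$pos, sites$chrom,
                    FUN = function(x) c(1L, diff(x)))
  if (any(dup <= 0L))
    stop("positions must be strictly increasing within a chromosome")
  out <- data.frame(sites$chrom, sites$pos, sites$strand, sites$meth_reads,
                    sites$total_reads - sites$meth_reads, sites$context,
                    sites$trinucleotide)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else
                       "none")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses \code{rtracklayer::readGFF} and keeps \code{gene} features; every
#' gene must carry an \code{ID} attribute. Models are returned sorted by
#' chromosome and start regardless of file order.
#'
#' @param path GFF3 file.
#' @return data.frame: gene_id, chrom, strand, start, end.
#' @export
read_gff3 <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0L) stop("no 'gene' features in ", path)
  if (is.null(g$ID) || any(is.na(g$ID) | g$ID == ""))
    stop("gene feature without ID attribute (e.g. ", path, " line for ",
         g$seqid[which(is.na(g$ID) | g$ID == "")[1]], ":",
         g$start[which(is.na(g$ID) | g$ID == "")[1]], ")")
  out <- data.frame(gene_id = as.character(g$ID),
                    chrom = as.character(g$seqid),
                    strand = as.character(g$strand),
                    start = g$start, end = g$end, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene models as GFF3
#'
#' @param genes data.frame: gene_id, chrom, strand, start, end.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tbsdmr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Convert 1-based inclusive intervals to BED and back
#'
#' Internal coordinates are 1-based inclusive (cytosine-report and GFF3
#' convention); BED is 0-based half-open. The pair of helpers is exact and
#' mutually inverse.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return For \code{to_bed}: list(start, end) 0-based half-open; for
#'   \code{from_bed}: list(start, end) 1-based inclusive.
#' @name bed_coords
NULL

#' @rdname bed_coords
#' @export
to_bed <- function(start, end) list(start = start - 1L, end = end)

#' @rdname bed_coords
#' @param bed_start,bed_end 0-based half-open coordinates.
#' @export
from_bed <- function(bed_start, bed_end) list(start = bed_start + 1L,
                                              end = bed_end)

#' Write intervals as BED6
#'
#' @param intervals data.frame with chrom, start, end (1-based inclusive)
#'   and optional name/score columns; strandless records get strand ".".
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(intervals, path) {
  b <- to_bed(intervals$start, intervals$end)
  name <- intervals$name %||% "."
  score <- intervals$score %||% 0
  strand <- intervals$strand %||% "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", intervals$chrom, b$start,
                   b$end, name, format(score, trim = TRUE), strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED file (3+ columns).
#' @return data.frame: chrom, start, end (1-based inclusive), and name
#'   where present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write called DMRs as BED6 plus a full TSV
#'
#' The BED name is \code{context:direction} and the score is
#' \code{-log10(p)} (capped at 1000); strand is ".". The TSV carries the
#' complete DMR table.
#'
#' @param dmrs DMR data.frame from \code{\link{call_dmrs}}.
#' @param bed_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the written paths.
#' @export
write_dmrs <- function(dmrs, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    iv <- data.frame(chrom = dmrs$chrom, start = dmrs$start,
                     end = dmrs$end,
                     name = paste0(dmrs$context, ":", dmrs$direction),
                     score = round(pmin(1000, -log10(pmax(dmrs$p_value,
                                                          1e-300)))),
                     strand = ".", stringsAsFactors = FALSE)
    write_bed(iv, bed_path)
  }
  if (!is.null(tsv_path))
    utils::write.table(dmrs, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read a DEG table
#'
#' Tab-separated with a header containing at least gene_id, log2fc and one
#' of p_adj / padj / p.
#'
#' @param path TSV path (.gz allowed).
#' @return data.frame with gene_id, log2fc, p (if present), p_adj.
#' @export
read_deg_table <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  names(d)[names(d) == "padj"] <- "p_adj"
  if (!all(c("gene_id", "log2fc") %in% names(d)))
    stop("DEG table needs gene_id and log2fc columns")
  if (!"p_adj" %in% names(d)) {
    if (!"p" %in% names(d)) stop("DEG table needs p_adj or p")
    d$p_adj <- p.adjust(d$p, "BH")
  }
  d
}

#' Read a term-annotation map
#'
#' Tab-separated with header gene_id, term_id, term_name and optional
#' category.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_term_annotations <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(d)))
    stop("term annotation needs gene_id and term_id columns")
  if (is.null(d$term_name)) d$term_name <- d$term_id
  d
}
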