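#' Strand-aware 2-kb flanks of gene models
#'
#' Derives the upstream (Up2k, the promoter proxy) and downstream (Down2k)
#' flank of each gene: on the plus strand Up2k is
#' \code{[start - flank_size, start - 1]} and Down2k is
#' \code{[end + 1, end + flank_size]}; on the minus strand the two are
#' mirrored. Intervals are clipped at chromosome bounds and dropped when
#' fully off-chromosome.
#'
#' @param genes data.frame with gene_id, chrom, strand, start, end.
#' @param flank_size Flank width in bp (default 2000).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   right-side clipping.
#' @return data.frame: gene_id, chrom, strand, element ("Up2k"/"Down2k"),
#'   start, end.
#' @export
build_flanks <- function(genes, flank_size = 2000L, chrom_lengths = NULL) {
  stopifnot(all(genes$start <= genes$end),
            all(genes$strand %in% c("+", "-")))
  plus <- genes$strand == "+"
  up_s <- ifelse(plus, genes$start - flank_size, genes$end + 1L)
  up_e <- ifelse(plus, genes$start - 1L, genes$end + flank_size)
  dn_s <- ifelse(plus, genes$end + 1L, genes$start - flank_size)
  dn_e <- ifelse(plus, genes$end + flank_size, genes$start - 1L)
  out <- data.frame(
    gene_id = rep(genes$gene_id, 2), chrom = rep(genes$chrom, 2),
    strand = rep(genes$strand, 2),
    element = rep(c("Up2k", "Down2k"), each = nrow(genes)),
    start = c(up_s, dn_s), end = c(up_e, dn_e), stringsAsFactors = FALSE)
  out$start <- pmax(out$start, 1L)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[out$chrom]
    out$end <- pmin(out$end, as.integer(len))
  }
  out <- out[out$start <= out$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate DMRs with gene bodies and promoters
#'
#' A DMR overlapping a gene body (the full transcriptional span) by at
#' least one bp yields a gene_body association; overlapping the gene's
#' Up2k promoter yields a promoter association. The two categories are
#' independent: one DMR can produce both, and a DMR overlapping several
#' genes associates with all of them. Genes carrying at least one
#' association are differentially methylated genes (DMGs), labelled
#' hyper/hypo from the DMR direction.
#'
#' @param dmrs DMR data.frame (chrom, start, end, direction, and optionally
#'   context, degree_of_difference).
#' @param genes Gene model data.frame.
#' @param flank_size Promoter size in bp (default 2000).
#' @param chrom_lengths Optional named lengths for flank clipping.
#' @return List with \code{associations} (one row per DMR-gene-category
#'   hit: dmr_id, chrom, start, end, context, direction,
#'   degree_of_difference, gene_id, association) and \code{counts}
#'   (n_gene_dmrs / n_promoter_dmrs: DMRs with at least one association of
#'   that category; n_dmg: distinct associated genes).
#' @export
associate_dmrs <- function(dmrs, genes, flank_size = 2000L,
                           chrom_lengths = NULL) {
  if (nrow(dmrs) && nrow(genes) &&
      !any(unique(dmrs$chrom) %in% unique(genes$chrom)))
    stop("no shared chromosome names between DMRs and genes; DMR chroms: ",
         paste(unique(dmrs$chrom), collapse = ","), " vs gene chroms: ",
         paste(unique(genes$chrom), collapse = ","))
  dmr_id <- if (nrow(dmrs))
    paste0(dmrs$chrom, ":", dmrs$start, "-", dmrs$end,
           if (!is.null(dmrs$context)) paste0(":", dmrs$context) else "")
  else character()
  fl <- build_flanks(genes, flank_size = flank_size,
                     chrom_lengths = chrom_lengths)
  prom <- fl[fl$element == "Up2k", , drop = FALSE]
  targets <- rbind(
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = genes$start, end = genes$end,
               association = "gene_body", stringsAsFactors = FALSE),
    data.frame(gene_id = prom$gene_id, chrom = prom$chrom,
               start = prom$start, end = prom$end,
               association = "promoter", stringsAsFactors = FALSE))
  assoc <- data.frame(dmr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      context = character(), direction = character(),
                      degree_of_difference = numeric(),
                      gene_id = character(), association = character(),
                      stringsAsFactors = FALSE)
  if (nrow(dmrs) && nrow(targets)) {
    dg <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start, dmrs$end))
    tg <- GenomicRanges::GRanges(targets$chrom,
                                 IRanges::IRanges(targets$start,
                                                  targets$end))
    hits <- GenomicRanges::findOverlaps(dg, tg)
    di <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
    assoc <- data.frame(
      dmr_id = dmr_id[di], chrom = dmrs$chrom[di], start = dmrs$start[di],
      end = dmrs$end[di],
      context = if (!is.null(dmrs$context)) dmrs$context[di] else
        NA_character_,
      direction = dmrs$direction[di],
      degree_of_difference = if (!is.null(dmrs$degree_of_difference))
        dmrs$degree_of_difference[di] else NA_real_,
      gene_id = targets$gene_id[ti], association = targets$association[ti],
      stringsAsFactors = FALSE)
    assoc <- assoc[order(assoc$chrom, assoc$start, assoc$gene_id,
                         assoc$association), , drop = FALSE]
    rownames(assoc) <- NULL
  }
  counts <- list(
    n_gene_dmrs = length(unique(
      assoc$dmr_id[assoc$association == "gene_body"])),
    n_promoter_dmrs = length(unique(
      assoc$dmr_id[assoc$association == "promoter"])),
    n_dmg = length(unique(assoc$gene_id)))
  list(associations = assoc, counts = counts)
}

#' Hyper/hypo DMG counts by subgroup
#'
#' Tabulates distinct genes per subgroup (gene body vs promoter) and
#' methylation direction. A gene with both hyper and hypo DMRs in one
#' subgroup is counted in both direction tallies.
#'
#' @param associations Association data.frame from
#'   \code{\link{associate_dmrs}}.
#' @return data.frame: association, direction, n_genes (all four cells,
#'   zero-filled).
#' @export
dmg_direction_table <- function(associations) {
  u <- unique(associations[, c("gene_id", "association", "direction")])
  tab <- table(factor(u$association, levels = c("gene_body", "promoter")),
               factor(u$direction, levels = c("hyper", "hypo")))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("association", "direction", "n_genes")
  out$n_genes <- as.integer(out$n_genes)
  out[order(out$association, out$direction), , drop = FALSE]
}

#' Detect CpG islands by the classical sliding-window rule
#'
#' Scans 200-bp windows at single-bp steps and marks those with G+C
#' fraction >= \code{min_gc}, observed/expected CpG ratio >=
#' \code{min_obs_exp} (obs/exp = n_CpG * L / (n_C * n_G)), and merges
#' maximal runs of qualifying windows into islands (always >=
#' \code{min_length} bp by construction). Island-level GC and obs/exp are
#' recomputed over the merged interval.
#'
#' @param genome Named \code{DNAStringSet} or character vector.
#' @param min_length Minimum island length (default 200).
#' @param min_gc Minimum G+C fraction (default 0.5).
#' @param min_obs_exp Minimum observed/expected CpG (default 0.6).
#' @param window Window size in bp (default 200).
#' @return data.frame: chrom, start, end, length, gc_fraction, obs_exp_cpg.
#' @export
detect_cpg_islands <- function(genome, min_length = 200L, min_gc = 0.5,
                               min_obs_exp = 0.6, window = 200L) {
  seqs <- as.character(genome)
  res <- lapply(names(seqs), function(chrom) {
    chars <- strsplit(toupper(seqs[[chrom]]), "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n < window) return(NULL)
    isC <- as.integer(chars == "C"); isG <- as.integer(chars == "G")
    isCG <- as.integer(isC == 1L & c(isG[-1], 0L) == 1L)
    csC <- cumsum(isC); csG <- cumsum(isG); csCG <- cumsum(isCG)
    starts <- seq_len(n - window + 1L)
    ends <- starts + window - 1L
    wsum <- function(cs) cs[ends] - c(0, cs)[starts]
    nC <- wsum(csC); nG <- wsum(csG)
    # CpG starts fully inside the window
    nCG <- (csCG[ends - 1L] - c(0, csCG)[starts])
    gc <- (nC + nG) / window
    oe <- ifelse(nC > 0 & nG > 0, nCG * window / (nC * nG), 0)
    ok <- gc >= min_gc & oe >= min_obs_exp
    if (!any(ok)) return(NULL)
    red <- IRanges::reduce(IRanges::IRanges(starts[ok], ends[ok]))
    s <- IRanges::start(red); e <- IRanges::end(red)
    L <- e - s + 1L
    iC <- csC[e] - c(0, csC)[s]; iG <- csG[e] - c(0, csG)[s]
    iCG <- csCG[e - 1L] - c(0, csCG)[s]
    isl <- data.frame(chrom = chrom, start = s, end = e, length = L,
                      gc_fraction = (iC + iG) / L,
                      obs_exp_cpg = ifelse(iC > 0 & iG > 0,
                                           iCG * L / (iC * iG), 0),
                      stringsAsFactors = FALSE)
    isl[isl$length >= min_length, , drop = FALSE]
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      gc_fraction = numeric(), obs_exp_cpg = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
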