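#' Classify differentially expressed genes
#'
#' Applies the standard two-sided thresholds: a gene is up-regulated when
#' \code{log2fc >= log2(fc_threshold)} and \code{p_adj <= padj_threshold},
#' down-regulated when \code{log2fc <= -log2(fc_threshold)} with the same
#' adjusted-p rule, otherwise not significant. Fold-change orientation is
#' sample A over sample B.
#'
#' @param deg_table data.frame with \code{gene_id}, \code{log2fc} and
#'   \code{p_adj} (a \code{p} column plus \code{adjust = TRUE} may be used
#'   instead of \code{p_adj}).
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @param padj_threshold Adjusted-p threshold (default 0.05).
#' @param adjust If \code{TRUE}, BH-adjust the \code{p} column to obtain
#'   \code{p_adj}.
#' @return The table with a \code{status} factor column (up/down/ns).
#' @export
classify_degs <- function(deg_table, fc_threshold = 2,
                          padj_threshold = 0.05, adjust = FALSE) {
  need <- c("gene_id", "log2fc", if (adjust) "p" else "p_adj")
  miss <- setdiff(need, names(deg_table))
  if (length(miss))
    stop("DEG table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (adjust) deg_table$p_adj <- p.adjust(deg_table$p, "BH")
  lfc_cut <- log2(fc_threshold)
  sig <- deg_table$p_adj <= padj_threshold
  deg_table$status <- ifelse(sig & deg_table$log2fc >= lfc_cut, "up",
                      ifelse(sig & deg_table$log2fc <= -lfc_cut, "down",
                             "ns"))
  deg_table
}

#' Minimal two-group differential expression test
#'
#' Plumbing for synthetic end-to-end runs only: not a replacement for a
#' dispersion-aware model. Log2 fold change is the ratio of library-size
#' normalised condition means with a pseudocount of 1; the p-value is a
#' two-sided exact binomial test of the summed counts of condition A
#' against the library-size expectation, BH-adjusted across genes.
#' All-zero genes get log2fc = 0 and p = 1.
#'
#' @param counts Integer matrix, genes x samples, with rownames.
#' @param condition Vector of "A"/"B" labels, one per column.
#' @return data.frame: gene_id, log2fc, p, p_adj.
#' @export
simple_de_test <- function(counts, condition) {
  stopifnot(ncol(counts) == length(condition),
            all(condition %in% c("A", "B")),
            any(condition == "A"), any(condition == "B"))
  lib <- colSums(counts)
  scale <- mean(lib) / pmax(lib, 1)
  norm <- sweep(counts, 2, scale, `*`)
  mean_a <- rowMeans(norm[, condition == "A", drop = FALSE])
  mean_b <- rowMeans(norm[, condition == "B", drop = FALSE])
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  sum_a <- rowSums(counts[, condition == "A", drop = FALSE])
  sum_b <- rowSums(counts[, condition == "B", drop = FALSE])
  lib_a <- sum(lib[condition == "A"]); lib_b <- sum(lib[condition == "B"])
  prob <- lib_a / (lib_a + lib_b)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    tot <- sum_a[i] + sum_b[i]
    if (tot == 0) return(1)
    binom.test(sum_a[i], tot, p = prob)$p.value
  }, numeric(1))
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             log2fc = unname(lfc), p = p, p_adj = p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Per-gene methylation direction calls
#'
#' Collapses DMR-gene associations to one direction per gene and subgroup:
#' the DMR with the largest absolute degree of difference wins (when no
#' degree is available, directions are scored +/-1).
#'
#' @param associations Association table from \code{\link{associate_dmrs}}.
#' @return data.frame: gene_id, association, direction,
#'   degree_of_difference.
#' @export
dmg_directions <- function(associations) {
  if (nrow(associations) == 0L)
    return(data.frame(gene_id = character(), association = character(),
                      direction = character(),
                      degree_of_difference = numeric(),
                      stringsAsFactors = FALSE))
  a <- associations
  if (all(is.na(a$degree_of_difference)))
    a$degree_of_difference <- ifelse(a$direction == "hyper", 1, -1)
  key <- paste(a$gene_id, a$association)
  ord <- order(key, -abs(a$degree_of_difference))
  a <- a[ord, , drop = FALSE]
  first <- !duplicated(paste(a$gene_id, a$association))
  out <- a[first, c("gene_id", "association", "direction",
                    "degree_of_difference"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect differentially methylated and differentially expressed genes
#'
#' Joins DMGs (from \code{\link{associate_dmrs}}) with classified DEGs and
#' assigns each overlapping gene to the hyper/hypo x up/down grid, per
#' subgroup (gene body / promoter) and combined. A gene associated with
#' several DMRs in a subgroup takes the direction of the DMR with the
#' largest absolute degree of difference; a gene with hyper DMRs in one
#' subgroup and hypo in the other contributes to both strata of the
#' combined table.
#'
#' @param associations Association data.frame from
#'   \code{\link{associate_dmrs}}.
#' @param degs Classified DEG table (\code{\link{classify_degs}}).
#' @return List with \code{dmegs} (gene_id, association, direction,
#'   degree_of_difference, log2fc, status; only genes both DMG and
#'   up/down), \code{venn} (n_dmg, n_up, n_down, n_hyper_up, n_hyper_down,
#'   n_hypo_up, n_hypo_down over distinct genes) and \code{by_subgroup}
#'   (the same four cells split by gene body / promoter).
#' @export
intersect_dmg_deg <- function(associations, degs) {
  if (!"status" %in% names(degs))
    stop("DEG table must be classified first (see classify_degs)")
  dirs <- dmg_directions(associations)
  m <- match(dirs$gene_id, degs$gene_id)
  dirs$log2fc <- degs$log2fc[m]
  dirs$status <- degs$status[m]
  dmegs <- dirs[!is.na(dirs$status) & dirs$status %in% c("up", "down"), ,
                drop = FALSE]
  rownames(dmegs) <- NULL

  cell <- function(d, mdir, status) {
    length(unique(d$gene_id[d$direction == mdir & d$status == status]))
  }
  venn <- list(
    n_dmg = length(unique(dirs$gene_id)),
    n_up = sum(degs$status == "up"),
    n_down = sum(degs$status == "down"),
    n_hyper_up = cell(dmegs, "hyper", "up"),
    n_hyper_down = cell(dmegs, "hyper", "down"),
    n_hypo_up = cell(dmegs, "hypo", "up"),
    n_hypo_down = cell(dmegs, "hypo", "down"))
  by_sub <- do.call(rbind, lapply(c("gene_body", "promoter"), function(sg) {
    d <- dmegs[dmegs$association == sg, , drop = FALSE]
    data.frame(association = sg,
               n_hyper_up = cell(d, "hyper", "up"),
               n_hyper_down = cell(d, "hyper", "down"),
               n_hypo_up = cell(d, "hypo", "up"),
               n_hypo_down = cell(d, "hypo", "down"),
               stringsAsFactors = FALSE)
  }))
  list(dmegs = dmegs, venn = venn, by_subgroup = by_sub)
}

#' Rank correlation between methylation difference and expression change
#'
#' Spearman correlation of the gene-level degree of difference (methylation,
#' sample A over B) against the expression log2 fold change, with a
#' two-sided p-value (exact for n <= 9 without ties, t-approximation
#' otherwise). A negative coefficient indicates hypermethylation
#' accompanying reduced expression.
#'
#' @param joined data.frame with \code{degree_of_difference} and
#'   \code{log2fc} columns (e.g. the \code{dmegs} table, or the full
#'   DMG-DEG join).
#' @return List with \code{rho}, \code{p}, \code{n}, \code{method}; rho is
#'   \code{NA} when fewer than 3 pairs or a constant vector is supplied.
#' @export
methylation_expression_correlation <- function(joined) {
  x <- joined$degree_of_difference
  y <- joined$log2fc
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                method = "spearman (undefined)"))
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- cor.test(x, y, method = "spearman",
                 exact = n <= 9L && !ties)
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       method = "spearman")
}
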