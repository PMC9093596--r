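#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic two-sample
#' methylome study. Defaults describe a small plant-like design: two 500-kb
#' chromosomes, 100 well-separated genes, 50 planted DMRs of 2 kb that shift
#' the methylation level of sample A by +/- 0.4, 30x mean depth, an
#' imperfect bisulfite conversion rate of 0.995, and gene expression in
#' which promoter-hypermethylated genes are forced down-regulated for a
#' configurable fraction of the planted promoter-hyper DMRs.
#'
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param n_chromosomes,chromosome_length Number and length (bp) of
#'   chromosomes.
#' @param gc_fraction G+C fraction of the random genome, in (0,1).
#' @param n_genes,gene_length Number and length (bp) of non-overlapping
#'   genes; genes keep a minimum 5-kb gap so 2-kb flanks never touch a
#'   neighbouring gene.
#' @param baseline_ml Named vector of baseline methylation levels per
#'   context (defaults CG 0.7, CHG 0.5, CHH 0.1).
#' @param n_dmrs,dmr_length,dmr_delta Planted differential regions: count,
#'   length (bp), and the methylation-level shift applied to sample A
#'   (added for hyper, subtracted for hypo; results clamped to [0,1]).
#' @param mean_depth Mean per-site read depth (Poisson).
#' @param conversion_rate Bisulfite conversion rate in (0,1]; conversion
#'   failures inflate apparent methylation of the unmethylated fraction.
#' @param n_deg Number of genes given a nonzero expression log2 fold change
#'   independently of methylation.
#' @param deg_log2fc_magnitude Magnitude of planted log2 fold changes.
#' @param coupling_fraction Fraction of promoter-hyper DMR genes whose
#'   expression is forced down by \code{deg_log2fc_magnitude}.
#' @param dispersion Negative-binomial dispersion of expression counts.
#' @param min_gap Minimum gap between genes (bp).
#' @param spike_in If \code{TRUE}, append a fully unmethylated control
#'   chromosome (for conversion-rate estimation).
#' @param spike_in_length Length (bp) of the control chromosome.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 42L,
                       n_chromosomes = 2L,
                       chromosome_length = 500000L,
                       gc_fraction = 0.4,
                       n_genes = 100L,
                       gene_length = 3000L,
                       baseline_ml = c(CG = 0.7, CHG = 0.5, CHH = 0.1),
                       n_dmrs = 50L,
                       dmr_length = 2000L,
                       dmr_delta = 0.4,
                       mean_depth = 30,
                       conversion_rate = 0.995,
                       n_deg = 30L,
                       deg_log2fc_magnitude = 2,
                       coupling_fraction = 0.8,
                       dispersion = 0.05,
                       min_gap = 5000L,
                       spike_in = TRUE,
                       spike_in_length = 20000L) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              baseline_ml = baseline_ml, n_dmrs = as.integer(n_dmrs),
              dmr_length = as.integer(dmr_length), dmr_delta = dmr_delta,
              mean_depth = mean_depth, conversion_rate = conversion_rate,
              n_deg = as.integer(n_deg),
              deg_log2fc_magnitude = deg_log2fc_magnitude,
              coupling_fraction = coupling_fraction,
              dispersion = dispersion, min_gap = as.integer(min_gap),
              spike_in = isTRUE(spike_in),
              spike_in_length = as.integer(spike_in_length))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1L, cfg$chromosome_length >= 1000L,
            cfg$gc_fraction > 0, cfg$gc_fraction < 1,
            cfg$n_genes >= 0L, cfg$gene_length >= 1L,
            cfg$n_dmrs >= 0L, cfg$dmr_length >= 1L,
            cfg$mean_depth > 0, cfg$dispersion > 0,
            cfg$conversion_rate > 0, cfg$conversion_rate <= 1,
            cfg$coupling_fraction >= 0, cfg$coupling_fraction <= 1,
            cfg$deg_log2fc_magnitude > 0)
  if (!all(c("CG", "CHG", "CHH") %in% names(cfg$baseline_ml)))
    stop("baseline_ml must name CG, CHG and CHH")
  if (any(cfg$baseline_ml < 0 | cfg$baseline_ml > 1))
    stop("baseline_ml values must lie in [0,1]")
  if (cfg$n_dmrs > cfg$n_genes)
    stop("n_dmrs exceeds n_genes: each planted DMR targets a distinct gene")
  if (cfg$dmr_length > max(cfg$gene_length, 2000L))
    stop("dmr_length must fit inside a gene body or a 2-kb promoter")
  total <- as.numeric(cfg$n_chromosomes) * cfg$chromosome_length
  if (as.numeric(cfg$dmr_length) * cfg$n_dmrs >= total)
    stop("planted DMRs exceed the genome length")
  invisible(cfg)
}

#' Generate a random reference genome and gene models
#'
#' Draws i.i.d. bases at the configured G+C fraction and places
#' non-overlapping genes with random gaps (at least \code{min_gap} apart and
#' clear of chromosome ends, so every gene owns unambiguous 2-kb flanks).
#' Roughly half of the genes are placed on the minus strand. Deterministic
#' given \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with \code{genome} (named \code{DNAStringSet}, including
#'   the unmethylated spike-in chromosome \code{"chrC"} when configured) and
#'   \code{genes} (data.frame: \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end}).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  gc <- config$gc_fraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqs <- vapply(chroms, function(ch) {
    paste(sample(names(p), config$chromosome_length, replace = TRUE,
                 prob = p), collapse = "")
  }, character(1))
  if (config$spike_in) {
    seqs <- c(seqs, chrC = paste(
      sample(names(p), config$spike_in_length, replace = TRUE, prob = p),
      collapse = ""))
  }
  genome <- Biostrings::DNAStringSet(seqs)

  # distribute genes over chromosomes, then pack with random slack
  n_per <- table(factor(sort(rep_len(seq_along(chroms), config$n_genes)),
                        levels = seq_along(chroms)))
  margin <- 2500L                       # keeps 2-kb flanks on-chromosome
  genes <- NULL
  idx0 <- 0L
  for (ci in seq_along(chroms)) {
    k <- as.integer(n_per[ci])
    if (k == 0L) next
    usable <- config$chromosome_length - 2L * margin
    need <- k * config$gene_length + (k - 1L) * config$min_gap
    if (need > usable)
      stop("infeasible packing: ", k, " genes of ", config$gene_length,
           " bp with ", config$min_gap, " bp gaps exceed chromosome ",
           chroms[ci])
    free <- usable - need
    cuts <- sort(runif(k, 0, free))
    gaps <- floor(diff(c(0, cuts)))
    starts <- margin + 1L + cumsum(gaps) +
      (seq_len(k) - 1L) * (config$gene_length + config$min_gap)
    genes <- rbind(genes, data.frame(
      gene_id = sprintf("gene%04d", idx0 + seq_len(k)),
      chrom = chroms[ci],
      strand = sample(rep_len(c("+", "-"), k)),
      start = as.integer(starts),
      end = as.integer(starts + config$gene_length - 1L),
      stringsAsFactors = FALSE))
    idx0 <- idx0 + k
  }
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  list(genome = genome, genes = genes)
}

#' Simulate two cytosine-report methylomes with planted DMRs
#'
#' Every cytosine of the genome (both strands) receives its baseline
#' methylation level by context. \code{n_dmrs} distinct genes are selected;
#' each gets one planted DMR, alternating between gene body and promoter
#' placement and between hyper and hypo direction. Inside a planted DMR the
#' true methylation level of sample A is shifted by \code{+/- dmr_delta}
#' (clamped to [0,1]) in every context; sample B keeps the baseline. Read
#' totals are Poisson(\code{mean_depth}) and methylated counts are
#' Binomial(total, ml + (1 - ml) * (1 - conversion_rate)), so conversion
#' failures add apparent methylation. The spike-in chromosome is fully
#' unmethylated in both samples.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genome,genes Output of \code{\link{simulate_genome}}.
#' @return A list with \code{sample_a} and \code{sample_b} (cytosine-report
#'   data.frames: \code{chrom}, \code{pos}, \code{strand},
#'   \code{meth_reads}, \code{total_reads}, \code{context},
#'   \code{trinucleotide}) and \code{truth}, itself a list of
#'   \code{dmrs} (chrom, start, end, direction, gene_id, association),
#'   \code{true_ml_a}/\code{true_ml_b} per-site vectors, and the site table.
#' @export
simulate_methylomes <- function(config, genome, genes) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  sites <- genome_cytosines(genome)
  base <- config$baseline_ml[sites$context]
  base[sites$chrom == "chrC"] <- 0      # unmethylated control

  planted <- plant_dmrs(config, genes)
  ml_b <- unname(base)
  ml_a <- ml_b
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      hit <- sites$chrom == planted$chrom[i] &
        sites$pos >= planted$start[i] & sites$pos <= planted$end[i]
      delta <- if (planted$direction[i] == "hyper") config$dmr_delta else
        -config$dmr_delta
      ml_a[hit] <- pmin(1, pmax(0, ml_a[hit] + delta))
    }
  }

  draw <- function(ml, seed_off) {
    set.seed(config$seed + seed_off)
    total <- rpois(nrow(sites), config$mean_depth)
    apparent <- ml + (1 - ml) * (1 - config$conversion_rate)
    meth <- rbinom(nrow(sites), total, apparent)
    data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
               meth_reads = meth, total_reads = total,
               context = sites$context, trinucleotide = sites$trinucleotide,
               stringsAsFactors = FALSE)
  }
  sample_a <- draw(ml_a, 2L)
  sample_b <- draw(ml_b, 3L)
  list(sample_a = sample_a, sample_b = sample_b,
       truth = list(dmrs = planted, true_ml_a = ml_a, true_ml_b = ml_b,
                    sites = sites))
}

# choose target genes and intervals for the planted DMRs
plant_dmrs <- function(config, genes) {
  if (config$n_dmrs == 0L || nrow(genes) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      gene_id = character(), association = character(),
                      stringsAsFactors = FALSE))
  pick <- genes[sample(nrow(genes), config$n_dmrs), , drop = FALSE]
  assoc <- rep_len(c("gene_body", "promoter"), config$n_dmrs)
  direction <- rep_len(c("hyper", "hyper", "hypo", "hypo"), config$n_dmrs)
  L <- config$dmr_length
  start <- integer(config$n_dmrs)
  for (i in seq_len(config$n_dmrs)) {
    if (assoc[i] == "gene_body") {
      lo <- pick$start[i]; hi <- pick$end[i] - L + 1L
    } else if (pick$strand[i] == "+") {
      lo <- pick$start[i] - 2000L; hi <- pick$start[i] - L
    } else {
      lo <- pick$end[i] + 1L; hi <- pick$end[i] + 2001L - L
    }
    if (hi < lo) stop("dmr_length does not fit the target element")
    start[i] <- as.integer(floor(runif(1, lo, hi + 1)))
  }
  data.frame(chrom = pick$chrom, start = start, end = start + L - 1L,
             direction = direction, gene_id = pick$gene_id,
             association = assoc, stringsAsFactors = FALSE)
}

#' Simulate gene expression coupled to promoter hypermethylation
#'
#' Assigns every gene a true log2 fold change (sample A over sample B):
#' zero by default, \code{+/- deg_log2fc_magnitude} for \code{n_deg}
#' randomly chosen genes, and forced to \code{-deg_log2fc_magnitude} for a
#' \code{coupling_fraction} of the genes carrying a planted promoter-hyper
#' DMR. In \code{mode = "counts"} negative-binomial counts are drawn for
#' both conditions and summarised by \code{\link{simple_de_test}}; in
#' \code{mode = "truth"} the DEG table is emitted deterministically from the
#' truth (p = 0 for nonzero fold changes, 1 otherwise).
#'
#' @param config A \code{\link{sim_config}}.
#' @param genes Gene table from \code{\link{simulate_genome}}.
#' @param truth Truth list from \code{\link{simulate_methylomes}}.
#' @param mode \code{"counts"} (simulate and test) or \code{"truth"}.
#' @return List with \code{deg_table} (gene_id, log2fc, p, p_adj),
#'   \code{true_log2fc} (named vector), \code{coupled_pairs} (data.frame of
#'   gene_id, methylation direction, expression direction) and, in counts
#'   mode, the count matrix.
#' @export
simulate_expression <- function(config, genes, truth,
                                mode = c("counts", "truth")) {
  mode <- match.arg(mode)
  validate_sim_config(config)
  set.seed(config$seed + 4L)
  n <- nrow(genes)
  lfc <- setNames(numeric(n), genes$gene_id)

  prom_hyper <- truth$dmrs$gene_id[truth$dmrs$association == "promoter" &
                                     truth$dmrs$direction == "hyper"]
  if (config$coupling_fraction > 0 && length(prom_hyper) == 0L)
    stop("coupling requested but no promoter-hyper DMRs are planted")
  n_couple <- round(config$coupling_fraction * length(prom_hyper))
  coupled <- if (n_couple > 0)
    sample(prom_hyper, n_couple) else character()

  free <- setdiff(genes$gene_id, coupled)
  n_deg <- min(config$n_deg, length(free))
  deg_genes <- if (n_deg > 0) sample(free, n_deg) else character()
  lfc[deg_genes] <- sample(c(-1, 1), n_deg, replace = TRUE) *
    config$deg_log2fc_magnitude
  lfc[coupled] <- -config$deg_log2fc_magnitude

  coupled_pairs <- data.frame(gene_id = coupled,
                              methylation = rep("hyper", length(coupled)),
                              expression = rep("down", length(coupled)),
                              stringsAsFactors = FALSE)

  if (mode == "truth") {
    deg_table <- data.frame(gene_id = genes$gene_id, log2fc = unname(lfc),
                            p = ifelse(lfc != 0, 1e-6, 1),
                            p_adj = ifelse(lfc != 0, 1e-6, 1),
                            stringsAsFactors = FALSE)
    return(list(deg_table = deg_table, true_log2fc = lfc,
                coupled_pairs = coupled_pairs))
  }

  base_mean <- rlnorm(n, meanlog = log(200), sdlog = 0.6)
  size <- 1 / config$dispersion
  mu_b <- base_mean
  mu_a <- base_mean * 2^lfc
  counts <- cbind(A = rnbinom(n, mu = mu_a, size = size),
                  B = rnbinom(n, mu = mu_b, size = size))
  rownames(counts) <- genes$gene_id
  deg_table <- simple_de_test(counts, condition = c("A", "B"))
  list(deg_table = deg_table, true_log2fc = lfc,
       coupled_pairs = coupled_pairs, counts = counts)
}

#' Write simulator outputs to disk
#'
#' Emits the reference FASTA, gene GFF3, both cytosine reports and the
#' ground-truth tables as plain text, all byte-deterministic for a given
#' configuration.
#'
#' @param sim Output of \code{\link{simulate_methylomes}}.
#' @param genome,genes Output of \code{\link{simulate_genome}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, genome, genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             gff = file.path(dir, "genes.gff3"),
             report_a = file.path(dir, "sample_A.cx.txt"),
             report_b = file.path(dir, "sample_B.cx.txt"),
             truth = file.path(dir, "truth_dmrs.tsv"))
  Biostrings::writeXStringSet(genome, paths["fasta"])
  write_gff3(genes, paths["gff"])
  write_cytosine_report(sim$sample_a, paths["report_a"])
  write_cytosine_report(sim$sample_b, paths["report_b"])
  utils::write.table(sim$truth$dmrs, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
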