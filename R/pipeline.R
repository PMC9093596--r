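#' Pipeline configuration
#'
#' Assembles, validates and defaults the configuration of a full run:
#' input paths, thresholds of every stage, seed and log level. A
#' configuration survives \code{\link{write_config}} /
#' \code{\link{read_config}} round-trips unchanged.
#'
#' @param fasta,gff,report_a,report_b Input paths (reference, gene models,
#'   the two cytosine reports).
#' @param deg_table Path to the differential-expression TSV (gene_id,
#'   log2fc, p, p_adj); required for the integrate stage.
#' @param terms Optional term-annotation TSV for enrichment.
#' @param repeats Optional repeat BED for element profiles.
#' @param out_dir Output directory.
#' @param min_coverage,window,step,min_sites,fold,p DMR-stage thresholds.
#' @param flank Promoter/flank size in bp.
#' @param merge_gap Maximum merge gap in bp.
#' @param fc_threshold,padj_threshold DEG thresholds.
#' @param q_threshold Enrichment significance threshold.
#' @param seed Integer seed recorded in the manifest.
#' @param log_level "quiet" or "info"; affects messages only, never
#'   outputs.
#' @return List of class \code{"bsdmr_config"}.
#' @export
pipeline_config <- function(fasta = NULL, gff = NULL, report_a = NULL,
                            report_b = NULL, deg_table = NULL,
                            terms = NULL, repeats = NULL,
                            out_dir = "bsdmr_out", min_coverage = 4L,
                            window = 1000L, step = 500L, min_sites = 5L,
                            fold = 2, p = 0.05, flank = 2000L,
                            merge_gap = 0L, fc_threshold = 2,
                            padj_threshold = 0.05, q_threshold = 0.05,
                            seed = 1L, log_level = "info") {
  cfg <- list(fasta = fasta, gff = gff, report_a = report_a,
              report_b = report_b, deg_table = deg_table, terms = terms,
              repeats = repeats, out_dir = out_dir,
              min_coverage = as.integer(min_coverage),
              window = as.integer(window), step = as.integer(step),
              min_sites = as.integer(min_sites), fold = fold, p = p,
              flank = as.integer(flank), merge_gap = as.integer(merge_gap),
              fc_threshold = fc_threshold,
              padj_threshold = padj_threshold, q_threshold = q_threshold,
              seed = as.integer(seed), log_level = log_level)
  stopifnot(cfg$min_coverage >= 1L, cfg$window >= 1L, cfg$step >= 1L,
            cfg$min_sites >= 1L, cfg$fold > 0, cfg$p > 0, cfg$p <= 1,
            cfg$flank >= 0L, cfg$merge_gap >= 0L, cfg$fc_threshold > 0,
            cfg$padj_threshold > 0, cfg$q_threshold > 0,
            cfg$log_level %in% c("quiet", "info"))
  class(cfg) <- "bsdmr_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config A \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   path)
  invisible(path)
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) message("[bsdmr] ", ...)
  invisible(NULL)
}

run_stage <- function(cfg, name, expr) {
  pipe_log(cfg, "stage ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full differential-methylation pipeline
#'
#' Executes profile -> call-dmrs -> annotate -> integrate -> enrich on the
#' configured inputs, writing each stage's tables plus a run manifest
#' (package version, configuration, config hash, seed, stage list) to
#' \code{out_dir}. Reruns with the same configuration are byte-identical
#' for all deterministic stages (every stage here is deterministic).
#'
#' @param config A \code{\link{pipeline_config}} or path to its YAML.
#' @return Invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  stopifnot(inherits(cfg, "bsdmr_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()

  genome <- run_stage(cfg, "load-reference", {
    if (is.null(cfg$fasta)) stop("no FASTA configured")
    Biostrings::readDNAStringSet(cfg$fasta)
  })
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- run_stage(cfg, "load-genes", {
    if (is.null(cfg$gff)) stop("no GFF3 configured")
    read_gff3(cfg$gff)
  })

  meth <- run_stage(cfg, "profile", {
    a <- load_methylome(cfg$report_a, min_coverage = cfg$min_coverage)
    b <- load_methylome(cfg$report_b, min_coverage = cfg$min_coverage)
    sum_a <- summarize_contexts(a, genome = genome)
    sum_b <- summarize_contexts(b, genome = genome)
    utils::write.table(sum_a$by_context,
                       file.path(cfg$out_dir, "context_summary_A.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sum_b$by_context,
                       file.path(cfg$out_dir, "context_summary_B.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    els <- element_intervals(genes, genome = genome,
                             repeats = cfg$repeats,
                             flank_size = cfg$flank)
    prof <- profile_elements(a, els)
    utils::write.table(prof,
                       file.path(cfg$out_dir, "element_profile_A.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(a = a, b = b, summary_a = sum_a, summary_b = sum_b,
         profile = prof)
  })
  stages <- c(stages, "profile")

  dmrs <- run_stage(cfg, "call-dmrs", {
    d <- call_dmrs(meth$a, meth$b, window_size = cfg$window,
                   step = cfg$step, min_sites = cfg$min_sites,
                   fold_threshold = cfg$fold, p_threshold = cfg$p,
                   merge_gap = cfg$merge_gap)
    write_dmrs(d, bed_path = file.path(cfg$out_dir, "dmrs.bed"),
               tsv_path = file.path(cfg$out_dir, "dmrs.tsv"))
    utils::write.table(dmr_chromosome_distribution(d),
                       file.path(cfg$out_dir, "dmr_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d
  })
  stages <- c(stages, "call-dmrs")

  assoc <- run_stage(cfg, "annotate", {
    a <- associate_dmrs(dmrs, genes, flank_size = cfg$flank,
                        chrom_lengths = setNames(Biostrings::width(genome),
                                                 names(genome)))
    utils::write.table(a$associations,
                       file.path(cfg$out_dir, "dmr_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dmg_direction_table(a$associations),
                       file.path(cfg$out_dir, "dmg_direction_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    a
  })
  stages <- c(stages, "annotate")

  integ <- run_stage(cfg, "integrate", {
    if (is.null(cfg$deg_table) || !file.exists(cfg$deg_table))
      stop("DEG table missing: ", cfg$deg_table %||% "<unset>")
    degs <- classify_degs(read_deg_table(cfg$deg_table),
                          fc_threshold = cfg$fc_threshold,
                          padj_threshold = cfg$padj_threshold)
    res <- intersect_dmg_deg(assoc$associations, degs)
    cor <- methylation_expression_correlation(res$dmegs)
    utils::write.table(res$dmegs, file.path(cfg$out_dir, "dmegs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$venn,
                         file.path(cfg$out_dir, "venn_counts.json"),
                         auto_unbox = TRUE, digits = NA)
    c(res, list(degs = degs, correlation = cor))
  })
  stages <- c(stages, "integrate")

  enr <- run_stage(cfg, "enrich", {
    if (is.null(cfg$terms)) {
      pipe_log(cfg, "no term annotations configured; skipping enrichment")
      NULL
    } else {
      ann <- read_term_annotations(cfg$terms)
      e <- enrich_terms(unique(integ$dmegs$gene_id), ann,
                        q_threshold = cfg$q_threshold)
      utils::write.table(e, file.path(cfg$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      e
    }
  })
  stages <- c(stages, "enrich")

  cfg_file <- file.path(cfg$out_dir, "config.yaml")
  write_config(cfg, cfg_file)
  manifest <- list(
    package = "bsdmr",
    version = as.character(utils::packageVersion("bsdmr")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = stages)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(methylomes = meth, dmrs = dmrs, associations = assoc,
                 integration = integ, enrichment = enr,
                 manifest = manifest))
}
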