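# Shared fixtures, built once per test run.

# hand-built methylome rows
make_meth <- function(chrom, pos, strand, context, meth, total,
                      min_coverage = 4L) {
  df <- data.frame(chrom = chrom, pos = pos, strand = strand,
                   meth_reads = meth, total_reads = total,
                   context = context, trinucleotide = NA_character_,
                   stringsAsFactors = FALSE)
  load_methylome(df, min_coverage = min_coverage)
}

# small end-to-end simulation: 1 x 60 kb chromosome, 6 genes, 4 planted
# DMRs (one per body/promoter x hyper/hypo cell)
small_cfg <- sim_config(seed = 7L, n_chromosomes = 1L,
                        chromosome_length = 60000L, n_genes = 6L,
                        n_dmrs = 4L, mean_depth = 30,
                        spike_in_length = 5000L, n_deg = 2L)
small_fix <- local({
  g <- simulate_genome(small_cfg)
  sim <- simulate_methylomes(small_cfg, g$genome, g$genes)
  list(genome = g$genome, genes = g$genes, sim = sim,
       meth_a = load_methylome(sim$sample_a),
       meth_b = load_methylome(sim$sample_b))
})
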