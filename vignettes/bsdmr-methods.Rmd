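---
title: "Methods: window-based DMR calling and methylome-expression integration"
author: "bsdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based DMR calling and methylome-expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsdmr)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) reads report each cytosine as
converted (unmethylated) or retained (methylated), so a methylome reduces
to per-cytosine counts: methylated reads $m$ out of total reads $t$. In
plants, methylation occurs in three sequence contexts — CG, CHG and CHH
(H = A, C or T) — with very different baseline levels and biological
roles. `bsdmr` compares two methylomes (e.g. a sterile line and its
near-isogenic maintainer, one library each), calls differentially
methylated regions (DMRs), relates them to genes and promoters, and asks
whether methylation differences track expression differences.

## Methylation level and the coverage filter

The methylation level of a cytosine is the exact integer ratio
$ML = m / t$, defined only where $t \ge$ `min_coverage` (default 4).
Below the filter the counts are kept in the site table, but the site has
no ML, never enters ML-based summaries, and is excluded from DMR windows
entirely (both from the site-count minimum and from the pooled tables),
keeping the window test consistent with the coverage rule. Both the $\ge 4$ and
$\ge 5$ readings of "more than four reads" are supported through the
`min_coverage` knob; 4 is the default and the convention used throughout
this vignette.

Whether a covered site is *methylated* (as opposed to merely covered) is
decided by a one-sided binomial test of $m$ out of $t$ against the
bisulfite conversion failure rate $1 - c$, BH-corrected at FDR 0.05
(`call_methylated_sites()`). The conversion rate $c$ is estimated from an
unmethylated spike-in chromosome as converted reads over total reads
(`estimate_conversion_rate()`); the simulator emits such a control
chromosome (`chrC`) for exactly this purpose.

## The DMR caller

For each context separately, fixed windows (default 1000 bp sliding by
500 bp) are kept when at least `min_sites` (default 5) cytosines of that
context have a defined ML in *both* samples — the stricter joint-coverage
reading. Counts of qualifying sites are pooled per sample into a 2x2
table and tested:

* **Fisher exact test** (two-sided) on
  $[[m_A, u_A], [m_B, u_B]]$, implemented as hypergeometric tail sums
  over the full support (`fisher_exact_p()`), identical to
  `fisher.test()` but vectorised for thousands of large-count tables.
* **Fold criterion**: pooled $ML_A / ML_B$ (larger over smaller, zeros
  replaced by 0.001) must be at least 2.

A window passes when $p \le 0.05$ *and* the fold ratio is $\ge 2$; the p
threshold applies to raw p-values by default (a BH option exists but is
off, since the procedure is defined on raw Fisher p). Passing windows of
the same context and direction that overlap or are book-ended
(`merge_gap` = 0) are *interdependent*: they are merged, pooled counts
are recomputed from the underlying sites, both criteria are re-applied,
and the cycle repeats until the surviving regions are mutually
independent. Each final DMR carries its recomputed p, pooled levels and
the **degree of difference**

$$\mathrm{DoD} = \log_2 \frac{ML_A'}{ML_B'}, \qquad x' = \begin{cases}
x & x > 0\\ 0.001 & x = 0,\end{cases}$$

positive for hypermethylation in sample A. Window geometry is a design
choice (no single standard exists): 1 kb / 500 bp makes neighbouring
windows share sites, which is precisely what gives the iterative-merging
step work to do. Window ML pools read counts (weighted by coverage)
rather than averaging per-site MLs, so the tested table and the fold
criterion describe the same quantity.

## Annotation

Gene bodies are full transcriptional spans. The promoter proxy is the
2-kb upstream flank (Up2k), mirrored on the minus strand and clipped at
chromosome ends; Down2k is the downstream analogue. Associations need
$\ge 1$ bp of overlap, and the body and promoter categories are
deliberately independent — one DMR may be counted in both, and a DMR
spanning several genes associates with all of them. CpG islands follow
the classical rule: 200-bp windows with GC $\ge 0.5$ and observed/expected
CpG $\ge 0.6$ (obs/exp $= n_{CG} \cdot L / (n_C \, n_G)$), merged into
maximal runs. Internal coordinates are 1-based inclusive everywhere; BED
conversion happens only at I/O boundaries.

## Integration with expression

DEGs use the standard inclusive thresholds: $|log_2 FC| \ge 1$ and
adjusted $p \le 0.05$, oriented as sample A over sample B. Genes that are
both DMG and DEG (DMEGs) fall into the hyper/hypo x up/down grid; a gene
with several DMRs in a subgroup takes the direction of the DMR with the
largest $|\mathrm{DoD}|$. The methylation-expression relationship is
summarised by the Spearman correlation between gene-level DoD and
$\log_2 FC$ (exact p for $n \le 9$ without ties, t-approximation
otherwise). `simple_de_test()` — normalised means with pseudocount 1 and
an exact binomial test on summed counts — exists so synthetic end-to-end
runs need no external DE tool; it is plumbing, not a dispersion-aware
model, and real analyses should supply their own DEG table.

## Enrichment

Term over-representation is the hypergeometric upper tail
$P(X \ge k)$ via `phyper`, with BH correction within each annotation
category and significance at $q \le 0.05$. The universe defaults to all
annotated genes (configurable); the test is one-sided over-representation.

## The simulator and what it does (not) show

`simulate_genome()` / `simulate_methylomes()` / `simulate_expression()`
generate a fully ground-truthed study: i.i.d. bases at a set GC fraction
(default 0.4), non-overlapping genes at least 5 kb apart so 2-kb flanks
are unambiguous, and planted 2-kb DMRs, one per target gene, alternating
body/promoter placement and hyper/hypo direction. Inside a planted DMR
every context shifts by $\pm$ `dmr_delta` (clamped to $[0,1]$); read
totals are Poisson(`mean_depth`) and methylated counts are
Binomial$(t,\; ml + (1-ml)(1-c))$, the standard additive model in which
conversion failures inflate apparent methylation. Expression counts are
negative binomial; a `coupling_fraction` of promoter-hyper genes is
forced down-regulated, which is the planted "methylation represses
expression" signal. Reference conditions: two 500-kb chromosomes, 100
genes, 50 DMRs, $\Delta = 0.4$, depth 30, conversion 0.995, seed 42 —
small enough that the full suite runs in well under a minute per
simulation, large enough that window site counts (~25 CG sites/kb)
match the caller's assumptions.

What the simulator does *not* emulate: read-level errors and mapping
bias, M-bias, replicate structure (one library per line, as in the
two-sample design it mirrors), locally varying methylation along gene
bodies, repeat-driven CHH islands, and realistic gene-length or
expression distributions beyond a lognormal mean. Passing tests
therefore demonstrate correctness of the statistics and bookkeeping
under a clean generative model, not robustness to artefacts of real
libraries.

## Numerical choices and edge cases

* Fisher two-sided p sums all tables with probability
  $\le p_{obs}(1 + 10^{-7})$ — the same tie tolerance as
  `stats::fisher.test`, so the two agree to near machine precision.
* Context classification needs two downstream bases in strand sense;
  chromosome-end cytosines and any trinucleotide containing N are
  undefined and excluded (applied identically in the simulator and the
  classifier).
* Zero methylation levels are replaced by 0.001 only inside ratio
  statistics (fold, DoD), never in the stored MLs.
* Windows with zero pooled reads in either sample fail with a reason
  rather than erroring; elements shorter than the bin count are
  fractionally binned, not dropped.
* Merging requires identical context *and* direction; "interdependence"
  is interval overlap or adjacency. The fixpoint loop converges because
  merging is monotone (regions only grow) and dropping failed regions
  cannot create new adjacencies.
* A/B symmetry holds exactly: swapping the samples flips every DMR
  direction, negates DoD and leaves p-values unchanged — this is a
  tested invariant.

## Known limitations

Single-library designs mean the Fisher test treats read sampling as the
only noise source; biological variability between replicates is out of
scope, as are smoothing/HMM DMR callers and dispersion-shrinkage DE
models. The 2-kb promoter is a proxy, not a TSS-resolved regulatory
annotation. Enrichment ignores term hierarchies (no GO DAG propagation)
and pathway topology.

## A small worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
g   <- simulate_genome(cfg)
sim <- simulate_methylomes(cfg, g$genome, g$genes)
a   <- load_methylome(sim$sample_a)
b   <- load_methylome(sim$sample_b)
dmrs <- call_dmrs(a, b)
dmr_recovery(dmrs, sim$truth$dmrs)   # recall/precision vs ground truth
```

See the README for the full pipeline (`run_pipeline()`) and the
acceptance script that recomputes the package's headline numbers.
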