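# tandem5ss

Integrated analysis of **competing tandem 5′ splice sites** — alternative 5′
splice site (A5SS) events where two donors a few nucleotides apart share one
downstream acceptor. Selecting the intron-proximal donor keeps the
exon-terminal segment (the *inclusion* isoform, fraction ψ); selecting the
intron-distal donor truncates it. The package is aimed at splicing and
RNA-binding-protein researchers who have already summarised their data into
junction counts and per-base CLIP coverage and want the downstream
statistics:

* **Bayesian PSI estimation** per event and sample from isoform-diagnostic
  counts: uniform prior, likelihood
  `p(ψ)^n_prox (1−p(ψ))^n_dist` with
  `p(ψ) = ψ·l_inc / (ψ·l_inc + (1−ψ)·l_exc)`, evaluated on a deterministic
  grid (equal effective lengths reduce to `Beta(n_prox+1, n_dist+1)`);
* **Δψ and Bayes factors** for two-condition comparisons
  (`BF = ∫L₁ ∫L₂ / ∫L₁L₂`), with the canonical filters
  `num_inc ≥ 1`, `num_exc ≥ 1`, `|Δψ| ≥ 0.2`, `BF ≥ 10`;
* **response classification**: significant events with `Δψ ≤ −0.2` are
  *distal-activated* by the perturbation, `Δψ ≥ +0.2` *proximal-activated*;
* **strand-aware CLIP metaprofiles**: normalized per-event tag densities in
  a 400-nt window around either donor (density = coverage / window total),
  class-by-anchor mean ± SE profiles, and an **eight-section argmax
  report** (section 4 = the 50 nt immediately upstream of the donor);
* **motif scoring**: additive ESE PWM scoring and scanning (the published
  ESEfinder SRSF1 heptamer matrix ships with the package), donor-strength
  scoring (log₂-odds weight matrix, pluggable 9-mer model tables), and
  block-scanning mutant design with ESE-gain annotation;
* a **synthetic-data generator** producing event tables, two-condition
  counts with known ψ, and CLIP coverage with planted peaks, so the whole
  pipeline is testable end-to-end from one seed.

All genomic I/O is 0-based half-open (BED/BedGraph conventions); a donor is
anchored at its first intronic base.

## Worked example

```r
library(tandem5ss)

# one event: 9 inclusion reads, 3 exclusion reads
p <- psi_posterior(n_distal = 3, n_proximal = 9)
round(c(p$posterior_mean, p$ci_low, p$ci_high), 3)
#> [1] 0.714 0.462 0.909

# a simulated 60-event knockdown experiment, end to end
mf <- run_pipeline(run_config(outdir = "run1",
                              sim = simulation_config(n_events = 60),
                              seed = 41))
str(mf$stages)
#> List of 5
#>  $ events            : int 60
#>  $ counts            : int 120
#>  $ psi_results       : int 60
#>  $ classified        :List of 3
#>   ..$ distal_activated  : int 23
#>   ..$ proximal_activated: int 22
#>   ..$ unchanged         : int 15
#>  $ metaprofile_panels: int 4

# ESE scores of a wild-type and a substituted heptamer
m <- esefinder_srsf1_matrix()
c(pwm_score("GGGACCA", m), pwm_score("AGAATCA", m))
#> [1]  1.74 -3.77
```

The run directory contains plain-text artifacts at every stage boundary
(`events.tsv`, `counts.tsv`, `clip.bedgraph`, `psi_results.tsv`,
`classified.tsv`, `metaprofiles.tsv`, `sections.tsv`, `manifest.json`);
`1.74` / `−3.77` are the additive PWM scores of the two heptamers under the
SRSF1 matrix — a strong versus a disrupted SR-protein binding site.

A thin command-line wrapper with `simulate`, `psi`, `classify`,
`metaprofile`, `scan-ese` and `run` subcommands is installed at
`inst/cli/tandem5ss.R`.

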