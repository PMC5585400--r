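---
title: "Analysing competing tandem 5' splice sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing competing tandem 5' splice sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandem5ss)
```

## The biological setting

Many introns carry two 5' splice sites (donors) a handful of nucleotides
apart that compete for the same downstream acceptor. Selecting the
*intron-proximal* donor retains the exon-terminal segment (the "inclusion"
isoform); selecting the *intron-distal* donor truncates it, often shifting
the reading frame. Which donor wins is set jointly by the intrinsic strength
of each donor and by nearby *cis*-elements — notably exonic splicing
enhancers (ESEs) bound by SR proteins, which can suppress the adjacent
distal donor. `tandem5ss` provides the downstream computational machinery
for studying this class of events genome-wide: inclusion-fraction (PSI)
estimation from junction counts, perturbation-response classification,
CLIP-binding metaprofiles around the two donors, and motif scoring.

Every donor is anchored at a single coordinate: its **first intronic base**,
0-based. Genomic files (event tables, BedGraph) are 0-based half-open
throughout; BedGraph gaps read as zero coverage.

## The PSI model

Let $\psi$ be the inclusion fraction — the fraction of transcripts using the
proximal donor. A read diagnostic of one isoform is drawn with probability
proportional to that isoform's abundance times its *effective length*
$l$ (the number of distinct diagnostic read placements), so an
inclusion-diagnostic read appears with probability

$$p(\psi) = \frac{\psi\, l_{inc}}{\psi\, l_{inc} + (1-\psi)\, l_{exc}}.$$

With $n_{prox}$ inclusion- and $n_{dist}$ exclusion-diagnostic reads and a
uniform prior on $(0,1)$, the posterior is
$\pi(\psi) \propto p(\psi)^{n_{prox}} (1-p(\psi))^{n_{dist}}$. The default
$l_{inc} = l_{exc}$ corresponds to pure junction-read counting and reduces
the posterior to $\mathrm{Beta}(n_{prox}+1,\, n_{dist}+1)$; unequal lengths
are exposed, not hidden, for reads overlapping the inter-donor segment.

**Numerics.** The one-dimensional posterior is evaluated deterministically
on the midpoint grid $\psi_i = (i - \tfrac12)h$, $i = 1..1/h$ (default
$h = 0.001$), in log space, and normalised by the midpoint Riemann sum —
chosen over endpoint rules because it makes $h \sum_i \pi(\psi_i) = 1$ hold
exactly for every input, including the flat no-data posterior, while the
accuracy against Beta closed forms stays far inside the $2h$ band the tests
require. Credible bounds are the first grid points where the cumulative sum
crosses 0.025/0.975. Both counts zero returns the prior with a `no_data`
flag; a Monte-Carlo sampler was deliberately avoided so that every result
is reproducible to the last digit and testable against closed forms.

## Two-condition comparison and filtering

For one event in conditions 1 (control) and 2 (perturbation),
$\Delta\psi = E[\psi_2] - E[\psi_1]$, and the Bayes factor compares
"independent inclusion fractions" (H1, independent uniform priors) against
"one shared fraction" (H0, uniform prior):

$$BF = \frac{\int L_1\,d\psi \int L_2\,d\psi}{\int L_1 L_2\,d\psi},$$

all three marginals on the same grid. An event is *significant* when all
four canonical filters hold: summed inclusion reads $\ge$ `num_inc` (1),
summed exclusion reads $\ge$ `num_exc` (1), $|\Delta\psi| \ge 0.2$, and
$BF \ge 10$. The read filters are applied to counts summed across the two
conditions; the thresholds are stored on every result so the choice is
auditable. Significant events are then classified by sign:
$\Delta\psi \le -0.2$ means inclusion falls, i.e. the perturbation
*activates the intron-distal donor*; $\Delta\psi \ge +0.2$ activates the
proximal donor. Fixing this convention once (and asserting it on
strand-mixed simulations) prevents silent sign flips.

```{r psi-demo}
p <- psi_posterior(n_distal = 3, n_proximal = 9)
c(mean = p$posterior_mean, lo = p$ci_low, hi = p$ci_high)
r <- apply_filters(delta_psi_bf(30, 10, 10, 30))
c(delta_psi = r$delta_psi, bf = r$bayes_factor, significant = r$significant)
```

## CLIP metaprofiles and the eight-section report

Per event and donor, the analysis window covers relative positions
$r = -200..+199$ in transcript orientation ($r = 0$ is the donor's first
intronic base; negative $r$ is the exonic side). The window is exactly 400
positions — the "±200 nt" convention is resolved so that eight 50-nt
sections tile it exactly, section $k$ spanning
$[-200 + 50(k-1),\, -200 + 50k)$; **section 4** is the 50 nt immediately
upstream of the donor. On the minus strand the window is read genomically
mirrored, so profiles are strand-equivariant by construction.

The normalised density divides each position's coverage by the window
total. Events with zero total coverage are excluded from means, standard
errors and histograms — the normalisation is undefined there — and their
count is reported, so accounting is exact. The metaprofile is the
positionwise mean with standard error $\mathrm{sd}/\sqrt{n}$ (sample SD,
$n-1$ denominator), the quantity conventionally drawn as a mean line with
an SE band. The section report assigns each event the section with the
highest summed raw coverage, breaking ties toward the lowest index and
flagging them.

## Motif scoring

ESE scoring is the standard additive PWM rule; the published ESEfinder
SRSF1 (SF2/ASF) heptamer matrix ships with the package
(`esefinder_srsf1_matrix()`), and scans flag the maximal window(s). Donor
strength is scored three ways: a log2-odds weight matrix against a
background distribution; a 9-mer model table lookup (the form in which
maximum-entropy donor models are distributed); and an optional genome-wide
donor-frequency (SD-score) table. Model tables the user has not supplied —
or 9-mers absent from a supplied table — yield `NA`, never a 0 score:
absence of a model is not evidence of weakness. RNA input (`U`) is
normalised to the DNA alphabet, since probe sequences are RNA but matrices
are DNA-alphabet. `block_scan_mutants()` reproduces the block-substitution
design used in splicing-reporter mutagenesis, with the standard 15-nt/19-nt
splicing-neutral replacements available via `neutral_block_sequences()`,
and annotates each mutant with the change in maximal ESE score to check
that a substitution does not gain a binding site de novo.

```{r ese-demo}
m <- esefinder_srsf1_matrix()
c(wt = pwm_score("GGGACCA", m), mut = pwm_score("AGAATCA", m))
```

## What the synthetic generator emulates — and what it does not

`simulation_config()` fixes the study conditions: a cohort of tandem-donor
events (default 200 events, donor spacing 11 nt, half on the minus strand)
placed in non-overlapping 400-nt windows; two-condition diagnostic counts
with total depth Poisson(200) per event per sample and binomial isoform
split under the same effective-length weighting the estimator inverts; and
CLIP coverage that is Poisson background (default 1 tag/nt) plus, in
distal-activated events, a rectangular peak (default height 10, width
30 nt) centred 25 nt upstream of the distal donor — inside section 4,
mirroring the empirical observation that SR-protein binding immediately
upstream of a distal donor suppresses it. Response classes default to 35%
distal-activated and 35% proximal-activated with a planted
$|\Delta\psi| = 0.4$; ground-truth direction labels are always derived from
the realised $\Delta\psi$ against the same 0.2 threshold the classifier
uses, so truth and call semantics cannot drift apart. Rectangular peaks
(not Gaussian) are the default because they make the section-argmax ground
truth exact; a Gaussian shape is available. One integer seed fixes
everything; dataset files are byte-identical across reruns.

The generator emulates summarised products, not raw data: no read-level
placement, alignment artifacts, PCR duplicates, multi-mapping, or
crosslink-induced mutations, and CLIP background is homogeneous Poisson —
real CLIP libraries have heavier-tailed, transcript-abundance-coupled
backgrounds. Passing tests therefore demonstrate that the estimators and
profile machinery are correct under the stated sampling model, not that
the model captures every property of real libraries.

## Problem sizes and calibration checks

The shipped checks use cohorts a desk machine handles in seconds: a 50-case
sweep against Beta closed forms; 200 events at depth 200 for parameter
recovery (RMSE of the posterior mean is ~0.03, planted-direction recovery
>95%); 1,000 null events at depth 100 for Bayes-factor calibration (the
fraction with $BF \ge 10$ stays well under 5% — uniform-prior Bayes factors
are conservative under H0); 100-event cohorts for normalisation,
strand-mirror equivariance, and section-4 recovery (100% with zero
background; ≥95% with background 1 against peak height 10).
`scripts/acceptance.R` recomputes all of these from scratch at a
user-supplied seed.

## Known limitations

* One pooled count set per condition; replicate-level modelling (and FDR
  across events) is out of scope.
* Two donors per event; multi-donor (>2) loci are not modelled.
* The effective-length correction is exposed but defaults to equal lengths;
  users counting reads that overlap the inter-donor segment must set
  `l_inc`/`l_exc` themselves.
* Donor model tables (maximum-entropy scores, SD scores) are consumed as
  external lookup files; the package does not re-derive them, and reports
  scores as unavailable when no table is given.
* Whether CLIP coverage is strand-separated is dataset-dependent; profile
  functions accept either a single track or one track per strand.
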