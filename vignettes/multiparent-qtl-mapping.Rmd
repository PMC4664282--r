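---
title: "Haplotype-based QTL mapping in multiparent RIL panels with mppscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based QTL mapping in multiparent RIL panels with mppscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multiparent panels of recombinant inbred lines (RILs) — the *Drosophila*
Synthetic Population Resource (DSPR) being the motivating design — map
quantitative trait loci by exploiting many generations of intercrossing
among a small set of resequenced founders. Each RIL genome is a fine-scale
mosaic of the eight founder haplotypes of its panel, fixed to homozygosity
by inbreeding. Because the founders are known, mapping proceeds in two
steps: infer, at every genome position, which founder each RIL inherited;
then regress the line-mean phenotype on those (probabilistic) ancestries.

`mppscan` implements that full analysis path for an activity-monitor
survival phenotype — adult flies dying on toxic (caffeine-supplemented)
food — together with a synthetic-data generator that emulates the
statistical structure of such a study, so the entire pipeline is testable
end to end without any external data.

## From monitor counts to phenotypes

TriKinetics DAM2 monitors record beam-break counts per fly tube, every
minute, for six days (8,640 bins). Death is operationalized as *permanent
cessation of activity*: the death time of a channel is the end of its last
non-zero bin. Two policies surround this rule:

* **Low-activity filter.** Channels nearly silent from the start of the
  assay (flies damaged during loading) are removed. The window (2 h) and
  count threshold (5) are explicit configuration — the operational
  definition of "very low activity" is a judgment call, so both knobs are
  exposed and recorded with results.
* **Censoring.** A channel active in the final bin is censored at the
  recording end (144 h) and excluded from line means by default.

An optional refractory rule (ignore a trailing single-count blip separated
from prior activity by many quiet hours) exists but defaults off: with no
principled blip definition, the conservative last-nonzero-bin rule is the
default and the option documents the sensitivity.

## Founder-haplotype inference

At a position a RIL's *diplotype* is the unordered pair of founder
ancestries: 36 states for 8 founders (8 homozygous + 28 heterozygous).
`posterior_decode()` runs forward–backward over this space:

* **Emission.** For state \{f, g\} at a biallelic marker, the product over
  the two founders of per-allele agreement: $1-\varepsilon$ if the
  founder's allele matches the observed call, $\varepsilon$ otherwise.
  Missing calls emit uniformly — which is also how posteriors are
  evaluated exactly on a regular cM grid (default 0.2 cM) interleaved with
  the markers.
* **Transition.** Per haplotype, ancestry switches over $d$ cM with
  probability $1-e^{-\rho d}$, uniformly to the other seven founders; the
  two haplotypes switch independently. This is the standard construction
  when the generating pedigree is not modelled explicitly; $\rho$
  (`recomb_scale`, default 0.15 per cM) should be set near the mosaic's
  expected breakpoint density.
* **Numerics.** Per-position renormalization of the forward and backward
  vectors prevents underflow; transition matrices are cached per unique
  inter-position distance. The unordered-state chain is an exact lumping
  of the ordered-pair chain because the switch model is symmetric — the
  test suite verifies forward–backward against brute-force enumeration
  over all ordered founder-path pairs to 1e-10.

Heterozygous states are treated as intermediate between their homozygous
states, giving the eight *additive probabilities*
$a(f) = P(f,f) + \tfrac12\sum_{g\neq f} P(f,g)$ used for mapping, and
`hard_call()` assigns a founder where $a(f) > 0.95$ — the threshold used
both for reporting founder means and for CNV imputation. Because simulated
RILs are fully homozygous, a `homozygous_only` flag restricts the state
space to the 8 homozygous states; the 36-state space stays the default so
that residual heterozygosity is representable.

## The genome scan

At each grid position the line means $y$ are regressed on the eight
additive probabilities (plus any covariates):

$$\mathrm{LOD} = \frac{n}{2}\,\log_{10}\frac{RSS_0}{RSS_1},\qquad
  VE = 1 - 10^{-2\,\mathrm{LOD}/n},$$

with $RSS_0$ from the intercept(+covariate) null. The probabilities sum to
one, so the full design is rank-deficient; the fit uses a rank-revealing
QR, making the LOD invariant to which redundant direction is dropped and
to any permutation of founder columns (asserted in tests). The variance
explained is exactly the $R^2$ increment of the full over the null model.

* **Thresholds.** Genomewide 5% significance comes from permuting the
  phenotype across lines (1,000 permutations conventionally; scaled-down
  counts in tests), one shared permutation across all positions per
  iteration so the linkage structure of the null is preserved; the
  threshold is the empirical 95th percentile of per-permutation maximum
  LOD. Calibration is checked by simulation: the realized genomewide
  type-I error is ~5% within binomial error.
* **Peaks and intervals.** Local maxima above threshold (leftmost position
  of a flat run) are extended into closed 2-LOD support intervals;
  overlapping intervals merge, keeping the higher peak. The merge rule is
  explicit configuration (`drop = 2`).
* **Covariates.** A subpopulation covariate and a square-root phenotype
  transform are supported but off by default, matching the common practice
  of mapping raw line means; CNV adjustment enters as a 0/1 covariate on
  the subset of lines with confident status (the LOD is invariant to
  affine recoding of that covariate, asserted as a test).
* **Scales.** Genetic–physical conversion for reporting uses monotone
  linear interpolation on the marker map.

`qtl_report()` converts peak LODs into variance explained and percent of
line-mean heritability, and sums the percents under the assumption of
independent, additive QTL.

## Heritability and power

`variance_components_h2()` decomposes per-fly values into among-line
($\sigma^2_G$) and within-line ($\sigma^2_E$) components by REML (lme4)
or by one-way ANOVA moments with the unbalanced correction
$n_0 = (N - \sum n_i^2/N)/(a-1)$. Per-observation $H^2 =
\sigma^2_G/(\sigma^2_G+\sigma^2_E)$; for line means the default is
$\sigma^2_G/(\sigma^2_G+\sigma^2_E/\bar n)$, with the
divide-by-variance-of-line-means convention available by flag — the two
differ slightly under unbalanced replication, so both are exposed rather
than silently chosen.

`assoc_power()` gives the power of a 1-df line-based association test with
noncentrality $\lambda = n r^2/(1-r^2)$. The default is the finite-sample
noncentral-F form ($df_2 = n-2$), which matches Monte-Carlo simulation of
line-mean regression closely at small $n$; the chi-square limit is an
option. The minor allele frequency affects power only through the chance
that the site segregates in the sample (optional `polymorphic_adjust`),
since $r^2$ already absorbs the frequency; whether "explains 10% of the
heritability" means 10% of among-line variance or 10% × $H^2$ is left to
the caller's choice of `r2` — both readings are computable and neither is
asserted as ground truth.

## What the generator emulates — and what it does not

`simulate_panel()` draws mosaics directly as a Poisson breakpoint process
on the genetic map (default 0.15 breakpoints/cM, mean segment ~6.7 cM),
with each switch moving uniformly to another founder and one starting
founder per RIL. This emulates the *consumed* structure — dense,
fine-scale mosaics — without re-simulating 50 generations of intercross
and 25 of sibling inbreeding: the analysis consumes mosaics, not
pedigrees. Consequences worth keeping in mind:

* Founder usage is uniform by construction; real panels drift.
* Breakpoints are unclustered and segment lengths exponential; real RIL
  breakpoints cluster by recombination-rate variation along chromosomes.
  The density itself is a tunable stand-in, not an estimated quantity.
* RILs are fully homozygous; residual heterozygosity is exercised only
  through the HMM state space on hand-built fixtures.
* Founder alleles are i.i.d. biallelic (monomorphic markers are flagged
  uninformative); there is no coalescent-realistic haplotype structure,
  no selection during maintenance, and no X-dosage model.

`simulate_phenotypes()` builds each fly as grand mean + founder effects at
the planted QTL + CNV effect + line deviation + within-line noise,
truncated at 0 h. The line-deviation variance is set so the total
among-line SD hits its target (default 17.82 h on a 37.3 h mean — a
realistic survival scale for this assay), and the within-line variance so
the per-observation $H^2$ hits its target (default 0.53) in expectation.
Replicate counts are a rounded normal (mean 16.5, SD 3.62, bounded 9–32).
Because truncation at zero acts after the variances are set, the realized
grand mean sits slightly above the nominal one (~1 h at the default
scale); passing tests on these synthetic panels therefore demonstrate
correctness of the machinery under the assumed variance structure, not
robustness to the skew, heteroscedasticity (within-line variance grows
with the mean in real data), or block effects of a real assay.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed and leaves the caller's
RNG untouched; `run_pipeline()` derives all stage seeds from one master
seed and writes a manifest with the config hash, so identical configs give
byte-identical outputs. The test suite and the reproduction script use
scaled-down designs chosen to keep Monte-Carlo error informative: null
calibration uses 100 traits x 200 lines x 100 permutations; support-
interval coverage uses 800-line panels with a QTL explaining ~10% of
among-line variance over 30–50 replicates; heritability recovery uses
2,000 lines. These sizes are the package's chosen operating points for
verification, mirroring the study-scale design (two ~850-RIL panels) at
reduced replication.

## Worked sketch

```{r example}
library(mppscan)

map <- sim_marker_map()
sim <- simulate_panel(400, map, seed = 1)
qtl <- qtl_spec("2", 30, effects = list(c(6, 6, 6, 6, -6, -6, -6, -6)))
phenos <- simulate_phenotypes(sim, qtl, sim_config(seed = 2))

lm_tab <- line_means(phenos)
probs <- true_additive(sim, grid_step = 0.5) # or infer_additive() via the HMM
scan <- genome_scan(lm_tab, probs)
perm <- permutation_threshold(lm_tab, probs, n_perm = 100, seed = 3)
peaks_and_intervals(scan, perm)
autoplot(scan, threshold = perm)
```

## Known limitations

Single-QTL scans only: no multiple-QTL model selection, epistasis, or
interval mapping by EM, and no X-specific dosage model. The HMM's error
and switch parameters are explicit configuration, not estimates; the
original panel's genotyping pipeline (RAD-seq processing, calling from
reads) is out of scope, as is any relatedness-adjusted mixed-model
association machinery for population panels.
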