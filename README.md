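# simpullr

Photobleaching step counting and oligomer analysis for single-molecule
pull-down (SiMPull) experiments.

## The problem

SiMPull captures individual protein complexes from cell lysate on an
antibody-coated surface and images each as a diffraction-limited spot.
Under continuous excitation the GFP tags bleach one by one, so a
spot's intensity trace is a descending staircase, and the number of
downward steps counts the tagged subunits in the complex. Aggregated
over thousands of spots this yields, per condition, a normalized
oligomer-size distribution

$$f(k) = \Pr(\text{complex shows } k \text{ steps}), \qquad
\bar s = \sum_k k\, f(k),$$

where the average step count $\bar s$ summarizes the oligomerization
state. Two corrections make this quantitative. First, GFP tags
self-dimerize: a GFP-only control shows ~70% one-step and ~30%
two-step spots, so 30 percentage points of dimer mass are background
and are subtracted (moved from the 2-step to the 1-step bin; an exact
deconvolution mode for the underlying mixing model
$g(k) = (1-p)f(k) + p f(k-1)$ is also provided). Second, steps are
conventionally counted manually; `simpullr` replaces the human with a
deterministic penalized change-point fit (binary segmentation with a
BIC-style penalty, level merging, and explicit rejection rules for
upward jumps and over-long staircases), validated against an exact
dynamic-programming oracle.

The package is aimed at anyone analyzing subunit-counting
photobleaching data — or building and validating such a pipeline
without access to raw published traces: it ships ground-truth
simulators for bleaching traces (including GFP self-dimerization,
dark fractions and blinking) and for two-channel fixed-cell images
(nuclear/cytosolic GFP split, granules), plus quantification of
subcellular localization and granule areas, dissolution difference
profiles, condition statistics, and a reproducible pipeline with run
manifests.

## Worked example

Simulate a 500-spot GFP-only control at SNR 20, count steps, and apply
the self-dimer correction:

```r
library(simpullr)
phys <- gfp_photophysics()   # self-dimer 0.30, SNR 20
ctrl <- simulate_population(oligomer_spec(c(`1` = 1), n_spots = 500, seed = 1),
                            phys)
dist <- build_distribution(batch_detect(ctrl), condition = "GFP-only")
dist
#> <oligomer_distribution 'GFP-only': n = 500>
#>     1     2
#> 0.684 0.316
```

Every spot truly carries one tagged molecule; the 31.6% two-step
population is pure GFP self-dimerization (plus counting noise).
Subtracting it recovers the monomer:

```r
corr <- correct_gfp_background(dist, correction_model(0.30))
average_step(corr, seed = 1)
#>   condition average_step        sem n_traces
#> 1  GFP-only        1.016 0.01617679      500
```

The corrected average step is 1.02 ± 0.02 (bootstrap SEM over 500
traces) — a monomer, as it should be. A strongly oligomerizing
condition separates cleanly; here a synthetic mixture whose true
corrected mean is 3.0:

```r
mut <- simulate_population(
  oligomer_spec(c(`1` = 0.15, `2` = 0.25, `3` = 0.25, `4` = 0.20,
                  `5` = 0.10, `6` = 0.05), n_spots = 500, seed = 2), phys)
mdist <- build_distribution(batch_detect(mut), condition = "NLS-mutant-like")
average_step(correct_gfp_background(mdist, correction_model(0.30)), seed = 1)
#>         condition average_step       sem n_traces
#> 1 NLS-mutant-like        3.108 0.0761419      500
compare_conditions(c(dist$steps, mdist$steps),
                   rep(c("control", "mutant"), c(500, 500)))$p_value
#> t = -29.1, p = 8.53e-117
```

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full
study on synthetic data and write tables under `results/`:

1. `01_simulate_and_detect.R` — simulate six conditions (GFP control,
   wildtype-like, two intermediate mutant-like, NLS-mutant-like,
   stressed wildtype; 1,000 spots each) and count steps per spot.
2. `02_oligomer_analysis.R` — distributions, GFP correction, average
   steps ± bootstrap SEM, ANOVA/t-tests across conditions.
3. `03_dissolution.R` — before/after dissolution difference profiles
   for an effective denaturant vs. a resistant (salt-like) treatment.
4. `04_image_quantification.R` — synthetic fixed-cell cohorts:
   nuclear/cytosolic fractions, granule areas, percent
   granule-positive cells per condition.

Run them in order with `Rscript analysis/01_simulate_and_detect.R`
etc.; each prints a short narrative of what it found.

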