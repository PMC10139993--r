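---
title: "Counting subunits by photobleaching: models and methods in simpullr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting subunits by photobleaching: models and methods in simpullr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simpullr)
```

## The measurement

Single-molecule pull-down (SiMPull) immobilizes antibody-captured
protein complexes from cell lysate on a passivated surface and images
each complex as a diffraction-limited spot under TIRF illumination.
When the tag is GFP, continuous excitation bleaches the fluorophores
one by one, and the spot's intensity trace descends a staircase: one
abrupt, permanent drop per fluorophore. The number of downward steps
therefore estimates the number of tagged subunits in the complex —
monomer, dimer, trimer and so on. Aggregating step counts over
hundreds to thousands of spots per condition gives a normalized
oligomer-size distribution, and the mean of that distribution (the
"average photobleaching step") is a one-number summary of the
oligomerization state.

Two complications make the raw counts biased estimators of
stoichiometry:

* **GFP self-dimerization.** GFP tags weakly associate with each
  other, so even a strictly monomeric protein shows a substantial
  two-step population. In a GFP-only control roughly 70% of spots
  bleach in one step and 30% in two; that 30% is tag chemistry, not
  biology, and must be subtracted from every condition.
* **Manual counting.** Steps are conventionally counted by eye, trace
  by trace. `simpullr` replaces this with a deterministic change-point
  fit so the counting rule is explicit, reproducible and testable.

Because published pull-down datasets of this kind are not deposited as
raw traces, the package is built around simulators with known ground
truth: every downstream stage is validated against data whose answer
is known by construction.

## The trace generator

`simulate_trace()` draws one spot. Its noiseless skeleton starts at

$$I_0 = \mathrm{background} + m \cdot \mathrm{unit\_intensity},$$

where $m$ is the number of active fluorophores after dark-fraction
thinning, and loses one `unit_intensity` at each fluorophore's bleach
frame. Bleach times are independent geometric waiting times with
per-frame hazard `bleach_rate`; every fluorophore survives the first
frame, so the initial level is always observed. Gaussian noise of sd
`noise_sd` is added per frame. `simulate_population()` layers the
population model on top: each spot's true oligomer size $k$ is drawn
from a ground-truth distribution, one extra tagged partner is
recruited with probability `self_dimer_fraction` (the increment is
capped at +1 — chained dimer-of-dimer association is deliberately not
modeled), and the result is thinned by `dark_fraction`.

Defaults of `gfp_photophysics()` and why:

| parameter | default | rationale |
|---|---|---|
| `self_dimer_fraction` | 0.30 | reproduces the canonical 70/30 GFP-only control |
| `dark_fraction` | 0 | the single-bin correction assumes every tag is counted; nonzero values are robustness knobs only |
| `bleach_rate` | 0.005 / frame | mean bleach time 20 s at 0.1 s frames — slow enough that two fluorophores essentially never bleach in the same frame (~0.25% per pair), so a 6-mer still resolves six distinct steps |
| `unit_intensity` | 100 counts | arbitrary camera scale |
| `background_level` | 50 counts | arbitrary |
| `noise_sd` | 5 counts | SNR 20, a clean EMCCD recording |

The default movie length (1600 frames) leaves a fluorophore only a
~0.03% chance of outliving the window. Both residual imperfections —
same-frame double bleaches and window survivors — bias counts slightly
*downward*; at the defaults they are an order of magnitude smaller
than counting noise at n = 2000 spots.

An optional blinking mode (`blink_rate > 0`) inserts transient dark
excursions. It exists to stress the rejection rules: blinking produces
upward recoveries, which the detector treats as grounds for discarding
the trace, exactly as a human curator discards ambiguous traces.

What the generator does **not** emulate: EMCCD gain statistics
(noise is plain Gaussian), point-spread-function overlap between
neighboring spots, focal drift, and heterogeneous per-fluorophore
brightness. Passing tests therefore demonstrate correctness of the
counting and correction machinery under idealized photophysics, not
robustness to every artifact of a real microscope.

## Step detection

`detect_steps()` fits a piecewise-constant staircase by greedy binary
segmentation on the residual sum of squares. A change point is
accepted while the best available split reduces the RSS by more than

$$\mathrm{penalty} \times \hat\sigma^2 \log n,$$

a BIC-style cost with `penalty = 10` by default. The noise scale
$\hat\sigma$ is estimated robustly as the median absolute deviation of
first differences divided by $\sqrt 2$, which is insensitive to the
steps themselves. The calibration argument is analytic: on a flat
white-noise trace the largest spurious split gain concentrates around
$2\sigma^2 \log n$, while a genuine bleach step of height $h$
contributes a gain of order $h^2$ — at SNR 20, $h^2 = 400\,\sigma^2$.
A penalty of $10\,\sigma^2 \log n$ sits far above the noise floor and
far below the signal, keeping the false-positive step rate on flat
traces below 1% while leaving true steps untouched.

After segmentation, adjacent levels closer than `min_step_size`
(default $5\hat\sigma$) are merged, smallest difference first, with
length-weighted means; remaining downward transitions are the counted
steps. Three rules then mirror manual curation:

* any upward transition beyond `blink_tolerance` (default 0)
  invalidates the trace (`upward_step`) — upward jumps mean blinking,
  a second molecule landing, or focus artifacts;
* more than `max_steps` (default 8) downward steps invalidates it
  (`too_many_steps`) — reported stoichiometries run up to 4–6 steps,
  so 8 allows headroom without admitting aggregates;
* optionally, a final level away from a *known* background invalidates
  it (`no_bleach_to_background`); this check is off by default because
  the detector does not otherwise know the background level.

Numerical choices: change-point ties break toward the earliest frame;
the penalty has a small floor proportional to the squared intensity
range so that exact-zero-noise staircases terminate cleanly; the fit
is fully deterministic for a fixed input. Degenerate inputs (fewer
than 10 frames, non-finite values) raise input errors rather than
guesses.

`brute_force_fit()` is the package's own independent oracle: exact
dynamic programming over all placements of up to 4 change points on
traces of up to 200 frames. It exists for testing — the greedy fit is
checked against the global RSS optimum — and is never used in the
pipeline itself.

## From step counts to oligomer distributions

`build_distribution()` tallies valid traces with at least one step;
empty spots (zero steps) and rejected traces are excluded before
normalization, so the reported `n` is the number of traces actually
informing the distribution.

**The GFP correction.** `correct_gfp_background()` implements two
modes because two distinct questions arise:

* `bin_shift` (default): move `min(f2, 0.30)` of total probability
  mass from the 2-step bin to the 1-step bin. This is the standard
  single-bin subtraction: applied to the GFP-only control it returns a
  pure monomer (the control's known truth), and it lowers the average
  step by exactly the moved mass. It is the right tool for comparing
  conditions the way the field reports them.
* `deconvolve`: invert the generative mixing model
  $g(k) = (1-p)\,D(k) + p\,D(k-1)$ by back-substitution, clipping
  negative bins and renormalizing. The bin-shift rule is exact only
  when the underlying population is monomeric; for a genuinely
  oligomeric population, self-dimerization moves mass out of *every*
  bin, and only the full inversion recovers the underlying
  distribution. The package's end-to-end recovery tests use this
  mode, because "recover the simulated ground truth" is precisely the
  question it answers. The two modes agree on the monomer control.

Both modes conserve probability mass to within 1e-9, an invariant the
test suite checks on randomized inputs.

`average_step()` reports $\sum_k k f(k)$ with a seeded nonparametric
bootstrap SEM (default 1000 resamples) over the retained traces,
reapplying any recorded correction inside each resample — the SEM
therefore reflects the full estimation pipeline, not just multinomial
noise. `dissolution_difference()` compares a condition before and
after a dissolving agent as the per-bin difference of two normalized
distributions (zero-filled to a common bin range, summing to zero by
construction), with optional bootstrap CIs. A difference of
differences normalized to pre-dissolution mass would be an
alternative reading; the plain per-bin difference is implemented
because it keeps the conservation property and reads directly as
"where did the mass go". `compare_conditions()` delegates to the
standard machinery: two-sample t-test, one-way ANOVA with
Holm-adjusted pairwise tests, or two-way ANOVA when a stress factor
is supplied, all on per-trace counts (per-replicate means would be
equally defensible; per-trace counts are used because the simulator
produces traces, not replicates).

`pool_steps()` pools display bins beyond 6 into a "6+" category,
matching how step histograms are conventionally drawn; analysis always
runs on the unpooled distribution.

## Image quantification

The fixed-cell arm mirrors the trace arm: `simulate_cell_image()`
renders elliptical cells with elliptical nuclei on a configurable
pixel grid (default 0.25 μm/px), splits each cell's integrated GFP
signal so nuclear pixels carry exactly the configured
`nuclear_signal_fraction`, stamps circular granules as local intensity
amplifications, and returns ground-truth label masks alongside the
channels. Images round-trip through 16-bit multi-page TIFF.

`segment_cells_and_nuclei()` thresholds the nuclear stain with Otsu's
method — appropriate because that channel is genuinely bimodal — and
the GFP channel with a background-based rule (median + 4 robust SDs of
the whole field) rather than Otsu. The GFP histogram is multi-modal
(background, cytosol, nucleus, granules), and Otsu's two-class
criterion reliably places its threshold *above* the faint cytosol,
truncating cells to their bright nuclei; the background rule instead
asks only "is this pixel above the empty-field level", which is the
actual question. Both methods, plus fixed thresholds, are selectable
in `segmentation_params()`. Components are labeled deterministically
in centroid order, each nucleus is paired with the unique cell
containing it, and touching cells are not split (the generator
guarantees separation; crowded real fields are out of scope).

`localization_ratio()` integrates background-subtracted GFP (off-cell
median background) over nucleus and cell; the nuclear and cytosolic
fractions sum to one per cell by construction.
`quantify_granules()` defines a granule as a connected component
exceeding `granule_contrast` (default 5) times the reference median
with at least `min_granule_area` (default 4) pixels — a relative
criterion, so granule calls are invariant to rescaling the channel.
When a nucleus mask is available the reference median is computed per
compartment; otherwise a brightly nuclear cell (nuclear fraction
above ~0.6 at typical geometries) would itself exceed the whole-cell
threshold and be called one large granule. A cell is granule-positive
when at least one granule is detected; this ≥1 convention is a
declared choice, not a community standard.

## Problem sizes and reproducibility

The validation suite runs the workflow at the scale the measurements
are reported at: 2,000-spot populations for the GFP control and the
mixture-recovery check, 100 traces against the exact dynamic-
programming oracle, cohorts of 50 cells per nuclear fraction
(0.2/0.5/0.8), and 1,000 null simulations for the ANOVA type-I error
calibration — sizes chosen to make binomial confidence intervals
decisive while keeping a full run in well under a minute per stage.
Every stochastic step takes an explicit seed, populations are drawn
from a single per-run RNG stream, and `run_pipeline()` writes a
manifest (configuration snapshot, output checksums, per-stage counts)
so that any reported number can be traced to a stage output;
re-running with the same seeds reproduces the tables byte for byte.

## Known limitations

* The step counter assumes steps of roughly uniform height; it counts
  a same-frame double bleach as a single step rather than attempting
  height-based splitting, and it does not infer blinking — blinking
  traces are rejected, not repaired. A hidden-Markov treatment would
  recover them at the cost of determinism.
* The `bin_shift` correction is exact only for the monomer control;
  the `deconvolve` mode assumes the +1 self-dimer model with a known
  rate and amplifies multinomial noise at high bins (each inverted bin
  divides by $1-p$). Neither estimates `dark_fraction`; a binomial
  dark-fraction deconvolution is intentionally not offered as a
  default estimator.
* Image analysis is 2D, single-plane, and assumes separated cells and
  registered channels; granule calls depend on two tunable constants
  with no claim to match any manual annotation standard.
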