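---
title: "Open-complex delay variability and gene-expression noise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-complex delay variability and gene-expression noise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetnoise)
```

# The model and its assumptions

`tetnoise` studies a single-copy gene behind a tet-repressible promoter.
Induction by anhydrotetracycline (aTc) is summarised entirely by the
transcription-initiation rate constant `k1`: aTc pulls the TetR repressor
off the operator more often, so initiation attempts become more frequent.
TetR/aTc binding is not modelled explicitly — `k1` is, by construction,
the empirical knob that matches each condition's mean expression, so an
explicit repressor would only re-parameterise it.

The expression model has four mass-action reactions with delayed
products (`X(τ)` appears τ seconds after the firing):

```
Pro --k1--> Pro(τ1) + RBS(τ2)
RBS --k2--> RBS + P(τ3)
RBS --k3--> ∅
P   --k4--> ∅
```

Key structural assumptions:

* **The promoter is sequestered during open-complex formation.** `Pro`
  is consumed at initiation and returns only after τ1, so τ1 is a
  refractory period: consecutive initiations are separated on average by
  `1/k1 + E[τ1]` seconds. This is the mechanism the whole package is
  about. The reconstruction is validated quantitatively below.
* **RBS is the transcript proxy.** The ribosome-binding-site region
  becomes available τ2 = 2 s after initiation (transcription elongation
  of the RBS region) and is translated catalytically at `k2` while it
  survives (`1/k3` = 250 s).
* **P is mature GFP.** τ3 = 420 s bundles translation elongation,
  folding and chromophore maturation (< 8 min); only mature protein
  fluoresces, so only `P` is compared with measurements.
* First-order degradation for RNA and protein; no transcription
  abortion; the cell is well-stirred. Cell growth, division and
  polymerase/ribosome pools are out of scope — the measured populations
  were imaged at one time point, which the simulator mimics by sampling
  independent cells.

Model **variant 1** uses a constant τ1 = 19 s. Variant **2** draws τ1
per initiation from a gamma distribution with mean 19 s and standard
deviation 400 s (configurable), moment-matched to shape
`(19/400)² ≈ 2.26·10⁻³` and scale `400²/19 ≈ 8421`. The gamma family is
the natural waiting-time model for a multi-step sequential process; at
this shape it is extremely fat-tailed — the median draw is practically
zero while rare draws stall the promoter for thousands of seconds. Both
variants share every mean; they differ only in initiation-interval
*variability*.

## Closed-form oracle

Initiations form a renewal process with mean interval `1/k1 + E[τ1]`,
so at steady state

* mean RNA = `(1/(1/k1 + E[τ1])) / k3`
* mean protein = mean RNA × `k2 / k4`

independent of the delay's distribution. `steady_state_oracle()` is kept
as an analytic cross-check of the simulator (tested to within
Monte-Carlo error), and supplies the model means used to calibrate
fluorescence units.

## Validation of the reconstructed reaction set

The bundled measured summary gives mean GFP fluorescence (arbitrary
units) for the five printed `k1` values. If the reaction structure is
right, measured mean ÷ model mean must be one *condition-independent*
constant φ (fluorescence per GFP molecule):

```{r phi}
m <- measured_gfp_summary()
oracle <- vapply(tet_conditions()$k1, function(k1)
  steady_state_oracle(model_params(k1))[["mean_protein"]], numeric(1))
ratios <- calibration_ratios(m$mean, oracle)
round(ratios, 2)
sd(ratios) / mean(ratios)
```

The per-condition ratios agree to a coefficient of variation of about
2% (φ ≈ 53 a.u./molecule by least squares through the origin).
Alternative reconstructions — e.g. a promoter that is *not* sequestered
during τ1 — break this consistency, which is why this structure was
adopted. φ is deliberately a single global constant: per-condition
factors would trivially equalise the means and have no physical reading.

# The delayed stochastic simulation algorithm

The engine keeps a waiting list of pending delayed releases ordered by
release time (FIFO among ties). Each iteration draws a candidate
reaction and waiting time by a standard SSA step; the candidate fires
only if it would occur strictly before the earliest pending release,
otherwise that release happens and the candidate is discarded.
Conventions the printed algorithm leaves open, fixed here:

* **Tie `t + t1 = t_min`:** the release happens first. The event has
  probability zero in exact arithmetic; a fixed rule keeps runs
  deterministic.
* **Zero total propensity with a non-empty waiting list:** time jumps to
  the next release. This case is not exotic — it is the normal state of
  the model while the only promoter copy sits in the waiting list.
* **Delayed products with stoichiometry > 1** draw one delay per copy.
  Only τ1 is random in these models, with stoichiometry 1, so the choice
  has no effect here.
* **Gamma sampling at shape ≪ 1** goes through `rgamma`, whose
  Ahrens–Dieter sampler is valid for shape < 1; naive rejection samplers
  are not.
* **Seeding:** every cell of a population gets its own stream,
  `master_seed + cell index`, so populations are reproducible and any
  single cell can be re-simulated in isolation.

The production engine is compiled (Rcpp); a pure-R reference
implementation (`advance_one_event()`, `run_simulation(engine = "r")`)
expresses the same algorithm step by step and is compared against the
compiled engine in distribution in the test suite. Engine validity is
also checked against analytic laws: exponential waiting times, the
Poisson stationary distribution of a zero-delay birth–death process
(χ² at α = 0.01), the delayed-pure-birth mean `λ(t − τ)`, and
conservation of the promoter (free + pending = 1) through every run.

# Population statistics and the delay-SD scan

The Fano factor (sample variance with the n−1 denominator, divided by
the sample mean) is the package's noise measure; it is 1 for a Poisson
process and scales linearly under multiplication — which is what lets
fluorescence-unit and molecule-count Fano factors be compared through φ.

The fit distance `D = Σᵢ (Fano(E)ᵢ − Fano(M)ᵢ)²` sums squared
Fano-factor differences over the five inductions, with both operands in
fluorescence units (the only choice under which the operands share units
with the measured table). `scan_open_complex_sd()` evaluates D on a grid
of candidate τ1 standard deviations — default
`{0, 25, 50, 100, 200, 400, 800, 1600}` s, roughly logarithmic, with 0
meaning the constant-delay variant — and reports the argmin. Defaults of
1000 cells/condition for production fits (measurement scale is 88–299
cells/condition) and steady-state sampling at `t_sample` = 25 000 s
(5 protein lifetimes, from empty RNA/protein) keep the oracle exact; the
printed `k1` values absorb any mean-scale factor, so sampling at the
60-minute measurement time instead only rescales means, which the
calibration removes. Parameter-recovery tests run 20 seeded repetitions
at 300 cells/condition — measurement-scale populations at desk-scale
runtime — and require the argmin within one grid step of the generating
SD in ≥ 90% of repetitions.

One empirical note: with a *constant* 19 s delay, the strongest
induction (mean interval 54.7 s, of which 19 s is deterministic) has
initiation intervals with CV² ≈ 0.43, so the constant delay genuinely
*filters* noise there and lowers that condition's Fano factor by ~25%
relative to weak induction. "Approximately flat" for variant 1 is
therefore assessed as the coefficient of variation of the five Fano
factors (< 25%), not the min–max range, which the filtering effect
alone would inflate.

# Imaging pipeline: numerical choices

* **2×2 median filter:** an even window needs a convention; the output
  is the *lower* median (second-smallest) of the window anchored
  top-left, with replicated edges. This removes isolated hot pixels
  exactly and is deterministic.
* **"Small" threshold:** 10% of the way from the background level (the
  image median — most pixels are background) to Otsu's threshold on the
  sum projection. Anchoring at the background level keeps the fraction
  meaningful when the camera adds a constant floor; for a zero-floor
  image it reduces to a fraction of Otsu's threshold. Permissive by
  design — dim cells must survive, clusters are handled downstream.
* **Cluster detection:** solidity < 0.9 (area over convex-hull area of
  the pixel squares) or eccentricity < 0.7 (second-moment ellipse, with
  the 1/12 pixel-variance term). Healthy rods are convex and elongated;
  merged objects fail one of the two. Touching *parallel* pairs can form
  a near-convex, still-elongated object that these printed cutoffs
  cannot flag even in principle; the synthetic generator therefore grows
  clusters as V-shaped junctions, the geometry the cutoffs do detect.
* **Cluster splitting:** cell centres are brighter than cell borders in
  the sum projection, so extended maxima of the (σ = 1.5 px smoothed)
  intensity seed individual cells; maxima must rise at least `h` (10% of
  the cluster's dynamic range above threshold) and sit ≥ 5 px apart.
  Because a dim cell touching a bright one can hide below any single
  intensity criterion, the number of seeds is additionally capped by
  `round(cluster area / typical single-cell area)`, the typical area
  being the median over well-formed (non-cluster) objects in the same
  image; pixels join their nearest seed. On synthetic scenes this keeps
  precision at 1.0 while recovering ≥ 95% of cells at cluster fractions
  up to 0.2.
* **Slice selection:** the brightest slice per cell; among ties the
  lowest *interior* index; if only the first or last slice attains the
  maximum the cell is flagged (its focal plane likely fell outside the
  stack).
* **Outlier filters:** exactly `floor(0.025 n)` highest-intensity cells,
  then the strict 0.5–1.5× median-area rule (median over cells surviving
  the intensity rule). Records are flagged, never deleted.
* **Background:** ordinary least squares of control-cell (no reporter)
  total fluorescence on area in pixels; corrected intensities may be
  negative and are kept so (clipping would bias population moments).
  "Cell size" is area in pixels; no physical calibration is needed since
  φ absorbs all proportionality.
* **RNA spot counting:** spot images are *despiked* (isolated outliers
  vs the 3×3 median are replaced) rather than median-filtered — an even
  2×2 median attenuates diffraction-limited spot integrals by a
  variable 30–50%, destroying the integer-multiple structure the
  slicing method depends on. Spots are enhanced by a
  difference-of-Gaussian response, thresholded by Otsu on the
  log-compressed response *within eroded cell interiors* (the cell
  boundary's own edge response and the empty background would otherwise
  dominate the histogram), split at local maxima ≥ 4σ apart, and each
  spot is integrated over a fixed window (radius 2σ) around its
  centroid after subtracting the cell's diffuse level (median over
  pixels clear of the dilated spot mask). The unit intensity is the
  first mode of the spot-intensity distribution; on small samples this
  estimator is noisy, so the recommended workflow — used in the tests —
  calibrates the unit on a weak-induction image where nearly all spots
  are single RNAs, then applies it. Sub-0.3-unit detections are
  discarded as noise; remaining counts are `max(1, round(I/unit))`.
* Coordinates are 0-based and pixel-centred; connectivity is
  8-connected; manual exclusion is an explicit label list, never
  interactive.

# What the synthetic data does and does not emulate

The generator renders rods as blurred capsules with a bright-centre
radial profile and a Gaussian axial profile centred on a random interior
slice (so slice selection and the first/last-slice discard rule are
exercisable), adds autofluorescence linear in area by construction
(matching the background model's assumption, so `fit_background()` can
be tested for exact recovery), a constant camera floor whose Poisson
noise gives ~10% background CV, Gaussian read noise, and rare hot
pixels. Spot images add a diffuse cytoplasmic MS2-GFP level and
Gaussian spots whose integrals are exact RNA multiples of a unit;
co-localisation is honest — when a cell cannot host another resolvable
spot, the RNA joins an existing spot in both the image and the ground
truth.

Passing round trips on these scenes shows the pipeline implements its
stated rules and is robust to shot noise, size-dependent background,
merged cells and merged spots. It does *not* show robustness to what the
generator omits: optically rigorous PSFs, depth-dependent aberrations,
debris and filaments, uneven illumination, or motile/dividing cells.
Real-data use should treat the defaults (threshold fraction, `h`, area
limits, spot σ) as starting points.

# Problem sizes and limitations

Simulation-based tests use 300–1000 cells/condition sampled at
25 000 s; scan tests use the 8-point default grid with 20 repetitions;
imaging tests use 24–40 cells per 320²–352² scene with 5 slices. These
sizes were chosen to keep Monte-Carlo error well inside each test's
tolerance at desk-scale runtime.

Known limitations: Fano-factor estimates from heavy-tailed populations
converge slowly (the delay-SD scan resolves the order of magnitude of
the SD, not fine structure, at a few hundred cells); the unit-intensity
estimator needs a singles-dominated sample; the splitter's area-ratio
cap assumes images contain at least some well-formed single cells; and
confidence intervals on Fano factors and intrinsic/extrinsic noise
decompositions are out of scope.
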