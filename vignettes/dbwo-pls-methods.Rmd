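---
title: "Wavelength selection for NIR calibration with discretized beluga whale optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection for NIR calibration with discretized beluga whale optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbwopls)
```

## The problem

Near-infrared (NIR) spectra of food and pharmaceutical samples contain
hundreds to thousands of absorbance channels, most of which are redundant
or irrelevant for any one analyte: overtone and combination bands are
broad, heavily overlapping, and ride on sample-to-sample scatter
artifacts. Partial least squares (PLS) regression tolerates this
collinearity, but channels that carry no analyte information still inject
noise and interference into the calibration. Selecting a subset of
informative wavelengths before modeling can simplify the model and
improve external prediction.

`dbwopls` implements one family of answers to that problem: a binary
(discretized) beluga whale optimization, **DBWO-PLS**, that searches the
space of channel subsets directly by cross-validated predictive error,
plus the three classical comparators it is usually judged against —
uninformative variable elimination (UVE), its Monte Carlo variant
(MC-UVE), and a response-permutation randomization test (RT) — together
with the supporting machinery: SNV/MSC/Savitzky–Golay preprocessing,
Kennard–Stone partitioning, Monte Carlo cross-validation (MCCV), and a
synthetic NIR generator with a known informative mask so that every claim
in this vignette is testable without external data.

## The calibration core: PLS1 by NIPALS

All selectors score channel subsets through a single-response PLS model.
For centered spectra $E_0 = X - \bar{x}$ and centered response
$f_0 = y - \bar{y}$, each latent variable $a$ extracts

$$w_a = E_{a-1}^\top f_{a-1} / \lVert E_{a-1}^\top f_{a-1} \rVert, \quad
  t_a = E_{a-1} w_a, \quad
  p_a = E_{a-1}^\top t_a / t_a^\top t_a, \quad
  q_a = f_{a-1}^\top t_a / t_a^\top t_a,$$

followed by deflation $E_a = E_{a-1} - t_a p_a^\top$,
$f_a = f_{a-1} - q_a t_a$. The regression vector on centered data is
$b = W (P^\top W)^{-1} q$ and predictions are
$\hat{y} = \bar{y} + (X - \bar{x}) b$. For a single response the weight
direction is available in closed form, so no inner iteration is needed.
If the residual covariance $E^\top f$ vanishes before the requested
number of components (exactly low-rank data), extraction stops early and
the attained count is recorded — requesting more components than the
rank is then harmless rather than an error, which keeps RMSECV curves
defined past the true rank.

With the maximal number of latent variables on full-column-rank data,
PLS predictions coincide with ordinary least squares; the test suite
verifies this equivalence against `lm()` on random instances, and checks
the score-space prediction path $\hat{y} = \bar{y} + T q$ against the
coefficient path.

**Model complexity.** The latent-variable count is the decisive
hyperparameter. `select_lv_mccv()` computes the RMSECV curve over
$1..A_{\max}$ on one shared set of MCCV splits (so the curve is paired
across counts) and takes the argmin, with ties within $10^{-12}$ resolved
toward the smallest count. RMSECV itself pools squared validation errors
over all repeats before the square root, so repeats with different
validation sizes are weighted by prediction, not by repeat.

**Metrics.** RMSEP is the root mean squared error on the held-out
prediction partition; $R^2 = 1 - SS_{res}/SS_{tot}$ is the
sum-of-squares form (it can go negative for a predictor worse than the
mean, which makes it the stricter diagnostic), not a squared correlation.

## Preprocessing

Three pretreatments are provided, each attacking the additive/
multiplicative scatter that dominates diffuse-reflectance NIR:

* **SNV** centers and scales each spectrum to unit sample standard
  deviation ($n-1$ denominator, the dominant chemometrics convention;
  idempotence holds either way). It removes per-sample affine scatter
  exactly.
* **MSC** regresses each spectrum on a reference spectrum,
  $x \approx a + b\,r$, and corrects to $(x - a)/b$. The reference
  defaults to the *calibration-partition* mean and is then applied
  unchanged to the prediction partition, so no information leaks across
  the split.
* **Savitzky–Golay derivatives** (via `signal::sgolayfilt`) with default
  window 11 and polynomial order 2. Boundary windows are handled by the
  polynomial fit itself, so the output keeps the full channel count and
  selector masks stay aligned with the wavelength axis. The derivative is
  per channel step; a ramp of slope $s$ per channel returns $s$ at every
  channel, including the edges.

Per-sample transforms (SNV, derivatives) commute with sample
partitioning, so the workbench applies them before the Kennard–Stone
split; MSC is applied after the split with the calibration-mean
reference.

A caution the test suite encodes: SNV's division by the per-spectrum
standard deviation is itself a nonlinear distortion of the
concentration–absorbance relation. It pays off when scatter dominates and
constituent concentrations vary a few percent around a typical
composition (the regime the SNV test constructs); when compositions vary
wildly, the distortion can exceed the scatter it removes. Preprocessing
is a modeling decision, not a free lunch.

## Partitioning

`kennard_stone_split()` is the deterministic maximin procedure: seed with
the two samples at maximal Euclidean distance, then repeatedly add the
sample whose minimum distance to the selected set is largest, until
`round(fraction * n)` samples (halves away from zero) are selected. Ties
resolve to the lowest sample index, making the split a pure function of
the matrix handed in. At fraction 2/3 this reproduces calibration sizes
67, 207 and 48 for 100-, 310- and 72-sample datasets. The implementation
is verified against a brute-force maximin oracle on all small instances.

`mccv_splits()` realizes a Monte Carlo cross-validation plan: independent
uniform splits without replacement at a calibration fraction (default 50
repeats at 0.8), reproducible from the plan's seed. Reusing one plan
across all candidate subsets inside a selector run makes every fitness
comparison paired, which removes split noise from subset rankings.

## The baseline selectors

All three judge channels through the PLS coefficient vector and are
deterministic given their seed.

* **UVE** appends one artificial uniform-noise channel per real channel
  (amplitude $10^{-10}$: small enough not to perturb the fit, nonzero so
  the coefficients exist), computes the stability
  $s_j = \text{mean}(b_j)/\text{sd}(b_j)$ over the $n$ leave-one-out
  refits, and keeps real channels with $|s_j|$ above the largest noise
  stability.
* **MC-UVE** replaces leave-one-out with `n_mc` random subsamples
  (default 500 at fraction 0.8) — the variant of choice for small sample
  sets, with an optional top-$k$ rule because noise-max cutoffs can be
  aggressive.
* **RT** refits on `n_perm` permutations of $y$ (default 499) and keeps
  channels with permutation p-value
  $p_j = (1 + \#\{|b_j^{perm}| \ge |b_j|\})/(n_{perm}+1)$ below
  $\alpha = 0.05$. The smallest attainable p-value is
  $1/(n_{perm}+1)$, which bounds the resolution; with 19 permutations
  selection is only possible exactly at the 0.05 boundary.

An empty selection raises a classed error
(`dbwopls_empty_selection`) rather than silently falling back: an empty
model is a configuration problem, not a result.

**A power caveat the benchmark exposed.** RT's size is calibrated (its
null selection rate tracks $\alpha$ in the test suite), but its power
can collapse on smooth $p \gg n$ spectra at small latent-variable
counts: refitting PLS on a permuted response yields unstable, often
*inflated* coefficient magnitudes, so genuine channels may never look
extreme against that null. On the package's planted-band benchmark RT
frequently selects nothing. This is a property of the naive
coefficient-permutation statistic, reported as such.

## DBWO: the optimizer

Beluga whale optimization is a population metaheuristic with three
phases. Each generation, whale $i$ draws a balance factor
$B_f = B_0 (1 - T/(2 T_{\max}))$, $B_0 \sim U(0,1)$:

* **Exploration** ($B_f > 0.5$, "swimming"): paired-dimension
  sine/cosine moves toward a randomly chosen whale, applied at a random
  permutation of the dimensions.
* **Exploitation** ($B_f \le 0.5$, "preying"): a move toward the
  incumbent best, $r_3 X_{best} - r_4 X_i + C_1 L_F (X_r - X_i)$ with
  $C_1 = 2 r_4 (1 - T/T_{\max})$ and $L_F$ a Lévy-flight step
  (Mantegna construction, stability exponent $\beta = 1.5$, scale 0.05),
  whose heavy tail supplies occasional long escapes from local optima.
* **Whale fall** ($B_f \le W_f$): replacement
  $r_5 X_i - r_6 X_r + r_7 X_{step}$ with
  $X_{step} = (u - l)\exp(-C_2 T/T_{\max})$, $C_2 = 2 W_f \cdot pop$,
  and $W_f$ decaying linearly from 0.1 to 0.05 — a re-seeding pressure
  on poorly balanced whales that fades as the run converges.

Positions are clamped to bounds after every update.

**Discretization.** A transfer function maps each continuous coordinate
to $[0,1]$: the S-shaped `sigmoid` ($1/(1+e^{-x})$) is read as the
probability that a channel is *included*; the V-shaped `V1`
($|\mathrm{erf}(\tfrac{\sqrt{\pi}}{2}x)|$) and `V2` ($|\tanh x|$) are
read as the probability that the channel's previous bit *flips*. The
V-shaped rules therefore carry memory: near the origin they preserve the
current mask and mutate it gently, which is exactly what makes them local
searchers rather than resamplers.

**Why the position bounds are $[-1, 1]$.** Under a V-shaped rule the
transfer output *is* the per-channel mutation rate, so the typical
position magnitude sets the effective mutation rate of the discrete
search. With wide bounds such as $[-6, 6]$, uniform positions give a mean
`V2` flip probability of about 0.85 — nearly every channel flips every
generation, the V-shaped search degenerates to density-preserving noise,
and it can neither settle on a small subset nor exploit a good incumbent.
Bounds of $[-1, 1]$ keep all three transfer functions in their responsive
region (mean `V2` flip probability ≈ 0.38 at initialization, lower as
exploitation contracts positions) and restore the memory semantics that
motivate V-shapes in the first place. This choice was made after
instrumenting the search dynamics, and it is the package default.

**Fitness and acceptance.** A mask's fitness is the MCCV RMSECV of a PLS
model restricted to it, at a fixed latent-variable count and one shared
MCCV plan per run (paired comparisons; default 10 repeats at fraction
0.8 inside the optimizer, a deliberate trade of fitness precision
against the roughly `pop × iterations` refits a run costs — too few
repeats lets the search overfit split noise and select masks that do not
generalize). Fitness values are cached per mask. Each whale's new
position+mask is accepted only if not worse than its current one (greedy
elitist acceptance), so per-whale fitness and the incumbent best are
monotone non-increasing — the convergence curves the package emits are
guaranteed monotone, and `convergence_report()` treats a rising curve as
a hard failure.

A minimum-selection guard activates uniformly random additional channels
whenever a binarized mask would drop below the latent-variable count, so
the PLS fitness is always defined.

**Defaults.** Population 30, 500 iterations, `V2` transfer — on the
package's benchmark (and in the convergence behavior the method is known
for) the best-so-far curve drops steeply early, slows, and stabilizes
well before 500 iterations; the fitness contains no variable-count
penalty, so any parsimony in the result emerges from the search itself.

## The synthetic generator and what passing tests mean

`generate_spectra()` draws Beer–Lambert mixtures: per-component pure
spectra are sums of Gaussian bands, sample spectra are
concentration-weighted sums, corrupted by a per-sample affine scatter
(uniform additive offset of amplitude `baseline_amp`, multiplicative
factor $\sim N(1, \texttt{scatter\_slope\_sd})$) and i.i.d. channel
noise. The response is the concentration of one designated component,
drawn independently uniform per component (full-rank design). In the
noiseless artifact-free limit the spectra–response map is exactly linear
with rank equal to the component count — the sanity anchor for the PLS
engine.

`planted_band_benchmark()` is the canonical selector fixture: 60 samples,
200 channels (1100–1498 nm by 2 nm), three broad-band interferents and a
target component with a single narrow band at 1300 nm (sd 8 nm, so 17
channels lie within two band widths — the informative-mask convention
used to score recall; it is a scoring convention, not a physical claim).
Two design points deserve emphasis:

* **The target band is spectrally isolated from the interferents.**
  Piloting the first draft of this benchmark, with interferent bands
  overlapping the target band, showed the full spectrum is then optimal
  essentially by construction: out-of-band channels are required to
  correct the interference under the target band, so no selector can
  beat full-spectrum PLS there. Variable selection can only pay off when
  the informative channels are separable from the interference — the
  regime a planted-band benchmark is meant to probe.
* **Artifact magnitudes are moderate benchtop-NIR levels** (baseline
  ±0.05 AU, 5% multiplicative scatter, noise sd 0.02 AU against band
  heights of 0.6–1.0 AU), set so a full-spectrum 4-LV calibration is
  decent (prediction $R^2 > 0.8$ on a Kennard–Stone held-out third)
  while uninformative channels still carry enough noise and interference
  for selection to matter.

What the generator does **not** emulate: instrument line-shape functions,
wavelength-dependent (non-affine) scatter, water-vapor and temperature
effects, reference-method error in $y$, and the band congestion of real
NIR overtone regions. Passing the selector tests therefore demonstrates
correct algorithmic behavior under a controlled, favorable geometry — it
does not promise comparable improvements on any particular real dataset,
where the informative/interfering structure is unknown and usually less
separable.

**Study sizes.** The optimizer studies in the tests and the acceptance
script run population 20 for 100 generations over 10 replicate seeds on
this benchmark, with a 10-repeat MCCV fitness — sizes chosen so the full
study is a desk-scale computation while still averaging over seed
variability. Measured at these conditions: the DBWO-selected model's mean
RMSEP beats the full spectrum's, and `V2` reaches a lower mean final
RMSECV than `sigmoid`, the two qualitative directions the method is known
for. The mean recall of the informative band at these conditions is about
0.45–0.5 (the test asserts ≥ 0.35); masks that beat the full spectrum
are not required to contain the whole planted band, because partial bands
plus quiet channels can already suppress most interference noise.

## Numerical choices and degenerate inputs

* Wavelength grids: inclusive arithmetic sequences; a partial final step
  is dropped; a $10^{-9}$ relative tolerance in the count guards against
  float round-off at exact endpoints.
* Kennard–Stone ties: lowest sample index (pure determinism); seed pair
  ties resolved lexicographically.
* Latent-variable ties: smallest count within $10^{-12}$ of the minimum.
* SNV on a constant spectrum, MSC on a row orthogonal to the reference,
  zero-variance responses, NaN cells, duplicate sample ids: all hard
  errors naming the offending sample or channel.
* UVE noise amplitude $10^{-10}$; stability denominators of exactly zero
  are floored at the smallest positive double, mapping constant
  coefficients to ±infinite stability rather than NaN.
* All stochastic routines take an explicit seed and restore the caller's
  RNG state, so library calls never perturb a user's random stream.

## Known limitations

* The optimizer is a stochastic search; per-seed results vary, and only
  seed-averaged directions are asserted. No convergence proof is implied
  by a monotone curve.
* The latent-variable count is fixed during subset search (the
  full-spectrum optimum), not re-selected per candidate subset; re-tuning
  per subset would be fairer to very small subsets at a large multiple of
  the compute cost.
* RT power in $p \gg n$ settings (above); UVE's noise-max threshold can
  be conservative enough to return empty masks on weak-signal data.
* MSC assumes the scatter model is affine in the reference; wavelength-
  dependent scatter is out of scope (no EMSC).
* The comparison workbench reproduces a protocol, not any particular
  published table: with unreported seeds, population sizes and
  thresholds, external results can be matched in direction but not
  digit-for-digit.
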