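---
title: "Methods: mass-spectrometric validation of complex models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-spectrometric validation of complex models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structms)
```

`structms` chains five measurements that together test whether a
predicted structure of a protein–peptide complex is consistent with
its behaviour in solution: theoretical collision cross-sections (CCS)
from coordinates, traveling-wave ion-mobility calibration, native-MS
stoichiometry, hydrogen–deuterium exchange (HDX) kinetics, and a
CCS-based accept/reject decision between candidate architectures.
This vignette records the models, the defaults, and the choices made
where the methods literature leaves room.

## Projection-approximation CCS

The projection approximation treats the ion as a union of hard
spheres, one per atom, each inflated by a probe radius representing
the collision gas, and estimates the CCS as the mean area of the 2-D
shadow over uniformly distributed orientations:

$$\Omega \;=\; \langle A(\hat u)\rangle_{\hat u \sim \mathrm{S^2}},
\qquad
A(\hat u) = \mathrm{area}\Big(\bigcup_i \mathrm{disc}\big(P_{\hat u} x_i,\; r_i + r_\mathrm{probe}\big)\Big).$$

`pa_ccs()` samples orientations as seeded uniform random directions
and reports the mean with a Monte-Carlo standard error from the
orientation-to-orientation variance. Projected areas are evaluated
analytically for one or two discs (single sphere, circular-lens
overlap) and by rasterization otherwise, with pixel size 0.1 × the
smallest disc radius; `pa_ccs_oracle()` is the deterministic
cross-check, using a Fibonacci-lattice orientation set and a 2× finer
raster, and is used throughout the tests as an independent reference.
For a single sphere both reduce to Cauchy's theorem (mean projection =
surface/4 = πR²), which anchors the analytic test cases.

Defaults and their reasons:

- **Probe radius 1.0 Å** — a nitrogen drift-gas proxy; the projection
  convention must be stated explicitly because the empirical scaling
  below was calibrated under a specific convention.
- **Radius table `"bondi"`** — Bondi van-der-Waals radii; a
  `"united"` table with inflated heavy atoms is available for
  hydrogen-free crystal structures. Models are never protonated.
- **Scaling ×1.14 only via `scale_ccs()`** — raw projection areas
  underestimate protein CCS systematically; the conventional constant
  correction is applied explicitly, recorded in the output, and the
  raw value stays recoverable (`value / scale_factor`), so scaled and
  unscaled numbers can never be confused silently.
- **Seeds are mandatory in outputs** — every stochastic estimate
  carries the seed that reproduces it.

The oracle's pixel and angular resolutions were fixed by a convergence
test (doubling the angular grid moves the dumbbell value by < 0.1%).
Projection areas ignore concavity shadowing and gas–ion interactions;
trajectory-style methods are out of scope, which is precisely why the
empirical scale factor is carried as explicit provenance.

## Traveling-wave calibration

T-wave drift times lack a closed-form CCS relation, so the standard
protocol calibrates against species of known drift-tube CCS:

$$t' = t - \frac{c\,\sqrt{m/z}}{1000}, \qquad
\Omega' = \Omega \frac{\sqrt{\mu}}{z}, \qquad
\ln \Omega' = a + b \ln t',$$

with reduced mass μ = mM/(m+M) against the drift gas. The EDC delay
coefficient `c` (default 1.41; the µs-scale instrument constant, hence
the /1000 when times are in ms) and the drift-gas mass (default
nitrogen, 28.0134 Da) are explicit configuration, not constants buried
in code. Reference CCS basis (He vs N₂) is carried as a label and two
bases are never mixed within one fit — the classic silent error in
this workflow. `drift_to_ccs()` inverts the fitted line;
`atd_peak()` locates arrival-time apexes by three-point parabolic
interpolation and reports FWHM by linear interpolation of the
half-height crossings. `simulate_atd()` warns when a simulated CCS
falls outside the corrected-CCS span of the calibrants, because the
power law is then an extrapolation.

## Native-MS deconvolution

`pick_peaks()` thresholds local maxima at `min_snr` × the median
absolute deviation of the intensity above its median — a robust noise
floor that returns an empty peak list (not an error) for flat or pure
noise input — and centroids by a three-point parabola.

`infer_mass()` exploits the defining property of an electrospray
charge-state series: adjacent charges z and z+1 of neutral mass M
appear at (M + z·m_H)/z, so two peaks determine z by
`round((p2 − m_H)/(p1 − p2))`. Candidate series are extended across
charges while per-peak implied masses agree within a ppm tolerance,
constrained to a *consecutive* charge run (a physical envelope has no
holes); the best-supported series is accepted, its peaks removed, and
the search repeats. The consecutive-run constraint is what separates
interleaved series from different species. A genuine limitation
remains: masses in exact harmonic ratio (a dimer at exactly 2×, with
coincident peaks) cannot be split where their peaks coincide — those
shared peaks are assigned to one series. Adduct mass defaults to the
proton (1.007276 Da, positive-mode native ESI).

`assign_stoichiometry()` enumerates all bounded count combinations
exhaustively and reports every hypothesis within tolerance sorted by
|error| with ties broken by fewer subunits; ambiguity is flagged,
never resolved silently, because distinguishing a true 1:4 complex
from a coincidental mass match is the job of orthogonal evidence
(e.g. dissociation experiments), not of the enumerator.

`species_abundance()` sums apex intensities over a species' charge
states and normalizes across species — the simplest auditable choice;
peak areas are an option the analyst can compute from the peak table.
`titration_transition()` fits a four-parameter logistic in log molar
ratio weighted by replicate SD and accepts a transition only when the
sigmoid beats a flat model by ΔAICc > 2 *and* describes a decline; a
rising profile for the queried species returns "no decline".

## HDX uptake and kinetics

Percent deuteration uses the fully deuterated control as the
back-exchange-absorbing denominator:

$$\%D(t) = 100\,\frac{m_t - m_0}{m_{full} - m_0}.$$

The labelling-buffer D₂O fraction (default 0.925) is recorded with
each curve; whether it should additionally normalize %D is a
convention that differs between labs, so it is provided as an explicit
switch (`normalize_d2o`, default off) rather than silently applied.
Exchangeable-amide counts exclude prolines and the two N-terminal
residues, the standard convention.

`fit_uptake()` fits one-phase and two-phase association by weighted
least squares and selects by corrected AIC, with two overrides: a
curve already at ≥95% of its plateau at the first timepoint is called
one-phase (the fast regime is unresolved by construction), and a flat
near-zero curve is flagged "no exchange". Three numerical choices
deserve a note:

- **Pooled replicate variance.** Per-timepoint SDs from triplicates
  are χ-distributed with 2 degrees of freedom — too noisy to weight
  with individually. The replicate SD is pooled across timepoints
  (the generator and most real peptides are homoscedastic on the %D
  scale), giving weights with ~10 df for the standard design of five
  timepoints × three replicates.
- **AICc on the replicate likelihood.** With five timepoint means the
  four-parameter model has n − k − 1 ≤ 0 and AICc is undefined. The
  likelihood is therefore that of the replicate summary statistics
  (mean, SD, n per timepoint), whose effective sample size is Σnᵢ
  (15 for triplicates), making AICc well-defined for both models.
- **Rate caps at 5/t_min.** A phase faster than ~5/t₁ is complete
  before the first timepoint; the data then carry only a lower bound
  on the rate, and an unbounded optimizer runs onto a zero-gradient
  ridge and fails. Rates are therefore capped at 5/t_min (5 min⁻¹ for
  the standard 1-min first timepoint); an estimate at the cap should
  be read as "faster than resolvable".

Confidence intervals undo the nls residual-variance rescaling (the
error scale is known from the pooled replicates), correct for the
inverse-chi-square bias of estimated weights (df/(df−2)), and use a t
quantile at the pooled degrees of freedom. In simulation at the
standard design this gives ~94% joint coverage for (D_max, k).

`protection_compare()` reports per-timepoint ΔD = free − bound with
the propagated pooled SD √(s²_free + s²_bound) and calls "protected"
only when ΔD exceeds `k_sd` (default 2) of that SD at one or more
timepoints with no significant opposite-sign difference. Using the SD
of a single-replicate difference (not the SE of the mean) is the
conservative convention common in HDX reporting; it keeps the
false-positive rate of the five-timepoint scan well below 5%.
Swapping the inputs maps protected ↔ deprotected by construction.

## Discrimination

`rank_models()` scores candidates by relative CCS deviation and
accepts within a threshold, default **5%**: wide enough to bracket
deviations of 1–4% that gas-phase measurements of compact complexes
routinely show for a correct model, narrow enough to reject a surface
pose ~6% away. When several accepted candidates are mutually closer
than the threshold, a warning notes that gas-phase compaction of
flexible regions can equalize the CCS of genuinely different
architectures — in that regime CCS supports but cannot select a
model, and `resolvability()` makes the grouping explicit.

## What the synthetic generators emulate — and what they do not

The generators produce every input the pipeline reads, each carrying
its ground truth and seed:

- `make_geometry()`: spheres and dumbbells (analytic CCS truth),
  self-avoiding bead chains, and pocket-vs-surface complexes of
  identical composition — the minimal pair reproducing the
  buried-ligand < surface-ligand CCS ordering that discrimination
  must detect. The ligand walk is confined to the host cavity;
  impossible geometries error.
- `simulate_spectrum()`: Gaussian peaks at (M + z·m_H)/z under a
  discretized-Gaussian charge envelope centred on the native-like
  heuristic z̄ = 0.0778·√M, additive seeded noise. No isotope fine
  structure, no adducting, no detector saturation.
- `simulate_atd()`: single Gaussian arrival-time peaks through the
  inverse calibration. No multi-conformer tails, no ion heating.
- `simulate_hdx()`: triplicate centroid tables inverted exactly
  through the uptake formula, with Gaussian replicate noise (default
  2 percentage points, a typical triplicate spread) at the standard
  1/5/10/30/60 min timepoints. No EX1 bimodality, no peptide overlap,
  no chromatographic carryover.

Passing tests on these inputs therefore demonstrates correctness of
the inference chain — deconvolution, calibration inversion, kinetic
model selection — under idealized peak shapes and noise, not
robustness to the pathologies of real spectra (overlapping envelopes,
baseline drift, in-source dissociation). The abundance analysis
offers a species-exclusion list for exactly such a known pathology:
oligomer dissociation in the source producing spurious dimer signal.

Problem sizes used in the test-suite recovery studies (100 seeded
replicates for kinetics and protection rates; 1500–2000 Monte-Carlo
orientations against 400–800 quadrature orientations; 20-bead chains)
were chosen as the smallest sizes at which the Monte-Carlo error is
comfortably below the tolerances being verified.

## Known limitations

- PA-CCS is a shadow-area approximation; for large concave ions it
  underestimates relative to trajectory methods, which is the role of
  the explicit ×1.14 factor — valid only for the convention it was
  calibrated under.
- Harmonically related masses with coincident peaks cannot be fully
  deconvolved from peak positions alone.
- Exact rates faster than 5/t₁ are reported as bounds, not estimates.
- The discrimination threshold is a calibrated convention, not a
  statistical test; `resolvability()` should always accompany an
  accept/reject call.
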