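---
title: "rodfold: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rodfold: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodfold)
```

rodfold analyses how an elongated tandem-repeat bacterial surface protein —
the staphylococcal biofilm adhesin SasG and its seven-G5/six-E repeat region
is the motivating system — achieves simultaneous length and mechanical
strength. It bundles four quantitative pipelines (single-molecule distance
measurement by stepwise photobleaching, AFM unfolding analysis, two-state
folding thermodynamics with an interface free-energy ledger, and coarse
bead-chain shape modelling) together with seeded generators that produce
synthetic data with known ground truth for every pipeline. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic benchmarks do and do not demonstrate.

## Unit conventions

All internal lengths are nm, forces pN, energies kcal/mol. Thermal energy is
`kBT = 4.114 pN nm` and `RT = 0.592 kcal/mol`, both at 25 °C
(`rodfold_constants()`). Contour-length increments are reported in Å only at
the presentation layer (`afm_pool_traces()` summaries), matching the
conventions of the force-spectroscopy literature.

## SHRImP distance measurement

Two fluorophores on one molecule, separated by far less than both the pixel
(157 nm) and the diffraction limit, cannot be resolved directly. After the
first fluorophore bleaches, however, the remaining image is a single-emitter
PSF; subtracting it from the pre-bleach image isolates the other emitter.
The pipeline is:

1. **Spot seeding** (`find_spots()`): local maxima of the early-frame mean
   above a robust intensity threshold. This stands in for the proprietary
   multi-step detector used with the original instrument software; it is a
   deliberate, documented simplification.
2. **Trace filtering** (`chung_kennedy_filter()`): each sample is predicted
   by the mean of a past and a future window; predictions are blended with
   weights `∝ (recent squared prediction error)^(-exponent)`. The filter is
   edge-preserving because the window that straddles a step predicts badly
   and loses its weight. *Window choice:* a window `w` preserves a plateau
   exactly only if the plateau is at least `2w + 1` frames long. Since the
   step-acceptance rule below requires 7-frame plateaus, the default window
   is 3 — the largest value that can never distort an acceptable trace.
   Exponent 2 is the conventional weighting.
3. **Step detection** (`detect_two_steps()`): candidate change points where
   the discrete derivative exceeds `max(4 × MAD, 0.25 × max |derivative|)`.
   The MAD term adapts to noise; the relative floor suppresses the small
   residual distortions the filter leaves between closely spaced steps. A
   trace is accepted only with exactly two downward steps, levels
   `I1 > I2 > I3`, and all plateaus ≥ 7 frames — the automated counterpart
   of selecting clean two-step bleaching traces by eye. Rejection is a
   result with a reason, not an error.
4. **Level images** (`level_images()`): per-pixel means of the 7 frames
   before and after the first step give `I1` (both emitters) and `I2`
   (survivor).
5. **PSF fitting** (`fit_psf()`): the survivor is localized on `I2` and the
   first-bleached emitter on `I1 − I2`, each with a rotated elliptical
   Gaussian `A exp(−(a Δx² + 2b ΔxΔy + c Δy²)) + B` integrated over each
   pixel (4×4 Gauss–Legendre quadrature per pixel; quadrature error is far
   below shot noise for σ ≈ 0.7 px). Levenberg–Marquardt with moment-based
   starts; a flat or non-converging region yields a failed fit, not an
   exception.
6. **QC and distance**: eccentricity `e = sqrt(1 − (σmin/σmax)²)` per fit;
   a pair passes when both fits converge and both `e` are below the
   threshold. The distance is the Euclidean separation of the two centres
   in nm.

**On the eccentricity threshold.** The historical cutoff `e < 0.04` demands
an axis ratio above 0.9992. A symmetric PSF fitted to `N` photons has width
fluctuations with CV ≈ `1/sqrt(2N)`, so the *typical* eccentricity of a
perfectly circular spot is `e ≈ sqrt(2 × CV)` — about 0.14 at the ~10⁴
photons a 7-frame level image collects. With the formula above, 0.04 would
reject essentially every shot-noise-limited fit. The default is kept at
0.04 for fidelity to the published workflow, but the recommended working
threshold at these photon budgets is 0.3 (several times the typical
shot-noise eccentricity, still strict enough to reject overlapping or
elongated spots); the reproduction script uses 0.3.

7. **Histogramming** (`distance_histogram()`): Freedman–Diaconis bin width
   `2·IQR·n^(−1/3)` rounded to the nearest 5 nm (25 nm reproduces the
   presentation binning of the original study); a Gaussian
   `A exp(−(r−μ)²/2σ²)` is least-squares fitted to the counts.

### What the TIRF generator emulates

`simulate_tirf_movie()` renders each molecule as two pixel-integrated
Gaussian PSFs (default σ = 110 nm: diffraction-limited for ~525 nm emission
at NA 1.4; the pixel is 157 nm and frames 500 ms at 2 fps). Each fluorophore
bleaches in a single irreversible step with a geometric lifetime (default
mean 40 frames); Poisson shot noise, camera gain and Gaussian read noise are
applied. Defaults are 1500 expected photons per active fluorophore per
frame and 10 background photons/pixel/frame — values typical of the dye and
camera class used in such experiments; photon budgets were not published,
so these are stated assumptions, not inferences from data. The generator
does **not** simulate blinking, drift, dipole-orientation effects or
dual-channel registration, so passing recovery tests demonstrate the
correctness of the estimator pipeline, not robustness to every
photophysical artefact of real movies.

## AFM unfolding analysis

A 13-domain polyprotein (seven G5, six E) is stretched between a surface and
a Hookean cantilever (nominal 30 pN/nm) retracting at constant speed.
Domains unfold in order of mechanical stability, each adding its
contour-length increment ΔLc to the unfolded chain, producing the familiar
sawtooth.

### Forward model

`simulate_afm_trace()` is quasi-static: at every instant the force balance
`F = k_c (z − x) = F_WLC(x; Lc, p)` holds, with the Marko–Siggia
interpolation

    F(x) = (kBT/p) [ 1/(4(1 − x/Lc)²) − 1/4 + x/Lc ].

Rather than root-solving per sample, the ramp is parametrized in force:
`z(F) = Lc·u(F) + F/k_c` is closed-form and monotone once the inverse
relative extension `u(F)` is tabulated (vectorized bisection to 80
iterations, interpolated thereafter), so force at the sample times follows
from one monotone interpolation per segment.

Two unfolding models are provided:

* `unfold_model = "threshold"` — each domain draws a rupture force from its
  class's Gaussian (defaults: E 250 ± 35 pN, G5 421 ± 36 pN at 800 nm/s,
  with ΔLc 14.5 and 21.6 nm) and ruptures when the force first reaches it.
  This mode encodes a measured rupture-force distribution directly as
  ground truth and is used for the recovery benchmarks.
* `unfold_model = "bell"` — each folded domain unfolds as a Poisson process
  with rate `k0 exp(F xu / kBT)`; the event time is sampled by inverting the
  trapezoid-integrated cumulative hazard along the ramp. This mode produces
  the physical speed dependence and is used for Bell–Evans studies.
  `bell_from_force_dist()` converts a modal force ± sd at one speed into
  `(k0, xu)` via `xu = kBT/sd` and the Bell mode equation, with the loading
  rate taken as speed × series stiffness of cantilever and chain.

The tether detaches deterministically at `detachment_force` (default
600 pN, above the G5 distribution); a short zero-force tail follows so the
detachment peak is detectable. Gaussian force noise (default 10 pN) is added
to the assembled trace. The initial contour length (default 60 nm) stands
for the folded rod plus attachment geometry.

### Analysis

`detect_events()` finds local maxima of a lightly smoothed force that are
followed by a drop ≥ 30 pN within 20 samples and exceed 50 pN, merges
candidates within the drop window (noise maxima on a rising edge near a
rupture pass the same test), then refines each peak to the sample preceding
the sharpest raw force drop and reports the mean of the last three
rising-edge samples — so the reported force is not the maximum of the local
noise. `fit_segment()` fits the single parameter `Lc` of the WLC (persistence
length fixed at 0.4 nm) to each rising edge above 20 pN;
`delta_lc()` takes exact differences of consecutive `Lc`; `classify_event()`
assigns E to ΔLc ∈ [12, 18.5) nm and G5 to [18.5, 26] nm — windows that
bracket the measured per-speed ranges (145–154 Å and 216–227 Å) with the
boundary at the midpoint gap. `accept_trace()` requires ≥ 3 classified
events, a detachment peak, and class counts within the construct
composition (≤ 6 E, ≤ 7 G5). Accepted traces are pooled within a speed
(mirroring the pooling of experimental triplicates) and
`modal_stats()` reports the mode ± sd of Gaussian fits to histograms —
0.5 nm (5 Å) bins for ΔLc, Freedman–Diaconis bins for force. When a
distribution collapses into a single bin the sample median/sd are reported
and flagged degenerate. `speed_series()` regresses modal force on ln(speed);
under Bell–Evans the slope estimates `kBT/xu`. Note the estimate is biased
downward by a drifting loading rate when the chain stiffness varies strongly
across the speed range; with a compliant cantilever (`k_c` small compared
with the chain stiffness) the loading rate is ~ `v·k_c` and the recovery is
clean.

Benchmark problem sizes: 200 traces at 800 nm/s for the recovery ensemble,
30 traces per speed for speed-dependence properties; at a 10 kHz sampling
rate a full 13-domain pull is ~3,900 samples.

## Folding thermodynamics

Equilibrium urea denaturation follows the two-state model with linear
baselines:

    Y(D) = [(αN + βN D) + (αD + βD D) K] / (1 + K),  K = exp(m(D − D50)/RT)

`fit_two_state()` fits all six parameters by Levenberg–Marquardt and reports
`ΔG = m·D50` as an exact identity with a delta-method standard error
including the m–D50 covariance. A fit is refused when a straight line
explains the data as well as the sigmoid or the fitted transition amplitude
is within 3 residual standard deviations of zero — the automated version of
"no detectable transition". `ddg()` differences two constructs with errors
in quadrature.

Chevron data (`fit_chevron()`) are fitted on log observed rates. Two-state:
`kobs = kf0 e^(−m_kf D) + ku0 e^(m_ku D)`. The sequential transition-state
variant replaces the unfolding limb with the harmonic combination
`1/ku = 1/(ku1 e^(m_ku1 D)) + 1/(ku2 e^(m_ku2 D))` — two barriers in series,
the slower limiting the rate, which curves the limb as the rate-limiting
barrier switches with denaturant. The cited kinetic analysis names the
model without equations; this harmonic form is the package's documented
choice and is swappable. With `model = "auto"` the extra barrier is adopted
only when it reduces the residual sum of squares by > 20%. Kinetic and
equilibrium measures are mutually consistent on matched synthetics:
`RT ln(kf0/ku0) = m·D50` and `RT(m_kf + m_ku) = m` to numerical precision.

### The interface free-energy ledger

Multi-domain stability is book-kept as per-domain folding free energies
(negative = stable) plus interface contributions. Sign conventions matter:
equilibrium tables report unfolding ΔG (positive = stable); the ledger
converts internally and tags every derived value with its rule and bound
direction. Two rules are implemented:

* **Rule A, partition additivity**: for a construct partitioned into
  independently measured parts,
  `ΔG_int = ΔG_fold(construct) − Σ ΔG_fold(parts)`. If any part is known
  only as a bound (e.g. a domain that never folds alone, `ΔG_fold ≥ +2.5`),
  the interface term is a lower bound on the conferred stabilization.
* **Rule B, midpoint-shift bound**: a domain folding inside a construct at a
  higher midpoint than in isolation is stabilized by at least
  `m_domain × (D50_construct − D50_domain)`; attributing the whole shift to
  the flanking interface bounds that interface from below. Rule-B outputs
  are always bounds.

With the measured domain stabilities (−3.2, ≥ +2.5, −2.8 kcal/mol for the
first G5, E, and second G5) and construct fits, rule A yields ≥ 6.0 kcal/mol
for the E:G5 interface and rule B ≥ 1.7 kcal/mol for the G5:E interface —
both consistent with the published bounds (≥ 6 and ≥ 1.5). These rules are
a declared reconstruction of the bound bookkeeping, not a transcription of
the original supplementary algebra (which is not available in the source
text); the invariant maintained is that a bounded input can never produce
an equality output.

## Bead-chain shape models

`build_chain()` lays alternating G5/E domains along an axis as bead
cylinders. The default domain lengths (G5 6.2 nm, E 4.6 nm) are the unique
solution of the two crystallographic anchors — 17 nm for the three-domain
fragment and 71 nm for the full 13-domain array — because individual domain
lengths are not printed in the source text. `sample_flexed()` tilts each
inter-domain junction by a Gaussian polar angle about a uniform azimuth,
keeping domains rigid: the minimal model of interface-limited flexibility.
A rigid 13-domain chain is 71 nm end-to-end; modest junction flexibility
(σ ≈ 10–20°) brings the apparent maximum dimension below the rigid length,
the same direction as the ~63 nm solution value.

Model observables: `pair_distribution()` (normalized pair-distance
histogram; Dmax is the exact maximum pairwise distance, computed in
memory-bounded blocks), `cross_section_distribution()` (pair distances
after projecting out the longest inertia axis; ties are resolved by
coordinate order), `debye_intensity()`
(`I(s) = ΣΣ sin(s r)/(s r)` evaluated through a finely binned pair-distance
histogram, exact at `s = 0`), `guinier_fit()` (`ln I` vs `s²`, slope
`−Rg²/3`), `cross_section_guinier()` (`ln(I·s)` vs `s²`, slope `−Rc²/2`)
and `porod_exponent()` (log–log mid-s slope: ~1 for thin rods, ~4 for
globules). Validity windows matter and are the caller's responsibility: the
Guinier linearization of a sphere is good to 1% only for `s·Rg ≲ 0.8`, and
for strongly elongated particles `s·Rg ≲ 0.5` keeps the bias below 2%;
the cross-sectional fit should sit at `s·Rc` of roughly 0.3–0.7, above the
overall-size regime. Nonlinear-residual warnings are flagged on both fits.

## Reproducibility

Every generator takes an explicit integer seed and is bit-reproducible;
ensemble drivers derive independent child seeds with integer arithmetic kept
below 2³¹. Config objects serialize to JSON snapshots
(`write_config_json()`) carrying the package version and seed. Movies write
as 16-bit TIFF; traces, curves, events and histograms as headered CSV (nm,
pN, M, s); chains as minimal PDB/XYZ; model profiles as 3-column `.dat`.
The package's functions, the test suite and `scripts/acceptance.R` form the
complete interface — there is no separate command-line binary.

## Known limitations

* Synthetic ground truth uses fixed per-class ΔLc, so recovered ΔLc spreads
  reflect fit noise only, not domain-to-domain heterogeneity; modal values
  are the meaningful comparison.
* Detachment is deterministic at a set force; real tether detachment is
  stochastic and sometimes precedes complete unfolding.
* The threshold unfolding mode ignores the (weak) re-loading history
  dependence a full kinetic model would produce; use the Bell mode when
  that matters.
* The bead-chain scattering model has uniform contrast and no hydration
  shell, so it supports shape reasoning (P(r), Dmax, Rc, Porod regimes) but
  not absolute-scale molecular-mass inference or fitting of measured
  scattering curves.
* The SHRImP generator's photon budget and the eccentricity threshold
  interact: at much lower photon counts the recommended threshold scales as
  `sqrt(2/sqrt(2N))` and QC acceptance drops accordingly.
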