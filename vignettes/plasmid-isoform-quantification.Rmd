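---
title: "Quantifying plasmid DNA isoforms from electrophoresis traces"
author: "plasmidcge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasmid DNA isoforms from electrophoresis traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidcge)
```

## The measurement problem

A plasmid such as pUC19 (2686 bp) exists in three topological isoforms that
report directly on DNA damage: the intact, compact **supercoiled** (SC/CCC)
form; the **open-circular** (OC) form produced by a single-strand break; and
the **linear** (Lin) form produced by a double-strand break. Capillary gel
electrophoresis (CGE) separates the three forms cleanly in a single run: on
a pUC19 densiogram the linear form appears as a sharp band near 400 s (it
comigrates with the 3000 bp band of a linear DNA ladder), the supercoiled
form as a sharp, tall band near 500 s, and the open-circular form as a low,
broad band near 750 s. The quantity of interest is almost never an absolute
amount but the *relative* composition of a sample — the fraction of
molecules in each form — which is what strand-break assays and
quality-control workflows report.

`plasmidcge` implements that quantification as a reproducible pipeline:

1. **Background correction** — subtract either a per-lane linear drift
   (least squares over all samples outside the isoform windows) or the
   signal of a pure-buffer lane, resampled onto the sample grid when
   needed.
2. **Windowed integration** — trapezoidal integration of the corrected
   signal over the three isoform windows on the native time grid.
3. **Normalization** — per-isoform areas divided by their dye attachment
   efficiencies and normalized to sum to one.
4. **Quality control** — robust per-window signal-to-noise estimation,
   saturation detection, and an explicit include/exclude decision per lane.
5. **Deconvolution (gels)** — Gaussian multipeak fitting for agarose-gel
   lane profiles whose OC and Lin bands overlap too strongly for window
   integration.

## Model and assumptions

The pipeline models a lane's corrected signal as a sum of isoform band
profiles plus residual noise. Window integration does not assume any band
shape — only that each band is contained in its window and that the windows
are disjoint. The multipeak route assumes Gaussian bands; the deliberately
simple saturation model assumes clipping shows up as a sustained plateau at
full scale.

Two quantities deserve explicit definitions, since instrument software
rarely documents them:

* **SNR.** For each window, SNR = (maximum corrected signal in the window) /
  sigma, with sigma = 1.4826 × the median absolute deviation of the
  corrected signal over all samples outside every window. The MAD-based
  scale is robust to band tails leaking past window edges, which would
  inflate a plain standard deviation. A lane is included only when *all
  three* windows clear the SNR threshold, the total intensity is adequate,
  and no saturation plateau exists; the default threshold is `min_snr = 10`.
* **Saturation.** `detect_saturation()` requires the full-scale `level` to
  be given explicitly (the instrument's detector maximum). We deliberately
  provide no quantile heuristic: a guessed level either misses clipping or
  flags legitimate tall bands, and both failure modes are silent.

### Windows

The default windows are centred on the canonical pUC19 positions — Lin
`[350, 450]` s, SC `[450, 600]` s, OC `[650, 850]` s — with half-widths
chosen to cover the visible bands without overlap; all of them are
config-exposed because migration times shift between capillaries,
injection times and buffers. `locate_windows()` re-anchors them per lane
from an alignment-marker apex (a pure time shift), or affinely when both
marker fragments are annotated.

A second window constructor, `matched_windows(config, k_sigma = 6)`, builds
windows spanning ±6 band sigmas around the peak centres of a simulation
configuration. This exists because window integration truncates Gaussian
tails: the default OC window covers only ±3.3 sigma of the default broad OC
band, which loses ≈0.09 % of its area — irrelevant against real measurement
noise, but visible in noiseless exactness checks. At ±6 sigma the tail loss
is ≈2·10⁻⁹ and, being proportionally equal for every isoform, cancels in
the fractions. Exactness tests and the equal-mass-ratio validation use
matched windows; realistic analyses use the defaults.

### Dye correction

On agarose gels stained with SYBR Gold, the dye binds the supercoiled form
1.05× as efficiently as the open-circular form; `dye_correction()` defaults
to efficiencies (Lin, SC, OC) = (1.0, 1.05, 1.0) and
`fractions_from_integrals()` divides areas by them before normalizing. For
CGE no correction is applied (the default `correction = NULL`): the
intercalation chemistry of the CGE kit dye is undocumented and published
CGE analyses of this kind apply none, so unit efficiencies are the honest
default.

### Multipeak deconvolution

`fit_multipeak()` fits a sum of up to five Gaussians, parameterised as
(centre, log sigma, area), by bounded Levenberg–Marquardt least squares
(`minpack.lm`). Area-parameterisation means a fitted peak area is directly
exchangeable with a window integral, and `multipeak_integrals()` feeds
labelled areas straight into the fraction computation. Initialisation
(`initial_peaks()`) seeds centres at the largest local maxima, sigma at
0.5 × FWHM / 2.355 and areas from a local trapezoid; for strongly
overlapping bands whose sum is unimodal the caller should seed from the
known band layout instead. Optimizer status codes 1–4 count as converged;
anything else returns the last iterate flagged `converged = FALSE`, which
`multipeak_integrals()` refuses to use.

## The synthetic-trace generator

No public trace data exist for this kind of instrument run, so the package
ships a generator (`simulate_trace()` and friends) that emulates the
statistical structure of pUC19 densiograms with known ground truth:

* three Gaussian bands at (400, 500, 750) s with sigmas (5, 8, 30) s —
  sharp Lin and SC, broad low OC, reproducing the qualitative band
  morphology of real runs at equal loads;
* band area = amount × response (unit responses by default, matching the
  uncorrected CGE analysis);
* a linear baseline (default intercept 2, slope 0.01 signal units/s) on a
  0–1320 s grid at 1 s sampling, the full separation time of an extended
  CGE profile;
* additive Gaussian detector noise per lane, migration-time jitter drawn
  once per *capillary* (lanes sharing a capillary share the shift), and
  optional clipping at a configured full scale.

All randomness derives deterministically from the config seed, so the same
seed reproduces a batch bit for bit. Scenario generators build on this:
`simulate_mixture_series()` (SC:OC dilution series with constant total
mass and a buffer lane), `simulate_digestion_series()` (first-order
conversion `f_lin(t) = 1 − exp(−kt)` of a supercoiled stock, a blind
no-enzyme lane, and a second instrument run modelled as one extra
conversion fraction of the remaining SC — a deliberate simplification,
since the continued room-temperature digestion between runs is observed
only as "more linear, less efficient", not as a fitted rate), and
`simulate_age_profile()` (gel profiles whose OC and Lin bands sit 1.5
sigma apart to reproduce the overlap that motivates deconvolution, with
the 1.05 SC staining efficiency built in).

What the generator does **not** emulate: band tailing/fronting
(exponentially modified Gaussians), injection-bias electrokinetics, drift
nonlinearity, correlated noise, or fluorescence photobleaching. Passing
tests on synthetic data therefore demonstrate that the *analysis* is
correct and self-consistent, not that the instrument behaves ideally;
QC thresholds in particular must be tuned against real runs.

## Downstream analyses

* `aggregate_replicates()` — per-isoform mean and n−1 standard deviation;
  a single replicate reports `sd = NA` with `sd_defined = FALSE` rather
  than a silent zero.
* `mixture_linearity()` — measured mean SC fractions normalized to the
  100 %-SC reference level (the reference's *mean* over replicates, since
  the aggregation order is otherwise arbitrary), then unweighted OLS of
  measured against prepared content; R² = 1 − SS_res/SS_tot. The
  regression runs through replicate *means*, one point per prepared level.
* `concentration_series()` — spread of mean SC fraction across
  concentration levels (expected ≈0: fractions are scale-invariant) and
  the Pearson correlation between concentration and mean total intensity
  (expected strongly positive, but too noisy to calibrate concentration).
* `kinetics_timecourse()` — tabulates fractions per (incubation time,
  run) and the run-2 minus run-1 change in linear fraction; no kinetic
  model is fitted, the exponential model lives only in the generator as
  ground truth.

## Numerical choices and degenerate inputs

* Trapezoidal integration on the native grid; at 1 s sampling the
  discretisation error for bands of sigma ≥ 5 s is far below every other
  error source. Splitting a window at a grid point is exactly additive.
* Negative window areas (noise around an empty window after background
  subtraction) are clipped to 0 and flagged, keeping fractions in [0, 1].
* A zero total area raises an error rather than returning NaN fractions.
* Zero estimated noise yields an `Inf` SNR sentinel, again never NaN.
* Ladder calibration refuses partial matching: the number of detected
  ladder peaks must equal the number of specified bands. Apparent size
  interpolates log(size) linearly in migration time — the time midpoint of
  two knots maps to their geometric-mean size — and out-of-range queries
  are extrapolated but flagged.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on generated
data at the study's native scale: 1321-sample traces, an 11-level × 3
replicate dilution series (34 lanes including the buffer lane), a
19-lane two-run digestion series, and gel profiles of 561 samples. The
full suite completes in well under two minutes on a single CPU.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1, noise_sd = 0.5)
batch <- simulate_mixture_series(seq(0, 1, 0.1), replicates = 3,
                                 config = cfg)
quant <- quantify_batch(batch)
mixture_linearity(replicate_summaries(quant))
```

## Known limitations

Only 1-D lane profiles are handled — gel images must be reduced to lanes
upstream. Band shapes are assumed symmetric; strongly tailed bands bias
both window integrals and Gaussian fits. The buffer-lane background
assumes the buffer trace is time-aligned with the sample lane up to linear
interpolation. QC defaults (`min_snr = 10`, `min_run = 5`) are
conventions: the underlying acceptance criterion for real data
("adequate" SNR and intensity) is qualitative and should be calibrated
per instrument.
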