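---
title: "Methods: the nemascreen virtual instrument and analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nemascreen virtual instrument and analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nemascreen is the complete software side of an automated microfluidic
screening platform for *C. elegans* sensory-neuron function: worms
expressing a FRET-based calcium sensor in a single labeled neuron are
loaded into a trap one at a time, brought into focus, checked for
orientation and brightness, stimulated with an osmotic pulse while a
dual-channel recording runs, and their calcium transients are quantified
and compared across compound-treated and control cohorts. Because the
hardware is not reproducible at a desk, the package pairs the analysis
chain with a *virtual instrument*: a seeded generator of synthetic image
data with exact ground truth, against which every stage of the analysis is
validated. This vignette documents the model, the parameter choices and
the numerical decisions.

## 1. The virtual instrument

### Scene and optics

A frame is a `height x width` count matrix (default 64 x 64 px at
0.4 µm/px). The labeled neuron is rendered as an isotropic 2-D Gaussian
spot on a uniform worm-body autofluorescence floor (80 counts). Defocus is
modeled energy-preservingly: at stage offset `z` from true focus the spot
sigma is

    sigma(z) = psf_sigma_px + defocus_coef * |z|

(defaults 1.8 px and 0.25 px/µm) while the peak amplitude falls as
`(sigma(0)/sigma(z))^2`, so total spot flux is conserved. This is the
minimal defocus model that makes a correlation-based focus measure
peak at the true plane and fall off smoothly on both sides; it does not
attempt diffraction rings or asymmetric aberrations.

### Channels, response and bleaching

The FRET pair is modeled through its ratio: calcium influx increases
acceptor/donor. The idealized ratio follows a piecewise transient
(`response_kinetics()`): constant baseline `R0` (default 1.5), a
saturating-exponential rise of fractional amplitude `A` and time constant
`tau_rise` (default 5 s) during the stimulus pulse, and an exponential
relaxation (`tau_decay`, default 8 s) after it. Its closed-form peak
percent change, `100 A (1 - exp(-(t_off - t_on)/tau_rise))`, is the
oracle for every recovery test.

Per frame, the total baseline flux (donor_peak + acceptor_peak = 2400
counts, split 960/1440 so that their ratio equals `R0`) is partitioned
between the channels so that the pre-noise acceptor/donor ratio equals the
ideal ratio *exactly* at every sample, and each channel is multiplied by
its own exponential bleach envelope `exp(-lambda t)` (defaults 0.004/s
donor, 0.002/s acceptor). Noise, when enabled, is Poisson shot noise on
the expected counts plus Gaussian read noise (default sd 6 counts),
quantized to integers as a camera would; with noise off the frames carry
the exact expected values, which the construction-identity tests rely on.

### Protocol and QC classes

The default timing reproduces a 100 s per-worm cycle: 5 s load, 40 s
pre-stimulus exposure, 50 s recording containing a 30 s stimulus pulse,
5 s unload, at 1 frame/s per channel. Plate-scale simulation assigns each
worm a QC class at configurable rates — tail-first entry 0.12, too dim
0.08, too bright 0.05, dead 0.05, i.e. roughly 30% of loaded worms are
discarded, matching the operating regime such instruments report. Worm
cohorts draw response amplitudes from a truncated normal around the
cohort mean with between-worm coefficient of variation 0.30; the CV is a
generator choice (per-worm response variability is real but its magnitude
is rarely published), and it is the single knob that sets how hard the
statistics problem is at a given group size.

Two fidelity levels exist: `simulate_screen()` draws per-worm metrics
through the closed-form transient (used for the thousand-plate
Monte-Carlo experiments, where rendering images would add nothing), and
`simulate_plate_dir()` renders full per-worm image sessions on disk for
end-to-end pipeline runs. Both share one ground-truth schema.

## 2. Detection

Template matching is zero-normalized cross-correlation (ZNCC), authored
directly rather than delegated, because exact, testable semantics are the
point: scores live in [-1, 1], are invariant to local affine intensity
changes, constant windows score 0 by convention, constant templates are
rejected, and argmax ties break toward the smallest (y, then x) offset.
The implementation enumerates all window offsets via an index matrix and
column operations; a brute-force double-loop oracle in the test suite
must agree with it to 1e-12.

Autofocus computes the best in-region ZNCC score per z-plane and takes
the argmax; a worm whose score vector never reaches the correlation
threshold (default 0.5) is rejected as `neuron_not_found`. Orientation
runs the detector in the head-side region first, then the tail-side
region; tail-first worms are discarded. For young worms without a stable
template an alternative edge-detection chain (Sobel gradient, Otsu
threshold, connected components, brightest blob within size bounds) is
provided, with `mode_for_age()` routing worms of Day <= 4 to it.
Brightness QC bounds (300–1800 counts, background-subtracted ROI mean)
discard worms too dim or too bright to yield measurable responses.

## 3. FRET quantification

The raw trace is the per-frame disc-ROI mean (radius 3 px) around the
tracked neuron minus the median of a background region, per channel.
Tracking re-matches the template within a 4 px radius of the previous
position per frame.

**Photobleach correction.** Each channel is fitted with a
mono-exponential `I0 exp(-lambda t)` by least squares on log-intensities
over the pre-stimulus window, clipped at `lambda >= 0`, and divided by its
fitted envelope; a linear envelope is the fallback, and a trace where both
fail is left uncorrected and flagged. The *fit* window is the whole 40 s
pre-stimulus period, while the *baseline ratio* for percent change uses
only the final 10 s before onset: the fitted rate is extrapolated across
the entire recording and its variance shrinks with the square of the
window's time span, so rate estimation wants the longest lever arm
available, whereas the baseline level should represent the settled
signal.

**Metrics.** The percent-change series is `100 (R - B)/B`. The peak is
picked on a lightly smoothed copy (centered 3-frame moving average,
`smooth_window = 1` restores raw semantics) because the raw per-frame
argmax is a positively biased estimator under shot noise. The
rising-phase slope is a plain linear least-squares fit over the
10–90%-of-peak window; that window is *located* by fitting a
saturating-exponential rise to the rising segment and taking the fitted
curve's 10% and 90% times, because a direct 90% threshold crossing sits
where the curve is nearly flat and its timing is noise-dominated. When
the parametric fit fails, the window falls back to first crossings, then
to the whole onset-to-peak segment. A worm whose peak does not exceed the
responder threshold (2%) is scored a non-responder.

At the default read noise the measured trace SNR (closed-form peak over
baseline percent-change sd at amplitude 0.3) is well above 10; a read
noise of 55 counts is the documented setting that brings the trace SNR to
about 10, and is what the noise-robustness experiments in the acceptance
suite use.

## 4. Screening statistics

Wells are processed per an interleaved-control schedule: after every
block of `controls_every = 9` compound wells a vehicle-control well is
visited (cycling through the available control wells), so every compound
cohort has an age-matched control cohort measured minutes apart. The
percent effect of a compound is `100 (mu_treated - mu_control) /
mu_control` on per-worm peaks; the p-value is a two-sided Welch t-test,
and compounds are classified positive/negative/none at `alpha = 0.05`
(optionally after Benjamini-Hochberg adjustment). Higher-level analyses —
aging trajectories with early (Day <= 6) / mid (Day 7–8) / late
(Day >= 9) phase binning, treated-versus-control timecourses (two-way
ANOVA plus Bonferroni-corrected per-day tests) and dose-response against
the zero-dose group — operate on the same per-worm records.

Monte-Carlo calibration on the virtual instrument (1000 null plates of
100 compounds, 15 analyzed worms per group) is part of the acceptance
suite; note that compounds sharing an interleaved control cohort are not
independent tests, which inflates the plate-to-plate variance of the
flagged fraction (design effect around 2 at 9 compounds per control)
without shifting its mean.

## 5. Orchestration, formats and determinism

Datasets live in a plain directory layout (`layout.yaml`, `template.tif`,
`wells/<well>/<worm>/{zstack,timeseries}.tif` + JSON sidecars,
`ground_truth.csv`). TIFFs are multi-page 16-bit grayscale with channels
interleaved donor-first; all acquisition metadata travels in JSON
sidecars, and a missing required sidecar field is a hard error naming the
field. `run_pipeline()` executes the full chain and writes records,
well summaries, effects, hit calls and a run log; the log indexes events
by schedule step, never wall-clock time, so a rerun of the same seeded
inputs is byte-identical. A thin command-line front end over the exported
functions ships in `inst/scripts/nemascreen-cli.R`.

## 6. What the generator does and does not emulate

Emulated: defocus and autofocus behavior, channel bleaching, shot and
read noise, per-worm amplitude variability, QC discard classes
(orientation, expression level, death), interleaved-control plate
structure, and full end-to-end determinism with ground truth.

Not emulated: worm body texture and movement within the trap (the neuron
is stationary; the tracker's drift handling is exercised only by its unit
tests), optical aberrations beyond symmetric Gaussian defocus,
stimulus-delivery dynamics, day-to-day instrument drift, and any real
pharmacology — compound "effects" are amplitude multipliers, not
mechanisms. Conclusions about real compounds require the real instrument;
the package's claims are about the correctness and calibration of the
analysis given the stated data model.

## 7. Worked example

```{r, eval = FALSE}
library(nemascreen)

# one simulated worm, quantified
sc <- scene_params()
session <- simulate_worm_session(sc, response_kinetics(A = 0.3), seed = 1)
trace <- extract_trace(session$timeseries, c(sc$neuron_x, sc$neuron_y))
quantify_trace(trace)$metrics

# a small screen with one real enhancer
lay <- plate_layout(sprintf("C%03d", 1:18))
sim <- simulate_screen(lay, effects = c(C001 = 1.0), worms_per_well = 20,
                       seed = 1)
eff <- screen_effects(sim$records, lay)
call_hits(eff)$counts
```
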