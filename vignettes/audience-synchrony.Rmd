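---
title: "Measuring audience synchrony: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring audience synchrony: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audiencesync)
```

## The problem

When many people experience the same story, their physiology tends to move
together. `audiencesync` quantifies that coupling for heart rate (and, with
the same machinery, skin conductance and movement) through *inter-subject
correlation* (ISC): windowed Pearson correlations of 1 Hz signals between
every pair of participants. Correlating **across** people discounts
idiosyncratic physiological fluctuation and isolates what is locked to the
stimulus. Comparing pairs drawn from audiences who received the *same
narrative through different senses* (an audio-only telling vs a subtitled
silent picture) goes one step further: any synchrony that survives cannot
come from low-level audiovisual features, only from shared processing of
the story itself.

## The ISC estimator

For participants $i, j$ with 1 Hz series $x_i, x_j$, the package computes
Pearson $r$ on every 15-sample window shifted at 1 s steps. Three
aggregations are exposed (`isc()` computes all of them from one pass):

* **pair scalar** — the mean of a pair's windowed correlations (options:
  median, Fisher-z mean);
* **participant ISC** — the *median* of a participant's row of pair
  scalars, robust to the skew of pairwise correlation values;
* **time course** — per window, the median $r$ across all included pairs.

Windows in which either signal has zero variance leave Pearson $r$
undefined; such windows are excluded rather than zeroed, which would bias
medians toward 0. Because Pearson correlation is translation- and positive
scale-invariant, raw bpm and z-scored input give identical ISC — a
property the test suite asserts on every output.

How a pair's windowed correlations collapse to the single matrix entry is
genuinely open (the row median and time-course median are fixed by the
design; the pair-level collapse is not). The arithmetic mean is the
default as the simplest reading of "correlation conducted across time";
`agg = "median"` and `agg = "fisherz"` support sensitivity analyses.

## Significance: circular shuffles and FDR

Pairwise correlations between all participants are heavily dependent, so
an ordinary parametric test across pairs is not defensible. Two
complementary tests are provided:

1. **Group level** — one-tailed one-sample $t$ of the per-participant ISC
   values against zero, with Cohen's $d$ = mean/SD and a noncentral-$t$
   95% CI. Interpretable, but participants' ISCs are themselves mildly
   dependent, so it is a companion, not the arbiter.
2. **Participant level** — a circular-shuffle permutation test: the
   participant's series is rotated by a random offset (the rotation
   preserves its autocorrelation but destroys stimulus alignment), the
   participant's ISC is recomputed against the unshifted partners, and
   the observed ISC is compared with `n_iter` such nulls. The p-value
   uses the add-one convention $p = (1 + \#\{r_0 \ge r_{obs}\})/(1 +
   n_{iter})$, never exactly zero and valid at finite iteration counts.
   Decisions across participants are corrected by Benjamini–Hochberg FDR
   at $q = 0.05$.

Offsets are drawn uniformly from $[w, T - w]$ (one window length of guard
band at each end) so a shifted series can never trivially realign with
itself. The shuffle shifts the target's series jointly against all
partners; shifting each partner instead gives the same decisions in
expectation, which a test verifies empirically. The default `n_iter`
is 10,000; the test suite uses 199–999, which is ample for decisions at
$q = 0.05$.

The permutation inner loop is implemented in C++ (via Rcpp) with
prefix-sum rolling statistics; the R and C++ paths are held to 1e-12
agreement in the tests, and both are checked against a naive
triple-loop oracle.

## Power arithmetic

`power_t()` solves the noncentral-$t$ power equation (one- or two-sample,
one- or two-tailed) for whichever of $d$, $n$, power is left unknown,
by bisection. It reproduces the design-level sensitivity quantities: the
minimal detectable one-sample effect at $n = 870$ pairs and 95% power
($d \approx 0.11$), the achieved power of a two-sample comparison at
$d = 0.52$, $n = 30$/group ($\approx 0.51$), and the minimal detectable
two-sample effect at 80% power ($d \approx 0.74$). `stats::power.t.test`
serves as an independent cross-check in the tests, not as the
implementation.

## Preprocessing

Heart rate comes from R-peak event times: the instantaneous rate 60/RR is
a step function of time, averaged over each 1 s bin $[t, t+1)$ (bins
before the first or after the last peak carry the nearest defined value).
Artifact handling replaces manual marking with a reproducible rule:
samples outside 40–180 bpm or jumping more than 20 bpm from their
predecessor are flagged, then bridged by the mean of the nearest clean
neighbors on each side. A run of flagged samples receives that same
bridging mean throughout — the natural, order-independent closure of the
single-sample rule — and the operation is idempotent. Both thresholds are
arguments.

Skin conductance and movement are z-scored per participant over the full
recording. Triaxial acceleration is collapsed per sample as the rectified
sum $|a_x| + |a_y| + |a_z|$ ("sum of the axes" is ambiguous between
signed, rectified and Euclidean readings; the signed sum would let axes
cancel, so the rectified sum is the default and the alternatives are
options).

Binning convention everywhere: second $t$ covers $[t, t+1)$, 0-based from
stimulus onset.

## Low-level salience features

To ask whether cross-modality synchrony could be explained by co-occurring
low-level events (an explosion is loud *and* bright), the package extracts
five conspicuity channels from the video — intensity, colour, orientation,
flicker, motion — and RMS volume from the audio, per second.

The visual channels follow the classic biologically inspired
center-surround architecture: Gaussian-pyramid levels, rectified
fine-minus-coarse differences, and a peak-promotion normalization that
multiplies each intermediate map by $(M - \bar m)^2$ (computed on the
unit-max rescaling, $\bar m$ = mean of the non-global local maxima), so
maps with one dominant peak outweigh maps with many comparable peaks.
Local maxima are located on a smoothed copy of the map and only above a
tenth of the global peak; without this the discrete maxima set — and with
it the squared factor — jumps under sub-pixel resampling shifts.
Colour uses red–green ($R - G$) and blue–yellow ($B - (R+G)/2$) opponency;
orientation uses four zero-DC Gabor responses (0°, 45°, 90°, 135°);
flicker is the pyramid contrast of $|L_t - L_{t-1}|$; motion uses
direction-shifted opponent products of consecutive luminance pyramids,
exactly zero for a static scene. This is a deliberate simplification of
the full 72-feature saliency model: downstream modeling only ever consumes
the five channel-level RMS traces, so channel fidelity rather than
feature-count fidelity is what matters. Pyramid depth and center/surround
level pairs are arguments; defaults adapt to the frame size (the classic
deep-pyramid setting assumes full-resolution video, while synthetic
fixtures here are small), using 2×2 mean pooling and clamped bilinear
interpolation so that uniform frames stay *exactly* featureless.

Audio volume is $\sqrt{\text{mean}(x^2)}$ per second bin, stereo averaged
to mono — so a sine of amplitude $A$ measures $A/\sqrt 2$, and doubling
amplitude exactly doubles every value.

## Narrative vs low-level models of heart rate

Each condition's heart rate is operationalized as the per-second mean of
its participants' z-scored series (one series per condition; averaging
standardized subjects lifts the stimulus-locked component). Three nested
OLS models predict one condition's series: time only; time + the other
condition's heart rate (the narrative proxy — the two audiences share
*only* the story); and additionally the five conspicuity channels + RMS
volume. Models are compared by $R^2$ and BIC in the Gaussian profile form
$n\ln(\mathrm{RSS}/n) + k\ln n$ with $k$ counting intercept, slopes and
the error variance (null model $k = 3$). The incremental $R^2$ of the
narrative predictor versus the low-level block measures their relative
weight. Features enter at lag 0 by default; a `lag` argument allows
exploring physiological delay. Whether condition heart rate should be
z-scored, raw, or per-participant long-format is not settled by the
design; the standardized condition mean is the package's choice and is
stated as such.

## Ratings and immersive moments

Interval-probed immersion ratings (7-point scale every 30 s) are cleaned
by two rules: responses slower than 5 s are blanked, and raters with more
than 20% missing responses overall are dropped. Reliability is the mean
pairwise Pearson correlation between raters' series over shared probes
(a pooled each-vs-others variant is available; the statistic is
under-specified in the source design and the pairwise mean is declared as
the default). The ISC time course is averaged over each probe's trailing
bin $[p - 30, p)$ — the rating reflects the content just experienced — and
correlated with the across-rater mean rating; `bin = "centered"` is the
alternative alignment. High-synchrony moments are maximal runs of seconds
with ISC above mean + 3 SD of the whole time course, a rule invariant to
affine rescaling.

## The synthetic audience

Every stage is testable without external recordings because the generator
produces audiences with known ground truth. Subject $i$ in group $g$:

$$x_i(t) = b_i + \lambda_s\, e(t)\, s(t) + \lambda_m\, m_g(t) +
\varepsilon_i(t)$$

with $s$ the narrative signal, $m_g$ a group-specific modality signal,
$\varepsilon_i$ AR(1) noise, $b_i$ a per-subject baseline, and $e(t)$ an
optional non-negative envelope (default 1) that models passages driving
the audience more or less strongly. $s$ and $m_g$ are low-pass filtered
(≈0.1 Hz Butterworth) standardized Gaussian noise, Gram-Schmidt
orthogonalized so their sample correlations vanish to 1e-10. The 0.1 Hz
cutoff is a modeling choice: heart-rate synchrony in audiences appears
modulated on a 5–10 s timescale, and smooth components give the
circular-shuffle null realistic autocorrelation to contend with.
Artifacts are isolated +40 bpm single-sample spikes strictly inside the
recording, matching exactly what the neighbor-mean correction is built
for. Baselines differ across subjects deliberately: windowed Pearson
correlations must not care, and tests verify they do not.

Defaults describe the study design the package targets — two groups of
30, 3300 s at 1 Hz, resting baselines 70 ± 7 bpm, AR(1) φ = 0.5 with unit
innovations, artifact rate 0.005/s — and the loadings
($\lambda_s = \lambda_m = 0.35$) were calibrated once so the default
audience's mean between-group ISC is ≈0.05, the magnitude regime of real
audience heart-rate synchrony; they are fixed, not tuning knobs. What the
generator does **not** emulate: respiratory sinus arrhythmia, circadian
drift, ECG waveform morphology, or any nonstationarity beyond the
envelope. Passing tests therefore demonstrate correctness of the
machinery and calibration of the inference under a plausible null — not
that real audiences synchronize.

The envelope deserves one more note. With a *constant* loading, the
bin-mean of $s(t)$ and the within-window variance of $s(t)$ are
uncorrelated (odd-moment symmetry of a Gaussian process), so ratings
generated from $s$ itself would not correlate with the ISC time course —
there is no mechanism. Amplitude modulation is the mechanism: when an
immersive passage drives everyone harder ($e(t)$ high), windowed
correlations rise, and raters probed on $e(t)$ report more immersion.
The coupled tests and the rating generator therefore use the envelope as
the immersion ground truth.

Synthetic stimuli (moving high-contrast blobs with scripted luminance
steps, colour changes, onset flicker; amplitude-modulated tones with
scripted loud seconds) return their event script, so feature extraction
is validated against known event times. Rating cohorts sample the
immersion signal at probes (trailing 30 s bin mean by default, instant
value as an option), add rater noise on the standardized latent scale —
making the expected inter-rater correlation $1/(1 + \sigma^2)$, which a
test recovers — then discretize to 1–7, and inject missingness and slow
reaction times at stated rates.

## Numerical choices

* Rolling correlations use prefix sums on globally demeaned series;
  window variances below $10^{-12} w$ count as zero variance (window
  undefined).
* Conspicuity maps floor values below 1e-10 to exactly 0 (FFT/resampling
  roundoff must not masquerade as salience).
* The noncentral-$t$ CI for Cohen's $d$ inverts `pt(..., ncp)` by
  root-finding; `pt`'s documented tail-precision warnings are suppressed
  as harmless at CI accuracy.
* WAV I/O is 16-bit PCM implemented directly with `readBin`/`writeBin`.
* BH decisions delegate to `stats::p.adjust(method = "BH")`; Welch tests
  to `stats::t.test`; OLS to `stats::lm`; filtering to `signal::butter`
  + `filtfilt`; blur to `EBImage::gblur`.

## Problem sizes used in validation

The shipped validation runs at desk scale by design: oracle-equivalence
checks on ≤ 20 subjects × 60 s; null calibration of the full significance
procedure on 20 seeded cohorts of 60 independent AR(1) subjects (600 s,
1,000 shuffle iterations each); parameter recovery over
$\lambda_s \in \{0, 0.3, 0.6\}$ with 50 replicates of 30 + 30 subjects ×
600 s for the rejection-rate checks; 200 simulated participants for the
p-value calibration. The full-scale defaults (3300 s, 10,000 iterations)
are exercised once end-to-end in the pipeline test with a reduced
iteration count.

## Known limitations

* The conspicuity implementation is a channel-level approximation; it is
  not numerically interchangeable with any reference saliency codebase.
* The permutation fast path supports the mean pair-collapse; median and
  Fisher-z collapses take the slower R path.
* Lagged or directed (leader–follower) synchrony and frequency-domain
  coherence are out of scope.
* `run_pipeline()` orchestrates single runs; it is not a streaming or
  online computation.
```{r example, eval = FALSE}
# a complete miniature run
cfg <- pipeline_config(
  out_dir = tempfile("demo_"), n_iter = 499, seed = 1,
  simulate = audience_spec(n_subjects_per_group = 10, duration_s = 600,
                           seed = 1))
res <- run_pipeline(cfg)
res$isc_between
res$permutation
```
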