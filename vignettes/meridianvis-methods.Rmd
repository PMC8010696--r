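---
title: "Measuring meridian-specific spatial vision: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meridian-specific spatial vision: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meridianvis)
```

## The scientific problem

In regular astigmatism the eye's refractive power differs between two
perpendicular meridians. When the resulting meridian-specific blur is
present during visual development it can leave a *neural* asymmetry
that persists under full optical correction: gratings oriented along
one meridian (the "strong" meridian) remain easier to resolve than
gratings along the other (the "weak" meridian), and in the extreme the
condition amounts to meridional amblyopia. `meridianvis` implements
the two measurement chains used to quantify this *meridional
disparity* — a psychophysical contrast-sensitivity chain and an
electrophysiological sweep-VEP chain — together with a synthetic
observer/EEG generator so that every stage of both chains can be
exercised, validated and stress-tested without human data.

## Chain 1: contrast sensitivity functions from adaptive staircases

### Task model

The simulated task is two-interval forced-choice (2IFC) grating
detection: the observer reports which of two intervals contained a
grating of spatial frequency $f$ (cycles/degree, cpd) and contrast
$c$. The observer model answers correctly with probability

$$P(\mathrm{correct}) = \gamma + (1 - \gamma - \lambda)
  \left[1 - e^{-(c\,S(f))^{\beta}}\right],$$

a Weibull psychometric function with guess rate $\gamma = 0.5$ (two
alternatives), lapse rate $\lambda$ (default 0.02) and slope $\beta$
(default 3, typical for contrast detection). $S(f)$ is the observer's
generative contrast sensitivity at $f$, one function per meridian.

The generative CSF is a truncated log-parabola — the standard
parametric form in the CSF literature:

$$\log_{10} S(f) = \log_{10} G - 4\log_{10}(2)
  \left(\frac{\log_{10}(f/f_c)}{B}\right)^2,$$

floored on the low-frequency side at a fixed fraction of the peak.
Defaults ($G = 45$, $f_c = 3$ cpd, $B = 0.9$ log units, truncation
0.5) were chosen so that the sampled log-sensitivities, the area under
the log CSF and the CSF acuity all land in the ranges reported for
corrected astigmatic observers in the literature this package's
design follows. The weak meridian is derived from the strong one by a
peak-gain drop (log10 units) and a bandwidth narrowing; because the
gain can only fall and the bandwidth only narrow, weak-meridian
sensitivity is mathematically guaranteed not to exceed
strong-meridian sensitivity at any frequency.

### The 3-down-1-up staircase

Thresholds are measured with a three-down one-up staircase: contrast
is multiplied by 0.9 after every run of three consecutive correct
responses (the run counter resets after each step) and divided by 0.9
after every error. With log-symmetric steps the staircase converges
to the contrast where $P(\mathrm{correct})^3 = 1/2$, i.e.
$(1/2)^{1/3} \approx 79.3\%$ correct — the canonical convergence
level of this rule. A literal $\times 1.1$ up-step is available via
`staircase_config(step_up_factor = 1.1)`; it shifts the convergence
level slightly and is not the default precisely because the 79.3%
level is the documented operating point.

Design choices where the protocol description is silent:

- **Up/down bookkeeping.** The consecutive-correct counter resets
  after every step (standard k-down-1-up bookkeeping).
- **Reversals** are the turning points (local extrema) of the
  contrast track; plateaus created by clipping at the contrast floor
  (1e-4) or ceiling (1.0) do not count as direction changes.
- **Threshold estimation** discards the first four reversals if that
  leaves an even count, otherwise the first three — so an even number
  is always averaged — and averages the retained reversal contrasts
  as a geometric mean (mean of log10 contrasts), matching the
  multiplicative step rule. Runs with fewer than six reversals are
  flagged non-converged rather than estimated. Arithmetic averaging
  is available as an option.
- **Starting contrast.** A single block defaults to starting at
  contrast 0.5. A full session (`run_csf_session()`: 7 spatial
  frequencies × 2 meridians × 100 trials) precedes each block with a
  short coarse practice staircase (25 trials, 2-down-1-up, ×0.5
  steps) whose end point sets the block's starting contrast. This
  plays the role of the practice run that precedes real sessions and
  is necessary on arithmetic grounds: with fixed 10% steps a
  staircase started at 0.5 needs roughly 90 trials of pure descent to
  reach a threshold of 0.02 (the CSF peak), so without an informed
  start the most sensitive cells cannot converge inside a 100-trial
  block.

### CSF summaries

Per-frequency thresholds are converted to log10 sensitivity
($S = 1/c_{th}$) and summarised three ways:

- **AULCSF** — the trapezoidal integral of log10 sensitivity (floored
  at 0) over log10 spatial frequency from 1.5 to 18 cpd. The measured
  grid (0.5–16 cpd) does not coincide with the integration band, so
  the piecewise-linear curve is extended from the outer two points to
  the bounds; the high-side extrapolation slope is clamped to be
  non-positive so an unphysical rising tail can never add area.
  Segments crossing zero are split analytically, making the floor
  exact rather than grid-dependent.
- **CSF acuity** — the log10 spatial frequency at which the
  descending limb crosses sensitivity 1 (contrast threshold 100%),
  interpolated in log–log coordinates, or extrapolated from the last
  two points (and flagged) when every measured sensitivity exceeds 1.
  Reported in log10 cpd; note that extrapolated acuities inherit a
  chord-versus-curve bias of up to ~0.1 log units when the true CSF
  is strongly curved beyond the measured grid — a property of the
  measurement design, not of the implementation.
- **SF threshold at 80% contrast** — the analogous crossing of
  $\log_{10}(1/0.8) \approx 0.097$, reported in linear cpd (the
  magnitudes ~20–45 cpd make the unit choice unambiguous). For any
  descending limb it cannot exceed the linear CSF acuity, since an
  80%-contrast grating is easier to detect than a 100%-contrast one.

## Chain 2: sweep-VEP thresholds

### Stimulus and generator

The simulated protocol presents an 80% contrast grating
phase-reversing at 6 Hz whose spatial frequency sweeps 2 → 16 cpd in
10 linear steps (one per second of a 10 s trial), repeated ten times.
Pattern-reversal stimulation drives cortex at even harmonics of the
reversal rate, so analysis targets the **second harmonic, 12 Hz**.

The generator emits already-digitised trials at 2048 Hz on four
channels (Oz, O1, O2 carrying signal; Cz as a signal-free control).
Within epoch $k$ the 12 Hz response amplitude follows a linear
descent to zero at the observer's generative threshold $f_{thr}$:

$$A(f_k) = A_{peak}\,\max\!\left(0,
  \frac{f_{thr} - f_k}{f_{thr} - f_{ref}}\right),$$

a choice made deliberately: the analysis estimates threshold by
linearly regressing amplitude to zero, so a linear generative law
makes parameter recovery well-posed and any recovery error
attributable to the estimation chain itself. Background noise is
$1/f^{\alpha}$-shaped Gaussian ($\alpha = 1$ by default; EEG
background is famously 1/f-like) at 10 µV RMS plus 2 µV white noise,
independent per channel, with a per-trial response-phase jitter
(SD 0.25 rad). With a 4 µV generative peak amplitude these defaults
put single-trial epoch SNRs near 1–3 and ten-trial coherent averages
comfortably above the 3:1 validity criterion at low spatial
frequencies — the regime in which real recordings that pass the
criterion operate. The hardware acquisition chain (0.16–100 Hz
hardware filter, electrode impedances, EOG channels) is not
simulated; its passband contains all analysed content.

### Analysis chain

1. **Zero-phase band-pass**, 1–30 Hz: a 4th-order Butterworth applied
   forward and backward (`signal::filtfilt`). Verified numerically:
   12 Hz transmitted within 0.1%, 50 Hz attenuated ≥ 37 dB, DC
   ≥ 79 dB.
2. **Epoching** into ten 1 s segments, epoch $k$ paired with swept
   frequency $f_k$.
3. **Recursive-least-squares harmonic estimation.** Each epoch is fit
   recursively as $y(t) \approx \sum_j a_j \cos(2\pi f_j t) + b_j
   \sin(2\pi f_j t)$ at 11, 12 and 13 Hz, with exponential
   forgetting and epoch-end readout; the complex coefficient
   $a_j - i b_j$ carries amplitude and phase. The forgetting factor
   defaults to $\lambda = 0.9995$ per sample, i.e. a memory constant
   $1/(1-\lambda) \approx 2000$ samples ≈ 1 s — the epoch length.
   This matters: a per-sample $\lambda$ of 0.995 at 2048 Hz would
   give a 0.1 s memory, inside which regressors spaced 1 Hz apart
   are nearly collinear and the coefficients become leakage-dominated
   (we verified that the recovered amplitudes then no longer track
   the generative ramp). With $\lambda = 1$ the recursion reduces to
   the ordinary least-squares projection (and, for integer-cycle
   epochs, to the DFT bin); that mode is retained as the testing
   oracle, and the recursion's initial inverse-covariance scale
   (1e6) keeps both the implicit regularisation and accumulated
   round-off below ~1e-8 relative.
4. **Occipital averaging**: complex mean of Oz, O1, O2.
5. **Coherent (vector) averaging across the ten repeats**: the
   complex coefficients are averaged, so phase-locked signal adds
   while random-phase noise cancels as $\sqrt{N}$. The vector
   standard error pools the sampling variances of the real and
   imaginary parts of the mean. The analysis uses the modulus of the
   vector mean, never the mean of moduli.
6. **SNR gating**: per epoch, noise is the mean modulus of the
   vector-averaged 11 and 13 Hz coefficients (the nearest resolvable
   non-harmonic bins at the 1 Hz epoch resolution); SNR is signal
   amplitude over noise amplitude, with a 3:1 validity criterion.
7. **Threshold by regression to zero.** The scoring window runs from
   the highest-amplitude epoch passing the criterion through the last
   subsequent passing epoch; ordinary least squares of amplitude
   against swept frequency over the window is extended to zero
   amplitude, and the crossing — which may lie beyond 16 cpd — is the
   sVEP threshold. Fits with fewer than three window epochs or a
   non-negative slope are flagged invalid (`"no-signal-window"`,
   `"too-few-epochs"`, `"non-negative-slope"`) and carried, not
   dropped; the study pipeline excludes eyes pairwise when either
   meridian's fit fails, so threshold contrasts always compare the
   same eyes.

## Statistics layer

Per-eye meridional disparities (strong − weak) of each metric are
summarised per group as mean ± SE with a one-sample t-test
(df = n − 1, eyes treated as the sampling unit, matching the design
being emulated); groups are compared with a pooled-variance
two-sample t-test on the disparities (df = n₁ + n₂ − 2); families of
comparisons can be Bonferroni-adjusted (min(1, p·m)); cross-paradigm
agreement uses Pearson correlation. Mixed-model analyses are out of
scope by design — the report exposes the per-eye disparities so any
external mixed-model tool can consume them. A single-random-eye mode
(`run_config(eye_mode = "random-one")`) reflects the known limitation
of treating two eyes of one subject as independent.

## Reproducibility and numerical choices

- One master seed fans out to per-eye, per-block and per-trial
  substreams through an integer mixing function
  (`substream_seed()`), so any stage can be re-run in isolation and
  reproduce exactly the stream it saw inside a full run; identical
  configurations are bit-reproducible.
- EEG trials serialise to a plain-text matrix plus JSON sidecar and
  round-trip losslessly (`%.17g`).
- Contrast is clipped to [1e-4, 1]; degenerate inputs (non-positive
  frequencies, contrasts outside (0, 1], missing channels, duplicate
  regressor frequencies, rising high-frequency limbs) raise errors at
  the operation level, while the session- and study-level wrappers
  degrade to flagged `NA`s so one bad cell cannot abort a cohort.
- Ties in the scoring window (equal peak amplitudes) resolve to the
  earliest epoch; zero noise with nonzero signal reports an infinite
  SNR sentinel, zero signal with zero noise reports 0.

## What the synthetic cohort does and does not show

The default cohort emulates the two-group design the package targets:
an astigmatism group (20 eyes) and a meridional-amblyopia group
(19 eyes), the latter configured with a larger mean generative
disparity. Simulated group tables land in realistic ranges (AULCSF
≈ 1.1–1.6, disparities ≈ 0.15–0.3, sVEP thresholds ≈ 15–19 cpd with
≈ 2.5 cpd disparity).

Passing tests demonstrate that the measurement chains recover the
parameters of the generative model under its assumptions — a
log-parabola CSF, a Weibull observer, a linear amplitude-vs-frequency
law, Gaussian 1/f noise, a phase-locked response. Real data violate
all of these to some degree (non-stationary noise, alpha intrusions,
blinks and eye movements, amplitude laws that are only locally
linear, inter-block learning), and no artifact rejection is
implemented. Recovery results here are therefore validation of the
analysis code, not evidence about biological effect sizes; the
generative constants are stand-ins, clearly flagged as such.

## Problem sizes used in validation

The packaged checks use 1000 × 200-trial staircase simulations for
the convergence level, 1000 × 80-trial runs for reversal counts, 100
random epochs for the RLS-versus-OLS oracle, a 20-eye default-noise
cohort (ten sweep repeats per meridian) for sVEP parameter recovery,
and 2000 replicates of a 20-eye null cohort for the type-I error of
the paired contrast — sizes at which the Monte-Carlo error is
comfortably below each check's tolerance.
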