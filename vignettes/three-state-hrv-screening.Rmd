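---
title: "Three-behavioral-state HRV screening: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-behavioral-state HRV screening: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrv3state)
```

## The measurement model

Heart rate variability decomposes into spectral bands with distinct
autonomic interpretations: HF power (0.15–0.4 Hz, ms²) tracks
respiration-gated parasympathetic outflow, LF power (0.04–0.15 Hz) mixes
sympathetic and parasympathetic influence, and LF/HF indexes their
balance. The three-behavioral-state paradigm measures how these quantities
*respond* to a standardized mental load: about 60 s of quiet Rest, 100 s
of paced random-number generation (Task), and 60 s of rest After the task.
A healthy profile suppresses HF and raises LF/HF and HR under load, then
returns to baseline. Postpartum depression presents as a *failure to
react* (Task/Rest HF near 1, elevated resting LF/HF); adjustment disorder
reacts normally but overshoots parasympathetically once the load is
removed (After/Rest HF well above 1). Because the discriminating signal
lives in ratios across states, the pipeline's core outputs are the Rest
levels plus Task/Rest and After/Rest ratios of HF, LF, LF/HF and HR — the
12-entry feature vector.

A 5-minute protocol rules out Fourier spectra, which need roughly 256
beats of stationary data per estimate. The package therefore uses the
maximum entropy method: each 30-s window of the uniformly resampled R-R
series is fitted with an autoregressive model by Burg's lattice recursion,
and band powers are integrals of the implied AR spectrum

$$ S(f) = \frac{2\,\sigma^2 \Delta t}{\bigl|1 - \sum_{k=1}^{p} \phi_k
   e^{-2\pi i f k \Delta t}\bigr|^2}, $$

one-sided so that $\int_0^{1/(2\Delta t)} S = $ process variance.

## The processing chain and its conventions

- **R-R acceptance window 273–1500 ms** (40–220 beats/min): anything
  outside is treated as a paroxysmal beat. An isolated outlier is replaced
  by the mean of its two neighbours; an outlier at either end of the
  record, which lacks two neighbours, is dropped (and reported); two or
  more *consecutive* outliers abort the analysis rather than fabricate
  data — runs of ectopy need clinical review, not interpolation. Cleaning
  is idempotent and every decision is flagged per interval.
- **Resampling at the mean heart rate**: the tachogram grid rate is
  1000/mean(R-R) Hz, interpolated with a natural cubic spline (linear
  below 4 beats). Tying the grid to the subject's own rate keeps the
  number of samples per 30-s window roughly constant across subjects.
- **Trend timing**: spectra are emitted every 2 s, stamped with the window
  *end* time, starting 30 s after the tachogram begins. A frame at $t$
  therefore summarises $(t-30, t]$.
- **State averaging with a 30-s skip**: a state's value is the mean over
  frames with $t \in (\text{start}+30, \text{end}]$. Because frames are
  end-stamped, every frame in that range contains data from this state
  only — the skip is exactly what makes per-state averages insensitive to
  carry-over from the previous state. Each state must exceed 30 s. A
  recording stopped at the nominal protocol end yields its last frame up
  to one step plus one beat early, so coverage checks allow 3 s of slack.
- **Band edges**: LF and HF share the 0.15 Hz edge. Band powers are
  trapezoidal integrals with the spectrum interpolated at the exact edge
  frequencies, so the shared edge has measure zero and the bands partition
  the spectrum without double counting.
- **LF/HF per state** is the mean of the per-frame LF/HF over the
  averaging window, not the ratio of the state-mean LF to state-mean HF.
  The trend is computed every 2 s and the state summary averages "the
  index"; with skewed frame-wise power distributions the two definitions
  differ, and the per-frame mean is the one consistent with treating LF/HF
  as an index in its own right. Frames with zero HF power leave LF/HF
  missing and are excluded from its mean.
- **Respiratory validity**: HF only reflects vagal outflow while breathing
  stays inside 9–24 cycles/min (0.15–0.4 Hz, inclusive at both ends);
  `check_respiration()` flags — but does not fail — measurements outside it.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| AR order | 16 | Burg model order per 30-s window (~30–40 samples at typical heart rates; about n/2 is the practical ceiling, n/15·beat-rate the convention). Results depend on it, so it is exposed everywhere. |
| window, step | 30 s, 2 s | spectral trend resolution |
| LF, HF bands | 0.04–0.15, 0.15–0.40 Hz | standard short-term HRV bands |
| R-R window | 273–1500 ms | paroxysmal-beat exclusion |
| EPDS cutoff | 9 | screening positivity threshold (configurable) |
| ridge | 1e-6 × mean diag(S) | regularisation of the pooled covariance: 12 features against clinical group sizes of 12–33 make S ill-conditioned; the default is large enough to stabilise the solve and small enough to leave well-posed problems untouched (closed-form tests run at ridge 0). |

Windows are detrended by mean subtraction only; no linear detrend is
applied. Windows may span state boundaries — the settling skip, not
window restarting, is the mechanism that protects the state averages.

## The discriminant

`fit_lda()` is the Fisher solution with equal priors:
$w = (S + \lambda I)^{-1}(\mu_1 - \mu_2)$, threshold at the midpoint
projection, so the D-score is $w^\top x - w^\top(\mu_1+\mu_2)/2$, positive
for the first-named group. Ties ($D = 0$) count as the second (negative)
class so the partition into $D>0$ / $D<0$ is deterministic. Features enter
in raw units — no standardisation — matching an equation whose
coefficients carry the inverse units of their features. Evaluation is by
resubstitution (training-set classification); no cross-validation is
attempted, and with 12 features on small groups, resubstitution estimates
are optimistic by construction. Separation is reported as the Mahalanobis
distance $\sqrt{(\mu_1-\mu_2)^\top (S+\lambda I)^{-1} (\mu_1-\mu_2)}$ with
Hotelling's two-sample $T^2$ referred to its exact F distribution.

The RNG task statistic is the digram-redundancy index
$\sum_{ij} n_{ij}\ln n_{ij} / \sum_i n_{i\cdot}\ln n_{i\cdot}$ over
adjacent ordered digit pairs: 0 when every digram is unique, 1 for a
single repeated digram. Reported human means near 0.34–0.42 sit well
inside this range, whereas a naive "same digit twice in a row" frequency
would concentrate near 0.1 under uniform guessing; the naive metric
remains available as `method = "repeat_frequency"`.

## The synthetic cohort generator

`simulate_rr()` is an integral pulse frequency modulation model: beats
fire when $\int m(t)\,dt$ crosses successive integers, with

$$ m(t) = \Bigl(1 + \frac{\mathrm{mod}(t)}{\overline{RR}(t)}\Bigr)
          \frac{1000}{\overline{RR}(t)}, $$

where mod(t) sums one LF sinusoid (0.1 Hz), one HF sinusoid (0.25 Hz) and
broadband noise, all in ms of R-R deviation, with state-dependent
amplitudes cross-faded over 5 s at transitions (an instantaneous parameter
step would inject spectral artifacts that have nothing to do with the
settling physiology the skip rule addresses). Generating beats through
IPFM rather than writing sinusoids straight into an interval list
exercises the pipeline's beat-domain effects: irregular sampling,
resampling at the mean rate, and interval quantisation.

Two deliberate design points:

- **Sinc pre-compensation.** Integrating the rate over each beat low-pass
  filters the modulation by $\operatorname{sinc}(fT)$ ($T$ = beat period);
  at 0.25 Hz and 60 beats/min that is a 19% power loss. The generator
  divides the commanded amplitudes by this factor, so `hf_amp = 50` means
  "the *observed* R-R oscillation is 50 ms", and the measured band power
  is the interpretable $A^2/2 = 1250$ ms². Parameter recovery through the
  full chain is then accurate to a few percent.
- **Between-subject spread structure.** Amplitudes vary lognormally with
  the spread split evenly between a subject-level factor shared across
  states and a state-specific factor; mean R-R likewise (shared log-sd
  `sd/4`, per-state `sd/8`). Absolute powers therefore scatter much more
  than the Task/Rest and After/Rest ratios — the pattern clinical cohorts
  show, where power s.d.s rival their means but HR response ratios are
  tight (s.d. ≈ 0.08). At `between_subject_sd = 0.4` the generator
  reproduces clinical-scale dispersion; the default 0.25 is deliberately
  tighter so that the group structure built into the presets is
  recoverable by the discriminant (Mahalanobis separation ≈ 3,
  resubstitution sensitivity/specificity comfortably above 85% at
  n = 40/40/40). A fixture that cannot be classified validates nothing;
  the spread is the one knob a user should raise when they want
  clinical-difficulty data.

The group presets encode the characteristic profiles as spectral-power and
heart-rate targets per state (control: Rest HF ≈ 526 ms², HR ≈ 73/min,
Task/Rest HF ≈ 0.4; AJD: After/Rest HF ≈ 1.9; PPD: Task/Rest HF ≈ 1,
resting LF/HF elevated, HR ≈ 82/min), converted to sinusoid amplitudes via
$A = \sqrt{2P}$. EPDS scores are drawn consistently with the screening
rule (patients ≥ 9, controls < 9); digit sequences come from a Markov
chain whose repeat bias rises from controls to PPD.

**What the simulator does *not* emulate** — and hence what passing tests
do not show about real data: respiration is a fixed-frequency sinusoid,
not a variable-rate, variable-depth process; there is no baroreflex
LF–HF coupling, no ectopy or missed beats beyond what the cleaning tests
inject; noise is broadband rather than 1/f; and group differences are
built in by construction, so recovery demonstrates pipeline correctness,
not clinical validity.

## Numerical choices

- **Degenerate Burg fits.** A noise-free sinusoid is exactly predictable:
  the lattice recursion drives reflection coefficients to ±1 and the
  prediction error to round-off, after which further stages fit numerical
  noise. The recursion caps $|k| \le 1 - 10^{-5}$ and stops once the error
  falls below $10^{-12}$ of the window variance, leaving the remaining
  coefficients at zero. Realistic (noisy) windows never trigger either
  guard.
- **Narrow spectral lines.** An AR resonance can be orders of magnitude
  narrower than any fixed frequency grid. Band integration therefore adds
  tangent-spaced local grid points across every pole whose half-width is
  below five grid steps — the substitution that makes a Lorentzian's
  integrand smooth — including poles at DC and Nyquist, whose areas
  otherwise leak into adjacent bands. Poles within $10^{-8}$ of the unit
  circle, where $|A(e^{-i\omega})|^2$ is cancellation noise in double
  precision, are pulled radially out to that width, with the innovation
  variance rescaled so the model's implied total power (fixed at the
  window variance by the lattice identity $\sigma^2 = r_0\prod(1-k_m^2)$)
  is unchanged.
- **Constant windows** yield a zero-power model (spectrum identically 0,
  LF/HF missing), not an error. A subject's tie-breaks are deterministic
  throughout: D = 0 classifies negative, band edges integrate by exact
  edge interpolation, reported percentages round half-up to one decimal.
- **Problem sizes.** The test suite and the acceptance script run the
  study-level checks at n = 40/40/40 subjects with 220-s records — large
  enough that group means stabilise (Monte-Carlo s.e. of the ratio means
  ≈ 0.03) while a full run stays around a minute.

## Known limitations

- Resubstitution performance on 12 features with tens of subjects per
  group overstates out-of-sample accuracy; the package reports it because
  that is the paradigm's published evaluation convention, not because it
  is unbiased.
- The commercial analysis stack this mirrors does not document its AR
  order, detrending or interpolation; numerical equality with device
  output is therefore not claimed, only agreement with the method's
  analytic ground truths.
- The discriminant assumes two groups with a shared covariance; QDA,
  logistic models and ROC analysis are out of scope.
- `read_ecg()`'s "wfdb" mode reads a simplified plain-text record
  directory, not binary WFDB files.
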