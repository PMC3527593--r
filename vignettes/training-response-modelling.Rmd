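---
title: "Modelling training responses of performance and nocturnal parasympathetic activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling training responses of performance and nocturnal parasympathetic activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taperlab)
library(dplyr)
```

## The problem

Competitive swimmers periodise a season around blocks of intensive training
(IT) followed by tapers: planned load reductions meant to dissipate fatigue
while retaining adaptation. Two weekly signals track how an athlete absorbs
that load: a 400-m time-trial velocity (performance) and the high-frequency
(HF, 0.15-0.4 Hz) spectral power of nocturnal heart-rate variability, which
indexes cardiac parasympathetic activity. `taperlab` implements the full
analysis chain for this setting: quantifying the daily training amount,
extracting nocturnal HF power from RR-interval recordings with a wavelet
transform, fitting the two-antagonistic-component impulse-response model to
both weekly outputs, and deriving the fatigue/adaptation indices and taper
timing windows that the fits imply — together with a synthetic-season
generator so the entire chain can be validated against known ground truth.

## The two-component impulse-response model

The core model treats daily training amounts $w(t)$ (arbitrary units) as
impulses feeding two antagonistic first-order systems:

$$
\hat y(t) \;=\; y_0
 \;+\; k_1 \sum_{i < t} w(i)\, e^{-(t-i)/\tau_1}
 \;-\; k_2 \sum_{i < t} w(i)\, e^{-(t-i)/\tau_2},
$$

where the slow positive term (gain $k_1$, time constant $\tau_1 \approx$
40-50 d) is the adaptation ("fitness") and the fast negative term ($k_2$,
$\tau_2 \approx$ 4-5 d) is the fatigue. The two sums are the daily *positive
influence* (PI) and *negative influence* (NI); the identity
$\hat y = y_0 + \mathrm{PI} - \mathrm{NI}$ holds exactly and is enforced to
machine precision in the tests. A bout on day $i$ first affects day $i+1$
(strict $i<t$), the standard convention that keeps a morning session from
influencing that same day's output.

Because $\tau_2 < \tau_1$ but typically $k_2 \gg k_1$, a single bout first
depresses the output and later leaves a net gain. The closed forms

$$
t_n = \frac{\tau_1 \tau_2}{\tau_1 - \tau_2} \ln\frac{k_2}{k_1},
\qquad
t_g = \frac{\tau_1 \tau_2}{\tau_1 - \tau_2} \ln\frac{k_2 \tau_1}{k_1 \tau_2}
$$

give the days to recover the pre-bout level and the days to peak; the
optimal taper duration lies between them. Both are cross-checked against a
numeric root/argmax of the impulse response on a 0.01-d grid. When
$k_2 \le k_1$ the dip is absent and $t_n$ is reported absent rather than
thrown as an error; $k_1 = k_2$ is flagged degenerate ($t_n = 0$).

```{r}
p <- banister_params(y0 = 0, k1 = 1, k2 = 2, tau1 = 10, tau2 = 2)
banister_timing(p)       # t_n = 2.5 log 2, t_g = 2.5 log 10
```

### Fitting

`banister_fit()` minimises the residual sum of squares over
$(y_0, k_1, k_2, \tau_1, \tau_2)$ on the observation days. The model is
linear in $(y_0, k_1, k_2)$ given the time constants, so the fit profiles
those out with an exact constrained linear solve (gains non-negative — a
four-pattern active-set enumeration, exact for two sign constraints — and a
free baseline) nested inside a search over $(\tau_1, \tau_2)$: a 20x20
log-spaced grid on the default box $\tau_1 \in [10, 120]$,
$\tau_2 \in [0.5, 30]$ d with $\tau_1 > \tau_2 + 0.5$, followed by
Nelder-Mead refinement from the five best grid points. The objective is
multimodal in the time constants, which is what the multi-start guards
against. At least 8 observations are required for the 5 free parameters.
$R^2$ is reported both as $1 - SS_{res}/SS_{tot}$ (`r2`) and as the squared
Pearson correlation (`r2_cor`), since published work is often ambiguous
about which convention it used; constant observation series make $SS_{tot}$
zero and are flagged rather than silently producing $R^2 = 1$.

Performance and HF power are fitted independently with identical machinery —
the scientific claim being tested is precisely that the *same* model
describes both outputs, not that they share parameters.

## Wavelet HRV band powers

Nocturnal RR series are artifact-filtered (absolute range 300-2000 ms plus a
30% maximum beat-to-beat change against the last accepted beat; thresholds
configurable — they replace visual validation of recordings, so they are a
package convention, deliberately conservative), resampled to a uniform 4-Hz
tachogram by linear interpolation, mean-subtracted, and decomposed with a
maximal-overlap discrete wavelet transform (MODWT). Level $j$ of the MODWT
nominally covers $[f_s/2^{j+1}, f_s/2^j]$; per-level energies (mean squared
detail coefficients) are mapped to the LF (0.04-0.15 Hz) and HF
(0.15-0.4 Hz) bands.

Two numerical choices deserve explanation:

* **Wavelet and band assignment.** The default is a Daubechies-8 (16-tap)
  extremal-phase wavelet with *whole-level majority assignment*: a level
  belongs to the band covering the majority of its nominal interval (at
  4 Hz: levels 3-4 to HF, levels 5-6 to LF). The obvious alternative —
  splitting level energies pro-rata by bandwidth overlap — was implemented
  and measured, and is retained as an option, but it materially
  misattributes energy for the canonical respiratory frequency: a 0.25-Hz
  tone sits exactly on the level-3/level-4 dyadic edge, and pro-rata
  assignment hands 40% of level 3 to "above HF" and 20% of level 4 to LF,
  so only ~69% of a pure HF tone lands in HF and LF/HF comes out near 0.15.
  Majority assignment with the sharper db8 filters puts 99.8% of the same
  tone in HF and keeps equal-amplitude LF/HF tone pairs within 30% of unit
  ratio. The shorter db4 filter leaks ~11% of a 0.1-Hz tone into the
  adjacent majority-HF level; db8 halves that. Both choices, and the mother
  wavelet, are user-configurable in `hrv_config()`.
* **Boundary and energy accounting.** The series is extended by reflection
  to twice its length and the MODWT is applied circularly; reflection
  removes wrap-around artifacts while keeping the decomposition exactly
  energy-preserving, so the per-level energies plus the smooth-level energy
  reproduce the variance of the (detrended) tachogram to machine precision —
  asserted at 1e-6 relative in the tests (Parseval identity).

Detrending is mean subtraction only; slow trends are absorbed by the smooth
level and the very-low-frequency levels, which enter `ptot_power` but not
LF or HF. Band powers are reported in ms² by default; a `s2_per_hz` mode
divides the (unit-converted) band power by its nominal bandwidth, mirroring
the power-density convention some HRV reports use. Whole nights are
summarised as the mean over consecutive 5-min windows (configurable up to a
single whole-night window), which is robust to within-night nonstationarity.

One known limitation: linear interpolation of a tachogram whose beats arrive
roughly once per second attenuates modulations near the upper HF band edge
(about 30% energy loss at 0.25 Hz). All validation checks that compare
against analytic signal content therefore use ratios (amplitude scaling,
LF/HF balance) or compare against a periodogram of the *same resampled
series*, which shares the attenuation.

Classical time-domain indices (SDNN, RMSSD, pNN50, SDANN, SDNNIDX over 5-min
segments) use sample ($n-1$) standard deviations throughout, strict
"> 50 ms" for pNN50, and exclude successive-difference pairs that straddle
an artifact rather than interpolating across it — interpolation would
fabricate intervals that were never observed.

## Training load

Daily training amount is the sum over sessions of intensity-weighted pool
kilometres plus a dry-land equivalent:
$\mathrm{load} = \sum_z \mathrm{km}_z c_z + (\mathrm{min}/60) \cdot
e \cdot c_{dry}$. The seven zone coefficients default to
$(1, 2, 3, 5, 8, 12, 16)$ with $e = 2$ km/h and $c_{dry} = 3$ — a steeply
increasing cost-of-intensity profile in the swimming
training-quantification tradition. The true coefficients behind any given
study are rarely printed; they are configuration here, never baked into
results, and every analysis function takes the resulting daily series, not
the coefficients.

## The synthetic world

The generator exists so that every stage can be tested against known truth,
and its defaults are a stated world, fixed once:

* **Schedule:** 30 weeks, Monday-start, 6 training days/week; multipliers
  1.0 (weeks 1-8), 1.5 (IT, 9-12), 0.5 (taper, 13-15), 1.0 (16-21), 1.6
  (IT, 22-26), 0.45 (recovery, 27-30) — overload and taper magnitudes
  typical of competitive swimming.
* **Base daily load 6 a.u.:** the reference gains below are expressed per
  arbitrary load unit, so only the product of load scale and gain is
  meaningful. 6 a.u. is the scale at which those gains keep both outputs
  physiological: a few percent seasonal swing in performance and HF power
  positive all season (steady-state fatigue $k_2 \tau_2 \bar w$ comfortably
  below the HF baseline). The model is exactly invariant under
  $w \to c\,w$, $k \to k/c$, so this choice affects units, not difficulty.
* **Athletes:** truncated-normal draws around reference means/SDs
  (performance: $y_0$ 1.42±0.12, $k_1$ 7e-5±6e-5, $k_2$ 1.1e-3±1.4e-3,
  $\tau_1$ 50±14 d, $\tau_2$ 4.8±2.9 d; HF: 8.36±5.22, 0.007±0.006,
  0.18±0.16, 42±15 d, 4.2±2.3 d). Truncation is by *joint* rejection —
  the whole athlete is redrawn until all parameters are valid — so marginals
  stay truncated-normal and latent correlations survive. `timing_cor`
  correlates each parameter's performance/HF pair through a shared
  bivariate-normal latent; at 0.8 the realised cross-athlete correlation of
  the timing indices is ~0.7 (the timing indices are nonlinear in the
  parameters, so some attenuation from the latent value is expected and
  real). Parameter pairs are drawn independently of each other within an
  output; any true joint distribution among gains and time constants is
  unknown, and independence is the declared default.
* **Observations:** one measurement day per week (day 5 — the Friday of a
  Monday-started week, matching a Thursday-night recording and Friday
  time-trial); additive Gaussian noise with SD equal to 5% of each output's
  true seasonal range. Two linkage modes: independent (each output driven by
  its own parameters) and log-linked (performance $= a + b \ln \mathrm{HF}$,
  defaults $a = 1$, $b = 0.2$), because the two empirical findings being
  mirrored are a shared training response *and* a within-athlete logarithmic
  HF-performance relationship. Nightly mean RR is mapped from true HF as
  $850 + 20\,\mathrm{HF}$ (+ 15 ms noise), placing RR in the 0.85-1.1 s
  range over the HF values the HF world produces; an optional cap emulates
  vagal saturation for testing the linearity screen.
* **RR nights:** beat-domain sinusoids (HF 0.25 Hz, LF 0.1 Hz) plus Gaussian
  jitter, accumulated beat by beat. This is deliberately *not* a mechanistic
  HRV simulator (no respiration coupling, baroreflex or circadian
  structure): its virtue is analytically known band content, which is what
  validating a spectral chain requires. A green spectral test therefore
  establishes correct band mapping and energy accounting, not physiological
  realism of the simulated nights.

Extreme athlete draws (e.g. $k_2$ two SDs above its mean) can push the
modelled HF power below zero under this schedule — with group-mean gains and
an arbitrary load scale nothing guarantees positivity. The per-athlete log
fit refuses non-positive HF by design (naming the offending week); the
cohort report records `NA` for that athlete's log relationship instead of
aborting, which is how a real cohort analysis would handle an athlete with
unusable HF weeks.

## Cohort-level analyses

`fit_log_relationship()` regresses performance on $\ln \mathrm{HF}$
(direction chosen because performance is the predicted quantity; the inverse
is available). `fit_rr_hf_linearity()` regresses nightly mean RR on HF
power; a weak fit ($R^2 < 0.2$ by default) flags possible vagal saturation —
the physiological regime where HF power stops tracking vagal outflow at long
RR intervals. `correlate_timing()` reports Pearson correlations of the
performance and HF timing indices across athletes with both the analytic
t-distribution p-value and a seeded permutation p-value; with cohorts of
~10 athletes the permutation companion is cheap insurance against relying on
normal theory at small $n$. `cohort_report()` collates per-athlete
parameters, $R^2$, timing and relationship fits into mean±SD summary tables
and writes them as deterministic CSVs.

## What the tests establish

The package's validation is property-based: the recursive $O(T)$ simulation
equals a direct $O(T^2)$ double sum to 1e-9; the PI/NI decomposition is
exact to 1e-12; closed-form timing matches the numeric impulse response to
within 0.02 d over random parameter draws; noiseless 30-week seasons are
refit with time constants within 5% and $R^2 > 0.999$, and at 5% noise the
median $\hat\tau_2$ error stays within 2 d and the median $\hat t_g$ error
within 3 d over 20 seeds; wavelet band totals satisfy Parseval to 1e-6 and
scale quadratically with modulation amplitude; time-domain indices equal an
independent brute-force implementation on hundreds of random series; and
noiseless simulated seasons dip during the intensive blocks and peak during
the tapers, with NI rising faster than PI at block onset. What none of this
establishes is fidelity to any particular athlete population beyond the
stated generator assumptions — the generator is a test harness, not a
physiological model.

## Known limitations

* No ectopic-beat interpolation or correction: artifacts are excluded, not
  repaired, so heavily corrupted nights lose statistical power.
* The tachogram interpolation attenuates band power near 0.25 Hz (above);
  absolute HF values are comparable within the package, not across tools.
* Whether indices should be computed on the whole night or a fixed
  sub-window is a user decision; the default is the whole valid recording.
* The fit treats observation noise as homoscedastic Gaussian; no
  measurement-error model for the 400-m trials is attempted.
* Joint fitting of the two outputs with shared time constants is out of
  scope by design: each output is fit independently.
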