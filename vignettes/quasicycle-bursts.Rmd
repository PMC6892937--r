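---
title: "Envelope-phase reduction and burst statistics of stochastic E-I rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope-phase reduction and burst statistics of stochastic E-I rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(quasiburst)
```

## The model

`quasiburst` studies *quasi-cycles*: noise-sustained oscillations of a
recurrent excitatory-inhibitory (E-I) spiking network operating below a Hopf
bifurcation, the regime widely used to model bursty gamma-band activity of
PING (pyramidal-interneuron network gamma) type.  The microscopic model is a
fully connected network of $N_E$ excitatory and $N_I$ inhibitory two-state
neurons.  A neuron decays from its active to its quiescent state at constant
rate $\alpha_i$ and activates at rate $\beta_i f(s_i)$, where $f$ is the
input-output response function and

$$s_E = \frac{W_{ee}}{N_E}k - \frac{W_{ei}}{N_I}\,l + h_E, \qquad
  s_I = \frac{W_{ie}}{N_E}k - \frac{W_{ii}}{N_I}\,l + h_I,$$

with $k, l$ the active counts.  Because the network is homogeneous,
$(k, l)$ is itself a Markov chain with four reaction channels, which
`simulate_gillespie()` samples exactly; a per-neuron raster is recovered by
exchangeability when requested.

Three further descriptions of the same system, in decreasing order of
microscopic fidelity, are provided and tested against one another:

1. **Nonlinear rate SDEs** (`simulate_rate_sde()`): the population
   activities $E = k/N_E$, $I = l/N_I$ follow stochastic Wilson-Cowan
   equations whose multiplicative noise variance
   $[(1-E)\beta_E f(s_E) + \alpha_E E]/N_E$ is inherited from the
   microscopic transition statistics.
2. **Linear noise approximation** (`lna_coefficients()`,
   `simulate_lna()`): fluctuations
   $\tilde V_E = \sqrt{N_E}(E - E_0^*)$ around the stable fixed point obey
   $d\tilde V = A \tilde V\,dt + \mathrm{diag}(\sigma_E,\sigma_I)\,dW$ with
   $\sigma_E = \sqrt{2\alpha_E E_0^*}$, $\sigma_I = \sqrt{2\alpha_I I_0^*}$.
3. **Envelope-phase reduction** (`reduce_lna()`, `simulate_sam()`):
   stochastic averaging of the narrowband fluctuations leaves two master
   parameters — the damping $\nu = -(A_{11}+A_{22})/2$ and an effective
   envelope noise strength
   $D = -\frac{A_{12}}{2\omega_0^2}\left(-A_{12}\sigma_I^2 + A_{21}\sigma_E^2\right)$ —
   governing $dZ = (-\nu Z + D/2Z)\,dt + \sqrt{D}\,dW_1$ and
   $d\varphi = \sqrt{D}/Z\,dW_2$.

The stationary envelope is Rayleigh,
$P(z) = (2\nu/D)\, z\, e^{-\nu z^2/D}$, with mode
$R = \sqrt{D/2\nu}$ — the package's synchronization-strength measure —
mean $\sqrt{\pi/2}\,R$ and SD $\sqrt{(4-\pi)/2}\,R$.

```{r reduce}
library(dplyr)
purrr::map_dfr(purrr::set_names(c("a", "b", "c", "d")),
               ~ tidy(quasicycle(wc_point(.x))), .id = "point")
```

## Choice of response function

The default $f$ is the logistic sigmoid $1/(1+e^{-s})$.  This is not
arbitrary: the fixed-point-substituted algebraic forms of the Jacobian
entries $A_{ij}$ (second `form` of `lna_coefficients()`) coincide with the
$f'$-based forms exactly when $f' = f(1-f)$, i.e. for the logistic.  The
test suite verifies the two forms agree to $10^{-10}$ over random parameter
draws.  A probit alternative is available for sensitivity analysis.

## Units and parameter conventions

Time is in milliseconds throughout: $\alpha_E = 0.1$ means a 10 ms decay
time, $\omega_0$ is in rad/ms and `freq_Hz` converts as
$\omega_0 / 2\pi \times 1000$.  The default parameter set
(`wc_params()`, shipped as `inst/extdata/table1.yaml`) places the network
in the transient-synchrony (quasi-cycle) regime with a gamma-band rhythm
near 80 Hz; the four named working points `wc_point("a")` …
`wc_point("d")` sweep the recurrent excitation $W_{ee}$ over
20.4, 27.4, 28.4, 29.4, moving the system towards the Hopf transition
($\nu \to 0$, $R$ growing).

## Numerical choices

* **Fixed point.**  `solve_fixed_point()` forward-integrates the
  deterministic rate equations from $(0.1, 0.1)$ (selecting the physically
  reached equilibrium under multistability) and polishes the result by
  Newton iteration with the analytic Jacobian to residuals below
  $10^{-10}$; a coarse multi-start exposes any additional roots.
* **Gillespie output grid.**  The jump process is resampled by zero-order
  hold at 0.5 ms (Nyquist-safe for a 100 Hz band edge).  Default burn-in
  500 ms; the chain starts at the rounded fixed point.  These choices are
  declared, not estimated.
* **Rate-SDE integration.**  Euler-Maruyama at $dt = 0.01$ ms; activities
  are clipped to $[0,1]$ and the clip fraction is reported (a warning above
  0.1%).
* **LNA integration.**  The default integrator is the *exact* Gaussian
  one-step scheme ($M = e^{A\,dt}$ with the exact discrete innovation
  covariance), which is unbiased at any step; an Euler variant is retained
  for cross-checks and agrees at small $dt$.
* **Envelope simulation.**  The envelope-phase pair is generated as the
  modulus/angle of two independent OU processes advanced by their exact
  transition kernel, avoiding both discretization bias and the numerical
  risk of negative envelopes near $Z = 0$; initial conditions are drawn
  from the stationary law, so no burn-in is needed.
* **Hilbert transform.**  Computed spectrally on the full trace; the
  envelope-phase reconstruction identity holds to machine precision.
  Instantaneous frequency is the centred difference of the unwrapped phase
  smoothed by a 5 ms moving average; the first and last two mean periods
  are excluded from statistics.
* **Band-pass.**  LFPs are mean-removed and filtered with a second-order
  Butterworth (20-100 Hz default) applied forward-backward so that burst
  timing is not lagged.

## Burst extraction

A burst is an epoch in which the envelope exceeds the threshold
$b = R\sqrt{\ln 2/2} \approx 0.59R$ (half the median of the Rayleigh law;
half the empirical median when $R$ is unknown).  Because the envelope is a
diffusion, rapid recrossings near $b$ would otherwise generate spurious
short bursts, so a candidate epoch is kept only if it contains a
*contiguous* sub-interval of at least two oscillation cycles
($2\,T_0 = 4\pi/\omega_0$) on which the envelope also exceeds its mean.
Contiguity is required because the criterion's purpose is to reject rapid
fluctuations; requiring the super-mean stretch to lie inside the
above-threshold epoch (rather than merely in the same fluctuation) is the
stricter and simpler reading, and is what `extract_bursts()` implements.
Burst boundaries are located by linear interpolation of the threshold
crossings.  Raising $b$ can only shorten or remove bursts; the suite tests
this monotonicity.

Per-burst peak frequency is the maximum of the Hann-windowed, zero-padded
periodogram of the corresponding LFP epoch, restricted to the analysis
band; epochs shorter than two cycles of the band floor yield `NA`.  The
across-burst SD of peak-frequency deviations (population denominator) is
the package's frequency-variability marker.  Note that this quantity is
strongly estimator-dependent: for short epochs the periodogram peak
location fluctuates on the scale of the spectral resolution $1/T$, so
windowing and padding choices (and the burst-duration distribution itself)
move it substantially.

## Mean burst duration: passage-time theory

With thresholds proportional to $R$, the burst duration decomposes into an
up-passage from $b$ to a typical ceiling
$c = R(\sqrt{\pi/2} + \sqrt{(4-\pi)/2})$ (mean plus one SD of the
envelope law) with a reflecting floor, plus the reverse down-passage.  Both
legs are closed forms in the exponential integral (`mfpt_up()`,
`mfpt_down()`), and their sum simplifies to

$$T = \frac{1}{2\nu}\left[e^{-\frac12 (b/R)^2} - e^{-\frac12 (c/R)^2}\right]
      \left[\mathrm{Ei}\!\left(\tfrac12 (c/R)^2\right)
          - \mathrm{Ei}\!\left(\tfrac12 (b/R)^2\right)\right],$$

with *positive* arguments inside $\mathrm{Ei}$.  A sign variant with
negated arguments is implemented only as a documented discrepancy: the
package's Monte-Carlo first-passage oracle (`mfpt_mc()`, Euler-Maruyama
with sign-mirroring reflection) confirms the positive-argument form and
rejects the negated one.  With the closed-form convention $b/R$ and $c/R$
are constants, so $T \propto 1/2\nu$ exactly — the suite asserts
$T\nu$ is constant to $10^{-10}$ across the working points.

```{r theory}
fpt_theory_table(wc_params())
```

## What the cross-level comparisons do and do not show

The reduction chain is validated at three seams:

* **Microscopic vs rate SDE.**  Mean and variance of the Gillespie
  activity agree with the nonlinear SDE within joint Monte-Carlo error —
  two independent implementations of the same physics.
* **LNA vs envelope reduction.**  For a stationary Gaussian process the
  Hilbert envelope is exactly Rayleigh with scale $\mathrm{sd}(\tilde
  V_E)$, and the Lyapunov-equation solution of the LNA matches
  $R$ from the reduction to a fraction of a percent at the default
  parameters; empirically the KS distance between the two envelope samples
  is a few hundredths.  This comparison uses the *unfiltered* $\tilde V_E$:
  the quasi-cycle spectrum has broad Lorentzian skirts, and band-passing
  first would discard roughly a third of the variance that the reduction
  folds into its single narrowband mode.
* **Microscopic vs LNA.**  Near the transition the linearization
  *overestimates* the fluctuation scale: at the default working point the
  scaled microscopic fluctuations have sd $\approx 0.97$ versus the LNA's
  $1.40$, because excursions $\delta E \sim R/\sqrt{N_E}$ are comparable
  to $E_0^*$ itself and the sigmoid saturates them.  This is a real
  limitation of the linear theory in the strongly amplified regime, not an
  implementation artifact (the Gillespie sampler reproduces the closed-form
  Binomial law of the uncoupled network to well under 1%).  Quantities that
  depend only on scale ratios — burst durations, threshold conventions,
  phase statistics — are unaffected, because the envelope process divided
  by $R$ depends on $\nu$ alone.

The synthetic-data generators emulate stationarity, homogeneous all-to-all
coupling and intrinsic finite-size noise.  They do not emulate synaptic
filtering, conduction delays, heterogeneity, or non-stationary drive, so
passing tests certify the internal consistency of the theory chain, not the
fidelity of any particular biological recording.

## Problem sizes used by the shipped checks

The test suite and the acceptance script use 15-60 s of microscopic
simulation, 120-200 s of linear-SDE simulation, and 300-500 s of envelope
simulation per working point (at 0.1-0.5 ms steps), with $10^4$
Monte-Carlo first-passage replicates; these sizes give a few hundred to a
couple of thousand bursts per point and Monte-Carlo errors comfortably
inside the tolerances asserted.

## Known limitations

* The envelope-phase reduction assumes a single narrowband mode; far from
  the transition ($\nu/\omega_0$ no longer small) its accuracy degrades.
* Empirical burst statistics (mean duration, peak-frequency-deviation SD)
  are procedure-dependent: sampling step, threshold convention, the
  two-cycle criterion and the periodogram estimator all shift them by
  tens of percent.  The package fixes one fully documented procedure and
  reports its outputs; comparisons across studies should compare
  procedures, not just numbers.
* The linear theory's envelope *scale* is biased upward near the Hopf
  transition (see above); the closed-form mean burst duration inherits
  only the $1/2\nu$ time scale and is insensitive to this.
* No delayed, spatially structured or conductance-based couplings.
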