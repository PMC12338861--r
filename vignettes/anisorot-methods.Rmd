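---
title: "Methods: planar-rotor decomposition and fluidity gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planar-rotor decomposition and fluidity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisorot)
```

## The model and its assumptions

A planar fluorophore such as the anthroyl ring of the
*n*-(9-anthroyloxy) fatty acids rotates in two distinguishable modes: an
out-of-plane rotation about the ester bond at C9 (rate $R_{op}$) and an
in-plane rotation that follows the segmental reorientation of the acyl
chain (rate $R_{ip}$).  In the slow-rotation regime — only small angular
excursions between excitation and emission — the steady-state anisotropy
$r$ measured with excitation at a wavelength where the zero-time
anisotropy is $r_o$ and the excited-state lifetime is $\tau_F$ satisfies

$$\frac{r_o}{r} = 1 +
  \frac{6\,\tau_F\,[\,R_{ip}(2\cos^2\alpha - 1) + R_{op}\cos^2\alpha\,]}
       {3\cos^2\alpha - 1},$$

where $\alpha$ is the angle between absorption and emission transition
dipoles, related to the fundamental anisotropy by
$r_o = (3\cos^2\alpha - 1)/5$, hence $\cos^2\alpha = (5 r_o + 1)/3$.
Substituting gives the exactly linear form

$$Y = R_{ip}\,X + R_{op}, \qquad
  Y = \frac{5 r_o\,(r_o/r - 1)}{2\,\tau_F\,(5 r_o + 1)}, \qquad
  X = \frac{10 r_o - 1}{5 r_o + 1}.$$

(Some printed renderings of the $\cos^2\alpha$ substitution are ambiguous
about the grouping; only $(5r_o+1)/3$ is consistent with
$r_o = (3\cos^2\alpha-1)/5$, with $r_o = 0.4 \Rightarrow \cos^2\alpha = 1$,
and with the $X$, $Y$ above.  The package implements that internally
consistent system; `test-acceptance.R` verifies the reduction numerically
to $<10^{-12}$.)

Because $r_o$ varies strongly across the five vibronic excitation bands
(319–381 nm) while the emission (collected at 440 nm, where the decay is
monoexponential) does not, a multi-wavelength anisotropy series traces a
straight line in $(X, Y)$; its intercept and slope are the two rates.
Assumptions inherited from the model: slow rotation
($R\,\tau_F \lesssim$ a few), coplanar absorption/emission oscillators,
monoexponential decay at the collection wavelength, and probes that do not
perturb the membrane (probe:lipid $\approx$ 1:200–1:400).

Rates are carried internally in ns$^{-1}$ and reported in MHz
($\times 1000$); rotational correlation times are
$\phi = 1/(6R) = 10^3/(6 R_{\mathrm{MHz}})$ ns, rounded to one decimal
only in printed reports.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| wavelength set | 319, 333, 347, 367, 381 | nm | excitation maxima; determine the $X$ design |
| window_c | 2 | °C | temperature window for one regression |
| bandwidth_c | 5 | °C | kernel sd of the profile smoother |
| weighting | `ivar` | — | delta-method inverse-variance weights (see below) |
| grid | 10, 15, …, 50 | °C | reporting grid of the gradient surface |
| ramp | 12 (10→52) | °C/h | heating-curve protocol |
| sigma_rel | 0.01 | — | per-channel relative noise of the simulator |
| temp_jitter_c | 0.02 | °C | thermistor accuracy of the recorded temperature |

## Photophysics inputs

$\tau_F$ and $r_o$ per probe, wavelength and temperature are *inputs*,
interpolated linearly in temperature between anchors (typically 21, 37,
47 °C); queries beyond the outermost anchors extrapolate linearly and are
flagged, and the flag propagates into every downstream decomposition and
gradient cell.  Three anchors cannot support higher-order interpolation,
hence linear.  Whether $r_o$ should itself be temperature-interpolated is
not settled in the source literature; `get_photophysics()` supports both
(`r_o_temperature = "interpolate"`, the default, or `"fixed"`, which takes
the nearest anchor).  The bundled `default_photophysics()` table is
**synthetic** — $\tau_F$ 4–12 ns falling $\approx 1.2\%$/°C, $r_o$ from
$-0.08$ at 319 nm to $0.30$ at 381 nm with a weak temperature drift — and
exists so that the pipeline is testable; it must not be mistaken for
measured values.

## Estimator choices

**Per-window regression.**  Within a temperature window the anisotropies
of each wavelength are first averaged and each wavelength contributes one
$(X, Y)$ point.  Averaging *before* the nonlinear $r_o/r$ transform
shrinks the Jensen bias of $1/r$ by the per-wavelength count and removes
near-singular points at wavelengths where $r$ passes close to zero (319 nm
at high temperature).  Weights are the delta-method inverse variances
$w \propto n_w\,(\mathrm{d}Y/\mathrm{d}r)^{-2}$ evaluated at the
per-wavelength mean $r$, with
$\mathrm{d}Y/\mathrm{d}r = -5r_o^2/[2\tau_F(5r_o+1)r^2]$, assuming
homoscedastic anisotropy noise.  Two deliberate deviations from the more
obvious scheme are worth recording:

* *No per-wavelength sample variances.*  With the 2–5 readings a window
  holds per wavelength, sample variances are $\chi^2$ with 1–4 df; using
  them as weights both costs efficiency and mis-calibrates the CIs
  (measured coverage dropped to ~0.89 vs ~0.95 with the deterministic
  weights).  The homoscedastic-$\sigma_r$ assumption is good because all
  four channels carry the same relative noise, making $\sigma_r$ nearly
  independent of $r$.
* *Weights from the mean $r$, not each point's own.*  Per-point weights
  $\propto r^4$ correlate with the errors they weight (an upward
  fluctuation in $r$ lowers $Y$ *and* raises its weight) and bias the
  rates downward by several percent; wavelength-level weights do not.

95 % confidence half-widths use the $t$ distribution with
$n_{\lambda} - 2$ degrees of freedom, matching the "mean and 95 %
confidence intervals of the linear regression" convention for this kind of
decomposition.  `weighting = "none"` provides the plain per-point
unweighted regression for comparison.

**Heating-curve smoothing.**  Windowed decompositions (all replicates
pooled — the closest reading of deriving the continuous profile "from the
whole dataset" of replicate heat curves) are smoothed by kernel-weighted
local-linear regression of $\log R$ on the Arrhenius coordinate
$1/T_K$, with a Gaussian kernel of sd `bandwidth_c` in °C:

* the log scale matches the multiplicative error structure and guarantees
  positive smoothed rates;
* on $(\log R,\ 1/T_K)$ an Arrhenius-type profile is a straight line, so
  the local-linear fit is nearly unbiased even with the kernel widened
  ($2\times$) near the ends of the ramp, where one-sided estimation would
  otherwise inflate variance;
* standard errors use the sandwich form
  $\sigma^2 B\,X'W^2X\,B$, $B=(X'WX)^{-1}$ — kernel weights are smoothing
  weights, not precisions, and the naive WLS formula under-covers
  (measured ratio-CI calibration 0.84 naive vs 0.98 sandwich).

Per-window CIs are *not* used as smoother weights: with 3 df they are
noisy enough that a chance small-CI window can dominate the local fit.

**Surfaces and comparison.**  Profiles are evaluated on the 5 °C grid and
arranged by attachment carbon $n$ (no conversion to Å from the bilayer
centre is attempted; the depth–carbon relation is close to linear but its
constants are system-specific).  Condition comparisons are cell-wise
ratios with CIs propagated on the log scale; the comparison summarises
mean fold per grid temperature for monotonicity checks.  $R_{ip} \ge
R_{op}$ is reported as a per-cell diagnostic, not enforced.

## The synthetic instrument

`simulate_run()` forward-models the experiment: per-probe Arrhenius truth
$R(T) = R_{37}\exp[-E_a/R_{gas}(1/T_K - 1/310.15)]$, inverted through the
planar-rotor relation to a true $r$ per wavelength, realized as four
channels with $I_{vv}/I_{vh} = g(1+2r)/(1-r)$, $I_{hv}/I_{hh} = g$, then
perturbed by independent multiplicative Gaussian noise per channel
(default $\sigma_{rel} = 0.01$; a Poisson photon-count option exists —
the Gaussian default reflects an analog-voltage instrument).  The recorded
temperature carries Gaussian jitter of sd 0.02 °C (the stated thermistor
accuracy); the underlying ramp does not.  Measurement cadence is drawn
uniformly from 72–122 s per run, reproducing the reported 98–180
anisotropy measurements per run (median near 130, i.e. 23–43 points per
10 °C interval *summed over the five wavelengths* — the per-wavelength
reading of that range is arithmetically impossible for a 42 °C ramp).
Wavelengths alternate cyclically as in the real protocol;
`acquisition = "simultaneous"` (all five wavelengths per time point) is
provided for exact-recovery testing, since with alternating excitation the
points of one window sit on slightly different truth lines and exact
recovery is only defined per isothermal cycle.

Built-in truth surfaces are **synthetic**, chosen once to embody the
qualitative structure of CHO plasma-membrane measurements: 37 °C rates in
the 10–90 MHz range; $R_{ip} \ge R_{op}$ everywhere; out-of-plane maxima
at $n = 2$ and 16 with the "microviscosity barrier" minimum at $n = 7$–9;
a resistant-like condition with a flatter out-of-plane depth gradient,
matching in-plane values except a $\approx 1.6\times$ lower $R_{ip}$ at
$n = 16$, and cell-wise differences within twofold; an inhibitor scenario
multiplying both rates by a fold factor rising linearly from 1.2 at 10 °C
to 2.4 at 40 °C and constant above.  Activation energies default to
25 kJ/mol (out-of-plane) and 22 kJ/mol (in-plane), giving the
$\approx$ 3–4-fold rate increase over the 10–50 °C span typical of
membrane microviscosity.  One physical constraint the truth tables must
respect: at wavelengths with $0 < r_o < 0.1$ ($X < 0$) the line
$R_{ip}X + R_{op}$ must stay positive, i.e. $R_{op} \ge |X| R_{ip}$ at
all temperatures — `make_scenario()` validates this at construction.

What a green test on these scenarios does **not** establish: correctness
for real instruments with wavelength-dependent calibration factors beyond
the configurable constant, scatter/background contamination (no
subtraction is modelled), non-monoexponential decays, probe partitioning
kinetics, or lipid phase transitions (the Arrhenius truth is smooth by
construction).

## Numerical choices and degenerate inputs

* $r = 0$ and $r_o = -0.2$ are singular points of the transform and raise
  errors; readings whose mean $r$ has the opposite sign to $r_o$ are
  excluded from the window fit (counted, not silently dropped).
* Anisotropy values outside $[-0.2, 0.4]$ are flagged and retained;
  exclusion happens only at the window-fit stage.
* A design with all $X$ equal (e.g. every wavelength at $r_o = 0.1$) is
  rank-deficient and raises an error rather than returning a spurious
  intercept.
* Windows need $\ge 2$ wavelengths; profiles need $\ge 3$ windows spanning
  $\ge 15$ °C.
* Temperatures are °C end to end; Kelvin appears only inside the
  Arrhenius evaluation and the smoother's regression coordinate.

## Known limitations

* The acceptance-grade stochastic recovery (full pipeline, default noise)
  achieves $\approx 3$–5 % RMSE relative to the RMS magnitude of the truth
  surfaces; single cells at the ends of the ramp carry the largest errors.
* Where a truth fold profile has a kink (the inhibitor scenario at 40 °C),
  kernel smoothing is locally biased and per-cell CIs near the kink
  under-cover; comparisons there should be read at the profile level.
* No spectral corrections, inner-filter effects, or time-resolved decay
  fitting; lifetimes are inputs, never estimated.
* Depth is indexed by the attachment carbon, not by Å from the bilayer
  centre; surface plots connect grid points without modelling
  intermediate depths.
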