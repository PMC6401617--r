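---
title: "Models and methods: lifetime-based analysis of self-dimerizing hosts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: lifetime-based analysis of self-dimerizing hosts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suprafit)
```

## The physical picture

A fluorescent host (the motivating case: a β-cyclodextrin carrying a
naphthylene clip on its secondary rim) self-associates in water,
2M ⇌ D, with association constant $K_D$ (L/mol). Monomer and dimer emit
with different excited-state lifetimes, so the intensity-weighted average
lifetime $\langle\tau\rangle$ of a solution tracks the position of the
equilibrium: it rises from the monomer lifetime $\tau_0$ at infinite
dilution to the dimer lifetime $\tau_\infty$ at saturation. This package
implements every quantitative step of that analysis — decay fitting,
speciation, the isotherm, quenching, van't Hoff and NMR-titration models —
plus generators that emulate each input.

## TCSPC decay fitting

A time-correlated single-photon-counting histogram records counts $N_k$
in uniform channels. The measured curve is the true decay
$I(t)=\sum_i A_i e^{-t/\tau_i}$ convolved with the instrument response
function (IRF), so `fit_decay()` minimizes

$$\chi^2 = \sum_{k \in \text{range}} \frac{\big[(R \ast I)_k - N_k\big]^2}{\max(N_k, 1)}$$

with $R$ the unit-normalized IRF and the convolution discrete, causal and
zero-padded (circular wrap-around would be unphysical). Choices that
matter:

* **Weights.** Neyman weights $1/\max(N_k,1)$ are the standard
  approximation to Poisson variance at the count levels of a typical
  acquisition (10,000 counts at the peak). They are biased for channels
  with very few counts, which motivates the default fit range below.
* **Fit range.** The default `"tail"` range runs from the peak channel to
  the last channel with at least $\max(10, N_{peak}/1000)$ counts. This
  keeps the statistic calibrated (reduced $\chi^2 \approx 1$ for data that
  match the model) by excluding the nearly empty far tail, where Neyman
  weights misbehave, and the rising edge, where IRF timing jitter
  dominates. `"full"` and explicit channel windows are available; fitting
  the rising edge is the right choice when a scatter term is included.
* **Parameterization.** Optimization (Levenberg–Marquardt,
  `minpack.lm`) runs over $\log A_i$ and $\log \tau_i$, enforcing
  positivity without constraints and making lifetime ratios
  well-conditioned. Initialization is deterministic — lifetimes log-spaced
  over [channel width, window/2], amplitudes split evenly from the peak
  count — so a fit of the same data is always the same fit.
* **Scatter.** Sub-nanosecond stray-light contributions (e.g., from
  cylindrical microcells) can be modeled as an IRF-shaped component via
  `scatter = TRUE`; the scatter fraction is fitted but excluded from
  $\langle\tau\rangle$ and the $f_i$, mirroring the usual practice of
  discarding the scatter component from photophysical interpretation.
* **Component count** is user-chosen (1–3), not auto-selected. Fits are
  flagged `overparameterized` when a component carries under 1% of the
  intensity or two lifetimes differ by less than 20%, the two ways a
  redundant component shows up in practice.

## Speciation and the two dimer-fraction conventions

`dimer_speciation()` solves $2K_D[M]^2+[M]-C_t=0$ in closed form and
polishes the root with one Newton step (the radical form loses precision
when $8K_DC_t \ll 1$). Two conventions for "fraction of dimer" coexist in
the literature and differ substantially at partial association:

* **molecule basis** $x_{mol} = 2[D]/C_t$ — the fraction of host
  *molecules* residing in dimers; this is what an intensity-proportional
  observable reports when monomer and dimer share a quantum yield, and it
  is the fraction used inside the isotherm model;
* **species basis** $x_{sp} = [D]/([M]+[D])$ — the fraction of dissolved
  *particles* that are dimers.

Both are returned on every call. Published tables sometimes mix the two
conventions (a reported fraction of 0.53 at $C_t=0.2$ mM with
$K_D=2.1\times10^4$ matches the species basis, 0.550, while a "90% dimer"
statement at 0.15 mM with $K_D=4.1\times10^5$ matches the molecule basis,
0.914), so the package never guesses: callers pick the column.

The coupled system (dimer binding one guest, D + G ⇌ DG, on top of
2M ⇌ D) reduces to one unknown: given $[M]$, $[D]=K_D[M]^2$ and the guest
balance is linear in $[G]$. The host-balance residual is strictly
increasing in $[M]$, so bracketed `uniroot` on $[0, C_t]$ plus Newton
polishing converges to mass-balance residuals below $10^{-10}$ relative;
the function errors rather than returning an unconverged point.

## The dimerization isotherm

With quantum yields equal between the forms ($\phi_{dimer} \simeq
\phi_{monomer}$, which is what a linear corrected-intensity-vs-concentration
plot demonstrates), the dimer contributes intensity in proportion to the
molecules it holds (it carries two chromophores), so the intensity
fraction of the dimer equals $x_{mol}$ and

$$\langle\tau\rangle(C_t) = \tau_0 + (\tau_\infty-\tau_0)\,
x_{mol}(C_t, K_D).$$

This molecule-basis construction is a reconstruction from the two-species
intensity-weighted average — the equal-yield assumption plus the
two-chromophore stoichiometry — and it is the form that reproduces the
">90% dimer at 0.15 mM" reference point. Fitting runs over
$(\log K_D, \tau_0, \tau_\infty)$; per-point weights default to uniform
(experimental tables rarely carry per-point uncertainties) with optional
$1/\sigma^2$ weighting. Standard errors come from the residual-scaled
covariance at the optimum; the $K_D$ error is delta-method back-transformed
from the log scale. Data with no lifetime trend (span under three times
the point-to-point scatter) raise an identifiability warning rather than
failing: the fit still returns, flagged.

A single 12-point isotherm at realistic noise determines $\tau_\infty$
tightly but $K_D$ and $\tau_0$ with wide bands — the low-concentration arm
carries few photons' worth of information. Replicated designs (the
recovery studies below) are the honest way to quote such constants.

## Quenching, van't Hoff, titration

**Stern–Volmer.** $\langle\tau\rangle_0/\langle\tau\rangle$ vs $[Q]$ is
fitted with a *free* intercept: for mixtures of emitters the plot is
linear only at low quencher concentrations, so a fixed unit intercept can
silently bias the slope. Intercepts off 1 by more than 5% are flagged,
and `max_q` restricts the range (quencher series typically span 0–8 mM).
$k_q = K_{SV}/\tau_0$ converts ns to s, giving the usual
$10^9$ L mol$^{-1}$s$^{-1}$ scale.

**Van't Hoff.** Unweighted regression of $\ln K$ on $1/T$ is the default:
equilibrium constants re-derived from isotherm fits have roughly constant
relative error, which makes unweighted log-scale regression the natural
choice; a $\sigma_{\ln K}=\sigma_K/K$ weighted option exists. $R = 8.314$
J K$^{-1}$mol$^{-1}$; temperatures are accepted in °C. Note that
re-running the regression on *rounded* published $K_D$ tables reproduces
published ΔH/ΔS only to a few percent — rounding in the table, not a
model discrepancy.

**NMR titration.** The fast-exchange observed shift is
$\delta = \delta_{free} + \Delta\delta_{max}[HG]/H_t$ with $[HG]$ from
the exact quadratic at every point; the dilute-host hyperbola
$K_aG_t/(1+K_aG_t)$ overstates binding once $H_tK_a \gtrsim 0.1$ because
it ignores guest depletion by the host. In `mode = "dimer"` the
self-assembled dimer is treated as an inert 1:1 binding partner with
effective concentration $C_t x_{mol}/2$ (or $C_t/2$ when dimerization is
saturated) — the standard approximation for a 2:1 monomer-basis
stoichiometry. The fully coupled alternative (`coupled_speciation`) is
exposed for cases where guest binding visibly shifts the dimer
equilibrium; an apparent $K_a$ from the inert-dimer model is then an
underestimate. Several resonances can be fitted jointly with one shared
$K_a$ (default) or independently; titrations whose final point leaves
less than half the host bound get a weak-identifiability warning.

## ICD sign rule

For a chromophore held by a cyclodextrin, the induced-CD band sign
follows the location of the chromophore and the angle $\theta$ between
its electric transition dipole moment and the host symmetry axis:
inside the cavity, positive for $\theta < 54.7°$ and negative above;
outside, reversed. `icd_sign()` implements exactly this rule with a
configurable near-zero band (default ±3°) around the magic angle,
expressing the vanishing intensity observed for transitions near the
node. The rule is qualitative by construction — no rotational strengths,
no exciton-coupling magnitudes — matching how it is used to assign
conformations.

## The synthetic-data generators

Each generator reproduces the statistical structure its fitter assumes,
at the designs typical of the motivating experiments:

* `simulate_decay()`: Gaussian IRF (default FWHM 1 ns at 10 ns into a
  200 ns window of 1024 channels), reconvolved truth scaled to 10,000
  expected counts at the peak, independent Poisson counts per channel.
  The IRF itself is kept noiseless; real measured IRFs carry their own
  counting noise, after-pulsing and wavelength-dependent timing shifts
  that are *not* emulated, so passing recovery tests bound fitter error
  under ideal-IRF conditions only.
* `simulate_isotherm()`: 12 log-spaced concentrations over
  $10^{-6}$–$3\times10^{-4}$ M with Gaussian lifetime noise (default
  σ = 0.2 ns, the scale of fit-to-fit lifetime scatter for a ~10 ns
  emitter; 1.0 ns is the comparable choice for a ~75 ns emitter since
  average-lifetime uncertainty grows with the lifetime itself).
* `simulate_titration()`: 15 evenly spaced guest additions from zero to
  95% host saturation (`titration_design()` inverts the exact quadratic
  for the endpoint), Gaussian shift noise σ = 0.002 ppm — the digitization
  scale of a 500 MHz shift reading. Default limiting shift 0.05 ppm.
* `simulate_vant_hoff()`: five temperatures, 5–45 °C in 10° steps,
  multiplicative lognormal noise (default CV 10%, the typical relative
  error of an isotherm-derived constant).
* `simulate_quench()`: nine quencher points over 0–8 mM.

Every generator draws from an RNG stream derived from (seed, kind), so
datasets for different stages under one master seed are independent, the
caller's RNG state is untouched, and changing the seed changes only the
noise. What the generators do **not** emulate: real emission spectra,
inner-filter drifts, flat background and after-pulsing in TCSPC (only
optional flat background), host impurities, or temperature gradients —
so green recovery tests certify the estimators against their own model
class, not against every instrumental pathology.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script use 50-seed recovery studies
(50 isotherm fits, 50 titration fits, 50 two-component reconvolution
fits of 1024-channel histograms), which give stable medians while keeping
a full run in the tens of seconds on one core. Root-finding tolerances
are $10^{-14}$ relative on brackets with mass balances verified to
$10^{-12}$ (closed forms) and $10^{-10}$ (coupled system); nonlinear fits
run to `ftol = ptol` $\approx 10^{-13}$ with bounded iteration counts and
report `converged = FALSE` plus the best point on failure rather than
erroring.

## Known limitations

* Only monomer–dimer self-association: no isodesmic or higher-order
  aggregation models, and no global multi-temperature isotherm fit (the
  van't Hoff step consumes per-temperature constants).
* The inert-dimer titration mode ignores guest-induced dimer
  dissociation; apparent constants for systems that disassemble on
  binding are underestimates (use the coupled model to explore this).
* The decay module fits a discrete sum of 1–3 exponentials — no lifetime
  distributions, maximum-entropy inversion, or global multi-wavelength
  analysis.
* The ICD module predicts signs, not intensities, and does not invert
  observed spectra to angles.
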