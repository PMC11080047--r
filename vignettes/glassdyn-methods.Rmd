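---
title: "Models and methods behind glassdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glassdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glassdyn)
```

# The problem

An amorphous active pharmaceutical ingredient dissolves faster than its
crystals, but it is thermodynamically doomed to recrystallize. Whether
and how fast it does so is governed by its molecular mobility — the
structural (α) relaxation of the supercooled liquid and the faster
secondary (β, γ) relaxations that survive in the glass — and by
nucleation, which excipients such as mesoporous silica can promote or
suppress. `glassdyn` implements the two experimental windows onto this
physics: broadband dielectric spectroscopy (BDS), which resolves the
relaxation processes as loss peaks in frequency, and differential
scanning calorimetry (DSC), which sees the glass transition,
crystallization and melting as heat-flow events. The default
parameterization throughout is the measured dynamics of amorphous
aripiprazole (ARP) and its composites with the mesoporous silica
Syloid 244FP, a system in which the silica loading tunes the drug's
physical state.

# Dielectric forward models

A relaxation process contributes the Havriliak–Negami (HN) loss

$$\varepsilon''(\omega) = -\mathrm{Im}\,
  \frac{\Delta\varepsilon}{\bigl(1 + (i\omega\tau_{HN})^a\bigr)^b},
  \qquad \omega = 2\pi f,$$

with dielectric strength $\Delta\varepsilon$ (proportional to the
number density of reorienting dipoles), symmetric broadening $a$ and
asymmetric broadening $b$, both in $(0, 1]$. Secondary relaxations are
symmetric and use the Cole–Cole special case $b = 1$. DC conduction by
residual ions adds $\sigma_{dc}/(\varepsilon_0\omega^s)$ with $s = 1$
(ohmic) by default; the exponent is exposed because electrode effects
can flatten it, but nothing in the package depends on $s \ne 1$.
Spectra are stored against frequency in Hz; $\omega = 2\pi f$ is used
consistently. Only the loss is modeled — $\varepsilon_\infty$ is
carried as metadata, never fitted, since the analysis works entirely in
$\varepsilon''$.

The loss-peak time of an HN process differs from $\tau_{HN}$; the
closed form

$$\tau_{max} = \tau_{HN}
  \Bigl[\sin\tfrac{a\pi}{2(1+b)}\Bigr]^{-1/a}
  \Bigl[\sin\tfrac{ab\pi}{2(1+b)}\Bigr]^{1/a}$$

is validated in the test suite against brute-force peak search to 0.5%
over 100 random $(a, b)$ shapes, and reduces to $\tau_{HN}$ at $b = 1$.

## The KWW shape in the frequency domain

Master-curve shapes are described by the stretched exponential
$\phi(t) = \exp[-(t/\tau)^{\beta}]$, whose loss

$$\varepsilon''(\omega) = \Delta\varepsilon \int_0^\infty
  \Bigl(-\frac{d\phi}{dt}\Bigr)\sin(\omega t)\,dt$$

has no closed form for $\beta < 1$. `kww_loss()` samples
$-d\phi/dt$ on a log-spaced time grid and integrates each segment's
linear interpolant against $\sin(\omega t)$ analytically (a Filon-type
rule), with series-stabilized kernels for small $\omega h$ so the
quadrature is uniformly accurate from the low-frequency to the
high-frequency flank. Two grid decisions matter and were set from the
structure of the integrand, not tuned to any test:

* the grid extends *below* $10^{-6}\tau$ to $10^{-4}/\omega_{max}$,
  because for $\omega\tau \gg 1$ the transform is dominated by the
  small-$t$ behavior of $-d\phi/dt \propto t^{\beta-1}$ — truncating at
  a fixed multiple of $\tau$ loses an $O(1)$ fraction of the
  high-frequency flank;
* the upper limit is where $\phi$ has decayed below $e^{-50}$.

The default density (250 points per decade) gives ~$10^{-4}$ relative
accuracy, sufficient for fitting; the Debye-limit identity
$\varepsilon''_{\beta=1} = \Delta\varepsilon\,\omega\tau/(1+\omega^2\tau^2)$
is verified to $10^{-6}$ at 5000 points per decade. An independent
adaptive-quadrature oracle (integration over half-periods of the sine)
cross-checks $\beta = 0.55$ values to $10^{-4}$.

# Spectral deconvolution

`fit_loss_spectrum()` performs Levenberg–Marquardt least squares on
$\log_{10}\varepsilon''$ with uniform weights (masking non-positive
points); the log scale balances the decades-spanning loss values, and
positivity of $\Delta\varepsilon$, $\tau$ and $\sigma_{dc}$ is enforced
by fitting their logarithms. Starting values are deterministic and
data-driven: local maxima of the lightly smoothed log-spectrum are
assigned to processes slowest-first; when a DC term is in the plan, an
ohmic-slope estimate anchored at the lowest frequency is subtracted
before peak-finding so buried α-peaks surface; shoulders that produce
no maximum get starts spread in log-frequency between the last resolved
peak and the window top; and a falling low-frequency edge signals a
slower process entering from below the window. Multi-peak assignment to
*labels* is nevertheless ambiguous in principle when only one peak is
resolvable, which is why the fit plan — which processes are active, and
any frozen parameters — is explicit user configuration rather than
automatic model selection.

`analyze_bds()` chains the plans the way a practitioner analyzes a
heating series with a 0.1 Hz–1 MHz window:

1. where the β-peak is resolvable (≈236–308 K for the default laws),
   both secondaries are fitted freely and β's points define its
   Arrhenius law;
2. at lower temperatures only γ peaks in-window; β's flank is pinned to
   the downward Arrhenius extrapolation (strength free) and γ is
   fitted;
3. above $T_g$ the α-process is fitted as free HN with conductivity,
   and both secondaries are pinned to their extrapolations with only
   strengths free — secondary peaks are barely visible above $T_g$, so
   refitting their shapes there is ill-posed.

Fits stuck in secondary minima are recognizable by residual RMS orders
of magnitude above the stage median and are excluded (factor 3 by
default); Arrhenius lines additionally reject isolated stray points by
a 3-MAD rule. On noiseless synthetic data this pipeline returns the
generating laws to machine precision; with 2% multiplicative noise,
mid-grid relaxation times are recovered to a few percent, while the
lowest supercooled temperature (peak at the window edge) is
intrinsically soft.

# Masterplot and shape analysis

`build_masterplot()` aligns each spectrum's α-peak maximum — refined by
a parabola through the five points around the discrete maximum in
$(\log_{10} f, \varepsilon'')$ — with the reference peak (312 K by
convention), applying only horizontal shifts and unit-peak
normalization. Peak alignment was chosen over overlap-region least
squares because it is deterministic and directly mirrors visual
superposition; spectra whose maximum touches the window edge are
excluded with a warning rather than extrapolated. `fit_kww()` then fits
the peak-normalized KWW shape with $\beta$ and $\tau$ free; points more
than 2 decades above the peak are down-weighted (weight 0.25,
configurable) because the high-frequency flank of structural peaks is
contaminated by the β-process.

# The relaxation map

`fit_vft()` exploits that the VFT model is linear in
$(\log_{10}\tau_\infty, D)$ once $T_0$ is fixed: the residual sum of
squares is profiled over $T_0$ by golden-section search. This is
deterministic, start-free, and exact to optimizer tolerance on
noiseless data. The parameterization carries $D$ in kelvin,
$\tau = \tau_\infty e^{D/(T-T_0)}$; with the default ARP triple
($\log_{10}\tau_\infty = -15.73$, $T_0 = 248.0$ K, $D = 2257$ K) the
closed-form inversion $T(\tau = 100\,\mathrm{s})$ gives
$T_g = 303$ K. The pre-exponential is taken as $10^{-15.73}$ s — a
sub-picosecond attempt time; a *positive* exponent would be unphysical
and inconsistent with that $T_g$.

The steepness index $m_p = (D/\ln 10)\,T_g/(T_g - T_0)^2$ evaluates to
≈97 for the default triple and is verified against a central-difference
derivative of $\log_{10}\tau$ versus $T_g/T$ to 0.1%. $m_p$ is
sensitive to the $T_g$ convention: evaluating the same derivative at
the calorimetric $T_g$ of 307 K gives ≈86, and literature values for
this drug cluster around 91 — the package always reports the
closed-form value at the kinetic $T_g$ it computed, and the two inputs
it used.

For the coupling model, $\tau_0 = t_c^{\,n}\tau_\alpha^{\,1-n}$ with
$n = 1-\beta_{KWW}$ and $t_c = 2$ ps. `classify_secondary()` calls a
process Johari–Goldstein when the mean $|\log_{10}\tau_0 -
\log_{10}\tau_{sec}|$ over the supplied structural points is within a
tolerance (1 decade by default — continuity in this literature is a
visual, order-of-magnitude judgment). `relaxation_map()` makes the
comparison over the five structural points nearest $T_g$: that is where
the measured secondary branch and the predicted primitive relaxation
actually meet, whereas deep in the liquid all fast processes crowd
together on a log axis and the metric loses discrimination. For the
default ARP laws the prediction runs 1.2–1.5 decades below the
β-extrapolation near $T_g$ but ~3 decades from γ, so the *ordering* is
unambiguous even though the absolute agreement for β is
order-of-magnitude; the tests assert exactly that.

# DSC analysis

Heat flow is exothermic-positive internally; readers flip sign via
`exo_up`. The glass transition is located from linear baselines fitted
to the outer thirds of the user window: $T_{g,mid}$ is the
midpoint-crossing temperature, the onset comes from the steepest
tangent, and $\Delta C_p$ is the baseline separation at $T_{g,mid}$
divided by the heating rate in K/s. $\Delta C_p$ is therefore exactly
linear in the step height, and both estimates are invariant to vertical
offsets — properties the suite tests directly.

Exotherm and endotherm onsets use the tangent construction: baseline
from the window edges, steepest leading-edge tangent on a 5-point
smoothed trace, onset at their intersection. For a Gaussian peak this
intersection is exactly $\mathrm{center} - 2\sigma$, which is also how
onsets of *deconvolved* melting components are computed — for
overlapping endotherms the raw-trace construction is meaningless, so
the per-component closed form is used. Gaussian multi-peak
deconvolution (sum of Gaussians plus a linear baseline,
Levenberg–Marquardt) is initialized greedily and deterministically:
components are added one at a time at the maximum of the current
residual, refitting after each addition, which resolves shoulders
(e.g., the 2.7 K-separated II/III melting pair) that are not local
maxima. Component collapse ($\sigma \to 0$) flags the fit as
unconverged rather than silently returning a degenerate component.

# Composition-series analyses

$\Delta C_p$ at $T_g$ is proportional to the mobile amorphous drug
fraction; molecules immobilized on the silica surface contribute
nothing, so $\Delta C_p(w)$ falls linearly and its zero-crossing is the
monomolecular loading capacity. `fit_mlc()` uses ordinary least squares
on the per-total-mass values (additivity is the physical argument, so
no drug normalization here) and propagates the crossing's standard
error by the delta method; a non-negative slope is flagged instead of
reporting a meaningless crossing. The crystallization-onset trend
$T_c(w)$ — down at low loadings (silica surface promotes nucleation),
up after a critical concentration (immobilization wins) — is modeled as
a continuous two-segment line with the breakpoint on a 0.1 wt % grid;
a V is the simplest shape with an interior minimum, and monotone data
flag a boundary breakpoint rather than inventing one. Polymorph
fractions are absolute component areas over their sum;
`label_polymorphs()` assigns forms from reference peak-temperature
windows (IV 406–409.5 K, III 409.5–414 K, II 414–417.5 K,
I 420–423.5 K), with `X` for anything outside — deliberately so, since
an unexpected melting component is a finding, not an error.

# The synthetic study design

The generators encode the reference parameterization for amorphous
aripiprazole: VFT α-dynamics as above; Arrhenius secondaries
(β: $-17.57$, 80.4 kJ/mol; γ: $-12.39$, 23.8 kJ/mol); $\beta_{KWW}$
falling linearly from 0.55 (pure drug, 312 K reference) to 0.40 at
50 wt % silica; strengths scaled by the drug mass fraction;
recrystallization onsets 338/333/327/325/337 K at 0/10/20/30/40 wt %
and none at 50; DSC $T_g = 307$ K with a 0.35 J/(g·K) step falling to
zero at 65 wt %; a V-shaped $T_c(w)$ with vertex 27.3 wt % and
357 K at $w = 0$; and melting components built from the polymorph
onset/peak pairs via $\sigma = (\mathrm{peak}-\mathrm{onset})/2$, so
the tangent-onset identity reproduces the source onsets by
construction. Measurement grids are 153–308 K (5 K) and 310–342 K
(2 K) over $10^{-1}$–$10^6$ Hz at 10 points per decade, and DSC traces
run 280–433 K at 0.1 K with 10 K/min.

Where no measured value exists, one realistic choice was made and
frozen: base $\Delta\varepsilon = 4$ and $\Delta C_p = 0.35$ J/(g·K)
(absolute magnitudes are figure-only information; no analysis depends
on them), conductivity tied to structural dynamics as
$\sigma_{dc} = 2\times10^{-12}/\tau_\alpha(T)$ S/m (a
Debye–Stokes–Einstein-like coupling producing a low-frequency
conductivity tail comparable to the α-peak, as observed above $T_g$),
HN shape $a = 0.82$, $b = 0.63$ for α, CC widths 0.35/0.30 for β/γ,
residual amorphous fraction $0.15 + 0.01w$ increasing with loading
(recrystallization in composites is always incomplete), exotherm
enthalpy 60 J/g, and crystallization-trend slopes $-0.51$ and $+0.60$
K/wt %. Recrystallization in BDS is a sigmoid suppression of
$\Delta\varepsilon_\alpha$,
$x_{res} + (1-x_{res})/(1+e^{(T-T_{on}-2\delta)/\delta})$ with
$\delta = 1$ K; note the 5%-drop detector therefore crosses ~0.6 K
below $T_{on}$ — within the 1 K round-trip tolerance, and a reminder
that "onset" is threshold-defined for any smooth drop. The $T_g$ step
is a logistic of 2 K width (slope-matched scale $w/4$). Noise is
multiplicative log-normal on loss (2% relative by default) and additive
Gaussian on heat flow (0.5% of the exotherm peak), both seeded.

What the generator does **not** emulate: electrode polarization and
Maxwell–Wagner–Sillars interfacial polarization (plausible in silica
composites), thermal-lag smearing of DSC events, baseline curvature,
$\varepsilon'$, and nucleation kinetics proper. Passing round trips
therefore demonstrate that the estimators recover the assumed structure
— not that real composite spectra are free of interfacial
contributions.

# Problem sizes and determinism

The test suite runs a full BDS round trip (49 spectra × 71
frequencies), DSC traces of 1531 points, 100-shape brute-force oracle
sweeps, and seeded-noise recovery studies; everything completes in
about a minute on one core. All stochastic inputs take explicit seeds
(default 42), and identical (scenario, seed) pairs produce bit-identical
output — asserted as a test, since reproducibility of the synthetic
study is itself part of the contract.

# Known limitations

* Label assignment in blind multi-process fits is heuristic; the fit
  plan is the user's responsibility, and the staged `analyze_bds()`
  defaults assume the default frequency window and grids.
* The lowest supercooled temperature puts the α-peak at the
  low-frequency window edge; its relaxation time is soft under noise.
* The JG/non-JG decision depends on the comparison temperatures and
  tolerance; the defaults make the comparison near $T_g$ and the
  package always reports the underlying mean log-distance so the
  decision is auditable.
* `fit_vft()` assumes a single α-branch; systems with a dynamic
  crossover need split fits.
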