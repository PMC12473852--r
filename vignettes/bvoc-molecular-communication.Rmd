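---
title: "Modeling inter-plant stress signaling as a molecular-communication link"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling inter-plant stress signaling as a molecular-communication link}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantmc)
```

# The model

Plants under biotic or abiotic stress emit stress-specific biogenic
volatile organic compounds (BVOCs): methyl jasmonate is a marker of pest
attack, ethanol of heat stress. `plantmc` treats the emitting plant as the
transmitter of a single-input single-output communication system, the air
as the channel, and a neighboring plant as the receiver. Each stress type
is modulated onto one compound (a one-to-one alphabet), and the receiver
demodulates by comparing the absorbed mass of every compound against a
per-compound threshold: a stress is declared when exactly one compound
reaches its threshold, and `ERROR` when none or several do.

The chain has four stages.

**Transmitter.** Synthesis is driven by a gene-regulation ODE with additive
sigmoid inputs and first-order decay,
$$\xi(t) = \frac{dG_x}{dt}
  = \frac{\eta_{x1}}{1+\exp(-a_{x0}-\sum_y a_{xy} G_y)} - \eta_{x2} G_x,$$
with no autoregulation. The synthesized compound partitions into aqueous
(fraction $\eta$) and lipid pools, drains into an intercellular gas pool,
and is vented through stomata at rate $J(t) = u_g Q_g(t)$. The expected
cumulative mass arriving at the receiver is the convolution of $J$ with
the channel's cumulative hit response; an impulse release of mass $M$ at
$t = 0$ (the default everywhere) gives simply $M\,F_{hit}(t)$.

**Channel.** A molecule released at a point source a distance $d$ from the
surface of a perfectly absorbing sphere of radius $R$, drifting downwind
at speed $v$ and diffusing with coefficient $D$, first hits the sphere at
a time with density
$$f(t) = \frac{R\,d}{R+d}\,\frac{1}{\sqrt{4\pi D t^3}}
  \exp\!\Big(\!-\frac{(d-vt)^2}{4Dt}\Big),$$
peaking at $t_{peak} = 2d^2/\big(6D+\sqrt{36D^2+4v^2d^2}\big)$ (equal to
$d^2/6D$ when $v=0$). The hit probability within an observation window
$\omega$ is $F_{hit}(\omega)=\int_0^{\omega} f\,dt$, bounded by the
no-drift escape probability $R/(R+d)$.

**Receiver.** The arrived mass sets a leaf-surface concentration
$C_{leaf} = 3MF_{hit}/(4\pi R^3\phi)$, where $\phi$ is the ratio of leaf
volume to the modeled absorption sphere. First-order uptake with rate
$\beta = A_L\rho_L g/(K_L m_L)$ saturates at the partition equilibrium,
and the absorbed mass over a stomatal window $\tau$ is
$$M_{abs} = \frac{3 M F_{hit}\, m_L K_L}{4\pi R^3 \phi \rho_L}
  \Big(\tau - \frac{1-e^{-\beta\tau}}{\beta}\Big).$$

**Detection.** Symbols occupy slots of length $T_s$; slot $k$'s detection
window is centered on $t_{peak}$ with width $T_s$ (lower edge clamped at
0). The received quantity is signal + inter-symbol interference (ISI) +
ambient noise: the current-slot signal is binomial $B(M, q_1)$, each
earlier slot contributes mean $pMq$ and variance $pMq(1-q)$ with transmit
probability $p$, and noise is Gaussian $(\mu_n, \sigma_n^2)$. Gaussian
approximation gives closed-form slot moments; scaling the mean linearly
and the variance quadratically by the absorption factor yields the
absorbed-quantity statistics, and the detection error rate (DER) for a
transmitted compound $i$ is
$$P_{err} = 1 - Q\!\Big(\frac{\theta_i-\mu_{abs}}{\sigma_{abs}}\Big)
  \prod_{j\neq i} Q\!\Big(\frac{\hat\mu_j-\theta_j}{\hat\sigma_j}\Big),$$
with $Q$ the standard normal right tail and $\hat\mu_j,\hat\sigma_j$ the
interferer statistics (ISI + noise, no current-slot signal).

# Parameters, units and defaults

All masses are mg, times s, lengths m. The reference parameter set used in
the worked examples:

| Parameter | Default | Meaning |
|---|---|---|
| $d$ | 1 m | transmitter-to-receiver surface distance |
| $v$ | 3 m/s (absorption) / 1 m/s (detection) | wind speed |
| $D$ | 0.008; 0.007 (MeJA), 0.009 (ethanol) m²/s | diffusion coefficient |
| $R$ | 0.15 m | receiver sphere radius |
| $\omega$ | 2 s | observation window |
| $A_L$ | 0.009 m² | leaf area |
| $g$ | 86.4 m/day | leaf conductance |
| $\rho_L$ | 1000 kg/m³ | leaf tissue density |
| $m_L$ | 0.05 kg | leaf mass |
| $K_L$ | 20 | leaf-air partition coefficient |
| $\phi$ | 0.5 | leaf-to-sphere volume ratio |
| $\tau$ | 2 s | stomatal absorption window |
| $M$ | 0.0016 mg | emitted mass per symbol |
| $T_s$ | 2 s | symbol interval |
| SNR | 10 | linear signal-to-noise ratio |
| $p$ | 0.5 | per-slot transmit probability |

The transmitter kinetics have no published values; the package defaults
($\eta = 0.5$, $u_a = u_l = 0.1$, $u_g = 0.05\ \mathrm{s^{-1}}$,
$a_{x0} = 0$, $\eta_{x1} = 1$ mg/s, $\eta_{x2} = 0.1\ \mathrm{s^{-1}}$)
were chosen once to give order-one dynamics on the seconds timescale of
the channel, and are fully overridable in configuration.

**Conductance units.** The leaf conductance is tabulated as 86.4 m/day.
In `si` mode (default of `leaf_params()`) it is converted to
$10^{-3}$ m/s, giving $\beta = 0.009\ \mathrm{s^{-1}}$ and an uptake
integral $I(2\,\mathrm{s}) \approx 0.0179$ s. In `as_printed` mode the
numeral 86.4 is used with seconds ($\beta = 777.6\ \mathrm{s^{-1}}$,
$I(2) \approx 2$ s). Detection thresholds of order $2\times10^{-4}$ mg
against emissions of $1.6\times10^{-3}$ mg are only reachable on the
`as_printed` scale, so the reference configuration for figure-style
sweeps uses it; the mode is always an explicit switch. Similarly, the
tabulated tissue density of 1000 kg per *square* meter is treated as
kg/m³ — the only reading under which $\beta$ has units of 1/s. The
absorbed-mass formula integrates a dimensionless saturation curve over
time, so taken literally its output carries mg·s; the package follows the
source convention of treating it as a mass in mg.

**Counts versus masses.** The binomial signal model needs an integer trial
count, while configurations state masses in mg. Detection functions
therefore take the emitted quantity as a dimensionless binomial size, and
`mc_config()` converts masses with a `molecules_per_mg` constant
(default $10^6$). Thresholds convert identically, so every threshold
comparison — and hence the DER — is invariant to the constant.

**Noise from SNR.** The ambient-noise model is closed with a single
parameter: $\sigma_n = Mq_1/\sqrt{SNR}$ and $\mu_n = \sigma_n$. The SNR
calibrates the noise at the current operating point, so in emission-mass
sweeps the noise shrinks with the emitted mass and the DER reaches exactly
1 in the zero-emission limit. The alternative — freezing the noise at a
reference mass — yields a DER that saturates at an interference floor for
large $M$ but stays measurably below 1 at $M = 0$ (ambient noise alone
then crosses the detection threshold a few percent of the time); the two
calibrations cannot both be had, and the per-point one is the package
default. A consequence worth knowing: with per-point calibration the DER
is non-increasing in $M$ only while the thresholds remain above the
growing noise floor, i.e. up to roughly the reference mass at which the
thresholds were optimized.

**Thresholds.** The single-symbol DER is monotone in each threshold
(raising your own threshold only hurts; raising an interferer's only
helps), so an interior optimum exists only for the *symbol-averaged* DER,
where each compound is both signal and interferer.
`optimal_thresholds()` minimizes that average by deterministic grid
search (41×41 coarse grid spanning zero to 30% above the largest absorbed
signal mean + 4 sd, one 21×21 local refinement). `threshold_grid` sweeps
report the same averaged surface.

# Numerical choices

* **Quadrature.** `hit_probability()` integrates the hit density
  adaptively (`stats::integrate`) piecewise between knots placed
  geometrically around $t_{peak}$, so a narrow arrival pulse inside a long
  window is never missed; the removable $t=0$ singularity is handled by
  the limit convention $f(0)=0$. Infinite windows integrate the far tail
  under the substitution $u = 1/\sqrt{t}$, which maps the $t^{-3/2}$ decay
  to a bounded integrand. Halving the tolerance does not move the result
  (a step-halving test guards this), so the low-wind discretization
  artifacts that plague naive fixed-grid integration do not appear.
* **Peak time.** Evaluated as $2d^2/(6D+\sqrt{36D^2+4v^2d^2})$, which is
  algebraically identical to the textbook root but free of the
  subtractive cancellation that corrupts it as $v \to 0$.
* **Pool ODEs.** The three-pool system is linear with constant
  coefficients; each step advances the augmented state (pools, cumulative
  emitted and produced mass, held synthesis rate) by an exact matrix
  exponential. There is no truncation error, which is what lets the test
  suite demand mass-balance residuals at the $10^{-6}$ relative level
  (observed: $\sim10^{-14}$).
* **Gene ODE.** The sigmoid network is nonlinear but tiny; classical RK4
  with step $\le 0.1/\max \eta_{x2}$ reproduces an `lsoda` reference to
  $10^{-5}$ relative in the tests.
* **Degenerate detection inputs.** Zero variances resolve the Q-function
  terms as step functions rather than dividing by zero; a warning is
  issued when $Mq_1 < 100$, where the Gaussian approximation of the
  binomial is doubtful, but computation proceeds.
* **Ties.** Threshold comparison uses $\ge$ for detection, exactly as the
  decision rule states; a quantity exactly at threshold counts as a
  detection.

# The Monte Carlo validators

Two simulators provide oracles that are independent of the closed forms.

**Brownian particles.** Each particle starts at the source (radius $R+d$
from the sphere center), takes drift $v\,dt$ along the wind axis plus
isotropic Gaussian increments of per-axis variance $2D\,dt$, and is
absorbed when a step ends inside the sphere. The near-surface step floor
is $10^{-4}\min(t_{peak}, R^2/D)$; away from the sphere the step grows
adaptively (exact in distribution for Brownian increments) so that six
per-axis standard deviations and the drift displacement stay below half
the clearance, making $10^4$-second horizons affordable. At $v=0$,
survivors at the horizon are resolved by the exact strong-Markov escape
probability $R/r$, giving an unbiased estimate of the eventual hit
fraction; with 20,000 particles the estimates at $d = R$ and $d = 3R$
match $R/(R+d)$ within three standard errors.

The drift case exposes a genuine limitation of the closed form: the
analytic density inserts drift into the no-drift absorbing-sphere
solution, so its time integral stays capped at $R/(R+d)$ no matter how
strong the wind, whereas true drift-dominated transport funnels nearly every
particle within the sphere's cross-section into absorption. At the
reference absorption geometry (Péclet number $vd/D = 375$) the empirical
hit fraction is roughly 0.9 against an analytic 0.13. The package
implements the closed form as printed — all absorption and detection
results inherit this conservative bias — and the particle tests quantify
the discrepancy directionally without gating on it.

**Symbol trials.** The detection chain is sampled directly (binomial
signal, per-slot binomial ISI gated by a physical transmit coin, Gaussian
noise, absorption scaling, threshold demodulation). At the reference
detection point ($Mq_1 \ge 500$, slots 1 and 3, SNR 5–20) the empirical
DER from $10^5$ trials agrees with the closed form within 0.02. One
modeling subtlety the tests document: the stated Gaussian ISI variance
$pMq(1-q)$ is that of a binomial of size $pM$; a literal transmit coin
adds a Bernoulli mixture term $p(1-p)(Mq)^2$. Both moments are asserted
against sampling in the suite; at the default $T_s = 2$ s the ISI is
vanishingly small (the arrival pulse is ~0.1 s wide), so the distinction
does not move the DER.

# What the generators emulate — and what they do not

The random fixture generators (`random_channel_fixtures()` and friends)
draw geometry, transport and leaf parameters across the regimes the model
covers (distances 0.3–3 m, winds 0–7 m/s, diffusivities 0.004–0.016 m²/s,
leaf constants within a factor of ~2 of the reference set). Passing the
property suite on these fixtures shows the *mathematics* is implemented
consistently across that envelope. It does not validate the model against
real canopies: the channel assumes an unbounded, still-structured
atmosphere with constant uniform wind, no turbulence, no ground boundary,
no gravitational settling or evaporation, no molecular degradation, and
single-compound emission without cross-interference. The receiver sphere
is perfectly absorbing, uptake is first-order with constant conductance,
and re-emission or metabolism of absorbed compound is not modeled beyond
the first-order loss already inside the uptake ODE.

# Problem sizes

The test suite and acceptance script run everything at sizes chosen to
keep a full check under a few minutes on one core: 20,000 particles for
the channel validation, $10^5$ symbol trials per DER comparison, 48
parameter combinations for the peak-time identity, 20 random fixtures for
the total-hit-probability limit, and 41×41 (+21×21) threshold grids.
Larger runs only tighten the Monte Carlo standard errors; nothing in the
implementation is specific to these sizes.
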