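# plantmc

Stressed plants emit stress-specific biogenic volatile organic compounds
(BVOCs) — methyl jasmonate under pest attack, ethanol under heat stress —
that neighboring plants can sense. `plantmc` models this exchange as a
molecular-communication link and asks the quantitative questions a
communication engineer would: how much compound reaches a receiving plant
a distance *d* downwind, how much its leaves absorb, and how reliably the
stress type can be identified from absorbed masses. It is aimed at
researchers in plant signaling, precision agriculture and molecular
communication who want a tested, configuration-driven reference
implementation of the full transmitter–channel–receiver–detection chain.

## The model in brief

* **Transmitter** — synthesis from a sigmoid gene-regulation ODE,
  `ξ(t) = η₁ σ(a₀ + Σ a_y G_y) − η₂ G`, feeding aqueous/lipid/gas storage
  pools that vent through stomata at rate `J(t) = u_g Q_g(t)`.
* **Channel** — drift–diffusion to a perfectly absorbing sphere of radius
  *R*; first-hitting-time density
  `f(t) = Rd/(R+d) · (4πDt³)^(−1/2) · exp(−(d−vt)²/(4Dt))`, peak time
  `t_peak = 2d²/(6D + √(36D² + 4v²d²))`, hit probability
  `F_hit(ω) = ∫₀^ω f dt ≤ R/(R+d)`.
* **Receiver** — leaf-surface concentration `3MF_hit/(4πR³φ)`, first-order
  uptake with rate `β = A_L ρ_L g/(K_L m_L)`, absorbed mass
  `M_abs = M F_hit · 3m_L K_L/(4πR³φρ_L) · (τ − (1−e^{−βτ})/β)`.
* **Detection** — per-slot Gaussian signal/ISI/noise statistics and the
  closed-form detection error rate (DER)
  `P_err = 1 − Q((θ−μ_abs)/σ_abs) · Π_j Q((μ̂_j−θ_j)/σ̂_j)`, plus the
  mutual-exclusion threshold demodulator (exactly one compound at or above
  threshold, otherwise `ERROR`).
* **Monte Carlo** — a Brownian-particle channel simulator and a direct
  symbol-trial simulator serve as independent oracles for the closed forms.

## Worked example

```r
library(plantmc)

ch <- channel_params(d = 1, v = 3, D = 0.008, R = 0.15, omega = 2)
ch
#> <channel_params>
#>   d = 1 m, v = 3 m/s, D = 0.008 m^2/s, R = 0.15 m, omega = 2 s
#>   t_peak = 0.330677 s, F_hit(omega) = 0.130435, F_hit(Inf) = 0.130435
```

The arrival pulse peaks 0.33 s after release and essentially all of the
reachable fraction `R/(R+d) = 0.1304` has arrived within the 2 s window.
Feeding that into the leaf-uptake stage (reference leaf constants,
printed-conductance scale, `φ = 0.5`, `τ = 2 s`):

```r
lp <- leaf_params(phi = 0.5, tau = 2, conductance_units = "as_printed")
absorbed_mass(0.0016, hit_probability(2, ch), lp, R = 0.15)
#> [1] 5.901082e-05
```

so a 0.0016 mg emission leaves 5.9e-5 mg in the receiver's leaves — below
a 2.1e-4 mg detection threshold at this 1 m distance, which is why
`detection_range(0.00021, reference_config("absorption"))` reports that
detection at that threshold is confined to about 0.17 m.

For stress identification, optimize the two detection thresholds at the
reference emission mass and decode a binary stress sequence (0 = methyl
jasmonate/pest, 1 = ethanol/heat) through the full chain:

```r
cfg <- reference_config("detection")
opt <- optimal_thresholds(cfg)
opt$thresholds            # count units; 47.81 for both compounds
round(opt$der, 4)
#> [1] 0.1141

demod_sequence_demo("001101", cfg, thresholds = opt$thresholds)$decoded
#> [1] "001101"
```

The symbol-averaged DER at the optimum is 0.114 at SNR 10, and the
six-symbol sequence decodes without error under these clean conditions.

## Command line

A thin CLI over the same functions ships in `inst/cli/plantmc`:

```sh
Rscript inst/cli/plantmc channel --d 1 --v 3 --D 0.008 --R 0.15 --omega 2
Rscript inst/cli/plantmc sweep --kind distance --grid 0.2,0.5,1,2,5 --out fig_d.csv
Rscript inst/cli/plantmc demod --sequence 001101
Rscript inst/cli/plantmc validate --particles 20000 --seed 1
```

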