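# Shared fixtures for the test suite. Everything is generated in code.

ref_channel <- function(omega = 2) {
  channel_params(d = 1, v = 3, D = 0.008, R = 0.15, omega = omega)
}

# Inverse-Gaussian first-passage CDF: independent closed-form oracle for the
# time integral of the drift-diffusion hit density (per-axis variance 2D).
ig_cdf <- function(t, d, v, D) {
  mu <- d / v
  lambda <- d^2 / (2 * D)
  a <- sqrt(lambda / t)
  pnorm(a * (t / mu - 1)) +
    exp(2 * lambda / mu + pnorm(-a * (t / mu + 1), log.p = TRUE))
}

# Dense-grid + golden-section argmax of the hit density; independent of the
# closed-form peak time.
argmax_hit_density <- function(ch, span = 50) {
  grid <- exp(seq(log(1e-4), log(span * ch$d^2 / ch$D + ch$d / max(ch$v, 1e-9)),
                  length.out = 4000L))
  i <- which.max(hit_density(grid, ch))
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  stats::optimize(function(t) hit_density(t, ch), c(lo, hi), maximum = TRUE,
                  tol = 1e-12)$maximum
}

detection_cfg <- function(...) reference_config("detection", ...)

# A slot scheme short enough that consecutive windows overlap the arrival
# pulse, so inter-symbol interference is non-trivial.
isi_cfg <- function() {
  reference_config("detection", T_s = 0.3, k = 3L)
}
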