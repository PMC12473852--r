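test_that("slot reception probabilities clamp, telescope and vanish with T_s", {
  ch <- channel_params(d = 1, v = 1, D = 0.007, R = 0.15, omega = 2)
  tp <- peak_time(ch)

  # t_peak < T_s/2: the first window's lower edge is clamped at 0
  sc2 <- slot_scheme(T_s = 2)
  q1 <- slot_hit_prob(1, 1, sc2, ch)
  expect_equal(q1, hit_probability(tp + 1, ch) - hit_probability(0, ch),
               tolerance = 1e-10)

  # vanishing window
  expect_lt(slot_hit_prob(1, 1, slot_scheme(T_s = 1e-6), ch), 1e-5)

  # contiguous windows telescope to the hit probability between outer edges
  sc <- slot_scheme(T_s = 0.3)
  qs <- vapply(1:6, function(k) slot_hit_prob(k, 1, sc, ch), numeric(1))
  lo1 <- max(0, tp - 0.15)
  hi6 <- 5 * 0.3 + tp + 0.15
  expect_equal(sum(qs),
               hit_probability(hi6, ch) - hit_probability(lo1, ch),
               tolerance = 1e-9)
  expect_lte(sum(qs), ch$R / (ch$R + ch$d) + 1e-9)

  expect_error(slot_hit_prob(1, 2, sc, ch), "after")
})

test_that("SNR-derived noise has the stated scaling", {
  ns <- noise_from_snr(10, M = 500, q1 = 0.2)   # M q1 = 100
  expect_equal(ns$sigma_n, 100 / sqrt(10), tolerance = 1e-12)
  expect_equal(ns$mu_n, ns$sigma_n, tolerance = 1e-15)
  ns1 <- noise_from_snr(1, M = 500, q1 = 0.2)
  expect_equal(ns1$sigma_n, 100, tolerance = 1e-12)
  ns_inf <- noise_from_snr(Inf, M = 500, q1 = 0.2)
  expect_identical(ns_inf$sigma_n, 0)
  expect_error(noise_from_snr(0, 500, 0.2), "snr")
})

test_that("Gaussian symbol model reproduces binomial moments and absorbed scaling", {
  cfg <- detection_cfg()
  mol <- cfg$alphabet$MeJA
  st <- gaussian_symbol_model(5000, mol, cfg$scheme, cfg$channel, cfg$leaf,
                              noise_spec(), k = 1)
  q1 <- st$q[1L]
  expect_equal(st$mu, 5000 * q1, tolerance = 1e-12)
  expect_equal(st$sigma2, 5000 * q1 * (1 - q1), tolerance = 1e-12)
  # absorbed moments: mean scales linearly, variance quadratically
  expect_equal(st$mu_abs, st$mu * st$scale, tolerance = 1e-12)
  expect_equal(st$sigma2_abs, st$sigma2 * st$scale^2, tolerance = 1e-12)

  # interferer estimate drops the current-slot signal
  sti <- gaussian_symbol_model(5000, mol, cfg$scheme, cfg$channel, cfg$leaf,
                               noise_spec(mu_n = 7, sigma_n = 3), k = 1,
                               signal = FALSE)
  expect_equal(sti$mu, 7, tolerance = 1e-12)
  expect_equal(sti$sigma2, 9, tolerance = 1e-12)

  expect_warning(
    gaussian_symbol_model(100, mol, cfg$scheme, cfg$channel, cfg$leaf,
                          noise_spec(), k = 1),
    "Gaussian approximation")
})

test_that("symbol moments match direct stochastic sampling with ISI and noise", {
  cfg <- isi_cfg()            # T_s = 0.3: consecutive windows carry ISI
  mol <- cfg$alphabet$MeJA
  noise <- noise_spec(mu_n = 30, sigma_n = 12)
  k <- 3L
  M <- 4000
  st <- gaussian_symbol_model(M, mol, cfg$scheme, cfg$channel, cfg$leaf,
                              noise, k = k)
  expect_gt(st$components$isi[["mu"]], 0)

  set.seed(4711)
  n <- 1e5
  # sampling model with exactly the stated per-slot interference moments
  # (mean p M q, variance p M q (1 - q)): a binomial of size p M
  samp <- stats::rbinom(n, M, st$q[1L]) + stats::rnorm(n, 30, 12)
  for (j in 2:k) {
    samp <- samp + stats::rbinom(n, round(mol$p * M), st$q[j])
  }
  se_mu <- sd(samp) / sqrt(n)
  expect_lt(abs(mean(samp) - st$mu), 3 * se_mu)
  se_var <- sd((samp - mean(samp))^2) / sqrt(n)
  expect_lt(abs(var(samp) - st$sigma2), 3 * se_var)

  # under the physical transmit-coin model the mean is unchanged but the
  # variance gains the Bernoulli mixture term p (1 - p) (M q)^2 per slot,
  # which the Gaussian interference model does not carry
  samp2 <- stats::rbinom(n, M, st$q[1L]) + stats::rnorm(n, 30, 12)
  for (j in 2:k) {
    samp2 <- samp2 + stats::rbinom(n, 1, mol$p) * stats::rbinom(n, M, st$q[j])
  }
  expect_lt(abs(mean(samp2) - st$mu), 3 * sd(samp2) / sqrt(n))
  mix_var <- st$sigma2 +
    sum(mol$p * (1 - mol$p) * (M * st$q[2:k])^2)
  se_var2 <- sd((samp2 - mean(samp2))^2) / sqrt(n)
  expect_lt(abs(var(samp2) - mix_var), 4 * se_var2)
})

test_that("closed-form DER has the Q-function structure and limits", {
  clean <- list(theta = 100, mu_abs = 1, sigma2_abs = 1e-6)  # always below
  st <- list(mu_abs = 50, sigma2_abs = 25)

  # threshold at the mean: Q(0) = 1/2
  expect_equal(der(50, st, list(clean))$p_error, 0.5, tolerance = 1e-9)
  # hopeless threshold -> certain error; trivial threshold -> none
  expect_equal(der(1e6, st, list(clean))$p_error, 1, tolerance = 1e-12)
  expect_equal(der(1e-9, st, list(clean))$p_error, 0, tolerance = 1e-9)

  # degenerate variances resolve as step functions, no division
  st0 <- list(mu_abs = 50, sigma2_abs = 0)
  expect_equal(der(50, st0, list())$p_error, 0)   # mu >= theta detects
  expect_equal(der(51, st0, list())$p_error, 1)
  bad_interferer <- list(theta = 10, mu_abs = 10, sigma2_abs = 0)
  expect_equal(der(50, st0, list(bad_interferer))$p_error, 1)  # mu >= theta

  expect_true(all(vapply(seq(1, 100, by = 7), function(th) {
    p <- der(th, st, list(clean))$p_error
    p >= 0 && p <= 1
  }, logical(1))))
})

test_that("DER is monotone in own and interferer thresholds", {
  cfg <- detection_cfg()
  M <- 1600
  noise <- plantmc:::noise_set_from_snr(10, M, cfg$alphabet, cfg$scheme,
                                        cfg$channel)
  ths <- seq(5, 120, by = 5)
  own <- vapply(ths, function(th) {
    symbol_der("MeJA", cfg$alphabet, M, scheme = cfg$scheme, ch = cfg$channel,
               lp = cfg$leaf, noise = noise,
               thresholds = c(MeJA = th, ethanol = 50))$p_error
  }, numeric(1))
  expect_true(all(diff(own) >= -1e-12))
  other <- vapply(ths, function(th) {
    symbol_der("MeJA", cfg$alphabet, M, scheme = cfg$scheme, ch = cfg$channel,
               lp = cfg$leaf, noise = noise,
               thresholds = c(MeJA = 50, ethanol = th))$p_error
  }, numeric(1))
  expect_true(all(diff(other) <= 1e-12))
})

test_that("DER is non-increasing in SNR on a parameter grid", {
  # thresholds must sit between the noise level and the signal level for
  # SNR to be purely beneficial; anchor them to each geometry's signal
  cfg <- detection_cfg()
  M <- 1600
  for (d in c(1, 2)) {
    ch <- channel_params(d = d, v = 1, D = 0.008, R = 0.15, omega = 2)
    th <- vapply(cfg$alphabet, function(mol) {
      ch_m <- channel_params(d = d, v = 1, D = mol$D, R = 0.15, omega = 2)
      q1 <- slot_hit_prob(1, 1, cfg$scheme, ch_m)
      0.7 * M * q1 * absorption_scale(cfg$leaf, 0.15)
    }, numeric(1))
    ders <- vapply(c(1, 3, 10, 30, 100), function(snr) {
      suppressWarnings(
        mean_der(cfg$alphabet, M, scheme = cfg$scheme, ch = ch,
                 lp = cfg$leaf, snr = snr, thresholds = th))
    }, numeric(1))
    expect_true(all(diff(ders) <= 1e-12),
                label = sprintf("DER vs SNR at d = %g", d))
  }
})

test_that("threshold demodulation implements mutual exclusion exactly", {
  ab <- default_alphabet(c(MeJA = 1, ethanol = 2))
  expect_identical(demodulate(c(MeJA = 1.01, ethanol = 1.99), ab), "pest")
  expect_identical(demodulate(c(MeJA = 0.99, ethanol = 2.0), ab), "heat")
  expect_identical(demodulate(c(MeJA = 1, ethanol = 2), ab), "ERROR")
  expect_identical(demodulate(c(MeJA = 0, ethanol = 0), ab), "ERROR")
  expect_error(demodulate(c(MeJA = 1), ab), "missing")
})
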