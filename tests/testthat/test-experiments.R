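test_that("sweep specs validate their grids before computing", {
  expect_error(sweep_spec("distance", numeric(0)), "non-empty")
  expect_error(sweep_spec("distance", c(2, 1)), "sorted")
  expect_error(sweep_spec("distance", c(0, 1)), "> 0")
  expect_error(sweep_spec("nonsense", 1:3), "arg")
})

test_that("absorption sweeps reproduce the distance and window trends", {
  cfg <- reference_config("absorption")
  sw <- run_sweep(sweep_spec("distance", seq(0.2, 5, by = 0.4), cfg))
  expect_equal(nrow(sw), length(seq(0.2, 5, by = 0.4)))
  expect_true(all(diff(sw$metric_value) < 0))    # inverse distance relation

  # absorption grows with the observation window across the arrival pulse
  sw_t <- run_sweep(sweep_spec("time", c(0.2, 0.25, 0.3, 0.35, 0.45), cfg))
  expect_true(all(diff(sw_t$metric_value) > 0))
})

test_that("detection sweeps: DER falls with SNR and with emitted mass", {
  cfg <- reference_config("detection")
  th <- c(MeJA = 47.8, ethanol = 47.8)
  sw_snr <- run_sweep(sweep_spec("snr", c(1, 2, 5, 10, 20, 50), cfg,
                                 thresholds = th))
  expect_true(all(diff(sw_snr$metric_value) < 0))

  sw_m <- run_sweep(sweep_spec("emission",
                               c(1e-5, 1e-4, 3e-4, 6e-4, 1e-3, 1.6e-3), cfg,
                               thresholds = th))
  expect_true(all(diff(sw_m$metric_value) <= 1e-12))
  expect_equal(sw_m$metric_value[1L], 1, tolerance = 1e-6)
})

test_that("threshold surface has an interior optimum", {
  cfg <- reference_config("detection")
  opt <- optimal_thresholds(cfg)
  expect_lt(opt$der, 0.5)
  surface <- opt$surface
  axis <- sort(unique(surface$MeJA))
  best <- surface[which.min(surface$der), ]
  # the argmin sits strictly inside the searched box on both axes
  expect_gt(best$MeJA, min(axis))
  expect_lt(best$MeJA, max(axis))
  expect_gt(best$ethanol, min(axis))
  expect_lt(best$ethanol, max(axis))
  # along each axis through the optimum the DER falls then rises
  ridge <- surface[surface$ethanol == best$ethanol, ]
  ridge <- ridge[order(ridge$MeJA), "der"]
  i <- which.min(ridge)
  expect_true(all(diff(ridge[seq_len(i)]) <= 1e-12))
  expect_true(all(diff(ridge[i:length(ridge)]) >= -1e-12))
})

test_that("detection range refines the largest qualifying distance", {
  cfg <- reference_config("absorption")
  expect_message(dr_none <- detection_range(1e3, cfg), "no distance")
  expect_true(is.na(dr_none))
  # a vanishing threshold is met everywhere in the search range
  expect_equal(detection_range(1e-12, cfg, d_range = c(0.05, 2)), 2,
               tolerance = 1e-9)

  dr <- detection_range(0.00021, cfg)
  expect_false(is.na(dr))
  # bisection bracket: qualifies at dr, fails 2 mm beyond
  mabs <- function(d) {
    ch <- channel_params(d = d, v = 3, D = 0.008, R = 0.15, omega = 2)
    absorbed_mass(cfg$M_mg, hit_probability(2, ch), cfg$leaf, 0.15)
  }
  expect_gte(mabs(as.numeric(dr)), 0.00021)
  expect_lt(mabs(as.numeric(dr) + 0.002), 0.00021)
})

test_that("binary sequences decode exactly under clean conditions", {
  cfg <- reference_config("detection")
  th <- c(MeJA = 47.8, ethanol = 47.8)
  demo <- demod_sequence_demo("001101", cfg, thresholds = th)
  expect_identical(demo$decoded, "001101")
  expect_identical(demo$n_errors, 0L)
  expect_equal(nrow(demo$slots), 6L)

  # all-zeros: the second compound must never fire
  d0 <- demod_sequence_demo("0000", cfg, thresholds = th)
  expect_identical(d0$decoded, "0000")
  expect_true(all(d0$slots$ethanol < th[["ethanol"]]))

  # noise-dominated limit: every slot is ambiguous
  cfg_noisy <- reference_config("detection", snr = 1e-8)
  dn <- demod_sequence_demo("001101", cfg_noisy, thresholds = th)
  expect_identical(dn$decoded, "EEEEEE")

  # stochastic mode is seed-reproducible
  s1 <- demod_sequence_demo("0110", cfg, thresholds = th, stochastic = TRUE,
                            seed = 5)
  s2 <- demod_sequence_demo("0110", cfg, thresholds = th, stochastic = TRUE,
                            seed = 5)
  expect_identical(s1$decoded, s2$decoded)

  expect_error(demod_sequence_demo("0102", cfg), "over \\{0, 1\\}")
})

test_that("sweep CSVs are deterministic and configs round-trip through YAML", {
  cfg <- reference_config("absorption")
  sw <- run_sweep(sweep_spec("distance", c(0.5, 1, 2), cfg))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, f1)
  write_sweep_csv(run_sweep(sweep_spec("distance", c(0.5, 1, 2), cfg)), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[1L], "^# config_hash=")

  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "channel: {d: 2, v: 1, D: 0.008, R: 0.15, omega: 2}",
    "leaf: {phi: 0.4, tau: 1.5, conductance_units: as_printed}",
    "molecules:",
    "  - {name: MeJA, D: 0.007, threshold: 40, stress: pest}",
    "  - {name: ethanol, D: 0.009, threshold: 45, stress: heat}",
    "detection: {T_s: 2, k: 1, snr: 15}",
    "simulate: {M_mg: 0.002, seed: 3}"), yml)
  cc <- read_config(yml)
  expect_equal(cc$channel$d, 2)
  expect_equal(cc$leaf$phi, 0.4)
  expect_equal(cc$leaf$conductance_units, "as_printed")
  expect_equal(alphabet_thresholds(cc$alphabet),
               c(MeJA = 40, ethanol = 45))
  expect_equal(cc$snr, 15)
  expect_equal(cc$M_mg, 0.002)
})
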