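test_that("gene expression rate follows the sigmoid-minus-decay form", {
  n <- gene_node("x", a0 = 0, eta1 = 1, eta2 = 0.1, G0 = 0)
  expect_equal(gene_expression_rate(n), 0.5, tolerance = 1e-12)

  # saturation fixed point: sigmoid ~ 1, G = eta1/eta2 => rate ~ 0
  n_sat <- gene_node("x", a0 = 50, eta1 = 1, eta2 = 0.1, G0 = 10)
  expect_equal(gene_expression_rate(n_sat), 0, tolerance = 1e-12)

  # monotone increasing in a positively weighted regulator's level
  n_reg <- gene_node("x", a0 = -1, eta1 = 2, eta2 = 0.2,
                     weights = c(y = 1.5), G0 = 0.3)
  lv <- seq(0, 5, by = 0.25)
  rates <- vapply(lv, function(g) gene_expression_rate(n_reg, c(y = g)),
                  numeric(1))
  expect_true(all(diff(rates) > 0))

  expect_error(gene_expression_rate(n_reg, c(z = 1)), "missing regulator")
  expect_error(gene_expression_rate(n_reg, c(y = NaN)), "finite")
  expect_error(gene_node("x", weights = c(x = 1)), "autoregulation")
})

test_that("single-gene trajectory matches the linear closed form", {
  # a0 = 0, no regulators: dG/dt = 0.5 - 0.1 G => G(t) = 5 (1 - e^{-t/10})
  net <- list(gene_node("x", a0 = 0, eta1 = 1, eta2 = 0.1, G0 = 0))
  ts <- synthesis_timeseries(net, seq(0, 1, by = 0.1))
  expect_equal(as.numeric(ts$levels[11L, "x"]), 5 * (1 - exp(-0.1)),
               tolerance = 1e-6)
  expect_equal(as.numeric(ts$xi[11L, "x"]),
               0.5 - 0.1 * 5 * (1 - exp(-0.1)), tolerance = 1e-6)
})

test_that("network trajectories: degenerate cases and an independent ODE oracle", {
  grid <- seq(0, 5, by = 0.25)
  # no production anywhere
  net0 <- list(gene_node("a", eta1 = 0, eta2 = 0.1, G0 = 0),
               gene_node("b", eta1 = 0, eta2 = 0.2, G0 = 0))
  ts0 <- synthesis_timeseries(net0, grid)
  expect_true(all(ts0$xi == 0))

  # a node initialized at its fixed point stays there: constant xi (zero)
  nfix <- gene_node("a", a0 = 0, eta1 = 1, eta2 = 0.1, G0 = 5)
  tsf <- synthesis_timeseries(list(nfix), grid)
  expect_equal(max(abs(tsf$xi)), 0, tolerance = 1e-10)
  expect_equal(max(abs(tsf$levels - 5)), 0, tolerance = 1e-9)

  # two-node mutual activation vs an lsoda integration
  skip_if_not_installed("deSolve")
  net <- list(gene_node("a", a0 = -1, eta1 = 1, eta2 = 0.1,
                        weights = c(b = 2), G0 = 0),
              gene_node("b", a0 = -1, eta1 = 1, eta2 = 0.1,
                        weights = c(a = 2), G0 = 0))
  ts <- synthesis_timeseries(net, grid)
  rhs <- function(t, y, parms) {
    list(c(1 / (1 + exp(1 - 2 * y[2])) - 0.1 * y[1],
           1 / (1 + exp(1 - 2 * y[1])) - 0.1 * y[2]))
  }
  ref <- deSolve::lsoda(c(0, 0), grid, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(ts$levels[, "a"]), unname(ref[, 2]), tolerance = 1e-5)
  expect_equal(unname(ts$levels[, "b"]), unname(ref[, 3]), tolerance = 1e-5)
})

test_that("pools reach the linear-ODE steady state and decay exactly", {
  pp <- pool_params(eta = 0.5, u_a = 0.1, u_l = 0.1, u_g = 0.05)
  xi <- 0.01
  # 20 time constants of the slowest pool (u_g = 0.05 -> 400 s)
  tr <- pool_trajectory(function(t) rep(xi, length(t)), seq(0, 400, by = 0.5),
                        pp)
  last <- nrow(tr)
  expect_equal(tr$Q_a[last], pp$eta * xi / pp$u_a, tolerance = 1e-8)
  expect_equal(tr$Q_l[last], (1 - pp$eta) * xi / pp$u_l, tolerance = 1e-8)
  expect_equal(tr$J_mg_per_s[last], xi, tolerance = 1e-8)  # throughput

  # pure decay of the aqueous pool
  tr2 <- pool_trajectory(function(t) rep(0, length(t)), seq(0, 10, by = 0.5),
                         pp, pool_state(Q_a = 1))
  expect_equal(tr2$Q_a, exp(-pp$u_a * tr2$t_s), tolerance = 1e-12)
})

test_that("mass balance holds to rounding for random pool fixtures", {
  fixtures <- random_pool_fixtures(6, seed = 101)
  set.seed(202)
  for (pp in fixtures) {
    grid <- seq(0, 10, by = 0.2)
    xi <- runif(length(grid), 0, 0.05)
    tr <- pool_trajectory(xi, grid, pp)
    produced <- tr$produced[nrow(tr)]
    expect_gt(produced, 0)
    expect_lt(max(abs(tr$residual)) / produced, 1e-6)
  }
  # audit under 10 s of constant synthesis
  tr <- pool_trajectory(function(t) rep(0.01, length(t)), seq(0, 10, by = 0.1),
                        pool_params())
  expect_lt(max(abs(tr$residual)) / tr$produced[nrow(tr)], 1e-6)
})

test_that("emission rate is linear in the gas pool", {
  pp <- pool_params()
  expect_identical(emission_rate(pool_state(Q_g = 0), pp), 0)
  expect_equal(emission_rate(pool_state(Q_g = 2), pp),
               2 * emission_rate(pool_state(Q_g = 1), pp), tolerance = 1e-15)
})

test_that("arrived mass: impulse identity and a nested-quadrature oracle", {
  ch <- ref_channel()
  expect_identical(
    arrived_mass_profile(emission_profile(time_grid = c(0, 3), J = c(0, 0),
                                          mode = "profile"), ch, 3), 0)

  imp <- emission_profile(M = 1, mode = "impulse")
  for (t in c(0.5, 1, 2)) {
    expect_equal(arrived_mass_profile(imp, ch, t), hit_probability(t, ch),
                 tolerance = 1e-12)
  }

  # rectangular pulse: 0.001 mg/s on [0, 1 s], evaluated at t = 3 s
  prof <- emission_profile(time_grid = c(0, 1, 1 + 1e-9, 3),
                           J = c(0.001, 0.001, 0, 0), mode = "profile")
  got <- arrived_mass_profile(prof, ch, 3)
  oracle <- stats::integrate(function(d) {
    vapply(d, function(dd) {
      J <- if (dd <= 1) 0.001 else 0
      J * stats::integrate(function(u) hit_density(u, ch), 0, 3 - dd,
                           rel.tol = 1e-10)$value
    }, numeric(1))
  }, 0, 3, rel.tol = 1e-9)$value
  expect_equal(got, oracle, tolerance = 1e-4)

  expect_error(arrived_mass_profile(prof, ch, 5), "ends at")
})
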