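#' Random valid channel fixtures
#'
#' Seeded generator of valid random channel parameter sets for
#' property-style tests: distances 0.3-3 m, wind speeds 0-7 m/s (a zero
#' wind case is always included), diffusion coefficients 0.004-0.016 m^2/s
#' and radii 0.05-0.3 m, spanning the regimes the transport model covers.
#'
#' @param n Number of fixtures.
#' @param seed Mandatory integer seed.
#' @param include_still Force the first fixture to have `v = 0`.
#' @return A list of [channel_params()] objects.
#' @export
random_channel_fixtures <- function(n, seed, include_still = TRUE) {
  check_scalar(n, "n", lower = 1)
  check_scalar(seed, "seed")
  set.seed(as.integer(seed))
  out <- lapply(seq_len(n), function(i) {
    channel_params(d = stats::runif(1, 0.3, 3),
                   v = stats::runif(1, 0.3, 7),
                   D = stats::runif(1, 0.004, 0.016),
                   R = stats::runif(1, 0.05, 0.3),
                   omega = stats::runif(1, 0.5, 5))
  })
  if (include_still) out[[1L]]$v <- 0
  out
}

#' Random valid pool-parameter fixtures
#'
#' @param n Number of fixtures.
#' @param seed Mandatory integer seed.
#' @return A list of [pool_params()] objects.
#' @export
random_pool_fixtures <- function(n, seed) {
  check_scalar(n, "n", lower = 1)
  check_scalar(seed, "seed")
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    pool_params(eta = stats::runif(1),
                u_a = stats::runif(1, 0.02, 0.5),
                u_l = stats::runif(1, 0.02, 0.5),
                u_g = stats::runif(1, 0.01, 0.3))
  })
}

#' Random valid leaf-parameter fixtures
#'
#' Leaf constants jittered around the reference parameter set (within a
#' factor of ~2), with `phi` spanning (0.1, 1] and `tau` 0.5-5 s.
#'
#' @param n Number of fixtures.
#' @param seed Mandatory integer seed.
#' @param conductance_units Passed through to [leaf_params()].
#' @return A list of [leaf_params()] objects.
#' @export
random_leaf_fixtures <- function(n, seed, conductance_units = "si") {
  check_scalar(n, "n", lower = 1)
  check_scalar(seed, "seed")
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    leaf_params(A_L = 0.009 * stats::runif(1, 0.5, 2),
                g = 86.4 * stats::runif(1, 0.5, 2),
                rho_L = 1000 * stats::runif(1, 0.8, 1.2),
                m_L = 0.05 * stats::runif(1, 0.5, 2),
                K_L = 20 * stats::runif(1, 0.5, 2),
                phi = stats::runif(1, 0.1, 1),
                tau = stats::runif(1, 0.5, 5),
                conductance_units = conductance_units)
  })
}
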