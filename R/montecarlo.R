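#' Brownian-particle simulation of the drift-diffusion channel
#'
#' Independent stochastic check of the analytic channel model: `n` point
#' particles start at the source (point-to-surface distance `d` from the
#' absorbing sphere, i.e. at radius `R + d` from its center), drift downwind
#' at speed `v` along the source-receiver axis, and diffuse isotropically
#' with per-axis increment variance `2 D dt`. A particle is absorbed on the
#' first step that ends inside the sphere.
#'
#' The step length adapts to the clearance from the sphere: near the surface
#' it is floored at `dt` (default `1e-4 * min(t_peak, R^2 / D)`), and far
#' away it grows so that six per-axis standard deviations and the drift
#' displacement stay below half the clearance — exact in distribution for
#' Brownian increments, and keeping the probability of stepping over the
#' sphere negligible. This makes very long horizons reachable.
#'
#' In the pure-diffusion case (`v = 0`) particles still alive at the horizon
#' can be resolved analytically: a particle at radius `r` eventually hits
#' the sphere with probability exactly `R / r` (strong Markov property),
#' giving an unbiased estimate of the *eventual* hit fraction. This tail
#' resolution is reported separately from the within-horizon fraction and is
#' only available for `v = 0`.
#'
#' @param ch A [channel_params()] object.
#' @param n Number of particles, >= 1.
#' @param horizon Simulation horizon (s); defaults to `ch$omega`.
#' @param dt Near-surface step floor (s); must satisfy
#'   `dt <= 0.01 * R^2 / D`, otherwise the run is refused with guidance.
#' @param seed Mandatory integer seed.
#' @param tail_resolution Resolve survivors at the horizon analytically
#'   (only for `v = 0`).
#' @return A list with `hit_times` (sorted absorption times), `n`,
#'   `n_hit`, `fraction` (hits within the horizon), `se`, and for `v = 0`
#'   with `tail_resolution` also `fraction_eventual` and `se_eventual`.
#' @examples
#' ch <- channel_params(d = 0.15, v = 0, D = 0.008, R = 0.15)
#' sim <- simulate_particles(ch, n = 2000, horizon = 1e4, seed = 7)
#' sim$fraction_eventual   # close to R / (R + d) = 0.5
#' @export
simulate_particles <- function(ch, n, horizon = ch$omega, dt = NULL,
                               seed, tail_resolution = TRUE) {
  ch <- as_channel_params(ch)
  check_scalar(n, "n", lower = 1)
  check_scalar(horizon, "horizon", lower = 0, allow_lower = FALSE)
  check_scalar(seed, "seed")
  dt_floor_max <- 0.01 * ch$R^2 / ch$D
  if (is.null(dt)) dt <- 1e-4 * min(peak_time(ch), ch$R^2 / ch$D)
  check_scalar(dt, "dt", lower = 0, allow_lower = FALSE)
  if (dt > dt_floor_max) {
    stop_cfg(paste0("dt = %g is too coarse relative to R^2/D = %g; a step ",
                    "this large can jump across the receiver. Use dt <= %g."),
             dt, ch$R^2 / ch$D, dt_floor_max)
  }
  set.seed(as.integer(seed))
  n <- as.integer(n)

  # Source on the -x axis; wind blows along +x toward the sphere at origin.
  pos <- cbind(x = rep(-(ch$R + ch$d), n), y = 0, z = 0)
  t_now <- numeric(n)
  hit_time <- rep(NA_real_, n)
  surv_radius <- rep(NA_real_, n)
  active <- rep(TRUE, n)

  while (any(active)) {
    idx <- which(active)
    p <- pos[idx, , drop = FALSE]
    r <- sqrt(rowSums(p^2))
    clear <- pmax(r - ch$R, 0)
    step <- pmax(dt, clear^2 / (72 * ch$D))          # 6 sd <= clearance / 2
    if (ch$v > 0) step <- pmin(step, pmax(clear / (2 * ch$v), dt))
    step <- pmin(step, horizon - t_now[idx])
    sd_axis <- sqrt(2 * ch$D * step)
    p <- p + cbind(ch$v * step, 0, 0) +
      matrix(stats::rnorm(3L * length(idx)), ncol = 3L) * sd_axis
    t_new <- t_now[idx] + step
    r_new <- sqrt(rowSums(p^2))

    hit <- r_new <= ch$R
    timed_out <- !hit & t_new >= horizon
    hit_time[idx[hit]] <- t_new[hit]
    surv_radius[idx[timed_out]] <- r_new[timed_out]
    keep <- !hit & !timed_out
    pos[idx[keep], ] <- p[keep, , drop = FALSE]
    t_now[idx[keep]] <- t_new[keep]
    active[idx[!keep]] <- FALSE
  }

  n_hit <- sum(!is.na(hit_time))
  frac <- n_hit / n
  out <- list(hit_times = sort(hit_time[!is.na(hit_time)]),
              n = n, n_hit = n_hit, fraction = frac,
              se = sqrt(frac * (1 - frac) / n))
  if (tail_resolution && ch$v == 0) {
    surv <- surv_radius[!is.na(surv_radius)]
    late <- stats::rbinom(length(surv), 1L, ch$R / surv)
    frac_ev <- (n_hit + sum(late)) / n
    out$fraction_eventual <- frac_ev
    out$se_eventual <- sqrt(frac_ev * (1 - frac_ev) / n)
  }
  out
}

#' Direct symbol-trial simulation of the detection chain
#'
#' Independent stochastic check of the closed-form DER: for each of
#' `n_trials` symbol transmissions the current-slot signal of the
#' transmitted compound is drawn binomially `B(M, q1)`, every earlier slot
#' contributes interference `B(M, q_{k+1-lambda})` gated by a transmit coin
#' with probability `p`, ambient noise is drawn from the compound's
#' Gaussian noise spec, the totals are scaled by the absorption factor, and
#' the threshold demodulation rule is applied. The empirical error
#' frequency estimates the DER.
#'
#' `M` is used as a binomial size and is rounded to an integer count;
#' configurations stated in mg should be converted with a molecules-per-mg
#' constant first (thresholds scale identically, so the DER is unchanged).
#'
#' @param transmitted Name of the transmitted compound.
#' @param alphabet A [stress_alphabet()] (thresholds in the same units as
#'   the absorbed quantities).
#' @param M Emitted quantity per transmission (integer count).
#' @param k Observation slot index.
#' @param scheme A [slot_scheme()].
#' @param ch A [channel_params()] (geometry).
#' @param lp A [leaf_params()].
#' @param snr,noise,M_ref Noise specification as in [symbol_der()].
#' @param n_trials Number of simulated symbols, >= 1.
#' @param seed Mandatory integer seed.
#' @return A list with `der` (empirical error rate), `se`, `n_trials`, and
#'   `decisions` (table of decoded labels).
#' @export
simulate_symbol_trials <- function(transmitted, alphabet, M, k = 1L, scheme,
                                   ch, lp, snr = NULL, noise = NULL,
                                   M_ref = M, n_trials = 1e4, seed) {
  if (!inherits(alphabet, "stress_alphabet")) {
    stop_cfg("expected a `stress_alphabet`")
  }
  if (!transmitted %in% names(alphabet)) {
    stop_cfg("`%s` is not in the alphabet", transmitted)
  }
  check_scalar(M, "M", lower = 0)
  check_scalar(n_trials, "n_trials", lower = 1)
  check_scalar(seed, "seed")
  ch <- as_channel_params(ch)
  lp <- as_leaf_params(lp)
  noise <- resolve_noise(noise, snr, M_ref, alphabet, scheme, ch)
  set.seed(as.integer(seed))
  n_trials <- as.integer(n_trials)
  k <- as.integer(k)
  M_count <- as.integer(round(M))
  scale <- absorption_scale(lp, ch$R)

  absorbed <- matrix(0, n_trials, length(alphabet),
                     dimnames = list(NULL, names(alphabet)))
  above <- matrix(FALSE, n_trials, length(alphabet))
  for (m in seq_along(alphabet)) {
    mol <- alphabet[[m]]
    ch_m <- channel_params(d = ch$d, v = ch$v, D = mol$D, R = ch$R,
                           omega = ch$omega)
    q <- vapply(seq_len(k), function(j) slot_hit_prob(j, 1L, scheme, ch_m),
                numeric(1))
    total <- numeric(n_trials)
    if (mol$name == transmitted) {
      total <- total + stats::rbinom(n_trials, M_count, q[1L])
    }
    if (k > 1L) {
      for (j in 2:k) {
        coin <- stats::rbinom(n_trials, 1L, mol$p)
        total <- total + coin * stats::rbinom(n_trials, M_count, q[j])
      }
    }
    ns <- noise[[mol$name]]
    total <- total + stats::rnorm(n_trials, ns$mu_n, ns$sigma_n)
    absorbed[, m] <- total * scale
    above[, m] <- absorbed[, m] >= mol$threshold
  }

  n_above <- rowSums(above)
  unique_hit <- n_above == 1L
  decided <- rep("ERROR", n_trials)
  stress_of <- vapply(alphabet, `[[`, character(1), "stress")
  decided[unique_hit] <- stress_of[max.col(above[unique_hit, , drop = FALSE])]
  correct <- decided == alphabet[[transmitted]]$stress
  der_hat <- mean(!correct)
  list(der = der_hat, se = sqrt(der_hat * (1 - der_hat) / n_trials),
       n_trials = n_trials, decisions = table(decided))
}
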