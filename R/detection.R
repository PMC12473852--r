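#' Symbol-slot scheme for threshold detection
#'
#' Symbols are transmitted every `T_s` seconds; molecules for slot `k` are
#' released at `(k - 1) T_s`. The detection window of slot `k` is centered
#' on the channel peak time and spans `T_s`:
#' `[(k - 1) T_s + t_peak - T_s / 2, (k - 1) T_s + t_peak + T_s / 2]`, with
#' the lower edge clamped at 0 (the hit probability is undefined for
#' negative elapsed time).
#'
#' @param T_s Symbol interval (s), > 0.
#' @param K Number of slots, >= 1.
#' @return An object of class `"slot_scheme"`.
#' @export
slot_scheme <- function(T_s, K = 1L) {
  check_scalar(T_s, "T_s", lower = 0, allow_lower = FALSE)
  check_scalar(K, "K", lower = 1)
  structure(list(T_s = T_s, K = as.integer(K)), class = "slot_scheme")
}

slot_window <- function(j, scheme, ch) {
  tp <- peak_time(ch)
  center <- (j - 1) * scheme$T_s + tp
  c(lo = max(0, center - scheme$T_s / 2), hi = center + scheme$T_s / 2)
}

#' Per-slot reception probability
#'
#' Probability that a molecule released at the start of slot `lambda` is
#' absorbed within the detection window of slot `k`, computed on the
#' elapsed time since its release. With contiguous windows these
#' probabilities telescope: summing over `k` at fixed `lambda` gives the
#' hit probability between the outermost window edges.
#'
#' @param k Observation slot index, >= 1.
#' @param lambda Emission slot index, `1 <= lambda <= k` (causality).
#' @param scheme A [slot_scheme()].
#' @param ch A [channel_params()] object (with the compound's `D`).
#' @return Reception probability `q` in `[0, 1]`.
#' @export
slot_hit_prob <- function(k, lambda, scheme, ch) {
  check_scalar(k, "k", lower = 1)
  check_scalar(lambda, "lambda", lower = 1)
  if (lambda > k) stop_cfg("emission slot lambda = %g is after observation slot k = %g", lambda, k)
  if (!inherits(scheme, "slot_scheme")) stop_cfg("expected a `slot_scheme`")
  j <- k + 1 - lambda     # window index on the elapsed-time axis
  w <- slot_window(j, scheme, ch)
  q <- hit_probability(w[["hi"]], ch) - hit_probability(w[["lo"]], ch)
  max(q, 0)
}

#' Ambient-noise specification
#'
#' Ambient molecules of a compound contributed by neighboring plants,
#' modeled as Gaussian with mean `mu_n` and standard deviation `sigma_n`
#' (same units as the arrived quantities).
#'
#' @param mu_n Mean ambient quantity, >= 0.
#' @param sigma_n Standard deviation, >= 0.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(mu_n = 0, sigma_n = 0) {
  check_scalar(mu_n, "mu_n", lower = 0)
  check_scalar(sigma_n, "sigma_n", lower = 0)
  structure(list(mu_n = mu_n, sigma_n = sigma_n), class = "noise_spec")
}

#' Noise specification from a linear signal-to-noise ratio
#'
#' Maps a linear SNR (signal power over noise power) to a Gaussian noise
#' spec via `sigma_n = M q1 / sqrt(snr)` with `mu_n = sigma_n`, closing the
#' two-unknown noise model with a single parameter. `M q1` is the mean
#' current-slot signal quantity at the calibration mass `M`.
#'
#' @param snr Linear SNR, > 0 (may be `Inf` for the noiseless limit).
#' @param M Calibration emission quantity, >= 0.
#' @param q1 Current-slot reception probability, in `[0, 1]`.
#' @return A [noise_spec()].
#' @export
noise_from_snr <- function(snr, M, q1) {
  check_scalar(snr, "snr", lower = 0, allow_lower = FALSE, finite = FALSE)
  check_scalar(M, "M", lower = 0)
  check_scalar(q1, "q1", lower = 0, upper = 1)
  sigma_n <- if (is.infinite(snr)) 0 else M * q1 / sqrt(snr)
  noise_spec(mu_n = sigma_n, sigma_n = sigma_n)
}

#' Gaussian moments of the per-slot received and absorbed quantity
#'
#' Builds the signal + inter-symbol-interference + noise model for one
#' compound in observation slot `k`. The current-slot signal is binomial
#' `B(M, q1)`, each earlier slot contributes interference `p M q_{k+1-lambda}`
#' in mean and `p M q (1 - q)` in variance (transmit probability `p`), and
#' ambient noise adds `mu_n` and `sigma_n^2`:
#' \deqn{\mu_k = M q_1 + \sum_{\lambda=1}^{k-1} p M q_{k+1-\lambda} + \mu_n,}
#' \deqn{\sigma_k^2 = M q_1 (1 - q_1)
#'   + \sum_{\lambda=1}^{k-1} p M q_{k+1-\lambda}(1 - q_{k+1-\lambda})
#'   + \sigma_n^2.}
#' The absorbed moments apply the [absorption_scale()] factor linearly to
#' the mean and squared to the variance. For a compound that is *not*
#' transmitted in the current slot (`signal = FALSE`) the current-slot term
#' is dropped, giving the interferer estimate (interference + noise only).
#'
#' A warning is issued when `M * q1 < 100`, where the Gaussian approximation
#' of the binomial becomes questionable; the computation still proceeds.
#'
#' @param M Emitted quantity per transmission (binomial size; a molecule
#'   count, or a mass scaled by a molecules-per-mg constant).
#' @param mol A [molecule_spec()] (supplies `D` and `p`).
#' @param scheme A [slot_scheme()].
#' @param ch A [channel_params()] object carrying the geometry (`d`, `v`,
#'   `R`, `omega`); its `D` is replaced by the compound's.
#' @param lp A [leaf_params()] object.
#' @param noise A [noise_spec()].
#' @param k Observation slot index, >= 1.
#' @param signal Include the current-slot signal term? Set `FALSE` for the
#'   interferer estimate.
#' @return An object of class `"symbol_stats"`: a list with arrived moments
#'   `mu`, `sigma2`, absorbed moments `mu_abs`, `sigma2_abs`, the per-window
#'   probabilities `q`, the absorption `scale`, and the additive
#'   `components`.
#' @export
gaussian_symbol_model <- function(M, mol, scheme, ch, lp, noise = noise_spec(),
                                  k = 1L, signal = TRUE) {
  check_scalar(M, "M", lower = 0)
  if (!inherits(mol, "molecule_spec")) stop_cfg("expected a `molecule_spec`")
  if (!inherits(noise, "noise_spec")) stop_cfg("expected a `noise_spec`")
  check_scalar(k, "k", lower = 1)
  ch <- as_channel_params(ch)
  lp <- as_leaf_params(lp)
  ch_m <- channel_params(d = ch$d, v = ch$v, D = mol$D, R = ch$R,
                         omega = ch$omega)
  k <- as.integer(k)
  q <- vapply(seq_len(k), function(j) slot_hit_prob(j, 1L, scheme, ch_m),
              numeric(1))
  if (any(q < 0 | q > 1)) stop_cfg("per-slot probabilities outside [0, 1]")
  if (signal && M * q[1L] < 100) {
    warning(sprintf(paste0("M * q1 = %.3g < 100: the Gaussian approximation",
                           " of the binomial signal may be inaccurate"),
                    M * q[1L]), call. = FALSE)
  }
  sig_mu <- if (signal) M * q[1L] else 0
  sig_var <- if (signal) M * q[1L] * (1 - q[1L]) else 0
  isi_q <- if (k > 1L) q[2:k] else numeric()      # j = k + 1 - lambda
  isi_mu <- sum(mol$p * M * isi_q)
  isi_var <- sum(mol$p * M * isi_q * (1 - isi_q))
  mu <- sig_mu + isi_mu + noise$mu_n
  sigma2 <- sig_var + isi_var + noise$sigma_n^2
  scale <- absorption_scale(lp, ch$R)
  structure(list(mu = mu, sigma2 = sigma2,
                 mu_abs = mu * scale, sigma2_abs = sigma2 * scale^2,
                 q = q, scale = scale,
                 components = list(signal = c(mu = sig_mu, var = sig_var),
                                   isi = c(mu = isi_mu, var = isi_var),
                                   noise = c(mu = noise$mu_n,
                                             var = noise$sigma_n^2))),
            class = "symbol_stats")
}

# Right tail of the standard normal.
qfun <- function(x) stats::pnorm(x, lower.tail = FALSE)

#' Closed-form detection error rate
#'
#' Probability that the receiver fails to uniquely identify the transmitted
#' compound: one minus the probability that the transmitted compound's
#' absorbed quantity reaches its threshold times the probability that every
#' other compound stays below its own,
#' \deqn{P_{err} = 1 - Q\!\left(\frac{\theta_i - \mu_{abs}}{\sigma_{abs}}\right)
#'   \prod_{j \ne i} Q\!\left(\frac{\hat\mu_j - \theta_j}{\hat\sigma_j}\right),}
#' with `Q` the standard normal right tail. Zero variances are handled by
#' the degenerate (step-function) limit rather than division.
#'
#' @param theta Detection threshold of the transmitted compound.
#' @param stats A `"symbol_stats"` for the transmitted compound (with the
#'   current-slot signal included), or a list with `mu_abs`, `sigma2_abs`.
#' @param interferers List of non-transmitted compounds, each a list with
#'   `theta` and either a `"symbol_stats"` in `stats` or `mu_abs`,
#'   `sigma2_abs` directly.
#' @return An object of class `"der_result"`: `p_error` in `[0, 1]`, plus
#'   the miss-term and per-interferer false-alarm factors.
#' @export
der <- function(theta, stats, interferers = list()) {
  check_scalar(theta, "theta", lower = 0, allow_lower = FALSE)
  tail_ge <- function(theta, mu, sigma2) {
    if (sigma2 < 0) stop_cfg("negative variance")
    if (sigma2 == 0) as.numeric(mu >= theta) else qfun((theta - mu) / sqrt(sigma2))
  }
  p_detect <- tail_ge(theta, stats$mu_abs, stats$sigma2_abs)
  p_below <- vapply(interferers, function(it) {
    st <- if (!is.null(it$stats)) it$stats else it
    1 - tail_ge(it$theta, st$mu_abs, st$sigma2_abs)
  }, numeric(1))
  p_error <- 1 - p_detect * prod(p_below)
  structure(list(p_error = min(max(p_error, 0), 1),
                 p_detect = p_detect, p_below = p_below),
            class = "der_result")
}

#' @export
print.der_result <- function(x, ...) {
  cat(sprintf("<der_result> P(error) = %.6g  [P(detect) = %.4g, P(all interferers below) = %.4g]\n",
              x$p_error, x$p_detect, prod(x$p_below)))
  invisible(x)
}

#' Threshold demodulation of absorbed quantities
#'
#' Applies the single-compound-threshold, mutual-exclusion decision rule:
#' the stress label of compound `b_i` is returned iff exactly `b_i`'s
#' absorbed quantity meets or exceeds its threshold and every other
#' compound's stays strictly below. When no compound or more than one
#' compound reaches threshold the decision is `"ERROR"` — a valid output,
#' not an exception.
#'
#' @param absorbed Named numeric vector of absorbed quantities covering
#'   every compound of the alphabet.
#' @param alphabet A [stress_alphabet()].
#' @return A stress label, or `"ERROR"`.
#' @examples
#' ab <- default_alphabet(c(MeJA = 1, ethanol = 1))
#' demodulate(c(MeJA = 1.2, ethanol = 0.3), ab)   # "pest"
#' demodulate(c(MeJA = 1.2, ethanol = 1.0), ab)   # "ERROR"
#' @export
demodulate <- function(absorbed, alphabet) {
  if (!inherits(alphabet, "stress_alphabet")) {
    stop_cfg("expected a `stress_alphabet`")
  }
  missing <- setdiff(names(alphabet), names(absorbed))
  if (length(missing)) {
    stop_cfg("absorbed quantities missing for: %s",
             paste(missing, collapse = ", "))
  }
  check_numeric(unname(absorbed[names(alphabet)]), "absorbed", lower = 0)
  above <- vapply(names(alphabet), function(nm) {
    absorbed[[nm]] >= alphabet[[nm]]$threshold
  }, logical(1))
  if (sum(above) == 1L) alphabet[[which(above)]]$stress else "ERROR"
}

# Per-compound noise specs from a shared linear SNR: each compound's noise is
# calibrated against its own current-slot signal at the reference quantity.
noise_set_from_snr <- function(snr, M_ref, alphabet, scheme, ch) {
  lapply(alphabet, function(mol) {
    ch_m <- channel_params(d = ch$d, v = ch$v, D = mol$D, R = ch$R,
                           omega = ch$omega)
    noise_from_snr(snr, M_ref, slot_hit_prob(1L, 1L, scheme, ch_m))
  })
}

#' Detection error rate for one transmitted compound
#'
#' Convenience wrapper assembling the full closed-form DER: builds the
#' Gaussian symbol model for the transmitted compound (signal + ISI +
#' noise) and the interferer estimates for every other compound (ISI +
#' noise only), then applies [der()].
#'
#' Noise can be given directly (`noise`: one [noise_spec()] or a named list
#' per compound) or derived from a linear `snr` calibrated at `M_ref`
#' (default: the emitted quantity `M`). For emission-mass sweeps pass a
#' fixed `M_ref` so the ambient noise does not track the swept mass.
#'
#' @param transmitted Name of the transmitted compound.
#' @param alphabet A [stress_alphabet()].
#' @param M Emitted quantity per transmission (binomial size).
#' @param k Observation slot index.
#' @param scheme A [slot_scheme()].
#' @param ch A [channel_params()] (geometry; per-compound `D` is taken from
#'   the alphabet).
#' @param lp A [leaf_params()].
#' @param snr Linear SNR (used when `noise` is `NULL`).
#' @param noise Optional [noise_spec()] or named list of them per compound.
#' @param M_ref Noise-calibration quantity for the SNR mapping.
#' @param thresholds Optional named threshold vector overriding the
#'   alphabet's.
#' @return A `"der_result"` (see [der()]).
#' @export
symbol_der <- function(transmitted, alphabet, M, k = 1L, scheme, ch, lp,
                       snr = NULL, noise = NULL, M_ref = M,
                       thresholds = alphabet_thresholds(alphabet)) {
  if (!inherits(alphabet, "stress_alphabet")) {
    stop_cfg("expected a `stress_alphabet`")
  }
  if (!transmitted %in% names(alphabet)) {
    stop_cfg("`%s` is not in the alphabet", transmitted)
  }
  noise <- resolve_noise(noise, snr, M_ref, alphabet, scheme, ch)
  stats_tx <- gaussian_symbol_model(M, alphabet[[transmitted]], scheme, ch,
                                    lp, noise[[transmitted]], k = k,
                                    signal = TRUE)
  others <- setdiff(names(alphabet), transmitted)
  interferers <- lapply(others, function(nm) {
    list(theta = thresholds[[nm]],
         stats = gaussian_symbol_model(M, alphabet[[nm]], scheme, ch, lp,
                                       noise[[nm]], k = k, signal = FALSE))
  })
  der(thresholds[[transmitted]], stats_tx, interferers)
}

resolve_noise <- function(noise, snr, M_ref, alphabet, scheme, ch) {
  if (is.null(noise)) {
    if (is.null(snr)) stop_cfg("supply either `noise` or `snr`")
    return(noise_set_from_snr(snr, M_ref, alphabet, scheme, ch))
  }
  if (inherits(noise, "noise_spec")) {
    noise <- stats::setNames(rep(list(noise), length(alphabet)),
                             names(alphabet))
  }
  missing <- setdiff(names(alphabet), names(noise))
  if (length(missing)) stop_cfg("noise spec missing for: %s",
                                paste(missing, collapse = ", "))
  noise
}

#' Symbol-averaged detection error rate
#'
#' Mean of [symbol_der()] over all compounds of the alphabet transmitted
#' with equal prior probability. This is the quantity whose threshold
#' surface has an interior optimum: raising a compound's threshold hurts
#' its own detection but protects the slots in which it is an interferer.
#'
#' @inheritParams symbol_der
#' @return Mean error probability in `[0, 1]`.
#' @export
mean_der <- function(alphabet, M, k = 1L, scheme, ch, lp, snr = NULL,
                     noise = NULL, M_ref = M,
                     thresholds = alphabet_thresholds(alphabet)) {
  noise <- resolve_noise(noise, snr, M_ref, alphabet, scheme, ch)
  errs <- vapply(names(alphabet), function(nm) {
    symbol_der(nm, alphabet, M, k = k, scheme = scheme, ch = ch, lp = lp,
               noise = noise, thresholds = thresholds)$p_error
  }, numeric(1))
  mean(errs)
}
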