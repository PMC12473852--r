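#' Full model configuration
#'
#' Bundles every parameter block of the end-to-end chain: channel geometry,
#' leaf uptake, the modulation alphabet, the emitted mass, the slot scheme
#' and the noise level. This is the unit the sweep runner, the sequence
#' demo and the YAML reader operate on.
#'
#' Detection statistics use the emitted quantity as a binomial size, so
#' masses in mg are converted to molecule counts with `molecules_per_mg`
#' (default 1e6); thresholds stated in mg convert identically, leaving
#' every threshold comparison unchanged.
#'
#' @param channel A [channel_params()] object (geometry and the diffusion
#'   coefficient used for absorption studies).
#' @param leaf A [leaf_params()] object.
#' @param alphabet A [stress_alphabet()] for detection studies.
#' @param M_mg Emitted mass per transmission (mg).
#' @param molecules_per_mg Count-per-mg conversion constant.
#' @param T_s Symbol interval (s).
#' @param k Observation slot index for DER evaluation.
#' @param snr Linear SNR of the ambient noise model.
#' @param seed Integer seed for any stochastic component.
#' @return An object of class `"mc_config"`.
#' @export
mc_config <- function(channel, leaf, alphabet = default_alphabet(),
                      M_mg = 0.0016, molecules_per_mg = 1e6,
                      T_s = 2, k = 1L, snr = 10, seed = 1L) {
  ch <- as_channel_params(channel)
  lp <- as_leaf_params(leaf)
  if (!inherits(alphabet, "stress_alphabet")) {
    stop_cfg("expected a `stress_alphabet`")
  }
  check_scalar(M_mg, "M_mg", lower = 0)
  check_scalar(molecules_per_mg, "molecules_per_mg", lower = 0,
               allow_lower = FALSE)
  check_scalar(snr, "snr", lower = 0, allow_lower = FALSE, finite = FALSE)
  check_scalar(seed, "seed")
  structure(list(channel = ch, leaf = lp, alphabet = alphabet, M_mg = M_mg,
                 molecules_per_mg = molecules_per_mg,
                 scheme = slot_scheme(T_s, max(1L, as.integer(k))),
                 k = as.integer(k), snr = snr, seed = as.integer(seed)),
            class = "mc_config")
}

#' Reference configuration of the worked examples
#'
#' The parameter set used throughout the package's absorption and detection
#' examples: emitted mass 0.0016 mg; absorption channel d = 1 m, v = 3 m/s,
#' D = 0.008 m^2/s, R = 0.15 m, observation window 2 s; detection channel
#' v = 1 m/s with the two-compound alphabet (MeJA D = 0.007, ethanol
#' D = 0.009 m^2/s); leaf parameters at their defaults with phi = 0.5,
#' tau = 2 s and the `as_printed` conductance scale (the scale on which
#' detection thresholds of order 2e-4 mg are meaningful); symbol interval
#' 2 s; SNR 10.
#'
#' @param purpose `"absorption"` (single generic compound, v = 3 m/s) or
#'   `"detection"` (two-compound alphabet, v = 1 m/s).
#' @param ... Overrides passed on to [mc_config()].
#' @return An [mc_config()].
#' @export
reference_config <- function(purpose = c("absorption", "detection"), ...) {
  purpose <- match.arg(purpose)
  lp <- leaf_params(phi = 0.5, tau = 2, conductance_units = "as_printed")
  dots <- list(...)
  base <- if (purpose == "absorption") {
    list(channel = channel_params(d = 1, v = 3, D = 0.008, R = 0.15,
                                  omega = 2),
         leaf = lp,
         alphabet = stress_alphabet(
           molecule_spec("BVOC", D = 0.008, threshold = 1, stress = "stress")))
  } else {
    list(channel = channel_params(d = 1, v = 1, D = 0.008, R = 0.15,
                                  omega = 2),
         leaf = lp, alphabet = default_alphabet())
  }
  do.call(mc_config, utils::modifyList(base, dots))
}

count_of <- function(config, M_mg = config$M_mg) {
  M_mg * config$molecules_per_mg
}

#' Sweep specification
#'
#' Declares one parameter sweep through the channel-receiver-detection
#' chain. Absorption sweeps (`distance`, `time`) report the absorbed mass
#' `M_abs` (mg) of the configuration's first compound; detection sweeps
#' (`threshold_grid`, `snr`, `emission`) report the symbol-averaged
#' closed-form DER.
#'
#' @param kind One of `"distance"`, `"time"`, `"threshold_grid"`, `"snr"`,
#'   `"emission"`.
#' @param grid Non-empty sorted numeric grid of the swept variable
#'   (distances in m, windows in s, linear SNRs, emitted masses in mg, or
#'   thresholds in count units for `threshold_grid`, applied to both axes).
#' @param config An [mc_config()].
#' @param thresholds Optional named threshold vector (count units) for the
#'   detection sweeps; computed by [optimal_thresholds()] when missing.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(kind, grid, config = reference_config(), thresholds = NULL) {
  kind <- match.arg(kind, c("distance", "time", "threshold_grid", "snr",
                            "emission"))
  if (!inherits(config, "mc_config")) stop_cfg("expected an `mc_config`")
  check_numeric(grid, "grid", lower = 0)
  if (length(grid) < 1L) stop_cfg("`grid` must be non-empty")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_cfg("`grid` must be sorted strictly increasing")
  }
  if (kind %in% c("distance") && any(grid <= 0)) {
    stop_cfg("distances must be > 0")
  }
  structure(list(kind = kind, grid = grid, config = config,
                 thresholds = thresholds),
            class = "sweep_spec")
}

# Precomputed Gaussian moments per compound and role; thresholds enter the
# DER afterwards as cheap algebra, so threshold grids cost one pass.
detection_moments <- function(config, M_count, noise) {
  lapply(config$alphabet, function(mol) {
    list(tx = gaussian_symbol_model(M_count, mol, config$scheme,
                                    config$channel, config$leaf,
                                    noise[[mol$name]], k = config$k,
                                    signal = TRUE),
         interferer = gaussian_symbol_model(M_count, mol, config$scheme,
                                            config$channel, config$leaf,
                                            noise[[mol$name]], k = config$k,
                                            signal = FALSE))
  })
}

mean_der_from_moments <- function(moments, thresholds) {
  nms <- names(moments)
  errs <- vapply(nms, function(tx) {
    st <- moments[[tx]]$tx
    interf <- lapply(setdiff(nms, tx), function(j) {
      list(theta = thresholds[[j]], stats = moments[[j]]$interferer)
    })
    der(thresholds[[tx]], st, interf)$p_error
  }, numeric(1))
  mean(errs)
}

#' Interior-optimum detection thresholds
#'
#' Finds the threshold vector minimizing the symbol-averaged closed-form
#' DER by deterministic grid search with one local refinement pass. The
#' search range spans from just above zero to 30% beyond the largest
#' absorbed signal mean plus four standard deviations, which brackets the
#' interior optimum between the noise floor and the signal level.
#'
#' @param config An [mc_config()].
#' @param M_mg Emission mass (mg) at which the optimum is sought; defaults
#'   to the configuration's reference mass.
#' @param n_grid Points per axis of the coarse grid.
#' @return A list with `thresholds` (named vector, count units), `der`
#'   (the minimized mean DER), and `surface` (the coarse-grid data frame).
#' @export
optimal_thresholds <- function(config, M_mg = config$M_mg, n_grid = 41L) {
  if (!inherits(config, "mc_config")) stop_cfg("expected an `mc_config`")
  M_count <- count_of(config, M_mg)
  noise <- noise_set_from_snr(config$snr, M_count, config$alphabet,
                              config$scheme, config$channel)
  moments <- detection_moments(config, M_count, noise)
  upper <- 1.3 * max(vapply(moments, function(m) {
    m$tx$mu_abs + 4 * sqrt(m$tx$sigma2_abs)
  }, numeric(1)))
  nms <- names(moments)
  axis <- seq(upper / n_grid, upper, length.out = n_grid)

  search <- function(axes) {
    grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
    names(grid) <- nms
    grid$der <- vapply(seq_len(nrow(grid)), function(i) {
      mean_der_from_moments(moments, as.list(grid[i, nms, drop = FALSE]))
    }, numeric(1))
    grid
  }
  axes <- stats::setNames(rep(list(axis), length(nms)), nms)
  coarse <- search(axes)
  best <- coarse[which.min(coarse$der), ]
  h <- diff(axis)[1L]
  fine_axes <- lapply(nms, function(nm) {
    seq(max(best[[nm]] - h, upper / n_grid / 10), best[[nm]] + h,
        length.out = 21L)
  })
  names(fine_axes) <- nms
  fine <- search(fine_axes)
  best <- fine[which.min(fine$der), ]
  list(thresholds = stats::setNames(as.numeric(best[nms]), nms),
       der = best$der, surface = coarse)
}

#' Run a parameter sweep
#'
#' Executes the sweep declared by a [sweep_spec()] through the full
#' channel-to-detection chain and returns a tidy long-format data frame
#' with one metric per row. Deterministic given the spec. In emission
#' sweeps the SNR calibrates the ambient noise at each swept mass, so the
#' noise vanishes with the emission and the DER reaches 1 in the
#' zero-emission limit; the decreasing branch holds while the thresholds
#' stay above the noise floor (up to about the reference mass).
#'
#' @param spec A [sweep_spec()].
#' @return A data frame with columns `sweep_var`, `value`, `value2`
#'   (second threshold axis, `NA` elsewhere), `molecule`, `metric`,
#'   `metric_value`; the spec is attached as attribute `"config"` and the
#'   thresholds used (detection sweeps) as `"thresholds"`.
#' @examples
#' sp <- sweep_spec("distance", seq(0.2, 2, by = 0.3))
#' head(run_sweep(sp))
#' @export
run_sweep <- function(spec) {
  if (!inherits(spec, "sweep_spec")) stop_cfg("expected a `sweep_spec`")
  config <- spec$config
  out <- switch(spec$kind,
    distance = sweep_absorption(spec, vary = "d"),
    time = sweep_absorption(spec, vary = "omega"),
    snr = sweep_detection(spec, vary = "snr"),
    emission = sweep_detection(spec, vary = "M"),
    threshold_grid = sweep_threshold_grid(spec))
  attr(out, "config") <- config
  out
}

sweep_absorption <- function(spec, vary) {
  config <- spec$config
  mol <- config$alphabet[[1L]]
  ch0 <- config$channel
  rows <- lapply(spec$grid, function(x) {
    ch <- channel_params(d = if (vary == "d") x else ch0$d,
                         v = ch0$v, D = mol$D, R = ch0$R,
                         omega = if (vary == "omega") x else ch0$omega)
    Fh <- hit_probability(ch$omega, ch)
    data.frame(sweep_var = if (vary == "d") "d_m" else "omega_s",
               value = x, value2 = NA_real_, molecule = mol$name,
               metric = "M_abs_mg",
               metric_value = absorbed_mass(config$M_mg, Fh, config$leaf,
                                            ch$R))
  })
  do.call(rbind, rows)
}

sweep_detection <- function(spec, vary) {
  config <- spec$config
  M_ref <- count_of(config)
  thresholds <- spec$thresholds
  if (is.null(thresholds)) thresholds <- optimal_thresholds(config)$thresholds
  rows <- lapply(spec$grid, function(x) {
    # the SNR calibrates the ambient noise against the current operating
    # point: sigma_n tracks the swept mass in emission sweeps, so the DER
    # reaches 1 as the emission vanishes
    if (vary == "snr") {
      noise <- noise_set_from_snr(x, M_ref, config$alphabet, config$scheme,
                                  config$channel)
      M_count <- M_ref
    } else {
      M_count <- count_of(config, x)
      noise <- noise_set_from_snr(config$snr, M_count, config$alphabet,
                                  config$scheme, config$channel)
    }
    moments <- suppressWarnings(detection_moments(config, M_count, noise))
    data.frame(sweep_var = if (vary == "snr") "snr" else "M_mg",
               value = x, value2 = NA_real_, molecule = "(mean)",
               metric = "der",
               metric_value = mean_der_from_moments(moments, thresholds))
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- thresholds
  out
}

sweep_threshold_grid <- function(spec) {
  config <- spec$config
  if (length(config$alphabet) != 2L) {
    stop_cfg("threshold_grid sweeps require a two-compound alphabet")
  }
  M_count <- count_of(config)
  noise <- noise_set_from_snr(config$snr, M_count, config$alphabet,
                              config$scheme, config$channel)
  moments <- detection_moments(config, M_count, noise)
  nms <- names(config$alphabet)
  grid <- expand.grid(value = spec$grid, value2 = spec$grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid_der <- vapply(seq_len(nrow(grid)), function(i) {
    th <- stats::setNames(list(grid$value[i], grid$value2[i]), nms)
    mean_der_from_moments(moments, th)
  }, numeric(1))
  data.frame(sweep_var = paste0("theta_", nms[1L], ":theta_", nms[2L]),
             value = grid$value, value2 = grid$value2, molecule = "(mean)",
             metric = "der", metric_value = grid_der)
}

#' Maximum detection distance for a threshold
#'
#' Largest transmitter-receiver distance at which the absorbed mass still
#' meets the detection threshold, under the absorption chain of the given
#' configuration. The absorbed-mass curve is scanned on the search grid for
#' threshold crossings; the largest crossing is refined by bisection to
#' 1 mm. Returns `NA` (with a message) when no distance qualifies.
#'
#' @param theta Detection threshold on absorbed mass (mg), > 0.
#' @param config An [mc_config()]; its first compound's diffusion
#'   coefficient is used.
#' @param d_range Search interval (m).
#' @param n_scan Points of the coarse scan.
#' @return Maximum distance (m), or `NA_real_` when none qualifies. All
#'   crossings found on the scan are attached as attribute `"crossings"`.
#' @examples
#' \donttest{
#' detection_range(0.00021, reference_config("absorption"))
#' }
#' @export
detection_range <- function(theta, config = reference_config("absorption"),
                            d_range = c(0.01, 5), n_scan = 60L) {
  check_scalar(theta, "theta", lower = 0, allow_lower = FALSE)
  if (!inherits(config, "mc_config")) stop_cfg("expected an `mc_config`")
  mol <- config$alphabet[[1L]]
  ch0 <- config$channel
  mabs <- function(d) {
    ch <- channel_params(d = d, v = ch0$v, D = mol$D, R = ch0$R,
                         omega = ch0$omega)
    absorbed_mass(config$M_mg, hit_probability(ch$omega, ch), config$leaf,
                  ch$R)
  }
  ds <- seq(d_range[1L], d_range[2L], length.out = n_scan)
  vals <- vapply(ds, mabs, numeric(1))
  meets <- vals >= theta
  if (!any(meets)) {
    message("no distance in the search range meets the threshold")
    return(NA_real_)
  }
  if (all(meets)) return(ds[length(ds)])
  # brackets where the curve crosses the threshold
  cross <- which(diff(meets) != 0L)
  refined <- vapply(cross, function(i) {
    lo <- ds[i]; hi <- ds[i + 1L]
    while (hi - lo > 1e-3) {
      mid <- (lo + hi) / 2
      if (mabs(mid) >= theta) lo <- mid else hi <- mid
    }
    lo
  }, numeric(1))
  out <- max(refined)
  attr(out, "crossings") <- refined
  out
}

#' Demodulate a binary stress sequence through the full chain
#'
#' Worked two-compound example: each bit selects a compound (0 transmits
#' the first compound of the alphabet, 1 the second), one symbol per slot.
#' For every slot the expected absorbed quantity of *each* compound is
#' assembled from its current-slot signal (if transmitted), the
#' inter-symbol interference from the slots where it was actually
#' transmitted, and the ambient-noise mean, then thresholded with the
#' mutual-exclusion rule. With `stochastic = TRUE` the binomial and
#' Gaussian quantities are sampled instead of taking means.
#'
#' @param bits Character string over `{0, 1}`, e.g. `"001101"`.
#' @param config An [mc_config()] with a two-compound alphabet.
#' @param thresholds Optional named thresholds (count units); computed by
#'   [optimal_thresholds()] when missing.
#' @param stochastic Sample the per-slot quantities instead of using their
#'   means.
#' @param seed Seed used when `stochastic = TRUE`; defaults to the
#'   configuration's.
#' @return A list with `decoded` (string over `{0, 1, E}`), `sent`,
#'   `n_errors`, and `slots` (per-slot data frame of absorbed quantities
#'   and decisions).
#' @export
demod_sequence_demo <- function(bits, config = reference_config("detection"),
                                thresholds = NULL, stochastic = FALSE,
                                seed = config$seed) {
  if (!is.character(bits) || length(bits) != 1L ||
      !grepl("^[01]+$", bits)) {
    stop_cfg("`bits` must be a non-empty string over {0, 1}")
  }
  if (length(config$alphabet) != 2L) {
    stop_cfg("the sequence demo requires a two-compound alphabet")
  }
  bit_vec <- as.integer(strsplit(bits, "")[[1L]])
  n_slots <- length(bit_vec)
  nms <- names(config$alphabet)
  tx_name <- nms[bit_vec + 1L]
  M_count <- count_of(config)
  noise <- noise_set_from_snr(config$snr, M_count, config$alphabet,
                              config$scheme, config$channel)
  if (is.null(thresholds)) thresholds <- optimal_thresholds(config)$thresholds
  alphabet <- set_thresholds(config$alphabet, thresholds)
  if (stochastic) set.seed(as.integer(seed))

  # q[j, m]: reception probability in a window j - 1 slots after emission
  ch0 <- config$channel
  q <- vapply(alphabet, function(mol) {
    ch_m <- channel_params(d = ch0$d, v = ch0$v, D = mol$D, R = ch0$R,
                           omega = ch0$omega)
    vapply(seq_len(n_slots), function(j) {
      slot_hit_prob(j, 1L, config$scheme, ch_m)
    }, numeric(1))
  }, numeric(n_slots))
  q <- matrix(q, nrow = n_slots, dimnames = list(NULL, nms))
  scale <- absorption_scale(config$leaf, ch0$R)

  slots <- vector("list", n_slots)
  decoded <- character(n_slots)
  for (k in seq_len(n_slots)) {
    absorbed <- vapply(nms, function(m) {
      lambda <- seq_len(k)                      # emission slots 1..k
      contrib_q <- q[k + 1L - lambda, m]        # elapsed-window probability
      sent <- tx_name[lambda] == m
      arrived <- if (stochastic) {
        sum(stats::rbinom(sum(sent), round(M_count), contrib_q[sent]))
      } else {
        sum(M_count * contrib_q[sent])
      }
      ns <- noise[[m]]
      arrived <- arrived + if (stochastic) {
        stats::rnorm(1L, ns$mu_n, ns$sigma_n)
      } else {
        ns$mu_n
      }
      max(arrived, 0) * scale
    }, numeric(1))
    label <- demodulate(absorbed, alphabet)
    decoded[k] <- if (label == "ERROR") "E" else
      as.character(match(label, vapply(alphabet, `[[`, character(1),
                                       "stress")) - 1L)
    slots[[k]] <- data.frame(slot = k, sent_bit = bit_vec[k],
                             sent_compound = tx_name[k],
                             t(absorbed), decoded = decoded[k])
  }
  list(decoded = paste(decoded, collapse = ""), sent = bits,
       n_errors = sum(decoded != as.character(bit_vec)),
       slots = do.call(rbind, slots))
}
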