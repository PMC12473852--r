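#' Channel geometry and transport parameters
#'
#' Bundles the physical parameters of the air channel between a point-source
#' transmitter plant and a receiver plant modeled as a perfectly absorbing
#' sphere: the point-to-surface distance `d`, downwind speed `v`, molecular
#' diffusion coefficient `D`, sphere radius `R`, and the observation window
#' `omega` over which arrivals are counted.
#'
#' `d` is the distance from the source point to the sphere surface, so the
#' no-drift total hit probability is `R / (R + d)`. Upwind receivers
#' (`v < 0`) are rejected: the transport model only treats downwind drift.
#'
#' @param d Transmitter-to-receiver surface distance (m), > 0.
#' @param v Wind speed along the transmitter-receiver axis (m/s), >= 0.
#' @param D Diffusion coefficient of the signaling compound (m^2/s), > 0.
#' @param R Radius of the absorbing receiver sphere (m), > 0.
#' @param omega Observation window (s), >= 0; may be `Inf`.
#' @return An object of class `"channel_params"` (a named list).
#' @examples
#' ch <- channel_params(d = 1, v = 3, D = 0.008, R = 0.15, omega = 2)
#' peak_time(ch)
#' @export
channel_params <- function(d, v, D, R, omega = 2) {
  check_scalar(d, "d", lower = 0, allow_lower = FALSE)
  check_scalar(v, "v", lower = 0)
  check_scalar(D, "D", lower = 0, allow_lower = FALSE)
  check_scalar(R, "R", lower = 0, allow_lower = FALSE)
  check_scalar(omega, "omega", lower = 0, finite = FALSE)
  structure(list(d = d, v = v, D = D, R = R, omega = omega),
            class = "channel_params")
}

#' @export
print.channel_params <- function(x, ...) {
  cat("<channel_params>\n")
  cat(sprintf("  d = %g m, v = %g m/s, D = %g m^2/s, R = %g m, omega = %g s\n",
              x$d, x$v, x$D, x$R, x$omega))
  cat(sprintf("  t_peak = %.6g s, F_hit(omega) = %.6g, F_hit(Inf) = %.6g\n",
              peak_time(x),
              if (is.finite(x$omega)) hit_probability(x$omega, x) else
                x$R / (x$R + x$d),
              x$R / (x$R + x$d)))
  invisible(x)
}

as_channel_params <- function(ch) {
  if (!inherits(ch, "channel_params")) {
    stop_cfg("expected a `channel_params` object")
  }
  ch
}

#' First-hitting-time density at the absorbing receiver
#'
#' Probability density (1/s) that a molecule released at the source at time 0
#' is absorbed by the receiver sphere at time `t`:
#' \deqn{f(t) = \frac{R d}{R + d} \frac{1}{\sqrt{4 \pi D t^3}}
#'       \exp\!\left(-\frac{(d - v t)^2}{4 D t}\right).}
#' The removable singularity at `t = 0` is handled by the limit convention
#' `f(0) = 0`.
#'
#' @param t Time since release (s), vectorized, >= 0.
#' @param ch A [channel_params()] object.
#' @return Density values, same length as `t`.
#' @export
hit_density <- function(t, ch) {
  ch <- as_channel_params(ch)
  check_numeric(t, "t", lower = 0)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- (ch$R * ch$d / (ch$R + ch$d)) / sqrt(4 * pi * ch$D * tp^3) *
    exp(-(ch$d - ch$v * tp)^2 / (4 * ch$D * tp))
  out
}

#' Peak time of the hit density
#'
#' Closed-form root of d f/d t = 0, evaluated in the cancellation-free form
#' `2 d^2 / (6 D + sqrt(36 D^2 + 4 v^2 d^2))`, which reduces analytically to
#' `d^2 / (6 D)` in the pure-diffusion limit `v = 0`.
#'
#' @inheritParams hit_density
#' @return Peak time (s).
#' @export
peak_time <- function(ch) {
  ch <- as_channel_params(ch)
  2 * ch$d^2 / (6 * ch$D + sqrt(36 * ch$D^2 + 4 * ch$v^2 * ch$d^2))
}

#' Cumulative hit probability within an observation window
#'
#' Adaptive quadrature of [hit_density()] over `(0, omega]`. The integral is
#' split at knots spread geometrically around the density peak so that the
#' narrow arrival pulse is never missed inside a long window; each piece is
#' integrated with `stats::integrate`. The total over an infinite window is
#' `R / (R + d)` for every `v >= 0`.
#'
#' @param omega Observation window (s), >= 0; may be `Inf`.
#' @param ch A [channel_params()] object.
#' @param rel.tol Relative tolerance passed to the quadrature.
#' @return Hit probability in `[0, R/(R+d)]` (up to quadrature tolerance).
#' @export
hit_probability <- function(omega, ch, rel.tol = 1e-10) {
  ch <- as_channel_params(ch)
  check_scalar(omega, "omega", lower = 0, finite = FALSE)
  if (omega == 0) return(0)
  tp <- peak_time(ch)
  tail <- 0
  if (is.infinite(omega)) {
    # the far tail decays like t^(-3/2); substituting u = 1/sqrt(t) maps it
    # to a bounded integrand on a finite interval
    omega <- 1e4 * tp
    amp <- 2 * (ch$R * ch$d / (ch$R + ch$d)) / sqrt(4 * pi * ch$D)
    g <- function(u) {
      amp * exp(-(ch$d - ch$v / u^2)^2 * u^2 / (4 * ch$D))
    }
    tail <- stats::integrate(g, 0, 1 / sqrt(omega), rel.tol = rel.tol,
                             abs.tol = 1e-13)$value
  }
  knots <- tp * c(1e-3, 0.1, 0.5, 1, 2, 10, 100, 1e4)
  knots <- unique(c(0, knots[knots < omega], omega))
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    piece <- stats::integrate(hit_density, knots[i], knots[i + 1L], ch = ch,
                              rel.tol = rel.tol, abs.tol = 1e-13,
                              subdivisions = 400L)
    if (piece$message != "OK") {
      stop_cfg("hit-probability quadrature did not converge on [%g, %g]: %s",
               knots[i], knots[i + 1L], piece$message)
    }
    total <- total + piece$value
  }
  total + tail
}

#' Tabulated hit density and cumulative hit probability
#'
#' Evaluates the hit density and its running integral on a time grid,
#' returning a data frame suitable for plotting or CSV export.
#'
#' @param ch A [channel_params()] object.
#' @param t_grid Strictly increasing times (s) starting at 0; default is a
#'   400-point grid covering `[0, omega]` (or 10 peak times if `omega` is
#'   infinite).
#' @return A data frame with columns `t_s`, `f_per_s`, `F_hit`.
#' @export
hit_curve <- function(ch, t_grid = NULL) {
  ch <- as_channel_params(ch)
  if (is.null(t_grid)) {
    horizon <- if (is.finite(ch$omega) && ch$omega > 0) ch$omega else
      10 * peak_time(ch)
    t_grid <- seq(0, horizon, length.out = 400L)
  }
  check_time_grid(t_grid)
  f <- hit_density(t_grid, ch)
  Fh <- vapply(t_grid, hit_probability, numeric(1), ch = ch, rel.tol = 1e-8)
  data.frame(t_s = t_grid, f_per_s = f, F_hit = Fh)
}

#' Compound concentration at the receiver leaf surface
#'
#' Converts the mass arrived within the observation window into a
#' leaf-surface air concentration,
#' `C_leaf = 3 M F_hit / (4 pi R^3 phi)` (mg/m^3), where `phi` is the ratio
#' of actual leaf volume to the modeled absorption-sphere volume.
#'
#' @param M Emitted mass (mg), >= 0.
#' @param ch A [channel_params()] object.
#' @param phi Leaf-to-sphere volume ratio, in `(0, 1]`.
#' @param F_hit Optional precomputed hit probability; defaults to
#'   `hit_probability(ch$omega, ch)`.
#' @return Concentration (mg/m^3).
#' @export
leaf_concentration <- function(M, ch, phi, F_hit = NULL) {
  ch <- as_channel_params(ch)
  check_scalar(M, "M", lower = 0)
  check_scalar(phi, "phi", lower = 0, upper = 1, allow_lower = FALSE)
  if (is.null(F_hit)) F_hit <- hit_probability(ch$omega, ch)
  check_scalar(F_hit, "F_hit", lower = 0, upper = 1)
  3 * M * F_hit / (4 * pi * ch$R^3 * phi)
}
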