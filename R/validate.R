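# Internal argument checks shared across modules.

stop_cfg <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_cfg("`%s` must be a single non-missing number", name)
  }
  if (finite && !is.finite(x)) stop_cfg("`%s` must be finite", name)
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop_cfg("`%s` = %g is outside the admissible range %s%g, %g%s", name, x,
             if (allow_lower) "[" else "(", lower, upper,
             if (allow_upper) "]" else ")")
  }
  invisible(x)
}

check_numeric <- function(x, name, lower = -Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop_cfg("`%s` must be a non-empty numeric vector without NA", name)
  }
  if (finite && any(!is.finite(x))) stop_cfg("`%s` must be finite", name)
  if (any(x < lower)) stop_cfg("`%s` must be >= %g", name, lower)
  invisible(x)
}

check_time_grid <- function(t, name = "t_grid", from_zero = TRUE) {
  check_numeric(t, name)
  if (length(t) < 2L || any(diff(t) <= 0)) {
    stop_cfg("`%s` must be strictly increasing with at least 2 points", name)
  }
  if (from_zero && t[1L] != 0) stop_cfg("`%s` must start at 0", name)
  invisible(t)
}
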