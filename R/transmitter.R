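#' Gene node of the synthesis-regulation network
#'
#' One gene in the additive-regulation model of stress-induced compound
#' synthesis. The synthesis rate of the compound controlled by gene `x` is
#' \deqn{\xi(t) = \frac{dG_x}{dt} =
#'   \frac{\eta_{x1}}{1 + \exp(-a_{x0} - \sum_y a_{xy} G_y)} - \eta_{x2} G_x,}
#' a sigmoid of the weighted regulator inputs minus first-order decay.
#' Autoregulation is excluded: `weights` may not contain the node's own id.
#'
#' @param id Node identifier (character scalar).
#' @param a0 Basal activation offset (dimensionless).
#' @param eta1 Maximum expression rate (mg/s), >= 0.
#' @param eta2 First-order decay rate (1/s), > 0.
#' @param weights Named numeric vector of regulator weights `a_xy`
#'   (names are regulator ids); may be empty.
#' @param G0 Initial expression level, >= 0.
#' @return An object of class `"gene_node"`.
#' @examples
#' n <- gene_node("mja", a0 = 0, eta1 = 1, eta2 = 0.1)
#' gene_expression_rate(n)   # sigmoid(0) * 1 - 0.1 * 0 = 0.5
#' @export
gene_node <- function(id, a0 = 0, eta1 = 1, eta2 = 0.1,
                      weights = numeric(), G0 = 0) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop_cfg("`id` must be a non-empty string")
  }
  check_scalar(a0, "a0")
  check_scalar(eta1, "eta1", lower = 0)
  check_scalar(eta2, "eta2", lower = 0, allow_lower = FALSE)
  check_scalar(G0, "G0", lower = 0)
  if (length(weights)) {
    check_numeric(weights, "weights")
    if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
      stop_cfg("`weights` must be a fully named vector of regulator ids")
    }
    if (id %in% names(weights)) {
      stop_cfg("node `%s` may not regulate itself (no autoregulation)", id)
    }
  }
  structure(list(id = id, a0 = a0, eta1 = eta1, eta2 = eta2,
                 weights = weights, G0 = G0),
            class = "gene_node")
}

#' Instantaneous synthesis rate of one gene node
#'
#' Evaluates the sigmoid-regulation rate at the node's current expression
#' level `G` and the supplied regulator levels. Every regulator named in the
#' node's weights must be present in `regulator_levels`.
#'
#' @param node A [gene_node()] object.
#' @param regulator_levels Named numeric vector of regulator expression
#'   levels; may be empty when the node has no regulators.
#' @param G Expression level of the node itself; defaults to `node$G0`.
#' @return Synthesis rate (mg/s).
#' @export
gene_expression_rate <- function(node, regulator_levels = numeric(),
                                 G = node$G0) {
  if (!inherits(node, "gene_node")) stop_cfg("expected a `gene_node` object")
  check_scalar(G, "G", lower = 0)
  drive <- node$a0
  if (length(node$weights)) {
    missing <- setdiff(names(node$weights), names(regulator_levels))
    if (length(missing)) {
      stop_cfg("missing regulator level(s): %s",
               paste(missing, collapse = ", "))
    }
    lv <- regulator_levels[names(node$weights)]
    if (anyNA(lv) || any(!is.finite(lv))) {
      stop_cfg("regulator levels must be finite and non-missing")
    }
    drive <- drive + sum(node$weights * lv)
  }
  node$eta1 * stats::plogis(drive) - node$eta2 * G
}

#' Synthesis-rate time series for a gene network
#'
#' Integrates the coupled sigmoid-regulation ODEs for a list of gene nodes
#' with a classical fixed-step fourth-order Runge-Kutta scheme (internal step
#' at most `0.1 / max(eta2)` and never larger than the output grid spacing)
#' and returns the expression levels and synthesis rates sampled on the
#' output grid. Deterministic given its inputs.
#'
#' @param network A list of [gene_node()] objects with unique ids; every
#'   regulator id referenced by a weight must name a node in the network.
#' @param t_grid Strictly increasing output times (s) starting at 0.
#' @param initial_levels Optional named vector overriding the nodes' `G0`.
#' @return A list with `time` (the grid), `levels` and `xi`
#'   (time-by-node matrices of expression levels and synthesis rates, mg/s).
#' @examples
#' net <- list(gene_node("a", eta1 = 1, eta2 = 0.1))
#' ts <- synthesis_timeseries(net, seq(0, 10, by = 0.5))
#' tail(ts$xi)
#' @export
synthesis_timeseries <- function(network, t_grid, initial_levels = NULL) {
  if (!is.list(network) || !length(network) ||
      !all(vapply(network, inherits, logical(1), "gene_node"))) {
    stop_cfg("`network` must be a non-empty list of gene_node objects")
  }
  ids <- vapply(network, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_cfg("node ids must be unique")
  check_time_grid(t_grid)
  refs <- unique(unlist(lapply(network, function(n) names(n$weights))))
  unknown <- setdiff(refs, ids)
  if (length(unknown)) {
    stop_cfg("regulator id(s) not in the network: %s",
             paste(unknown, collapse = ", "))
  }

  G <- vapply(network, `[[`, numeric(1), "G0")
  names(G) <- ids
  if (!is.null(initial_levels)) {
    bad <- setdiff(names(initial_levels), ids)
    if (length(bad)) stop_cfg("unknown initial level id(s): %s",
                              paste(bad, collapse = ", "))
    G[names(initial_levels)] <- initial_levels
  }

  deriv <- function(G) {
    vapply(network, function(n) gene_expression_rate(n, G, G = G[[n$id]]),
           numeric(1))
  }
  max_eta2 <- max(vapply(network, `[[`, numeric(1), "eta2"))
  h_max <- min(0.1 / max_eta2, min(diff(t_grid)))

  nt <- length(t_grid)
  levels <- matrix(NA_real_, nt, length(ids), dimnames = list(NULL, ids))
  xi <- levels
  levels[1L, ] <- G
  xi[1L, ] <- deriv(G)
  for (i in seq_len(nt - 1L)) {
    span <- t_grid[i + 1L] - t_grid[i]
    nsub <- max(1L, ceiling(span / h_max))
    h <- span / nsub
    for (s in seq_len(nsub)) {
      k1 <- deriv(G)
      k2 <- deriv(G + h / 2 * k1)
      k3 <- deriv(G + h / 2 * k2)
      k4 <- deriv(G + h * k3)
      G <- G + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (anyNA(G) || any(!is.finite(G))) {
        stop_cfg("gene ODE integration diverged near t = %g", t_grid[i])
      }
      G <- pmax(G, 0)
    }
    levels[i + 1L, ] <- G
    xi[i + 1L, ] <- deriv(G)
  }
  list(time = t_grid, levels = levels, xi = xi)
}

#' Storage-pool kinetic parameters
#'
#' Rates of the three-compartment storage model: synthesized compound
#' partitions into an aqueous pool (fraction `eta`) and a lipid pool
#' (fraction `1 - eta`); both feed the intercellular gas pool, which is
#' vented to the atmosphere through stomata at rate `u_g`.
#'
#' @param eta Aqueous/lipid partition coefficient, in `[0, 1]`.
#' @param u_a,u_l,u_g Release rates (1/s) of the aqueous, lipid and gas
#'   pools, all > 0.
#' @return An object of class `"pool_params"`.
#' @export
pool_params <- function(eta = 0.5, u_a = 0.1, u_l = 0.1, u_g = 0.05) {
  check_scalar(eta, "eta", lower = 0, upper = 1)
  check_scalar(u_a, "u_a", lower = 0, allow_lower = FALSE)
  check_scalar(u_l, "u_l", lower = 0, allow_lower = FALSE)
  check_scalar(u_g, "u_g", lower = 0, allow_lower = FALSE)
  structure(list(eta = eta, u_a = u_a, u_l = u_l, u_g = u_g),
            class = "pool_params")
}

#' Storage-pool state
#'
#' Pool contents (mg) at time `t`, plus the cumulative emitted and produced
#' masses used for the conservation audit:
#' `produced + initial pools = current pools + emitted` at all times.
#'
#' @param Q_a,Q_l,Q_g Aqueous, lipid, gas pool contents (mg), >= 0.
#' @param t Time (s).
#' @param emitted Cumulative mass vented to the atmosphere (mg).
#' @param produced Cumulative synthesized mass (mg).
#' @return An object of class `"pool_state"`.
#' @export
pool_state <- function(Q_a = 0, Q_l = 0, Q_g = 0, t = 0,
                       emitted = 0, produced = 0) {
  for (nm in c("Q_a", "Q_l", "Q_g", "emitted", "produced")) {
    check_scalar(get(nm), nm, lower = 0)
  }
  check_scalar(t, "t", lower = 0)
  structure(list(Q_a = Q_a, Q_l = Q_l, Q_g = Q_g, t = t,
                 emitted = emitted, produced = produced),
            class = "pool_state")
}

# The pool ODEs are linear with constant coefficients; for a synthesis rate
# held constant over a step they are advanced exactly by the exponential of
# the augmented system (Q_a, Q_l, Q_g, emitted, produced, xi) with xi' = 0.
pool_propagator <- function(params, dt) {
  key <- paste(params$eta, params$u_a, params$u_l, params$u_g, dt, sep = "|")
  cached <- .pool_cache[[key]]
  if (!is.null(cached)) return(cached)
  A <- matrix(0, 6, 6)
  A[1, 1] <- -params$u_a; A[1, 6] <- params$eta
  A[2, 2] <- -params$u_l; A[2, 6] <- 1 - params$eta
  A[3, 1] <- params$u_a;  A[3, 2] <- params$u_l; A[3, 3] <- -params$u_g
  A[4, 3] <- params$u_g
  A[5, 6] <- 1
  Phi <- as.matrix(Matrix::expm(A * dt))
  if (length(.pool_cache) > 64L) rm(list = ls(.pool_cache), envir = .pool_cache)
  .pool_cache[[key]] <- Phi
  Phi
}
.pool_cache <- new.env(parent = emptyenv())

#' Advance the storage pools one step
#'
#' Advances the three-pool linear ODE system by `dt` under a synthesis rate
#' `xi` held constant over the step, using the exact matrix-exponential
#' propagator (no truncation error, so mass balance holds to rounding).
#'
#' @param state A [pool_state()] object.
#' @param xi Synthesis rate over the step (mg/s), >= 0.
#' @param params A [pool_params()] object.
#' @param dt Step length (s), > 0.
#' @return The advanced [pool_state()].
#' @export
update_pools <- function(state, xi, params, dt) {
  if (!inherits(state, "pool_state")) stop_cfg("expected a `pool_state`")
  if (!inherits(params, "pool_params")) stop_cfg("expected `pool_params`")
  check_scalar(xi, "xi", lower = 0)
  check_scalar(dt, "dt", lower = 0, allow_lower = FALSE)
  Phi <- pool_propagator(params, dt)
  x <- c(state$Q_a, state$Q_l, state$Q_g, state$emitted, state$produced, xi)
  y <- drop(Phi %*% x)
  if (any(y[1:3] < -1e-12)) {
    stop_cfg("negative pool content after step (dt = %g); reduce the step", dt)
  }
  pool_state(Q_a = max(y[1], 0), Q_l = max(y[2], 0), Q_g = max(y[3], 0),
             t = state$t + dt, emitted = y[4], produced = y[5])
}

#' Storage-pool trajectory on a time grid
#'
#' Steps the pools across `t_grid` with the synthesis rate treated as
#' piecewise constant over each interval (the left-endpoint value of `xi`),
#' each step taken exactly. The returned `residual` column is the
#' conservation error `produced + initial pools - (pools + emitted)`.
#'
#' @param xi Either a numeric vector of synthesis rates on `t_grid` (mg/s)
#'   or a function of time returning the rate.
#' @param t_grid Strictly increasing times (s) starting at 0.
#' @param params A [pool_params()] object.
#' @param state0 Initial [pool_state()].
#' @return A data frame with columns `t_s`, `Q_a`, `Q_l`, `Q_g`,
#'   `J_mg_per_s`, `emitted`, `produced`, `residual`.
#' @export
pool_trajectory <- function(xi, t_grid, params = pool_params(),
                            state0 = pool_state()) {
  check_time_grid(t_grid)
  if (is.function(xi)) xi <- xi(t_grid)
  check_numeric(xi, "xi", lower = 0)
  if (length(xi) != length(t_grid)) {
    stop_cfg("`xi` must have one value per grid point")
  }
  n <- length(t_grid)
  out <- data.frame(t_s = t_grid, Q_a = NA_real_, Q_l = NA_real_,
                    Q_g = NA_real_, J_mg_per_s = NA_real_,
                    emitted = NA_real_, produced = NA_real_,
                    residual = NA_real_)
  init_mass <- state0$Q_a + state0$Q_l + state0$Q_g
  st <- state0
  fill <- function(i, st) {
    out$Q_a[i] <<- st$Q_a; out$Q_l[i] <<- st$Q_l; out$Q_g[i] <<- st$Q_g
    out$J_mg_per_s[i] <<- emission_rate(st, params)
    out$emitted[i] <<- st$emitted; out$produced[i] <<- st$produced
    out$residual[i] <<- st$produced + init_mass -
      (st$Q_a + st$Q_l + st$Q_g + st$emitted)
  }
  fill(1L, st)
  for (i in seq_len(n - 1L)) {
    st <- update_pools(st, xi[i], params, t_grid[i + 1L] - t_grid[i])
    fill(i + 1L, st)
  }
  out
}

#' Atmospheric release rate
#'
#' `J = u_g Q_g` (mg/s), the stomatal venting rate of the gas pool.
#'
#' @param state A [pool_state()] object.
#' @param params A [pool_params()] object.
#' @return Release rate (mg/s).
#' @export
emission_rate <- function(state, params) {
  if (!inherits(state, "pool_state")) stop_cfg("expected a `pool_state`")
  if (!inherits(params, "pool_params")) stop_cfg("expected `pool_params`")
  params$u_g * state$Q_g
}

#' Emission profile of the transmitter
#'
#' Either an impulse (`mode = "impulse"`): all mass `M` released at `t = 0`,
#' matching the channel model's initial condition and the default for every
#' detection computation; or a tabulated release-rate profile
#' (`mode = "profile"`): `J` (mg/s) on a time grid, interpolated linearly.
#'
#' @param M Impulse mass (mg), used when `mode = "impulse"`.
#' @param time_grid,J Release-rate tabulation, used when `mode = "profile"`.
#' @param mode `"impulse"` or `"profile"`.
#' @return An object of class `"emission_profile"`.
#' @export
emission_profile <- function(M = NULL, time_grid = NULL, J = NULL,
                             mode = c("impulse", "profile")) {
  mode <- match.arg(mode)
  if (mode == "impulse") {
    check_scalar(M, "M", lower = 0)
    return(structure(list(mode = "impulse", M = M), class = "emission_profile"))
  }
  check_time_grid(time_grid)
  check_numeric(J, "J", lower = 0)
  if (length(J) != length(time_grid)) {
    stop_cfg("`J` must have one value per grid point")
  }
  structure(list(mode = "profile", time_grid = time_grid, J = J),
            class = "emission_profile")
}

#' Expected cumulative mass arrived at the receiver
#'
#' Convolves the release-rate profile with the channel hit response:
#' `M(t) = integral_0^t J(delta) F_hit(t - delta) d delta`, the expected
#' cumulative mass absorbed by the receiver sphere up to `t`. In impulse
#' mode this reduces exactly to `M * F_hit(t)`.
#'
#' @param profile An [emission_profile()] object.
#' @param ch A [channel_params()] object.
#' @param t Evaluation time (s), >= 0; for profile mode must not exceed the
#'   profile's time grid.
#' @return Arrived mass (mg).
#' @export
arrived_mass_profile <- function(profile, ch, t) {
  if (!inherits(profile, "emission_profile")) {
    stop_cfg("expected an `emission_profile` object")
  }
  ch <- as_channel_params(ch)
  check_scalar(t, "t", lower = 0)
  if (profile$mode == "impulse") {
    return(profile$M * hit_probability(t, ch))
  }
  if (t > max(profile$time_grid)) {
    stop_cfg("profile time grid ends at %g s, before t = %g s",
             max(profile$time_grid), t)
  }
  if (t == 0) return(0)
  Jfun <- stats::approxfun(profile$time_grid, profile$J, rule = 2)
  integrand <- function(delta) {
    Jfun(delta) *
      vapply(t - delta, hit_probability, numeric(1), ch = ch, rel.tol = 1e-8)
  }
  knots <- sort(unique(c(0, profile$time_grid[profile$time_grid < t], t)))
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    total <- total + stats::integrate(integrand, knots[i], knots[i + 1L],
                                      rel.tol = 1e-8, abs.tol = 1e-13)$value
  }
  total
}

#' Export an emission profile as a two-column data frame
#'
#' @param profile An [emission_profile()] object (profile mode).
#' @return A data frame with columns `t_s`, `J_mg_per_s`.
#' @export
emission_profile_table <- function(profile) {
  if (!inherits(profile, "emission_profile") || profile$mode != "profile") {
    stop_cfg("expected a profile-mode `emission_profile`")
  }
  data.frame(t_s = profile$time_grid, J_mg_per_s = profile$J)
}
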