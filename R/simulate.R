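#' Default simulation output grid
#'
#' Log-spaced points over the first two days (the distribution phase of an IV
#' bolus) followed by half-daily points to the horizon.
#'
#' @param horizon End of the grid (days).
#' @return Strictly increasing numeric vector starting at 0.
#' @export
default_time_grid <- function(horizon = 120) {
  stopifnot(horizon > 2)
  early <- exp(seq(log(0.005), log(2), length.out = 48))
  sort(unique(c(0, early, seq(2.5, horizon, by = 0.5), horizon)))
}

# Shared post-solve checks and clipping: states below -100*atol raise, small
# negative undershoot is clipped to zero in the outputs only.
clip_states <- function(m, cols, atol) {
  for (cl in cols) {
    v <- m[, cl]
    if (any(v < -100 * atol, na.rm = TRUE)) {
      stop("solver produced negative ", cl, " beyond tolerance (min ",
           format(min(v)), "); check parameters", call. = FALSE)
    }
    m[, cl] <- pmax(v, 0)
  }
  m
}

finish_sim <- function(out, params, regimen, model, atol, diagnostics) {
  res <- tibble::as_tibble(as.data.frame(out))
  attr(res, "params") <- params
  attr(res, "regimen") <- regimen
  attr(res, "model") <- model
  attr(res, "diagnostics") <- diagnostics
  class(res) <- c("tmdd_sim", class(res))
  res
}

#' Simulate the full TMDD model for a single IV bolus
#'
#' Integrates the four-state TMDD system with a stiff solver
#' (`deSolve::lsoda`, atol 1e-10, rtol 1e-8) from the initial condition
#' `a1(0) = molar dose`, `a2(0) = 0`, `r(0) = R0`, `dr(0) = 0`. The horizon
#' is extended (doubling, up to `max_horizon`) until the free-drug
#' concentration has decayed to below `1e-5 * Cmax`, so that downstream AUC
#' extrapolation stays small.
#'
#' @param params A [tmdd_params()] object.
#' @param regimen A [build_regimen()] row.
#' @param horizon Initial simulation horizon (days).
#' @param grid Output time grid; defaults to [default_time_grid()] over the
#'   (possibly extended) horizon.
#' @param r0 Initial free-target concentration; defaults to
#'   [steady_state_target()].
#' @param atol,rtol Solver absolute/relative tolerances.
#' @param max_horizon Cap on horizon auto-extension (days).
#' @return A `tmdd_sim` tibble with columns `time`, `conc` (free drug,
#'   nmol/l), `a1`, `a2` (amounts, nmol), `r`, `dr`, `occupancy`, `c_tot`,
#'   `r_tot`, and attributes `params`, `regimen`, `model`, `diagnostics`.
#' @export
simulate_tmdd <- function(params, regimen, horizon = 120, grid = NULL,
                          r0 = NULL, atol = 1e-10, rtol = 1e-8,
                          max_horizon = 1920) {
  stopifnot(inherits(params, "tmdd_params"))
  if (is.null(r0)) r0 <- steady_state_target(params)
  dose <- regimen$molar_dose
  y0 <- c(a1 = dose, a2 = 0, r = r0, dr = 0)

  repeat {
    times <- if (is.null(grid)) default_time_grid(horizon) else grid
    out <- deSolve::lsoda(y0, times, tmdd_rhs_desolve, params,
                          atol = atol, rtol = rtol, maxsteps = 50000)
    d <- attr(out, "istate")
    if (is.null(d) || d[1] < 0) {
      stop("lsoda failed to converge (istate ", d[1], ") after ",
           d[3], " steps", call. = FALSE)
    }
    cmax <- max(out[, "a1"]) / params$v1
    clast <- out[nrow(out), "a1"] / params$v1
    if (!is.null(grid) || dose == 0 || clast <= 1e-5 * cmax ||
        horizon >= max_horizon) {
      break
    }
    horizon <- min(2 * horizon, max_horizon)
  }

  m <- clip_states(unclass(out), c("a1", "a2", "r", "dr"), atol)
  conc <- m[, "a1"] / params$v1
  res <- data.frame(
    time = m[, "time"], conc = conc, a1 = m[, "a1"], a2 = m[, "a2"],
    r = m[, "r"], dr = m[, "dr"],
    occupancy = occupancy(m[, "r"], m[, "dr"]),
    c_tot = conc + m[, "dr"], r_tot = m[, "r"] + m[, "dr"]
  )
  finish_sim(res, params, regimen, "tmdd", atol,
             list(steps = unname(attr(out, "istate")[3]), horizon = horizon))
}

#' Simulate the Michaelis-Menten approximation
#'
#' Drug-only counterpart of [simulate_tmdd()]; the output carries the same
#' drug columns with target columns absent.
#'
#' @inheritParams simulate_tmdd
#' @param params An [mm_params()] object.
#' @return A `tmdd_sim` tibble with columns `time`, `conc`, `a1`, `a2`.
#' @export
simulate_mm <- function(params, regimen, horizon = 120, grid = NULL,
                        atol = 1e-10, rtol = 1e-8, max_horizon = 1920) {
  stopifnot(inherits(params, "mm_params"))
  dose <- regimen$molar_dose
  y0 <- c(a1 = dose, a2 = 0)

  repeat {
    times <- if (is.null(grid)) default_time_grid(horizon) else grid
    out <- deSolve::lsoda(y0, times, mm_rhs_desolve, params,
                          atol = atol, rtol = rtol, maxsteps = 50000)
    d <- attr(out, "istate")
    if (is.null(d) || d[1] < 0) {
      stop("lsoda failed to converge (istate ", d[1], ") after ",
           d[3], " steps", call. = FALSE)
    }
    cmax <- max(out[, "a1"]) / params$v1
    clast <- out[nrow(out), "a1"] / params$v1
    if (!is.null(grid) || dose == 0 || clast <= 1e-5 * cmax ||
        horizon >= max_horizon) {
      break
    }
    horizon <- min(2 * horizon, max_horizon)
  }

  m <- clip_states(unclass(out), c("a1", "a2"), atol)
  res <- data.frame(
    time = m[, "time"], conc = m[, "a1"] / params$v1,
    a1 = m[, "a1"], a2 = m[, "a2"]
  )
  finish_sim(res, params, regimen, "mm", atol,
             list(steps = unname(attr(out, "istate")[3]), horizon = horizon))
}

#' Closed-form two-compartment IV bolus concentration
#'
#' Bi-exponential solution of the linear two-compartment model (the TMDD
#' model with `kon = 0`, or the MM model with `vmax = 0`), by
#' eigen-decomposition of the 2x2 amount system. Serves as the analytic
#' oracle for the linear limit of both simulators.
#'
#' @param t Time(s), days.
#' @param dose Molar dose (nmol) given as IV bolus at t = 0.
#' @param kel,v1,v2,q Linear disposition parameters.
#' @return Central concentration(s) in nmol/l.
#' @export
two_compartment_conc <- function(t, dose, kel, v1, v2, q) {
  k12 <- q / v1
  k21 <- q / v2
  a <- matrix(c(-(kel + k12), k21, k12, -k21), 2, 2, byrow = TRUE)
  eg <- eigen(a)
  w <- solve(eg$vectors, c(dose, 0))
  amounts <- eg$vectors %*% (exp(outer(eg$values, t)) * w)
  as.numeric(amounts[1, ]) / v1
}
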