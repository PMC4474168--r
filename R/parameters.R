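#' TMDD micro-parameter set
#'
#' Constructs and validates the parameter set of the two-compartment
#' target-mediated drug disposition (TMDD) model with 1:1 binding in the
#' central compartment. Units are fixed package-wide: time in days,
#' concentrations in nmol/l, volumes in l, amounts in nmol.
#'
#' @param kel First-order antibody elimination rate constant (1/day). The
#'   linear catabolic clearance is `kel * v1`.
#' @param kon Target binding association rate constant (1/(nmol/l)/day).
#' @param koff Dissociation rate constant of the drug-target complex (1/day).
#' @param kint Internalization (degradation) rate constant of the complex
#'   (1/day).
#' @param ksyn Zero-order target synthesis rate (nmol/l/day, referenced to the
#'   central volume).
#' @param kdeg First-order degradation rate constant of the free target
#'   (1/day).
#' @param v1,v2 Central and peripheral volumes of distribution (l).
#' @param q Distributional clearance between the two compartments (l/day).
#'
#' @return An object of class `tmdd_params`: a named list of the nine micro
#'   constants.
#' @seealso [steady_state_target()], [mm_from_micro()], [cl_linear()]
#' @export
#' @examples
#' p <- tmdd_params(
#'   kel = 0.25 / 2.8, kon = 20, koff = 3.69, kint = 4.37,
#'   ksyn = 3.48, kdeg = 2, v1 = 2.8, v2 = 2.8, q = 0.6
#' )
#' steady_state_target(p)
tmdd_params <- function(kel, kon, koff, kint, ksyn, kdeg, v1, v2, q) {
  p <- list(
    kel = kel, kon = kon, koff = koff, kint = kint,
    ksyn = ksyn, kdeg = kdeg, v1 = v1, v2 = v2, q = q
  )
  validate_tmdd_params(p)
  structure(p, class = "tmdd_params")
}

validate_tmdd_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("all TMDD parameters must be finite numeric scalars; offending: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  rates <- c("kel", "kon", "koff", "kint", "ksyn", "kdeg", "q")
  bad <- rates[unlist(p[rates]) < 0]
  if (length(bad) > 0) {
    stop("rate constants must be non-negative; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$v1 <= 0 || p$v2 <= 0) {
    stop("volumes v1 and v2 must be strictly positive", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.tmdd_params <- function(x, ...) {
  cat("<tmdd_params>  (day / nmol/l / l / nmol)\n")
  vals <- unlist(x)
  cat(paste0("  ", format(names(vals), width = 5), " = ",
             format(vals, digits = 6)), sep = "\n")
  if (x$kdeg > 0) {
    cat(sprintf("  derived: R0 = %.4g nmol/l, CL_linear = %.4g l/day\n",
                steady_state_target(x), cl_linear(x)))
  }
  invisible(x)
}

#' Michaelis-Menten (quasi-steady-state) parameter set
#'
#' Parameters of the reduced model in which target-mediated elimination is a
#' Michaelis-Menten loss from the central compartment with capacity `vmax`
#' and affinity constant `km`.
#'
#' @param kel First-order elimination rate constant (1/day).
#' @param vmax Maximal target-mediated elimination rate (nmol/l/day).
#' @param km Michaelis constant (nmol/l).
#' @param v1,v2 Central and peripheral volumes (l).
#' @param q Distributional clearance (l/day).
#'
#' @return An object of class `mm_params`.
#' @export
mm_params <- function(kel, vmax, km, v1, v2, q) {
  p <- list(kel = kel, vmax = vmax, km = km, v1 = v1, v2 = v2, q = q)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("all MM parameters must be finite numeric scalars; offending: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  if (p$vmax < 0) stop("vmax must be non-negative", call. = FALSE)
  if (p$km <= 0) stop("km must be strictly positive", call. = FALSE)
  if (p$kel < 0 || p$q < 0) {
    stop("kel and q must be non-negative", call. = FALSE)
  }
  if (p$v1 <= 0 || p$v2 <= 0) {
    stop("volumes v1 and v2 must be strictly positive", call. = FALSE)
  }
  structure(p, class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat("<mm_params>  (day / nmol/l / l / nmol)\n")
  vals <- unlist(x)
  cat(paste0("  ", format(names(vals), width = 4), " = ",
             format(vals, digits = 6)), sep = "\n")
  invisible(x)
}

#' Steady-state free target concentration
#'
#' The endogenous free target concentration at steady state,
#' `R0 = ksyn / kdeg`.
#'
#' @param params A [tmdd_params()] object.
#' @return R0 in nmol/l.
#' @export
steady_state_target <- function(params) {
  stopifnot(inherits(params, "tmdd_params"))
  if (params$kdeg <= 0) {
    stop("steady_state_target requires kdeg > 0", call. = FALSE)
  }
  params$ksyn / params$kdeg
}

#' Linear (catabolic) clearance
#'
#' The non-specific clearance route, `CL_linear = kel * v1` (l/day).
#'
#' @param params A [tmdd_params()] or [mm_params()] object.
#' @return Clearance in l/day.
#' @export
cl_linear <- function(params) {
  stopifnot(inherits(params, c("tmdd_params", "mm_params")))
  params$kel * params$v1
}

#' Reduce TMDD micro constants to Michaelis-Menten parameters
#'
#' Quasi-steady-state reduction of the full TMDD model: `km = (koff + kint) /
#' kon` and `vmax = kint * R0`, with `kel`, `v1`, `v2` and `q` carried over
#' unchanged. `vmax` therefore tracks the target level: after a target policy
#' changes R0 for an age group, the reduction recomputes `vmax` accordingly.
#'
#' @param params A [tmdd_params()] object with `kon > 0` and `kdeg > 0`.
#' @return An [mm_params()] object.
#' @export
#' @examples
#' p <- reference_params()
#' mm <- mm_from_micro(p)
#' mm$vmax # 7.6038 nmol/l/day
#' mm$km   # 0.403 nmol/l
mm_from_micro <- function(params) {
  stopifnot(inherits(params, "tmdd_params"))
  if (params$kon <= 0) {
    stop("mm_from_micro requires kon > 0 (no binding, no reduced model)",
         call. = FALSE)
  }
  r0 <- steady_state_target(params)
  mm_params(
    kel = params$kel,
    vmax = params$kint * r0,
    km = (params$koff + params$kint) / params$kon,
    v1 = params$v1, v2 = params$v2, q = params$q
  )
}

#' Target occupancy
#'
#' Fraction of the total target pool bound in complex, `DR / (R + DR)`.
#' Undefined where the total target `R + DR` is zero; those entries are
#' returned as `NA` rather than 0/0.
#'
#' @param r Free target concentration (nmol/l), vectorised.
#' @param dr Drug-target complex concentration (nmol/l), vectorised.
#' @return Occupancy fraction in \[0, 1\], `NA` where `r + dr == 0`.
#' @export
occupancy <- function(r, dr) {
  if (any(r < 0 | dr < 0, na.rm = TRUE)) {
    stop("occupancy requires non-negative r and dr", call. = FALSE)
  }
  tot <- r + dr
  out <- ifelse(tot > 0, dr / tot, NA_real_)
  out
}

#' Concentration-dependent total clearance of the reduced model
#'
#' Clearance decomposition `CL_TOT(C) = CL_linear + CL_nonlinear(C)` with
#' `CL_nonlinear(C) = kint * R_TOT * v1 / (km + C)`, where the total target
#' `R_TOT` is held at its baseline R0 (the quasi-steady-state assumption) and
#' `km` comes from the micro constants. The nonlinear term saturates away at
#' high concentration, so `CL_TOT` falls monotonically from
#' `CL_linear + kint * R0 * v1 / km` at C = 0 to `CL_linear` as C grows.
#'
#' @param c_free Free drug concentration (nmol/l), vectorised, non-negative.
#' @param params A [tmdd_params()] object.
#' @return Total clearance in l/day, same length as `c_free`.
#' @export
cl_total_model <- function(c_free, params) {
  stopifnot(inherits(params, "tmdd_params"))
  if (any(c_free < 0, na.rm = TRUE)) {
    stop("cl_total_model requires non-negative concentrations", call. = FALSE)
  }
  km <- (params$koff + params$kint) / params$kon
  r_tot <- steady_state_target(params)
  cl_linear(params) + params$kint * r_tot * params$v1 / (km + c_free)
}
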