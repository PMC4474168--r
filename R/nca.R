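#' Non-compartmental AUC with extrapolation to infinity
#'
#' Computes `AUC_0_last` by the linear-up/log-down trapezoid rule on the
#' profile's own grid, estimates the terminal slope `lambda_z` by log-linear
#' regression over the window (of at least 3 points, excluding Cmax) that
#' maximizes adjusted R-squared — ties broken toward more points — and
#' extrapolates `AUC_0_inf = AUC_0_last + C_last / lambda_z`.
#'
#' @param profile A `tmdd_sim` tibble (or any data frame with `time` and
#'   `conc` columns).
#' @param extrap_warn Extrapolated fraction above which the result is flagged.
#' @return A one-row tibble: `auc_0_last`, `auc_0_inf`, `extrap_frac`,
#'   `cmax`, `tmax`, `lambda_z`, `lambda_z_n` (points in the terminal fit),
#'   `flag` (`"ok"` or `"high_extrapolation"`).
#' @export
auc_0_inf <- function(profile, extrap_warn = 0.2) {
  t <- profile$time
  cc <- profile$conc
  stopifnot(length(t) == length(cc), !is.unsorted(t, strictly = TRUE))
  if (all(cc <= 0)) {
    stop("all-zero concentration profile: AUC not estimable", call. = FALSE)
  }
  auc_last <- trapz_linuplogdown(t, cc)
  imax <- which.max(cc)
  lz <- lambda_z(t, cc, exclude_before = imax + 1L)
  clast <- cc[length(cc)]
  auc_inf <- auc_last + clast / lz$lambda
  extrap <- (auc_inf - auc_last) / auc_inf
  tibble::tibble(
    auc_0_last = auc_last,
    auc_0_inf = auc_inf,
    extrap_frac = extrap,
    cmax = cc[imax],
    tmax = t[imax],
    lambda_z = lz$lambda,
    lambda_z_n = lz$n,
    flag = if (extrap > extrap_warn) "high_extrapolation" else "ok"
  )
}

# Linear-up/log-down trapezoid: log interpolation on strictly declining
# positive segments, linear elsewhere.
trapz_linuplogdown <- function(t, cc) {
  dt <- diff(t)
  c1 <- cc[-length(cc)]
  c2 <- cc[-1]
  logdown <- c2 < c1 & c2 > 0
  seg <- ifelse(logdown,
                (c1 - c2) / log(c1 / c2) * dt,
                (c1 + c2) / 2 * dt)
  sum(seg)
}

# Terminal-slope estimation by best adjusted R^2 over candidate windows
# ending at the last positive observation.
lambda_z <- function(t, cc, exclude_before = 1L, min_points = 3L) {
  keep <- cc > 0
  last <- max(which(keep))
  hi <- last - min_points + 1L
  if (hi < 1L) {
    stop("lambda_z not estimable: fewer than ", min_points,
         " positive observations", call. = FALSE)
  }
  starts <- seq.int(min(exclude_before, hi), hi)
  starts <- starts[starts >= 1]
  best <- NULL
  for (s in starts) {
    idx <- s:last
    idx <- idx[cc[idx] > 0]
    if (length(idx) < min_points) next
    fit <- stats::lm.fit(cbind(1, t[idx]), log(cc[idx]))
    slope <- unname(fit$coefficients[2])
    if (!is.finite(slope) || slope >= 0) next
    n <- length(idx)
    rss <- sum(fit$residuals^2)
    tss <- sum((log(cc[idx]) - mean(log(cc[idx])))^2)
    r2adj <- if (tss > 0) 1 - (rss / (n - 2)) / (tss / (n - 1)) else 1
    # ties toward more points: earlier (longer) windows win on near-equality
    if (is.null(best) || r2adj > best$r2adj + 1e-12) {
      best <- list(lambda = -slope, n = n, r2adj = r2adj)
    }
  }
  if (is.null(best)) {
    stop("lambda_z not estimable: no declining terminal segment of >= ",
         min_points, " points", call. = FALSE)
  }
  best
}

#' Partition total clearance into linear and target-mediated routes
#'
#' `CL_TOT = Dose / AUC_0_inf`; the target-mediated component is the excess
#' over the linear catabolic clearance, `CL_TMDD = CL_TOT - kel * v1`
#' (floored at zero with a warning when numerically negative), and
#' `cl_fraction = CL_TMDD / CL_TOT`.
#'
#' @param dose Molar dose (nmol).
#' @param nca A one-row result of [auc_0_inf()] (or a number, the AUC itself).
#' @param params A [tmdd_params()] or [mm_params()] object (for `kel * v1`).
#' @return A one-row tibble: `cl_tot`, `cl_linear`, `cl_tmdd`, `cl_fraction`
#'   (l/day and dimensionless).
#' @export
clearance_partition <- function(dose, nca, params) {
  auc <- if (is.data.frame(nca)) nca$auc_0_inf else nca
  if (auc <= 0) stop("AUC_0_inf must be positive", call. = FALSE)
  cl_tot <- dose / auc
  cl_lin <- cl_linear(params)
  cl_tmdd <- cl_tot - cl_lin
  if (cl_tmdd < 0) {
    if (cl_tmdd < -1e-6 * cl_tot) {
      warning("CL_TOT below CL_linear by ", format(-cl_tmdd),
              " l/day; CL_TMDD floored at 0", call. = FALSE)
    }
    cl_tmdd <- 0
  }
  tibble::tibble(
    cl_tot = cl_tot, cl_linear = cl_lin, cl_tmdd = cl_tmdd,
    cl_fraction = cl_tmdd / cl_tot
  )
}

#' Duration of target occupancy above a threshold
#'
#' Total time the occupancy curve sits at or above the threshold, with
#' crossing times located by linear interpolation between grid points. For
#' the monotone post-peak occupancy profiles produced here this equals the
#' single contiguous interval above the threshold.
#'
#' @param profile A `tmdd_sim` tibble with `time` and `occupancy` columns.
#' @param threshold Occupancy fraction, default 0.90.
#' @return Duration in days.
#' @export
occupancy_duration <- function(profile, threshold = 0.90) {
  t <- profile$time
  occ <- profile$occupancy
  if (is.null(occ)) stop("profile has no occupancy column", call. = FALSE)
  keep <- !is.na(occ)
  t <- t[keep]; occ <- occ[keep]
  if (length(t) < 2) return(0)
  if (threshold <= 0) return(t[length(t)] - t[1])
  above <- occ >= threshold
  total <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    if (above[i] && above[i + 1]) {
      total <- total + dt
    } else if (above[i] != above[i + 1]) {
      frac <- (threshold - occ[i]) / (occ[i + 1] - occ[i])
      total <- total + if (above[i]) frac * dt else (1 - frac) * dt
    }
  }
  total
}

#' Exposure ratio in percent
#'
#' `100 * AUC_child / AUC_adult`. Accepts [auc_0_inf()] rows or bare numbers;
#' also used for MM-vs-full comparisons of the ratios themselves.
#'
#' @param child,adult AUC values or one-row NCA results.
#' @return Ratio in percent.
#' @export
auc_ratio <- function(child, adult) {
  a <- if (is.data.frame(child)) child$auc_0_inf else child
  b <- if (is.data.frame(adult)) adult$auc_0_inf else adult
  if (any(b <= 0)) stop("reference AUC must be positive", call. = FALSE)
  100 * a / b
}

#' Full NCA summary of a simulated profile
#'
#' Convenience wrapper: [auc_0_inf()] plus [clearance_partition()] and, where
#' the profile carries target columns, [occupancy_duration()].
#'
#' @param profile A `tmdd_sim` tibble.
#' @param params Parameter object used for the simulation; defaults to the
#'   profile's `params` attribute.
#' @param dose Molar dose; defaults to the profile's regimen attribute.
#' @param threshold Occupancy threshold for the duration metric.
#' @return A one-row tibble combining exposure, clearance and occupancy
#'   metrics.
#' @export
nca_summary <- function(profile, params = attr(profile, "params"),
                        dose = attr(profile, "regimen")$molar_dose,
                        threshold = 0.90) {
  base <- auc_0_inf(profile)
  cl <- clearance_partition(dose, base, params)
  occ_days <- if ("occupancy" %in% names(profile)) {
    occupancy_duration(profile, threshold)
  } else {
    NA_real_
  }
  dplyr::bind_cols(base, cl, tibble::tibble(occupancy_days = occ_days))
}
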