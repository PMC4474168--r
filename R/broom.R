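#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the estimates of an MM fit
#'
#' @param x An `mm_fit` from [fit_mm()].
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `term`, `estimate`,
#'   and, when the generating truth is attached, `truth` and `rel_error`.
#' @export
tidy.mm_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$estimate),
                        estimate = unname(x$estimate))
  truth <- x$truth
  if (!is.null(truth) && inherits(truth, "mm_params")) {
    tv <- unlist(truth[out$term])
    out$truth <- unname(tv)
    out$rel_error <- (out$estimate - out$truth) / out$truth
  }
  out
}

#' One-row summary of an MM fit
#'
#' @inheritParams tidy.mm_fit
#' @return A tibble: weighted residual sum of squares, observation count,
#'   iterations, convergence code and message.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_obs = x$n_obs,
    niter = x$niter,
    info = x$info,
    converged = x$info %in% 1:4,
    message = x$message
  )
}

#' Tidy a simulated profile
#'
#' Long-format view of a `tmdd_sim`: one row per (time, quantity).
#'
#' @param x A `tmdd_sim` tibble.
#' @param ... Unused.
#' @return A tibble with `time`, `quantity`, `value`.
#' @export
tidy.tmdd_sim <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "quantity", values_to = "value")
}

#' One-row summary of a simulated profile
#'
#' @param x A `tmdd_sim` tibble.
#' @param ... Unused.
#' @return A tibble with the model kind, dose, horizon, Cmax and (full model
#'   only) baseline target level.
#' @export
glance.tmdd_sim <- function(x, ...) {
  reg <- attr(x, "regimen")
  tibble::tibble(
    model = attr(x, "model"),
    molar_dose = reg$molar_dose,
    horizon = max(x$time),
    n_times = nrow(x),
    cmax = max(x$conc),
    r0 = if ("r" %in% names(x)) x$r[1] else NA_real_
  )
}
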