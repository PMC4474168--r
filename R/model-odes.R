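#' Right-hand side of the full TMDD system
#'
#' Time derivatives of the four-state TMDD model: free drug amount in the
#' central (`a1`, nmol) and peripheral (`a2`, nmol) compartments, free target
#' concentration (`r`, nmol/l) and drug-target complex concentration (`dr`,
#' nmol/l). Binding occurs in the central compartment only; complex is
#' eliminated by internalization at `kint`; the target turns over by
#' zero-order synthesis `ksyn` and first-order degradation `kdeg`.
#'
#' With `c = a1 / v1`:
#' \deqn{da1/dt = -kel\,a1 - Q(a1/V_1 - a2/V_2) - k_{on} c R V_1 + k_{off} DR\,V_1}
#' \deqn{da2/dt = Q(a1/V_1 - a2/V_2)}
#' \deqn{dR/dt = k_{syn} - k_{deg} R - k_{on} c R + k_{off} DR}
#' \deqn{dDR/dt = k_{on} c R - (k_{off} + k_{int}) DR}
#'
#' @param state Named numeric vector with components `a1`, `a2`, `r`, `dr`.
#' @param params A [tmdd_params()] object.
#' @return Named numeric vector of derivatives (per day), same names.
#' @export
tmdd_rhs <- function(state, params) {
  stopifnot(inherits(params, "tmdd_params"))
  if (!all(is.finite(unlist(state)))) {
    stop("non-finite state passed to tmdd_rhs (solver divergence?)",
         call. = FALSE)
  }
  a1 <- state[["a1"]]; a2 <- state[["a2"]]
  r <- state[["r"]]; dr <- state[["dr"]]
  cc <- a1 / params$v1
  flow <- params$q * (a1 / params$v1 - a2 / params$v2)
  bind <- params$kon * cc * r
  c(
    a1 = -params$kel * a1 - flow - bind * params$v1 + params$koff * dr * params$v1,
    a2 = flow,
    r = params$ksyn - params$kdeg * r - bind + params$koff * dr,
    dr = bind - (params$koff + params$kint) * dr
  )
}

#' Right-hand side of the Michaelis-Menten approximation
#'
#' Drug-only two-compartment system in which target-mediated elimination is a
#' saturable loss `vmax * c / (km + c) * v1` from the central compartment.
#'
#' @param state Named numeric vector with components `a1`, `a2` (nmol).
#' @param params An [mm_params()] object.
#' @return Named numeric vector of derivatives (nmol/day).
#' @export
mm_rhs <- function(state, params) {
  stopifnot(inherits(params, "mm_params"))
  if (!all(is.finite(unlist(state)))) {
    stop("non-finite state passed to mm_rhs (solver divergence?)",
         call. = FALSE)
  }
  a1 <- state[["a1"]]; a2 <- state[["a2"]]
  cc <- a1 / params$v1
  flow <- params$q * (a1 / params$v1 - a2 / params$v2)
  c(
    a1 = -params$kel * a1 - flow - params$vmax * cc / (params$km + cc) * params$v1,
    a2 = flow
  )
}

# deSolve-signature wrappers (time-invariant systems)
tmdd_rhs_desolve <- function(t, state, params) {
  list(tmdd_rhs(state, params))
}

mm_rhs_desolve <- function(t, state, params) {
  list(mm_rhs(state, params))
}
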