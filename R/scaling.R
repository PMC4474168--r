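#' Canonical age-group body weights
#'
#' Mean body weights used for the pediatric age groups: 12.8 kg (2 y),
#' 21.3 kg (6 y), 43.5 kg (12 y) and 66.1 kg (18 y). The scaling reference
#' remains the 70-kg adult; the 18-year group is itself scaled down from it.
#'
#' @format Named numeric vector, kg.
#' @export
age_group_weights <- c("2y" = 12.8, "6y" = 21.3, "12y" = 43.5, "18y" = 66.1)

#' Construct a subject
#'
#' @param age_label One of `"2y"`, `"6y"`, `"12y"`, `"18y"` (canonical body
#'   weights) or `"custom"` (supply `bw`).
#' @param bw Body weight in kg; defaults to the canonical weight for the age
#'   label.
#' @return A one-row tibble with columns `age_label`, `bw`.
#' @export
subject <- function(age_label, bw = NULL) {
  age_label <- as.character(age_label)
  if (is.null(bw)) {
    if (!age_label %in% names(age_group_weights)) {
      stop("unknown age label '", age_label,
           "'; supply bw explicitly or use one of: ",
           paste(names(age_group_weights), collapse = ", "), call. = FALSE)
    }
    bw <- unname(age_group_weights[age_label])
  }
  if (!is.numeric(bw) || length(bw) != 1 || !is.finite(bw) || bw <= 0) {
    stop("bw must be a single positive number (kg)", call. = FALSE)
  }
  tibble::tibble(age_label = age_label, bw = bw)
}

#' Allometric scaling policy
#'
#' Fixed-exponent power-law scaling `Y = Y_adult * (BW / ref_bw)^b`, with
#' separate exponents for clearances (default 0.75) and volumes (default 1),
#' anchored at a 70-kg adult with 2.8 l plasma volume.
#'
#' @param cl_exponent Allometric exponent for clearances.
#' @param v_exponent Allometric exponent for volumes.
#' @param ref_bw Reference adult body weight (kg).
#' @param ref_plasma_volume Plasma volume of the reference adult (l).
#' @return An object of class `scaling_policy`.
#' @export
scaling_policy <- function(cl_exponent = 0.75, v_exponent = 1,
                           ref_bw = 70, ref_plasma_volume = 2.8) {
  if (cl_exponent <= 0 || cl_exponent >= 2 || v_exponent <= 0 || v_exponent >= 2) {
    stop("allometric exponents must lie in (0, 2)", call. = FALSE)
  }
  if (ref_bw <= 0 || ref_plasma_volume <= 0) {
    stop("reference body weight and plasma volume must be positive",
         call. = FALSE)
  }
  structure(
    list(cl_exponent = cl_exponent, v_exponent = v_exponent,
         ref_bw = ref_bw, ref_plasma_volume = ref_plasma_volume),
    class = "scaling_policy"
  )
}

#' Allometric scaling of a single value
#'
#' @param value_adult Adult reference value (any rate or volume).
#' @param bw Body weight (kg), vectorised.
#' @param exponent Allometric exponent.
#' @param policy A [scaling_policy()] (supplies the reference weight).
#' @return Scaled value(s): `value_adult * (bw / ref_bw)^exponent`.
#' @export
allometric_scale <- function(value_adult, bw, exponent,
                             policy = scaling_policy()) {
  if (any(bw <= 0)) stop("bw must be positive", call. = FALSE)
  value_adult * (bw / policy$ref_bw)^exponent
}

#' Plasma volume at a given body weight
#'
#' Linear (exponent-1) scaling of the reference plasma volume; used to convert
#' whole-body target amounts to central target concentrations.
#'
#' @inheritParams allometric_scale
#' @return Plasma volume in l.
#' @export
plasma_volume <- function(bw, policy = scaling_policy()) {
  allometric_scale(policy$ref_plasma_volume, bw, 1, policy)
}

#' Scale TMDD parameters from the adult reference to a subject
#'
#' Volumes `v1`, `v2` are scaled with the volume exponent; the linear
#' clearance `kel * v1` and the distributional clearance `q` with the
#' clearance exponent, `kel` then recomputed as scaled clearance over scaled
#' volume. The micro constants `kon`, `koff`, `kint` and `kdeg` are held
#' constant across ages (cellular-level processes); `ksyn` is left untouched
#' here and set by [apply_target_policy()].
#'
#' @param adult A [tmdd_params()] object for the reference adult.
#' @param subj A [subject()] row (or tibble with `bw`).
#' @param policy A [scaling_policy()].
#' @return A [tmdd_params()] object for the subject.
#' @export
scale_parameters <- function(adult, subj, policy = scaling_policy()) {
  stopifnot(inherits(adult, "tmdd_params"))
  bw <- subj$bw
  f_v <- (bw / policy$ref_bw)^policy$v_exponent
  f_cl <- (bw / policy$ref_bw)^policy$cl_exponent
  v1 <- adult$v1 * f_v
  cl <- cl_linear(adult) * f_cl
  tmdd_params(
    kel = cl / v1,
    kon = adult$kon, koff = adult$koff, kint = adult$kint,
    ksyn = adult$ksyn, kdeg = adult$kdeg,
    v1 = v1, v2 = adult$v2 * f_v, q = adult$q * f_cl
  )
}

#' Target-level policy
#'
#' Anchors the pediatric target level to the adult either by concentration
#' (`same_concentration`: every age gets the adult R0 in nmol/l) or by
#' whole-body amount (`same_amount`: every age gets the adult amount in nmol,
#' so smaller children see a higher concentration).
#'
#' @param mode `"same_concentration"` or `"same_amount"`.
#' @param adult_r0 Adult target concentration anchor (nmol/l); required for
#'   `same_concentration`.
#' @param adult_amount Adult whole-body target amount anchor (nmol); required
#'   for `same_amount`.
#' @return An object of class `target_policy`.
#' @export
target_policy <- function(mode = c("same_concentration", "same_amount"),
                          adult_r0 = NULL, adult_amount = NULL) {
  mode <- match.arg(mode)
  if (mode == "same_concentration") {
    if (is.null(adult_r0) || !is.null(adult_amount)) {
      stop("same_concentration takes adult_r0 only", call. = FALSE)
    }
    if (adult_r0 <= 0) stop("adult_r0 must be positive", call. = FALSE)
  } else {
    if (is.null(adult_amount) || !is.null(adult_r0)) {
      stop("same_amount takes adult_amount only", call. = FALSE)
    }
    if (adult_amount <= 0) stop("adult_amount must be positive", call. = FALSE)
  }
  structure(
    list(mode = mode, adult_r0 = adult_r0, adult_amount = adult_amount),
    class = "target_policy"
  )
}

#' Apply a target-level policy to scaled parameters
#'
#' Sets the subject's baseline target concentration according to the policy —
#' the adult concentration directly, or the adult amount divided by the
#' subject's plasma volume — and re-anchors the synthesis rate as
#' `ksyn = R0 * kdeg` so the drug-free steady state matches.
#'
#' @param params A (scaled) [tmdd_params()] object.
#' @param subj A [subject()] row.
#' @param tpolicy A [target_policy()].
#' @param spolicy A [scaling_policy()] (plasma-volume reference).
#' @return A [tmdd_params()] object with updated `ksyn`.
#' @export
#' @examples
#' pol <- target_policy("same_amount", adult_amount = 4.87)
#' p <- apply_target_policy(reference_params(), subject("2y"), pol)
#' steady_state_target(p) # 9.51 nmol/l in a 12.8-kg child
apply_target_policy <- function(params, subj, tpolicy,
                                spolicy = scaling_policy()) {
  stopifnot(inherits(params, "tmdd_params"), inherits(tpolicy, "target_policy"))
  if (params$kdeg <= 0) {
    stop("target policy requires kdeg > 0 to anchor ksyn", call. = FALSE)
  }
  r0 <- if (tpolicy$mode == "same_concentration") {
    tpolicy$adult_r0
  } else {
    tpolicy$adult_amount / plasma_volume(subj$bw, spolicy)
  }
  params$ksyn <- r0 * params$kdeg
  validate_tmdd_params(params)
  structure(params, class = "tmdd_params")
}

#' Whole-body target amount from a concentration
#'
#' @param r0 Target concentration (nmol/l).
#' @param bw Body weight (kg).
#' @param spolicy A [scaling_policy()].
#' @return Target amount in nmol: `r0 * plasma_volume(bw)`.
#' @export
target_amount_from_concentration <- function(r0, bw,
                                             spolicy = scaling_policy()) {
  if (any(r0 < 0)) stop("r0 must be non-negative", call. = FALSE)
  r0 * plasma_volume(bw, spolicy)
}
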