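#' Build a single IV bolus dose regimen in molar units
#'
#' Converts a nominal dose — mg/kg (`per_kg`) or absolute mg (`fixed`) — to a
#' total molar dose in nmol using the antibody molecular weight (default
#' 150 kDa): `nmol = mg * 1e6 / MW` with the per-kg nominal first multiplied
#' by body weight. 0.5 mg/kg at 150 kDa is 3.33 nmol/kg; 4.5 mg/kg is
#' 30 nmol/kg; fixed 315 mg equals 4.5 mg/kg for a 70-kg subject.
#'
#' @param nominal Nominal dose: mg/kg for `per_kg`, mg for `fixed`.
#' @param mode `"per_kg"` or `"fixed"`.
#' @param subj A [subject()] row (body weight used for `per_kg`).
#' @param mw Molecular weight in g/mol.
#' @return A one-row tibble of class `dose_regimen` with columns `mode`,
#'   `nominal`, `bw`, `mw`, `molar_dose` (nmol), `time` (day 0, IV bolus).
#' @export
build_regimen <- function(nominal, mode = c("per_kg", "fixed"), subj,
                          mw = 150000) {
  mode <- match.arg(mode)
  if (!is.numeric(nominal) || length(nominal) != 1 || nominal < 0) {
    stop("nominal dose must be a single non-negative number", call. = FALSE)
  }
  if (mw <= 0) stop("molecular weight must be positive", call. = FALSE)
  mg_total <- if (mode == "per_kg") nominal * subj$bw else nominal
  out <- tibble::tibble(
    mode = mode,
    nominal = nominal,
    bw = subj$bw,
    mw = mw,
    molar_dose = mg_total * 1e6 / mw,
    time = 0
  )
  class(out) <- c("dose_regimen", class(out))
  out
}
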