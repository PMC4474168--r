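#' Canonical scenario axes
#'
#' The default hierarchical grid crosses two target policies, two dosing
#' policies, five doses per policy, seven target levels per policy (fourfold
#' increments around the physiological anchor), four age groups, and the two
#' model kinds (full TMDD and its MM approximation): 560 cells in all.
#'
#' Doses: 0.5, 1, 2, 3, 4.5 mg/kg (3.33-30 nmol/kg at 150 kDa) and the
#' corresponding fixed doses 35, 70, 140, 210, 315 mg for a 70-kg adult.
#' Target levels: concentrations 6.96, 1.74, 0.44, 0.11, 0.027, 0.0068,
#' 0.0017 nmol/l for the same-concentration policy; amounts 19.5, 4.87, 1.23,
#' 0.31, 0.076, 0.019, 0.005 nmol for the same-amount policy.
#'
#' @return A tibble with one row per grid cell, columns `target_policy`,
#'   `dose_policy`, `nominal_dose`, `target_level`, `age_label`,
#'   `model_kind`, in deterministic lexicographic order.
#' @export
default_grid <- function() {
  axes <- list(
    same_concentration = list(levels = c(6.96, 1.74, 0.44, 0.11, 0.027,
                                         0.0068, 0.0017)),
    same_amount = list(levels = c(19.5, 4.87, 1.23, 0.31, 0.076, 0.019,
                                  0.005))
  )
  doses <- list(per_kg = c(0.5, 1, 2, 3, 4.5),
                fixed = c(35, 70, 140, 210, 315))
  grid <- tidyr::expand_grid(
    target_policy = c("same_concentration", "same_amount"),
    dose_policy = c("per_kg", "fixed"),
    dose_index = 1:5,
    level_index = 1:7,
    age_label = names(age_group_weights),
    model_kind = c("tmdd", "mm")
  )
  grid$nominal_dose <- purrr::map2_dbl(
    grid$dose_policy, grid$dose_index, ~ doses[[.x]][.y]
  )
  grid$target_level <- purrr::map2_dbl(
    grid$target_policy, grid$level_index, ~ axes[[.x]]$levels[.y]
  )
  dplyr::arrange(
    dplyr::select(grid, "target_policy", "dose_policy", "nominal_dose",
                  "target_level", "age_label", "model_kind"),
    .data$target_policy, .data$dose_policy, .data$nominal_dose,
    dplyr::desc(.data$target_level), .data$age_label, .data$model_kind
  )
}

# Run one grid cell: scale -> target policy -> regimen -> simulate -> metrics.
run_cell <- function(tpol_name, dpol_name, nominal_dose, target_level,
                     age_label, model_kind, adult_params, spolicy, mw,
                     occ_threshold) {
  subj <- subject(age_label)
  tpol <- if (tpol_name == "same_concentration") {
    target_policy("same_concentration", adult_r0 = target_level)
  } else {
    target_policy("same_amount", adult_amount = target_level)
  }
  p <- scale_parameters(adult_params, subj, spolicy)
  p <- apply_target_policy(p, subj, tpol, spolicy)
  reg <- build_regimen(nominal_dose, dpol_name, subj, mw = mw)
  sim <- if (model_kind == "mm") {
    simulate_mm(mm_from_micro(p), reg)
  } else {
    simulate_tmdd(p, reg)
  }
  met <- nca_summary(sim, params = p, dose = reg$molar_dose,
                     threshold = occ_threshold)
  tibble::tibble(
    bw = subj$bw, molar_dose = reg$molar_dose,
    r0 = steady_state_target(p),
    auc_0_inf = met$auc_0_inf, cmax = met$cmax,
    cl_tot = met$cl_tot, cl_tmdd = met$cl_tmdd,
    cl_fraction = met$cl_fraction,
    occupancy_days = met$occupancy_days,
    extrap_frac = met$extrap_frac, flag = met$flag
  )
}

#' Run the hierarchical scenario grid
#'
#' Executes every cell of a scenario grid deterministically (no randomness;
#' identical inputs give identical tables) and appends the comparison
#' columns: `auc_ratio_vs_18y`, each cell's exposure relative to the
#' 18-year row sharing its (policy, dose, target level, model kind) key, and
#' `mm_vs_full_ratio`, the MM-based child/adult AUC ratio relative to the
#' full-model one for the same key and age. Failed cells are kept as rows
#' with `flag` set to the error message, never dropped.
#'
#' @param grid A grid tibble as from [default_grid()] (any subset of rows
#'   works and slices of the default grid are the usual way to run one
#'   figure-style comparison).
#' @param adult_params Adult reference [tmdd_params()]; defaults to
#'   [reference_params()].
#' @param spolicy A [scaling_policy()].
#' @param mw Antibody molecular weight (g/mol).
#' @param occ_threshold Occupancy threshold for the duration metric.
#' @return The grid tibble with result columns appended (class
#'   `scenario_table`).
#' @export
run_grid <- function(grid = default_grid(), adult_params = reference_params(),
                     spolicy = scaling_policy(), mw = 150000,
                     occ_threshold = 0.90) {
  res <- purrr::pmap(
    grid[c("target_policy", "dose_policy", "nominal_dose", "target_level",
           "age_label", "model_kind")],
    function(target_policy, dose_policy, nominal_dose, target_level,
             age_label, model_kind) {
      tryCatch(
        run_cell(tpol_name = target_policy, dpol_name = dose_policy,
                 nominal_dose = nominal_dose, target_level = target_level,
                 age_label = age_label, model_kind = model_kind,
                 adult_params = adult_params, spolicy = spolicy, mw = mw,
                 occ_threshold = occ_threshold),
        error = function(e) {
          tibble::tibble(
            bw = NA_real_, molar_dose = NA_real_, r0 = NA_real_,
            auc_0_inf = NA_real_, cmax = NA_real_, cl_tot = NA_real_,
            cl_tmdd = NA_real_, cl_fraction = NA_real_,
            occupancy_days = NA_real_, extrap_frac = NA_real_,
            flag = paste0("error: ", conditionMessage(e))
          )
        }
      )
    }
  )
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))

  key <- c("target_policy", "dose_policy", "nominal_dose", "target_level",
           "model_kind")
  ref <- dplyr::select(
    dplyr::filter(out, .data$age_label == "18y"),
    dplyr::all_of(key), ref_auc = "auc_0_inf"
  )
  out <- dplyr::left_join(out, ref, by = key)
  out$auc_ratio_vs_18y <- ifelse(
    is.na(out$ref_auc) | out$ref_auc <= 0, NA_real_,
    100 * out$auc_0_inf / out$ref_auc
  )
  out$ref_auc <- NULL

  cmp_key <- c("target_policy", "dose_policy", "nominal_dose", "target_level",
               "age_label")
  wide <- tidyr::pivot_wider(
    dplyr::select(out, dplyr::all_of(cmp_key), "model_kind",
                  "auc_ratio_vs_18y"),
    names_from = "model_kind", values_from = "auc_ratio_vs_18y"
  )
  if (all(c("mm", "tmdd") %in% names(wide))) {
    wide$mm_vs_full_ratio <- 100 * wide$mm / wide$tmdd
    out <- dplyr::left_join(
      out, dplyr::select(wide, dplyr::all_of(cmp_key), "mm_vs_full_ratio"),
      by = cmp_key
    )
  } else {
    out$mm_vs_full_ratio <- NA_real_
  }
  class(out) <- c("scenario_table", class(out))
  out
}

#' Compare MM and full-model child/adult exposure ratios
#'
#' For each (target policy, dose policy, dose, target level, age) key with
#' both model kinds present, reports the child/adult AUC ratio under each
#' model and their relative agreement `100 * ratio_mm / ratio_full`, flagging
#' keys where the two disagree by more than `flag_pct` percent — the regime
#' (low dose, high target amount) where the quasi-steady-state assumption
#' breaks down.
#'
#' @param table A `scenario_table` from [run_grid()].
#' @param flag_pct Disagreement (percent, either direction) above which a key
#'   is flagged.
#' @return A tibble with `auc_ratio_full`, `auc_ratio_mm`,
#'   `mm_vs_full_ratio`, `flagged`.
#' @export
compare_mm_full <- function(table, flag_pct = 25) {
  cmp_key <- c("target_policy", "dose_policy", "nominal_dose", "target_level",
               "age_label")
  wide <- tidyr::pivot_wider(
    dplyr::select(table, dplyr::all_of(cmp_key), "model_kind",
                  "auc_ratio_vs_18y"),
    names_from = "model_kind", values_from = "auc_ratio_vs_18y"
  )
  if (!all(c("mm", "tmdd") %in% names(wide))) {
    stop("both model kinds must be present in the table", call. = FALSE)
  }
  wide <- dplyr::rename(wide, auc_ratio_full = "tmdd", auc_ratio_mm = "mm")
  wide$mm_vs_full_ratio <- 100 * wide$auc_ratio_mm / wide$auc_ratio_full
  wide$flagged <- abs(wide$mm_vs_full_ratio - 100) > flag_pct
  wide
}
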