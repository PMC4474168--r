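canonical_units <- list(time = "day", concentration = "nmol/l",
                        volume = "l", amount = "nmol")

default_config <- function() {
  ref <- reference_params()
  prov <- attr(ref, "provenance")
  list(
    units = canonical_units,
    parameters = as.list(unclass(ref)),
    provenance = stats::setNames(as.list(prov$source), prov$param),
    scaling = list(cl_exponent = 0.75, v_exponent = 1, ref_bw = 70,
                   ref_plasma_volume = 2.8),
    scenario = list(
      per_kg_doses = c(0.5, 1, 2, 3, 4.5),
      fixed_doses = c(35, 70, 140, 210, 315),
      target_concentrations = c(6.96, 1.74, 0.44, 0.11, 0.027, 0.0068,
                                0.0017),
      target_amounts = c(19.5, 4.87, 1.23, 0.31, 0.076, 0.019, 0.005),
      age_labels = names(age_group_weights),
      molecular_weight = 150000,
      occupancy_threshold = 0.90
    ),
    synthetic = list(n_per_group = 20, bw_cv = 0.15, obs_cv = 0.10)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections `units`, `parameters`, `scaling`,
#' `scenario` and `synthetic`, fills missing entries from the package
#' defaults (the shipped surrogate parameter set and the canonical scenario
#' axes), and rejects unknown keys and unit conventions other than
#' day / nmol/l / l / nmol. An empty or missing-section file yields the full
#' default configuration. A commented template ships at
#' `system.file("extdata", "config-default.yml", package = "pedtmdd")`.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A validated `run_config` list; `$adult_params` holds the
#'   [tmdd_params()] object and `$provenance` the per-parameter source tags.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }

  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  cfg <- utils::modifyList(defaults, user)
  # yaml renders mixed int/double sequences as lists; the numeric axes are
  # always plain vectors
  for (nm in c("per_kg_doses", "fixed_doses", "target_concentrations",
               "target_amounts")) {
    cfg$scenario[[nm]] <- as.numeric(unlist(cfg$scenario[[nm]]))
  }
  cfg$scenario$age_labels <- as.character(unlist(cfg$scenario$age_labels))

  if (!identical(cfg$units[names(canonical_units)], canonical_units)) {
    stop("config units must declare time: day, concentration: nmol/l, ",
         "volume: l, amount: nmol", call. = FALSE)
  }
  if (!is.null(user$parameters)) {
    overridden <- names(user$parameters)
    cfg$provenance[overridden] <- "user"
  }
  if (cfg$scaling$cl_exponent <= 0 || cfg$scaling$cl_exponent >= 2) {
    stop("scaling cl_exponent out of range (0, 2)", call. = FALSE)
  }

  cfg$adult_params <- do.call(tmdd_params, cfg$parameters)
  cfg$spolicy <- scaling_policy(cfg$scaling$cl_exponent,
                                cfg$scaling$v_exponent,
                                cfg$scaling$ref_bw,
                                cfg$scaling$ref_plasma_volume)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>  units:", paste(unlist(x$units), collapse = " / "), "\n")
  prov <- unlist(x$provenance)
  cat("  parameters (source):\n")
  for (nm in names(x$parameters)) {
    cat(sprintf("    %-5s = %-10.5g [%s]\n", nm, x$parameters[[nm]],
                prov[[nm]]))
  }
  cat("  scenario axes:", length(x$scenario$per_kg_doses), "per-kg doses,",
      length(x$scenario$fixed_doses), "fixed doses,",
      length(x$scenario$target_concentrations), "target levels,",
      length(x$scenario$age_labels), "ages\n")
  invisible(x)
}

#' Scenario grid from a configuration
#'
#' Builds the scenario grid tibble from the axes declared in a `run_config`
#' (defaults give the canonical 560-cell grid of [default_grid()]).
#'
#' @param config A `run_config` from [load_config()].
#' @return A grid tibble as produced by [default_grid()].
#' @export
config_grid <- function(config = load_config()) {
  sc <- config$scenario
  grid <- tidyr::expand_grid(
    target_policy = c("same_concentration", "same_amount"),
    dose_policy = c("per_kg", "fixed"),
    dose_index = seq_along(sc$per_kg_doses),
    level_index = seq_along(sc$target_concentrations),
    age_label = sc$age_labels,
    model_kind = c("tmdd", "mm")
  )
  doses <- list(per_kg = sc$per_kg_doses, fixed = sc$fixed_doses)
  levels <- list(same_concentration = sc$target_concentrations,
                 same_amount = sc$target_amounts)
  grid$nominal_dose <- purrr::map2_dbl(grid$dose_policy, grid$dose_index,
                                       ~ doses[[.x]][.y])
  grid$target_level <- purrr::map2_dbl(grid$target_policy, grid$level_index,
                                       ~ levels[[.x]][.y])
  dplyr::arrange(
    dplyr::select(grid, "target_policy", "dose_policy", "nominal_dose",
                  "target_level", "age_label", "model_kind"),
    .data$target_policy, .data$dose_policy, .data$nominal_dose,
    dplyr::desc(.data$target_level), .data$age_label, .data$model_kind
  )
}

#' Write a result table to CSV
#'
#' Deterministic, full-precision CSV output (shortest round-trip float
#' representation; re-reading reproduces the doubles bit-exactly) with fixed
#' column order. Rerunning the producing pipeline on the same config yields a
#' byte-identical file.
#'
#' @param table A tibble (scenario table, NCA rows, or profile).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  tryCatch(
    readr::write_csv(tibble::as_tibble(table), path, progress = FALSE),
    error = function(e) {
      stop("failed to write table to '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  invisible(path)
}
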