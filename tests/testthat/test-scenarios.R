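test_that("default grid enumerates the canonical axes", {
  g <- default_grid()
  cells <- dplyr::distinct(g, target_policy, dose_policy, nominal_dose,
                           target_level, age_label)
  expect_equal(nrow(cells), 560)
  expect_equal(nrow(g), 2 * nrow(cells)) # each cell under both model kinds
  expect_equal(nrow(dplyr::distinct(g)), nrow(g))
  conc_axis <- sort(unique(g$target_level[g$target_policy ==
                                            "same_concentration"]))
  expect_true(1.74 %in% conc_axis)
  expect_equal(length(conc_axis), 7)
  amt_axis <- unique(g$target_level[g$target_policy == "same_amount"])
  expect_true(all(c(19.5, 4.87, 0.005) %in% amt_axis))
  perkg <- unique(g$nominal_dose[g$dose_policy == "per_kg"])
  expect_equal(sort(perkg) * 1e6 / 150000,
               c(10 / 3, 20 / 3, 40 / 3, 20, 30))
  expect_equal(sort(unique(g$nominal_dose[g$dose_policy == "fixed"])),
               c(35, 70, 140, 210, 315))
  # config-driven grid with defaults matches the canonical one
  expect_equal(as.data.frame(config_grid(load_config())), as.data.frame(g))
})

slice_grid <- function(...) dplyr::filter(default_grid(), ...)

test_that("the 18-year rows are their own exposure reference", {
  tb <- run_grid(slice_grid(target_policy == "same_concentration",
                            dose_policy == "per_kg",
                            target_level == 1.74, nominal_dose == 1,
                            model_kind == "tmdd"))
  expect_equal(tb$auc_ratio_vs_18y[tb$age_label == "18y"], 100)
  expect_true(all(tb$flag == "ok"))
  # per-kg dosing: dose and V1 both scale with BW, so C0 matches across ages
  expect_equal(tb$cmax[tb$age_label == "2y"], tb$cmax[tb$age_label == "18y"],
               tolerance = 1e-6)
})

test_that("an exactly-linear construction gives identical child and adult exposure", {
  # kon = 0 (no target route) and CL exponent 1: dose and clearance both
  # scale linearly with BW, so AUC ratios are exactly 100%
  g <- slice_grid(target_policy == "same_concentration",
                  dose_policy == "per_kg", target_level == 1.74,
                  model_kind == "tmdd", nominal_dose %in% c(0.5, 4.5))
  tb <- run_grid(g, adult_params = linear_params(),
                 spolicy = scaling_policy(cl_exponent = 1, v_exponent = 1))
  expect_equal(tb$auc_ratio_vs_18y, rep(100, nrow(tb)), tolerance = 1e-4)
})

test_that("fixed dosing yields Cmax strictly decreasing with age", {
  tb <- run_grid(slice_grid(target_policy == "same_concentration",
                            dose_policy == "fixed", target_level == 1.74,
                            nominal_dose == 140, model_kind == "tmdd"))
  ord <- match(c("2y", "6y", "12y", "18y"), tb$age_label)
  expect_true(all(diff(tb$cmax[ord]) < 0))
})

test_that("same-concentration per-kg AUC ratios approach 100% along the stated axes", {
  g <- slice_grid(target_policy == "same_concentration",
                  dose_policy == "per_kg", model_kind == "tmdd",
                  nominal_dose %in% c(0.5, 4.5),
                  target_level %in% c(6.96, 1.74, 0.44, 0.027))
  tb <- run_grid(g)
  tol <- 0.5 # percent; weak monotonicity
  # increasing target concentration -> ratio rises toward 100
  for (d in c(0.5, 4.5)) {
    r <- dplyr::arrange(
      dplyr::filter(tb, age_label == "2y", nominal_dose == d), target_level
    )$auc_ratio_vs_18y
    expect_true(all(diff(r) > -tol))
    expect_true(all(r <= 100 + tol))
  }
  # decreasing dose -> ratio rises
  for (lv in c(6.96, 1.74)) {
    r <- dplyr::filter(tb, age_label == "2y", target_level == lv)
    expect_gte(r$auc_ratio_vs_18y[r$nominal_dose == 0.5] + tol,
               r$auc_ratio_vs_18y[r$nominal_dose == 4.5])
  }
  # increasing age -> ratio rises; 12-year always closer to 100 than 2-year
  r2 <- dplyr::filter(tb, target_level == 1.74, nominal_dose == 4.5)
  ratios <- r2$auc_ratio_vs_18y[match(c("2y", "6y", "12y"), r2$age_label)]
  expect_true(all(diff(ratios) > -tol))
  expect_lt(abs(100 - ratios[3]), abs(100 - ratios[1]))
})

test_that("12-year exposure sits closer to the adult reference than 2-year in all four scenarios", {
  g <- dplyr::filter(default_grid(), model_kind == "tmdd",
                     target_level %in% c(1.74, 4.87),
                     nominal_dose %in% c(1, 70),
                     age_label %in% c("2y", "12y", "18y"))
  tb <- run_grid(g)
  by_scen <- dplyr::group_split(tb, target_policy, dose_policy)
  expect_equal(length(by_scen), 4)
  for (sc in by_scen) {
    d2 <- abs(100 - sc$auc_ratio_vs_18y[sc$age_label == "2y"])
    d12 <- abs(100 - sc$auc_ratio_vs_18y[sc$age_label == "12y"])
    expect_lt(d12, d2)
  }
})

test_that("MM and full models agree in the linear regime and are compared per key", {
  g <- slice_grid(target_policy == "same_concentration",
                  dose_policy == "per_kg", nominal_dose == 4.5,
                  target_level == 0.0017, age_label %in% c("2y", "18y"))
  tb <- run_grid(g)
  cmp <- compare_mm_full(tb)
  expect_equal(nrow(cmp), 2)
  expect_equal(cmp$mm_vs_full_ratio, rep(100, 2), tolerance = 0.03)
  expect_false(any(cmp$flagged))
  # identical AUCs by construction -> exactly 100
  fake <- tb
  fake$auc_ratio_vs_18y <- 80
  expect_equal(compare_mm_full(fake)$mm_vs_full_ratio, rep(100, 2))
})

test_that("failed cells are recorded, not dropped", {
  g <- slice_grid(target_policy == "same_concentration",
                  dose_policy == "per_kg", nominal_dose == 0.5,
                  target_level == 1.74, age_label == "2y")
  # kon = 0 makes the MM reduction impossible: the mm cell must error out
  tb <- run_grid(g, adult_params = linear_params())
  expect_equal(nrow(tb), 2)
  mmrow <- tb[tb$model_kind == "mm", ]
  expect_match(mmrow$flag, "error")
  expect_true(is.na(mmrow$auc_0_inf))
})

test_that("scenario tables are deterministic and round-trip through CSV", {
  g <- slice_grid(target_policy == "same_amount", dose_policy == "fixed",
                  nominal_dose == 70, target_level == 4.87,
                  age_label %in% c("2y", "18y"))
  t1 <- run_grid(g)
  t2 <- run_grid(g)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_table(t1, f1); write_table(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- readr::read_csv(f1, show_col_types = FALSE)
  expect_equal(back$auc_0_inf, t1$auc_0_inf)
})
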