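test_that("mono-exponential profiles integrate to C0/lambda", {
  t <- c(0, exp(seq(log(0.01), log(60), length.out = 120)))
  c0 <- 50; lam <- 0.2
  prof <- tibble::tibble(time = t, conc = c0 * exp(-lam * t))
  res <- auc_0_inf(prof)
  expect_equal(res$auc_0_inf, c0 / lam, tolerance = 1e-3)
  expect_equal(res$lambda_z, lam, tolerance = 1e-6)
  expect_equal(res$cmax, c0)
  # linearity: doubling the profile doubles every AUC component
  prof2 <- dplyr::mutate(prof, conc = 2 * conc)
  res2 <- auc_0_inf(prof2)
  expect_equal(res2$auc_0_last, 2 * res$auc_0_last)
  expect_equal(res2$auc_0_inf, 2 * res$auc_0_inf)
})

test_that("linear-model AUC matches Dose/CL within 0.5%", {
  p <- linear_params()
  reg <- build_regimen(1, "per_kg", adult70)
  res <- auc_0_inf(simulate_tmdd(p, reg))
  expect_equal(res$auc_0_inf, reg$molar_dose / cl_linear(p),
               tolerance = 0.005)
  expect_equal(res$flag, "ok")
})

test_that("NCA trapezoid agrees with high-resolution quadrature", {
  reg <- build_regimen(1, "per_kg", subject("2y"))
  coarse <- auc_0_inf(simulate_tmdd(ref, reg))
  dense_grid <- sort(unique(c(default_time_grid(240),
                              exp(seq(log(0.001), log(240), length.out = 2000)))))
  fine <- simulate_tmdd(ref, reg, grid = dense_grid)
  fine_auc <- sum(diff(fine$time) *
                    (fine$conc[-1] + fine$conc[-nrow(fine)]) / 2)
  expect_equal(coarse$auc_0_inf, fine_auc, tolerance = 0.005)
})

test_that("clearance partition splits total into linear and target routes", {
  # constructed arithmetic: AUC chosen so CL_linear is half of CL_TOT
  p <- linear_params()
  d <- 100
  auc <- d / (cl_linear(p) / 0.5)
  part <- clearance_partition(d, auc, p)
  expect_equal(part$cl_fraction, 0.5)
  # linear simulation: no target route
  reg <- build_regimen(1, "per_kg", adult70)
  res <- auc_0_inf(simulate_tmdd(p, reg))
  part_lin <- clearance_partition(reg$molar_dose, res, p)
  expect_lt(part_lin$cl_fraction, 0.01)
  expect_gte(part_lin$cl_tmdd, 0)
})

test_that("clearance fraction shrinks toward zero as dose grows", {
  fracs <- sapply(c(0.5, 1, 2, 3, 4.5, 20, 100), function(d) {
    reg <- build_regimen(d, "per_kg", adult70)
    sim <- simulate_tmdd(ref, reg)
    clearance_partition(reg$molar_dose, auc_0_inf(sim), ref)$cl_fraction
  })
  expect_true(all(diff(fracs) < 0))
  expect_lt(fracs[length(fracs)], 0.05)
})

test_that("occupancy duration interpolates crossings on a tent profile", {
  # rises through 0.9 at t = 2, falls back through it at t = 12
  prof <- tibble::tibble(time = c(0, 4, 10, 14),
                         occupancy = c(0.5, 1.3, 1.3, 0.5) * 0.75)
  # occ: 0.375, 0.975, 0.975, 0.375; crossings at 0.9:
  # up: 4 * (0.9-0.375)/0.6 = 3.5; down: 10 + 4*(0.975-0.9)/0.6 = 10.5
  expect_equal(occupancy_duration(prof, 0.9), 7.0)
  tent <- tibble::tibble(time = c(0, 7, 14),
                         occupancy = c(0.62, 1.6, 0.62))
  # crosses 0.9 at t = 2 and t = 12 by linear interpolation
  expect_equal(occupancy_duration(tent, 0.9), 10.0)
  expect_equal(occupancy_duration(tent, 0), 14)
  low <- tibble::tibble(time = c(0, 5, 10), occupancy = c(0.1, 0.2, 0.1))
  expect_equal(occupancy_duration(low, 0.9), 0)
})

test_that("occupancy duration grows with dose", {
  days <- sapply(c(0.5, 1, 2, 4.5), function(d) {
    sim <- simulate_tmdd(ref, build_regimen(d, "per_kg", subject("2y")))
    occupancy_duration(sim)
  })
  expect_true(all(diff(days) > 0))
})

test_that("exposure ratios behave like percent ratios", {
  expect_equal(auc_ratio(10, 10), 100)
  expect_equal(auc_ratio(5, 10), 50)
  expect_equal(auc_ratio(3.2, 7.7) * auc_ratio(7.7, 3.2), 100^2)
  expect_error(auc_ratio(1, 0), "positive")
})

test_that("degenerate profiles are rejected with clear errors", {
  flat <- tibble::tibble(time = 0:10, conc = rep(0, 11))
  expect_error(auc_0_inf(flat), "not estimable|all-zero")
  short <- tibble::tibble(time = 0:2, conc = c(1, 0, 0))
  expect_error(auc_0_inf(short), "not estimable")
})
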