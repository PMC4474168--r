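test_that("allometric scaling reproduces the fixed-exponent factors", {
  pol <- scaling_policy()
  expect_equal(allometric_scale(5, 70, 0.75, pol), 5)
  expect_equal(allometric_scale(1, 12.8, 0.75, pol), 0.279630118814,
               tolerance = 1e-10)
  expect_equal(allometric_scale(1, 12.8, 1, pol), 0.182857142857,
               tolerance = 1e-10)
})

test_that("allometric scaling is multiplicative and exponent-additive", {
  pol <- scaling_policy()
  bw <- c(12.8, 21.3, 43.5, 66.1, 70, 95)
  b1 <- 0.4; b2 <- 0.35
  expect_equal(
    allometric_scale(allometric_scale(2, bw, b1, pol), bw, b2, pol) /
      allometric_scale(1, bw, b1, pol) / allometric_scale(1, bw, b2, pol),
    rep(2, length(bw))
  )
  expect_equal(allometric_scale(1, bw, b1 + b2, pol),
               allometric_scale(1, bw, b1, pol) *
                 allometric_scale(1, bw, b2, pol))
})

test_that("parameter scaling follows clearance/volume exponents and fixes micro constants", {
  s <- subject("2y")
  sc <- scale_parameters(ref, s)
  expect_equal(sc$v1, ref$v1 * 0.182857142857, tolerance = 1e-10)
  expect_equal(sc$v2, ref$v2 * 0.182857142857, tolerance = 1e-10)
  expect_equal(cl_linear(sc), cl_linear(ref) * 0.279630118814,
               tolerance = 1e-10)
  expect_equal(sc$kel / ref$kel, 1.52922721227, tolerance = 1e-10)
  expect_equal(sc$q, ref$q * 0.279630118814, tolerance = 1e-10)
  for (nm in c("kon", "koff", "kint", "kdeg")) {
    expect_identical(sc[[nm]], ref[[nm]])
  }
  # reference weight: identity
  expect_equal(unclass(scale_parameters(ref, adult70))[1:9],
               unclass(ref)[1:9])
})

test_that("plasma volume scales linearly from 2.8 l at 70 kg", {
  expect_equal(plasma_volume(70), 2.8)
  expect_equal(plasma_volume(12.8), 0.512)
  expect_equal(plasma_volume(66.1), 2.644)
})

test_that("target policies anchor concentration or whole-body amount", {
  same_amt <- target_policy("same_amount", adult_amount = 4.87)
  p2 <- apply_target_policy(ref, subject("2y"), same_amt)
  expect_equal(steady_state_target(p2), 9.51171875, tolerance = 1e-9)
  p18 <- apply_target_policy(ref, subject("18y"), same_amt)
  expect_equal(steady_state_target(p18), 1.84190620272, tolerance = 1e-9)

  same_conc <- target_policy("same_concentration", adult_r0 = 1.74)
  for (lab in names(age_group_weights)) {
    pc <- apply_target_policy(ref, subject(lab), same_conc)
    expect_equal(steady_state_target(pc), 1.74)
  }
  expect_error(target_policy("same_amount", adult_r0 = 1), "adult_amount")
})

test_that("amount and concentration anchors round-trip through plasma volume", {
  expect_equal(target_amount_from_concentration(1.74, 70), 4.872)
  expect_equal(target_amount_from_concentration(6.96, 70), 19.488)
  expect_equal(target_amount_from_concentration(0, 12.8), 0)
  for (bw in c(12.8, 21.3, 43.5, 66.1, 70)) {
    amt <- 4.87
    pol <- target_policy("same_amount", adult_amount = amt)
    p <- apply_target_policy(ref, subject("custom", bw), pol)
    expect_equal(
      target_amount_from_concentration(steady_state_target(p), bw), amt
    )
  }
})

test_that("dose regimens convert to molar units at 150 kDa", {
  s2 <- subject("2y")
  r <- build_regimen(0.5, "per_kg", s2)
  expect_equal(r$molar_dose / s2$bw, 10 / 3, tolerance = 1e-12)
  expect_equal(build_regimen(4.5, "per_kg", s2)$molar_dose / s2$bw, 30)
  expect_equal(build_regimen(35, "fixed", s2)$molar_dose, 233.333333333,
               tolerance = 1e-9)
  # fixed and per-kg coincide at the reference weight
  expect_equal(build_regimen(35, "fixed", adult70)$molar_dose,
               build_regimen(0.5, "per_kg", adult70)$molar_dose)
  expect_equal(build_regimen(315, "fixed", adult70)$molar_dose,
               build_regimen(4.5, "per_kg", adult70)$molar_dose)
})

test_that("policy constructors validate their ranges", {
  expect_error(scaling_policy(cl_exponent = -1), "exponents")
  expect_error(scaling_policy(cl_exponent = 2.4), "exponents")
  expect_error(subject("7y"), "unknown age label")
  expect_error(build_regimen(-1, "per_kg", adult70), "non-negative")
})
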