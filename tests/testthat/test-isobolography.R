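mk_point <- function(dose, se, df = 16, arm = "X", p = 50)
  otoisobol:::new_htdd(arm, p, dose, se, df, "delta")

test_that("the additive dose follows the Loewe closed form", {
  A <- mk_point(1006, 95, arm = "AMI+VEH")   # co-drug alone
  B <- mk_point(63.24, 4.68, arm = "FUR+VEH") # variable drug alone
  ap <- additive_point(B, A, d_fix = 500)
  expect_equal(ap$dose, 63.24 * (1 - 500 / 1006), tolerance = 1e-9)
  expect_equal(ap$dose, 31.80857, tolerance = 1e-4)

  # reversed axes: AMI variable, FUR fixed at 30
  A2 <- mk_point(63.24, 4.68, arm = "FUR+VEH")
  B2 <- mk_point(1006, 95, arm = "AMI+VEH")
  ap2 <- additive_point(B2, A2, d_fix = 30)
  expect_equal(ap2$dose, 1006 * (1 - 30 / 63.24), tolerance = 1e-9)
  expect_equal(ap2$dose, 528.7697, tolerance = 1e-3)

  # d_fix = 0 degenerates to the single-drug point
  ap0 <- additive_point(B, A, d_fix = 0)
  expect_equal(ap0$dose, 63.24, tolerance = 1e-12)
  expect_equal(ap0$se, 4.68, tolerance = 1e-12)
})

test_that("additive-dose variance propagates both components", {
  A <- mk_point(1006, 95); B <- mk_point(63.24, 4.68)
  ap <- additive_point(B, A, d_fix = 500)
  w <- 1 - 500 / 1006
  v_hand <- w^2 * 4.68^2 + (63.24 * 500 / 1006^2)^2 * 95^2
  expect_equal(ap$se^2, v_hand, tolerance = 1e-9)
  # Var(A) = 0 reduces to the single-component form
  ap0 <- additive_point(B, mk_point(1006, 0), d_fix = 500)
  expect_equal(ap0$se^2, w^2 * 4.68^2, tolerance = 1e-9)
  # Satterthwaite df lies between min component df and their sum
  expect_gt(ap$df, min(16, 16) - 1e-9)
  expect_lte(ap$df, 32)
})

test_that("additive dose is linear and decreasing in the fixed dose", {
  A <- mk_point(1006, 95); B <- mk_point(63.24, 4.68)
  d <- c(0, 100, 250, 503, 750)
  doses <- vapply(d, function(x) additive_point(B, A, x)$dose, 0)
  expect_true(all(diff(doses) < 0))
  # linearity: second differences vanish
  expect_equal(diff(doses, differences = 2),
               diff(63.24 * (1 - d / 1006), differences = 2),
               tolerance = 1e-9)
  # at d_fix = A/2 it equals B/2
  expect_equal(additive_point(B, A, 503)$dose, 63.24 / 2, tolerance = 1e-9)
  expect_error(additive_point(B, A, 1006), "infeasible")
  expect_error(additive_point(B, mk_point(1006, 95, p = 20), 500),
               "same effect level")
})

test_that("point comparison reproduces direct t arithmetic", {
  # experimental combination vs modifier-treated combination, 6-animal groups
  b <- list(dose = 37.35, se = 4.10, df = 5)
  c_ <- list(dose = 38.52, se = 4.26, df = 5)
  res <- compare_points(b, c_, mode = "pooled")
  t_hand <- abs(37.35 - 38.52) / sqrt(4.10^2 + 4.26^2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 10)
  expect_equal(res$p_value, 2 * pt(-t_hand, 10), tolerance = 1e-12)
  expect_equal(res$t, 0.198, tolerance = 1e-3)
  expect_equal(res$p_value, 0.847, tolerance = 1e-3)

  # symmetric in its arguments
  rev <- compare_points(c_, b, mode = "pooled")
  expect_equal(rev$t, res$t)
  expect_equal(rev$df, res$df)
  expect_equal(rev$p_value, res$p_value)

  # identical points
  same <- compare_points(b, b, mode = "welch")
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # Welch df matches the Satterthwaite formula
  w <- compare_points(list(dose = 46.73, se = 4.39, df = 16),
                      list(dose = 31.81, se = 3.8, df = 20.5),
                      mode = "welch")
  v1 <- 4.39^2; v2 <- 3.8^2
  expect_equal(w$df, (v1 + v2)^2 / (v1^2 / 16 + v2^2 / 20.5),
               tolerance = 1e-9)
  expect_true(w$significant)

  expect_error(compare_points(list(dose = 1, se = 0, df = 5),
                              list(dose = 2, se = 0, df = 5)),
               "degenerate")
})

test_that("interaction classification follows the sign and significance", {
  A <- mk_point(31.81, 2.5, df = 12)
  # experimental well above additive -> antagonistic
  res <- classify_interaction(A, mk_point(46.73, 2.0, df = 16))
  expect_identical(res$call_label, "antagonistic")
  # well below -> synergistic
  expect_identical(classify_interaction(A, mk_point(18, 2.0, df = 16))$call_label,
                   "synergistic")
  # exactly equal -> additive
  expect_identical(classify_interaction(A, mk_point(31.81, 2.0))$call_label,
                   "additive")
  # large but non-significant difference -> additive (NS)
  expect_identical(classify_interaction(mk_point(31.81, 40, df = 12),
                                        mk_point(46.73, 40))$call_label,
                   "additive")
})

test_that("classification is invariant to a common dose rescaling", {
  A <- mk_point(31.81, 2.5, df = 12); B <- mk_point(46.73, 2.0, df = 16)
  base <- classify_interaction(A, B)
  for (k in c(0.1, 3.7)) {
    sc <- classify_interaction(mk_point(31.81 * k, 2.5 * k, df = 12),
                               mk_point(46.73 * k, 2.0 * k, df = 16))
    expect_equal(sc$t, base$t, tolerance = 1e-12)
    expect_equal(sc$p_value, base$p_value, tolerance = 1e-12)
    expect_identical(sc$call_label, base$call_label)
  }
})

test_that("modifier comparison uses pooled df and labels effectiveness", {
  B <- list(dose = 37.35, se = 1.2, df = 5)
  C <- list(dose = 48.52, se = 1.3, df = 5)
  res <- modifier_effect(B, C)
  expect_equal(res$df, 10)
  expect_identical(res$call_label, "modifier-effective")
  expect_identical(modifier_effect(B, list(dose = 38, se = 1.3, df = 5))$call_label,
                   "modifier-ineffective")
})

test_that("effect-subtraction variant gives a finite alternative point", {
  specs <- ami_fur_scenarios("both")
  cfg <- synth_config(specs, noise_sd = 8, seed = 17)
  rec <- generate_animals(cfg)
  fits <- suppressWarnings(lapply(split(rec, rec$arm), fit_arm))
  B <- estimate_htdd(fits[["FUR+VEH"]], 50, warn = FALSE)
  A <- estimate_htdd(fits[["AMI+VEH"]], 50, warn = FALSE)
  ap <- additive_point(B, A, d_fix = 500, variant = "effect-subtraction",
                       variable_fit = fits[["FUR+VEH"]],
                       codrug_fit = fits[["AMI+VEH"]])
  expect_true(is.finite(ap$dose) && ap$dose > 0)
  expect_true(is.finite(ap$se) && ap$se > 0)
  expect_identical(ap$variant, "effect-subtraction")
  # the two variants agree at d_fix = 0 on the dose scale
  ap_l0 <- additive_point(B, A, 0)
  ap_e0 <- additive_point(B, A, 0, variant = "effect-subtraction",
                          variable_fit = fits[["FUR+VEH"]],
                          codrug_fit = fits[["AMI+VEH"]])
  expect_equal(ap_e0$dose, ap_l0$dose, tolerance = 1e-9)
  expect_error(additive_point(B, A, 500, variant = "effect-subtraction"),
               "drfit")
})

test_that("isobologram rendering writes a plot file", {
  A <- mk_point(1006, 95, arm = "AMI+VEH")
  B <- mk_point(63.24, 4.68, arm = "FUR+VEH")
  ap <- additive_point(B, A, d_fix = 500)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, width = 400, height = 400)
  plot_isobologram(A, B, fixed_axis = "x", d_fix = 500,
                   A = ap, B = mk_point(46.73, 4.39),
                   C = mk_point(53.64, 4.13))
  grDevices::dev.off()
  expect_gt(file.info(f)$size, 0)
})
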