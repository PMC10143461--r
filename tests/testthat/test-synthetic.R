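test_that("curve calibration passes exactly through both anchors", {
  cv <- calibrate_curve(10, 100)
  expect_equal(cv$b, 30)
  expect_equal(cv$a, -10)
  for (anchors in list(c(797, 1006), c(56.25, 63.24), c(37.35, 46.73))) {
    cv <- calibrate_curve(anchors[1], anchors[2])
    expect_equal(cv$a + cv$b * log10(anchors[1]), 20, tolerance = 1e-9)
    expect_equal(cv$a + cv$b * log10(anchors[2]), 50, tolerance = 1e-9)
    expect_gt(cv$b, 0)
  }
  expect_error(calibrate_curve(100, 100), "invalid calibration")
  expect_error(calibrate_curve(120, 100), "invalid calibration")
  expect_error(calibrate_curve(-1, 100), "positive")
})

test_that("noise-free generation reproduces the latent line exactly", {
  cfg <- synth_config(
    list(synth_arm("A", structure(list(a = -10, b = 20),
                                  class = "oto_curve"),
                   variable_drug = "AMI", doses = c(10, 100, 1000))),
    n_per_dose = 2, noise_sd = 0, seed = 3)
  rec <- generate_animals(cfg)
  expect_equal(sort(unique(rec$effect)), c(10, 30, 50), tolerance = 1e-9)
  expect_equal(rec$effect, rec$latent_effect, tolerance = 1e-12)
})

test_that("generation is seed-deterministic and bounded", {
  specs <- ami_fur_scenarios("FUR")
  cfg <- synth_config(specs, noise_sd = 8, seed = 123)
  r1 <- generate_animals(cfg)
  r2 <- generate_animals(cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$effect >= 0 & r1$effect <= 100))
  expect_true(all(r1$post_dB <= 90 + 1e-12))
  expect_true(all(r1$pre_dB >= 25 & r1$pre_dB <= 45))
  # different seeds differ
  cfg2 <- synth_config(specs, noise_sd = 8, seed = 124)
  expect_false(identical(generate_animals(cfg2), r1))
})

test_that("config invariants are enforced", {
  cv <- calibrate_curve(10, 100)
  expect_error(synth_arm("A", cv, "AMI", doses = c(10, 100)), "at least 3")
  expect_error(synth_arm("A", cv, "AMI", doses = c(100, 10, 1000)),
               "strictly")
  expect_error(synth_arm("A", structure(list(a = 10, b = -5),
                                        class = "oto_curve"), "AMI",
                         doses = c(1, 2, 3)), "slope")
  expect_error(synth_config(list(), n_per_dose = 6), "at least one arm")
  expect_error(synth_config(list(synth_arm("A", cv, "AMI")),
                            n_per_dose = 1), "n_per_dose")
})

test_that("default dose design brackets both target levels", {
  anchors <- ami_fur_anchors()
  for (i in which(anchors$calibratable)) {
    cv <- calibrate_curve(anchors$htdd20[i], anchors$htdd50[i])
    spec <- synth_arm(anchors$arm[i], cv, anchors$set[i])
    eff <- cv$a + cv$b * log10(range(spec$doses))
    expect_lt(eff[1], 20)
    expect_gt(eff[2], 50)
    expect_true(all(eff > 0 & eff < 100))
  }
})

test_that("interaction scenarios impose the stated ground truth", {
  rec <- generate_interaction_scenario("additive", ami_veh, fur_veh,
                                       d_fix = 30, p = 20, seed = 5)
  truth <- attr(rec, "truth")
  loewe <- 797 * (1 - 30 / 56.25)  # variable AMI, co-drug FUR at 30
  expect_equal(truth$loewe_htdd, loewe, tolerance = 1e-9)
  expect_equal(truth$combo_htdd, loewe, tolerance = 1e-9)

  ant <- attr(generate_interaction_scenario("antagonistic", ami_veh, fur_veh,
                                            d_fix = 30, p = 20, seed = 5),
              "truth")
  expect_equal(ant$combo_htdd, 2 * loewe, tolerance = 1e-9)
  syn <- attr(generate_interaction_scenario("synergistic", ami_veh, fur_veh,
                                            d_fix = 30, p = 20, seed = 5),
              "truth")
  expect_equal(syn$combo_htdd, 0.5 * loewe, tolerance = 1e-9)

  # degenerate factor 1 in antagonistic mode == additive mode
  a <- generate_interaction_scenario("additive", ami_veh, fur_veh,
                                     d_fix = 30, p = 20, seed = 9)
  b <- generate_interaction_scenario("antagonistic", ami_veh, fur_veh,
                                     d_fix = 30, p = 20, factor = 1,
                                     seed = 9)
  attr(a, "truth") <- attr(b, "truth") <- NULL
  expect_identical(a, b)

  # fixed dose at/above the co-drug HTDDp is infeasible
  expect_error(generate_interaction_scenario("additive", ami_veh, fur_veh,
                                             d_fix = 60, p = 20),
               "infeasible")
})

test_that("non-monotone anchors are flagged and excluded from calibration", {
  anchors <- ami_fur_anchors()
  expect_identical(anchors$arm[!anchors$calibratable],
                   "AMI+FUR(30)+NAC(500)")
  expect_length(ami_fur_scenarios("both"), 7)
  full <- ami_fur_scenarios("both", include_infeasible = TRUE)
  expect_length(full, 8)
  # the stand-in arm still hits its HTDD50 anchor
  cv <- full[["AMI+FUR(30)+NAC(500)"]]$curve
  expect_equal(cv$a + cv$b * log10(513), 50, tolerance = 1e-9)
})
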