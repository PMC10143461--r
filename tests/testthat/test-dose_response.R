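test_that("a noise-free line is recovered exactly", {
  rec <- noiseless_records()
  fit <- suppressWarnings(fit_arm(rec))
  expect_s3_class(fit, "drfit")
  expect_equal(fit$a, -10, tolerance = 1e-9)
  expect_equal(fit$b, 20, tolerance = 1e-9)
  expect_equal(fit$s2, 0, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), c(-10, 20), tolerance = 1e-9)
  expect_equal(fit$df, fit$n - 2)
  expect_equal(predict(fit, 100), 30, tolerance = 1e-9)
})

test_that("OLS matches the brute-force normal-equations oracle", {
  fx <- noisy_fixture()
  fit <- suppressWarnings(fit_arm(fx))
  oracle <- ols_oracle(fx$dose_mg_kg, fx$effect)
  expect_equal(fit$a, oracle$a, tolerance = 1e-10)
  expect_equal(fit$b, oracle$b, tolerance = 1e-10)
  expect_equal(unname(fit$cov), unname(oracle$cov), tolerance = 1e-10)
  expect_equal(fit$s2, oracle$s2, tolerance = 1e-10)

  # duplicating every animal leaves the coefficients unchanged and scales
  # the covariance exactly as the OLS formula prescribes
  dup <- rbind(fx, fx)
  fit2 <- suppressWarnings(fit_arm(dup))
  oracle2 <- ols_oracle(dup$dose_mg_kg, dup$effect)
  expect_equal(fit2$a, oracle$a, tolerance = 1e-10)
  expect_equal(fit2$b, oracle$b, tolerance = 1e-10)
  expect_equal(unname(fit2$cov), unname(oracle2$cov), tolerance = 1e-10)
  expect_equal(fit2$s2, oracle2$s2, tolerance = 1e-10)
})

test_that("degenerate designs are refused", {
  rec <- noiseless_records()
  two <- rec[rec$dose_mg_kg %in% c(10, 100), ]
  expect_error(fit_arm(two), "at least 3 distinct doses")
  one <- rec; one$dose_mg_kg <- 100
  expect_error(fit_arm(one), "at least 3 distinct doses")
  zero <- rec; zero$dose_mg_kg[1] <- 0
  expect_error(fit_arm(zero), "positive")
})

test_that("bracketing violations are flagged with a warning, not an error", {
  # steep line: effects 5/50/95 at the three doses still bracket; shift the
  # intercept so the lowest fitted effect exceeds 20%
  rec <- noiseless_records()
  rec$effect <- rec$effect + 25   # effects 35/55/75: lower bound not bracketed
  expect_warning(fit <- fit_arm(rec), "bracket")
  expect_true(fit$extrapolating)
})

test_that("HTDD inversion matches its closed form and orders by level", {
  rec <- noiseless_records()
  fit <- suppressWarnings(fit_arm(rec))
  h20 <- estimate_htdd(fit, 20)
  expect_equal(h20$dose, 10^1.5, tolerance = 1e-9)
  expect_equal(h20$se, 0, tolerance = 1e-9)
  expect_equal(h20$df, fit$n - 2)
  h50 <- estimate_htdd(fit, 50, warn = FALSE)
  expect_equal(h50$dose, 1000, tolerance = 1e-9)
  expect_lt(h20$dose, h50$dose)

  # monotone in p for any fitted arm with positive slope
  fx <- suppressWarnings(fit_arm(noisy_fixture()))
  doses <- vapply(c(10, 20, 35, 50, 70),
                  function(p) estimate_htdd(fx, p, warn = FALSE)$dose, 0)
  expect_true(all(diff(doses) > 0))

  expect_error(estimate_htdd(fit, 0), "strictly inside")
  expect_error(estimate_htdd(fit, 100), "strictly inside")
  down <- fit; down$b <- -2
  expect_error(estimate_htdd(down, 20), "non-ototoxic")
})

test_that("delta-method SE matches the hand formula on a noisy fit", {
  fit <- suppressWarnings(fit_arm(noisy_fixture()))
  p <- 20
  g <- (p - fit$a) / fit$b
  vg <- (fit$cov[1, 1] + g^2 * fit$cov[2, 2] + 2 * g * fit$cov[1, 2]) /
    fit$b^2
  expect_equal(estimate_htdd(fit, p, warn = FALSE)$se,
               log(10) * 10^g * sqrt(vg), tolerance = 1e-12)
})

test_that("per-animal HTDDs follow the common-slope conversion", {
  rec <- noiseless_records()
  fit <- suppressWarnings(fit_arm(rec))
  # zero residuals: every animal's value equals the arm estimate
  vals <- per_animal_htdd(fit, p = 20)
  expect_equal(vals, rep(10^1.5, fit$n), tolerance = 1e-9)

  # an animal one slope-unit (b%) above the line implies HTDD / 10
  one <- rec[1, ]
  one$effect <- predict(fit, one$dose_mg_kg) + fit$b
  expect_equal(per_animal_htdd(fit, one, p = 20), 10^1.5 / 10,
               tolerance = 1e-9)

  # geometric mean over animals approximates the arm estimate
  fx <- suppressWarnings(fit_arm(noisy_fixture()))
  gm <- exp(mean(log(per_animal_htdd(fx, p = 20))))
  expect_equal(log(gm), log(estimate_htdd(fx, 20, warn = FALSE)$dose),
               tolerance = 0.05)

  # dose subsetting restricts to the requested groups
  mid <- per_animal_htdd(fit, p = 20, doses = 100)
  expect_length(mid, 2)
})

test_that("htdd_table reports every arm at every level", {
  specs <- ami_fur_scenarios("FUR")
  cfg <- synth_config(specs, noise_sd = 8, seed = 21)
  rec <- generate_animals(cfg)
  fits <- suppressWarnings(lapply(split(rec, rec$arm), fit_arm))
  tab <- htdd_table(fits, p = c(20, 50))
  expect_setequal(tab$arm, names(specs))
  expect_true(all(tab$htdd20 < tab$htdd50))
  expect_true(all(tab$se20 > 0 & tab$se50 > 0))
})

test_that("simulated arms recover the calibration slope", {
  cv <- calibrate_curve(797, 1006)
  r <- mc_htdd_recovery(797, 1006, p = 50, nsim = 200, seed = 31)
  # Monte-Carlo mean within ~2 MC SEs of the truth
  mc_se <- r$sd / sqrt(200)
  expect_lt(abs(r$mean - 1006), 3 * mc_se + 0.02 * 1006)
})
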