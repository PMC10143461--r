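# Shared fixtures built in code.

# Noise-free records on the line E = -10 + 20 * log10(dose).
noiseless_records <- function(doses = c(10, 100, 1000), n = 2) {
  cfg <- synth_config(
    list(synth_arm("LINE", structure(list(a = -10, b = 20),
                                     class = "oto_curve"),
                   variable_drug = "AMI", doses = doses)),
    n_per_dose = n, noise_sd = 0, seed = 7)
  generate_animals(cfg)
}

# A 6-point noisy fixture (2 animals per dose) with hand-set effects.
noisy_fixture <- function() {
  data.frame(
    arm = "NOISY", variable_drug = "AMI",
    dose_mg_kg = rep(c(10, 100, 1000), each = 2),
    effect = c(12, 8, 33, 27, 52, 48),
    stringsAsFactors = FALSE
  )
}

# Brute-force OLS of effect on log10(dose) via explicit normal equations.
ols_oracle <- function(doses, effects) {
  X <- cbind(1, log10(doses))
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% effects)
  res <- effects - X %*% beta
  s2 <- sum(res^2) / (length(effects) - 2)
  list(a = beta[1], b = beta[2], cov = s2 * solve(XtX), s2 = s2)
}

# Anchor pairs used throughout: published single-drug and combination arms.
ami_veh <- list(drug = "AMI", htdd20 = 797, htdd50 = 1006)
fur_veh <- list(drug = "FUR", htdd20 = 56.25, htdd50 = 63.24)
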