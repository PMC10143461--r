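#' Monte-Carlo parameter-recovery study for HTDD estimation
#'
#' Repeatedly simulates one treatment arm from a log-linear curve calibrated
#' to a pair of HTDD anchors (the published study design: 3 doses, 6 animals
#' per dose, Gaussian effect noise), re-estimates the HTDDs from each
#' simulated dataset, and summarises the sampling distribution. Used to
#' check that the estimator recovers the calibration truth under the study's
#' design.
#'
#' @param htdd20,htdd50 calibration anchors, mg/kg.
#' @param p effect levels to estimate.
#' @param nsim number of simulated datasets.
#' @param n_per_dose animals per dose group.
#' @param noise_sd effect noise SD, percent.
#' @param seed optional seed.
#' @return list with \code{mean} (named mean estimate per level),
#'   \code{sd} (Monte-Carlo SDs) and the \code{nsim x length(p)} matrix of
#'   \code{estimates}.
#' @export
mc_htdd_recovery <- function(htdd20, htdd50, p = c(20, 50), nsim = 500,
                             n_per_dose = 6, noise_sd = 8, seed = NULL) {
  curve <- calibrate_curve(htdd20, htdd50)
  spec <- synth_arm("sim", curve, variable_drug = "AMI")
  cfg <- synth_config(list(spec), n_per_dose = n_per_dose,
                      noise_sd = noise_sd)
  with_seed(seed, {
    est <- t(replicate(nsim, {
      rec <- generate_animals(cfg)
      fit <- suppressWarnings(fit_arm(rec))
      vapply(p, function(pp)
        suppressWarnings(estimate_htdd(fit, pp, warn = FALSE)$dose), 0)
    }))
    if (length(p) == 1L) est <- matrix(est, ncol = 1L)
    colnames(est) <- paste0("htdd", p)
    list(mean = colMeans(est), sd = apply(est, 2, stats::sd),
         estimates = est)
  })
}

#' Monte-Carlo calibration of the isobolographic interaction test
#'
#' Simulates the full fixed-dose interaction analysis under a known ground
#' truth: single-drug arms for the variable drug and the co-drug plus a
#' combination arm placed relative to the Loewe-additive dose (see
#' [generate_interaction_scenario()]), then runs the pipeline's A-vs-B test
#' (theoretical additive point vs experimental combination HTDD, Welch t)
#' and records the rejection/classification outcome. In \code{additive} mode
#' the rejection rate estimates the test's type-I error; in
#' \code{antagonistic}/\code{synergistic} mode its power.
#'
#' @inheritParams generate_interaction_scenario
#' @param nsim number of simulated experiments.
#' @param alpha significance level of the A-vs-B test.
#' @return list with \code{reject_rate}, the table of classification
#'   \code{calls}, and \code{nsim}.
#' @export
mc_interaction_calibration <- function(mode = c("additive", "antagonistic",
                                                "synergistic"),
                                       variable, codrug, d_fix, p = 20,
                                       factor = NULL, nsim = 1000,
                                       alpha = 0.05, n_per_dose = 6,
                                       noise_sd = 8, seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    calls <- replicate(nsim, {
      rec <- generate_interaction_scenario(
        mode, variable = variable, codrug = codrug, d_fix = d_fix, p = p,
        factor = factor, n_per_dose = n_per_dose, noise_sd = noise_sd)
      truth <- attr(rec, "truth")
      fits <- suppressWarnings(lapply(
        split(rec, rec$arm), fit_arm))
      var_alone <- paste0(variable$drug, "+VEH")
      co_alone <- paste0(codrug$drug, "+VEH")
      A <- suppressWarnings(additive_point(
        estimate_htdd(fits[[var_alone]], p, warn = FALSE),
        estimate_htdd(fits[[co_alone]], p, warn = FALSE),
        d_fix = d_fix))
      B <- suppressWarnings(
        estimate_htdd(fits[[truth$combo_arm]], p, warn = FALSE))
      classify_interaction(A, B, alpha = alpha)$call_label
    })
    list(reject_rate = mean(calls != "additive"), calls = table(calls),
         nsim = nsim)
  })
}
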