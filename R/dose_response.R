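#' Fit the log-linear dose-response curve of one treatment arm
#'
#' Fits the working model of the pipeline, ordinary least squares of the
#' percent hearing-threshold-decrease effect on \eqn{\log_{10}(dose)} across
#' individual animals:
#' \deqn{E_i = a + b \log_{10}(d_i) + \epsilon_i, \qquad \epsilon_i \sim
#' N(0, \sigma^2).}
#' Over the 20-80\% working range this line is the usable portion of the
#' sigmoidal dose-response curve; with three dose groups it is also the
#' richest model the design can support. The slope of an ototoxic drug is
#' positive (higher dose, larger threshold shift).
#'
#' The study design requires the fitted effects at the lowest and highest
#' dose to bracket the target levels (below 20\%, above 50\%) so that HTDD
#' estimation interpolates rather than extrapolates; an arm violating this is
#' still fitted but flagged and a warning is raised.
#'
#' @param records a record data frame (from [load_records()] or
#'   [generate_animals()]) with \code{dose_mg_kg} and \code{effect} columns.
#' @param arm optional arm label to subset \code{records}; by default the
#'   records must already belong to a single arm.
#' @param bracket target effect levels whose bracketing is checked.
#' @return an object of class \code{"drfit"}: a list with the arm label,
#'   coefficients \code{a} and \code{b}, their covariance matrix \code{cov},
#'   residual variance \code{s2}, animal count \code{n}, residual degrees of
#'   freedom \code{df}, the dose levels used, the extrapolation flag, and the
#'   underlying \code{lm} fit.
#' @seealso [estimate_htdd()], [per_animal_htdd()], [htdd_table()]
#' @export
fit_arm <- function(records, arm = NULL, bracket = c(20, 50)) {
  if (!is.null(arm)) records <- records[records$arm == arm, , drop = FALSE]
  if (!nrow(records)) stop("no records for arm ", arm, call. = FALSE)
  if (length(unique(records$arm)) > 1L)
    stop("records span several arms; pass `arm` or pre-subset", call. = FALSE)
  if (!all(c("dose_mg_kg", "effect") %in% names(records)))
    stop("records need dose_mg_kg and effect columns (see load_records)",
         call. = FALSE)
  d <- records$dose_mg_kg
  if (any(d <= 0)) stop("doses must be positive (mg/kg)", call. = FALSE)
  doses <- sort(unique(d))
  if (length(doses) < 3L)
    stop("design error: at least 3 distinct doses are required per ",
         "dose-response curve (arm ", unique(records$arm), " has ",
         length(doses), ")", call. = FALSE)

  x <- log10(d)
  fit <- stats::lm(records$effect ~ x)
  co <- stats::coef(fit)
  s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  # covariance from the normal equations directly; summary.lm would warn on
  # noise-free (perfect-fit) input
  X <- cbind(1, x)
  V <- s2 * chol2inv(chol(crossprod(X)))
  dimnames(V) <- list(c("(Intercept)", "x"), c("(Intercept)", "x"))

  flo <- co[[1]] + co[[2]] * log10(min(doses))
  fhi <- co[[1]] + co[[2]] * log10(max(doses))
  extrapolating <- !(flo < min(bracket) && fhi > max(bracket))
  if (extrapolating)
    warning("arm ", unique(records$arm), ": fitted effects at the extreme ",
            "doses (", round(flo, 1), "%, ", round(fhi, 1), "%) do not ",
            "bracket the ", paste(bracket, collapse = "-"), "% target ",
            "levels; HTDD estimates will extrapolate", call. = FALSE)

  structure(list(
    arm = unique(records$arm), a = co[[1]], b = co[[2]],
    cov = V, s2 = s2, n = nrow(records), df = fit$df.residual,
    doses = doses, extrapolating = extrapolating,
    convention = attr(records, "convention"), lm = fit,
    data = records
  ), class = "drfit")
}

#' @export
print.drfit <- function(x, ...) {
  cat("Log-linear dose-response fit: arm", x$arm, "\n")
  cat(sprintf("  effect = %.2f + %.2f * log10(dose)   (n = %d, df = %d)\n",
              x$a, x$b, x$n, x$df))
  cat(sprintf("  residual SD %.2f %%; doses %s mg/kg%s\n", sqrt(x$s2),
              paste(signif(x$doses, 4), collapse = ", "),
              if (x$extrapolating) "  [extrapolating]" else ""))
  invisible(x)
}

#' @export
coef.drfit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
vcov.drfit <- function(object, ...) object$cov

#' @export
residuals.drfit <- function(object, ...) stats::residuals(object$lm)

#' Predicted percent effect at new doses
#' @param object a \code{"drfit"}.
#' @param doses doses (mg/kg) at which to evaluate the fitted line.
#' @param ... unused.
#' @export
predict.drfit <- function(object, doses = object$doses, ...) {
  stopifnot(all(doses > 0))
  object$a + object$b * log10(doses)
}

#' @export
summary.drfit <- function(object, ...) {
  est <- lapply(c(20, 50), function(p)
    tryCatch(estimate_htdd(object, p, warn = FALSE),
             error = function(e) NULL))
  structure(list(fit = object, htdd = Filter(Negate(is.null), est)),
            class = "summary.drfit")
}

#' @export
print.summary.drfit <- function(x, ...) {
  print(x$fit)
  for (h in x$htdd)
    cat(sprintf("  HTDD%g = %.4g +/- %.3g mg/kg (df %d)\n",
                h$p, h$dose, h$se, h$df))
  invisible(x)
}

#' Dose-response plot of a fitted arm
#' @param x a \code{"drfit"}.
#' @param p effect levels to mark with reference lines.
#' @param ... passed to \code{plot}.
#' @export
plot.drfit <- function(x, p = c(20, 50), ...) {
  d <- x$data$dose_mg_kg
  graphics::plot(d, x$data$effect, log = "x",
                 xlab = "dose (mg/kg)", ylab = "hearing threshold decrease (%)",
                 main = x$arm, ...)
  dd <- 10^seq(log10(min(d)) - 0.05, log10(max(d)) + 0.05, length.out = 100)
  graphics::lines(dd, x$a + x$b * log10(dd))
  graphics::abline(h = p, lty = 3, col = "grey40")
  invisible(x)
}

#' Simulate effect data from a fitted arm
#'
#' Draws new per-animal effects from the fitted line plus Gaussian residual
#' noise at the arm's dose design (parametric simulation from the fit).
#'
#' @param object a \code{"drfit"}.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return a data frame with one column per simulation, rows matching
#'   \code{object$data}.
#' @export
simulate.drfit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    mu <- object$a + object$b * log10(object$data$dose_mg_kg)
    out <- replicate(nsim,
      pmin(100, pmax(0, mu + stats::rnorm(length(mu), 0, sqrt(object$s2)))))
    as.data.frame(out)
  })
}

#' Invert a dose-response fit to the HTDD at a target effect level
#'
#' The hearing-threshold-decreasing dose at level \eqn{p} is
#' \eqn{HTDD_p = 10^{g}}, \eqn{g = (p - a)/b}. Its standard error comes from
#' the delta method applied to \eqn{g}:
#' \deqn{Var(g) = \frac{Var(a) + g^2 Var(b) + 2 g\, Cov(a,b)}{b^2}, \qquad
#' SE(HTDD_p) = \ln(10)\, HTDD_p \sqrt{Var(g)},}
#' with \eqn{n - 2} residual degrees of freedom.
#'
#' @param fit a \code{"drfit"} from [fit_arm()].
#' @param p target percent effect, strictly inside (0, 100).
#' @param warn warn when the estimate extrapolates beyond the fitted effect
#'   range at the extreme doses.
#' @return an object of class \code{"htdd"}: arm, \code{p}, \code{dose}
#'   (mg/kg), \code{se}, \code{df}, and \code{method = "delta"}.
#' @examples
#' rec <- generate_animals(synth_config(
#'   list(synth_arm("AMI+VEH", calibrate_curve(797, 1006), "AMI")),
#'   noise_sd = 0, seed = 1))
#' estimate_htdd(fit_arm(rec), 20)
#' @export
estimate_htdd <- function(fit, p, warn = TRUE) {
  stopifnot(inherits(fit, "drfit"))
  if (p <= 0 || p >= 100)
    stop("target effect level must lie strictly inside (0, 100)%",
         call. = FALSE)
  if (fit$b <= 0)
    stop("non-ototoxic slope: fitted effect does not increase with dose in ",
         "arm ", fit$arm, call. = FALSE)
  g <- (p - fit$a) / fit$b
  dose <- 10^g
  vg <- (fit$cov[1, 1] + g^2 * fit$cov[2, 2] + 2 * g * fit$cov[1, 2]) /
    fit$b^2
  se <- log(10) * dose * sqrt(max(vg, 0))
  flo <- predict(fit, min(fit$doses))
  fhi <- predict(fit, max(fit$doses))
  if (warn && !(p > flo && p < fhi))
    warning("HTDD", p, " for arm ", fit$arm, " extrapolates beyond the ",
            "fitted effect range [", round(flo, 1), ", ", round(fhi, 1),
            "]%", call. = FALSE)
  new_htdd(fit$arm, p, dose, se, fit$df, method = "delta")
}

new_htdd <- function(arm, p, dose, se, df, method) {
  structure(list(arm = arm, p = p, dose = dose, se = se, df = df,
                 method = method), class = "htdd")
}

#' @export
print.htdd <- function(x, ...) {
  cat(sprintf("HTDD%g [%s] = %.4g +/- %.3g mg/kg (df %s, %s)\n",
              x$p, x$arm, x$dose, x$se, format(x$df), x$method))
  invisible(x)
}

#' Summarise per-animal HTDD replicates into an HTDD point
#'
#' Mean, SEM and \eqn{n - 1} degrees of freedom of a set of per-animal HTDD
#' values; the replicate-based counterpart of the delta-method
#' [estimate_htdd()], used where group comparisons need per-group replicate
#' variance (e.g. t-tests between two experimental points with 6-animal
#' groups, giving \eqn{df = 10}).
#'
#' @param values per-animal HTDD doses, mg/kg.
#' @param arm arm label.
#' @param p effect level.
#' @return an \code{"htdd"} with \code{method = "replicate"}.
#' @export
htdd_from_replicates <- function(values, arm = "", p = NA_real_) {
  stopifnot(length(values) >= 2, all(values > 0))
  new_htdd(arm, p, mean(values), stats::sd(values) / sqrt(length(values)),
           length(values) - 1L, method = "replicate")
}

#' Per-animal implied HTDD values under a common slope
#'
#' Converts each animal's observed effect into the dose at which that animal
#' would have reached the target level, sliding along the arm's common slope:
#' \deqn{\log_{10}(HTDD_{p,i}) = \log_{10}(d_i) + (p - E_i)/b.}
#' The geometric mean over an arm's animals approximates the arm-level HTDD.
#' These replicate values feed the one-way ANOVA and pairwise comparisons.
#'
#' @param fit a \code{"drfit"}.
#' @param records records to convert; defaults to the fit's own data.
#' @param p target percent effect.
#' @param doses optional dose subset: keep only animals at these dose levels
#'   (e.g. the middle dose group, to reproduce a 6-replicate-per-arm design).
#' @return numeric vector of per-animal HTDD doses, mg/kg.
#' @export
per_animal_htdd <- function(fit, records = fit$data, p, doses = NULL) {
  stopifnot(inherits(fit, "drfit"))
  if (fit$b <= 0) stop("non-ototoxic slope in arm ", fit$arm, call. = FALSE)
  if (p <= 0 || p >= 100)
    stop("target effect level must lie strictly inside (0, 100)%",
         call. = FALSE)
  if (!is.null(doses)) {
    keep <- records$dose_mg_kg %in% doses
    if (!any(keep)) stop("no records at the requested dose levels",
                         call. = FALSE)
    records <- records[keep, , drop = FALSE]
  }
  10^(log10(records$dose_mg_kg) + (p - records$effect) / fit$b)
}

#' HTDD summary table across arms
#'
#' The report shape of the study's dose tables: one row per arm with HTDD
#' estimates and standard errors at each requested level.
#'
#' @param fits a list of \code{"drfit"} objects (e.g. one per arm).
#' @param p effect levels.
#' @param warn passed to [estimate_htdd()].
#' @return a data frame with columns \code{arm}, then \code{htdd<p>} and
#'   \code{se<p>} per level.
#' @export
htdd_table <- function(fits, p = c(20, 50), warn = FALSE) {
  rows <- lapply(fits, function(f) {
    est <- lapply(p, function(pp) estimate_htdd(f, pp, warn = warn))
    vals <- unlist(lapply(est, function(e) c(e$dose, e$se)))
    names(vals) <- as.vector(rbind(paste0("htdd", p), paste0("se", p)))
    c(list(arm = f$arm), as.list(vals))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Parametric-bootstrap standard error of an HTDD estimate
#'
#' Cross-check for the delta-method SE: resamples the coefficient pair
#' \eqn{(a, b)} from the fitted bivariate normal and recomputes
#' \eqn{10^{(p-a)/b}} for each draw. Draws with non-positive slope are
#' dropped (they correspond to a sign-flipped curve outside the model's
#' domain).
#'
#' @param fit a \code{"drfit"}.
#' @param p target percent effect.
#' @param ndraw number of bootstrap draws.
#' @param seed optional seed.
#' @return list with \code{se} (bootstrap SD of the dose), \code{mean}, and
#'   the number of retained draws.
#' @export
htdd_bootstrap_se <- function(fit, p, ndraw = 10000, seed = NULL) {
  stopifnot(inherits(fit, "drfit"))
  with_seed(seed, {
    ab <- MASS::mvrnorm(ndraw, mu = c(fit$a, fit$b), Sigma = fit$cov)
    keep <- ab[, 2] > 0
    doses <- 10^((p - ab[keep, 1]) / ab[keep, 2])
    list(se = stats::sd(doses), mean = mean(doses), n = sum(keep))
  })
}
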