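#' Theoretically additive dose of the variable drug at a fixed co-drug dose
#'
#' Loewe additivity treats the two drugs as dose-equivalents: on the isobole
#' connecting the two single-drug HTDDp intercepts, the dose of the variable
#' drug that is additively iso-effective with a constant co-drug dose
#' \eqn{d_{fix}} is
#' \deqn{D_{add} = B_p \left(1 - \frac{d_{fix}}{A_p}\right),}
#' where \eqn{A_p} is the co-drug-alone HTDDp and \eqn{B_p} the
#' variable-drug-alone HTDDp. Its variance propagates both single-drug
#' uncertainties,
#' \deqn{Var(D_{add}) = \left(1 - \frac{d_{fix}}{A_p}\right)^2 Var(B_p) +
#'   \left(\frac{B_p d_{fix}}{A_p^2}\right)^2 Var(A_p),}
#' with effective degrees of freedom by Welch-Satterthwaite over the two
#' variance components.
#'
#' An alternative \code{"effect-subtraction"} additivity is available for
#' sensitivity analysis: the additive dose is the dose of the variable drug
#' producing \eqn{p} minus the co-drug's own fitted effect at \eqn{d_{fix}},
#' i.e. \eqn{10^{(p - E_{co}(d_{fix}) - a_B)/b_B}} on the variable drug's
#' curve. This variant needs the two \code{"drfit"} objects.
#'
#' @param variable \code{"htdd"} estimate of the variable drug alone
#'   (\eqn{B_p}).
#' @param codrug \code{"htdd"} estimate of the co-drug alone (\eqn{A_p}).
#' @param d_fix constant co-drug dose, mg/kg; must satisfy
#'   \code{0 <= d_fix < codrug$dose}.
#' @param variant additivity model, \code{"loewe"} (default) or
#'   \code{"effect-subtraction"}.
#' @param variable_fit,codrug_fit the \code{"drfit"} objects, required for
#'   the effect-subtraction variant.
#' @return an object of class \code{"additive_point"} (also \code{"htdd"}):
#'   \code{dose}, \code{se}, Satterthwaite \code{df}, the inputs, and the
#'   variant label.
#' @examples
#' A <- htdd_from_replicates(c(950, 1000, 1060), "AMI+VEH", 50)
#' B <- htdd_from_replicates(c(60, 63, 66), "FUR+VEH", 50)
#' additive_point(B, A, d_fix = 500)
#' @export
additive_point <- function(variable, codrug, d_fix,
                           variant = c("loewe", "effect-subtraction"),
                           variable_fit = NULL, codrug_fit = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(variable, "htdd"), inherits(codrug, "htdd"))
  if (!isTRUE(all.equal(variable$p, codrug$p)))
    stop("both HTDD estimates must be at the same effect level (got ",
         variable$p, "% and ", codrug$p, "%)", call. = FALSE)
  if (d_fix < 0) stop("fixed co-drug dose must be non-negative", call. = FALSE)
  A <- codrug$dose
  if (d_fix >= A)
    stop("infeasible: fixed co-drug dose ", d_fix, " mg/kg alone already ",
         "reaches the ", codrug$p, "% level (co-drug HTDD = ",
         signif(A, 4), " mg/kg)", call. = FALSE)

  if (variant == "loewe") {
    B <- variable$dose
    w <- 1 - d_fix / A
    dose <- B * w
    v_var <- w^2 * variable$se^2
    v_co <- (B * d_fix / A^2)^2 * codrug$se^2
  } else {
    if (is.null(variable_fit) || is.null(codrug_fit))
      stop("effect-subtraction additivity needs the drfit objects of both ",
           "single-drug arms", call. = FALSE)
    p <- variable$p
    if (d_fix == 0) {
      e_fix <- 0
      v_efix <- 0
    } else {
      x <- log10(d_fix)
      e_fix <- codrug_fit$a + codrug_fit$b * x
      v_efix <- codrug_fit$cov[1, 1] + x^2 * codrug_fit$cov[2, 2] +
        2 * x * codrug_fit$cov[1, 2]
    }
    if (e_fix >= p)
      stop("infeasible: co-drug's fitted effect at ", d_fix, " mg/kg (",
           round(e_fix, 1), "%) already reaches the ", p, "% level",
           call. = FALSE)
    g <- (p - e_fix - variable_fit$a) / variable_fit$b
    dose <- 10^g
    vg_var <- (variable_fit$cov[1, 1] + g^2 * variable_fit$cov[2, 2] +
                 2 * g * variable_fit$cov[1, 2]) / variable_fit$b^2
    vg_co <- v_efix / variable_fit$b^2
    v_var <- (log(10) * dose)^2 * vg_var
    v_co <- (log(10) * dose)^2 * vg_co
  }

  v <- v_var + v_co
  df_eff <- satterthwaite_df(c(v_var, v_co), c(variable$df, codrug$df))
  structure(list(
    arm = paste0(variable$arm, " | ", codrug$arm, " fixed at ", d_fix),
    p = variable$p, dose = dose, se = sqrt(v), df = df_eff,
    method = paste0("additive-", variant),
    d_fix = d_fix, variable = variable, codrug = codrug, variant = variant
  ), class = c("additive_point", "htdd"))
}

# Welch-Satterthwaite effective df of a sum of independent variance
# components v_i carrying df_i each. Zero components contribute nothing.
satterthwaite_df <- function(v, df) {
  stopifnot(length(v) == length(df), all(v >= 0), all(df > 0))
  tot <- sum(v)
  if (tot == 0) return(sum(df))
  denom <- sum(v^2 / df)
  tot^2 / denom
}

#' @export
print.additive_point <- function(x, ...) {
  cat(sprintf(
    "Additive point (%s): dose = %.4g +/- %.3g mg/kg at %g%% (df %.3g)\n",
    x$variant, x$dose, x$se, x$p, x$df))
  cat("  ", x$arm, "\n")
  invisible(x)
}

as_dose_point <- function(x) {
  if (inherits(x, "htdd")) list(dose = x$dose, se = x$se, df = x$df)
  else if (is.list(x) && all(c("dose", "se", "df") %in% names(x))) x
  else stop("expected an htdd/additive_point or list(dose, se, df)",
            call. = FALSE)
}

#' Student's t comparison of two dose points
#'
#' Compares two HTDD-type points (dose +/- SE with degrees of freedom) with
#' \deqn{t = \frac{|d_1 - d_2|}{\sqrt{SE_1^2 + SE_2^2}}.}
#' With \code{mode = "pooled"} the reference distribution uses
#' \eqn{df_1 + df_2} degrees of freedom (two experimental points backed by
#' per-group replicates: two 6-animal groups give \eqn{df = 10}); with
#' \code{mode = "welch"} the Welch-Satterthwaite effective df, appropriate
#' when one side carries propagated variance (comparisons against a
#' theoretical additive point, giving fractional df).
#'
#' @param d1,d2 \code{"htdd"}/\code{"additive_point"} objects, or lists with
#'   \code{dose}, \code{se}, \code{df}.
#' @param mode \code{"welch"} or \code{"pooled"}.
#' @param alpha two-sided significance level.
#' @return an object of class \code{"interaction_test"}: \code{t}, \code{df},
#'   \code{p_value}, \code{alpha}, \code{significant}, the two points and the
#'   mode.
#' @examples
#' b <- list(dose = 37.35, se = 4.10, df = 5)
#' c_ <- list(dose = 38.52, se = 4.26, df = 5)
#' compare_points(b, c_, mode = "pooled")
#' @export
compare_points <- function(d1, d2, mode = c("welch", "pooled"), alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1)
  p1 <- as_dose_point(d1)
  p2 <- as_dose_point(d2)
  v <- p1$se^2 + p2$se^2
  if (v == 0) {
    if (p1$dose != p2$dose)
      stop("degenerate comparison: unequal doses with zero variance on ",
           "both sides", call. = FALSE)
    t_stat <- 0
  } else {
    t_stat <- abs(p1$dose - p2$dose) / sqrt(v)
  }
  df <- if (mode == "pooled") p1$df + p2$df
        else satterthwaite_df(c(p1$se^2, p2$se^2), c(p1$df, p2$df))
  p_value <- if (v == 0) 1 else 2 * stats::pt(-t_stat, df)
  structure(list(t = t_stat, df = df, p_value = p_value, alpha = alpha,
                 significant = p_value < alpha, mode = mode,
                 point1 = p1, point2 = p2),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.4g, p = %.4g (%s)%s\n", x$t, x$df,
              x$p_value, x$mode,
              if (!is.null(x$call_label)) paste0("  -> ", x$call_label)
              else ""))
  invisible(x)
}

#' Classify a fixed-dose drug interaction from its isobolographic points
#'
#' Compares the experimentally determined combination HTDD (point B) with the
#' theoretically additive dose (point A) by Welch's t-test and classifies:
#' antagonistic when the experimental dose is significantly larger than
#' additive (more drug needed than dose-equivalence predicts), synergistic
#' when significantly smaller, additive (not significant) otherwise.
#'
#' @param A an \code{"additive_point"} (or any dose point) — the theoretical
#'   additive dose.
#' @param B an \code{"htdd"} — the experimental combination dose.
#' @param alpha two-sided significance level.
#' @return an \code{"interaction_test"} with an added \code{call_label} in
#'   \code{c("antagonistic", "synergistic", "additive")}.
#' @export
classify_interaction <- function(A, B, alpha = 0.05) {
  res <- compare_points(A, B, mode = "welch", alpha = alpha)
  dA <- as_dose_point(A)$dose
  dB <- as_dose_point(B)$dose
  res$call_label <- if (res$significant && dB > dA) "antagonistic"
    else if (res$significant && dB < dA) "synergistic"
    else "additive"
  res$comparison <- "A-vs-B"
  res
}

#' Test whether a modifier shifts the combination dose
#'
#' Pooled-variance t comparison of the experimental combination point (B)
#' with the modifier-treated combination point (C); with per-group replicate
#' SEs from 6-animal groups this is the \eqn{df = 10} comparison of the
#' study design.
#'
#' @param B,C dose points (experimental combination, and combination plus
#'   modifier).
#' @param alpha significance level.
#' @return an \code{"interaction_test"} with \code{call_label} in
#'   \code{c("modifier-effective", "modifier-ineffective")}.
#' @export
modifier_effect <- function(B, C, alpha = 0.05) {
  res <- compare_points(B, C, mode = "pooled", alpha = alpha)
  res$call_label <- if (res$significant) "modifier-effective"
    else "modifier-ineffective"
  res$comparison <- "B-vs-C"
  res
}

#' Isobologram of a fixed-dose combination
#'
#' Plots the additivity isobole connecting the two single-drug HTDDp
#' intercepts (amikacin dose on the X-axis, furosemide dose on the Y-axis), a
#' dotted line at the constant co-drug dose, and the theoretical additive
#' point (A), the experimental combination point (B) and, when given, the
#' modifier-treated point (C) with error bars along the variable-drug axis.
#'
#' @param htdd_x,htdd_y single-drug \code{"htdd"} estimates for the X-axis
#'   drug and the Y-axis drug.
#' @param fixed_axis which axis carries the constant co-drug dose
#'   (\code{"x"} or \code{"y"}); the other axis is the variable drug.
#' @param d_fix the constant dose, mg/kg.
#' @param A,B,C dose points of the variable drug (see [additive_point()],
#'   [estimate_htdd()]); \code{C} optional.
#' @param xlab,ylab axis labels.
#' @param main plot title.
#' @return invisibly, \code{NULL}.
#' @export
plot_isobologram <- function(htdd_x, htdd_y, fixed_axis = c("x", "y"), d_fix,
                             A, B, C = NULL,
                             xlab = "AMI dose (mg/kg)",
                             ylab = "FUR dose (mg/kg)", main = NULL) {
  fixed_axis <- match.arg(fixed_axis)
  ix <- htdd_x$dose
  iy <- htdd_y$dose
  pts <- Filter(Negate(is.null), list(A = A, B = B, C = C))
  pts <- lapply(pts, as_dose_point)
  var_max <- max(unlist(lapply(pts, function(p) p$dose + p$se)))
  xmax <- if (fixed_axis == "x") max(ix, d_fix) else max(ix, var_max)
  ymax <- if (fixed_axis == "y") max(iy, d_fix) else max(iy, var_max)
  graphics::plot(NA, xlim = c(0, 1.1 * xmax), ylim = c(0, 1.1 * ymax),
                 xlab = xlab, ylab = ylab,
                 main = if (is.null(main))
                   sprintf("Isobologram at %g%% effect", htdd_x$p) else main)
  graphics::segments(ix, 0, 0, iy)
  cols <- c(A = "black", B = "red3", C = "blue3")
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (fixed_axis == "x") {
      graphics::points(d_fix, p$dose, pch = 19, col = cols[[nm]])
      graphics::arrows(d_fix, p$dose - p$se, d_fix, p$dose + p$se,
                       angle = 90, code = 3, length = 0.04, col = cols[[nm]])
      graphics::text(d_fix, p$dose, labels = nm, pos = 4, col = cols[[nm]])
    } else {
      graphics::points(p$dose, d_fix, pch = 19, col = cols[[nm]])
      graphics::arrows(p$dose - p$se, d_fix, p$dose + p$se, d_fix,
                       angle = 90, code = 3, length = 0.04, col = cols[[nm]])
      graphics::text(p$dose, d_fix, labels = nm, pos = 3, col = cols[[nm]])
    }
  }
  if (fixed_axis == "x") graphics::abline(v = d_fix, lty = 3)
  else graphics::abline(h = d_fix, lty = 3)
  invisible(NULL)
}
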