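as_group_list <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$arm)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a named list of at least 2 replicate groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  small <- vapply(groups, length, 1L) < 2L
  if (any(small))
    stop("design error: group(s) ", paste(names(groups)[small],
         collapse = ", "), " have fewer than 2 replicates", call. = FALSE)
  groups
}

#' One-way fixed-effects ANOVA across treatment arms
#'
#' Classical one-way ANOVA on per-animal replicate values (e.g. per-animal
#' HTDD doses), the omnibus test preceding pairwise comparisons. With 4 arms
#' of 6 replicates the degrees of freedom are (3, 20), the shape of every F
#' statistic the study design produces.
#'
#' @param groups a named list of numeric replicate vectors (one per arm), or
#'   a data frame with \code{arm} and \code{value} columns.
#' @return list with \code{F}, \code{df1} (\eqn{k - 1}), \code{df2}
#'   (\eqn{N - k}), and \code{p}.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  value <- unlist(groups, use.names = FALSE)
  arm <- factor(rep(names(groups), vapply(groups, length, 1L)))
  tab <- stats::anova(stats::lm(value ~ arm))
  list(F = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab[2, "Df"],
       p = tab[1, "Pr(>F)"])
}

#' Pooled-variance pairwise t-tests between all arm pairs
#'
#' Two-sample Student's t-tests (pooled variance, two-sided) for every
#' unordered pair of arms; the raw p-values feed [holm_sidak()].
#'
#' @inheritParams one_way_anova
#' @return data frame with one row per pair: \code{arm_i}, \code{arm_j},
#'   \code{t}, \code{df}, \code{raw_p}.
#' @export
pairwise_t <- function(groups) {
  groups <- as_group_list(groups)
  nm <- names(groups)
  pairs <- utils::combn(length(groups), 2)
  rows <- apply(pairs, 2, function(ij) {
    tt <- stats::t.test(groups[[ij[1]]], groups[[ij[2]]], var.equal = TRUE)
    data.frame(arm_i = nm[ij[1]], arm_j = nm[ij[2]],
               t = unname(tt$statistic), df = unname(tt$parameter),
               raw_p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Step-down procedure with Sidak-type adjustment: order the m raw p-values
#' ascending and set \eqn{\tilde p_{(i)} = 1 - (1 - p_{(i)})^{m - i + 1}},
#' enforcing monotonicity by a running maximum; reject while
#' \eqn{\tilde p \le \alpha}. Uniformly at least as powerful as
#' Holm-Bonferroni.
#'
#' @param raw_p raw p-values in \code{[0, 1]}.
#' @param alpha family-wise error rate.
#' @return data frame in the input order: \code{raw_p}, \code{adjusted_p},
#'   \code{reject}; attribute \code{"method"} is \code{"holm-sidak"}.
#' @examples
#' holm_sidak(c(0.01, 0.03, 0.04))
#' @export
holm_sidak <- function(raw_p, alpha = 0.05) {
  if (any(raw_p < 0 | raw_p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  m <- length(raw_p)
  o <- order(raw_p)
  adj_sorted <- 1 - (1 - raw_p[o])^(m - seq_len(m) + 1)
  adj_sorted <- cummax(adj_sorted)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  structure(data.frame(raw_p = raw_p, adjusted_p = adjusted,
                       reject = adjusted <= alpha),
            method = "holm-sidak", alpha = alpha)
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "NS"))
}

#' Arm-wise comparison report: ANOVA plus Holm-Sidak pairwise tests
#'
#' The group-level significance analysis of the study's dose tables: a
#' one-way ANOVA across arms followed by pooled pairwise t-tests with
#' Holm-Sidak adjustment and star tiers (\code{*} p < 0.05 up to \code{****}
#' p < 0.0001 on the adjusted p).
#'
#' @inheritParams one_way_anova
#' @param alpha family-wise error rate.
#' @return list of class \code{"arm_comparison"}: \code{anova} (see
#'   [one_way_anova()]) and \code{pairs} (a data frame with t, df, raw and
#'   adjusted p, reject flag and stars).
#' @export
compare_arms <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  an <- one_way_anova(groups)
  pw <- pairwise_t(groups)
  hs <- holm_sidak(pw$raw_p, alpha)
  pw$adjusted_p <- hs$adjusted_p
  pw$reject <- hs$reject
  pw$stars <- as.character(significance_stars(pw$adjusted_p))
  structure(list(anova = an, pairs = pw, alpha = alpha),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d;%d) = %.4g, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  cat("Holm-Sidak pairwise comparisons:\n")
  print(x$pairs, digits = 4)
  invisible(x)
}
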