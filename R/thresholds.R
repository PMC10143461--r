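#' Convert pre-/post-treatment ABR thresholds to a percent effect
#'
#' Ototoxic drugs raise the auditory brainstem response (ABR) threshold; the
#' effect magnitude is expressed as a percent "hearing threshold decrease"
#' relative to the animal's pre-treatment hearing. Two conventions are
#' supported:
#' \describe{
#'   \item{\code{"headroom"} (default)}{the threshold shift normalised by the
#'     headroom between the pre-treatment threshold and the maximum stimulus
#'     level (the ceiling, 90 dB SPL for click ABR): \eqn{100 (post - pre) /
#'     (ceiling - pre)}. 0 when unchanged, 100 when the animal no longer
#'     responds at the loudest stimulus.}
#'   \item{\code{"baseline"}}{the shift as a percent of the pre-treatment
#'     threshold: \eqn{100 (post - pre) / pre}.}
#' }
#' The convention used is recorded as the \code{"convention"} attribute of the
#' result and propagated into every downstream report.
#'
#' @param pre_db pre-treatment hearing threshold, dB SPL; must satisfy
#'   \code{0 < pre_db < ceiling}.
#' @param post_db post-treatment hearing threshold, dB SPL; must lie in
#'   \code{[pre_db, ceiling]}.
#' @param ceiling maximum stimulus level of the ABR protocol, dB SPL.
#' @param convention effect convention, \code{"headroom"} or \code{"baseline"}.
#' @return numeric vector of percent effects in \code{[0, 100]} (headroom
#'   convention; the baseline convention can exceed 100 for large shifts),
#'   with attribute \code{"convention"}.
#' @examples
#' compute_effect(40, 65, 90)   # 50: shift of 25 dB over 50 dB of headroom
#' compute_effect(30, 90, 90)   # 100: ceiling reached
#' @export
compute_effect <- function(pre_db, post_db, ceiling = 90,
                           convention = c("headroom", "baseline")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(pre_db), is.numeric(post_db), length(ceiling) == 1L)
  if (any(pre_db >= ceiling))
    stop("undefined baseline: pre-treatment threshold at or above the ",
         ceiling, " dB SPL ceiling", call. = FALSE)
  if (any(pre_db <= 0))
    stop("pre-treatment threshold must be positive (dB SPL)", call. = FALSE)
  if (any(post_db > ceiling))
    stop("post-treatment threshold exceeds the ", ceiling,
         " dB SPL stimulus ceiling", call. = FALSE)
  if (any(post_db < pre_db))
    stop("negative effect: post-treatment threshold below pre-treatment; ",
         "such records indicate a measurement or labelling problem",
         call. = FALSE)
  eff <- switch(convention,
    headroom = 100 * (post_db - pre_db) / (ceiling - pre_db),
    baseline = 100 * (post_db - pre_db) / pre_db
  )
  structure(eff, convention = convention)
}

#' Invert the effect convention to a post-treatment threshold
#'
#' Given a pre-treatment threshold and a percent effect, returns the
#' post-treatment threshold that [compute_effect()] maps back to exactly that
#' effect. Used by the synthetic-data generator.
#'
#' @inheritParams compute_effect
#' @param effect percent effect in \code{[0, 100]}.
#' @return post-treatment thresholds, dB SPL.
#' @export
effect_to_post <- function(pre_db, effect, ceiling = 90,
                           convention = c("headroom", "baseline")) {
  convention <- match.arg(convention)
  stopifnot(all(effect >= 0))
  switch(convention,
    headroom = pre_db + effect / 100 * (ceiling - pre_db),
    baseline = pre_db * (1 + effect / 100)
  )
}

record_columns <- c("animal_id", "arm", "variable_drug", "dose_mg_kg",
                    "fixed_codrug", "fixed_dose_mg_kg", "modifier",
                    "pre_dB", "post_dB")

#' Read and validate a per-animal ABR record table
#'
#' Reads a comma-delimited table with columns \code{animal_id, arm,
#' variable_drug, dose_mg_kg, fixed_codrug, fixed_dose_mg_kg, modifier,
#' pre_dB, post_dB}, validates every row against the design invariants, and
#' populates the derived \code{effect} column.
#'
#' Rows with \code{post_dB < pre_dB} (the drug apparently improving hearing)
#' are excluded with a warning naming the rows: a negative shift signals a
#' measurement or labelling problem, not a zero effect. Structural violations
#' (non-positive dose, thresholds outside \code{(0, ceiling]}, baseline at the
#' ceiling) abort the load with an error naming the offending rows.
#'
#' @param path path to a delimited text file, or a data frame already holding
#'   the columns above.
#' @param ceiling ABR stimulus ceiling, dB SPL.
#' @param convention effect convention passed to [compute_effect()].
#' @return a data frame of validated records with an \code{effect} column and
#'   attributes \code{"convention"} and \code{"ceiling"}.
#' @export
load_records <- function(path, ceiling = 90,
                         convention = c("headroom", "baseline")) {
  convention <- match.arg(convention)
  if (is.data.frame(path)) {
    df <- as.data.frame(path)
  } else {
    if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(record_columns, names(df))
  if (length(missing_cols))
    stop("malformed record table, missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[record_columns]
  for (col in c("dose_mg_kg", "fixed_dose_mg_kg", "modifier", "pre_dB", "post_dB")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad_parse <- which(is.na(df$dose_mg_kg) | is.na(df$pre_dB) | is.na(df$post_dB))
  if (length(bad_parse))
    stop("malformed row(s): ", paste(bad_parse, collapse = ", "),
         " (non-numeric dose or threshold)", call. = FALSE)
  df$fixed_dose_mg_kg[is.na(df$fixed_dose_mg_kg)] <- 0
  df$modifier[is.na(df$modifier)] <- 0

  problems <- character(0)
  chk <- function(bad, msg) {
    if (any(bad)) problems <<- c(problems,
      paste0(msg, " in row(s) ", paste(which(bad), collapse = ", ")))
  }
  chk(df$dose_mg_kg <= 0, "non-positive dose")
  chk(df$pre_dB <= 0, "non-positive pre-treatment threshold")
  chk(df$pre_dB >= ceiling, "pre-treatment threshold at/above ceiling")
  chk(df$post_dB > ceiling, "post-treatment threshold above ceiling")
  if (length(problems))
    stop("record validation failed: ", paste(problems, collapse = "; "),
         call. = FALSE)

  neg <- df$post_dB < df$pre_dB
  if (any(neg)) {
    warning("excluding ", sum(neg), " record(s) with post < pre threshold ",
            "(row(s) ", paste(which(neg), collapse = ", "), ")",
            call. = FALSE)
    df <- df[!neg, , drop = FALSE]
    rownames(df) <- NULL
  }

  df$effect <- as.numeric(compute_effect(df$pre_dB, df$post_dB, ceiling,
                                         convention))
  attr(df, "convention") <- convention
  attr(df, "ceiling") <- ceiling
  df
}

#' Write a record table as delimited text
#'
#' Inverse of [load_records()]: writes the declared columns (and the derived
#' effect, rounded to 2 decimal places) as comma-delimited text with header.
#'
#' @param records a record data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records[intersect(c(record_columns, "effect"), names(records))]
  if ("effect" %in% names(out)) out$effect <- round(out$effect, 2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
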