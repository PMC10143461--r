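#' Pipeline run configuration
#'
#' Bundles and validates everything a full analysis run needs. Either
#' \code{input} (a record file in the [load_records()] schema) or
#' \code{scenario} (a bundled synthetic scenario name, currently
#' \code{"ami-fur"}) must be given.
#'
#' @param input path to a per-animal record table, or \code{NULL}.
#' @param scenario bundled scenario name, or \code{NULL}.
#' @param p_levels target effect levels, percent.
#' @param alpha significance level for all tests.
#' @param convention effect convention (see [compute_effect()]).
#' @param additivity additivity variant for the theoretical point (see
#'   [additive_point()]).
#' @param outdir output directory; created if missing.
#' @param seed integer seed for scenario generation.
#' @param n_per_dose,noise_sd synthetic design parameters (scenario runs).
#' @param verbose emit progress messages to standard error.
#' @return a validated \code{"run_config"} list.
#' @export
run_config <- function(input = NULL, scenario = NULL, p_levels = c(20, 50),
                       alpha = 0.05,
                       convention = c("headroom", "baseline"),
                       additivity = c("loewe", "effect-subtraction"),
                       outdir = tempfile("oto_report_"), seed = 1L,
                       n_per_dose = 6, noise_sd = 8, verbose = TRUE) {
  convention <- match.arg(convention)
  additivity <- match.arg(additivity)
  if (is.null(input) && is.null(scenario))
    stop("either an input record file or a scenario name is required",
         call. = FALSE)
  if (!is.null(input) && !is.data.frame(input) && !file.exists(input))
    stop("input path not found: ", input, call. = FALSE)
  if (!is.null(scenario) && !scenario %in% c("ami-fur"))
    stop("unknown scenario: ", scenario, call. = FALSE)
  stopifnot(all(p_levels > 0 & p_levels < 100),
            !anyDuplicated(p_levels),
            alpha > 0, alpha < 1)
  structure(list(input = input, scenario = scenario,
                 p_levels = sort(p_levels), alpha = alpha,
                 convention = convention, additivity = additivity,
                 outdir = outdir, seed = as.integer(seed),
                 n_per_dose = n_per_dose, noise_sd = noise_sd,
                 verbose = verbose),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file with fields matching the [run_config()] arguments.
#' @param ... overrides applied on top of the file's values.
#' @return a \code{"run_config"}.
#' @export
read_run_config <- function(path, ...) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- utils::modifyList(vals, list(...))
  do.call(run_config, vals)
}

pipeline_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[otoisobol] ", ...)
}

# Resolve the arm roles of one experiment set from record metadata:
# the variable drug's solo/+NAC arms, and the fixed-dose combination arms.
set_roles <- function(records, drug) {
  sub <- records[records$variable_drug == drug, , drop = FALSE]
  has_co <- !is.na(sub$fixed_codrug) & sub$fixed_dose_mg_kg > 0
  pick <- function(co, mod) unique(sub$arm[has_co == co &
                                             (sub$modifier > 0) == mod])
  first_or_na <- function(x) if (length(x)) x[1] else NA_character_
  combo <- pick(TRUE, FALSE)
  list(
    alone = first_or_na(pick(FALSE, FALSE)),
    alone_nac = first_or_na(pick(FALSE, TRUE)),
    combo = first_or_na(combo),
    combo_nac = first_or_na(pick(TRUE, TRUE)),
    d_fix = if (length(combo))
      unique(sub$fixed_dose_mg_kg[sub$arm == combo[1]])[1] else NA_real_,
    codrug = if (length(combo))
      unique(sub$fixed_codrug[sub$arm == combo[1]])[1] else NA_character_
  )
}

#' Run the full ototoxic-interaction analysis pipeline
#'
#' Orchestrates every stage: load or simulate per-animal records, compute
#' percent effects, fit the per-arm dose-response curves, estimate
#' HTDD20/HTDD50, run the per-set ANOVA with Holm-Sidak pairwise
#' comparisons on per-animal HTDD replicates, compute the isobolographic
#' points A (theoretical additive), B (experimental combination) and C
#' (combination plus modifier), classify each interaction, and write a
#' report bundle (delimited tables, a JSON results record, isobologram
#' images, and a manifest sufficient to re-run the pipeline). Identical
#' inputs and seed produce identical machine-readable outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list of class \code{"oto_report"} with the records,
#'   fits, HTDD table, group comparisons, interaction results and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  # --- stage: records -------------------------------------------------
  if (!is.null(config$input)) {
    pipeline_log(config, "loading records from ",
                 if (is.data.frame(config$input)) "data frame"
                 else config$input)
    records <- load_records(config$input, convention = config$convention)
  } else {
    pipeline_log(config, "generating scenario '", config$scenario,
                 "' with seed ", config$seed)
    specs <- ami_fur_scenarios("both", include_infeasible = TRUE)
    cfg <- synth_config(specs, n_per_dose = config$n_per_dose,
                        noise_sd = config$noise_sd,
                        convention = config$convention, seed = config$seed)
    records <- generate_animals(cfg)
  }

  # --- stage: dose-response fits -------------------------------------
  arms <- unique(records$arm)
  fits <- lapply(arms, function(a)
    withCallingHandlers(
      tryCatch(fit_arm(records, arm = a),
               error = function(e) stop("stage fit_arm, arm ", a, ": ",
                                        conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        pipeline_log(config, "fit_arm: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
  names(fits) <- arms
  pipeline_log(config, "fitted ", length(fits), " arms")

  htdds <- htdd_table(fits, p = config$p_levels)

  # --- stage: group inference per experiment set ---------------------
  sets <- unique(records$variable_drug)
  comparisons <- list()
  for (drug in sets) {
    set_arms <- unique(records$arm[records$variable_drug == drug])
    for (p in config$p_levels) {
      groups <- lapply(fits[set_arms], function(f)
        per_animal_htdd(f, p = p, doses = middle_dose(f)))
      names(groups) <- set_arms
      key <- sprintf("%s_p%g", drug, p)
      comparisons[[key]] <- tryCatch(
        compare_arms(groups, alpha = config$alpha),
        error = function(e) stop("stage group_inference, set ", drug, ": ",
                                 conditionMessage(e), call. = FALSE))
    }
  }

  # --- stage: isobolography ------------------------------------------
  interactions <- list()
  for (drug in sets) {
    roles <- set_roles(records, drug)
    if (is.na(roles$combo) || is.na(roles$codrug)) next
    co_roles <- set_roles(records, roles$codrug)
    if (is.na(co_roles$alone)) next
    for (p in config$p_levels) {
      B_est <- estimate_htdd(fits[[roles$combo]], p, warn = FALSE)
      A_pt <- tryCatch(additive_point(
          estimate_htdd(fits[[roles$alone]], p, warn = FALSE),
          estimate_htdd(fits[[co_roles$alone]], p, warn = FALSE),
          d_fix = roles$d_fix, variant = config$additivity,
          variable_fit = fits[[roles$alone]],
          codrug_fit = fits[[co_roles$alone]]),
        error = function(e) {
          pipeline_log(config, "set ", drug, " p", p,
                       ": additive point infeasible (",
                       conditionMessage(e), ")")
          NULL
        })
      entry <- list(set = drug, p = p, d_fix = roles$d_fix,
                    codrug = roles$codrug, B = B_est, A = A_pt)
      if (!is.null(A_pt))
        entry$a_vs_b <- classify_interaction(A_pt, B_est,
                                             alpha = config$alpha)
      if (!is.na(roles$combo_nac)) {
        B_rep <- htdd_from_replicates(
          per_animal_htdd(fits[[roles$combo]], p = p,
                          doses = middle_dose(fits[[roles$combo]])),
          roles$combo, p)
        C_rep <- htdd_from_replicates(
          per_animal_htdd(fits[[roles$combo_nac]], p = p,
                          doses = middle_dose(fits[[roles$combo_nac]])),
          roles$combo_nac, p)
        entry$C <- C_rep
        entry$b_vs_c <- modifier_effect(B_rep, C_rep, alpha = config$alpha)
      }
      interactions[[sprintf("%s_p%g", drug, p)]] <- entry
    }
  }

  # --- stage: report bundle ------------------------------------------
  paths <- write_report(config, records, fits, htdds, comparisons,
                        interactions)
  pipeline_log(config, "report written to ", config$outdir)

  invisible(structure(list(
    config = config, records = records, fits = fits, htdd = htdds,
    comparisons = comparisons, interactions = interactions, paths = paths
  ), class = "oto_report"))
}

middle_dose <- function(fit) fit$doses[ceiling(length(fit$doses) / 2)]

point_record <- function(pt) {
  if (is.null(pt)) return(NULL)
  p <- as_dose_point(pt)
  list(dose = p$dose, se = p$se, df = p$df,
       method = if (!is.null(pt$method)) pt$method else "point")
}

test_record <- function(tt) {
  if (is.null(tt)) return(NULL)
  list(t = tt$t, df = tt$df, p_value = tt$p_value, mode = tt$mode,
       call = tt$call_label)
}

write_report <- function(config, records, fits, htdds, comparisons,
                         interactions) {
  out <- function(f) file.path(config$outdir, f)
  write_records(records, out("records.csv"))
  utils::write.csv(data.frame(lapply(htdds, function(col)
    if (is.numeric(col)) round(col, 4) else col)),
    out("htdd_table.csv"), row.names = FALSE, quote = FALSE)

  comp_rows <- do.call(rbind, lapply(names(comparisons), function(k) {
    pw <- comparisons[[k]]$pairs
    cbind(data.frame(set_level = k, stringsAsFactors = FALSE), pw)
  }))
  if (!is.null(comp_rows)) {
    num <- vapply(comp_rows, is.numeric, TRUE)
    comp_rows[num] <- lapply(comp_rows[num], function(v) signif(v, 6))
    utils::write.csv(comp_rows, out("pairwise_comparisons.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  results <- list(
    htdd = htdds,
    anova = lapply(comparisons, function(cc) cc$anova),
    interactions = lapply(interactions, function(e) {
      list(set = e$set, p = e$p, d_fix = e$d_fix, codrug = e$codrug,
           A = point_record(e$A), B = point_record(e$B),
           C = point_record(e$C),
           a_vs_b = test_record(e$a_vs_b), b_vs_c = test_record(e$b_vs_c))
    })
  )
  jsonlite::write_json(results, out("results.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")

  manifest <- list(
    package = "otoisobol",
    version = as.character(utils::packageVersion("otoisobol")),
    seed = config$seed,
    effect_convention = config$convention,
    additivity_variant = config$additivity,
    alpha = config$alpha,
    p_levels = config$p_levels,
    scenario = config$scenario,
    input = if (is.character(config$input)) config$input else NULL,
    n_per_dose = config$n_per_dose,
    noise_sd = config$noise_sd
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")

  figs <- character(0)
  for (key in names(interactions)) {
    e <- interactions[[key]]
    if (is.null(e$A)) next
    fig <- out(paste0("isobologram_", gsub("[^A-Za-z0-9_]", "_", key),
                      ".png"))
    grDevices::png(fig, width = 700, height = 700)
    # X axis is always the AMI dose, Y the FUR dose
    roles_var <- e$set
    htdd_var <- e$A$variable
    htdd_co <- e$A$codrug
    if (roles_var == "AMI") {
      plot_isobologram(htdd_var, htdd_co, fixed_axis = "y",
                       d_fix = e$d_fix, A = e$A, B = e$B, C = e$C)
    } else {
      plot_isobologram(htdd_co, htdd_var, fixed_axis = "x",
                       d_fix = e$d_fix, A = e$A, B = e$B, C = e$C)
    }
    grDevices::dev.off()
    figs <- c(figs, fig)
  }

  list(records = out("records.csv"), htdd_table = out("htdd_table.csv"),
       pairwise = out("pairwise_comparisons.csv"),
       results = out("results.json"), manifest = out("manifest.json"),
       figures = figs)
}

#' @export
print.oto_report <- function(x, ...) {
  cat("otoisobol pipeline report\n")
  cat("  arms:", length(x$fits), " animals:", nrow(x$records), "\n")
  cat("  HTDD table:\n")
  print(x$htdd, digits = 5)
  for (key in names(x$interactions)) {
    e <- x$interactions[[key]]
    cat(sprintf("  [%s] d_fix = %g %s:\n", key, e$d_fix, e$codrug))
    if (!is.null(e$a_vs_b))
      cat(sprintf("    A-vs-B: A = %.4g, B = %.4g -> %s (t = %.3f, df = %.3g, p = %.4g)\n",
                  e$A$dose, e$B$dose, e$a_vs_b$call_label, e$a_vs_b$t,
                  e$a_vs_b$df, e$a_vs_b$p_value))
    if (!is.null(e$b_vs_c))
      cat(sprintf("    B-vs-C: C = %.4g -> %s (t = %.3f, df = %g, p = %.4g)\n",
                  e$C$dose, e$b_vs_c$call_label, e$b_vs_c$t, e$b_vs_c$df,
                  e$b_vs_c$p_value))
  }
  cat("  outputs:", x$config$outdir, "\n")
  invisible(x)
}
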