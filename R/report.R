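# Full cohort analysis: ratings contrasts, parameter contrasts with
# FDR-corrected post-hocs, craving correlations, addiction-characteristic
# correlations, and the posterior-alpha mediation model.

#' Assemble a cohort table
#'
#' Joins a per-subject/condition microstate parameter table, per-
#' subject/condition alpha power, and the behavioural table into the wide
#' cohort format (one row per subject x condition).
#'
#' @param params Tibble: `subject`, `condition`, `class`, `duration_ms`,
#'   `occurrence_per_s`, `contribution` (plus optionally `gev`).
#' @param alpha Tibble: `subject`, `condition`, `alpha_power`.
#' @param behaviour Per-subject behavioural tibble in the
#'   [generate_cohort()] layout (craving/vividness per condition and
#'   covariates as columns).
#' @return Wide cohort tibble, one row per subject x condition.
#' @export
build_cohort_table <- function(params, alpha = NULL, behaviour = NULL) {
  wide <- params |>
    tidyr::pivot_wider(
      id_cols = c("subject", "condition"),
      names_from = "class",
      values_from = dplyr::any_of(c("duration_ms", "occurrence_per_s",
                                    "contribution", "gev")),
      names_sep = "_"
    )
  if ("gev" %in% names(params)) {
    gv <- params |>
      dplyr::distinct(.data$subject, .data$condition, .data$gev)
    wide <- wide |>
      dplyr::select(-dplyr::starts_with("gev_")) |>
      dplyr::left_join(gv, by = c("subject", "condition"))
  }
  if (!is.null(alpha)) {
    wide <- dplyr::left_join(wide, alpha, by = c("subject", "condition"))
  }
  if (!is.null(behaviour)) {
    rate <- behaviour |>
      dplyr::select("subject",
                    dplyr::matches("^(craving|vividness)_(neutral|smoking)$")) |>
      tidyr::pivot_longer(
        cols = -"subject",
        names_to = c("measure", "condition"), names_sep = "_"
      ) |>
      tidyr::pivot_wider(names_from = "measure", values_from = "value")
    covs <- behaviour |>
      dplyr::select(dplyr::any_of(c("subject", "ftnd", "dsm5",
                                    "cigs_per_day", "years_smoking")))
    wide <- wide |>
      dplyr::left_join(rate, by = c("subject", "condition")) |>
      dplyr::left_join(covs, by = "subject")
  }
  wide
}

# Wide cohort table -> long parameter table for one measure family.
cohort_long <- function(table, measure) {
  prefix <- paste0(measure, "_")
  table |>
    dplyr::select("subject", "condition", dplyr::starts_with(prefix)) |>
    tidyr::pivot_longer(dplyr::starts_with(prefix), names_to = "class",
                        names_prefix = prefix, values_to = measure)
}

#' Analyse a cohort table
#'
#' Runs the full statistical report on a wide cohort table: (1) paired
#' condition contrasts of craving and vividness; (2) per-measure 2 x K
#' repeated-measures ANOVA with interaction-gated, FDR-corrected per-class
#' post-hoc contrasts for duration, occurrence and contribution;
#' (3) condition-difference variables (smoking minus neutral), created only
#' for measures/classes whose condition contrast was significant;
#' (4) Pearson correlations between the craving change and each
#' significant parameter change (raw and BH-adjusted); (5) correlations
#' between addiction covariates and the significant parameter changes; and
#' (6) the mediation model: class-C duration change -> posterior alpha
#' power change -> craving change (run when those columns are available).
#'
#' @param table Wide cohort tibble (see [build_cohort_table()]).
#' @param n_boot,conf_level,seed Mediation bootstrap settings.
#' @param mediation_class Class whose duration change is the mediation
#'   predictor (default `"C"`, falling back to the third class present).
#' @return An `ms_report` list with components `ratings`, `parameters`
#'   (per-measure ANOVA + post-hocs), `diffs`, `craving_correlations`,
#'   `covariate_correlations`, `mediation`.
#' @export
analyze_cohort <- function(table, n_boot = 5000, conf_level = 0.95,
                           seed = 1, mediation_class = "C") {
  conds <- sort(unique(table$condition))  # "neutral" < "smoking"
  stopifnot(length(conds) == 2)
  neutral <- table[table$condition == "neutral", ]
  smoking <- table[table$condition == "smoking", ]
  neutral <- neutral[order(neutral$subject), ]
  smoking <- smoking[order(smoking$subject), ]

  ratings <- NULL
  if (all(c("craving", "vividness") %in% names(table))) {
    ratings <- dplyr::bind_rows(
      cbind(measure = "craving",
            paired_t(neutral$craving, smoking$craving)),
      cbind(measure = "vividness",
            paired_t(neutral$vividness, smoking$vividness))
    ) |> as_tibble()
    ratings$p.value <- as.numeric(ratings$p.value)
  }

  measures <- c("duration_ms", "occurrence_per_s", "contribution")
  measures <- measures[vapply(measures, function(m)
    any(startsWith(names(table), paste0(m, "_"))), logical(1))]
  parameters <- lapply(measures, function(m) {
    posthoc_condition_tests(cohort_long(table, m), m)
  })
  names(parameters) <- measures

  # difference variables only where the condition contrast was significant
  diffs <- tibble(subject = neutral$subject)
  sig_vars <- character()
  for (m in measures) {
    ph <- parameters[[m]]$posthoc
    if (is.null(ph)) next
    for (cl in ph$class[ph$significant]) {
      col <- paste0(m, "_", cl)
      diffs[[paste0("d_", col)]] <- smoking[[col]] - neutral[[col]]
      sig_vars <- c(sig_vars, paste0("d_", col))
    }
  }
  if ("craving" %in% names(table) && !is.null(ratings) &&
      ratings$p.value[ratings$measure == "craving"] < 0.05) {
    diffs$d_craving <- smoking$craving - neutral$craving
  }
  if ("alpha_power" %in% names(table)) {
    at <- paired_t(neutral$alpha_power, smoking$alpha_power)
    if (at$p.value < 0.05) {
      diffs$d_alpha_power <- smoking$alpha_power - neutral$alpha_power
    }
    ratings <- dplyr::bind_rows(
      ratings, cbind(measure = "alpha_power", at) |> as_tibble())
  }

  corr_family <- function(yvar) {
    if (!yvar %in% names(diffs) || !length(sig_vars)) return(NULL)
    rows <- lapply(sig_vars, function(v) {
      r <- pearson(diffs[[v]], diffs[[yvar]])
      r$variable <- v
      r
    })
    out <- dplyr::bind_rows(rows)
    out$p.fdr <- fdr_bh(out$p.value)
    out[, c("variable", "estimate", "statistic", "df", "p.value", "p.fdr")]
  }
  craving_correlations <- corr_family("d_craving")

  covariate_correlations <- NULL
  covs <- intersect(c("ftnd", "dsm5", "cigs_per_day", "years_smoking"),
                    names(table))
  if (length(covs) && length(sig_vars)) {
    rows <- list()
    for (cv in covs) {
      for (v in sig_vars) {
        r <- pearson(neutral[[cv]], diffs[[v]])
        r$covariate <- cv; r$variable <- v
        rows[[length(rows) + 1]] <- r
      }
    }
    covariate_correlations <- dplyr::bind_rows(rows)
    covariate_correlations$p.fdr <- fdr_bh(covariate_correlations$p.value)
    covariate_correlations <- covariate_correlations[
      , c("covariate", "variable", "estimate", "statistic", "df",
          "p.value", "p.fdr")]
  }

  mediation <- NULL
  med_x <- paste0("d_duration_ms_", mediation_class)
  if (all(c(med_x, "d_alpha_power", "d_craving") %in% names(diffs)) &&
      nrow(diffs) >= 10) {
    mediation <- mediation_model4(diffs[[med_x]], diffs$d_alpha_power,
                                  diffs$d_craving, n_boot = n_boot,
                                  conf_level = conf_level, seed = seed)
  }

  structure(
    list(ratings = ratings, parameters = parameters, diffs = diffs,
         craving_correlations = craving_correlations,
         covariate_correlations = covariate_correlations,
         mediation = mediation,
         n = nrow(neutral)),
    class = "ms_report"
  )
}

#' @export
print.ms_report <- function(x, ...) {
  cat(sprintf("<ms_report> n = %d subjects\n", x$n))
  if (!is.null(x$ratings)) {
    cat("-- condition contrasts (neutral vs smoking) --\n")
    print(as.data.frame(x$ratings), row.names = FALSE, digits = 4)
  }
  for (m in names(x$parameters)) {
    p <- x$parameters[[m]]
    ip <- p$anova$table$p.value[p$anova$table$term == "condition:class"]
    cat(sprintf("-- %s: interaction p = %.4g%s --\n", m, ip,
                if (p$gated) " (post-hocs gated off)" else ""))
    if (!is.null(p$posthoc)) {
      print(as.data.frame(p$posthoc), row.names = FALSE, digits = 4)
    }
  }
  if (!is.null(x$craving_correlations)) {
    cat("-- craving-change correlations --\n")
    print(as.data.frame(x$craving_correlations), row.names = FALSE, digits = 4)
  }
  if (!is.null(x$mediation)) print(x$mediation)
  invisible(x)
}

# JSON-serialisable form of an ms_report.
report_to_list <- function(report) {
  list(
    n = report$n,
    ratings = report$ratings,
    parameters = lapply(report$parameters, function(p) {
      list(anova = p$anova$table, gated = p$gated, posthoc = p$posthoc)
    }),
    diff_variables = names(report$diffs)[-1],
    craving_correlations = report$craving_correlations,
    covariate_correlations = report$covariate_correlations,
    mediation = if (!is.null(report$mediation)) {
      list(paths = report$mediation$paths,
           indirect = report$mediation$indirect,
           ci = report$mediation$ci,
           verdict = report$mediation$verdict)
    }
  )
}

#' Write a cohort report to JSON
#'
#' @param report An `ms_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
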