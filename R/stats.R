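# Statistical layer: paired contrasts, 2 x K repeated-measures ANOVA with
# FDR-corrected post-hoc tests, Pearson correlations of condition
# differences, and percentile-bootstrap mediation.

#' Paired t-test
#'
#' Classical paired t on the within-subject differences (df = n - 1),
#' returned as a one-row tibble. Zero-variance differences are an error.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return Tibble with `estimate` (mean of `x - y`), `statistic`, `df`,
#'   `p.value`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble(estimate = 0, statistic = 0, df = length(d) - 1,
                    p.value = 1))
    }
    abort("zero variance in the paired differences")
  }
  fit <- t.test(x, y, paired = TRUE)
  tibble(estimate = unname(fit$estimate), statistic = unname(fit$statistic),
         df = unname(fit$parameter), p.value = fit$p.value)
}

#' Two-way repeated-measures ANOVA (condition x class)
#'
#' Fully within-subject two-way ANOVA for a balanced condition x class
#' design, with subject x factor interactions as error terms (fitted via
#' `stats::aov` error strata). Greenhouse-Geisser epsilon and corrected
#' p-values are reported alongside the uncorrected ones; the uncorrected
#' values are the headline.
#'
#' @param table Long tibble with columns `subject`, `condition`, `class`,
#'   and the measure column.
#' @param measure Name of the measure column (string).
#' @return An `ms_rmanova` object; `tidy()` gives the effect table.
#' @export
rm_anova_2x4 <- function(table, measure) {
  d <- tibble(
    subject = factor(table$subject),
    condition = factor(table$condition),
    class = factor(table$class),
    value = table[[measure]]
  )
  n_s <- nlevels(d$subject)
  n_c <- nlevels(d$condition); n_k <- nlevels(d$class)
  if (nrow(d) != n_s * n_c * n_k || anyNA(d$value)) {
    abort("need a complete balanced subject x condition x class table")
  }
  fit <- aov(value ~ condition * class + Error(subject / (condition * class)),
             data = d)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    row <- trimws(rownames(tab)) == term
    list(F = tab[row, "F value"], p = tab[row, "Pr(>F)"],
         df1 = tab[row, "Df"], df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"])
  }
  eff <- list(
    condition = pick("Error: subject:condition", "condition"),
    class = pick("Error: subject:class", "class"),
    `condition:class` = pick("Error: subject:condition:class",
                             "condition:class")
  )
  eps <- c(
    condition = gg_epsilon(d, "condition"),
    class = gg_epsilon(d, "class"),
    `condition:class` = gg_epsilon_interaction(d)
  )
  tab <- dplyr::bind_rows(lapply(names(eff), function(term) {
    e <- eff[[term]]
    tibble(term = term, df1 = e$df1, df2 = e$df2, statistic = e$F,
           p.value = e$p, gg_epsilon = unname(eps[term]),
           p.value.gg = pf(e$F, e$df1 * eps[term], e$df2 * eps[term],
                           lower.tail = FALSE))
  }))
  structure(list(table = tab, measure = measure, n = n_s,
                 levels = list(condition = levels(d$condition),
                               class = levels(d$class))),
            class = "ms_rmanova")
}

# Greenhouse-Geisser epsilon for a one-within factor (levels averaged over
# the other factor): eps = tr(M)^2 / (q * sum(M^2)) with M = C S C' for
# orthonormal contrasts C.
gg_epsilon <- function(d, factor_name) {
  wide <- tapply(d$value, list(d$subject, d[[factor_name]]), mean)
  gg_from_cov(stats::cov(wide))
}

# Epsilon for the condition x class interaction: apply the 2-level
# condition contrast per class (the per-subject difference profile).
gg_epsilon_interaction <- function(d) {
  conds <- levels(d$condition)
  a <- tapply(d$value[d$condition == conds[1]],
              list(d$subject[d$condition == conds[1]],
                   d$class[d$condition == conds[1]]), mean)
  b <- tapply(d$value[d$condition == conds[2]],
              list(d$subject[d$condition == conds[2]],
                   d$class[d$condition == conds[2]]), mean)
  gg_from_cov(stats::cov(a - b))
}

gg_from_cov <- function(S) {
  L <- nrow(S)
  if (L <= 2) return(1)
  C <- contr_orthonormal(L)
  M <- t(C) %*% S %*% C
  q <- L - 1
  unname(sum(diag(M))^2 / (q * sum(M^2)))
}

# Orthonormal contrast matrix (L x (L-1)) via QR of centered identity.
contr_orthonormal <- function(L) {
  qr.Q(qr(stats::contr.helmert(L)))
}

#' @export
print.ms_rmanova <- function(x, ...) {
  cat(sprintf("<ms_rmanova> measure '%s', n = %d subjects\n", x$measure, x$n))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.ms_rmanova <- function(x, ...) x$table

#' @export
glance.ms_rmanova <- function(x, ...) {
  tibble(measure = x$measure, n = x$n,
         interaction.p = x$table$p.value[x$table$term == "condition:class"])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, capped at 1), via
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values, same order as input.
#' @export
fdr_bh <- function(pvalues) p.adjust(pvalues, method = "BH")

#' Post-hoc per-class condition contrasts with FDR
#'
#' Runs the 2 x K repeated-measures ANOVA for the measure and, only when
#' the condition x class interaction is significant (p < `gate_alpha`),
#' computes one paired t-test per class (smoking minus neutral) with
#' Benjamini-Hochberg correction across the K classes. The gate can be
#' overridden (`force = TRUE`), which is recorded in the result.
#'
#' @param table Long tibble (`subject`, `condition`, `class`, measure).
#' @param measure Measure column name.
#' @param gate_alpha Interaction significance gate (default 0.05).
#' @param force Run post-hocs regardless of the gate.
#' @param conditions Character vector `c(reference, treatment)`; the
#'   contrast is treatment minus reference (default neutral, smoking).
#' @return List with `anova` (`ms_rmanova`), `gated` (logical: were
#'   post-hocs suppressed), `forced`, and `posthoc` (tibble: `class`,
#'   `estimate`, `statistic`, `df`, `p.value`, `p.fdr`, `significant`; NULL
#'   when gated).
#' @export
posthoc_condition_tests <- function(table, measure, gate_alpha = 0.05,
                                    force = FALSE,
                                    conditions = c("neutral", "smoking")) {
  an <- rm_anova_2x4(table, measure)
  inter_p <- an$table$p.value[an$table$term == "condition:class"]
  gated <- inter_p >= gate_alpha && !force
  if (inter_p >= gate_alpha && force) {
    inform(sprintf(
      "interaction p = %.3f >= %.2f for '%s': post-hocs forced despite the gate",
      inter_p, gate_alpha, measure))
  }
  posthoc <- NULL
  if (!gated) {
    classes <- sort(unique(table$class))
    rows <- lapply(classes, function(cl) {
      tr <- table[table$class == cl & table$condition == conditions[2], ]
      rf <- table[table$class == cl & table$condition == conditions[1], ]
      tr <- tr[order(tr$subject), ]; rf <- rf[order(rf$subject), ]
      tt <- paired_t(tr[[measure]], rf[[measure]])
      tt$class <- cl
      tt
    })
    posthoc <- dplyr::bind_rows(rows)
    posthoc$p.fdr <- fdr_bh(posthoc$p.value)
    posthoc$significant <- posthoc$p.fdr < 0.05
    posthoc <- posthoc[, c("class", "estimate", "statistic", "df",
                           "p.value", "p.fdr", "significant")]
  }
  list(anova = an, gated = gated, forced = force && inter_p >= gate_alpha,
       posthoc = posthoc)
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length.
#' @return Tibble with `estimate` (r), `statistic` (t), `df`, `p.value`.
#' @export
pearson <- function(x, y) {
  fit <- cor.test(x, y, method = "pearson")
  tibble(estimate = unname(fit$estimate), statistic = unname(fit$statistic),
         df = unname(fit$parameter), p.value = fit$p.value)
}

#' Simple mediation analysis (model 4) with percentile bootstrap
#'
#' Ordinary-least-squares path model on standardised variables:
#' `m = a x`, `y = c' x + b m`, `y = c x`. The indirect effect `a * b` gets
#' a percentile bootstrap confidence interval over subject resampling.
#' Verdict: `"full"` when the CI excludes 0 and the direct path `c'` is
#' non-significant (two-tailed p >= 0.05); `"partial"` when the CI excludes
#' 0 and `c'` is significant; `"none"` otherwise.
#'
#' @param x,m,y Numeric vectors (predictor, mediator, outcome), complete
#'   cases, n >= 10.
#' @param n_boot Bootstrap resamples (default 5000; < 1000 warns).
#' @param conf_level CI level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return An `ms_mediation` object; `tidy()` gives the path table and
#'   `glance()` the verdict.
#' @export
mediation_model4 <- function(x, m, y, n_boot = 5000, conf_level = 0.95,
                             seed = NULL) {
  stopifnot(length(x) == length(m), length(x) == length(y))
  ok <- stats::complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) abort("mediation needs at least 10 complete cases")
  if (sd(x) == 0 || sd(m) == 0 || sd(y) == 0) abort("zero-variance input")
  if (n_boot < 1000) warn("n_boot < 1000: bootstrap CI will be unstable")
  zx <- as.vector(scale(x)); zm <- as.vector(scale(m)); zy <- as.vector(scale(y))
  path <- function(fit, term) {
    s <- summary(fit)$coefficients
    c(est = s[term, 1], se = s[term, 2], p = s[term, 4])
  }
  f_a <- lm(zm ~ zx)
  f_y <- lm(zy ~ zx + zm)
  f_c <- lm(zy ~ zx)
  a <- path(f_a, "zx"); b <- path(f_y, "zm")
  cp <- path(f_y, "zx"); cc <- path(f_c, "zx")
  indirect <- unname(a["est"] * b["est"])
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    vapply(seq_len(n_boot), function(bi) {
      i <- idx[, bi]
      xb <- zx[i]; mb <- zm[i]; yb <- zy[i]
      vx <- stats::var(xb)
      if (vx == 0) return(NA_real_)
      ab <- stats::cov(xb, mb) / vx
      # b from the two-predictor regression of y on (x, m)
      S <- stats::cov(cbind(xb, mb))
      if (abs(det(S)) < 1e-12) return(NA_real_)
      coefs <- solve(S, c(stats::cov(xb, yb), stats::cov(mb, yb)))
      ab * coefs[2]
    }, numeric(1))
  })
  alpha <- 1 - conf_level
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  excl0 <- ci[1] > 0 || ci[2] < 0
  verdict <- if (excl0 && cp["p"] >= 0.05) "full"
  else if (excl0) "partial" else "none"
  structure(
    list(
      paths = tibble(
        term = c("a", "b", "c", "c_prime", "indirect"),
        estimate = unname(c(a["est"], b["est"], cc["est"], cp["est"],
                            indirect)),
        std.error = unname(c(a["se"], b["se"], cc["se"], cp["se"],
                             stats::sd(boot, na.rm = TRUE))),
        p.value = unname(c(a["p"], b["p"], cc["p"], cp["p"], NA))
      ),
      indirect = indirect, ci = ci, conf_level = conf_level,
      n = n, n_boot = n_boot, verdict = verdict, seed = seed
    ),
    class = "ms_mediation"
  )
}

#' @export
print.ms_mediation <- function(x, ...) {
  cat(sprintf("<ms_mediation> n = %d, %d bootstrap resamples\n", x$n, x$n_boot))
  print(as.data.frame(x$paths), row.names = FALSE, digits = 3)
  cat(sprintf("  indirect %.3f, %g%% CI [%.3f, %.3f] -> verdict: %s\n",
              x$indirect, 100 * x$conf_level, x$ci[1], x$ci[2], x$verdict))
  invisible(x)
}

#' @export
tidy.ms_mediation <- function(x, ...) {
  out <- x$paths
  out$conf.low <- c(NA, NA, NA, NA, x$ci[1])
  out$conf.high <- c(NA, NA, NA, NA, x$ci[2])
  out
}

#' @export
glance.ms_mediation <- function(x, ...) {
  tibble(verdict = x$verdict, indirect = x$indirect,
         conf.low = x$ci[1], conf.high = x$ci[2],
         n = x$n, n_boot = x$n_boot, conf_level = x$conf_level)
}
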