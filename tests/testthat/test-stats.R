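test_that("paired t matches the closed form and handles degenerate input", {
  x <- c(2, 4, 6, 8)
  y <- x - c(1, 2, 3, 4)          # differences 1,2,3,4
  res <- paired_t(x, y)
  expect_equal(res$statistic, 2.5 / (sd(1:4) / 2), tolerance = 1e-4)
  expect_equal(round(res$statistic, 4), 3.873)
  expect_equal(res$df, 3)
  expect_equal(res$estimate, 2.5)

  same <- paired_t(1:5, 1:5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  expect_error(paired_t(c(1, 2), c(0, 1)), "zero variance")
})

test_that("BH adjustment matches hand-applied and brute-force step-up", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- fdr_bh(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order-preserving
  }
})

test_that("rm-ANOVA F statistics equal the sum-of-squares oracle", {
  for (s in 1:5) {
    tab <- random_rm_table(n_subjects = sample(6:12, 1), seed = s)
    fit <- rm_anova_2x4(tab, "value")
    oracle <- rm_anova_oracle(tab)
    td <- tidy(fit)
    expect_equal(td$statistic[td$term == "condition"], oracle$F_condition,
                 tolerance = 1e-9)
    expect_equal(td$statistic[td$term == "class"], oracle$F_class,
                 tolerance = 1e-9)
    expect_equal(td$statistic[td$term == "condition:class"],
                 oracle$F_interaction, tolerance = 1e-9)
    # full decomposition: components add to the total sum of squares
    expect_equal(sum(oracle$ss[-1]), oracle$ss[["total"]], tolerance = 1e-9)
    # epsilon bounds: 1/(L-1) <= eps <= 1
    expect_true(all(td$gg_epsilon >= 1 / 3 - 1e-9 & td$gg_epsilon <= 1 + 1e-9))
  }
})

test_that("a pure condition shift moves only the condition effect", {
  tab <- random_rm_table(10, seed = 42)
  fit0 <- rm_anova_2x4(tab, "value")
  tab2 <- tab
  tab2$value[tab2$condition == "smoking"] <-
    tab2$value[tab2$condition == "smoking"] + 5
  fit1 <- rm_anova_2x4(tab2, "value")
  F0 <- tidy(fit0); F1 <- tidy(fit1)
  expect_gt(F1$statistic[F1$term == "condition"],
            F0$statistic[F0$term == "condition"])
  expect_equal(F1$statistic[F1$term == "condition:class"],
               F0$statistic[F0$term == "condition:class"], tolerance = 1e-9)
  expect_equal(F1$statistic[F1$term == "class"],
               F0$statistic[F0$term == "class"], tolerance = 1e-9)
})

test_that("rm-ANOVA rejects incomplete designs", {
  tab <- random_rm_table(6, seed = 1)
  expect_error(rm_anova_2x4(tab[-1, ], "value"), "balanced")
})

test_that("post-hoc tests are gated on the interaction and FDR-corrected", {
  # strong interaction: class-specific condition effects
  tab <- random_rm_table(12, seed = 7)
  bump <- c(A = 0, B = 3, C = 4, D = 5)
  tab$value <- tab$value + ifelse(tab$condition == "smoking",
                                  bump[tab$class], 0)
  res <- posthoc_condition_tests(tab, "value")
  expect_false(res$gated)
  expect_equal(nrow(res$posthoc), 4)
  expect_equal(res$posthoc$p.fdr, fdr_bh(res$posthoc$p.value))
  expect_true(all(res$posthoc$significant[res$posthoc$class %in% c("B", "C", "D")]))

  # null data: gate suppresses the post-hocs (checked over a few seeds to
  # dodge chance interactions)
  gated_any <- FALSE
  for (s in 1:5) {
    null <- random_rm_table(8, seed = 100 + s)
    r0 <- posthoc_condition_tests(null, "value")
    if (r0$gated) {
      gated_any <- TRUE
      expect_null(r0$posthoc)
    }
  }
  expect_true(gated_any)

  # forcing past the gate is possible and flagged
  null <- random_rm_table(8, seed = 321)
  r1 <- suppressMessages(posthoc_condition_tests(null, "value", force = TRUE))
  expect_false(r1$gated)
  expect_equal(nrow(r1$posthoc), 4)
})

test_that("pearson matches the closed form", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$estimate, 1)
  expect_lt(abs(pearson(c(1, -1, 1, -1), c(1, 1, -1, -1))$estimate), 1e-12)
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b)$estimate, hand, tolerance = 1e-12)
})

test_that("mediation paths, bootstrap reproducibility and verdicts behave", {
  d <- simulate_mediation_data(200, a = 0.6, b = 0.6, c_prime = 0, seed = 3)
  m1 <- mediation_model4(d$x, d$m, d$y, n_boot = 2000, seed = 4)
  m2 <- mediation_model4(d$x, d$m, d$y, n_boot = 2000, seed = 4)
  expect_identical(m1$ci, m2$ci)
  expect_equal(m1$verdict, "full")
  td <- tidy(m1)
  expect_equal(td$estimate[td$term == "indirect"],
               td$estimate[td$term == "a"] * td$estimate[td$term == "b"],
               tolerance = 1e-12)
  # standardised total effect ~ a*b + c'
  expect_equal(td$estimate[td$term == "c"],
               cor(d$x, d$y), tolerance = 1e-9)

  # y = x exactly with a noise mediator: strong direct path, no mediation
  set.seed(5)
  x <- rnorm(40); mnoise <- rnorm(40)
  res <- mediation_model4(x, mnoise, x + rnorm(40, 0, 1e-8),
                          n_boot = 1500, seed = 6)
  expect_equal(res$verdict, "none")
  p_c <- res$paths$p.value[res$paths$term == "c"]
  expect_lt(p_c, 1e-6)
  expect_true(res$ci[1] <= 0 && res$ci[2] >= 0)

  expect_error(mediation_model4(1:5, 1:5, 1:5), "10")
  expect_error(mediation_model4(rep(1, 12), rnorm(12), rnorm(12)),
               "zero-variance")
  expect_warning(mediation_model4(rnorm(20), rnorm(20), rnorm(20),
                                  n_boot = 500, seed = 1), "unstable")
})

test_that("glance and print surfaces expose the verdict", {
  d <- simulate_mediation_data(60, a = 0.7, b = 0.7, seed = 8)
  m <- mediation_model4(d$x, d$m, d$y, n_boot = 1200, seed = 9)
  g <- glance(m)
  expect_true(g$verdict %in% c("full", "partial", "none"))
  expect_equal(g$n, 60)
  expect_output(print(m), "verdict")
})
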