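test_that("generated templates are zero-mean, unit-norm and separated", {
  m <- fx_montage()
  tpl <- generate_templates(m, 4, min_separation = 0.7, seed = 1)
  expect_equal(dim(tpl), c(4, 64))
  expect_lt(max(abs(rowMeans(tpl))), 1e-12)
  expect_lt(max(abs(rowSums(tpl^2) - 1)), 1e-12)
  C <- tpl %*% t(tpl)
  expect_lt(max(abs(C[upper.tri(C)])), 0.7 + 1e-12)
})

test_that("orthogonal construction gives exactly uncorrelated maps", {
  tpl <- generate_templates(fx_montage(), 2, orthogonalize = TRUE, seed = 2)
  expect_lt(abs(spatial_correlation(tpl[1, ], tpl[2, ])), 1e-12)
})

test_that("a map and its sign-flip are perfectly anti/co-related", {
  tpl <- generate_templates(fx_montage(), 2, seed = 3)
  expect_equal(spatial_correlation(tpl[1, ], -tpl[1, ]), -1)
  expect_equal(spatial_correlation(tpl[1, ], -tpl[1, ],
                                   polarity_invariant = TRUE), 1)
})

test_that("unreachable separation fails after bounded retries", {
  expect_error(
    generate_templates(fx_montage(), 6, min_separation = 0.001,
                       max_tries = 10, seed = 4),
    "min_separation"
  )
})

test_that("state sequences have the requested length and no self-transitions", {
  lab <- generate_state_sequence(4, 250, rep(100, 4), seed = 5)
  expect_length(lab, 1000)
  r <- rle(lab)
  expect_true(all(diff(r$values) != 0))
  expect_true(all(lab %in% 1:4))
})

test_that("a single-class sequence is one run covering all samples", {
  lab <- generate_state_sequence(2, 250, 100, seed = 6)
  expect_equal(lab, rep(1L, 500))
})

test_that("empirical dwell times match the gamma target in mean and spread", {
  # Monte-Carlo: interior (non-truncated) run lengths across many seeds
  shape <- 4
  lens <- unlist(lapply(1:50, function(s) {
    lab <- generate_state_sequence(60, 250, rep(100, 4), shape, seed = s)
    r <- rle(lab)
    r$lengths[-c(1, length(r$lengths))] * 4   # ms at 250 Hz
  }))
  expect_lt(abs(mean(lens) - 100), 10)
  # coefficient of variation close to the gamma prediction 1/sqrt(shape)
  cv <- sd(lens) / mean(lens)
  expect_lt(abs(cv - 1 / sqrt(shape)) / (1 / sqrt(shape)), 0.15)
})

test_that("recordings have coherent dimensions, truth labels and provenance", {
  truth <- make_ground_truth(fx_montage())
  rec <- generate_recording(truth, "smoking", n_trials = 2, trial_s = 10,
                            seed = 7)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$data), 64)
  expect_length(rec$labels_true, ncol(rec$data))
  expect_length(rec$onsets_s, 2)
  expect_error(generate_recording(truth, "placebo"), "condition")
})

test_that("noiseless recordings are perfectly identifiable at GFP peaks", {
  truth <- make_ground_truth(fx_montage(),
                             alpha_amp = c(neutral = 0, smoking = 0))
  rec <- generate_recording(truth, "neutral", n_trials = 1, trial_s = 8,
                            noise_amp = 0, seed = 8)
  # minimal chain: 1 s windows + average reference, filters disabled
  ep <- make_epochs(rec$data, rec$srate, truth$montage)
  ep <- average_reference(ep)
  tpl <- microstatr:::new_ms_templates(truth$templates, truth$montage$name)
  seg <- backfit(ep, tpl)
  expect_gt(length(seg$peaks), 50)
  expect_equal(seg$peak_labels, rec$labels_true[seg$peaks])
})

test_that("alpha injection raises posterior alpha power above the no-alpha baseline", {
  t0 <- make_ground_truth(fx_montage(), alpha_amp = c(neutral = 0, smoking = 0))
  t1 <- make_ground_truth(fx_montage(), alpha_amp = c(neutral = 3, smoking = 3))
  p <- sapply(list(t0, t1), function(tr) {
    rec <- generate_recording(tr, "neutral", n_trials = 1, trial_s = 8,
                              seed = 9)
    posterior_alpha_power(make_epochs(rec$data, rec$srate, tr$montage))$power
  })
  expect_lt(p[1], p[2])
  # injected amplitude A contributes ~A^2/2
  expect_lt(abs((p[2] - p[1]) - 3^2 / 2) / (3^2 / 2), 0.25)
})

test_that("cohort generation is reproducible and carries ground truth", {
  a <- generate_cohort(4, n_trials = 1, trial_s = 6, seed = 10)
  b <- generate_cohort(4, n_trials = 1, trial_s = 6, seed = 10)
  expect_identical(a$behaviour, b$behaviour)
  expect_identical(a$recordings[[1]]$data, b$recordings[[1]]$data)
  expect_identical(a$truth_params, b$truth_params)
  expect_equal(sort(unique(a$truth_params$condition)),
               c("neutral", "smoking"))
  expect_equal(nrow(a$behaviour), 4)
})

test_that("null effects give zero expected condition difference in dwell truth", {
  co <- generate_cohort(40, effect_config = null_effects(),
                        signal = "labels", n_trials = 1, trial_s = 10,
                        seed = 11)
  st <- co$subject_truth
  d <- st$dwell_smoking_ms - st$dwell_neutral_ms
  # per-class mean generating difference is centred on zero
  for (k in 1:4) {
    dk <- d[st$class == k]
    expect_lt(abs(mean(dk)) / 100, 0.03)
  }
})

test_that("a zero behaviour-link slope leaves craving unrelated to class-C dwell", {
  rs <- sapply(1:10, function(s) {
    truth <- make_ground_truth(fx_montage(8))
    truth$behaviour_link$alpha_dwell_slope <- 0
    truth$behaviour_link$craving_slope <- 0
    co <- generate_cohort(20, truth = truth, signal = "labels",
                          n_trials = 1, trial_s = 20, seed = s)
    tp <- co$truth_params
    dC <- tp$duration_ms[tp$class == 3 & tp$condition == "smoking"] -
      tp$duration_ms[tp$class == 3 & tp$condition == "neutral"]
    dcrav <- co$behaviour$craving_smoking - co$behaviour$craving_neutral
    cor(dC, dcrav)
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("mediation test data obeys its generating model", {
  d <- simulate_mediation_data(5000, a = 0.5, b = 0.5, c_prime = 0, seed = 12)
  expect_equal(cor(d$x, d$m), 0.5, tolerance = 0.05)
  # no direct path: partial correlation of x and y given m is near zero
  rxy <- cor(d$x, d$y); rxm <- cor(d$x, d$m); rmy <- cor(d$m, d$y)
  pc <- (rxy - rxm * rmy) / sqrt((1 - rxm^2) * (1 - rmy^2))
  expect_lt(abs(pc), 0.05)
})
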