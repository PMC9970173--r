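tpl_set <- function(tpl, montage = fx_montage()) {
  microstatr:::new_ms_templates(tpl, montage$name, LETTERS[seq_len(nrow(tpl))])
}

# epoch set whose GFP peaks and labels are fully controlled: each sample is
# template[lab] * envelope, so peak maps equal templates exactly.
controlled_epochs <- function(tpl, lab, env, srate = 250) {
  data <- t(tpl[lab, , drop = FALSE]) * rep(env, each = ncol(tpl))
  make_epochs(data, srate)
}

test_that("peak maps equal to a template get that template's label", {
  tpl <- fx_templates()
  lab <- rep(c(1, 3, 2, 4), each = 25)                 # 100 samples
  env <- rep(abs(sin(pi * (1:25) / 26)), 4)            # peaks inside runs
  ep <- controlled_epochs(tpl, rep(lab, 3), rep(env, 3), srate = 100)
  seg <- backfit(ep, tpl_set(tpl))
  expect_equal(seg$peak_labels, rep(lab, 3)[seg$peaks])
  expect_true(all(seg$peak_corr > 0.999))
})

test_that("non-peak samples inherit the nearest peak label, earlier on ties", {
  tpl <- fx_templates()
  # one epoch of 30 samples; peaks forced at samples 10 and 20
  env <- rep(0.5, 30); env[10] <- 1; env[20] <- 1
  lab <- c(rep(1, 15), rep(2, 15))
  ep <- controlled_epochs(tpl, lab, env, srate = 30)
  seg <- backfit(ep, tpl_set(tpl))
  expect_equal(seg$peaks, c(10L, 20L))
  expect_equal(seg$labels[15], seg$labels[10])   # equidistant -> earlier
  expect_equal(seg$labels[1:14], rep(seg$labels[10], 14))
  expect_equal(seg$labels[16:30], rep(seg$labels[20], 15))
})

test_that("epochs without GFP peaks stay unassigned and are excluded", {
  tpl <- fx_templates()
  env1 <- abs(sin(pi * ((1:50) - 0.2) / 50))
  flat <- rep(1, 50)                                  # monotone GFP: no peak
  ep <- controlled_epochs(tpl, rep(1, 100), c(env1, flat), srate = 50)
  seg <- backfit(ep, tpl_set(tpl))
  expect_true(all(is.na(seg$labels[51:100])))
  expect_true(all(!is.na(seg$labels[1:50])))
  pars <- compute_parameters(seg)
  expect_equal(sum(pars$n_samples), 50)
})

test_that("template electrode-count mismatch is an error", {
  tpl <- fx_templates()
  ep <- make_epochs(matrix(rnorm(8 * 250), 8), 250)
  expect_error(backfit(ep, tpl_set(tpl)), "electrode")
})

test_that("parameter arithmetic matches closed forms", {
  seg <- microstatr:::new_ms_segmentation(
    labels = rep(c(1L, 2L), each = 125), epoch = rep(1L, 250),
    gfp = rep(1, 250), peaks = c(60L, 190L), peak_labels = c(1L, 2L),
    peak_corr = c(1, 1), srate = 250, class_labels = c("A", "B"))
  pars <- compute_parameters(seg)
  expect_equal(pars$duration_ms, c(500, 500))
  expect_equal(pars$occurrence_per_s, c(1, 1))
  expect_equal(pars$contribution, c(0.5, 0.5))

  # all one class over several epochs
  seg2 <- microstatr:::new_ms_segmentation(
    labels = rep(1L, 500), epoch = rep(1:2, each = 250),
    gfp = rep(1, 500), peaks = c(60L, 310L), peak_labels = c(1L, 1L),
    peak_corr = c(1, 1), srate = 250, class_labels = c("A", "B"))
  p2 <- compute_parameters(seg2)
  expect_equal(p2$contribution, c(1, 0))
  expect_equal(p2$occurrence_per_s[1], 2 / 2)  # one run per 1 s epoch
  expect_equal(p2$duration_ms[2], 0)
})

test_that("parameters equal an independent run-length oracle on random labels", {
  set.seed(4)
  for (i in 1:10) {
    n <- 600
    labels <- sample(1:4, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    epoch <- rep(1:3, each = 200)
    seg <- microstatr:::new_ms_segmentation(
      labels = labels, epoch = epoch, gfp = runif(n), peaks = integer(),
      peak_labels = integer(), peak_corr = numeric(), srate = 200,
      class_labels = LETTERS[1:4])
    pars <- compute_parameters(seg)
    oracle <- rle_params_oracle(labels, epoch, 200, 4)
    expect_equal(pars$duration_ms, unname(oracle[, "duration_ms"]))
    expect_equal(pars$occurrence_per_s, unname(oracle[, "occurrence_per_s"]))
    expect_equal(pars$contribution, unname(oracle[, "contribution"]))
  }
})

test_that("contribution = occurrence x duration and contributions sum to one", {
  truth <- make_ground_truth(fx_montage())
  rec <- generate_recording(truth, "neutral", n_trials = 1, trial_s = 10,
                            seed = 5)
  ep <- average_reference(make_epochs(rec$data, rec$srate, truth$montage))
  seg <- backfit(ep, tpl_set(truth$templates))
  pars <- compute_parameters(seg)
  expect_equal(sum(pars$contribution), 1, tolerance = 1e-9)
  expect_equal(pars$contribution,
               pars$occurrence_per_s * pars$duration_ms / 1000,
               tolerance = 1e-9)
  # excluding truncated runs changes duration but not contribution
  pars2 <- compute_parameters(seg, include_truncated = FALSE)
  expect_equal(pars2$contribution, pars$contribution)
  expect_true(all(pars2$n_runs <= pars$n_runs))
})

test_that("sign flips and positive rescaling leave labels and parameters unchanged", {
  truth <- make_ground_truth(fx_montage())
  rec <- generate_recording(truth, "smoking", n_trials = 1, trial_s = 8,
                            seed = 6)
  tset <- tpl_set(truth$templates)
  base <- average_reference(make_epochs(rec$data, rec$srate, truth$montage))
  seg0 <- backfit(base, tset)

  flip <- average_reference(make_epochs(-rec$data, rec$srate, truth$montage))
  segf <- backfit(flip, tset)
  expect_identical(segf$labels, seg0$labels)
  expect_identical(segf$peaks, seg0$peaks)
  expect_equal(compute_parameters(segf), compute_parameters(seg0))

  scaled <- average_reference(make_epochs(3.7 * rec$data, rec$srate,
                                          truth$montage))
  segs <- backfit(scaled, tset)
  expect_identical(segs$labels, seg0$labels)
  expect_equal(segs$gfp, 3.7 * seg0$gfp, tolerance = 1e-9)
  expect_equal(compute_parameters(segs), compute_parameters(seg0))
  expect_equal(compute_gev(segs), compute_gev(seg0), tolerance = 1e-9)
})

test_that("polarity-flipped input data yields templates identical up to sign", {
  truth <- make_ground_truth(fx_montage())
  rec <- generate_recording(truth, "neutral", n_trials = 1, trial_s = 8,
                            seed = 7)
  ep <- average_reference(make_epochs(rec$data, rec$srate, truth$montage))
  epf <- average_reference(make_epochs(-rec$data, rec$srate, truth$montage))
  f1 <- fit_individual_templates(ep, k = 4, n_restarts = 5, seed = 8)
  f2 <- fit_individual_templates(epf, k = 4, n_restarts = 5, seed = 8)
  C <- abs(f1$maps %*% t(f2$maps))
  expect_equal(unname(sort(apply(C, 1, max))), rep(1, 4), tolerance = 1e-9)
})

test_that("GEV is one for perfectly fitting data and degrades under shuffling", {
  tpl <- fx_templates()
  lab <- rep(rep(1:4, each = 25), 2)
  env <- rep(rep(abs(sin(pi * (1:25) / 26)), 4), 2)
  ep <- controlled_epochs(tpl, lab, env, srate = 100)
  seg <- backfit(ep, tpl_set(tpl))
  expect_equal(compute_gev(seg), 1, tolerance = 1e-9)

  # shuffled peak labels: strictly lower GEV
  seg_bad <- seg
  set.seed(9)
  seg_bad$peak_labels <- sample(seg$peak_labels)
  tplm <- microstatr:::normalize_maps(tpl)
  L <- 100
  pm <- t(sapply(seg$peaks, function(p) {
    e <- ((p - 1) %/% L) + 1; s <- ((p - 1) %% L) + 1
    ep$epochs[[e]][, s]
  }))
  pm <- microstatr:::normalize_maps(pm)
  seg_bad$peak_corr <- abs(rowSums(pm * tplm[seg_bad$peak_labels, ]))
  expect_lt(compute_gev(seg_bad), compute_gev(seg))

  # small instance equals the hand-expanded sum
  g <- seg$gfp[seg$peaks]
  hand <- sum((g * seg$peak_corr)^2) / sum(g^2)
  expect_equal(compute_gev(seg), hand, tolerance = 1e-12)
})

test_that("sample-based GEV agrees with the peak-based value on clean data", {
  tpl <- fx_templates()
  lab <- rep(1:4, each = 50)
  env <- rep(abs(sin(pi * ((1:50) - 0.2) / 50)), 4)
  ep <- controlled_epochs(tpl, lab, env, srate = 100)
  seg <- backfit(ep, tpl_set(tpl))
  gs <- compute_gev(seg, ep, tpl_set(tpl), method = "samples")
  expect_gt(gs, 0.999)
  expect_equal(gs, compute_gev(seg), tolerance = 1e-3)
  expect_error(compute_gev(seg, method = "samples"), "templates")
})
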