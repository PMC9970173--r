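sinusoid_rec <- function(freq_hz, amp = 1, srate = 250, dur_s = 10,
                         n_ch = 4, dc = 0) {
  tt <- (seq_len(dur_s * srate) - 1) / srate
  data <- matrix(rep(amp * sin(2 * pi * freq_hz * tt) + dc, each = n_ch),
                 n_ch)
  montage <- fx_montage(n_ch)
  eeg_recording(data, srate, montage$name, montage, onsets_s = 1)
}

trim <- function(x, srate, s = 1) x[(s * srate):(length(x) - s * srate)]

test_that("band-pass keeps in-band sinusoids and removes out-of-band power", {
  rec10 <- sinusoid_rec(10)
  out10 <- bandpass(rec10, 2, 20)
  a <- max(abs(trim(out10$data[1, ], 250)))
  expect_lt(abs(a - 1), 0.05)
  expect_equal(out10$srate, 250)

  rec40 <- sinusoid_rec(40)
  out40 <- bandpass(rec40, 2, 20)
  rms_in <- sqrt(mean(trim(rec40$data[1, ], 250)^2))
  rms_out <- sqrt(mean(trim(out40$data[1, ], 250)^2))
  expect_lt(rms_out / rms_in, 0.05)
})

test_that("broadband filtering removes a DC offset", {
  rec <- sinusoid_rec(10, dc = 50, dur_s = 40)
  out <- bandpass(rec, 0.1, 80)
  expect_lt(abs(mean(trim(out$data[1, ], 250, 10))), 0.5)
})

test_that("band edges outside Nyquist are rejected", {
  rec <- sinusoid_rec(10)
  expect_error(bandpass(rec, 2, 200), "Nyquist")
  expect_error(bandpass(rec, 30, 20), "Nyquist|band")
})

test_that("epoching windows, baseline correction and selection follow the timing rules", {
  # constant channel: baseline correction cancels everything
  srate <- 100
  montage <- fx_montage(2)
  data <- matrix(7, 2, 95 * srate)
  rec <- eeg_recording(data, srate, montage$name, montage, onsets_s = 2)
  ep <- epoch_and_baseline(rec, t_min_s = -1, t_max_s = 90,
                           baseline = c(-1, 0), select = c(1, 89))
  expect_equal(n_epochs(ep), 1)
  expect_equal(ncol(ep$epochs[[1]]), 88 * srate)
  expect_true(all(ep$epochs[[1]] == 0))

  # onset too close to the edge: trial dropped with a warning
  expect_warning(
    ep0 <- epoch_and_baseline(rec, onsets_s = 100, t_min_s = -1,
                              t_max_s = 90),
    "dropped"
  )
  expect_equal(n_epochs(ep0), 0)
})

test_that("the default trial window arithmetic yields 88 x 250 samples", {
  srate <- 250
  montage <- fx_montage(2)
  rec <- eeg_recording(matrix(rnorm(2 * 95 * srate), 2), srate,
                       montage$name, montage, onsets_s = 2)
  ep <- epoch_and_baseline(rec)
  expect_equal(ncol(ep$epochs[[1]]), 22000)
  seg <- segment_1s(ep)
  expect_equal(n_epochs(seg), 88)
  expect_equal(ncol(seg$epochs[[1]]), 250)
})

test_that("1 s segmentation truncates trailing partial windows", {
  ep <- make_epochs(matrix(rnorm(2 * 625), 2), 250)  # builds full windows
  expect_equal(n_epochs(ep), 2)
  # direct check of the truncation rule on a 2.5 s trial epoch
  montage <- fx_montage(2)
  trial <- microstatr:::new_eeg_epochs(
    list(matrix(rnorm(2 * 625), 2)), 250, 2.5, montage$name, montage,
    "t", "neutral")
  seg <- segment_1s(trial)
  expect_equal(n_epochs(seg), 2)
  empty <- microstatr:::new_eeg_epochs(list(), 250, 1, montage$name,
                                       montage, "t", "neutral")
  expect_equal(n_epochs(segment_1s(empty)), 0)
})

test_that("amplitude rejection applies both criteria and stays monotone", {
  montage <- fx_montage(2)
  mk <- function(peak) {
    e <- matrix(0, 2, 100)
    e[1, 50] <- peak
    e
  }
  eps <- c(lapply(c(150, 150, 150), mk), lapply(rep(50, 7), mk))
  set <- microstatr:::new_eeg_epochs(eps, 100, 1, montage$name, montage,
                                     "t", "neutral")
  kept <- reject_amplitude(set, 100)
  expect_equal(n_epochs(kept), 7)
  expect_equal(sum(kept$kept_mask), 7)

  # epoch with all samples within +/-99 is kept
  ok <- microstatr:::new_eeg_epochs(list(matrix(99, 2, 100) * sin(1:100)),
                                    100, 1, montage$name, montage, "t", "n")
  expect_equal(n_epochs(reject_amplitude(ok, 100)), 1)

  # the two criteria are separable: a large constant offset has zero
  # peak-to-peak range but violates the absolute bound
  flat <- matrix(150, 2, 100)
  s2 <- microstatr:::new_eeg_epochs(list(flat, matrix(0, 2, 100)), 100, 1,
                                    montage$name, montage, "t", "n")
  expect_equal(n_epochs(reject_amplitude(s2, 100, criterion = "ptp")), 2)
  expect_equal(n_epochs(reject_amplitude(s2, 100, criterion = "abs")), 1)

  # monotone: every epoch kept at threshold t1 < t2 is kept at t2
  set.seed(1)
  sds <- seq(10, 60, length.out = 20)
  eps <- lapply(sds, function(s) matrix(rnorm(200, 0, s), 2))
  s3 <- microstatr:::new_eeg_epochs(eps, 100, 1, montage$name, montage,
                                    "t", "n")
  for (th in c(60, 80, 100, 120)) {
    k_lo <- reject_amplitude(s3, th)$epoch_index
    k_hi <- reject_amplitude(s3, th + 20)$epoch_index
    expect_true(all(k_lo %in% k_hi))
  }
  # all epochs rejected is a hard, named error
  loud <- microstatr:::new_eeg_epochs(list(matrix(500, 2, 100)), 100, 1,
                                      montage$name, montage, "s07", "smoking")
  expect_error(reject_amplitude(loud, 100), "s07.*smoking")
})

test_that("downsampling scales counts exactly and preserves the passband", {
  tt <- (0:999) / 1000
  montage <- fx_montage(2)
  data <- matrix(rep(sin(2 * pi * 10 * tt), each = 2), 2)
  set <- microstatr:::new_eeg_epochs(list(data, data), 1000, 1,
                                     montage$name, montage, "t", "n")
  ds <- downsample(set, 250)
  expect_equal(ds$srate, 250)
  expect_equal(ncol(ds$epochs[[1]]), 250)
  a <- max(abs(ds$epochs[[1]][1, 50:200]))
  expect_lt(abs(a - 1), 0.05)
  # no-op at the target rate
  set250 <- microstatr:::new_eeg_epochs(list(data[, 1:250]), 250, 0.25,
                                        montage$name, montage, "t", "n")
  expect_identical(downsample(set250, 250)$epochs, set250$epochs)
  expect_error(downsample(set250, 500), "exceeds")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  ep <- make_epochs(matrix(rnorm(8 * 500), 8), 250)
  ar <- average_reference(ep)
  mx <- max(vapply(ar$epochs, function(e) max(abs(colMeans(e))), numeric(1)))
  expect_lt(mx, 1e-10)
  ar2 <- average_reference(ar)
  expect_equal(ar2$epochs, ar$epochs, tolerance = 1e-12)
  # two channels (+3, +1) -> (+1, -1)
  two <- make_epochs(matrix(c(3, 1), 2, 100), 100)
  expect_equal(unname(average_reference(two)$epochs[[1]][, 1]), c(1, -1))
})

test_that("posterior alpha power matches the sinusoid closed form and an independent oracle", {
  srate <- 250
  montage <- fx_montage(64)
  tt <- (seq_len(8 * srate) - 1) / srate
  amp <- 2
  wave <- amp * sin(2 * pi * 10 * tt + 0.3)
  data <- matrix(0, 64, length(tt))
  post <- microstatr:::match_electrodes(default_posterior_set(), montage$name)
  data[post, ] <- rep(wave, each = length(post))
  ep <- make_epochs(data, srate, montage)
  res <- posterior_alpha_power(ep)
  expect_lt(abs(res$power - amp^2 / 2) / (amp^2 / 2), 0.10)
  # independent direct-DFT oracle on one epoch
  oracle <- band_power_oracle(ep$epochs[[1]][post[1], ], srate, c(8, 12))
  one <- posterior_alpha_power(
    microstatr:::new_eeg_epochs(ep$epochs[1], srate, 1, montage$name,
                                montage, "t", "n"),
    electrode_set = montage$name[post[1]])
  expect_equal(one$power, oracle, tolerance = 1e-9)
  expect_error(posterior_alpha_power(ep, electrode_set = "XX"), "unknown")
})

test_that("alpha band power separates from other bands and scales quadratically", {
  srate <- 250
  montage <- fx_montage(64)
  tt <- (seq_len(4 * srate) - 1) / srate
  post <- microstatr:::match_electrodes(default_posterior_set(), montage$name)
  mk <- function(freq, amp) {
    data <- matrix(0, 64, length(tt))
    data[post, ] <- rep(amp * sin(2 * pi * freq * tt), each = length(post))
    make_epochs(data, srate, montage)
  }
  ep30 <- mk(30, 1)
  p_alpha <- posterior_alpha_power(ep30, band = c(8, 12))$power
  p_own <- posterior_alpha_power(ep30, band = c(28, 32))$power
  expect_lt(p_alpha / p_own, 0.01)

  p1 <- posterior_alpha_power(mk(10, 1))$power
  p2 <- posterior_alpha_power(mk(10, 2))$power
  expect_lt(abs(p2 / p1 - 4), 0.04)
})

test_that("EOG regression removes a linear blink contribution", {
  set.seed(3)
  srate <- 100
  n <- 10 * srate
  montage <- fx_montage(6)
  blink <- rnorm(n)
  eeg <- matrix(rnorm(5 * n, 0, 0.5), 5)
  eeg <- eeg + outer(c(0.9, 0.5, 0.3, 0.1, 0.05), blink)
  data <- rbind(eeg, blink)
  names6 <- c(montage$name[1:5], "VEOU")
  m6 <- montage; m6$name <- names6
  ep <- make_epochs(data, srate, m6)
  out <- regress_eog(ep, "VEOU")
  expect_equal(length(out$channel_names), 5)
  # residual correlation with the blink channel is near zero
  resid <- do.call(cbind, out$epochs)
  expect_lt(max(abs(cor(t(resid), blink))), 0.05)
})
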