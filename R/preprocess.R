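# Preprocessing: filtering, epoching, baseline correction, 1 s
# segmentation, amplitude rejection, downsampling, average reference,
# posterior alpha power. The canonical order is: broadband filter ->
# epoch/baseline -> select window -> (optional EOG regression) -> 1 s
# segmentation -> amplitude rejection -> downsample -> analysis band
# filter -> average reference.

# Cascaded zero-phase Butterworth band-pass of a channels x samples matrix:
# high-pass then low-pass, each applied forward-backward (filtfilt), which
# is numerically robust for very low cut-offs relative to one combined
# band-pass design.
filter_matrix <- function(data, srate, low_hz, high_hz, order = 4) {
  nyq <- srate / 2
  if (low_hz < 0 || high_hz <= low_hz || high_hz >= nyq) {
    abort(sprintf("band (%g, %g) Hz outside (0, Nyquist = %g)", low_hz,
                  high_hz, nyq))
  }
  out <- data
  if (low_hz > 0) {
    hp <- signal::butter(order, low_hz / nyq, type = "high")
    out <- t(apply(out, 1, function(ch) signal::filtfilt(hp, ch)))
  }
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  t(apply(out, 1, function(ch) signal::filtfilt(lp, ch)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass per
#' channel, implemented as a high-pass / low-pass cascade. `order` is the
#' order of each Butterworth prototype (default 4); forward-backward
#' application doubles the effective roll-off. A `low_hz` of 0 gives a pure
#' low-pass.
#'
#' @param x An `eeg_recording` or `eeg_epochs` object.
#' @param low_hz,high_hz Band edges in Hz; `0 <= low_hz < high_hz <
#'   srate/2`.
#' @param order Butterworth prototype order.
#' @return Object of the same class with filtered data; sampling rate
#'   unchanged.
#' @export
bandpass <- function(x, low_hz, high_hz, order = 4) UseMethod("bandpass")

#' @export
bandpass.eeg_recording <- function(x, low_hz, high_hz, order = 4) {
  x$data <- filter_matrix(x$data, x$srate, low_hz, high_hz, order)
  x
}

#' @export
bandpass.eeg_epochs <- function(x, low_hz, high_hz, order = 4) {
  x$epochs <- lapply(x$epochs, filter_matrix, srate = x$srate,
                     low_hz = low_hz, high_hz = high_hz, order = order)
  x
}

#' Epoch a recording around trial onsets with baseline correction
#'
#' Cuts `[t_min_s, t_max_s]` windows around each onset, subtracts the
#' per-channel mean of the `baseline` window, and retains only the `select`
#' sub-window (relative to onset). Onsets too close to the recording edge
#' are dropped with a warning.
#'
#' @param recording An `eeg_recording`.
#' @param onsets_s Trial onset times in seconds; defaults to the onsets
#'   stored in the recording.
#' @param t_min_s,t_max_s Epoch window relative to onset (seconds).
#' @param baseline Baseline window `c(from, to)` relative to onset.
#' @param select Retained sub-window `c(from, to)` relative to onset.
#' @return An `eeg_epochs` with one epoch per retained trial.
#' @export
epoch_and_baseline <- function(recording, onsets_s = NULL, t_min_s = -1,
                               t_max_s = 90, baseline = c(-1, 0),
                               select = c(1, 89)) {
  rec <- recording
  if (is.null(onsets_s)) onsets_s <- rec$onsets_s
  if (!length(onsets_s)) abort("no trial onsets given")
  fs <- rec$srate
  n <- ncol(rec$data)
  epochs <- list()
  trial <- integer()
  for (i in seq_along(onsets_s)) {
    on <- onsets_s[i]
    i0 <- round((on + t_min_s) * fs) + 1
    i1 <- round((on + t_max_s) * fs)
    if (i0 < 1 || i1 > n) {
      warn(sprintf("trial %d at %g s does not fit in the recording; dropped",
                   i, on))
      next
    }
    b0 <- round((on + baseline[1]) * fs) + 1
    b1 <- round((on + baseline[2]) * fs)
    bl <- rowMeans(rec$data[, b0:b1, drop = FALSE])
    s0 <- round((on + select[1]) * fs) + 1
    s1 <- round((on + select[2]) * fs)
    epochs[[length(epochs) + 1]] <- rec$data[, s0:s1, drop = FALSE] - bl
    trial <- c(trial, i)
  }
  new_eeg_epochs(epochs, srate = fs, epoch_s = diff(select),
                 channel_names = rec$channel_names, montage = rec$montage,
                 subject_id = rec$subject_id, condition = rec$condition,
                 trial = trial)
}

#' Segment trial epochs into non-overlapping 1 s windows
#'
#' Each epoch is cut into consecutive windows of `window_s` seconds; a
#' trailing partial window is discarded.
#'
#' @param epochset An `eeg_epochs` (e.g. one epoch per trial).
#' @param window_s Window length in seconds (default 1).
#' @return An `eeg_epochs` of fixed-length windows; provenance tracks the
#'   source trial of every window.
#' @export
segment_1s <- function(epochset, window_s = 1) {
  L <- round(window_s * epochset$srate)
  out <- list(); trial <- integer()
  for (i in seq_along(epochset$epochs)) {
    e <- epochset$epochs[[i]]
    nwin <- ncol(e) %/% L
    for (w in seq_len(nwin)) {
      out[[length(out) + 1]] <- e[, ((w - 1) * L + 1):(w * L), drop = FALSE]
      trial <- c(trial, epochset$trial[i])
    }
  }
  new_eeg_epochs(out, srate = epochset$srate, epoch_s = window_s,
                 channel_names = epochset$channel_names,
                 montage = epochset$montage,
                 subject_id = epochset$subject_id,
                 condition = epochset$condition, trial = trial)
}

#' Reject epochs by amplitude criteria
#'
#' An epoch is rejected when any channel's peak-to-peak range within the
#' epoch exceeds `2 * threshold_uv` (criterion `"ptp"`) or any sample's
#' absolute value exceeds `threshold_uv` (criterion `"abs"`). The default
#' applies both. The threshold defaults to 100 microvolts. Rejection is
#' monotone: lowering the threshold never keeps an epoch a higher threshold
#' rejected.
#'
#' @param epochset An `eeg_epochs` of 1 s windows.
#' @param threshold_uv Rejection threshold in microvolts (> 0).
#' @param criterion `"both"` (default), `"ptp"`, or `"abs"`.
#' @return The epoch set with offending epochs removed and `kept_mask`
#'   updated. All epochs rejected is an error naming the subject/condition.
#' @export
reject_amplitude <- function(epochset, threshold_uv = 100,
                             criterion = c("both", "ptp", "abs")) {
  criterion <- match.arg(criterion)
  stopifnot(threshold_uv > 0)
  bad <- vapply(epochset$epochs, function(e) {
    ptp <- max(apply(e, 1, function(ch) max(ch) - min(ch)))
    amax <- max(abs(e))
    switch(criterion,
           ptp = ptp > 2 * threshold_uv,
           abs = amax > threshold_uv,
           both = ptp > 2 * threshold_uv || amax > threshold_uv)
  }, logical(1))
  if (all(bad)) {
    abort(sprintf("all epochs rejected for subject %s, condition %s",
                  epochset$subject_id, epochset$condition))
  }
  keep <- !bad
  epochset$kept_mask[epochset$epoch_index[bad]] <- FALSE
  epochset$epochs <- epochset$epochs[keep]
  epochset$trial <- epochset$trial[keep]
  epochset$epoch_index <- epochset$epoch_index[keep]
  epochset
}

#' Downsample an epoch set
#'
#' Anti-alias low-pass filters (zero-phase Butterworth at 80% of the target
#' Nyquist) then decimates when the original rate is an integer multiple of
#' the target; otherwise polyphase resampling is used. Epoch sample counts
#' scale exactly for integer factors.
#'
#' @param epochset An `eeg_epochs`.
#' @param target_hz Target sampling rate (default 250).
#' @return The epoch set at `target_hz`. A no-op when already at the
#'   target rate.
#' @export
downsample <- function(epochset, target_hz = 250) {
  fs <- epochset$srate
  if (fs == target_hz) return(epochset)
  if (fs < target_hz) abort("target rate exceeds the current rate")
  fac <- fs / target_hz
  if (abs(fac - round(fac)) < 1e-9) {
    fac <- round(fac)
    lp <- signal::butter(4, 0.8 / fac, type = "low")
    epochset$epochs <- lapply(epochset$epochs, function(e) {
      f <- t(apply(e, 1, function(ch) signal::filtfilt(lp, ch)))
      f[, seq(1, ncol(e), by = fac), drop = FALSE]
    })
  } else {
    pq <- find_resample_ratio(target_hz, fs)
    epochset$epochs <- lapply(epochset$epochs, function(e) {
      t(apply(e, 1, function(ch) signal::resample(ch, pq[1], pq[2])))
    })
  }
  epochset$srate <- target_hz
  epochset
}

# Small integer ratio p/q = target/original for polyphase resampling.
find_resample_ratio <- function(target, original) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  scale <- 1000
  p <- round(target * scale); q <- round(original * scale)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Re-reference every epoch to the average reference
#'
#' Subtracts, at each sample, the mean across channels; the channel mean of
#' the output is exactly zero at every sample. Idempotent.
#'
#' @param epochset An `eeg_epochs`.
#' @return The re-referenced epoch set.
#' @export
average_reference <- function(epochset) {
  epochset$epochs <- lapply(epochset$epochs, function(e) {
    sweep(e, 2, colMeans(e))
  })
  epochset
}

#' Posterior alpha band power
#'
#' Welch power spectral density with Hann-windowed segments of
#' `welch_window_s` seconds (each epoch is one segment when the epochs are
#' already 1 s long), integrated over the `band` and averaged over the
#' requested electrodes and epochs. The normalisation is such that a pure
#' sinusoid of amplitude A inside the band yields a band power of A^2 / 2.
#'
#' @param epochset An `eeg_epochs` (typically broadband, post-rejection).
#' @param electrode_set Electrode names; default is the nine-channel
#'   parieto-occipital set of [default_posterior_set()].
#' @param band Frequency band in Hz (default 8-12, the alpha band).
#' @param welch_window_s Welch segment length in seconds (default 1).
#' @return A list with `power` (scalar, microvolt^2), `electrode_set`, and
#'   `method_params`.
#' @export
posterior_alpha_power <- function(epochset,
                                  electrode_set = default_posterior_set(),
                                  band = c(8, 12), welch_window_s = 1) {
  idx <- match_electrodes(electrode_set, epochset$channel_names)
  fs <- epochset$srate
  if (band[2] >= fs / 2) abort("band above Nyquist")
  L <- round(welch_window_s * fs)
  w <- hann_window(L)
  u <- sum(w^2)
  df <- fs / L
  freqs <- (0:(L %/% 2)) * df
  in_band <- freqs >= band[1] & freqs <= band[2]
  pows <- vapply(epochset$epochs, function(e) {
    nseg <- ncol(e) %/% L
    if (nseg < 1) return(NA_real_)
    acc <- 0
    for (s in seq_len(nseg)) {
      seg <- e[idx, ((s - 1) * L + 1):(s * L), drop = FALSE]
      seg <- seg - rowMeans(seg)           # detrend (mean removal)
      ft <- t(apply(seg * rep(w, each = nrow(seg)), 1, stats::fft))
      p <- (Mod(ft[, seq_along(freqs), drop = FALSE])^2) * (2 / (fs * u))
      p[, 1] <- p[, 1] / 2
      if (L %% 2 == 0) p[, ncol(p)] <- p[, ncol(p)] / 2
      acc <- acc + mean(rowSums(p[, in_band, drop = FALSE]) * df)
    }
    acc / nseg
  }, numeric(1))
  list(power = mean(pows, na.rm = TRUE),
       electrode_set = epochset$channel_names[idx],
       method_params = list(band = band, welch_window_s = welch_window_s,
                            window = "hann"))
}

hann_window <- function(L) {
  0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

#' EOG regression blink correction
#'
#' Optional multi-channel linear-regression subtraction of EOG reference
#' channels from the EEG channels (ordinary least squares per EEG channel,
#' coefficients fitted over the whole epoch set). Off by default in the
#' pipeline; intended for real recordings that carry EOG channels.
#'
#' @param epochset An `eeg_epochs` containing both EEG and EOG channels.
#' @param eog_channels Names of the EOG channels.
#' @return The epoch set with EOG contributions regressed out of the EEG
#'   channels and the EOG channels removed.
#' @export
regress_eog <- function(epochset, eog_channels) {
  eog_idx <- match_electrodes(eog_channels, epochset$channel_names)
  eeg_idx <- setdiff(seq_along(epochset$channel_names), eog_idx)
  X <- do.call(cbind, lapply(epochset$epochs, function(e) e[eog_idx, , drop = FALSE]))
  Y <- do.call(cbind, lapply(epochset$epochs, function(e) e[eeg_idx, , drop = FALSE]))
  B <- t(solve(X %*% t(X), X %*% t(Y)))      # EEG x EOG coefficients
  epochset$epochs <- lapply(epochset$epochs, function(e) {
    e[eeg_idx, , drop = FALSE] - B %*% e[eog_idx, , drop = FALSE]
  })
  epochset$channel_names <- epochset$channel_names[eeg_idx]
  epochset$montage <- epochset$montage[eeg_idx, ]
  epochset
}
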