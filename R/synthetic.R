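# Synthetic cohort generator: multichannel EEG with known ground-truth
# microstate structure, condition effects, posterior alpha modulation, and
# behavioural linkage, so every downstream stage can be checked against a
# recoverable truth.

#' Generate well-separated template topographies
#'
#' Builds `k` smooth dipolar scalp patterns over a montage: each map is the
#' signed distance of every electrode to a random dipole plane, passed
#' through a saturating nonlinearity, average-referenced and
#' unit-normalised. Maps are redrawn until every pairwise absolute spatial
#' correlation is at most `min_separation`; generation fails after a
#' bounded number of retries if the separation is unreachable.
#'
#' @param montage Montage tibble; `n_electrodes` rows are used.
#' @param k Number of templates (>= 2).
#' @param min_separation Maximum allowed pairwise `|r|` (default 0.7).
#' @param orthogonalize Gram-Schmidt-orthogonalise the maps (pairwise
#'   correlation exactly 0); useful for exactly identifiable fixtures.
#' @param max_tries Redraw budget per map.
#' @param seed RNG seed.
#' @return K x N matrix of zero-mean unit-norm rows.
#' @export
generate_templates <- function(montage, k, min_separation = 0.7,
                               orthogonalize = FALSE, max_tries = 500,
                               seed = NULL) {
  n_el <- nrow(montage)
  if (k < 2) abort("k must be >= 2")
  if (n_el < k) abort("need at least k electrodes")
  pos <- as.matrix(montage[, c("x", "y", "z")])
  with_seed(seed, {
    maps <- matrix(0, k, n_el)
    for (j in seq_len(k)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
        offset <- runif(1, -0.3, 0.3)
        raw <- tanh(2 * (pos %*% axis - offset))
        m <- normalize_maps(matrix(raw, 1))
        if (j == 1 ||
            all(abs(maps[seq_len(j - 1), , drop = FALSE] %*% t(m)) <=
                min_separation)) {
          maps[j, ] <- m
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "could not reach pairwise |r| <= %g after %d retries; min_separation too strict",
          min_separation, max_tries))
      }
    }
    if (orthogonalize) {
      for (j in seq_len(k)) {
        v <- maps[j, ]
        if (j > 1) {
          prev <- maps[seq_len(j - 1), , drop = FALSE]
          v <- v - drop(t(prev) %*% (prev %*% v))
        }
        v <- v - mean(v)
        maps[j, ] <- v / sqrt(sum(v^2))
      }
    }
    maps
  })
}

#' Generate a semi-Markov microstate label sequence
#'
#' Dwell times are drawn per class from a gamma distribution with shape
#' `dwell_shape` and the requested class mean (in ms), rounded to at least
#' one sample. Successive classes always differ; the next class is drawn
#' among the others with probabilities proportional to `entry_weights`.
#' The sequence is truncated to exactly `duration_s * srate` samples.
#'
#' @param duration_s Sequence length in seconds.
#' @param srate Sampling rate (Hz).
#' @param dwell_mean_ms Mean dwell per class (ms), length K.
#' @param dwell_shape Gamma shape parameter (default 4; larger = less
#'   variable dwell times; the coefficient of variation is
#'   `1/sqrt(shape)`).
#' @param entry_weights Relative probability of entering each class
#'   (default uniform).
#' @param seed RNG seed.
#' @return Integer vector of class indices, length `round(duration_s *
#'   srate)`.
#' @export
generate_state_sequence <- function(duration_s, srate, dwell_mean_ms,
                                    dwell_shape = 4, entry_weights = NULL,
                                    seed = NULL) {
  stopifnot(duration_s > 0, all(dwell_mean_ms > 0), dwell_shape > 0)
  K <- length(dwell_mean_ms)
  if (is.null(entry_weights)) entry_weights <- rep(1, K)
  n <- round(duration_s * srate)
  with_seed(seed, {
    labels <- integer(n)
    pos <- 0L
    cur <- sample.int(K, 1, prob = entry_weights)
    while (pos < n) {
      dwell_s <- rgamma(1, shape = dwell_shape,
                        rate = dwell_shape / (dwell_mean_ms[cur] / 1000))
      len <- max(1L, as.integer(round(dwell_s * srate)))
      take <- min(len, n - pos)
      labels[(pos + 1):(pos + take)] <- cur
      pos <- pos + take
      if (K > 1) {
        others <- setdiff(seq_len(K), cur)
        cur <- if (length(others) == 1) others else
          sample(others, 1, prob = entry_weights[others])
      }
    }
    labels
  })
}

#' Ground-truth configuration for the synthetic cohort
#'
#' Bundles everything the generator needs: template maps, per-condition
#' dwell means and entry weights, gamma dwell shape, posterior alpha
#' amplitudes, signal-to-noise ratio, and the behavioural linkage. The
#' defaults emulate a cue-reactivity study: 4 microstate classes with
#' ~100 ms dwell in the neutral condition; in the smoking condition
#' classes B/C/D dwell longer and class D is entered more often, and
#' posterior alpha amplitude is higher.
#'
#' @param montage Montage tibble.
#' @param k Number of microstate classes (default 4).
#' @param dwell_mean_ms K x 2 matrix (columns `neutral`, `smoking`) of mean
#'   dwell times in ms.
#' @param entry_weights K x 2 matrix of class entry weights.
#' @param dwell_shape Gamma shape of dwell times.
#' @param alpha_amp Named numeric `c(neutral=, smoking=)`: posterior 10 Hz
#'   amplitude in microvolts.
#' @param alpha_electrodes Electrode names receiving the alpha sinusoid.
#' @param snr Ratio of microstate-signal RMS to noise RMS.
#' @param signal_rms_uv RMS amplitude of the microstate signal (microvolts).
#' @param behaviour_link List: `alpha_dwell_slope` (standardised slope from
#'   class-C dwell change to alpha-amplitude change), `alpha_noise_sd`,
#'   `craving_slope` (standardised slope from alpha-power change to craving
#'   change), `craving_noise_sd`, `craving_base_change`.
#' @param dwell_subject_sd Log-scale SD of per-subject, per-class dwell
#'   multipliers (subject heterogeneity).
#' @param seed Seed used when drawing the default templates.
#' @return A `ms_truth` list.
#' @export
make_ground_truth <- function(montage = standard_montage(), k = 4,
                              dwell_mean_ms = NULL, entry_weights = NULL,
                              dwell_shape = 4,
                              alpha_amp = c(neutral = 1.2, smoking = 1.6),
                              alpha_electrodes = default_posterior_set(),
                              snr = 2, signal_rms_uv = 15,
                              behaviour_link = list(
                                alpha_dwell_slope = 0.15,
                                alpha_noise_sd = 0.10,
                                craving_slope = 0.8,
                                craving_noise_sd = 0.6,
                                craving_base_change = 3
                              ),
                              dwell_subject_sd = 0.05,
                              seed = 100) {
  if (is.null(dwell_mean_ms)) {
    dwell_mean_ms <- cbind(neutral = rep(100, k),
                           smoking = c(100, 115, 118, 125)[seq_len(k)])
  }
  if (is.null(entry_weights)) {
    entry_weights <- cbind(neutral = rep(1, k),
                           smoking = c(0.85, 1, 1, 1.45)[seq_len(k)])
  }
  stopifnot(all(dwell_mean_ms > 0), snr > 0)
  templates <- generate_templates(montage, k, seed = seed)
  structure(
    list(montage = montage, k = k, templates = templates,
         dwell_mean_ms = dwell_mean_ms, entry_weights = entry_weights,
         dwell_shape = dwell_shape, alpha_amp = alpha_amp,
         alpha_electrodes = alpha_electrodes, snr = snr,
         signal_rms_uv = signal_rms_uv, behaviour_link = behaviour_link,
         dwell_subject_sd = dwell_subject_sd, seed = seed),
    class = "ms_truth"
  )
}

# Spatially correlated pink (1/f) noise, channels x samples, unit RMS.
# Temporal spectrum ~ 1/f via frequency-domain shaping; spatial structure
# from a squared-exponential kernel over electrode chord distances.
pink_noise_matrix <- function(n_channels, n_samples, montage,
                              length_scale = 0.6) {
  n <- n_samples
  freqs <- seq_len(n %/% 2)
  amp <- 1 / sqrt(freqs)
  white <- matrix(rnorm(n_channels * n), n_channels, n)
  pink <- t(apply(white, 1, function(x) {
    ft <- stats::fft(x)
    scale <- c(0, amp, if (n %% 2 == 0) rev(amp)[-1] else rev(amp))
    scale <- scale[seq_len(n)]
    Re(stats::fft(ft * scale, inverse = TRUE)) / n
  }))
  D <- montage_distances(montage)
  Kmat <- exp(-D^2 / (2 * length_scale^2)) + diag(1e-8, n_channels)
  L <- chol(Kmat)
  mixed <- t(L) %*% pink
  unname(mixed / sqrt(mean(mixed^2)))
}

# Signed amplitude envelope tied to the state sequence: within each run
# the field strength oscillates as sin(pi * m * u) with m half-cycles at
# roughly `half_cycle_hz` (default 28/s, i.e. a 14 Hz carrier, outside the
# 8-12 Hz alpha band so spectral power measures are not confounded), so it is
# exactly zero at every transition (GFP troughs between states) and peaks
# inside stable segments, with polarity reversals within a run. Per-run
# log-normal amplitude jitter; unit RMS overall.
amplitude_envelope <- function(labels, srate, half_cycle_hz = 28,
                               run_amp_sd = 0.3) {
  n <- length(labels)
  env <- numeric(n)
  r <- rle(labels)
  pos <- 0L
  for (j in seq_along(r$lengths)) {
    L <- r$lengths[j]
    m <- max(1, round(L * half_cycle_hz / srate))
    u <- (seq_len(L) - 0.5) / L
    env[pos + seq_len(L)] <- exp(rnorm(1, 0, run_amp_sd)) * sin(pi * m * u)
    pos <- pos + L
  }
  env / sqrt(mean(env^2))
}

#' Generate one synthetic EEG recording
#'
#' Simulates `n_trials` trials for one subject/condition: a semi-Markov
#' microstate label sequence drives `template[label] * envelope`, spatially
#' correlated pink noise is added at the configured SNR, and a 10 Hz
#' sinusoid of the condition's alpha amplitude is injected into the
#' posterior electrodes. Trials are laid out in one continuous recording
#' with 2 s lead-in/gaps; onset times are stored so the standard epoching
#' applies.
#'
#' @param truth A `ms_truth` from [make_ground_truth()].
#' @param condition `"neutral"` or `"smoking"`.
#' @param subject_params Optional list overriding per-subject parameters:
#'   `dwell_mean_ms` (length K), `entry_weights`, `alpha_amp` (scalar).
#' @param n_trials,trial_s Number and length (s) of trials.
#' @param srate Sampling rate (Hz, default 250).
#' @param subject_id Identifier stored in the recording.
#' @param noise_amp Multiplier on the noise level (0 = noiseless).
#' @param seed RNG seed.
#' @return An `eeg_recording` with `labels_true` and `onsets_s` set.
#' @export
generate_recording <- function(truth, condition, subject_params = NULL,
                               n_trials = 4, trial_s = 90, srate = 250,
                               subject_id = "s01", noise_amp = 1,
                               seed = NULL) {
  if (!condition %in% c("neutral", "smoking")) {
    abort(sprintf("unknown condition '%s'", condition))
  }
  dwell <- subject_params$dwell_mean_ms %||% truth$dwell_mean_ms[, condition]
  weights <- subject_params$entry_weights %||% truth$entry_weights[, condition]
  alpha_a <- subject_params$alpha_amp %||% unname(truth$alpha_amp[condition])
  montage <- truth$montage
  n_ch <- nrow(montage)
  gap_s <- 2
  total_s <- gap_s + n_trials * (trial_s + gap_s)
  n <- round(total_s * srate)
  with_seed(seed, {
    labels <- generate_state_sequence(total_s, srate, dwell,
                                      truth$dwell_shape, weights)
    env <- amplitude_envelope(labels, srate)
    sig <- t(truth$templates[labels, , drop = FALSE]) *
      rep(env, each = n_ch) * truth$signal_rms_uv
    data <- sig
    if (noise_amp > 0) {
      noise <- pink_noise_matrix(n_ch, n, montage)
      sig_rms <- sqrt(mean(sig^2))
      data <- data + noise * (noise_amp * sig_rms / truth$snr)
    }
    if (alpha_a > 0) {
      post <- match_electrodes(truth$alpha_electrodes, montage$name)
      tt <- (seq_len(n) - 1) / srate
      wave <- alpha_a * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
      data[post, ] <- data[post, ] + rep(wave, each = length(post))
    }
    onsets <- gap_s + (seq_len(n_trials) - 1) * (trial_s + gap_s)
    eeg_recording(data, srate, montage$name, montage,
                  subject_id = subject_id, condition = condition,
                  onsets_s = onsets, labels_true = labels)
  })
}

#' Default condition-effect configuration
#'
#' Multiplicative smoking-condition effects applied to the neutral-condition
#' dwell means and entry weights, subject heterogeneity, the alpha effect,
#' and the behavioural linkage. `null_effects()` zeroes every effect (both
#' conditions identical in expectation), for calibration studies.
#'
#' @return A list understood by [generate_cohort()].
#' @export
default_effects <- function() {
  list(
    dwell_mult_smoking = c(1.00, 1.15, 1.18, 1.25),
    entry_weights_smoking = c(0.85, 1, 1, 1.45),
    alpha_amp_change = 0.4,
    years_smoking_slope = 4,
    years_smoking_sd = 3
  )
}

#' @rdname default_effects
#' @export
null_effects <- function() {
  list(
    dwell_mult_smoking = c(1, 1, 1, 1),
    entry_weights_smoking = c(1, 1, 1, 1),
    alpha_amp_change = 0,
    years_smoking_slope = 0,
    years_smoking_sd = 3
  )
}

#' Generate a synthetic cohort
#'
#' Simulates `n_subjects` subjects in both conditions. Per-subject dwell
#' means are the condition means perturbed by log-normal subject jitter;
#' the smoking condition applies the dwell multipliers and entry-weight
#' changes of `effect_config`. The behavioural table encodes a
#' full-mediation structure: each subject's alpha-amplitude change is
#' linear in their realised class-C dwell change (plus noise), and the
#' craving change is linear in the realised alpha-power change (plus
#' noise) with no direct dwell path. Years of smoking is generated
#' correlated with the class-D dwell change.
#'
#' With `signal = "labels"` no EEG is synthesised; the per-subject
#' ground-truth label sequences are still generated and summarised into
#' realised microstate parameters, which is sufficient (and fast) for
#' statistical calibration studies.
#'
#' @param n_subjects Number of subjects (>= 3; the study default is 40).
#' @param truth A `ms_truth`; its smoking-column dwell/entry settings are
#'   overridden by `effect_config`.
#' @param effect_config See [default_effects()].
#' @param n_trials,trial_s,srate Recording layout per subject/condition.
#' @param signal `"eeg"` (full recordings) or `"labels"` (label sequences
#'   only).
#' @param seed RNG seed; all randomness in the cohort flows from it.
#' @return A `ms_cohort` list: `recordings` (named list, or NULL),
#'   `behaviour` (one row per subject: ratings, covariates, true alpha
#'   amplitudes), `truth_params` (tibble of realised per-subject,
#'   per-condition, per-class parameters computed from the true labels),
#'   `subject_truth` (per-subject generating parameters), `truth`.
#' @export
generate_cohort <- function(n_subjects = 40, truth = NULL,
                            effect_config = default_effects(),
                            n_trials = 4, trial_s = 90, srate = 250,
                            signal = c("eeg", "labels"), seed = 1) {
  signal <- match.arg(signal)
  if (n_subjects < 3) abort("n_subjects must be >= 3")
  if (is.null(truth)) truth <- make_ground_truth()
  K <- truth$k
  link <- truth$behaviour_link
  with_seed(seed, {
    subjects <- sprintf("s%02d", seq_len(n_subjects))
    recordings <- if (signal == "eeg") list() else NULL
    truth_params <- list()
    subject_truth <- list()
    for (i in seq_len(n_subjects)) {
      base_dwell <- truth$dwell_mean_ms[, "neutral"] *
        exp(rnorm(K, 0, truth$dwell_subject_sd))
      mult <- effect_config$dwell_mult_smoking[seq_len(K)] *
        exp(rnorm(K, 0, truth$dwell_subject_sd))
      dwell_n <- base_dwell
      dwell_s <- base_dwell * mult
      w_n <- truth$entry_weights[, "neutral"]
      w_s <- effect_config$entry_weights_smoking[seq_len(K)]
      for (cond in c("neutral", "smoking")) {
        dw <- if (cond == "neutral") dwell_n else dwell_s
        wt <- if (cond == "neutral") w_n else w_s
        if (signal == "eeg") {
          rec <- generate_recording(
            truth, cond,
            subject_params = list(dwell_mean_ms = dw, entry_weights = wt,
                                  alpha_amp = 0),   # alpha added below
            n_trials = n_trials, trial_s = trial_s, srate = srate,
            subject_id = subjects[i])
          recordings[[paste(subjects[i], cond, sep = "_")]] <- rec
          seg_labels <- rec$labels_true
        } else {
          seg_labels <- generate_state_sequence(n_trials * trial_s, srate,
                                                dw, truth$dwell_shape, wt)
        }
        tp <- truth_label_parameters(seg_labels, srate, K)
        tp$subject <- subjects[i]; tp$condition <- cond
        truth_params[[length(truth_params) + 1]] <- tp
      }
      subject_truth[[i]] <- tibble(
        subject = subjects[i],
        class = seq_len(K),
        dwell_neutral_ms = dwell_n,
        dwell_smoking_ms = dwell_s
      )
    }
    truth_params <- dplyr::bind_rows(truth_params)
    subject_truth <- dplyr::bind_rows(subject_truth)

    # behavioural linkage from the *realised* class dwell changes
    durC <- truth_params |>
      dplyr::filter(.data$class == 3) |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "condition",
                         values_from = "duration_ms")
    d_durC <- durC$smoking - durC$neutral
    durD <- truth_params |>
      dplyr::filter(.data$class == min(K, 4)) |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "condition",
                         values_from = "duration_ms")
    d_durD <- durD$smoking - durD$neutral
    z <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0

    alpha_n <- unname(truth$alpha_amp["neutral"]) * exp(rnorm(n_subjects, 0, 0.05))
    d_alpha_amp <- effect_config$alpha_amp_change +
      link$alpha_dwell_slope * z(d_durC) +
      rnorm(n_subjects, 0, link$alpha_noise_sd)
    alpha_s <- pmax(alpha_n + d_alpha_amp, 0)
    d_alpha_pow <- (alpha_s^2 - alpha_n^2) / 2   # injected power change

    craving_n <- pmin(pmax(rnorm(n_subjects, 2, 0.8), 0), 10)
    d_craving <- link$craving_base_change +
      link$craving_slope * z(d_alpha_pow) +
      rnorm(n_subjects, 0, link$craving_noise_sd)
    craving_s <- pmin(pmax(craving_n + d_craving, 0), 10)

    behaviour <- tibble(
      subject = subjects,
      craving_neutral = craving_n, craving_smoking = craving_s,
      vividness_neutral = pmin(pmax(rnorm(n_subjects, 7, 1), 0), 10),
      vividness_smoking = pmin(pmax(rnorm(n_subjects, 7, 1), 0), 10),
      ftnd = pmin(pmax(round(rnorm(n_subjects, 5, 2)), 0), 10),
      dsm5 = pmin(pmax(round(rnorm(n_subjects, 7, 2)), 4), 11),
      cigs_per_day = pmax(round(rnorm(n_subjects, 16, 5)), 3),
      years_smoking = pmax(round(
        12 + effect_config$years_smoking_slope * z(d_durD) +
          rnorm(n_subjects, 0, effect_config$years_smoking_sd)), 1),
      alpha_amp_neutral = alpha_n, alpha_amp_smoking = alpha_s
    )

    # inject the per-subject alpha sinusoids into the recordings
    if (signal == "eeg") {
      post <- match_electrodes(truth$alpha_electrodes, truth$montage$name)
      for (i in seq_len(n_subjects)) {
        for (cond in c("neutral", "smoking")) {
          key <- paste(subjects[i], cond, sep = "_")
          rec <- recordings[[key]]
          a <- if (cond == "neutral") alpha_n[i] else alpha_s[i]
          tt <- (seq_len(ncol(rec$data)) - 1) / rec$srate
          wave <- a * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
          rec$data[post, ] <- rec$data[post, ] + rep(wave, each = length(post))
          recordings[[key]] <- rec
        }
      }
    }

    structure(
      list(recordings = recordings, behaviour = behaviour,
           truth_params = truth_params, subject_truth = subject_truth,
           truth = truth, seed = seed,
           layout = list(n_trials = n_trials, trial_s = trial_s,
                         srate = srate)),
      class = "ms_cohort"
    )
  })
}

# Run-length summary of a ground-truth label sequence into microstate
# parameters (duration/occurrence/contribution per class).
truth_label_parameters <- function(labels, srate, K) {
  r <- rle(labels)
  total_samples <- length(labels)
  out <- lapply(seq_len(K), function(cls) {
    lens <- r$lengths[r$values == cls]
    tibble(
      class = cls,
      duration_ms = if (length(lens)) mean(lens) * 1000 / srate else 0,
      occurrence_per_s = length(lens) / (total_samples / srate),
      contribution = sum(lens) / total_samples
    )
  })
  dplyr::bind_rows(out)
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf("<ms_cohort> %d subjects x 2 conditions (%s)\n",
              nrow(x$behaviour),
              if (is.null(x$recordings)) "label sequences only"
              else sprintf("%d recordings", length(x$recordings))))
  cat(sprintf("  layout: %d trials x %g s @ %g Hz, seed %d\n",
              x$layout$n_trials, x$layout$trial_s, x$layout$srate, x$seed))
  invisible(x)
}

#' Simulate data with a prescribed mediation structure
#'
#' Generates standardised triples (x, m, y) under `m = a x + e_m`,
#' `y = c' x + b m + e_y`; with `c_prime = 0` the effect of x on y is
#' fully mediated by m. Used to calibrate and validate the mediation
#' analysis.
#'
#' @param n Sample size.
#' @param a,b,c_prime Path coefficients.
#' @param seed RNG seed.
#' @return Tibble with columns `x`, `m`, `y`.
#' @export
simulate_mediation_data <- function(n, a = 0.5, b = 0.5, c_prime = 0,
                                    seed = NULL) {
  with_seed(seed, {
    x <- rnorm(n)
    m <- a * x + rnorm(n, 0, sqrt(max(1 - a^2, 0.05)))
    res <- sqrt(max(1 - c_prime^2 - b^2 - 2 * a * b * c_prime, 0.05))
    y <- c_prime * x + b * m + rnorm(n, 0, res)
    tibble(x = x, m = m, y = y)
  })
}
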