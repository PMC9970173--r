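# Shared fixtures, built once per test run.

fx <- new.env()

fx_montage <- function(n = 64) {
  key <- paste0("m", n)
  if (is.null(fx[[key]])) fx[[key]] <- standard_montage(n)
  fx[[key]]
}

fx_templates <- function() {
  if (is.null(fx$tpl)) fx$tpl <- generate_templates(fx_montage(), 4, seed = 11)
  fx$tpl
}

# Epoch set built directly from a channels x samples matrix, split into
# 1 s windows.
make_epochs <- function(data, srate, montage = NULL, window_s = 1) {
  n_ch <- nrow(data)
  if (is.null(montage)) montage <- fx_montage(max(n_ch, 2))[seq_len(n_ch), ]
  rec <- eeg_recording(data, srate, montage$name, montage,
                       subject_id = "t01", condition = "neutral",
                       onsets_s = 0)
  L <- round(window_s * srate)
  nwin <- ncol(data) %/% L
  eps <- lapply(seq_len(nwin), function(w) {
    data[, ((w - 1) * L + 1):(w * L), drop = FALSE]
  })
  microstatr:::new_eeg_epochs(eps, srate, window_s, montage$name, montage,
                              "t01", "neutral")
}

# Synthetic GFP-peak maps: rho * template (random polarity) + orthogonal
# unit noise, rows unit-norm zero-mean.
make_peak_maps <- function(templates, n, rho, seed) {
  set.seed(seed)
  K <- nrow(templates); N <- ncol(templates)
  lab <- sample(seq_len(K), n, replace = TRUE)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  noise <- matrix(rnorm(n * N), n)
  noise <- noise - rowMeans(noise)
  noise <- noise / sqrt(rowSums(noise^2))
  maps <- rho * templates[lab, , drop = FALSE] * sgn +
    sqrt(1 - rho^2) * noise
  list(maps = maps, labels = lab)
}

# Balanced random 2 x 4 within-subject long table.
random_rm_table <- function(n_subjects, seed) {
  set.seed(seed)
  expand.grid(subject = sprintf("s%02d", seq_len(n_subjects)),
              condition = c("neutral", "smoking"),
              class = c("A", "B", "C", "D"),
              stringsAsFactors = FALSE) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
}

# Wide cohort table from a label-level synthetic cohort (no EEG): realised
# truth parameters plus behavioural columns; alpha power proxied by the
# generator's injected amplitude (power = A^2/2).
label_cohort_table <- function(n_subjects, seed, effects = default_effects(),
                               n_trials = 2, trial_s = 30) {
  co <- generate_cohort(n_subjects = n_subjects, effect_config = effects,
                        n_trials = n_trials, trial_s = trial_s,
                        signal = "labels", seed = seed)
  params <- dplyr::mutate(co$truth_params, class = LETTERS[class])
  alpha <- dplyr::bind_rows(
    tibble::tibble(subject = co$behaviour$subject, condition = "neutral",
                   alpha_power = co$behaviour$alpha_amp_neutral^2 / 2),
    tibble::tibble(subject = co$behaviour$subject, condition = "smoking",
                   alpha_power = co$behaviour$alpha_amp_smoking^2 / 2)
  )
  build_cohort_table(params, alpha, co$behaviour)
}
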