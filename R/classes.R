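# Light S3 containers for the signal layer. Tabular results elsewhere are
# plain tibbles; these hold channels x samples matrices plus metadata.

#' Construct an EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param srate Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param montage Montage tibble (`name`, `x`, `y`, `z`); must cover all
#'   channels.
#' @param subject_id,condition Provenance strings.
#' @param onsets_s Trial onset times in seconds (optional).
#' @param labels_true Optional per-sample ground-truth microstate class
#'   indices (synthetic data only).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, srate, channel_names, montage,
                          subject_id = NA_character_,
                          condition = NA_character_,
                          onsets_s = numeric(),
                          labels_true = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), srate > 0)
  if (nrow(data) != length(channel_names)) {
    abort("channel_names length must equal the number of data rows")
  }
  if (nrow(data) != nrow(montage)) {
    abort("montage size must equal the number of channels")
  }
  if (!all(is.finite(data))) abort("recording contains non-finite samples")
  if (!is.null(labels_true) && length(labels_true) != ncol(data)) {
    abort("labels_true length must equal the number of samples")
  }
  structure(
    list(data = data, srate = srate, channel_names = channel_names,
         montage = montage, subject_id = subject_id, condition = condition,
         onsets_s = onsets_s, labels_true = labels_true),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  cat(sprintf("  subject: %s  condition: %s  trials: %d\n",
              x$subject_id, x$condition, length(x$onsets_s)))
  invisible(x)
}

# Internal epoch-set constructor. `epochs` is a list of channels x L
# matrices; `kept_mask` spans the original (pre-rejection) epoch count and
# `epoch_index` maps retained epochs to original positions.
new_eeg_epochs <- function(epochs, srate, epoch_s, channel_names, montage,
                           subject_id, condition, trial = NULL,
                           kept_mask = NULL, epoch_index = NULL) {
  n <- length(epochs)
  if (is.null(trial)) trial <- rep(NA_integer_, n)
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, n)
  if (is.null(epoch_index)) epoch_index <- seq_len(n)
  structure(
    list(epochs = epochs, srate = srate, epoch_s = epoch_s,
         channel_names = channel_names, montage = montage,
         subject_id = subject_id, condition = condition,
         trial = trial, kept_mask = kept_mask, epoch_index = epoch_index),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  L <- if (length(x$epochs)) ncol(x$epochs[[1]]) else 0
  cat(sprintf("<eeg_epochs> %d epochs of %g s (%d samples) x %d ch @ %g Hz\n",
              length(x$epochs), x$epoch_s, L, length(x$channel_names), x$srate))
  cat(sprintf("  subject: %s  condition: %s  kept: %d/%d\n",
              x$subject_id, x$condition, sum(x$kept_mask), length(x$kept_mask)))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x An `eeg_epochs` object.
#' @return Integer count of retained epochs.
#' @export
n_epochs <- function(x) length(x$epochs)

# Template-set constructor; maps are rows (K x N), zero-mean unit-norm.
new_ms_templates <- function(maps, channel_names, class_labels = NULL,
                             level = "individual", chosen_k = nrow(maps),
                             kl = NULL) {
  maps <- as.matrix(maps)
  if (is.null(class_labels)) class_labels <- paste0("M", seq_len(nrow(maps)))
  stopifnot(length(class_labels) == nrow(maps),
            !anyDuplicated(class_labels))
  rownames(maps) <- class_labels
  colnames(maps) <- channel_names
  structure(
    list(maps = maps, channel_names = channel_names,
         class_labels = class_labels, level = level,
         chosen_k = chosen_k, kl = kl),
    class = "ms_templates"
  )
}

#' @export
print.ms_templates <- function(x, ...) {
  cat(sprintf("<ms_templates> K = %d maps over %d electrodes (level: %s)\n",
              nrow(x$maps), ncol(x$maps), x$level))
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  if (!is.null(x$kl)) {
    cat(sprintf("  chosen k = %d by Krzanowski-Lai criterion\n", x$chosen_k))
  }
  invisible(x)
}

#' @export
tidy.ms_templates <- function(x, ...) {
  tibble(
    class = rep(x$class_labels, each = ncol(x$maps)),
    channel = rep(x$channel_names, times = nrow(x$maps)),
    value = as.vector(t(x$maps))
  )
}

# Segmentation constructor. labels use NA for unassigned samples.
new_ms_segmentation <- function(labels, epoch, gfp, peaks, peak_labels,
                                peak_corr, srate, class_labels) {
  stopifnot(length(labels) == length(epoch), length(labels) == length(gfp))
  structure(
    list(labels = labels, epoch = epoch, gfp = gfp, peaks = peaks,
         peak_labels = peak_labels, peak_corr = peak_corr,
         srate = srate, class_labels = class_labels),
    class = "ms_segmentation"
  )
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf("<ms_segmentation> %d samples @ %g Hz, %d GFP peaks, %d epochs\n",
              length(x$labels), x$srate, length(x$peaks),
              length(unique(x$epoch))))
  cat(sprintf("  labelled: %.1f%%\n", 100 * mean(!is.na(x$labels))))
  invisible(x)
}

#' @export
tidy.ms_segmentation <- function(x, ...) {
  tibble(
    sample = seq_along(x$labels),
    time_s = (seq_along(x$labels) - 1) / x$srate,
    epoch = x$epoch,
    gfp = x$gfp,
    class = ifelse(is.na(x$labels), NA_character_,
                   x$class_labels[x$labels])
  )
}
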