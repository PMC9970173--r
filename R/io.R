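# Recording and template I/O: raw float32 matrix + JSON sidecar for
# recordings; plain-matrix + JSON for templates; CSV for tabular results.

#' Write / read a recording as float32 + JSON sidecar
#'
#' `data` is stored row-major (channel by channel) as little-endian
#' float32 in `<stem>.dat`; the sidecar `<stem>.json` records the
#' sampling rate, channel names, provenance and onsets.
#'
#' @param recording An `eeg_recording`.
#' @param stem Output path without extension.
#' @param montage Montage to attach on read (`read_recording` accepts a
#'   montage tibble or a montage file path; defaults to the built-in
#'   layout matched by channel count).
#' @return `write_recording()` returns `stem` invisibly; `read_recording()`
#'   an `eeg_recording`.
#' @export
write_recording <- function(recording, stem) {
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(recording$data)), con, size = 4, endian = "little")
  sidecar <- list(
    srate = recording$srate,
    channel_names = recording$channel_names,
    n_channels = nrow(recording$data),
    n_samples = ncol(recording$data),
    subject_id = recording$subject_id,
    condition = recording$condition,
    onsets_s = recording$onsets_s
  )
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem, montage = NULL) {
  sidecar <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n <- sidecar$n_channels * sidecar$n_samples
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  data <- matrix(v, nrow = sidecar$n_channels, byrow = TRUE)
  if (is.null(montage)) {
    montage <- standard_montage(sidecar$n_channels)
  } else if (is.character(montage)) {
    montage <- read_montage(montage)
  }
  eeg_recording(data, sidecar$srate, sidecar$channel_names, montage,
                subject_id = sidecar$subject_id,
                condition = sidecar$condition,
                onsets_s = as.numeric(sidecar$onsets_s))
}

#' Write / read a template set
#'
#' Maps go to `<stem>.tsv` (classes x electrodes, tab-separated with a
#' header of channel names); metadata (class labels, level, chosen k, KL
#' curve) to `<stem>.json`.
#'
#' @param templates An `ms_templates`.
#' @param stem Output path without extension.
#' @return `write_templates()` returns `stem` invisibly; `read_templates()`
#'   an `ms_templates`.
#' @export
write_templates <- function(templates, stem) {
  utils::write.table(templates$maps, paste0(stem, ".tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  meta <- list(class_labels = templates$class_labels,
               level = templates$level, chosen_k = templates$chosen_k,
               kl_curve = templates$kl)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_templates
#' @export
read_templates <- function(stem) {
  maps <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t",
                                      header = TRUE, row.names = 1,
                                      check.names = FALSE))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  kl <- if (!is.null(meta$kl_curve)) as_tibble(meta$kl_curve)
  new_ms_templates(maps, colnames(maps), meta$class_labels,
                   level = meta$level, chosen_k = meta$chosen_k, kl = kl)
}
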