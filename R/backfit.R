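#' Fit template maps back to the GFP peaks of an epoch set
#'
#' Each GFP-peak topography is labelled with the template class of maximal
#' polarity-invariant spatial correlation. Every non-peak sample then
#' inherits the label of its temporally nearest peak within the same epoch
#' (ties go to the earlier peak). Samples in epochs containing no GFP peak
#' are left unassigned (`NA`) and excluded from parameter computation. No
#' temporal smoothing is applied.
#'
#' @param epochset An `eeg_epochs` object (average-referenced, band-passed
#'   data at the analysis rate).
#' @param templates An `ms_templates` object over the same electrodes.
#' @param min_peak_distance Minimum GFP-peak spacing in samples (default 0).
#' @return An `ms_segmentation`.
#' @export
backfit <- function(epochset, templates, min_peak_distance = 0) {
  if (ncol(templates$maps) != length(epochset$channel_names)) {
    abort("template electrode count does not match the epoch set")
  }
  g <- gfp_series(epochset)
  peaks <- detect_gfp_peaks(g$gfp, g$epoch, min_distance = min_peak_distance)
  n <- nrow(g)
  labels <- rep(NA_integer_, n)
  peak_labels <- integer(0)
  peak_corr <- numeric(0)
  if (length(peaks)) {
    # peak topographies as rows, centered and unit-normalised
    L <- ncol(epochset$epochs[[1]])
    pm <- t(vapply(peaks, function(p) {
      e <- ((p - 1) %/% L) + 1
      s <- ((p - 1) %% L) + 1
      epochset$epochs[[e]][, s]
    }, numeric(length(epochset$channel_names))))
    pm <- normalize_maps(pm)
    Tm <- normalize_maps(templates$maps)
    C <- pm %*% t(Tm)
    peak_labels <- max.col(C^2, ties.method = "first")
    peak_corr <- abs(C[cbind(seq_along(peaks), peak_labels)])
    # nearest-peak fill within epochs
    for (e in unique(g$epoch[peaks])) {
      idx <- which(g$epoch == e)
      pe <- peaks[g$epoch[peaks] == e]
      ple <- peak_labels[g$epoch[peaks] == e]
      # for each sample, nearest peak; ties -> earlier peak. Peaks are
      # sorted, so findInterval gives the candidates either side.
      pos <- findInterval(idx, pe)
      lo <- pmax(pos, 1)
      hi <- pmin(pos + 1, length(pe))
      d_lo <- abs(idx - pe[lo])
      d_hi <- abs(pe[hi] - idx)
      use_lo <- (pos >= 1) & (d_lo <= d_hi | pos + 1 > length(pe))
      nearest <- ifelse(use_lo, lo, hi)
      labels[idx] <- ple[nearest]
    }
  }
  new_ms_segmentation(
    labels = labels, epoch = g$epoch, gfp = g$gfp, peaks = peaks,
    peak_labels = peak_labels, peak_corr = peak_corr,
    srate = epochset$srate, class_labels = templates$class_labels
  )
}

#' Microstate segmentation parameters
#'
#' Computes, per class, the classical microstate parameters from a
#' segmentation: `duration_ms` (mean length of the class's segments),
#' `occurrence_per_s` (number of segments per second of labelled data) and
#' `contribution` (fraction of labelled time covered). Segments are maximal
#' same-label sample runs; runs never cross epoch boundaries. Runs touching
#' an epoch boundary (truncated) are included by default; with
#' `include_truncated = FALSE` they are dropped from the duration and
#' occurrence statistics (contribution always uses all labelled samples).
#' When truncated runs are included, `contribution ==
#' occurrence_per_s * duration_ms / 1000` holds exactly.
#'
#' @param segmentation An `ms_segmentation`.
#' @param include_truncated Include epoch-boundary-truncated runs (default
#'   TRUE).
#' @return A tibble with columns `class`, `duration_ms`, `occurrence_per_s`,
#'   `contribution`, `n_runs`, `n_samples`. Absent classes get zeros.
#' @export
compute_parameters <- function(segmentation, include_truncated = TRUE) {
  seg <- segmentation
  K <- length(seg$class_labels)
  keep <- !is.na(seg$labels)
  total_samples <- sum(keep)
  total_s <- total_samples / seg$srate
  run_len <- vector("list", K)
  counted_len <- vector("list", K)
  for (e in unique(seg$epoch)) {
    lab <- seg$labels[seg$epoch == e]
    if (all(is.na(lab))) next
    r <- rle(lab)
    for (j in seq_along(r$lengths)) {
      cls <- r$values[j]
      if (is.na(cls)) next
      truncated <- j == 1 || j == length(r$lengths)
      run_len[[cls]] <- c(run_len[[cls]], r$lengths[j])
      if (include_truncated || !truncated) {
        counted_len[[cls]] <- c(counted_len[[cls]], r$lengths[j])
      }
    }
  }
  out <- lapply(seq_len(K), function(cls) {
    samp <- sum(run_len[[cls]])
    lens <- counted_len[[cls]]
    if (length(lens) == 0) {
      tibble(class = seg$class_labels[cls], duration_ms = 0,
             occurrence_per_s = 0,
             contribution = if (total_samples) samp / total_samples else 0,
             n_runs = 0L, n_samples = samp)
    } else {
      tibble(
        class = seg$class_labels[cls],
        duration_ms = mean(lens) * 1000 / seg$srate,
        occurrence_per_s = length(lens) / total_s,
        contribution = samp / total_samples,
        n_runs = length(lens),
        n_samples = samp
      )
    }
  })
  dplyr::bind_rows(out)
}

#' Global explained variance of a segmentation
#'
#' GEV is the fraction of GFP-weighted topographic variance explained by
#' the fitted templates:
#' \deqn{GEV = \frac{\sum_t (GFP_t \, r_t)^2}{\sum_t GFP_t^2}}
#' where \eqn{r_t} is the spatial correlation between the map at time t and
#' its assigned template. The default (`method = "peaks"`) sums over the
#' labelled GFP peaks, matching the domain on which templates were fitted;
#' `method = "samples"` sums over all labelled samples and requires the
#' epoch set and templates to recompute per-sample correlations.
#'
#' @param segmentation An `ms_segmentation` produced by [backfit()].
#' @param epochset,templates Required for `method = "samples"` only.
#' @param method `"peaks"` (default) or `"samples"`.
#' @return Scalar GEV in \eqn{[0, 1]}.
#' @export
compute_gev <- function(segmentation, epochset = NULL, templates = NULL,
                        method = c("peaks", "samples")) {
  method <- match.arg(method)
  seg <- segmentation
  if (method == "peaks") {
    if (!length(seg$peaks)) return(NA_real_)
    g <- seg$gfp[seg$peaks]
    sum((g * seg$peak_corr)^2) / sum(g^2)
  } else {
    if (is.null(epochset) || is.null(templates)) {
      abort("method = 'samples' needs the epoch set and templates")
    }
    L <- ncol(epochset$epochs[[1]])
    keep <- which(!is.na(seg$labels))
    Tm <- normalize_maps(templates$maps)
    num <- 0; den <- 0
    for (i in keep) {
      e <- ((i - 1) %/% L) + 1
      s <- ((i - 1) %% L) + 1
      v <- epochset$epochs[[e]][, s]
      r <- spatial_correlation(v, Tm[seg$labels[i], ])
      num <- num + (seg$gfp[i] * r)^2
      den <- den + seg$gfp[i]^2
    }
    num / den
  }
}
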