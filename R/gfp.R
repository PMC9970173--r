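#' Global field power
#'
#' GFP of a topography is the population standard deviation of the
#' potentials across electrodes:
#' \deqn{GFP = \sqrt{\frac{1}{N}\sum_i (\mu_i - \bar\mu)^2}}
#' where \eqn{\mu_i} is the potential at electrode \eqn{i} and \eqn{\bar\mu}
#' their mean. Troughs of the GFP time series mark transitions between
#' topographies; peaks mark moments of maximal topographic signal-to-noise.
#'
#' @param map Numeric vector of electrode potentials (one time point).
#' @return Scalar GFP (same units as the input).
#' @export
#' @examples
#' gfp(c(1, -1))      # 1
#' gfp(rep(2, 64))    # 0
gfp <- function(map) {
  if (length(map) < 2) abort("GFP needs at least 2 electrodes")
  m <- mean(map)
  sqrt(mean((map - m)^2))
}

# GFP of every column of a channels x samples matrix (population sd).
gfp_columns <- function(data) {
  n <- nrow(data)
  mu <- colMeans(data)
  sqrt(colMeans(data^2) - mu^2) * sqrt(n / n) # population sd per column
}

#' GFP time series of an epoch set
#'
#' @param epochset An `eeg_epochs` object (average-referenced data is
#'   conventional but not required; GFP removes the mean at each sample).
#' @return A tibble with columns `epoch`, `sample` (within-epoch),
#'   `time_s` (global, concatenated), `gfp`.
#' @export
gfp_series <- function(epochset) {
  L <- if (n_epochs(epochset)) ncol(epochset$epochs[[1]]) else 0
  vals <- unlist(lapply(epochset$epochs, gfp_columns), use.names = FALSE)
  n <- length(vals)
  tibble(
    epoch = rep(seq_len(n_epochs(epochset)), each = L),
    sample = rep(seq_len(L), times = n_epochs(epochset)),
    time_s = (seq_len(n) - 1) / epochset$srate,
    gfp = vals
  )
}

#' Detect GFP peaks
#'
#' Strict local maxima of the GFP series within each epoch; peaks are never
#' placed at epoch edges and never span epoch boundaries. An optional
#' minimum spacing keeps, greedily by descending height, only peaks at
#' least `min_distance` samples apart.
#'
#' @param gfp Numeric GFP vector (concatenated epochs).
#' @param epoch Integer epoch id per sample (same length as `gfp`); a single
#'   epoch is assumed if missing.
#' @param min_distance Minimum spacing between retained peaks, in samples
#'   (0 = no constraint).
#' @return Integer vector of peak positions (indices into `gfp`), strictly
#'   increasing.
#' @export
detect_gfp_peaks <- function(gfp, epoch = NULL, min_distance = 0) {
  n <- length(gfp)
  if (is.null(epoch)) epoch <- rep(1L, n)
  stopifnot(length(epoch) == n)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  is_peak <- gfp[i] > gfp[i - 1] & gfp[i] > gfp[i + 1] &
    epoch[i] == epoch[i - 1] & epoch[i] == epoch[i + 1]
  peaks <- i[is_peak]
  if (min_distance > 0 && length(peaks) > 1) {
    ord <- peaks[order(gfp[peaks], decreasing = TRUE)]
    kept <- integer()
    for (p in ord) {
      if (!length(kept) || all(abs(kept - p) >= min_distance)) {
        kept <- c(kept, p)
      }
    }
    peaks <- sort(kept)
  }
  peaks
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across electrodes of two average-referenced maps.
#' With `polarity_invariant = TRUE` the absolute value is returned, treating
#' a map and its sign-flip as the same topography (the standard convention
#' for spontaneous EEG microstates).
#'
#' @param map1,map2 Numeric vectors of equal length (electrode potentials).
#' @param polarity_invariant Return `|r|` instead of `r`.
#' @return Scalar in \eqn{[-1, 1]} (or \eqn{[0, 1]} when polarity-invariant).
#' @export
spatial_correlation <- function(map1, map2, polarity_invariant = FALSE) {
  stopifnot(length(map1) == length(map2))
  r <- stats::cor(map1, map2)
  if (polarity_invariant) abs(r) else r
}

# Center rows to zero mean and scale to unit norm. Rows with ~zero variance
# are left as zero vectors (they correlate 0 with everything).
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  nz <- nrm > 1e-300
  maps[nz, ] <- maps[nz, , drop = FALSE] / nrm[nz]
  maps
}
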