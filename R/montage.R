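#' Built-in approximate 10-20 montage
#'
#' Returns electrode names and approximate 3D positions (unit head sphere)
#' for a 64-channel extended 10-20 layout. Positions are constructed from a
#' standard 2D azimuthal-equidistant layout grid and lifted onto the sphere,
#' which is accurate enough for distance-based noise models and topographic
#' plotting; they are not digitised coordinates.
#'
#' @param n_electrodes Number of electrodes; currently only 64 (the full
#'   layout) or fewer (the first `n_electrodes` rows, anterior to posterior)
#'   are supported.
#' @return A tibble with columns `name`, `x`, `y`, `z` (unit sphere; +x right,
#'   +y anterior, +z superior).
#' @export
#' @examples
#' m <- standard_montage()
#' nrow(m)
standard_montage <- function(n_electrodes = 64) {
  rows <- list(
    list(y = 0.90, names = c("FP1", "FPZ", "FP2")),
    list(y = 0.70, names = c("AF7", "AF3", "AFZ", "AF4", "AF8")),
    list(y = 0.50, names = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8")),
    list(y = 0.25, names = c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8")),
    list(y = 0.00, names = c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8")),
    list(y = -0.25, names = c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8")),
    list(y = -0.50, names = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8")),
    list(y = -0.70, names = c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8")),
    list(y = -0.90, names = c("O1", "OZ", "O2")),
    list(y = -0.98, names = c("IZ"))
  )
  tabs <- lapply(rows, function(r) {
    m <- length(r$names)
    half_width <- 0.92 * sqrt(max(1 - r$y^2, 0.02))
    x <- if (m == 1) 0 else seq(-half_width, half_width, length.out = m)
    tibble(name = r$names, x2d = x, y2d = r$y)
  })
  flat <- dplyr::bind_rows(tabs)
  stopifnot(nrow(flat) == 64)
  if (n_electrodes < 2 || n_electrodes > 64) {
    abort("n_electrodes must be in [2, 64] for the built-in montage")
  }
  flat <- flat[seq_len(n_electrodes), ]
  # Lift: 2D radius maps linearly to polar angle; r2d = 1 ~ 105 degrees
  # from the vertex (electrodes slightly below the equator at the rim).
  r2d <- sqrt(flat$x2d^2 + flat$y2d^2)
  theta <- pmin(r2d, 1.3) * (105 / 180) * pi
  phi <- atan2(flat$y2d, flat$x2d)
  tibble(
    name = flat$name,
    x = sin(theta) * cos(phi),
    y = sin(theta) * sin(phi),
    z = cos(theta)
  )
}

#' Default posterior electrode set for alpha power
#'
#' The parieto-occipital electrodes over which 8-12 Hz band power is
#' averaged by default.
#'
#' @return Character vector of electrode names.
#' @export
default_posterior_set <- function() {
  c("O1", "O2", "OZ", "PO3", "PO4", "POZ", "P3", "P4", "PZ")
}

# Pairwise chord distances between electrodes of a montage tibble.
montage_distances <- function(montage) {
  p <- as.matrix(montage[, c("x", "y", "z")])
  as.matrix(dist(p))
}

#' Read / write a montage file
#'
#' Plain whitespace-delimited text, one electrode per line: `name x y z`.
#'
#' @param path File path.
#' @param montage A montage tibble (`name`, `x`, `y`, `z`).
#' @return `read_montage()` returns the montage tibble; `write_montage()`
#'   returns `path` invisibly.
#' @export
read_montage <- function(path) {
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("name", "x", "y", "z"),
                         stringsAsFactors = FALSE)
  as_tibble(d)
}

#' @rdname read_montage
#' @export
write_montage <- function(montage, path) {
  utils::write.table(as.data.frame(montage), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Resolve electrode names against a montage (case-insensitive); errors on
# unknown names.
match_electrodes <- function(names, channel_names) {
  idx <- match(toupper(names), toupper(channel_names))
  if (anyNA(idx)) {
    abort(paste0("unknown electrode(s): ",
                 paste(names[is.na(idx)], collapse = ", ")))
  }
  idx
}
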