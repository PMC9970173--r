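#' Polarity-invariant modified k-means for GFP-peak topographies
#'
#' Clusters unit-normalised topographic maps ignoring polarity: a map is
#' assigned to the template with the largest squared spatial correlation,
#' and each template is updated as the first principal eigenvector of its
#' members (equivalently the first right singular vector of the member
#' matrix), which is blind to per-map sign flips. The best of `n_restarts`
#' random initialisations by explained variance is returned.
#'
#' @param peak_maps Numeric matrix, maps x electrodes (rows are GFP-peak
#'   topographies; they are average-referenced and unit-normalised
#'   internally).
#' @param k Number of clusters; `2 <= k <= nrow(peak_maps)`.
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Maximum iterations per restart.
#' @param tol Convergence tolerance on mean explained variance.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with elements `templates` (k x N, zero-mean unit-norm
#'   rows), `assignment` (integer per map), `ev` (mean squared correlation
#'   of maps with their templates), `W` (dispersion
#'   \eqn{\sum_m (1 - r^2(m, t_m))}, used by the Krzanowski-Lai criterion),
#'   and `iterations`.
#' @export
modified_kmeans <- function(peak_maps, k, n_restarts = 20, max_iter = 100,
                            tol = 1e-7, seed = NULL) {
  X <- normalize_maps(as.matrix(peak_maps))
  m <- nrow(X)
  if (k < 1) abort("k must be >= 1")
  if (k > m) abort(sprintf("k = %d exceeds the number of maps (%d)", k, m))
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- kmeans_once(X, k, max_iter, tol)
      if (is.null(best) || fit$ev > best$ev) best <- fit
    }
    best
  })
}

# One k-means run from a random initialisation. X rows are centered
# unit-norm, so correlation = dot product.
kmeans_once <- function(X, k, max_iter, tol) {
  m <- nrow(X)
  templates <- X[sample.int(m, k), , drop = FALSE]
  ev_old <- -Inf
  assignment <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    C <- X %*% t(templates)        # m x k correlations
    C2 <- C^2
    assignment <- max.col(C2, ties.method = "first")
    # empty cluster: reseed from the worst-fit map
    fit2 <- C2[cbind(seq_len(m), assignment)]
    for (j in seq_len(k)) {
      if (!any(assignment == j)) {
        worst <- which.min(fit2)
        templates[j, ] <- X[worst, ]
        assignment[worst] <- j
        fit2[worst] <- Inf    # never re-seed two clusters from one map
      }
    }
    for (j in seq_len(k)) {
      members <- X[assignment == j, , drop = FALSE]
      templates[j, ] <- principal_map(members)
    }
    C <- X %*% t(templates)
    fit2 <- C[cbind(seq_len(m), assignment)]^2
    ev <- mean(fit2)
    if (iter >= max_iter || abs(ev - ev_old) < tol) break
    ev_old <- ev
  }
  # final re-assignment against the converged templates
  C2 <- (X %*% t(templates))^2
  assignment <- max.col(C2, ties.method = "first")
  fit2 <- C2[cbind(seq_len(m), assignment)]
  list(templates = templates, assignment = assignment,
       ev = mean(fit2), W = sum(1 - fit2), iterations = iter)
}

# First principal eigenvector of a set of unit-norm zero-mean maps
# (rows); polarity-blind template update. Centered input keeps the result
# centered; returned unit-norm.
principal_map <- function(members) {
  if (nrow(members) == 1) return(members[1, ])
  G <- members %*% t(members)
  e <- eigen(G, symmetric = TRUE)
  v <- drop(t(members) %*% e$vectors[, 1])
  v / sqrt(sum(v^2))
}

#' Choose the number of microstate classes by the Krzanowski-Lai criterion
#'
#' For each k in the search range the cluster dispersion W(k) from
#' [modified_kmeans()] is computed, then
#' \deqn{DIFF(k) = (k-1)^{2/p} W(k-1) - k^{2/p} W(k)}
#' with p the number of electrodes, and
#' \deqn{KL(k) = |DIFF(k)| / |DIFF(k+1)|.}
#' On typical data the KL curve is high at the k = 2 boundary of the
#' search range, dips, and peaks again at the optimal k; the boundary
#' point is the curve's first maximum, and the chosen k is its second
#' maximum: the interior local maximum with the largest KL value. When no
#' interior local maximum exists the global maximum over the range is
#' used. The full curve is returned so the choice can be audited, and
#' `rule = "second_largest"` gives the second-largest-value reading.
#'
#' @inheritParams modified_kmeans
#' @param k_range Integer vector `c(kmin, kmax)`, `kmin >= 2`.
#' @param rule `"second_local_max"` (default) or `"second_largest"`.
#' @param n_restarts,max_iter,tol,seed Passed to [modified_kmeans()].
#' @return List with `chosen_k`, `kl_curve` (tibble: `k`, `W`, `diff`,
#'   `kl`), `rule`, and `fits` (the per-k [modified_kmeans()] fits).
#' @export
select_k_kl <- function(peak_maps, k_range = c(2, 8), n_restarts = 20,
                        max_iter = 100, tol = 1e-7, seed = NULL,
                        rule = c("second_local_max", "second_largest")) {
  rule <- match.arg(rule)
  X <- normalize_maps(as.matrix(peak_maps))
  m <- nrow(X)
  kmin <- k_range[1]; kmax <- k_range[2]
  if (kmin < 2) abort("k_range must start at 2 or above")
  if (kmax > m - 1) abort("k_range upper bound must be <= #maps - 1")
  p <- ncol(X)
  ks <- (kmin - 1):(kmax + 1)   # W needed one step beyond both ends
  fits <- with_seed(seed, {
    lapply(ks, function(k) modified_kmeans(X, k, n_restarts, max_iter, tol))
  })
  W <- vapply(fits, `[[`, numeric(1), "W")
  names(W) <- ks
  if (all(W < 1e-12)) {
    abort("degenerate dispersion: W(k) is zero for every k (too few or duplicate maps)")
  }
  curve <- kl_curve_from_w(W, kmin:kmax, p)
  kl_ks <- curve$k
  kl <- curve$kl
  # the boundary of the range is the curve's first maximum; the second
  # maximum is the dominant interior local maximum
  loc <- local_maxima(kl)
  chosen <- if (rule == "second_largest") {
    kl_ks[order(kl, decreasing = TRUE)[min(2, length(kl))]]
  } else if (length(loc)) {
    kl_ks[loc[which.max(kl[loc])]]
  } else {
    kl_ks[which.max(kl)]
  }
  keep <- ks >= kmin & ks <= kmax
  list(chosen_k = chosen, kl_curve = curve, rule = rule,
       fits = setNames(fits[keep], ks[keep]))
}

# Krzanowski-Lai curve from a named dispersion sequence W (names = k,
# spanning kl_ks extended one step both ways) and dimensionality p.
kl_curve_from_w <- function(W, kl_ks, p) {
  diff_at <- function(k) {
    (k - 1)^(2 / p) * W[as.character(k - 1)] - k^(2 / p) * W[as.character(k)]
  }
  diffs <- vapply(kl_ks, diff_at, numeric(1))
  diffs_next <- vapply(kl_ks + 1, diff_at, numeric(1))
  tibble(k = kl_ks, W = unname(W[as.character(kl_ks)]), diff = diffs,
         kl = abs(diffs) / pmax(abs(diffs_next), 1e-300))
}

# Indices of strict interior local maxima of a numeric vector.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  i[v[i] > v[i - 1] & v[i] > v[i + 1]]
}
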