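#' Permutation-average template sets across participants
#'
#' Averages several K-map template sets into one, allowing each set's maps
#' to be relabelled (permuted) and sign-flipped so that corresponding
#' topographies line up before averaging. Starting from the first set as
#' the provisional mean, each set is aligned to the mean by the label
#' permutation maximising the total squared spatial correlation, the mean
#' is recomputed per class as the polarity-aligned principal eigenvector of
#' the aligned maps, and the two steps iterate to convergence.
#'
#' @param map_sets List of K x N matrices (or `ms_templates` objects), all
#'   with identical K and N.
#' @param max_iter,tol Iteration cap and convergence tolerance on the total
#'   squared correlation.
#' @param seed Unused randomness hook kept for interface stability (the
#'   algorithm is deterministic); reserved.
#' @return List with `mean_maps` (K x N, unit-norm zero-mean rows),
#'   `permutations` (list of integer vectors: entry j of a permutation is
#'   the row of that set assigned to mean class j), `signs` (list of +/-1
#'   vectors), and `score` (mean squared correlation attained).
#' @export
permutation_average <- function(map_sets, max_iter = 100, tol = 1e-6,
                                seed = NULL) {
  mats <- lapply(map_sets, function(s) {
    if (inherits(s, "ms_templates")) s$maps else as.matrix(s)
  })
  K <- nrow(mats[[1]]); N <- ncol(mats[[1]])
  ok <- vapply(mats, function(m) nrow(m) == K && ncol(m) == N, logical(1))
  if (!all(ok)) abort("all template sets must share the same K and N")
  mats <- lapply(mats, normalize_maps)
  mean_maps <- mats[[1]]
  total_old <- -Inf
  perms <- NULL; signs <- NULL
  for (iter in seq_len(max_iter)) {
    ali <- lapply(mats, align_set, mean_maps = mean_maps)
    perms <- lapply(ali, `[[`, "perm")
    signs <- lapply(ali, `[[`, "sign")
    total <- sum(vapply(ali, `[[`, numeric(1), "score"))
    # per class, polarity-aligned eigenvector average of the aligned maps
    for (j in seq_len(K)) {
      stack <- t(vapply(seq_along(mats), function(s) {
        signs[[s]][j] * mats[[s]][perms[[s]][j], ]
      }, numeric(N)))
      v <- principal_map(stack)
      # keep the eigenvector pointing with the majority of aligned maps
      if (sum(stack %*% v) < 0) v <- -v
      mean_maps[j, ] <- v
    }
    if (abs(total - total_old) < tol) break
    total_old <- total
  }
  list(mean_maps = mean_maps, permutations = perms, signs = signs,
       score = total / (length(mats) * K))
}

# Best label permutation (+ per-map polarity signs) aligning one K x N set
# to the mean. Exhaustive over permutations for K <= 7, greedy otherwise.
align_set <- function(set, mean_maps) {
  K <- nrow(mean_maps)
  C <- mean_maps %*% t(set)            # C[j, i] = corr(mean j, set map i)
  C2 <- C^2
  if (K <= 7) {
    perms <- permutations_of(K)
    scores <- apply(perms, 1, function(p) sum(C2[cbind(seq_len(K), p)]))
    best <- perms[which.max(scores), ]
  } else {
    best <- integer(K)
    avail <- seq_len(K)
    for (j in order(apply(C2, 1, max), decreasing = TRUE)) {
      pick <- avail[which.max(C2[j, avail])]
      best[j] <- pick
      avail <- setdiff(avail, pick)
    }
  }
  sg <- sign(C[cbind(seq_len(K), best)])
  sg[sg == 0] <- 1
  list(perm = best, sign = sg,
       score = sum(C2[cbind(seq_len(K), best)]))
}

# All permutations of 1..n as rows of a matrix (n! x n).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  dimnames(out) <- NULL
  out
}

#' Build condition-level and overall template maps
#'
#' Permutation-averages the individual template sets within each condition,
#' then permutation-averages the condition-level sets into one overall set.
#' Overall maps are (optionally) labelled A-D by best bijective match to
#' canonical microstate topographies: A = right-frontal-to-left-posterior
#' diagonal, B = left-frontal-to-right-posterior diagonal, C =
#' anterior-posterior, D = fronto-central maximum.
#'
#' @param individual_sets_by_condition Named list (one entry per condition)
#'   of lists of `ms_templates` (or K x N matrices), one per subject.
#' @param montage Montage tibble (needed for canonical labelling).
#' @param channel_names Electrode names for the maps.
#' @param canonical_labels Assign A-D labels by canonical match (default
#'   TRUE for K = 4; otherwise generic labels are used).
#' @param reference Optional K x N matrix of reference maps (e.g. a
#'   synthetic generator's ground-truth templates): when given, classes are
#'   labelled A-D (in reference row order) by best bijective
#'   polarity-invariant match to the reference instead of the canonical
#'   topographies.
#' @return List with `overall` (an `ms_templates`, level `"overall"`),
#'   `condition` (named list of condition-level `ms_templates`), and the
#'   alignment diagnostics from [permutation_average()].
#' @export
build_level_templates <- function(individual_sets_by_condition, montage,
                                  channel_names,
                                  canonical_labels = TRUE,
                                  reference = NULL) {
  cond_fits <- lapply(individual_sets_by_condition, permutation_average)
  cond_maps <- lapply(cond_fits, `[[`, "mean_maps")
  overall_fit <- if (length(cond_maps) > 1) {
    permutation_average(cond_maps)
  } else {
    list(mean_maps = cond_maps[[1]], permutations = NULL, signs = NULL,
         score = 1)
  }
  maps <- overall_fit$mean_maps
  K <- nrow(maps)
  labels <- paste0("M", seq_len(K))
  if (!is.null(reference)) {
    ord <- reference_assignment(maps, reference)
    maps <- maps[ord, , drop = FALSE]
    labels <- head(LETTERS, K)
    cond_maps <- lapply(cond_maps, function(m) m[ord, , drop = FALSE])
  } else if (canonical_labels && K == 4) {
    ord <- canonical_assignment(maps, montage)
    maps <- maps[ord, , drop = FALSE]
    labels <- c("A", "B", "C", "D")
    cond_maps <- lapply(cond_maps, function(m) m[ord, , drop = FALSE])
  }
  overall <- new_ms_templates(maps, channel_names, labels, level = "overall")
  condition <- lapply(cond_maps, new_ms_templates,
                      channel_names = channel_names, class_labels = labels,
                      level = "condition")
  list(overall = overall, condition = condition,
       condition_fits = cond_fits, overall_fit = overall_fit)
}

# Row order aligning maps to an arbitrary reference set: ord[j] is the map
# row matched to reference row j, maximising total |corr| bijectively.
reference_assignment <- function(maps, reference) {
  K <- nrow(maps)
  C <- abs(normalize_maps(as.matrix(reference)) %*% t(normalize_maps(maps)))
  perms <- permutations_of(K)
  scores <- apply(perms, 1, function(p) sum(C[cbind(seq_len(K), p)]))
  perms[which.max(scores), ]
}

# Map row order such that maps[ord[1],] best matches canonical A, etc.
# Bijective assignment maximising total |corr|, exhaustive over 4! = 24.
canonical_assignment <- function(maps, montage) {
  canon <- canonical_topographies(montage)
  C <- abs(normalize_maps(canon) %*% t(normalize_maps(maps)))
  perms <- permutations_of(4)
  scores <- apply(perms, 1, function(p) sum(C[cbind(1:4, p)]))
  perms[which.max(scores), ]
}

# Idealised class A-D topographies over a montage: smooth gradients along
# the conventional axes (rows: A, B, C, D).
canonical_topographies <- function(montage) {
  x <- montage$x; y <- montage$y
  r2 <- x^2 + y^2
  rbind(
    A = -x + 0.7 * y,     # left-posterior to right-frontal diagonal
    B =  x + 0.7 * y,     # right-posterior to left-frontal diagonal
    C =  y,               # anterior-posterior
    D = 1 - 1.6 * r2      # fronto-central maximum
  )
}
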