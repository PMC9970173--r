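# Independent oracles, deliberately coded differently from the package
# implementations they check.

# Population standard deviation by explicit summation.
pop_sd_oracle <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  sqrt(sum((v - m)^2) / n)
}

# Benjamini-Hochberg step-up from the definition: adjusted p_(i) =
# min over j >= i of min(1, m * p_(j) / j).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- pmin(1, m * ranked / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Balanced two-way within-subject ANOVA by explicit sum-of-squares
# decomposition (cell means), returning F for condition, class and the
# interaction.
rm_anova_oracle <- function(d) {
  # d: subject, condition, class, value; balanced, one obs per cell
  s <- factor(d$subject); a <- factor(d$condition); b <- factor(d$class)
  y <- d$value
  n <- nlevels(s); p <- nlevels(a); q <- nlevels(b)
  gm <- mean(y)
  m_s <- tapply(y, s, mean); m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_sa <- tapply(y, list(s, a), mean); m_sb <- tapply(y, list(s, b), mean)
  m_ab <- tapply(y, list(a, b), mean)
  ss_a <- n * q * sum((m_a - gm)^2)
  ss_b <- n * p * sum((m_b - gm)^2)
  ss_s <- p * q * sum((m_s - gm)^2)
  ss_sa <- q * sum((m_sa - outer(m_s, m_a, "+") + gm)^2)
  ss_sb <- p * sum((m_sb - outer(m_s, m_b, "+") + gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, "+") + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_s - ss_sa - ss_sb - ss_ab
  list(
    F_condition = (ss_a / (p - 1)) / (ss_sa / ((n - 1) * (p - 1))),
    F_class = (ss_b / (q - 1)) / (ss_sb / ((n - 1) * (q - 1))),
    F_interaction = (ss_ab / ((p - 1) * (q - 1))) /
      (ss_sab / ((n - 1) * (p - 1) * (q - 1))),
    ss = c(total = ss_tot, subject = ss_s, condition = ss_a, class = ss_b,
           interaction = ss_ab, s_x_cond = ss_sa, s_x_class = ss_sb,
           s_x_inter = ss_sab)
  )
}

# Run-length microstate parameters straight from the definition, splitting
# at epoch boundaries; truncated runs included.
rle_params_oracle <- function(labels, epoch, srate, n_classes) {
  runs <- list()
  for (e in unique(epoch)) {
    lab <- labels[epoch == e]
    r <- rle(lab)
    keep <- !is.na(r$values)
    runs[[length(runs) + 1]] <- data.frame(class = r$values[keep],
                                           len = r$lengths[keep])
  }
  runs <- do.call(rbind, runs)
  tot <- sum(!is.na(labels))
  t(sapply(seq_len(n_classes), function(k) {
    l <- runs$len[runs$class == k]
    c(duration_ms = if (length(l)) mean(l) * 1000 / srate else 0,
      occurrence_per_s = length(l) / (tot / srate),
      contribution = if (tot) sum(l) / tot else 0)
  }))
}

# Exhaustive polarity-invariant k-means optimum: enumerate every labelling
# of the (unit-norm, zero-mean) maps into k groups; the best achievable
# sum of squared correlations for a group is the top eigenvalue of its
# Gram matrix. Returns the maximal explained variance and one optimal
# partition (as a canonical grouping signature).
kmeans_bruteforce <- function(X, k) {
  m <- nrow(X)
  G <- X %*% t(X)
  labelings <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  best_ev <- -Inf; best_lab <- NULL
  for (i in seq_len(nrow(labelings))) {
    lab <- labelings[i, ]
    if (length(unique(lab)) < k) next
    ev <- 0
    for (j in seq_len(k)) {
      idx <- which(lab == j)
      ev <- ev + max(eigen(G[idx, idx, drop = FALSE], symmetric = TRUE,
                           only.values = TRUE)$values)
    }
    if (ev > best_ev) {
      best_ev <- ev
      best_lab <- lab
    }
  }
  list(ev = best_ev / m, partition = partition_signature(best_lab))
}

# Label-permutation-invariant signature of a partition.
partition_signature <- function(lab) {
  groups <- split(seq_along(lab), lab)
  paste(sort(vapply(groups, function(g) paste(g, collapse = ","),
                    character(1))), collapse = "|")
}

# One-sided band power by direct DFT summation (independent of the
# package's Welch implementation): Hann window, integrate over band.
band_power_oracle <- function(x, fs, band) {
  L <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  xw <- (x - mean(x)) * w
  nf <- L %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / L
  pw <- numeric(nf)
  tt <- 0:(L - 1)
  for (i in seq_len(nf)) {
    f <- freqs[i]
    re <- sum(xw * cos(-2 * pi * f * tt / fs))
    im <- sum(xw * sin(-2 * pi * f * tt / fs))
    pw[i] <- (re^2 + im^2) * 2 / (fs * sum(w^2))
  }
  pw[1] <- pw[1] / 2
  if (L %% 2 == 0) pw[nf] <- pw[nf] / 2
  sum(pw[freqs >= band[1] & freqs <= band[2]]) * fs / L
}

# Exhaustive alignment of one K-map set to a mean: all permutations x all
# sign patterns, maximising total squared correlation.
align_bruteforce <- function(set, mean_maps) {
  K <- nrow(mean_maps)
  perms <- microstatr:::permutations_of(K)
  best <- -Inf; best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    score <- sum(vapply(seq_len(K), function(j) {
      cor(mean_maps[j, ], set[p[j], ])^2
    }, numeric(1)))
    if (score > best) {
      best <- score; best_perm <- p
    }
  }
  list(perm = best_perm, score = best)
}
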