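# Independent brute-force oracles used to check the package's fast paths.
# These are deliberately naive re-derivations from first principles and share
# no code with the implementation.

# Adjusted Rand index by explicit pair counting.
oracle_ari <- function(a, b) {
  n <- length(a)
  both <- same_a <- same_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      same_a <- same_a + sa
      same_b <- same_b + sb
      both <- both + (sa && sb)
    }
  }
  tot <- n * (n - 1) / 2
  expected <- same_a * same_b / tot
  unname((both - expected) / ((same_a + same_b) / 2 - expected))
}

# AUC by exhaustive positive/negative pair comparison, ties = 1/2.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# Improved precision/recall via O(n^2) double loops over pairwise distances.
oracle_precision_recall <- function(real, syn, k_nn) {
  eu <- function(a, b) sqrt(sum((a - b)^2))
  radius <- function(x, k) {
    n <- nrow(x)
    vapply(seq_len(n), function(i) {
      d <- vapply(seq_len(n), function(j) {
        if (i == j) Inf else eu(x[i, ], x[j, ])
      }, numeric(1))
      sort(d)[k]
    }, numeric(1))
  }
  in_manifold <- function(pts, centers, radii) {
    vapply(seq_len(nrow(pts)), function(i) {
      any(vapply(seq_len(nrow(centers)), function(j) {
        eu(pts[i, ], centers[j, ]) <= radii[j]
      }, logical(1)))
    }, logical(1))
  }
  r_real <- radius(real, k_nn)
  r_syn <- radius(syn, k_nn)
  c(precision = mean(in_manifold(syn, real, r_real)),
    recall = mean(in_manifold(real, syn, r_syn)))
}

# Frechet distance from an eigendecomposition of the (nonsymmetric) product
# sigma1 %*% sigma2 -- a different route than the implementation's
# symmetrized square root.
oracle_fid_moments <- function(mu1, s1, mu2, s2) {
  ev <- eigen(s1 %*% s2, only.values = TRUE)$values
  sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) -
    2 * sum(sqrt(pmax(Re(ev), 0)))
}

# SD validity index evaluated literally from its definition.
oracle_sd_index <- function(x, assign0, centroids, alpha) {
  popvar <- function(m) {
    apply(m, 2, function(col) mean((col - mean(col))^2))
  }
  norm_total <- sqrt(sum(popvar(x)^2))
  k <- nrow(centroids)
  scat <- mean(vapply(seq_len(k) - 1L, function(j) {
    sqrt(sum(popvar(x[assign0 == j, , drop = FALSE])^2))
  }, numeric(1))) / norm_total
  dmat <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) dmat[i, j] <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
  }
  pairs <- dmat[upper.tri(dmat)]
  dis <- (max(pairs) / min(pairs)) * sum(1 / rowSums(dmat))
  alpha * scat + dis
}

# Small constant-color RGB patch.
flat_patch <- function(size, rgb) {
  img <- array(0L, dim = c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}
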