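# k-means clustering of patch feature vectors and selection of the number of
# morphology clusters by minimizing the SD validity index over a scanned
# range of k.
#
# The SD index balances average within-cluster scattering against
# inter-centroid separation:
#   SD(k) = alpha * Scat(k) + Dis(k)
#   Scat(k) = (1/k) * sum_i ||sigma(C_i)|| / ||sigma(X)||
#   Dis(k)  = (D_max / D_min) * sum_i ( sum_j ||v_i - v_j|| )^-1
# with sigma(.) the per-dimension (population) variance vector, ||.|| the
# Euclidean norm, v_i the centroids, and D_max/D_min the largest/smallest
# inter-centroid distance. alpha is conventionally Dis(k_max) at the largest
# scanned k. Smaller is better; the scan picks argmin.

# Squared Euclidean distances between rows of x (n x d) and c (k x d).
dist2_to_centers <- function(x, centers) {
  n2x <- rowSums(x^2)
  n2c <- rowSums(centers^2)
  d2 <- outer(n2x, n2c, "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

# Greedy k-means++ seeding: at each step several candidate centers are drawn
# with probability proportional to the squared distance to the nearest chosen
# center, and the candidate that most reduces the total potential is kept
# (the standard refinement of the ++ scheme in widely used implementations).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  n_trials <- 2L + as.integer(floor(log(k)))
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    closest <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      tot <- sum(closest)
      if (!is.finite(tot) || tot <= 0) {
        picks <- sample.int(n, 1L)         # all points coincide with centers
      } else {
        picks <- sample.int(n, n_trials, replace = TRUE, prob = closest / tot)
      }
      cand_d2 <- dist2_to_centers(x, x[picks, , drop = FALSE])
      potentials <- colSums(pmin(cand_d2, closest))
      best <- picks[which.min(potentials)]
      centers[j, ] <- x[best, ]
      closest <- pmin(closest, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

lloyd_once <- function(x, centers, max_iter) {
  k <- nrow(centers)
  assign_prev <- rep(0L, nrow(x))
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: move the farthest member of the largest cluster
    repeat {
      sizes <- tabulate(assign, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      j <- empty[1]
      big <- which.max(sizes)
      members <- which(assign == big)
      far <- members[which.max(d2[cbind(members, assign[members])])]
      assign[far] <- j
      centers[j, ] <- x[far, ]
      d2[, j] <- rowSums(sweep(x, 2, centers[j, ])^2)
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }
  d2 <- dist2_to_centers(x, centers)
  inertia <- sum(d2[cbind(seq_len(nrow(x)), assign)])
  list(centers = centers, assign = assign, inertia = inertia)
}

#' Fit k-means with seeded k-means++ restarts
#'
#' Lloyd iterations from k-means++ seedings, keeping the best of
#' `n_restarts` runs by within-cluster sum of squares (inertia). Clusters
#' that empty out during an iteration are repaired by reseeding them with
#' the farthest point of the largest cluster, so the returned model never
#' has an empty cluster. Fully deterministic given `seed`.
#'
#' @param features A [feature_matrix] or numeric matrix.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed driving all restarts.
#' @param n_restarts Number of independent seedings (default 10).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return Object of class `cluster_model`: `k`, `centroids` (k x D),
#'   `assignments` (0-based, per row), `inertia`, `seed`.
#' @export
fit_kmeans <- function(features, k, seed = 1, n_restarts = 10, max_iter = 100) {
  x <- as_values(features)
  k <- check_count(k, "k")
  n_restarts <- check_count(n_restarts, "n_restarts")
  if (k > nrow(x)) {
    abort_mp(sprintf("k = %d exceeds the number of rows (%d)", k, nrow(x)),
             "mp_invalid_argument")
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(seed, r), {
      lloyd_once(x, kmeanspp_init(x, k), max_iter)
    })
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(
    list(k = k, centroids = best$centers, assignments = best$assign - 1L,
         inertia = best$inertia, seed = seed),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, n = %d, inertia = %.4g\n",
              x$k, length(x$assignments), x$inertia))
  invisible(x)
}

# Per-dimension population variance vector of a matrix.
pop_var <- function(x) {
  if (nrow(x) <= 1L) return(rep(0, ncol(x)))
  colMeans(sweep(x, 2, colMeans(x))^2)
}

#' SD validity index of a clustering
#'
#' Computes `alpha * Scat(k) + Dis(k)` (see the package vignette for the
#' formula). Requires `k >= 2` so that inter-centroid distances exist;
#' coincident centroids make the index undefined and raise a
#' degenerate-clustering error.
#'
#' @param features The clustered [feature_matrix] or numeric matrix.
#' @param model A [fit_kmeans()] result on the same rows.
#' @param alpha Weight of the scattering term; conventionally `Dis(k_max)`
#'   of the largest scanned k (see [select_k()]).
#' @return Positive scalar; smaller indicates a better balance of
#'   compactness and separation.
#' @export
sd_index <- function(features, model, alpha = 1) {
  x <- as_values(features)
  alpha <- check_scalar(alpha, "alpha")
  if (!inherits(model, "cluster_model")) {
    abort_mp("`model` must be a cluster_model", "mp_invalid_argument")
  }
  if (model$k < 2L) {
    abort_mp("SD index requires k >= 2", "mp_invalid_argument")
  }
  if (length(model$assignments) != nrow(x)) {
    abort_mp("model assignments do not match feature rows",
             "mp_invalid_argument")
  }
  scat <- sd_scat(x, model)
  dis <- sd_dis(model$centroids)
  alpha * scat + dis
}

sd_scat <- function(x, model) {
  norm_x <- sqrt(sum(pop_var(x)^2))
  if (norm_x == 0) {
    abort_mp("features have zero total variance", "mp_degenerate_clustering")
  }
  cl_norms <- vapply(seq_len(model$k) - 1L, function(j) {
    sqrt(sum(pop_var(x[model$assignments == j, , drop = FALSE])^2))
  }, numeric(1))
  mean(cl_norms) / norm_x
}

sd_dis <- function(centroids) {
  dmat <- as.matrix(dist(centroids))
  pair <- dmat[upper.tri(dmat)]
  dmin <- min(pair)
  if (dmin == 0) {
    abort_mp("coincident centroids: SD index undefined",
             "mp_degenerate_clustering")
  }
  dmax <- max(pair)
  (dmax / dmin) * sum(1 / rowSums(dmat))
}

#' Choose the number of clusters by SD-index minimization
#'
#' Fits k-means for every k in `k_min:k_max` and evaluates the SD index,
#' with the scattering weight `alpha` set to `Dis(k_max)` of the
#' largest-k model (the index's convention) unless given explicitly. The
#' chosen k attains the minimum; ties break toward smaller k. A k whose
#' index is degenerate (coincident centroids) is recorded as `NA` and
#' skipped with a warning; the scan errors only if every k degenerates.
#'
#' @param features A [feature_matrix] or numeric matrix.
#' @param k_min,k_max Scan bounds, `2 <= k_min < k_max <= n - 1`.
#' @param seed Integer seed for all k-means fits.
#' @param n_restarts Restarts per k (default 10).
#' @param alpha Optional explicit scattering weight.
#' @return Object of class `kscan_result`: `k_values`, `sd_index` (per k),
#'   `chosen_k`, `alpha`, plus `model`, the fitted `cluster_model` at
#'   `chosen_k`.
#' @export
select_k <- function(features, k_min = 2, k_max = 50, seed = 1,
                     n_restarts = 10, alpha = NULL) {
  x <- as_values(features)
  k_min <- check_count(k_min, "k_min", min = 2L)
  k_max <- check_count(k_max, "k_max")
  if (k_min >= k_max) {
    abort_mp("`k_min` must be < `k_max`", "mp_invalid_argument")
  }
  if (k_max > nrow(x) - 1L) {
    abort_mp("`k_max` must be <= n - 1", "mp_invalid_argument")
  }
  k_values <- k_min:k_max
  models <- lapply(k_values, function(k) {
    fit_kmeans(x, k, seed = derive_seed(seed, k), n_restarts = n_restarts)
  })
  if (is.null(alpha)) {
    alpha <- tryCatch(sd_dis(models[[length(models)]]$centroids),
                      mp_degenerate_clustering = function(e) NA_real_)
    if (is.na(alpha)) {
      abort_mp("clustering at k_max is degenerate; supply `alpha` explicitly",
               "mp_degenerate_clustering")
    }
  }
  scores <- vapply(models, function(m) {
    tryCatch(sd_index(x, m, alpha = alpha),
             mp_degenerate_clustering = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(scores)) {
    warning(sprintf("SD index degenerate at k = %s; excluded from the scan",
                    paste(k_values[is.na(scores)], collapse = ", ")))
  }
  if (all(is.na(scores))) {
    abort_mp("SD index degenerate at every scanned k",
             "mp_degenerate_clustering")
  }
  best <- which.min(scores)            # first minimum -> smallest k on ties
  structure(
    list(k_values = k_values, sd_index = scores,
         chosen_k = k_values[best], alpha = alpha, model = models[[best]]),
    class = "kscan_result"
  )
}

#' @export
print.kscan_result <- function(x, ...) {
  cat(sprintf("<kscan_result> scanned k in [%d, %d]; chosen k = %d (SD = %.4g, alpha = %.4g)\n",
              min(x$k_values), max(x$k_values), x$chosen_k,
              x$sd_index[match(x$chosen_k, x$k_values)], x$alpha))
  invisible(x)
}

#' Serialize a k scan and cluster assignments
#'
#' `write_kscan` writes the scan curve (k, SD index, chosen k, alpha) as
#' JSON; `write_assignments` writes a CSV `id,cluster` for a fitted model.
#'
#' @param scan A `kscan_result`.
#' @param model A `cluster_model`.
#' @param ids Row ids aligned with the model's assignments.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kscan <- function(scan, path) {
  stopifnot(inherits(scan, "kscan_result"))
  jsonlite::write_json(
    list(k_values = scan$k_values, sd_index = scan$sd_index,
         chosen_k = scan$chosen_k, alpha = scan$alpha),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_kscan
#' @export
write_assignments <- function(model, ids, path) {
  stopifnot(inherits(model, "cluster_model"))
  if (length(ids) != length(model$assignments)) {
    abort_mp("`ids` must align with the model's assignments",
             "mp_invalid_argument")
  }
  write.csv(data.frame(id = ids, cluster = model$assignments),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
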