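# Quantitative generation metrics on embedding sets: Frechet distance
# between fitted Gaussians (FID) and the improved precision/recall manifold
# metrics estimated with k-nearest-neighbor balls.

check_embedding <- function(x, name) {
  x <- as_values(x)
  if (!is.matrix(x) || nrow(x) < 2L) {
    abort_mp(sprintf("`%s` must be a matrix with at least 2 rows", name),
             "mp_invalid_argument")
  }
  if (!all(is.finite(x))) {
    abort_mp(sprintf("`%s` contains non-finite values", name),
             "mp_invalid_argument")
  }
  x
}

# Symmetric PSD square root via eigendecomposition, clamping small negative
# eigenvalues (|lambda| < tol * spectral radius) to zero.
sym_sqrtm <- function(s, tol = 1e-8) {
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  lam <- e$values
  rad <- max(abs(lam), 0)
  if (rad > 0 && any(lam < -tol * rad)) {
    abort_mp("matrix is not positive semidefinite within tolerance",
             "mp_invalid_argument")
  }
  lam <- pmax(lam, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' Frechet distance between two Gaussians given their moments
#'
#' `||mu1 - mu2||^2 + Tr(sigma1 + sigma2 - 2 (sigma1 sigma2)^(1/2))`. The
#' cross-covariance square root is computed as
#' `sqrtm(sqrtm(sigma1) sigma2 sqrtm(sigma1))` through symmetric
#' eigendecompositions with small negative eigenvalues clamped to zero.
#'
#' @param mu1,mu2 Mean vectors of length E.
#' @param sigma1,sigma2 E x E symmetric positive semidefinite covariance
#'   matrices.
#' @return Nonnegative scalar.
#' @examples
#' fid_from_moments(c(0, 0), diag(2), c(3, 0), diag(2))  # 9
#' @export
fid_from_moments <- function(mu1, sigma1, mu2, sigma2) {
  mu1 <- as.numeric(mu1); mu2 <- as.numeric(mu2)
  sigma1 <- as.matrix(sigma1); sigma2 <- as.matrix(sigma2)
  e <- length(mu1)
  if (length(mu2) != e || any(dim(sigma1) != e) || any(dim(sigma2) != e)) {
    abort_mp("moment dimensions do not agree", "mp_invalid_argument")
  }
  for (s in list(sigma1, sigma2)) {
    asym <- max(abs(s - t(s)))
    if (asym > 1e-8 * max(1, max(abs(s)))) {
      abort_mp("covariance matrix is not symmetric within tolerance",
               "mp_invalid_argument")
    }
  }
  s1h <- sym_sqrtm(sigma1)
  cross <- sym_sqrtm(s1h %*% sigma2 %*% s1h)
  val <- sum((mu1 - mu2)^2) + sum(diag(sigma1)) + sum(diag(sigma2)) -
    2 * sum(diag(cross))
  max(val, 0)
}

#' Frechet Inception Distance between two embedding sets
#'
#' Fits a mean vector and unbiased covariance to each set and evaluates
#' [fid_from_moments()]. The embedder is whatever produced the rows (the
#' conventional choice is an ImageNet-pretrained Inception network; any
#' fixed embedder works and desk-scale runs use the reference extractor).
#'
#' @param real,syn Embedding matrices (or [feature_matrix] objects) with a
#'   common column dimension E. A warning is given when a set has fewer
#'   rows than E (covariance is then singular).
#' @return Nonnegative scalar; 0 for identical distributions.
#' @export
fid <- function(real, syn) {
  xr <- check_embedding(real, "real")
  xs <- check_embedding(syn, "syn")
  if (ncol(xr) != ncol(xs)) {
    abort_mp("embedding dimensions differ between sets", "mp_invalid_argument")
  }
  if (min(nrow(xr), nrow(xs)) < ncol(xr)) {
    warning("fewer rows than embedding dimensions; covariance is singular")
  }
  fid_from_moments(colMeans(xr), cov(xr), colMeans(xs), cov(xs))
}

# distance from each row of a to each row of b
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# per-point radius: distance to the k-th nearest neighbor within the same
# set, excluding the point itself
knn_radius <- function(x, k) {
  d <- cross_dist(x, x)
  diag(d) <- Inf
  apply(d, 1, function(r) sort(r, partial = k)[k])
}

#' Improved precision and recall for generative models
#'
#' Approximates each set's manifold by the union of balls centered at its
#' points with radius equal to the distance to the k-th nearest neighbor
#' within the same set (self excluded). Precision is the fraction of
#' synthetic points inside at least one real ball (realism of the synthetic
#' set); recall is the fraction of real points inside at least one synthetic
#' ball (coverage of the real diversity). Points exactly at a ball's radius
#' count as inside.
#'
#' @param real,syn Embedding matrices with a common column dimension.
#' @param k_nn Neighborhood size; must be smaller than both set sizes
#'   (default 3).
#' @return Named numeric vector `c(precision =, recall =)`.
#' @export
improved_precision_recall <- function(real, syn, k_nn = 3) {
  xr <- check_embedding(real, "real")
  xs <- check_embedding(syn, "syn")
  if (ncol(xr) != ncol(xs)) {
    abort_mp("embedding dimensions differ between sets", "mp_invalid_argument")
  }
  k_nn <- check_count(k_nn, "k_nn")
  if (k_nn >= min(nrow(xr), nrow(xs))) {
    abort_mp("`k_nn` must be smaller than both set sizes",
             "mp_invalid_argument")
  }
  r_real <- knn_radius(xr, k_nn)
  r_syn <- knn_radius(xs, k_nn)
  d_sr <- cross_dist(xs, xr)      # syn rows x real cols
  precision <- mean(apply(sweep(d_sr, 2, r_real, "-") <= 0, 1, any))
  recall <- mean(apply(sweep(t(d_sr), 2, r_syn, "-") <= 0, 1, any))
  c(precision = precision, recall = recall)
}

#' Bundle FID and improved precision/recall into a metric report
#'
#' @param real,syn Embedding matrices or [feature_matrix] objects.
#' @param k_nn Neighborhood size for precision/recall.
#' @param embedder_id Provenance string recorded in the report.
#' @return Object of class `metric_report`: `fid`, `precision`, `recall`,
#'   `k_nn`, `n_real`, `n_syn`, `embedder_id`.
#' @export
evaluate_generation <- function(real, syn, k_nn = 3,
                                embedder_id = NULL) {
  if (is.null(embedder_id)) {
    embedder_id <- if (inherits(real, "feature_matrix")) real$extractor_id
                   else "unknown"
  }
  xr <- check_embedding(real, "real")
  xs <- check_embedding(syn, "syn")
  pr <- improved_precision_recall(xr, xs, k_nn)
  structure(
    list(fid = fid(xr, xs), precision = unname(pr["precision"]),
         recall = unname(pr["recall"]), k_nn = as.integer(k_nn),
         n_real = nrow(xr), n_syn = nrow(xs),
         embedder_id = as.character(embedder_id)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> FID = %.4g, precision = %.3f, recall = %.3f (k_nn = %d, n_real = %d, n_syn = %d, embedder = %s)\n",
    x$fid, x$precision, x$recall, x$k_nn, x$n_real, x$n_syn, x$embedder_id))
  invisible(x)
}

#' Write / read a metric report as JSON
#'
#' @param x A `metric_report`.
#' @param path JSON file path.
#' @return `write_metric_report` returns `path` invisibly;
#'   `read_metric_report` returns a `metric_report`.
#' @export
write_metric_report <- function(x, path) {
  stopifnot(inherits(x, "metric_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(fid = x$fid, precision = x$precision, recall = x$recall,
                 k_nn = as.integer(x$k_nn), n_real = as.integer(x$n_real),
                 n_syn = as.integer(x$n_syn), embedder_id = x$embedder_id),
            class = "metric_report")
}
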