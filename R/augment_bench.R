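# Mixed real/synthetic classifier benchmark: a grid over real-data regimes,
# synthetic augmentation ratios and seeded folds. Each cell draws a
# class-balanced training set from the pools, trains a classifier through a
# pluggable trainer contract (with validation-AUC model selection), and
# scores it on a held-out test set by AUC.

#' Specify the benchmark grid
#'
#' Defaults follow the standard protocol: 7 real-data regimes x
#' 6 augmentation ratios x 10 folds = 420 cells.
#'
#' @param regimes Initial real training-set sizes.
#' @param ratios Synthetic augmentation ratios in percent of the regime
#'   size.
#' @param n_folds Folds (independently sampled training subsets) per cell.
#' @param seed Master seed used to derive one fold seed per fold when
#'   `seeds` is not given.
#' @param seeds Optional explicit fold seeds (length `n_folds`).
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(regimes = c(10, 25, 50, 100, 500, 1000, 10000),
                      ratios = c(0, 25, 50, 100, 200, 300),
                      n_folds = 10, seed = 1, seeds = NULL) {
  regimes <- vapply(regimes, check_count, integer(1), name = "regimes")
  if (any(ratios < 0)) {
    abort_mp("augmentation ratios must be nonnegative", "mp_invalid_argument")
  }
  n_folds <- check_count(n_folds, "n_folds")
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(n_folds), function(i) derive_seed(seed, i),
                    numeric(1))
  }
  if (length(seeds) != n_folds) {
    abort_mp("`seeds` must have length `n_folds`", "mp_invalid_argument")
  }
  structure(list(regimes = regimes, ratios = as.numeric(ratios),
                 n_folds = n_folds, seeds = as.numeric(seeds)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d regimes x %d ratios x %d folds = %d cells\n",
              length(x$regimes), length(x$ratios), x$n_folds,
              length(x$regimes) * length(x$ratios) * x$n_folds))
  invisible(x)
}

#' Read / write a grid specification as YAML
#'
#' @param spec A `grid_spec`.
#' @param path YAML file path.
#' @return `write_grid_spec` returns `path` invisibly; `read_grid_spec`
#'   returns a `grid_spec`.
#' @export
write_grid_spec <- function(spec, path) {
  stopifnot(inherits(spec, "grid_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_grid_spec
#' @export
read_grid_spec <- function(path) {
  x <- yaml::read_yaml(path)
  allowed <- c("regimes", "ratios", "n_folds", "seed", "seeds")
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    abort_mp(sprintf("unknown grid spec key: '%s'", unknown[1]),
             "mp_config_error")
  }
  do.call(grid_spec, x)
}

# class-balanced draw of n ids from a pool; positive class gets the extra
# sample on odd n
balanced_draw <- function(pool, n, pool_name) {
  n_pos <- ceiling(n / 2)
  n_neg <- n - n_pos
  pos <- which(pool$labels == 1L)
  neg <- which(pool$labels == 0L)
  if (length(pos) < n_pos || length(neg) < n_neg) {
    short <- if (length(pos) < n_pos) "positive" else "negative"
    abort_mp(sprintf(
      "%s pool has too few %s samples (need %d positive / %d negative, have %d / %d)",
      pool_name, short, n_pos, n_neg, length(pos), length(neg)),
      "mp_insufficient_pool")
  }
  c(pos[sample.int(length(pos), n_pos)],
    neg[sample.int(length(neg), n_neg)])
}

#' Draw one mixed real/synthetic training set
#'
#' Draws `n_real` real samples plus `round(n_real * ratio_pct / 100)`
#' synthetic samples, each class-balanced to within one sample (the
#' positive class receives the extra sample on odd counts), without
#' replacement and deterministically under `seed`.
#'
#' @param real_pool,syn_pool [sample_pool] objects.
#' @param n_real Number of real samples.
#' @param ratio_pct Synthetic augmentation ratio in percent (e.g. 200 adds
#'   200 synthetic samples to a 100-real-sample set).
#' @param seed Integer seed.
#' @return List with `ids`, `labels`, `features`, and `provenance`
#'   (`"real"`/`"synthetic"` per row).
#' @export
sample_training_set <- function(real_pool, syn_pool, n_real, ratio_pct,
                                seed = 1) {
  stopifnot(inherits(real_pool, "sample_pool"))
  n_real <- check_count(n_real, "n_real")
  if (!is.numeric(ratio_pct) || length(ratio_pct) != 1L || ratio_pct < 0) {
    abort_mp("`ratio_pct` must be a single nonnegative number",
             "mp_invalid_argument")
  }
  n_syn <- round(n_real * ratio_pct / 100)
  with_seed(seed, {
    ri <- balanced_draw(real_pool, n_real, "real")
    si <- if (n_syn > 0) {
      stopifnot(inherits(syn_pool, "sample_pool"))
      balanced_draw(syn_pool, n_syn, "synthetic")
    } else integer(0)
    list(
      ids = c(real_pool$ids[ri], syn_pool$ids[si]),
      labels = c(real_pool$labels[ri], syn_pool$labels[si]),
      features = rbind(real_pool$features[ri, , drop = FALSE],
                       syn_pool$features[si, , drop = FALSE]),
      provenance = c(rep("real", length(ri)), rep("synthetic", length(si)))
    )
  })
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with score ties counted one half. Computed from midranks
#' in O(n log n).
#'
#' @param labels Binary 0/1 vector; both classes must be present.
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    abort_mp("labels and scores must have equal length", "mp_invalid_argument")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort_mp("AUC undefined: both classes must be present",
             "mp_undefined_auc")
  }
  r <- rank(scores)              # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Reference trainer: closed-form ridge classifier
#'
#' A regularized linear scorer on feature vectors, trained in closed form
#' (`beta = (X'X + lambda I)^-1 X'(y - mean(y))` on centered features).
#' The ridge penalty `lambda` is selected from `lambdas` by AUC on the
#' validation set, mirroring best-epoch selection on a validation holdout.
#' Deterministic; serves as the reference implementation of the classifier
#' contract (a function `(x, y, x_val, y_val) -> list(score = function(x))`).
#'
#' @param lambdas Candidate ridge penalties.
#' @return A trainer function following the contract.
#' @export
ridge_trainer <- function(lambdas = 10^c(-2, 0, 2)) {
  force(lambdas)
  function(x, y, x_val = NULL, y_val = NULL) {
    x <- as.matrix(x)
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    xty <- crossprod(xc, y - mean(y))
    xtx <- crossprod(xc)
    fit_one <- function(lambda) {
      beta <- solve(xtx + diag(lambda, ncol(x)), xty)
      function(xnew) drop(sweep(as.matrix(xnew), 2, mu) %*% beta)
    }
    scorers <- lapply(lambdas, fit_one)
    pick <- 1L
    if (!is.null(x_val) && !is.null(y_val) && length(unique(y_val)) == 2L) {
      val_auc <- vapply(scorers, function(s) auc(y_val, s(x_val)), numeric(1))
      pick <- which.max(val_auc)
    }
    list(score = scorers[[pick]], lambda = lambdas[pick])
  }
}

#' Run the augmentation benchmark grid
#'
#' For every (regime, ratio, fold) cell: draw a balanced mixed training set
#' from the pools under the fold seed, train through the trainer contract
#' with validation-based model selection, and record the test-set AUC.
#' Trainer failures are recorded per cell (AUC `NA` plus the message), not
#' fatal to the grid. The fold seeds are shared across cells, so cells in
#' the same fold draw comparable subsets.
#'
#' @param spec A [grid_spec()].
#' @param real_pool,syn_pool [sample_pool]s to draw training data from.
#' @param trainer Classifier contract (default [ridge_trainer()]).
#' @param val_pool,test_pool [sample_pool]s used for model selection and
#'   final AUC.
#' @return Data frame with one row per cell: `n_real`, `ratio_pct`, `fold`,
#'   `fold_seed`, `n_syn_added`, `auc`, `error`.
#' @export
run_grid <- function(spec, real_pool, syn_pool, trainer = ridge_trainer(),
                     val_pool, test_pool) {
  stopifnot(inherits(spec, "grid_spec"), inherits(val_pool, "sample_pool"),
            inherits(test_pool, "sample_pool"))
  cells <- expand.grid(fold = seq_len(spec$n_folds),
                       ratio_pct = spec$ratios, n_real = spec$regimes)
  cells <- cells[, c("n_real", "ratio_pct", "fold")]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    n_real <- cells$n_real[i]
    ratio <- cells$ratio_pct[i]
    fold <- cells$fold[i]
    fold_seed <- spec$seeds[fold]
    cell_seed <- derive_seed(fold_seed, n_real * 1000 + ratio)
    n_syn <- round(n_real * ratio / 100)
    res <- tryCatch({
      tr <- sample_training_set(real_pool, syn_pool, n_real, ratio,
                                seed = cell_seed)
      fitted <- trainer(tr$features, tr$labels,
                        val_pool$features, val_pool$labels)
      list(auc = auc(test_pool$labels, fitted$score(test_pool$features)),
           error = NA_character_)
    }, error = function(e) list(auc = NA_real_, error = conditionMessage(e)))
    out[[i]] <- data.frame(
      n_real = n_real, ratio_pct = ratio, fold = fold,
      fold_seed = fold_seed, n_syn_added = n_syn,
      auc = res$auc, error = res$error, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Summarize grid results per (regime, ratio)
#'
#' @param results Data frame from [run_grid()].
#' @return Data frame with `n_real`, `ratio_pct`, `n` (non-failed folds),
#'   `median`, `q1`, `q3`, ordered by regime then ratio. Cells in which
#'   every fold failed are dropped with a warning.
#' @export
summarize_grid <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    abort_mp("`results` must be a nonempty data frame", "mp_invalid_argument")
  }
  key <- interaction(results$n_real, results$ratio_pct, drop = TRUE)
  rows <- lapply(split(results, key), function(cell) {
    ok <- cell$auc[!is.na(cell$auc)]
    if (length(ok) == 0L) {
      warning(sprintf("all folds failed for regime %d, ratio %g%%; dropped",
                      cell$n_real[1], cell$ratio_pct[1]))
      return(NULL)
    }
    q <- unname(quantile(ok, c(0.25, 0.5, 0.75), type = 7))
    data.frame(n_real = cell$n_real[1], ratio_pct = cell$ratio_pct[1],
               n = length(ok), median = q[2], q1 = q[1], q3 = q[3])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(n_real = integer(), ratio_pct = numeric(),
                      n = integer(), median = numeric(),
                      q1 = numeric(), q3 = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n_real, out$ratio_pct), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write grid results and their summary
#'
#' Writes one CSV row per cell plus a JSON per-(regime, ratio) summary.
#'
#' @param results Data frame from [run_grid()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_grid_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(results, file.path(dir, "grid_results.csv"), row.names = FALSE)
  jsonlite::write_json(summarize_grid(results),
                       file.path(dir, "grid_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
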