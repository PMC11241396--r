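# Projection-based coverage analysis: fit a 2-D projector on the real
# embeddings only, transform both sets into that space, and summarize how
# much of the real occupancy the synthetic set reaches.
#
# The projector is a contract (id / fit / transform) so that any external
# 2-D embedding method (e.g. UMAP) can be plugged in; the bundled reference
# projector is PCA and an identity projector makes the path exactly
# verifiable on 2-D inputs.

#' Bundled projector contracts
#'
#' `pca_projector()` fits a rank-2 PCA (centered, unscaled) on the reference
#' set; `identity_projector()` passes 2-D embeddings through unchanged.
#'
#' @return A list with `id`, `fit(x)` and `transform(model, x)`, the
#'   projector contract used by [project_embeddings()].
#' @export
pca_projector <- function() {
  list(
    id = "pca_2d",
    fit = function(x) stats::prcomp(x, rank. = 2, center = TRUE, scale. = FALSE),
    transform = function(model, x) {
      unname(stats::predict(model, x)[, 1:2, drop = FALSE])
    }
  )
}

#' @rdname pca_projector
#' @export
identity_projector <- function() {
  list(
    id = "identity",
    fit = function(x) {
      if (ncol(x) != 2L) {
        abort_mp("identity projector requires 2-D embeddings",
                 "mp_invalid_argument")
      }
      NULL
    },
    transform = function(model, x) unname(as.matrix(x))
  )
}

#' Project real and synthetic embeddings into a common 2-D space
#'
#' The projector is fitted on the real embeddings only and then applied to
#' both sets, so the synthetic set is viewed strictly through the lens of
#' the real data distribution.
#'
#' @param real,syn Embedding matrices or [feature_matrix] objects.
#' @param projector Projector contract (default [pca_projector()]).
#' @param seed Integer seed made available to stochastic projectors.
#' @return Object of class `projected_sets`: `real_2d`, `syn_2d`,
#'   `projector_id`, `seed`.
#' @export
project_embeddings <- function(real, syn, projector = pca_projector(),
                               seed = 1) {
  xr <- check_embedding(real, "real")
  xs <- check_embedding(syn, "syn")
  if (!is.list(projector) || !is.function(projector$fit) ||
      !is.function(projector$transform)) {
    abort_mp("`projector` must be a list with id, fit, transform",
             "mp_invalid_argument")
  }
  res <- tryCatch(
    with_seed(seed, {
      model <- projector$fit(xr)
      list(real_2d = projector$transform(model, xr),
           syn_2d = projector$transform(model, xs))
    }),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    if (inherits(res, "morphoprompt_error")) stop(res)
    abort_mp(sprintf("projector '%s' failed: %s", projector$id,
                     conditionMessage(res)), "mp_projection_error")
  }
  if (!all(is.finite(res$real_2d)) || !all(is.finite(res$syn_2d))) {
    abort_mp("projector produced non-finite coordinates",
             "mp_projection_error")
  }
  structure(
    list(real_2d = res$real_2d, syn_2d = res$syn_2d,
         projector_id = projector$id, seed = seed),
    class = "projected_sets"
  )
}

#' @export
print.projected_sets <- function(x, ...) {
  cat(sprintf("<projected_sets> %d real + %d synthetic points (projector: %s)\n",
              nrow(x$real_2d), nrow(x$syn_2d), x$projector_id))
  invisible(x)
}

cell_index <- function(xy, xlim, ylim, grid_n) {
  ix <- pmin(grid_n, pmax(1, floor((xy[, 1] - xlim[1]) /
                                     (xlim[2] - xlim[1]) * grid_n) + 1))
  iy <- pmin(grid_n, pmax(1, floor((xy[, 2] - ylim[1]) /
                                     (ylim[2] - ylim[1]) * grid_n) + 1))
  (ix - 1) * grid_n + iy
}

#' Occupancy coverage of the real distribution by the synthetic set
#'
#' Divides the bounding box of the real 2-D coordinates into a
#' `grid_n` x `grid_n` grid and returns the fraction of real-occupied cells
#' that are also occupied by synthetic points. Synthetic points outside the
#' real bounding box are ignored. A scalar counterpart of the usual visual
#' overlap inspection of projected embedding clouds.
#'
#' @param p A `projected_sets` object.
#' @param grid_n Grid resolution per axis (default 50).
#' @return Proportion in \[0, 1\].
#' @export
occupancy_coverage <- function(p, grid_n = 50) {
  stopifnot(inherits(p, "projected_sets"))
  grid_n <- check_count(grid_n, "grid_n", min = 2L)
  xlim <- range(p$real_2d[, 1])
  ylim <- range(p$real_2d[, 2])
  if (diff(xlim) == 0 || diff(ylim) == 0) {
    abort_mp("degenerate (zero-area) real bounding box", "mp_invalid_argument")
  }
  real_cells <- unique(cell_index(p$real_2d, xlim, ylim, grid_n))
  inside <- p$syn_2d[, 1] >= xlim[1] & p$syn_2d[, 1] <= xlim[2] &
    p$syn_2d[, 2] >= ylim[1] & p$syn_2d[, 2] <= ylim[2]
  if (!any(inside)) return(0)
  syn_cells <- unique(cell_index(p$syn_2d[inside, , drop = FALSE],
                                 xlim, ylim, grid_n))
  length(intersect(real_cells, syn_cells)) / length(real_cells)
}

#' Write projected coordinates and an overlap scatter figure
#'
#' `write_projection` writes a CSV with columns `set` (real/synthetic),
#' `x`, `y`; `plot_projected_sets` renders the two clouds into a PNG.
#'
#' @param p A `projected_sets` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(p, path) {
  stopifnot(inherits(p, "projected_sets"))
  df <- rbind(
    data.frame(set = "real", x = p$real_2d[, 1], y = p$real_2d[, 2]),
    data.frame(set = "synthetic", x = p$syn_2d[, 1], y = p$syn_2d[, 2])
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_projection
#' @export
plot_projected_sets <- function(p, path) {
  stopifnot(inherits(p, "projected_sets"))
  grDevices::png(path, width = 800, height = 700)
  on.exit(grDevices::dev.off())
  plot(p$real_2d, col = grDevices::adjustcolor("steelblue", 0.5), pch = 16,
       cex = 0.6, xlab = "dim 1", ylab = "dim 2",
       main = sprintf("Real vs synthetic embeddings (%s)", p$projector_id))
  graphics::points(p$syn_2d, col = grDevices::adjustcolor("firebrick", 0.5),
                   pch = 16, cex = 0.6)
  graphics::legend("topright", legend = c("real", "synthetic"),
                   col = c("steelblue", "firebrick"), pch = 16)
  invisible(path)
}
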