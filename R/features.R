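# Feature-extractor contract and the deterministic reference extractor.
#
# An extractor is a list with fields `id` (string), `dim` (output length D),
# and `fn` (function mapping one H x W x 3 integer image to a length-D finite
# numeric vector). Pretrained deep extractors (e.g. a self-supervised ViT
# class token, D = 768) plug in through the same contract via an adapter; the
# package itself ships a cheap, fully deterministic reference extractor so
# every stage runs without downloaded weights.

#' Construct a feature matrix
#'
#' @param ids Character vector of row ids.
#' @param values Numeric matrix, one row per id; must be finite.
#' @param extractor_id Identifier of the extractor that produced the rows.
#' @return An object of class `feature_matrix`: list with `ids`, `values`
#'   (rownames set to ids) and `extractor_id`.
#' @export
feature_matrix <- function(ids, values, extractor_id = "unknown") {
  ids <- as.character(ids)
  values <- as.matrix(values)
  if (length(ids) != nrow(values)) {
    abort_mp("`ids` length must equal nrow(values)", "mp_invalid_argument")
  }
  if (anyDuplicated(ids)) {
    abort_mp(sprintf("duplicate id in feature matrix: '%s'",
                     ids[anyDuplicated(ids)]), "mp_invalid_argument")
  }
  if (!all(is.finite(values))) {
    bad <- ids[which(!apply(is.finite(values), 1, all))[1]]
    abort_mp(sprintf("non-finite feature values for id '%s'", bad),
             "mp_extraction_error")
  }
  rownames(values) <- ids
  structure(list(ids = ids, values = values,
                 extractor_id = as.character(extractor_id)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (extractor: %s)\n",
              nrow(x$values), ncol(x$values), x$extractor_id))
  invisible(x)
}

# Coerce feature_matrix / matrix to a plain numeric matrix.
as_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

#' Reference patch feature extractor
#'
#' A deterministic, weight-free image descriptor used for desk-scale runs:
#' per-channel 8-bin intensity histograms (normalized to sum 1), per-channel
#' mean and standard deviation, and mean gradient-magnitude energy in four
#' orientation bands (horizontal, vertical, and the two diagonals), giving
#' D = 8*3 + 2*3 + 4 = 34 components, each normalized into \[0, 1\].
#'
#' @param image H x W x 3 integer array with 8-bit channel values.
#' @return Numeric vector of length 34.
#' @seealso [make_reference_extractor()] for the contract object.
#' @export
reference_extractor <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort_mp("reference_extractor expects an H x W x 3 RGB array",
             "mp_invalid_argument")
  }
  if (any(dim(image)[1:2] < 1L)) {
    abort_mp("empty image", "mp_invalid_argument")
  }
  img <- array(as.numeric(image), dim = dim(image))
  npix <- dim(img)[1] * dim(img)[2]

  feats <- numeric(0)
  for (ch in 1:3) {
    v <- img[, , ch]
    bins <- pmin(7L, as.integer(v %/% 32))     # 8 bins of width 32
    h <- tabulate(bins + 1L, nbins = 8L) / npix
    feats <- c(feats, h)
  }
  for (ch in 1:3) {
    v <- img[, , ch]
    feats <- c(feats, mean(v) / 255)
  }
  for (ch in 1:3) {
    v <- img[, , ch]
    # sd of 8-bit values is at most 127.5 (half the pixels at 0, half at 255)
    feats <- c(feats, if (npix > 1) sqrt(mean((v - mean(v))^2)) / 127.5 else 0)
  }
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  feats <- c(feats, grad_energy(gray))
  feats
}

# Mean absolute forward difference along 4 orientations, scaled to [0, 1].
grad_energy <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  e <- numeric(4)
  if (w > 1) e[1] <- mean(abs(gray[, -1, drop = FALSE] - gray[, -w, drop = FALSE]))
  if (h > 1) e[2] <- mean(abs(gray[-1, , drop = FALSE] - gray[-h, , drop = FALSE]))
  if (h > 1 && w > 1) {
    e[3] <- mean(abs(gray[-1, -1, drop = FALSE] - gray[-h, -w, drop = FALSE]))
    e[4] <- mean(abs(gray[-1, -w, drop = FALSE] - gray[-h, -1, drop = FALSE]))
  }
  e / 255
}

#' Extractor contract for the reference extractor
#'
#' @return A list with `id`, `dim` and `fn`, the shape every extractor
#'   (including pretrained-model adapters) must follow.
#' @export
make_reference_extractor <- function() {
  list(id = "reference_v1", dim = 34L, fn = reference_extractor)
}

#' Extract features for a list of patches
#'
#' Applies an extractor conforming to the contract to each patch and collects
#' the rows, aligned with the input order, into a [feature_matrix].
#'
#' @param patches List of patch records (`id`, `image`, `label`) or a
#'   `synthetic_patch_set`.
#' @param extractor Extractor contract (default [make_reference_extractor()]).
#' @return A [feature_matrix] with one row per patch.
#' @export
extract_features <- function(patches, extractor = make_reference_extractor()) {
  if (inherits(patches, "synthetic_patch_set")) patches <- patches$patches
  if (!is.list(extractor) || !is.function(extractor$fn) ||
      is.null(extractor$dim) || is.null(extractor$id)) {
    abort_mp("`extractor` must be a list with fields id, dim, fn",
             "mp_invalid_argument")
  }
  d <- check_count(extractor$dim, "extractor$dim")
  ids <- vapply(patches, function(p) p$id, character(1))
  values <- matrix(NA_real_, length(patches), d)
  for (i in seq_along(patches)) {
    v <- extractor$fn(patches[[i]]$image)
    if (length(v) != d) {
      abort_mp(sprintf(
        "extractor '%s' returned %d values (expected %d) for patch id '%s'",
        extractor$id, length(v), d, ids[i]), "mp_extraction_error")
    }
    if (!all(is.finite(v))) {
      abort_mp(sprintf("extractor '%s' returned non-finite values for patch id '%s'",
                       extractor$id, ids[i]), "mp_extraction_error")
    }
    values[i, ] <- v
  }
  feature_matrix(ids, values, extractor_id = extractor$id)
}

#' Write / read a feature matrix as a delimited table
#'
#' Single-file dialect: a CSV with an `id` column followed by the D feature
#' columns (`f1`..`fD`); `extractor_id` is kept in a `# extractor:` comment
#' on the first line.
#'
#' @param x A [feature_matrix].
#' @param path Output CSV path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns a [feature_matrix].
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# extractor: %s", x$extractor_id), con)
  df <- data.frame(id = x$ids, x$values, check.names = FALSE)
  colnames(df) <- c("id", sprintf("f%d", seq_len(ncol(x$values))))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  first <- readLines(path, n = 1L)
  extractor_id <- if (startsWith(first, "# extractor:")) {
    trimws(sub("^# extractor:", "", first))
  } else "unknown"
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  feature_matrix(df$id, as.matrix(df[, -1, drop = FALSE]),
                 extractor_id = extractor_id)
}

#' Construct a labeled sample pool
#'
#' A pool couples ids, binary labels and feature rows; the augmentation
#' benchmark draws its training sets from pools.
#'
#' @param ids Character vector.
#' @param labels Integer 0/1 vector.
#' @param features Numeric matrix with one row per id.
#' @return Object of class `sample_pool`.
#' @export
sample_pool <- function(ids, labels, features) {
  ids <- as.character(ids)
  labels <- as.integer(labels)
  features <- as.matrix(features)
  if (length(ids) != length(labels) || nrow(features) != length(ids)) {
    abort_mp("ids, labels and feature rows must have equal length",
             "mp_invalid_argument")
  }
  if (!all(labels %in% c(0L, 1L))) {
    abort_mp("pool labels must be 0 or 1", "mp_invalid_argument")
  }
  rownames(features) <- ids
  structure(list(ids = ids, labels = labels, features = features),
            class = "sample_pool")
}

#' @export
print.sample_pool <- function(x, ...) {
  cat(sprintf("<sample_pool> %d samples (%d positive), %d features\n",
              length(x$ids), sum(x$labels), ncol(x$features)))
  invisible(x)
}
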