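# Patch dataset I/O: PNG/TIFF patches with a `train_labels.csv`-style label
# table (columns id,label), the foreground filter, and the JSON-Lines caption
# manifest handed to text-to-image fine-tuning stacks.

#' Construct a patch record
#'
#' @param id Unique patch identifier.
#' @param image H x W x 3 integer array, 8-bit values in 0-255.
#' @param label Binary label: 0 = healthy, 1 = cancer.
#' @return Object of class `patch_record`.
#' @export
patch_record <- function(id, image, label) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort_mp(sprintf("patch '%s': image must be H x W x 3", id),
             "mp_invalid_argument")
  }
  label <- as.integer(label)
  if (length(label) != 1L || !label %in% c(0L, 1L)) {
    abort_mp(sprintf("patch '%s': label must be 0 or 1", id), "mp_load_error")
  }
  structure(list(id = as.character(id), image = image, label = label),
            class = "patch_record")
}

read_patch_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort_mp("the 'tiff' package is required to read TIFF patches",
                 "mp_load_error")
      }
      tiff::readTIFF(path)
    },
    abort_mp(sprintf("unsupported image format '%s' (%s)", ext, path),
             "mp_load_error")
  )
  if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 1L))
  if (dim(raw)[3] >= 3L) raw <- raw[, , 1:3, drop = FALSE]
  else raw <- array(raw[, , 1], dim = c(dim(raw)[1:2], 3L))  # gray -> RGB
  img <- round(raw * 255)
  storage.mode(img) <- "integer"
  img
}

#' Load a patch dataset from an image directory and a label table
#'
#' The on-disk layout mirrors the common patch-classification benchmark
#' layout: a directory of per-patch image files named `<id>.png` (or
#' `.tif`/`.tiff`) plus a CSV label table with header `id,label`.
#'
#' @param image_dir Directory containing one image file per id.
#' @param label_table Path to the CSV with columns `id` and `label`.
#' @return List of [patch_record]s ordered lexicographically by id.
#' @export
load_dataset <- function(image_dir, label_table) {
  df <- read.csv(label_table, colClasses = c("character", "integer"))
  if (!all(c("id", "label") %in% names(df))) {
    abort_mp("label table must have columns 'id' and 'label'", "mp_load_error")
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    abort_mp(sprintf("duplicate id in label table: '%s'", dup[1]),
             "mp_load_error")
  }
  bad <- df$id[!df$label %in% c(0L, 1L)]
  if (length(bad)) {
    abort_mp(sprintf("non-binary label for id '%s'", bad[1]), "mp_load_error")
  }
  df <- df[order_lex(df$id), , drop = FALSE]

  lapply(seq_len(nrow(df)), function(i) {
    id <- df$id[i]
    candidates <- file.path(image_dir, paste0(id, c(".png", ".tif", ".tiff")))
    path <- candidates[file.exists(candidates)]
    if (length(path) == 0L) {
      abort_mp(sprintf("no image file found for id '%s' in %s", id, image_dir),
               "mp_load_error")
    }
    patch_record(id, read_patch_image(path[1]), df$label[i])
  })
}

#' Write a patch dataset to disk
#'
#' Writes `images/<id>.png` per patch plus `train_labels.csv` (`id,label`).
#' For a `synthetic_patch_set`, a ground-truth sidecar `morphology.csv`
#' (`id,morphology`) is written as well.
#'
#' @param x A `synthetic_patch_set` or list of [patch_record]s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patch_dataset <- function(x, dir) {
  morph <- NULL
  if (inherits(x, "synthetic_patch_set")) {
    morph <- x$true_morphology
    x <- x$patches
  }
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(x, function(p) p$id, character(1))
  for (p in x) {
    png::writePNG(array(p$image / 255, dim = dim(p$image)),
                  file.path(img_dir, paste0(p$id, ".png")))
  }
  labels <- vapply(x, function(p) p$label, integer(1))
  write.csv(data.frame(id = ids, label = labels),
            file.path(dir, "train_labels.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(morph)) {
    write.csv(data.frame(id = ids, morphology = morph),
              file.path(dir, "morphology.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Foreground filter for tissue patches
#'
#' Flags a patch as foreground when at least `min_tissue_fraction` of its
#' pixels are "tissue" pixels, i.e. have `min(R, G, B) < white_threshold`.
#' Near-white pixels (glass background) fail that test. This simple
#' min-channel whiteness rule is the package's documented foreground
#' criterion; both parameters are exposed.
#'
#' @param image H x W x 3 integer array (0-255).
#' @param white_threshold 8-bit level below which a pixel's darkest channel
#'   must fall to count as tissue (default 220).
#' @param min_tissue_fraction Minimum tissue-pixel fraction (default 0.10).
#' @return `TRUE` if the patch passes the filter.
#' @export
is_foreground <- function(image, white_threshold = 220,
                          min_tissue_fraction = 0.10) {
  if (length(image) == 0L) abort_mp("empty image", "mp_invalid_argument")
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort_mp("image must be H x W x 3", "mp_invalid_argument")
  }
  white_threshold <- check_scalar(white_threshold, "white_threshold",
                                  positive = TRUE)
  if (white_threshold > 255) {
    abort_mp("`white_threshold` must be <= 255", "mp_invalid_argument")
  }
  min_tissue_fraction <- check_fraction(min_tissue_fraction,
                                        "min_tissue_fraction")
  min_chan <- pmin(image[, , 1], image[, , 2], image[, , 3])
  mean(min_chan < white_threshold) >= min_tissue_fraction
}

#' Filter a patch list to foreground patches
#'
#' @param patches List of [patch_record]s.
#' @inheritParams is_foreground
#' @return The sub-list of patches passing [is_foreground()].
#' @export
filter_foreground <- function(patches, white_threshold = 220,
                              min_tissue_fraction = 0.10) {
  keep <- vapply(patches, function(p) {
    is_foreground(p$image, white_threshold, min_tissue_fraction)
  }, logical(1))
  patches[keep]
}

#' Write a caption manifest (JSON Lines)
#'
#' One UTF-8 JSON object per line with keys `file_name`, `text`, `label` and,
#' for morphology-enriched prompts, `cluster`; the key is omitted entirely
#' for baseline captions. Lines are ordered lexicographically by id, so the
#' file is bit-stable across runs.
#'
#' @param prompts Prompt table as returned by [build_prompts()] (columns
#'   `id`, `label`, `cluster`, `caption`, `strategy`).
#' @param out Output file path.
#' @param image_ext File extension used to derive `file_name` from `id`.
#' @return Invisibly, the manifest as a data frame.
#' @export
write_manifest <- function(prompts, out, image_ext = ".png") {
  prompts <- validate_prompts(prompts)
  prompts <- prompts[order_lex(prompts$id), , drop = FALSE]
  file_names <- sprintf("%s%s", prompts$id, image_ext)  # length 0 stays 0
  lines <- vapply(seq_len(nrow(prompts)), function(i) {
    entry <- list(
      file_name = file_names[i],
      text = prompts$caption[i],
      label = prompts$label[i]
    )
    if (!is.na(prompts$cluster[i])) entry$cluster <- prompts$cluster[i]
    jsonlite::toJSON(entry, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, out, useBytes = TRUE)
  invisible(data.frame(
    file_name = file_names,
    text = prompts$caption,
    label = prompts$label,
    cluster = prompts$cluster,
    stringsAsFactors = FALSE
  ))
}

#' Read a caption manifest written by [write_manifest()]
#'
#' @param path Manifest path (JSON Lines).
#' @return Data frame with columns `file_name`, `text`, `label`, `cluster`
#'   (NA where the key is absent).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) {
    return(data.frame(file_name = character(), text = character(),
                      label = integer(), cluster = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
  data.frame(
    file_name = vapply(rows, `[[`, character(1), "file_name"),
    text = vapply(rows, `[[`, character(1), "text"),
    label = vapply(rows, function(r) as.integer(r$label), integer(1)),
    cluster = vapply(rows, function(r) {
      if (is.null(r$cluster)) NA_integer_ else as.integer(r$cluster)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
}
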