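# Synthetic fixture generators: stain-like image patches with known latent
# morphology types, Gaussian-mixture feature sets, and labeled feature pools
# for the augmentation benchmark. Everything is deterministic given one seed.

# Stain-inspired base palette (RGB, 0-255). Entries are >= 2 histogram bins
# apart in at least one channel so that distinct recipes stay separable under
# the reference extractor's 8-bin histograms.
stain_palette <- function() {
  matrix(c(
    230, 150, 180,   # light pink (eosin)
    120,  60, 160,   # deep purple (hematoxylin)
    190, 100, 210,   # orchid
     90, 110, 200,   # blue-violet
    240, 200, 220,   # pale pink
    160,  40,  90,   # dark magenta
    200, 160, 240,   # lavender
     60,  30, 100,   # dark purple
    250, 120, 140,   # salmon
    140, 140, 220,   # periwinkle
    210,  70, 160,   # fuchsia
    100,  80,  60    # brown (pigment-like)
  ), ncol = 3, byrow = TRUE)
}

#' Generate a synthetic patch dataset with known morphology structure
#'
#' Produces stain-like RGB patches in which each latent morphology type has a
#' distinct procedural recipe: a base hue drawn from a stain palette, a blob
#' (nucleus-like) density, a blob radius distribution, and a texture grain
#' level. Recipes are designed so that morphology types are separable in any
#' reasonable color/texture feature space (guaranteed for up to 12 types,
#' the palette size). Binary labels are assigned as a seeded random subset of
#' size `round(n * cancer_fraction)`, mirroring loose patch-level annotation.
#'
#' @param n Number of patches.
#' @param n_morphologies Number of latent morphology types (recipes).
#' @param cancer_fraction Requested fraction of patches labeled 1 (cancer).
#'   The realized fraction is within `1/n` of the request.
#' @param image_size Patch side length in pixels (patches are square).
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @return An object of class `synthetic_patch_set`: list with `patches`
#'   (list of `patch_record`: `id`, `image` (H x W x 3 integer array, 0-255),
#'   `label`), `true_morphology` (0-based integer vector), `true_label`
#'   (0/1 integer vector) and `seed`.
#' @examples
#' ps <- make_patch_dataset(12, n_morphologies = 3, cancer_fraction = 0.5,
#'                          image_size = 32, seed = 1)
#' table(ps$true_label)
#' @export
make_patch_dataset <- function(n, n_morphologies, cancer_fraction,
                               image_size = 96, seed = 1) {
  n <- check_count(n, "n")
  n_morphologies <- check_count(n_morphologies, "n_morphologies")
  image_size <- check_count(image_size, "image_size")
  cancer_fraction <- check_fraction(cancer_fraction, "cancer_fraction")
  if (n < n_morphologies) {
    abort_mp("`n` must be >= `n_morphologies`", "mp_invalid_argument")
  }

  with_seed(seed, {
    pal <- stain_palette()
    m_idx <- ((seq_len(n_morphologies) - 1L) %% nrow(pal)) + 1L
    recipes <- lapply(seq_len(n_morphologies), function(m) {
      list(
        base       = pal[m_idx[m], ] +
          if (m > nrow(pal)) round(runif(3, -12, 12)) else c(0, 0, 0),
        blob_color = pmax(0, pal[m_idx[m], ] * 0.35 + c(20, 0, 40) +
                            round(runif(3, -10, 10))),
        density    = runif(1, 6, 26),          # expected blobs per patch
        radius     = runif(1, 0.02, 0.07) * image_size,
        grain_sd   = runif(1, 3, 10)
      )
    })

    # round-robin morphology assignment, then shuffled
    morph <- sample(rep_len(seq_len(n_morphologies), n)) - 1L
    n_pos <- round(n * cancer_fraction)
    labels <- integer(n)
    labels[sample.int(n, n_pos)] <- 1L

    ids <- sprintf("syn_%06d", seq_len(n) - 1L)
    rows <- matrix(seq_len(image_size), image_size, image_size)
    cols <- t(rows)

    patches <- vector("list", n)
    for (i in seq_len(n)) {
      rc <- recipes[[morph[i] + 1L]]
      img <- array(0, dim = c(image_size, image_size, 3))
      for (ch in 1:3) {
        img[, , ch] <- rc$base[ch] + rnorm(image_size^2, sd = rc$grain_sd)
      }
      n_blobs <- rpois(1, rc$density)
      if (n_blobs > 0) {
        cy <- runif(n_blobs, 1, image_size)
        cx <- runif(n_blobs, 1, image_size)
        rad <- pmax(1, rnorm(n_blobs, mean = rc$radius, sd = rc$radius / 4))
        for (b in seq_len(n_blobs)) {
          mask <- (rows - cy[b])^2 + (cols - cx[b])^2 <= rad[b]^2
          for (ch in 1:3) {
            plane <- img[, , ch]
            plane[mask] <- rc$blob_color[ch] + rnorm(sum(mask), sd = 4)
            img[, , ch] <- plane
          }
        }
      }
      img <- round(pmin(pmax(img, 0), 255))
      storage.mode(img) <- "integer"
      patches[[i]] <- patch_record(ids[i], img, labels[i])
    }

    structure(
      list(patches = patches, true_morphology = morph,
           true_label = labels, seed = seed),
      class = "synthetic_patch_set"
    )
  })
}

#' @export
print.synthetic_patch_set <- function(x, ...) {
  d <- dim(x$patches[[1]]$image)
  cat(sprintf(
    "<synthetic_patch_set> %d patches (%dx%d px), %d morphology types, %d labeled cancer\n",
    length(x$patches), d[1], d[2], length(unique(x$true_morphology)),
    sum(x$true_label)))
  invisible(x)
}

#' Generate an isotropic Gaussian mixture feature sample
#'
#' Surrogate for a deep-feature space with known cluster structure: `k`
#' component centers placed with mutual distance at least
#' `separation * within_sd`, and `n_per_component` rows drawn from an
#' isotropic normal around each center. Row order is shuffled
#' deterministically by the seed.
#'
#' @param k Number of mixture components.
#' @param d Feature dimension.
#' @param n_per_component Rows drawn per component.
#' @param separation Minimum inter-center distance in units of `within_sd`.
#' @param within_sd Within-component standard deviation (default 1).
#' @param seed Integer seed.
#' @return An object of class `mixture_sample`: list with `features`
#'   (a [feature_matrix]), `true_component` (0-based integers), `centers`
#'   (k x d matrix), `within_sd`, `seed`.
#' @examples
#' mx <- make_feature_mixture(k = 3, d = 5, n_per_component = 10,
#'                            separation = 12, seed = 2)
#' dim(mx$features$values)
#' @export
make_feature_mixture <- function(k, d, n_per_component, separation,
                                 within_sd = 1, seed = 1) {
  k <- check_count(k, "k")
  d <- check_count(d, "d")
  n_per_component <- check_count(n_per_component, "n_per_component", min = 2L)
  separation <- check_scalar(separation, "separation", positive = TRUE)
  within_sd <- check_scalar(within_sd, "within_sd", positive = TRUE)

  with_seed(seed, {
    min_dist <- separation * within_sd
    # Scale the center cloud so typical pairwise distances comfortably exceed
    # the requirement; reject-and-retry with a bounded budget.
    scale <- min_dist * max(1, 3 / sqrt(d))
    centers <- NULL
    for (attempt in 1:200) {
      cand <- matrix(rnorm(k * d, sd = scale), k, d)
      if (k == 1L || min(dist(cand)) >= min_dist) {
        centers <- cand
        break
      }
    }
    if (is.null(centers)) {
      abort_mp(
        sprintf("could not place %d centers at mutual distance >= %.3g in %d dims",
                k, min_dist, d), "mp_generation_error")
    }

    n <- k * n_per_component
    comp <- rep(seq_len(k), each = n_per_component)
    x <- centers[comp, , drop = FALSE] +
      matrix(rnorm(n * d, sd = within_sd), n, d)
    perm <- sample.int(n)
    x <- x[perm, , drop = FALSE]
    comp <- comp[perm] - 1L
    ids <- sprintf("mix_%06d", seq_len(n) - 1L)

    structure(
      list(features = feature_matrix(ids, x, extractor_id = "gaussian_mixture"),
           true_component = comp, centers = centers,
           within_sd = within_sd, seed = seed),
      class = "mixture_sample"
    )
  })
}

#' Generate labeled feature pools for the augmentation benchmark
#'
#' Builds four pools of class-labeled feature vectors (real training pool,
#' synthetic pool, validation set, test set) from two Gaussian class
#' distributions whose means differ by `class_sep` along the first
#' `min(4, d)` dimensions. The synthetic pool is drawn from a mildly
#' perturbed version of the class distributions (means shrunk by
#' `syn_shrink`, standard deviation inflated) to emulate a generative model
#' that approximates, but does not equal, the real distribution.
#'
#' @param n_real,n_syn,n_val,n_test Pool sizes (split evenly across classes).
#' @param d Feature dimension.
#' @param class_sep Euclidean distance between the class means.
#' @param syn_shrink Multiplier applied to the synthetic class means.
#' @param seed Integer seed.
#' @return List with elements `real`, `syn`, `val`, `test`, each a
#'   [sample_pool].
#' @export
make_benchmark_pools <- function(n_real, n_syn, n_val = 1000, n_test = 2000,
                                 d = 8, class_sep = 1.5, syn_shrink = 0.9,
                                 seed = 1) {
  n_real <- check_count(n_real, "n_real", min = 2L)
  n_syn <- check_count(n_syn, "n_syn", min = 2L)
  n_val <- check_count(n_val, "n_val", min = 2L)
  n_test <- check_count(n_test, "n_test", min = 2L)
  d <- check_count(d, "d")
  class_sep <- check_scalar(class_sep, "class_sep", positive = TRUE)

  u <- rep(0, d)
  k <- min(4L, d)
  u[seq_len(k)] <- 1 / sqrt(k)
  mu1 <- u * class_sep / 2
  mu0 <- -mu1

  draw <- function(n, prefix, shrink = 1, sd = 1) {
    n0 <- n %/% 2L
    labels <- c(rep(0L, n0), rep(1L, n - n0))
    mu <- rbind(mu0, mu1)[labels + 1L, , drop = FALSE] * shrink
    x <- mu + matrix(rnorm(n * d, sd = sd), n, d)
    perm <- sample.int(n)
    sample_pool(sprintf("%s_%06d", prefix, seq_len(n) - 1L),
                labels[perm], x[perm, , drop = FALSE])
  }

  with_seed(seed, list(
    real = draw(n_real, "real"),
    syn  = draw(n_syn, "synth", shrink = syn_shrink, sd = 1.05),
    val  = draw(n_val, "val"),
    test = draw(n_test, "test")
  ))
}
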