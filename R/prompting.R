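# Caption construction. The baseline caption encodes only the binary class
# label; the morphology-enriched (MEP) caption appends the k-means cluster
# index as a "morphology type" token, e.g.
#   "Histology image of healthy tissue, morphology type five".

label_word <- function(label) {
  if (any(!label %in% c(0, 1)) || anyNA(label)) {
    abort_mp("label must be 0 (healthy) or 1 (cancer)", "mp_invalid_argument")
  }
  c("healthy", "cancer")[as.integer(label) + 1L]
}

# Lower-case English words for 0..99 ("five", "twenty-one").
number_word <- function(n) {
  ones <- c("zero", "one", "two", "three", "four", "five", "six", "seven",
            "eight", "nine", "ten", "eleven", "twelve", "thirteen",
            "fourteen", "fifteen", "sixteen", "seventeen", "eighteen",
            "nineteen")
  tens <- c("twenty", "thirty", "forty", "fifty", "sixty", "seventy",
            "eighty", "ninety")
  vapply(as.integer(n), function(x) {
    if (is.na(x) || x < 0 || x > 99) {
      abort_mp("word rendering is defined for cluster indices 0-99",
               "mp_invalid_argument")
    }
    if (x < 20L) return(ones[x + 1L])
    t <- tens[x %/% 10L - 1L]
    if (x %% 10L == 0L) t else paste0(t, "-", ones[x %% 10L + 1L])
  }, character(1))
}

#' Build a baseline (class-only) caption
#'
#' @param label Binary label vector (0 = healthy, 1 = cancer).
#' @return Character vector: `"Histology image of healthy tissue"` or
#'   `"Histology image of cancer tissue"`.
#' @examples
#' build_baseline_prompt(c(0, 1))
#' @export
build_baseline_prompt <- function(label) {
  sprintf("Histology image of %s tissue", label_word(label))
}

#' Build a morphology-enriched caption
#'
#' Appends the morphology cluster index to the baseline caption. The index
#' can be rendered as a lower-case English word (`"five"`, defined for
#' 0-99) or as decimal digits (`"12"`).
#'
#' @param label Binary label vector.
#' @param cluster Non-negative cluster index vector (0-based).
#' @param rendering `"word"` (default) or `"numeral"`.
#' @return Character vector of captions.
#' @examples
#' build_mep_prompt(0, 5)                          # "... morphology type five"
#' build_mep_prompt(1, 12, rendering = "numeral")  # "... morphology type 12"
#' @export
build_mep_prompt <- function(label, cluster, rendering = c("word", "numeral")) {
  rendering <- match.arg(rendering)
  cluster <- as.integer(cluster)
  if (anyNA(cluster) || any(cluster < 0L)) {
    abort_mp("cluster index must be a non-negative integer",
             "mp_invalid_argument")
  }
  idx <- switch(rendering,
    word = number_word(cluster),
    numeral = as.character(cluster)
  )
  sprintf("Histology image of %s tissue, morphology type %s",
          label_word(label), idx)
}

#' Build a prompt table for a dataset
#'
#' @param ids Character vector of patch ids.
#' @param labels Binary label vector aligned with `ids`.
#' @param clusters 0-based cluster assignment aligned with `ids`; required
#'   for `strategy = "mep"`, ignored for `"baseline"`.
#' @param strategy `"mep"` or `"baseline"`.
#' @param rendering Index rendering for MEP captions, see
#'   [build_mep_prompt()].
#' @return Data frame with columns `id`, `label`, `cluster` (NA for
#'   baseline), `caption`, `strategy`.
#' @export
build_prompts <- function(ids, labels, clusters = NULL,
                          strategy = c("mep", "baseline"),
                          rendering = c("word", "numeral")) {
  strategy <- match.arg(strategy)
  rendering <- match.arg(rendering)
  ids <- as.character(ids)
  labels <- as.integer(labels)
  if (length(labels) != length(ids)) {
    abort_mp("`labels` must align with `ids`", "mp_invalid_argument")
  }
  if (strategy == "mep") {
    if (is.null(clusters) || length(clusters) != length(ids)) {
      abort_mp("MEP prompts require a cluster index per id",
               "mp_invalid_argument")
    }
    clusters <- as.integer(clusters)
    caption <- build_mep_prompt(labels, clusters, rendering)
  } else {
    clusters <- rep(NA_integer_, length(ids))
    caption <- build_baseline_prompt(labels)
  }
  data.frame(id = ids, label = labels, cluster = clusters,
             caption = caption, strategy = rep_len(strategy, length(ids)),
             stringsAsFactors = FALSE)
}

validate_prompts <- function(prompts) {
  need <- c("id", "label", "cluster", "caption", "strategy")
  if (!is.data.frame(prompts) || !all(need %in% names(prompts))) {
    abort_mp(sprintf("prompt table must have columns %s",
                     paste(need, collapse = ", ")), "mp_invalid_argument")
  }
  if (anyDuplicated(prompts$id)) {
    abort_mp(sprintf("duplicate prompt id '%s'",
                     prompts$id[anyDuplicated(prompts$id)]),
             "mp_invalid_argument")
  }
  prompts
}

#' Strip morphology information from MEP prompts
#'
#' Rewrites morphology-enriched captions as baseline captions (same ids and
#' labels, cluster dropped), producing the label-only copy of a captioned
#' dataset used to compare the two prompt-building strategies on identical
#' images.
#'
#' @param prompts Prompt table with `strategy == "mep"` throughout.
#' @return Prompt table with `strategy = "baseline"`, order preserved.
#' @export
strip_morphology <- function(prompts) {
  prompts <- validate_prompts(prompts)
  if (nrow(prompts) == 0L) return(prompts)
  if (any(prompts$strategy != "mep")) {
    abort_mp("strip_morphology expects MEP prompts only",
             "mp_invalid_argument")
  }
  data.frame(id = prompts$id, label = prompts$label,
             cluster = NA_integer_,
             caption = build_baseline_prompt(prompts$label),
             strategy = "baseline", stringsAsFactors = FALSE)
}
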