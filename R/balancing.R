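# Dataset balancing: keep the most-populated prompts per class, undersample
# to a near-uniform prompt distribution, and split into train/validation
# sets that both preserve the +/-1 per-prompt uniformity.

caption_class <- function(prompts) {
  # class of a caption group = the (unique) label of its members
  cls <- tapply(prompts$label, prompts$caption, function(l) {
    u <- unique(l)
    if (length(u) != 1L) {
      abort_mp("a caption group mixes labels; captions must determine the class",
               "mp_invalid_argument")
    }
    u
  })
  data.frame(caption = names(cls), class = as.integer(cls),
             stringsAsFactors = FALSE)
}

# Deterministic priority order over caption groups used for every remainder
# (+1) assignment: alternate classes (starting from the smallest label),
# lexicographic caption order within each class. Using one fixed order for
# both the undersample quotas and the validation quotas keeps the train-side
# per-prompt counts within +/-1 as well.
priority_order <- function(captions, classes) {
  classes <- as.integer(classes)
  by_class <- split(captions, classes)
  by_class <- lapply(by_class, sort_lex)
  n_class <- length(by_class)
  maxlen <- max(lengths(by_class))
  out <- character(0)
  for (i in seq_len(maxlen)) {
    for (cl in seq_len(n_class)) {
      grp <- by_class[[cl]]
      if (i <= length(grp)) out <- c(out, grp[i])
    }
  }
  out
}

#' Select the most-populated prompts per class
#'
#' Returns the `per_class` most frequent captions within each class label,
#' breaking count ties by lexicographic caption order; the result is sorted
#' by (class, caption).
#'
#' @param prompts Prompt table (see [build_prompts()]).
#' @param per_class Number of captions to keep per class (e.g. 21, giving
#'   42 captions over two classes).
#' @return Character vector of selected captions.
#' @export
select_top_prompts <- function(prompts, per_class) {
  prompts <- validate_prompts(prompts)
  per_class <- check_count(per_class, "per_class")
  out <- character(0)
  for (cl in sort(unique(prompts$label))) {
    sub <- prompts[prompts$label == cl, , drop = FALSE]
    counts <- table(sub$caption)
    if (length(counts) < per_class) {
      abort_mp(sprintf(
        "class %d has only %d non-empty prompt groups (need %d)",
        cl, length(counts), per_class), "mp_invalid_argument")
    }
    caps <- names(counts)
    ord <- order_lex_by_count(caps, as.integer(counts))
    out <- c(out, sort_lex(caps[ord][seq_len(per_class)]))
  }
  out
}

# order captions by descending count, ties by C-locale caption order
order_lex_by_count <- function(caps, counts) {
  lex_rank <- match(caps, sort_lex(caps))
  order(-counts, lex_rank)
}

# floor/remainder quotas over groups in priority order
group_quotas <- function(captions, classes, total) {
  g <- length(captions)
  base <- total %/% g
  r <- total %% g
  prio <- priority_order(captions, classes)
  quota <- rep(base, g)
  names(quota) <- prio
  if (r > 0) quota[seq_len(r)] <- base + 1L
  quota[captions]  # back to caller's order
}

#' Undersample selected prompt groups to a near-uniform subset
#'
#' Draws `total` examples across the `selected` caption groups with
#' per-group quotas of `floor(total/G)` plus one for the first
#' `total mod G` groups in the fixed priority order (classes alternating,
#' lexicographic captions within class). Members are sampled without
#' replacement under the seed.
#'
#' @param prompts Prompt table.
#' @param selected Captions to keep (e.g. from [select_top_prompts()]).
#' @param total Exact output size (e.g. 51000).
#' @param seed Integer seed.
#' @return Character vector of exactly `total` selected ids.
#' @export
undersample_uniform <- function(prompts, selected, total, seed = 1) {
  prompts <- validate_prompts(prompts)
  total <- check_count(total, "total")
  selected <- as.character(selected)
  if (length(selected) == 0L || total < length(selected)) {
    abort_mp("`total` must be at least the number of selected groups",
             "mp_invalid_argument")
  }
  sub <- prompts[prompts$caption %in% selected, , drop = FALSE]
  cls <- caption_class(sub)
  missing <- setdiff(selected, cls$caption)
  if (length(missing)) {
    abort_mp(sprintf("selected caption has no members: '%s'", missing[1]),
             "mp_invalid_argument")
  }
  quota <- group_quotas(cls$caption, cls$class, total)

  sizes <- table(sub$caption)[cls$caption]
  deficient <- cls$caption[as.integer(sizes) < quota]
  if (length(deficient)) {
    abort_mp(sprintf(
      "caption group '%s' has %d members, fewer than its quota %d",
      deficient[1], as.integer(sizes[deficient[1]]),
      quota[deficient[1]]), "mp_invalid_argument")
  }

  prio <- priority_order(cls$caption, cls$class)
  with_seed(seed, {
    unlist(lapply(prio, function(cap) {
      pool <- sort_lex(sub$id[sub$caption == cap])
      pool[sample.int(length(pool), quota[cap])]
    }), use.names = FALSE)
  })
}

#' Split a balanced id set into train and validation sets
#'
#' Computes per-prompt validation quotas with the same floor/remainder rule
#' (applied to `val_size`) and the same priority order as
#' [undersample_uniform()], samples the validation members without
#' replacement under the seed, and assigns the rest to training. Both sides
#' keep per-prompt counts within +/-1 of uniform.
#'
#' @param ids Ids to split (typically the undersampled subset).
#' @param prompts Prompt table covering `ids`.
#' @param train_size,val_size Exact output sizes;
#'   `train_size + val_size` must equal `length(ids)`.
#' @param seed Integer seed.
#' @return Object of class `balanced_split`: `train_ids`, `val_ids`,
#'   `per_prompt_counts` (data frame caption/class/train/val), `seed`.
#' @export
split_balanced <- function(ids, prompts, train_size, val_size, seed = 1) {
  prompts <- validate_prompts(prompts)
  train_size <- check_count(train_size, "train_size", min = 0L)
  val_size <- check_count(val_size, "val_size", min = 0L)
  if (train_size + val_size != length(ids)) {
    abort_mp("train_size + val_size must equal length(ids)",
             "mp_invalid_argument")
  }
  sub <- prompts[match(ids, prompts$id), , drop = FALSE]
  if (anyNA(sub$id)) {
    abort_mp(sprintf("id not found in prompt table: '%s'",
                     ids[which(is.na(sub$id))[1]]), "mp_invalid_argument")
  }
  cls <- caption_class(sub)

  if (val_size == 0L) {
    val_quota <- stats::setNames(rep(0L, nrow(cls)), cls$caption)
  } else {
    val_quota <- group_quotas(cls$caption, cls$class, val_size)
  }
  sizes <- table(sub$caption)[cls$caption]
  if (any(as.integer(sizes) < val_quota)) {
    bad <- cls$caption[which(as.integer(sizes) < val_quota)[1]]
    abort_mp(sprintf("group '%s' too small for its validation quota", bad),
             "mp_invalid_argument")
  }

  prio <- priority_order(cls$caption, cls$class)
  val_ids <- with_seed(seed, {
    unlist(lapply(prio, function(cap) {
      pool <- sort_lex(sub$id[sub$caption == cap])
      if (val_quota[cap] == 0L) return(character(0))
      pool[sample.int(length(pool), val_quota[cap])]
    }), use.names = FALSE)
  })
  train_ids <- setdiff(ids, val_ids)

  counts <- data.frame(
    caption = cls$caption,
    class = cls$class,
    train = as.integer(table(factor(sub$caption[sub$id %in% train_ids],
                                    levels = cls$caption))),
    val = as.integer(table(factor(sub$caption[sub$id %in% val_ids],
                                  levels = cls$caption))),
    stringsAsFactors = FALSE
  )
  structure(
    list(train_ids = train_ids, val_ids = val_ids,
         per_prompt_counts = counts, seed = seed),
    class = "balanced_split"
  )
}

#' @export
print.balanced_split <- function(x, ...) {
  cat(sprintf("<balanced_split> %d train / %d val over %d prompt groups\n",
              length(x$train_ids), length(x$val_ids),
              nrow(x$per_prompt_counts)))
  invisible(x)
}

#' Serialize a balanced split
#'
#' Writes `train_ids.csv`, `val_ids.csv` and `counts.json` under `dir`.
#'
#' @param x A `balanced_split`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_split <- function(x, dir) {
  stopifnot(inherits(x, "balanced_split"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(id = x$train_ids), file.path(dir, "train_ids.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(id = x$val_ids), file.path(dir, "val_ids.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(x$per_prompt_counts, file.path(dir, "counts.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
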