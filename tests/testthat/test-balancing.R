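# Prompt-group selection, uniform undersampling, balanced splitting.

# fixture: prompt table with the given per-(class, cluster) group sizes
prompt_fixture <- function(sizes_by_class) {
  rows <- list()
  counter <- 0L
  for (cl in seq_along(sizes_by_class) - 1L) {
    sizes <- sizes_by_class[[cl + 1L]]
    for (m in seq_along(sizes) - 1L) {
      n <- sizes[m + 1L]
      ids <- sprintf("p%07d", counter + seq_len(n))
      counter <- counter + n
      rows[[length(rows) + 1L]] <-
        data.frame(id = ids, label = cl, cluster = m)
    }
  }
  df <- do.call(rbind, rows)
  build_prompts(df$id, df$label, df$cluster, strategy = "mep")
}

test_that("top-prompt selection keeps the most populated groups per class", {
  prompts <- prompt_fixture(list(c(30, 10, 50), c(5, 40, 20)))
  one <- select_top_prompts(prompts, 1)
  expect_length(one, 2)
  modal0 <- names(which.max(table(prompts$caption[prompts$label == 0])))
  modal1 <- names(which.max(table(prompts$caption[prompts$label == 1])))
  expect_setequal(one, c(modal0, modal1))

  two <- select_top_prompts(prompts, 2)
  expect_length(two, 4)
  expect_error(select_top_prompts(prompts, 4), regexp = "3",
               class = "mp_invalid_argument")
})

test_that("count ties at the selection boundary break lexicographically", {
  # clusters 1 and 2 tie at rank 2 within class 0
  prompts <- prompt_fixture(list(c(30, 20, 20), c(30, 20, 10)))
  sel <- select_top_prompts(prompts, 2)
  tied <- sort(unique(prompts$caption[prompts$label == 0 &
                                        prompts$cluster %in% c(1, 2)]),
               method = "radix")
  expect_true(tied[1] %in% sel)
  expect_false(tied[2] %in% sel)
})

test_that("undersampling hits exact quotas with the remainder rule", {
  prompts <- prompt_fixture(list(c(10, 10, 10)))
  sel <- sort(unique(prompts$caption), method = "radix")
  ids <- undersample_uniform(prompts, sel, 9, seed = 1)
  expect_length(ids, 9)
  expect_true(all(table(prompts$caption[match(ids, prompts$id)]) == 3))
})

test_that("the +1 remainder goes to the priority-rule group", {
  # one group per class; remainder of 5 over 2 groups -> class 0 gets 3
  prompts <- prompt_fixture(list(10, 10))
  sel <- unique(prompts$caption)
  ids <- undersample_uniform(prompts, sel, 5, seed = 3)
  tab <- table(prompts$label[match(ids, prompts$id)])
  expect_equal(as.integer(tab[c("0", "1")]), c(3L, 2L))
})

test_that("infeasible quotas name the deficient group", {
  prompts <- prompt_fixture(list(c(10, 2)))
  sel <- sort(unique(prompts$caption), method = "radix")
  small <- unique(prompts$caption[prompts$cluster == 1])
  expect_error(undersample_uniform(prompts, sel, 12, seed = 1),
               regexp = small, fixed = TRUE, class = "mp_invalid_argument")
})

test_that("undersampling is seeded: membership varies, profile does not", {
  prompts <- prompt_fixture(list(c(40, 40), c(40, 40)))
  sel <- sort(unique(prompts$caption), method = "radix")
  a <- undersample_uniform(prompts, sel, 50, seed = 1)
  b <- undersample_uniform(prompts, sel, 50, seed = 2)
  a2 <- undersample_uniform(prompts, sel, 50, seed = 1)
  expect_identical(a, a2)
  expect_false(setequal(a, b))
  profile <- function(ids) sort(table(prompts$caption[match(ids, prompts$id)]))
  expect_equal(profile(a), profile(b))
})

test_that("balanced split preserves per-prompt uniformity on both sides", {
  prompts <- prompt_fixture(list(c(40, 40, 40), c(40, 40, 40)))
  sel <- sort(unique(prompts$caption), method = "radix")
  ids <- undersample_uniform(prompts, sel, 200, seed = 5)
  sp <- split_balanced(ids, prompts, 180, 20, seed = 6)
  expect_length(sp$train_ids, 180)
  expect_length(sp$val_ids, 20)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  expect_setequal(c(sp$train_ids, sp$val_ids), ids)
  counts <- sp$per_prompt_counts
  expect_lte(diff(range(counts$train)), 1)
  expect_lte(diff(range(counts$val)), 1)
})

test_that("a zero-size validation split returns everything as train", {
  prompts <- prompt_fixture(list(c(10, 10)))
  ids <- prompts$id
  sp <- split_balanced(ids, prompts, length(ids), 0, seed = 1)
  expect_length(sp$val_ids, 0)
  expect_setequal(sp$train_ids, ids)
})

test_that("split sizes must be conserved and seeds reproduce membership", {
  prompts <- prompt_fixture(list(c(20, 20), c(20, 20)))
  ids <- undersample_uniform(prompts, sort(unique(prompts$caption), method = "radix"),
                             60, seed = 2)
  expect_error(split_balanced(ids, prompts, 50, 20, seed = 1),
               class = "mp_invalid_argument")
  s1 <- split_balanced(ids, prompts, 48, 12, seed = 9)
  s2 <- split_balanced(ids, prompts, 48, 12, seed = 9)
  expect_identical(s1$val_ids, s2$val_ids)
  s3 <- split_balanced(ids, prompts, 48, 12, seed = 10)
  expect_false(setequal(s1$val_ids, s3$val_ids))
  expect_equal(s1$per_prompt_counts[c("train", "val")],
               s3$per_prompt_counts[c("train", "val")])
})

test_that("splits serialize to id lists plus a count profile", {
  prompts <- prompt_fixture(list(c(12, 12), c(12, 12)))
  ids <- undersample_uniform(prompts, sort(unique(prompts$caption), method = "radix"),
                             40, seed = 2)
  sp <- split_balanced(ids, prompts, 32, 8, seed = 3)
  dir <- withr::local_tempdir()
  write_split(sp, dir)
  expect_equal(read.csv(file.path(dir, "train_ids.csv"))$id, sp$train_ids)
  expect_equal(read.csv(file.path(dir, "val_ids.csv"))$id, sp$val_ids)
  counts <- jsonlite::fromJSON(file.path(dir, "counts.json"))
  expect_equal(counts$train, sp$per_prompt_counts$train)
})
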