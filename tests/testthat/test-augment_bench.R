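# Mixed real/synthetic benchmark: sampling, AUC, grid, summaries.

small_pools <- function(seed = 2) {
  make_benchmark_pools(n_real = 600, n_syn = 1200, n_val = 200, n_test = 400,
                       d = 6, seed = seed)
}

test_that("training sets mix real and synthetic at the requested ratio", {
  pools <- small_pools()
  tr <- sample_training_set(pools$real, pools$syn, 100, 200, seed = 1)
  expect_equal(sum(tr$provenance == "real"), 100)
  expect_equal(sum(tr$provenance == "synthetic"), 200)
  expect_length(tr$ids, 300)
  expect_equal(nrow(tr$features), 300)

  only_real <- sample_training_set(pools$real, pools$syn, 50, 0, seed = 1)
  expect_true(all(only_real$provenance == "real"))
})

test_that("odd counts stay class-balanced with the extra positive", {
  pools <- small_pools()
  tr <- sample_training_set(pools$real, pools$syn, 25, 300, seed = 3)
  expect_equal(sum(tr$provenance == "synthetic"), 75)
  real_lab <- tr$labels[tr$provenance == "real"]
  syn_lab <- tr$labels[tr$provenance == "synthetic"]
  expect_equal(as.integer(table(real_lab)[c("1", "0")]), c(13L, 12L))
  expect_equal(as.integer(table(syn_lab)[c("1", "0")]), c(38L, 37L))
})

test_that("drawing from an exhausted pool names the deficient side", {
  pools <- small_pools()
  expect_error(sample_training_set(pools$real, pools$syn, 1000, 0, seed = 1),
               regexp = "real", class = "mp_insufficient_pool")
  expect_error(sample_training_set(pools$real, pools$syn, 500, 300, seed = 1),
               regexp = "synthetic", class = "mp_insufficient_pool")
})

test_that("training-set membership reproduces exactly under a seed", {
  pools <- small_pools()
  a <- sample_training_set(pools$real, pools$syn, 40, 150, seed = 11)
  b <- sample_training_set(pools$real, pools$syn, 40, 150, seed = 11)
  expect_identical(a$ids, b$ids)
  c <- sample_training_set(pools$real, pools$syn, 40, 150, seed = 12)
  expect_false(identical(a$ids, c$ids))
})

test_that("AUC matches its closed forms and the ties rule", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.6)), 1)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.7, 0.6)), 0.5)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), class = "mp_undefined_auc")
})

test_that("AUC equals the exhaustive pairwise oracle, ties included", {
  for (seed in 1:5) {
    inst <- withr::with_seed(seed, {
      n <- sample(10:60, 1)
      list(labels = rbinom(n, 1, 0.4),
           scores = round(runif(n), 1))   # rounding forces ties
    })
    if (length(unique(inst$labels)) < 2) next
    expect_equal(auc(inst$labels, inst$scores),
                 oracle_auc(inst$labels, inst$scores))
  }
})

test_that("the ridge trainer separates the benchmark classes", {
  pools <- small_pools()
  fitted <- ridge_trainer()(pools$real$features, pools$real$labels,
                            pools$val$features, pools$val$labels)
  expect_gt(auc(pools$test$labels, fitted$score(pools$test$features)), 0.7)
})

test_that("grid enumeration covers every (regime, ratio, fold) cell", {
  pools <- small_pools()
  spec <- grid_spec(regimes = c(10, 25), ratios = c(0, 100), n_folds = 3,
                    seed = 5)
  res <- run_grid(spec, pools$real, pools$syn, ridge_trainer(),
                  pools$val, pools$test)
  expect_equal(nrow(res), 2 * 2 * 3)
  expect_equal(res$n_syn_added, round(res$n_real * res$ratio_pct / 100))
  expect_true(all(res$auc >= 0 & res$auc <= 1))

  tiny <- grid_spec(regimes = 20, ratios = 50, n_folds = 1, seed = 1)
  expect_equal(nrow(run_grid(tiny, pools$real, pools$syn, ridge_trainer(),
                             pools$val, pools$test)), 1)
})

test_that("synthetic augmentation helps in the low-data regime", {
  pools <- make_benchmark_pools(n_real = 2000, n_syn = 2000, n_val = 300,
                                n_test = 1000, d = 6, seed = 4)
  spec <- grid_spec(regimes = 25, ratios = c(0, 300), n_folds = 10, seed = 2)
  res <- run_grid(spec, pools$real, pools$syn, ridge_trainer(),
                  pools$val, pools$test)
  med <- tapply(res$auc, res$ratio_pct, median)
  expect_gte(med[["300"]], med[["0"]])
})

test_that("trainer failures are recorded per cell, not fatal", {
  pools <- small_pools()
  flaky <- function(x, y, xv, yv) {
    if (nrow(x) < 30) stop("not enough samples")
    ridge_trainer()(x, y, xv, yv)
  }
  spec <- grid_spec(regimes = c(10, 100), ratios = 0, n_folds = 2, seed = 1)
  res <- run_grid(spec, pools$real, pools$syn, flaky, pools$val, pools$test)
  expect_equal(nrow(res), 4)
  expect_true(all(is.na(res$auc[res$n_real == 10])))
  expect_match(res$error[res$n_real == 10][1], "not enough samples")
  expect_true(all(!is.na(res$auc[res$n_real == 100])))
})

test_that("summaries report medians and quartiles per cell", {
  res <- data.frame(n_real = 50, ratio_pct = 0, fold = 1:10, fold_seed = 1:10,
                    n_syn_added = 0, auc = rep(0.8, 10), error = NA_character_)
  s <- summarize_grid(res)
  expect_equal(s$median, 0.8)
  expect_equal(s$q3 - s$q1, 0)

  known <- res
  known$auc <- c(0.62, 0.71, 0.55, 0.90, 0.66, 0.73, 0.68, 0.59, 0.77, 0.70)
  s2 <- summarize_grid(known)
  expect_equal(s2$median, median(sort(known$auc)))
  expect_equal(s2$n, 10)
})

test_that("all-failed cells are dropped from the summary with a warning", {
  res <- data.frame(n_real = c(10, 10, 50, 50), ratio_pct = 0, fold = c(1, 2, 1, 2),
                    fold_seed = 1, n_syn_added = 0,
                    auc = c(NA, NA, 0.7, 0.9), error = NA_character_)
  expect_warning(s <- summarize_grid(res), regexp = "dropped")
  expect_equal(nrow(s), 1)
  expect_equal(s$median, 0.8)
})

test_that("grid specs round-trip through YAML and reject unknown keys", {
  spec <- grid_spec(regimes = c(10, 50), ratios = c(0, 25), n_folds = 4, seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_grid_spec(spec, f)
  rt <- read_grid_spec(f)
  expect_equal(rt$regimes, spec$regimes)
  expect_equal(rt$seeds, spec$seeds)

  writeLines("regimes: [10]\nbogus_key: 1\n", f)
  expect_error(read_grid_spec(f), regexp = "bogus_key",
               class = "mp_config_error")
})

test_that("results and summary serialize together", {
  pools <- small_pools()
  spec <- grid_spec(regimes = 20, ratios = c(0, 100), n_folds = 2, seed = 6)
  res <- run_grid(spec, pools$real, pools$syn, ridge_trainer(),
                  pools$val, pools$test)
  dir <- withr::local_tempdir()
  write_grid_results(res, dir)
  back <- read.csv(file.path(dir, "grid_results.csv"))
  expect_equal(nrow(back), 4)
  summ <- jsonlite::fromJSON(file.path(dir, "grid_summary.json"))
  expect_equal(nrow(summ), 2)
})
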