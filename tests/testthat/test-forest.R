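# Regression forest: gain, splits, training, prediction, evaluation.

test_that("information gain matches hand computations and a brute oracle", {
  expect_equal(information_gain(c(20, 30, 20, 30), c(20, 30), c(20, 30)), 0)
  expect_equal(information_gain(c(20, 22, 30, 32), c(20, 22), c(30, 32)),
               log(26), tolerance = 1e-12)
  expect_equal(information_gain(c(20, 20), c(20), c(20)), 0,
               tolerance = 1e-12)   # floored variances cancel
  expect_identical(information_gain(c(20, 30), numeric(0), c(20, 30)), -Inf)
  expect_error(information_gain(c(20, 30, 40), c(20), c(30)), "partition")
  # brute-force oracle on random multisets
  oracle <- function(p, l, r, floor = 1e-6) {
    v <- function(x) max(mean((x - mean(x))^2), floor)
    log(v(p)) - length(l) / length(p) * log(v(l)) -
      length(r) / length(p) * log(v(r))
  }
  set.seed(51)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    p <- runif(n, 18, 34)
    k <- sample(seq_len(n - 1), 1)
    idx <- sample(n, k)
    expect_equal(information_gain(p, p[idx], p[-idx]),
                 oracle(p, p[idx], p[-idx]), tolerance = 1e-12)
  }
})

test_that("best_split behaves on degenerate and separable nodes", {
  hs <- fx_hs_random()
  mk_ex <- function(val) list(hs = hs, inner_hc = val, age = NA,
                              volume = NULL, mesh = NULL, tt = NULL)
  # all ages equal: no admissible gain above the floor
  exs <- lapply(seq(100, 120, length.out = 12), mk_ex)
  ages_eq <- rep(25, 12)
  set.seed(52)
  bs <- best_split(exs, ages_eq, m = 5, banks = "inner_hc", min_samples = 2)
  expect_true(is.null(bs) || bs$gain <= 1e-9)
  # separable toy: feature = age + tiny noise
  set.seed(53)
  ages <- runif(20, 18, 34)
  exs2 <- lapply(ages + rnorm(20, sd = 1e-3), mk_ex)
  bs2 <- best_split(exs2, ages, m = 3, banks = "inner_hc", min_samples = 2)
  expect_gt(bs2$gain, 0)
  med <- median(ages)
  expect_true(all((bs2$scores < bs2$tau) == (ages < med)) ||
                abs(mean(ages < bs2$tau) - 0.5) <= 0.2)
  # brute-force scan over all inter-decile midpoints confirms the optimum
  qs <- quantile(bs2$scores, seq(0, 1, 0.1), names = FALSE)
  taus <- unique((qs[-11] + qs[-1]) / 2)
  gains <- vapply(taus, function(tau) {
    l <- bs2$scores < tau
    if (sum(l) < 2 || sum(!l) < 2) return(-Inf)
    information_gain(ages, ages[l], ages[!l])
  }, numeric(1))
  expect_equal(bs2$gain, max(gains), tolerance = 1e-12)
  # m = 1 returns the single drawn descriptor
  set.seed(54)
  bs3 <- best_split(exs2, ages, m = 1, banks = "size_euclid", min_samples = 2)
  expect_true(is.null(bs3) || bs3$descriptor$kind == "size_euclid")
})

test_that("training respects depth, leaf-size and hemisphere contracts", {
  exs <- fx_examples40()
  ages <- vapply(exs, function(e) e$age, numeric(1))
  hp <- forest_hyperparams(n_trees = 3, max_depth = 4, m_candidates = 8,
                           min_samples = 3, seed = 5L)
  fo <- train_forest(exs, hp, banks = c("size_euclid", "inner_hc"))
  walk <- function(node, depth) {
    if (node$type == "leaf") {
      expect_lte(depth, 4)
      expect_gte(node$n, 3)
      expect_gte(node$var, hp$var_floor)
      return(invisible())
    }
    expect_gt(node$gain, hp$min_gain)
    walk(node$left, depth + 1)
    walk(node$right, depth + 1)
  }
  for (t in fo$trees) walk(t, 0)
  # mixing hemispheres errors
  bad <- exs
  bad[[1]]$hs$side <- "left"
  expect_error(train_forest(bad, hp), "hemisphere")
  # determinism: same seed, same forest
  fo2 <- train_forest(exs, hp, banks = c("size_euclid", "inner_hc"))
  expect_equal(fo, fo2)
})

test_that("deep trees with permissive leaves nearly memorize the cohort", {
  exs <- fx_examples40()
  ages <- vapply(exs, function(e) e$age, numeric(1))
  hp <- forest_hyperparams(n_trees = 4, max_depth = 15, m_candidates = 20,
                           min_samples = 1, bag_fraction = 1, seed = 11L)
  fo <- train_forest(exs, hp, banks = c("inner_hc", "size_euclid",
                                        "size_ortho"))
  preds <- vapply(exs, function(e) predict_age(fo, e)$age, numeric(1))
  expect_lt(rmse_ga(preds, ages)$gw, 0.5)
})

test_that("prediction applies the variance filter and its fallback exactly", {
  ex <- list(inner_hc = 0)
  p1 <- predict_age(leaf_forest(list(c(20, 0.5), c(30, 2.0))), ex,
                    sigma_max2 = 1.0)
  expect_equal(p1$age, 20)
  expect_equal(p1$used_leaves, 1)
  expect_false(p1$fallback_used)
  p2 <- predict_age(leaf_forest(list(c(20, 0.5), c(22, 0.9))), ex,
                    sigma_max2 = 1.0)
  expect_equal(p2$age, 21)
  expect_equal(p2$used_leaves, 2)
  p3 <- predict_age(leaf_forest(list(c(20, 2.0), c(30, 2.0))), ex,
                    sigma_max2 = 1.0)
  expect_equal(p3$age, 25)
  expect_true(p3$fallback_used)
  # prediction lies within the admitted leaf means; smaller sigma_max2
  # never admits more leaves
  lf <- leaf_forest(list(c(19, 0.2), c(21, 0.8), c(27, 3)))
  pa <- predict_age(lf, ex, sigma_max2 = 1.0)
  expect_gte(pa$age, 19)
  expect_lte(pa$age, 21)
  pb <- predict_age(lf, ex, sigma_max2 = 0.5)
  expect_lte(pb$used_leaves, pa$used_leaves)
})

test_that("RMSE follows the closed form and a naive-loop oracle", {
  expect_equal(rmse_ga(c(20, 30), c(20, 30))$gw, 0)
  r <- rmse_ga(c(21, 28), c(20, 30))
  expect_equal(r$gw, sqrt(2.5), tolerance = 1e-12)
  expect_equal(r$days, sqrt(2.5) * 7, tolerance = 1e-12)
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(1:50, 1)
    a <- runif(n, 18, 34); b <- runif(n, 18, 34)
    acc <- 0
    for (i in seq_len(n)) acc <- acc + (a[i] - b[i])^2
    expect_equal(rmse_ga(a, b)$gw, sqrt(acc / n), tolerance = 1e-12)
  }
  expect_error(rmse_ga(numeric(0), numeric(0)))
  expect_error(rmse_ga(1, c(1, 2)))
})

test_that("forests serialize and round-trip with identical predictions", {
  exs <- fx_examples40()[1:20]
  hp <- forest_hyperparams(n_trees = 3, max_depth = 6, m_candidates = 10,
                           min_samples = 2, seed = 21L)
  fo <- train_forest(exs, hp)
  tf <- withr::local_tempfile(fileext = ".json")
  write_forest(fo, tf)
  fo2 <- read_forest(tf)
  p1 <- vapply(exs, function(e) predict_age(fo, e)$age, numeric(1))
  p2 <- vapply(exs, function(e) predict_age(fo2, e)$age, numeric(1))
  expect_identical(p1, p2)
  # corrupted file: parse error, no partial model
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(tf), collapse = ""), 1, 50), bad)
  expect_error(read_forest(bad))
  # version mismatch refused
  obj <- jsonlite::read_json(tf)
  obj$format_version <- "0.0"
  jsonlite::write_json(obj, bad, auto_unbox = TRUE)
  expect_error(read_forest(bad), "version")
})
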