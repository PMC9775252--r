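# Group statistics, feature extraction, cross-validated classification.

test_that("group_compare: identical samples give p = 1", {
  r <- group_compare(c(1, 2, 3, 4), c(1, 2, 3, 4), seed = 1)
  expect_equal(r$p_value, 1)
})

test_that("group_compare enumerates small unpaired problems exactly", {
  # oracle: 70 label splits of 4+4, only the two perfectly separated ones
  # reach |t| = Inf, so p = 2/70
  r <- group_compare(c(1, 1, 1, 1), c(5, 5, 5, 5), n_permutations = 999,
                     seed = 1)
  expect_true(r$exact)
  expect_identical(r$n_permutations, 70L)
  expect_equal(r$p_value, 2 / 70)
})

test_that("group_compare paired sign-flip is exact for n = 8", {
  d <- rep(1, 8)
  r <- group_compare(d + 1, rep(1, 8), paired = TRUE, n_permutations = 999,
                     seed = 1)
  expect_true(r$exact)
  expect_identical(r$n_permutations, 256L)
  # only all-plus and all-minus sign patterns give |t| = Inf
  expect_equal(r$p_value, 2 / 256)
})

test_that("group_compare is reproducible and validates input", {
  set.seed(30)
  a <- rnorm(20); b <- rnorm(20) + 0.5
  r1 <- group_compare(a, b, n_permutations = 199, seed = 42)
  r2 <- group_compare(a, b, n_permutations = 199, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_false(r1$exact)
  expect_error(group_compare(c(1, 2), rnorm(5)),
               class = "plvnet_insufficient_sample")
  expect_error(group_compare(rnorm(4), rnorm(5), paired = TRUE),
               class = "plvnet_invalid_input")
})

test_that("metrics_table counts rows and is deterministic", {
  cfg <- tiny_cohort_config(n_per_group = 2, seed = 5)
  mats <- cohort_connectivity(generate_cohort(cfg))
  tab <- metrics_table(mats)
  expect_identical(nrow(tab$metrics), 2L * 2L * 2L * 4L)
  expect_setequal(unique(tab$metrics$band),
                  c("delta", "theta", "alpha", "beta"))
  expect_identical(nrow(tab$degrees), nrow(tab$metrics) * 19L)
  tab2 <- metrics_table(mats)
  expect_identical(tab$metrics, tab2$metrics)
  # the generator's built-in delta direction: MDD pre above HC pre
  d <- tab$metrics[tab$metrics$band == "delta" & tab$metrics$condition == "pre", ]
  expect_gt(mean(d$mean_cc[d$group == "MDD"]),
            mean(d$mean_cc[d$group == "HC"]))
  expect_error(metrics_table(mats[-1]), class = "plvnet_incomplete_cohort")
})

make_metrics_df <- function(n_per_group = 8, effect = 0) {
  grid <- expand.grid(subject_id = sprintf("s%02d", 1:(2 * n_per_group)),
                      condition = c("pre", "post"),
                      band = c("delta", "theta", "alpha", "beta"),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(as.integer(sub("s", "", grid$subject_id)) <=
                         n_per_group, "MDD", "HC")
  grid$mean_cc <- rnorm(nrow(grid)) + effect * (grid$group == "MDD")
  grid$cpl <- rnorm(nrow(grid)) + 1.5
  grid
}

test_that("extract_features shapes, ordering and degenerate columns", {
  set.seed(31)
  df <- make_metrics_df()
  f <- extract_features(df)
  expect_identical(dim(f$x), c(16L, 3L))
  expect_identical(colnames(f$x), c("delta_mean_cc", "delta_cpl", "beta_cpl"))
  expect_identical(as.vector(table(f$y)), c(8L, 8L))
  expect_equal(unname(colMeans(f$x)), rep(0, 3), tolerance = 1e-12)

  f1 <- extract_features(df, features = "delta_mean_cc")
  expect_identical(dim(f1$x), c(16L, 1L))

  df$cpl <- 2  # constant -> dropped with a warning
  expect_warning(fc <- extract_features(df),
                 class = "plvnet_constant_feature")
  expect_identical(colnames(fc$x), "delta_mean_cc")

  expect_error(extract_features(df, features = "gamma_cpl"),
               class = "plvnet_unknown_feature")
})

test_that("cross-validation is stratified, deterministic, and validates", {
  set.seed(32)
  x <- matrix(rnorm(32), 16, 2)
  y <- factor(rep(c("HC", "MDD"), each = 8))
  r <- crossval_classify(x, y, k = 10, seed = 9, classifiers = "KNN")
  sizes <- table(r$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(sum(sizes), 16L)
  r2 <- crossval_classify(x, y, k = 10, seed = 9, classifiers = "KNN")
  expect_identical(r$report, r2$report)
  expect_identical(r$predictions, r2$predictions)
  expect_error(crossval_classify(x, y, k = 20, seed = 1),
               class = "plvnet_invalid_input")
  expect_error(crossval_classify(x, factor(rep("a", 16)), k = 4, seed = 1),
               class = "plvnet_invalid_input")
})

test_that("all four classifiers separate two distant clusters perfectly", {
  set.seed(33)
  x <- rbind(matrix(rnorm(24, mean = -5), 8), matrix(rnorm(24, mean = 5), 8))
  y <- factor(rep(c("HC", "MDD"), each = 8))
  r <- crossval_classify(x, y, k = 10, seed = 2)
  for (cl in c("KNN", "SVM", "DT", "RF"))
    expect_equal(r$report[[cl]]$accuracy, 1)
  expect_equal(r$report$SVM$precision, 1)
  expect_equal(r$report$SVM$recall, 1)
})

test_that("shuffled labels yield chance-level accuracy (no leakage)", {
  set.seed(34)
  x <- matrix(rnorm(48), 16, 3)
  accs <- replicate(25, {
    y <- factor(sample(rep(c("HC", "MDD"), each = 8)))
    crossval_classify(x, y, k = 10, seed = 5,
                      classifiers = "KNN")$report$KNN$accuracy
  })
  expect_gt(mean(accs), 0.2)
  expect_lt(mean(accs), 0.8)
})

test_that("knn agrees with a brute-force oracle", {
  set.seed(35)
  xtr <- matrix(rnorm(40), 20, 2)
  ytr <- factor(sample(c("a", "b"), 20, replace = TRUE))
  xte <- matrix(rnorm(10), 5, 2)
  got <- plvnet:::knn_predict(xtr, ytr, xte, k = 3)
  for (i in 1:5) {
    d <- sqrt(colSums((t(xtr) - xte[i, ])^2))
    nb <- ytr[order(d)[1:3]]
    tab <- table(nb)
    expect_identical(as.character(got[i]), names(tab)[which.max(tab)])
  }
})

test_that("decision tree fits separable training data exactly", {
  set.seed(36)
  x <- matrix(rnorm(30), 15, 2)
  y <- factor(ifelse(x[, 1] > 0, "a", "b"))
  tr <- plvnet:::tree_build(x, y)
  expect_identical(as.character(plvnet:::tree_predict(tr, x)),
                   as.character(y))
})

test_that("compare_cohort runs all standard contrasts", {
  set.seed(37)
  df <- make_metrics_df(effect = 3)
  cmp <- compare_cohort(df, n_permutations = 99, seed = 4)
  # 4 bands x 2 metrics x (2 unpaired conditions + 2 paired groups)
  expect_identical(nrow(cmp), 4L * 2L * 4L)
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
  delta_cc_pre <- cmp[cmp$band == "delta" & cmp$metric == "mean_cc" &
                        cmp$contrast == "MDD_vs_HC" & cmp$within == "pre", ]
  expect_lt(delta_cc_pre$p_value, 0.05)   # effect = 3 sd is huge
  cmp2 <- compare_cohort(df, n_permutations = 99, seed = 4)
  expect_identical(cmp, cmp2)
})
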