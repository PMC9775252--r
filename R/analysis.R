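# Cohort-level analysis: per-subject network metric tables, permutation
# group comparisons, feature extraction and cross-validated classification.

#' Per-subject network metrics for a cohort of connectivity matrices
#'
#' Binarizes every matrix at `fraction` of its off-diagonal maximum and
#' computes mean clustering coefficient, characteristic path length and
#' node degrees.
#'
#' @param matrices List of `connectivity_matrix` objects carrying
#'   `subject_id`, `group`, `condition` and `band` provenance (as produced
#'   by [cohort_connectivity()]).
#' @param fraction Binarization fraction (default 0.8).
#' @param diagonal Passed to [binarize()].
#' @return List with `metrics` (data frame: subject_id, group, condition,
#'   band, mean_cc, cpl, n_edges) and `degrees` (long data frame:
#'   subject_id, group, condition, band, channel, degree).
#' @export
metrics_table <- function(matrices, fraction = 0.8,
                          diagonal = c("exclude", "include")) {
  diagonal <- match.arg(diagonal)
  rows <- vector("list", length(matrices))
  degs <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    if (is.null(m$subject_id) || is.null(m$condition) || is.null(m$band))
      plv_stop("invalid_input",
               "matrix %d lacks subject/condition/band provenance", i)
    g <- suppressWarnings(binarize(m, fraction, diagonal))
    nm <- network_metrics(g)
    rows[[i]] <- data.frame(subject_id = m$subject_id,
                            group = m$group %||% NA_character_,
                            condition = m$condition, band = m$band$name,
                            mean_cc = nm$mean_cc, cpl = nm$cpl,
                            n_edges = sum(g$adjacency) / 2,
                            stringsAsFactors = FALSE)
    degs[[i]] <- data.frame(subject_id = m$subject_id,
                            group = m$group %||% NA_character_,
                            condition = m$condition, band = m$band$name,
                            channel = names(nm$degrees),
                            degree = unname(nm$degrees),
                            stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, rows)
  # completeness check over the (subject, condition, band) grid
  grid <- expand.grid(subject_id = unique(metrics$subject_id),
                      condition = unique(metrics$condition),
                      band = unique(metrics$band),
                      stringsAsFactors = FALSE)
  have <- paste(metrics$subject_id, metrics$condition, metrics$band)
  want <- paste(grid$subject_id, grid$condition, grid$band)
  if (!all(want %in% have))
    plv_stop("incomplete_cohort", "missing (subject, condition, band) cells: %s",
             paste(utils::head(setdiff(want, have), 10), collapse = "; "))
  list(metrics = metrics, degrees = do.call(rbind, degs))
}

#' Two-sided permutation test on a mean difference
#'
#' Uses Welch's t as the test statistic. Unpaired comparisons permute group
#' labels; paired comparisons flip the signs of within-pair differences
#' (and use the one-sample t on differences). When the total number of
#' distinct permutations is at most `n_permutations` the test enumerates
#' them exhaustively and reports `p = #(|T*| >= |T|) / n_total`; otherwise
#' it samples and reports `p = (1 + #(|T*| >= |T|)) / (1 + B)`.
#'
#' @param values_a,values_b Numeric vectors, at least 3 values each (equal
#'   lengths when paired).
#' @param paired Logical (default `FALSE`).
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `comparison_result`: list with `statistic`,
#'   `p_value`, `n_permutations` (count actually used), `exact` (logical:
#'   exhaustive enumeration) and `seed`.
#' @examples
#' group_compare(rnorm(8), rnorm(8), seed = 1)
#' @export
group_compare <- function(values_a, values_b, paired = FALSE,
                          n_permutations = 999, seed = 1L) {
  if (length(values_a) < 3)
    plv_stop("insufficient_sample", "side a has %d < 3 values",
             length(values_a))
  if (length(values_b) < 3)
    plv_stop("insufficient_sample", "side b has %d < 3 values",
             length(values_b))
  if (paired && length(values_a) != length(values_b))
    plv_stop("invalid_input", "paired test needs equal lengths")

  welch_t <- function(a, b) {
    num <- mean(a) - mean(b)
    den <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (den == 0) { if (num == 0) 0 else sign(num) * Inf } else num / den
  }
  one_t <- function(d) {
    den <- stats::sd(d) / sqrt(length(d))
    m <- mean(d)
    if (den == 0) { if (m == 0) 0 else sign(m) * Inf } else m / den
  }

  if (paired) {
    d <- values_a - values_b
    n <- length(d)
    t_obs <- one_t(d)
    exact <- 2^n <= n_permutations
    t_perm <- if (exact) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      apply(signs, 1, function(s) one_t(d * s))
    } else {
      with_seed(seed, replicate(n_permutations,
                                one_t(d * sample(c(-1, 1), n, replace = TRUE))))
    }
  } else {
    x <- c(values_a, values_b)
    na <- length(values_a)
    t_obs <- welch_t(values_a, values_b)
    n_total <- choose(length(x), na)
    exact <- n_total <= n_permutations
    t_perm <- if (exact) {
      idx <- utils::combn(length(x), na)
      apply(idx, 2, function(i) welch_t(x[i], x[-i]))
    } else {
      with_seed(seed, replicate(n_permutations, {
        i <- sample(length(x), na)
        welch_t(x[i], x[-i])
      }))
    }
  }
  hits <- sum(abs(t_perm) >= abs(t_obs) - 1e-12)
  p <- if (exact) hits / length(t_perm) else (1 + hits) / (1 + length(t_perm))
  structure(list(statistic = t_obs, p_value = p,
                 n_permutations = length(t_perm), exact = exact,
                 paired = paired, seed = as.integer(seed)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison: t = %.3f, p = %.4g (%s, %d permutations)>\n",
              x$statistic, x$p_value,
              if (x$exact) "exact" else "sampled", x$n_permutations))
  invisible(x)
}

#' All standard group and condition contrasts on a metrics table
#'
#' For each band and metric (mean CC, CPL) runs the unpaired MDD-vs-HC
#' contrast within each condition and the paired pre-vs-post contrast
#' within each group.
#'
#' @param metrics The `metrics` data frame from [metrics_table()].
#' @param n_permutations,seed Passed to [group_compare()].
#' @return Data frame with contrast, condition_or_group, band, metric,
#'   statistic, p_value, n_permutations, seed.
#' @export
compare_cohort <- function(metrics, n_permutations = 999, seed = 1L) {
  out <- list()
  add <- function(contrast, within, band, metric, res) {
    out[[length(out) + 1]] <<- data.frame(
      contrast = contrast, within = within, band = band, metric = metric,
      statistic = res$statistic, p_value = res$p_value,
      n_permutations = res$n_permutations, seed = res$seed,
      stringsAsFactors = FALSE)
  }
  for (band in unique(metrics$band)) for (metric in c("mean_cc", "cpl")) {
    mb <- metrics[metrics$band == band, ]
    for (cond in intersect(c("pre", "post"), unique(mb$condition))) {
      a <- mb[mb$group == "MDD" & mb$condition == cond, metric]
      b <- mb[mb$group == "HC" & mb$condition == cond, metric]
      if (length(a) >= 3 && length(b) >= 3)
        add("MDD_vs_HC", cond, band, metric,
            group_compare(a, b, paired = FALSE, n_permutations,
                          derive_seed(seed, band, metric, cond, "grp")))
    }
    for (grp in unique(mb$group)) {
      gsub_ <- mb[mb$group == grp, ]
      pre <- gsub_[gsub_$condition == "pre", ]
      post <- gsub_[gsub_$condition == "post", ]
      pre <- pre[order(pre$subject_id), ]
      post <- post[order(post$subject_id), ]
      if (nrow(pre) >= 3 && identical(pre$subject_id, post$subject_id))
        add("pre_vs_post", grp, band, metric,
            group_compare(pre[[metric]], post[[metric]], paired = TRUE,
                          n_permutations,
                          derive_seed(seed, band, metric, grp, "cond")))
    }
  }
  if (!length(out)) {
    plv_warn("no_contrasts",
             "no contrast had enough subjects per side; empty table")
    return(data.frame(contrast = character(), within = character(),
                      band = character(), metric = character(),
                      statistic = numeric(), p_value = numeric(),
                      n_permutations = integer(), seed = integer()))
  }
  do.call(rbind, out)
}

#' Build the classification design matrix from network features
#'
#' One row per subject at the chosen condition (default `"pre"`, the
#' diagnostic resting state). The default feature set is delta-band mean
#' clustering coefficient, delta-band characteristic path length and
#' beta-band characteristic path length; a feature name is
#' `"<band>_<metric>"` with metric `mean_cc` or `cpl`.
#'
#' @param metrics The `metrics` data frame from [metrics_table()].
#' @param features Character vector of feature names.
#' @param condition Condition whose metrics feed classification.
#' @param standardize Z-score each column (default `TRUE`). Constant
#'   columns are dropped with a warning. Note [crossval_classify()]
#'   re-standardizes inside training folds; pass it raw features.
#' @return List with `x` (numeric matrix, subjects x features), `y`
#'   (factor of groups, levels `HC`, `MDD`) and `subject_id`.
#' @export
extract_features <- function(metrics,
                             features = c("delta_mean_cc", "delta_cpl",
                                          "beta_cpl"),
                             condition = "pre", standardize = TRUE) {
  m <- metrics[metrics$condition == condition, ]
  if (!nrow(m))
    plv_stop("invalid_input", "no rows for condition '%s'", condition)
  subjects <- sort(unique(m$subject_id))
  cols <- list()
  for (f in features) {
    parts <- regmatches(f, regexec("^([a-z]+)_(mean_cc|cpl)$", f))[[1]]
    if (length(parts) != 3)
      plv_stop("unknown_feature", "unknown feature name '%s'", f)
    band <- parts[2]; metric <- parts[3]
    mb <- m[m$band == band, ]
    if (!nrow(mb))
      plv_stop("unknown_feature", "no metrics for band '%s'", band)
    v <- mb[[metric]][match(subjects, mb$subject_id)]
    if (anyNA(v))
      plv_stop("invalid_input", "feature '%s' has undefined values", f)
    cols[[f]] <- v
  }
  x <- do.call(cbind, cols)
  rownames(x) <- subjects
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      plv_warn("constant_feature", "dropping constant feature(s): %s",
               paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    x <- scale(x)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  grp <- m$group[match(subjects, m$subject_id)]
  list(x = x, y = factor(grp, levels = c("HC", "MDD")),
       subject_id = subjects)
}

# Stratified fold assignment: shuffle within class, then deal folds from a
# global counter cycling 1..k so overall fold sizes differ by at most one.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  counter <- 0
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- (counter + seq_along(idx) - 1) %% k + 1
    counter <- counter + length(idx)
  }
  folds
}

#' Cross-validated classification of network features
#'
#' Stratified k-fold cross-validation of the four classifiers (KNN, SVM
#' with RBF kernel, decision tree, random forest). Standardization is
#' fitted on each training fold and applied to its test fold, so no
#' information leaks across folds. Out-of-fold predictions are pooled and
#' summarized as accuracy, precision and recall with `positive` as the
#' positive class.
#'
#' @param x Numeric feature matrix (subjects x features), unstandardized.
#' @param y Factor of class labels (2 classes).
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling folds and classifier randomness.
#' @param classifiers Subset of `c("KNN", "SVM", "DT", "RF")`.
#' @param positive Positive class for precision/recall (default `"MDD"`
#'   when present).
#' @param params Hyperparameters: `knn_k` (3), `svm_c` (1), `svm_gamma`
#'   (`NULL` = 1 / (d * var)), `rf_trees` (100), `min_leaf` (1).
#' @return Object of class `classifier_report`: per-classifier list of
#'   accuracy/precision/recall, plus `folds`, `predictions` and `seed`.
#' @export
crossval_classify <- function(x, y, k = 10, seed = 1L,
                              classifiers = c("KNN", "SVM", "DT", "RF"),
                              positive = NULL, params = list()) {
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x)
  if (k > n) plv_stop("invalid_input", "k = %d folds but only %d samples", k, n)
  if (nlevels(y) < 2) plv_stop("invalid_input", "need at least 2 classes")
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  positive <- positive %||% (if ("MDD" %in% levels(y)) "MDD" else levels(y)[2])
  p <- utils::modifyList(list(knn_k = 3, svm_c = 1, svm_gamma = NULL,
                              rf_trees = 100, min_leaf = 1), params)

  folds <- with_seed(derive_seed(seed, "folds"), stratified_folds(y, k))
  preds <- matrix(NA_character_, n, length(classifiers),
                  dimnames = list(rownames(x), classifiers))
  for (fold in sort(unique(folds))) {
    test <- folds == fold
    xtr <- x[!test, , drop = FALSE]; ytr <- y[!test]
    xte <- x[test, , drop = FALSE]
    ctr <- colMeans(xtr)
    str_ <- apply(xtr, 2, stats::sd)
    str_[str_ == 0] <- 1
    xtr <- scale(xtr, center = ctr, scale = str_)
    xte <- scale(xte, center = ctr, scale = str_)
    for (cl in classifiers) {
      pred <- with_seed(derive_seed(seed, cl, fold), switch(cl,
        KNN = knn_predict(xtr, ytr, xte, k = p$knn_k),
        SVM = svm_predict(svm_train(xtr, ytr, C = p$svm_c,
                                    gamma = p$svm_gamma), xte),
        DT = tree_predict(tree_build(xtr, ytr, min_leaf = p$min_leaf), xte),
        RF = forest_predict(forest_train(xtr, ytr, n_trees = p$rf_trees,
                                         min_leaf = p$min_leaf), xte)))
      preds[test, cl] <- as.character(pred)
    }
  }
  report <- lapply(classifiers, function(cl) {
    pr <- factor(preds[, cl], levels = levels(y))
    tp <- sum(pr == positive & y == positive)
    fp <- sum(pr == positive & y != positive)
    fn <- sum(pr != positive & y == positive)
    list(accuracy = mean(pr == y),
         precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
  })
  names(report) <- classifiers
  structure(list(report = report, folds = folds, predictions = preds,
                 positive = positive, seed = as.integer(seed), k = k),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report: %d-fold CV, positive = %s>\n", x$k,
              x$positive))
  for (cl in names(x$report)) {
    r <- x$report[[cl]]
    cat(sprintf("  %-4s accuracy %.4f  precision %s  recall %s\n", cl,
                r$accuracy,
                ifelse(is.na(r$precision), "NA", sprintf("%.4f", r$precision)),
                ifelse(is.na(r$recall), "NA", sprintf("%.4f", r$recall))))
  }
  invisible(x)
}
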