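#' Area under the ROC curve (midrank convention)
#'
#' Computed via the Wilcoxon/Mann-Whitney identity with midranks, so tied
#' scores contribute 1/2 and a constant score vector gives exactly 0.5.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Binary 0/1 labels (1 = case).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUROC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration over the distinct score thresholds (ties handled as one
#' block): `sum_k (R_k - R_{k-1}) * P_k` walking thresholds from high to
#' low.
#'
#' @inheritParams auroc
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  if (n1 == 0) stop("at least one case required to compute AUPR", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  block_end <- which(diff(s) != 0)
  cut_idx <- c(block_end, length(s))
  tp <- cumsum(y)[cut_idx]
  pred_pos <- cut_idx
  recall <- tp / n1
  precision <- tp / pred_pos
  sum(diff(c(0, recall)) * precision)
}

#' Seeded, optionally grouped and stratified, train/test split
#'
#' When `patient_ids` is given, all samples of one patient land on the same
#' side of the split (longitudinal datasets must never contribute the same
#' patient to both sides). Without grouping the split is stratified by label
#' when labels are supplied. If grouping makes the requested fraction
#' unreachable, the closest achievable split is returned with a warning.
#'
#' @param x A [sample_table()], `property_table`, matrix/data frame with
#'   sample rows, or a plain sample count.
#' @param test_fraction Fraction of samples for the test side, in `(0, 1)`.
#' @param labels Optional 0/1 labels for stratification.
#' @param patient_ids Optional per-sample grouping vector.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(x, test_fraction, labels = NULL,
                             patient_ids = NULL, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- if (inherits(x, "sample_table")) nrow(x$counts)
       else if (is.numeric(x) && length(x) == 1) as.integer(x)
       else nrow(x)
  n_test <- round(test_fraction * n)
  n_test <- max(1L, min(n - 1L, n_test))
  set.seed(seed)
  if (!is.null(patient_ids)) {
    stopifnot(length(patient_ids) == n)
    groups <- split(seq_len(n), patient_ids)
    ord <- sample(length(groups))
    test <- integer(0)
    for (g in ord) {
      if (length(test) >= n_test) break
      # take the group only if it brings us closer to the target size
      overshoot <- length(test) + length(groups[[g]]) - n_test
      if (overshoot <= 0 || overshoot < n_test - length(test)) {
        test <- c(test, groups[[g]])
      }
    }
    if (abs(length(test) - n_test) > max(lengths(groups))) {
      warning("grouped split deviates from requested test fraction")
    }
    if (length(test) == 0 || length(test) == n) {
      stop("grouping makes the requested split impossible", call. = FALSE)
    }
    if (abs(length(test) - n_test) > 1) {
      warning(sprintf("grouped split has %d test samples (requested %d)",
                      length(test), n_test))
    }
  } else if (!is.null(labels)) {
    labels <- as.integer(labels)
    idx1 <- which(labels == 1L)
    idx0 <- which(labels == 0L)
    k1 <- round(test_fraction * length(idx1))
    test <- c(sample(idx1, k1), sample(idx0, n_test - k1))
  } else {
    test <- sample.int(n, n_test)
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Random-forest configuration and hyperparameter grid
#'
#' The grid covers number of trees, maximum tree depth (0 = unlimited) and
#' the weight placed on a positive (case) prediction; one triple is chosen
#' by cross-validated mean of the configured score. 10-fold cross-validation
#' is the usual within-dataset tuning protocol; 3-fold is common when a
#' model is tuned once and deployed unchanged on external datasets.
#'
#' @param n_trees,max_depth,positive_class_weight Grid values.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param scoring `"auroc"` or `"aupr"`.
#' @param seed Integer seed for folds and forests.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = c(100, 500, 1000),
                      max_depth = c(2, 5, 10, 0),
                      positive_class_weight = c(1, 3, 6),
                      cv_folds = 10, scoring = c("auroc", "aupr"), seed = 1) {
  scoring <- match.arg(scoring)
  stopifnot(length(n_trees) >= 1, length(max_depth) >= 1,
            length(positive_class_weight) >= 1, cv_folds >= 2)
  structure(
    list(grid = expand.grid(n_trees = n_trees, max_depth = max_depth,
                            positive_class_weight = positive_class_weight),
         cv_folds = as.integer(cv_folds), scoring = scoring,
         seed = as.integer(seed)),
    class = "rf_config"
  )
}

feature_matrix <- function(features, metadata = NULL) {
  m <- if (inherits(features, "sample_table")) features$counts else unclass(features)
  m <- as.matrix(m)
  if (!is.null(metadata)) {
    md <- as.matrix(as.data.frame(metadata))
    storage.mode(md) <- "double"
    # impute missing covariates as the column median
    for (j in seq_len(ncol(md))) {
      miss <- is.na(md[, j])
      if (any(miss)) md[miss, j] <- stats::median(md[, j], na.rm = TRUE)
    }
    m <- cbind(m, md)
  }
  if (anyDuplicated(colnames(m))) stop("duplicate feature names", call. = FALSE)
  m
}

rf_fit_one <- function(x, y, n_trees, max_depth, pos_weight, seed) {
  ranger::ranger(
    x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
    num.trees = n_trees, max.depth = if (max_depth > 0) max_depth else NULL,
    class.weights = c(1, pos_weight), probability = TRUE,
    seed = seed, num.threads = 1
  )
}

rf_predict <- function(model, x) {
  stats::predict(model, data = as.data.frame(x), num.threads = 1)$predictions[, "1"]
}

cv_folds_stratified <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Tune and train a random-forest phenotype classifier
#'
#' Exhaustive grid search over the `rf_config` grid, scored by the
#' cross-validated mean of the configured metric, then refit on the full
#' training set with the best triple. Metadata covariates, when supplied,
#' are appended as extra features (e.g. 100 properties + 13 covariates =
#' 113 model features); missing covariate values are imputed as the column
#' median.
#'
#' @param features A `property_table`, [sample_table()] or matrix of
#'   training features (samples x variables).
#' @param labels Binary 0/1 labels (1 = case), one per training sample.
#' @param metadata Optional data frame of numeric covariates.
#' @param config An [rf_config()].
#' @return An object of class `rf_phenotype_fit`: the refit ranger `model`,
#'   `best` (chosen hyperparameters), `cv_results` (one row per grid point),
#'   `feature_names` and `config`.
#' @export
tune_and_train <- function(features, labels, metadata = NULL,
                           config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  x <- feature_matrix(features, metadata)
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  metric <- if (config$scoring == "auroc") auroc else aupr
  fold <- cv_folds_stratified(y, config$cv_folds, config$seed)
  grid <- config$grid
  cv_score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    scores <- rep(NA_real_, length(y))
    for (f in seq_len(config$cv_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      m <- rf_fit_one(x[tr, , drop = FALSE], y[tr],
                      grid$n_trees[g], grid$max_depth[g],
                      grid$positive_class_weight[g],
                      seed = config$seed + f)
      scores[!tr] <- rf_predict(m, x[!tr, , drop = FALSE])
    }
    ok <- !is.na(scores)
    cv_score[g] <- metric(scores[ok], y[ok])
  }
  best <- which.max(cv_score)
  model <- rf_fit_one(x, y, grid$n_trees[best], grid$max_depth[best],
                      grid$positive_class_weight[best], seed = config$seed)
  structure(
    list(model = model,
         best = tibble::as_tibble(grid[best, , drop = FALSE]),
         cv_results = dplyr::arrange(
           tibble::tibble(tibble::as_tibble(grid), cv_score = cv_score,
                          metric = config$scoring),
           dplyr::desc(.data$cv_score)),
         feature_names = colnames(x), config = config),
    class = "rf_phenotype_fit"
  )
}

#' @export
print.rf_phenotype_fit <- function(x, ...) {
  cat(sprintf(
    "<rf_phenotype_fit> %d features; best: %d trees, depth %s, weight %g (cv %s %.3f)\n",
    length(x$feature_names), x$best$n_trees,
    if (x$best$max_depth > 0) x$best$max_depth else "unlimited",
    x$best$positive_class_weight, x$config$scoring, max(x$cv_results$cv_score)
  ))
  invisible(x)
}

#' @method tidy rf_phenotype_fit
#' @export
tidy.rf_phenotype_fit <- function(x, ...) x$cv_results

#' @method glance rf_phenotype_fit
#' @export
glance.rf_phenotype_fit <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_trees = x$best$n_trees, max_depth = x$best$max_depth,
    positive_class_weight = x$best$positive_class_weight,
    cv_metric = x$config$scoring, cv_score = max(x$cv_results$cv_score)
  )
}

#' Evaluate a fitted classifier on a test set
#'
#' AUROC and AUPR are computed from the continuous case-probability scores;
#' precision and recall use the model's default 0.5 decision threshold
#' (deployment on external datasets re-tunes neither hyperparameters nor
#' the threshold). When the model predicts no positives, precision and
#' recall are both reported as 0.
#'
#' @param fit An [tune_and_train()] result.
#' @param features Test features with the same columns as in training.
#' @param labels Binary test labels.
#' @param metadata Optional covariates matching the training covariates;
#'   missing covariate columns are an error.
#' @return A one-row tibble of class `eval_result` with `auroc`, `aupr`,
#'   `precision`, `recall`, `n_test`, and the per-sample scores in
#'   `attr(, "scores")`.
#' @export
evaluate <- function(fit, features, labels, metadata = NULL) {
  stopifnot(inherits(fit, "rf_phenotype_fit"))
  x <- feature_matrix(features, metadata)
  missing <- setdiff(fit$feature_names, colnames(x))
  if (length(missing) > 0) {
    stop("test features are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, fit$feature_names, drop = FALSE]
  y <- as.integer(labels)
  scores <- rf_predict(fit$model, x)
  pred <- scores > 0.5
  tp <- sum(pred & y == 1L)
  res <- tibble::tibble(
    auroc = auroc(scores, y), aupr = aupr(scores, y),
    precision = if (sum(pred) == 0) 0 else tp / sum(pred),
    recall = if (sum(pred) == 0) 0 else tp / sum(y == 1L),
    n_test = length(y)
  )
  attr(res, "scores") <- scores
  class(res) <- c("eval_result", class(res))
  res
}

#' Learning curve over training-set sizes and representations
#'
#' For each training size and data representation, draws seeded (group-aware
#' when `patient_ids` is given) splits with `size` training samples, tunes a
#' forest on the training side and records test AUROC, aggregated over
#' `n_seeds` replicate splits.
#'
#' @param representations Named list of feature matrices/`property_table`s
#'   over the same samples (e.g. `list(properties = ..., counts = ...)`).
#' @param labels Binary labels, one per sample.
#' @param sizes Training-set sizes, each smaller than the sample count.
#' @param n_seeds Number of replicate splits.
#' @param patient_ids Optional grouping for the splits.
#' @param config An [rf_config()].
#' @return A tibble with one row per (size, representation): `mean_auroc`,
#'   `sd_auroc`, `n_runs`.
#' @export
learning_curve <- function(representations, labels, sizes, n_seeds = 10,
                           patient_ids = NULL, config = rf_config()) {
  stopifnot(is.list(representations), !is.null(names(representations)))
  y <- as.integer(labels)
  n <- length(y)
  stopifnot(all(sizes < n))
  out <- list()
  for (size in sizes) {
    for (rep_name in names(representations)) {
      x <- feature_matrix(representations[[rep_name]])
      aucs <- c()
      for (s in seq_len(n_seeds)) {
        sp <- withCallingHandlers(
          split_train_test(n, test_fraction = 1 - size / n, labels = y,
                           patient_ids = patient_ids,
                           seed = config$seed + 1000 * s),
          warning = function(w) invokeRestart("muffleWarning")
        )
        if (length(unique(y[sp$train])) < 2 || length(unique(y[sp$test])) < 2) {
          warning(sprintf("size %d seed %d leaves a single class; skipped", size, s))
          next
        }
        fit <- tune_and_train(x[sp$train, , drop = FALSE], y[sp$train],
                              config = rf_config(
                                n_trees = unique(config$grid$n_trees),
                                max_depth = unique(config$grid$max_depth),
                                positive_class_weight =
                                  unique(config$grid$positive_class_weight),
                                cv_folds = config$cv_folds,
                                scoring = config$scoring,
                                seed = config$seed + s))
        ev <- evaluate(fit, x[sp$test, , drop = FALSE], y[sp$test])
        aucs <- c(aucs, ev$auroc)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        size = size, representation = rep_name,
        mean_auroc = mean(aucs), sd_auroc = stats::sd(aucs), n_runs = length(aucs)
      )
    }
  }
  dplyr::bind_rows(out)
}
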