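intersect_embedding_pathways <- function(embedding, pathways) {
  common <- intersect(rownames(embedding), rownames(pathways))
  if (length(common) < 3) {
    stop("fewer than 3 ASVs shared between embedding and pathway table", call. = FALSE)
  }
  list(E = unclass(embedding)[common, , drop = FALSE],
       B = pathways[common, , drop = FALSE], asvs = common)
}

standardize_columns <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(m, 2, mu), 2, sdv, "/")
}

#' Correlations between properties and metabolic pathways
#'
#' Restricts both tables to their shared ASVs (in practice, the ASVs with
#' near neighbors in the pathway database), standardizes each property
#' column to mean 0 / variance 1 over those ASVs, and correlates every
#' standardized property vector with every binary pathway column. Pathway
#' columns constant over the shared ASVs get correlation 0 and are flagged.
#'
#' @param embedding An [asv_embedding()] (or PCA rotation matrix wrapped as
#'   one — standardization makes the two spaces comparable).
#' @param pathways Binary ASV x pathway matrix ([read_pathway_table()]).
#' @param method `"pearson"` (default; standardization implies a linear
#'   association measure) or `"spearman"`.
#' @return A property x pathway correlation matrix with the constant
#'   pathway IDs in `attr(, "constant_pathways")`.
#' @export
property_pathway_correlations <- function(embedding, pathways,
                                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xs <- intersect_embedding_pathways(embedding, pathways)
  constant <- colnames(xs$B)[apply(xs$B, 2, function(v) length(unique(v)) == 1)]
  E <- standardize_columns(xs$E)
  r <- suppressWarnings(stats::cor(E, xs$B, method = method))
  r[, constant] <- 0
  r[is.na(r)] <- 0  # zero-variance properties
  attr(r, "constant_pathways") <- constant
  r
}

max_abs_cor <- function(E_std, B, method) {
  r <- suppressWarnings(stats::cor(E_std, B, method = method))
  r[is.na(r)] <- 0
  r
}

#' Maximum-correlation permutation test for property-pathway association
#'
#' For each property, finds its maximally correlated (absolute value)
#' pathway, then assesses significance against a null built by permuting
#' the rows (ASVs) of the pathway table jointly `n_permutations` times and
#' recording the maximum absolute correlation per property each time. The
#' p-value uses the add-one convention
#' `p = (#\{null >= observed\} + 1) / (n_permutations + 1)` (10,000
#' permutations give a floor of 1/10001), with Benjamini-Hochberg
#' adjustment across properties. A property's significant pathway set
#' contains the pathways whose absolute correlation exceeds that property's
#' null 95th percentile.
#'
#' @inheritParams property_pathway_correlations
#' @param n_permutations Number of row permutations (10,000 is the standard
#'   protocol).
#' @param seed Integer seed.
#' @return An object of class `pathway_correlation`: list with `summary`
#'   (tibble: `property`, `max_pathway`, `max_r`, `p_value`, `p_adjusted`,
#'   `n_significant`), `significant` (named list of pathway IDs per
#'   property), the observed `correlations` matrix, `null_q95`, and
#'   `n_permutations`.
#' @export
max_correlation_permutation_test <- function(embedding, pathways,
                                             n_permutations = 10000, seed = 1,
                                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(n_permutations >= 1)
  r_obs <- property_pathway_correlations(embedding, pathways, method)
  xs <- intersect_embedding_pathways(embedding, pathways)
  E <- standardize_columns(xs$E)
  obs_max <- apply(abs(r_obs), 1, max)
  obs_which <- colnames(r_obs)[apply(abs(r_obs), 1, which.max)]

  set.seed(seed)
  n <- nrow(xs$B)
  null_max <- matrix(NA_real_, n_permutations, ncol(E))
  for (b in seq_len(n_permutations)) {
    Bp <- xs$B[sample.int(n), , drop = FALSE]
    null_max[b, ] <- apply(abs(max_abs_cor(E, Bp, method)), 1, max)
  }
  exceed <- colSums(sweep(null_max, 2, obs_max, ">="))
  p <- (exceed + 1) / (n_permutations + 1)
  q95 <- apply(null_max, 2, stats::quantile, probs = 0.95, names = FALSE)
  significant <- lapply(seq_len(nrow(r_obs)), function(k) {
    colnames(r_obs)[abs(r_obs[k, ]) > q95[k]]
  })
  names(significant) <- rownames(r_obs)
  structure(
    list(
      summary = tibble::tibble(
        property = rownames(r_obs), max_pathway = obs_which, max_r = obs_max,
        p_value = p, p_adjusted = stats::p.adjust(p, method = "BH"),
        n_significant = lengths(significant)
      ),
      significant = significant, correlations = r_obs,
      null_q95 = stats::setNames(q95, rownames(r_obs)),
      n_permutations = n_permutations
    ),
    class = "pathway_correlation"
  )
}

#' @export
print.pathway_correlation <- function(x, ...) {
  cat(sprintf(
    "<pathway_correlation> %d properties x %d pathways, %d permutations; %d properties with adjusted p < 0.05\n",
    nrow(x$correlations), ncol(x$correlations), x$n_permutations,
    sum(x$summary$p_adjusted < 0.05)
  ))
  invisible(x)
}

#' @method tidy pathway_correlation
#' @export
tidy.pathway_correlation <- function(x, ...) x$summary

#' Variance in each property explained by pathway presence
#'
#' Ordinary least squares per property: the property values per ASV are the
#' response, the binary pathway columns the predictors;
#' `r^2 = 1 - RSS/TSS` is reported. With fewer shared ASVs than pathways
#' the fit is rank-deficient (least-norm solution) and a warning is issued.
#' Zero-variance properties have undefined r^2, reported as `NA`.
#'
#' @inheritParams property_pathway_correlations
#' @return A tibble with columns `property`, `r_squared`.
#' @export
variance_explained <- function(embedding, pathways) {
  xs <- intersect_embedding_pathways(embedding, pathways)
  if (nrow(xs$B) <= ncol(xs$B)) {
    warning("shared ASV count does not exceed pathway count; rank-deficient fit")
  }
  X <- cbind(`(Intercept)` = 1, xs$B)
  r2 <- vapply(seq_len(ncol(xs$E)), function(k) {
    y <- xs$E[, k]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(NA_real_)
    fit <- stats::lm.fit(X, y)
    1 - sum(fit$residuals^2) / tss
  }, numeric(1))
  if (anyNA(r2)) warning("zero-variance property: r^2 undefined, reported as NA")
  tibble::tibble(property = colnames(xs$E), r_squared = r2)
}

#' Mantel test between two dissimilarity matrices
#'
#' The statistic is the Pearson correlation of the strictly-lower-triangle
#' entries; the null is built by jointly permuting rows and columns of the
#' second matrix. The one-sided p-value uses the add-one convention, so
#' 10,000 permutations give a minimum attainable p of 1/10001.
#'
#' @param d1,d2 Square symmetric dissimilarity matrices with zero diagonal
#'   and identical dimensions.
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @return An object of class `mantel_result`: list with `statistic` (r),
#'   `p_value`, `n_permutations` and the permutation `null` values.
#' @export
mantel_test <- function(d1, d2, n_permutations = 10000, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) {
    stop(sprintf("size mismatch: %dx%d vs %dx%d",
                 nrow(d1), ncol(d1), nrow(d2), ncol(d2)), call. = FALSE)
  }
  for (d in list(d1, d2)) {
    if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12)) {
      stop("dissimilarity matrices must be symmetric with zero diagonal",
           call. = FALSE)
    }
  }
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  r_obs <- stats::cor(v1, d2[lt])
  set.seed(seed)
  n <- nrow(d1)
  null <- vapply(seq_len(n_permutations), function(b) {
    idx <- sample.int(n)
    stats::cor(v1, d2[idx, idx][lt])
  }, numeric(1))
  p <- (sum(null >= r_obs) + 1) / (n_permutations + 1)
  structure(
    list(statistic = r_obs, p_value = p, n_permutations = n_permutations,
         null = null),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, p = %.3g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_permutations = x$n_permutations)
}

#' Property-by-property dissimilarities
#'
#' Correlation distance (1 - Pearson r) between property columns, viewing
#' each property either through its per-ASV values (`type = "asv"`) or
#' through its vector of pathway correlations
#' (`type = "pathway_correlation"`). The two views feed the Mantel
#' comparison of property structure with metabolic capacity.
#'
#' @param embedding An [asv_embedding()].
#' @param pathways Pathway table, required for
#'   `type = "pathway_correlation"`.
#' @param type Which view of the properties to use.
#' @return A symmetric property x property distance matrix, zero diagonal.
#' @export
property_distance <- function(embedding, pathways = NULL,
                              type = c("asv", "pathway_correlation")) {
  type <- match.arg(type)
  if (type == "asv") {
    v <- unclass(embedding)
  } else {
    if (is.null(pathways)) stop("`pathways` required for pathway-correlation distances",
                                call. = FALSE)
    v <- t(property_pathway_correlations(embedding, pathways))
  }
  d <- 1 - stats::cor(v)
  diag(d) <- 0
  d
}

## --- association score -------------------------------------------------

# Backtrace one ranger tree (treeInfo data frame): every root-to-leaf path
# ending in a majority-case leaf contributes +1 for each split where the
# path took the greater-than branch and -1 where it took the <= branch.
backtrace_tree <- function(ti, feature_names, case_class = "1") {
  score <- stats::setNames(numeric(length(feature_names)), feature_names)
  used <- character(0)
  pred_case <- ti[[paste0("pred.", case_class)]]
  walk <- function(node_row, path_vars, path_dirs) {
    row <- ti[ti$nodeID == node_row, ]
    if (row$terminal) {
      if (!is.na(pred_case[ti$nodeID == node_row]) &&
          pred_case[ti$nodeID == node_row] > 0.5 && length(path_vars) > 0) {
        for (k in seq_along(path_vars)) {
          score[path_vars[k]] <<- score[path_vars[k]] + path_dirs[k]
        }
        used <<- union(used, path_vars)
      }
      return(invisible(NULL))
    }
    v <- row$splitvarName
    walk(row$leftChild, c(path_vars, v), c(path_dirs, -1))  # value <= split
    walk(row$rightChild, c(path_vars, v), c(path_dirs, +1)) # value > split
  }
  walk(0, character(0), numeric(0))
  list(score = score, used = used)
}

#' Tree-backtrace association score between features and the case class
#'
#' Trains cross-validated random forests of depth-2 trees (each tree splits
#' on at most 3 variables) and backtraces every root-to-leaf path that ends
#' in a majority-case leaf: a split adds +1 to its variable's score when
#' the path followed the greater-than branch and -1 when it followed the
#' less-or-equal branch. Scores accumulate over all trees of all folds, so
#' a strongly positive score marks a property whose high values push the
#' forest toward a case prediction. The alternative reading of the
#' depth restriction — at most 3 candidate variables per split with
#' unlimited depth — is available as `mode = "mtry_three"`.
#'
#' @param features A `property_table` or feature matrix (samples x
#'   variables).
#' @param labels Binary 0/1 labels (1 = case).
#' @param n_folds Cross-validation folds; one forest per fold, trained on
#'   the fold's training side.
#' @param n_trees Trees per forest.
#' @param seed Integer seed.
#' @param mode `"depth_two"` (default) or `"mtry_three"`.
#' @param case_class `"1"` (default) scores paths toward case predictions;
#'   `"0"` re-orients the backtrace toward the control class on identically
#'   trained forests (useful for direction-of-association checks: on fully
#'   resolved trees the two orientations are exact negatives).
#' @return An object of class `association_score`: tibble with columns
#'   `property`, `score` (signed integer) and `n_trees_support` (cumulative
#'   number of trees whose case paths used the property).
#' @export
association_score <- function(features, labels, n_folds = 10, n_trees = 100,
                              seed = 1, mode = c("depth_two", "mtry_three"),
                              case_class = c("1", "0")) {
  mode <- match.arg(mode)
  case_class <- match.arg(case_class)
  x <- feature_matrix(features)
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  fold <- cv_folds_stratified(y, n_folds, seed)
  score <- stats::setNames(numeric(ncol(x)), colnames(x))
  support <- stats::setNames(numeric(ncol(x)), colnames(x))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    rf <- ranger::ranger(
      x = as.data.frame(x[tr, , drop = FALSE]),
      y = factor(y[tr], levels = c(0, 1)),
      num.trees = n_trees,
      max.depth = if (mode == "depth_two") 2 else NULL,
      mtry = if (mode == "mtry_three") min(3, ncol(x)) else NULL,
      probability = TRUE, seed = seed + f, num.threads = 1
    )
    for (t in seq_len(rf$num.trees)) {
      ti <- ranger::treeInfo(rf, t)
      bt <- backtrace_tree(ti, colnames(x), case_class)
      score <- score + bt$score
      support[bt$used] <- support[bt$used] + 1
    }
  }
  structure(
    tibble::tibble(property = names(score), score = unname(score),
                   n_trees_support = unname(support)),
    class = c("association_score", class(tibble::tibble()))
  )
}

#' Pathways important for the phenotype
#'
#' Combines association scores from one or more datasets with the
#' significantly correlated pathway sets of a permutation test.
#' "Consistently predictive" properties reach `|score| >= score_threshold`
#' with the same sign in every supplied dataset; a pathway is called
#' important when it is significantly correlated with at least
#' `min_properties` of them.
#'
#' @param scores A single [association_score()] result or a (named) list of
#'   them, one per dataset.
#' @param correlations A [max_correlation_permutation_test()] result.
#' @param score_threshold Minimum absolute score (default 8).
#' @param min_properties Minimum number of consistent properties a pathway
#'   must correlate with (default 2).
#' @return A tibble with columns `pathway`, `n_properties`, `properties`
#'   (list column), sorted by `n_properties`. Empty (with a warning) when
#'   no property is consistently predictive.
#' @export
pathway_importance <- function(scores, correlations, score_threshold = 8,
                               min_properties = 2) {
  stopifnot(inherits(correlations, "pathway_correlation"))
  if (inherits(scores, "association_score")) scores <- list(scores)
  score_mat <- vapply(scores, function(s) {
    stats::setNames(s$score, s$property)[scores[[1]]$property]
  }, numeric(nrow(scores[[1]])))
  score_mat <- matrix(score_mat, nrow = nrow(scores[[1]]),
                      dimnames = list(scores[[1]]$property, NULL))
  consistent <- rownames(score_mat)[
    apply(score_mat, 1, function(v) {
      all(abs(v) >= score_threshold) && (all(v > 0) || all(v < 0))
    })
  ]
  if (length(consistent) == 0) {
    warning("no consistently predictive property at |score| >= ", score_threshold)
    return(tibble::tibble(pathway = character(), n_properties = integer(),
                          properties = list()))
  }
  sig <- correlations$significant[consistent]
  counts <- table(unlist(sig))
  keep <- names(counts)[counts >= min_properties]
  tibble::tibble(
    pathway = keep,
    n_properties = as.integer(counts[keep]),
    properties = lapply(keep, function(p) {
      consistent[vapply(sig, function(s) p %in% s, logical(1))]
    })
  ) |> dplyr::arrange(dplyr::desc(.data$n_properties), .data$pathway)
}
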