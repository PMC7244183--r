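#' GloVe training configuration
#'
#' Hyperparameters of the weighted least-squares co-occurrence factorization.
#' The number of properties (embedding dimensions) is the main tunable;
#' typical sweeps cover 50, 100, 250, 500 and 750 dimensions, with 100 a good
#' default for 16S gut data. The weighting-function cap `x_max = 100`,
#' exponent `alpha = 0.75`, AdaGrad learning rate 0.05, 50 epochs and
#' uniform initialization in `(-0.5/dim, 0.5/dim)` follow the canonical GloVe
#' recommendations.
#'
#' @param n_properties Embedding dimension (number of properties).
#' @param x_max Weighting cap: co-occurrence counts at or above `x_max` get
#'   full weight 1.
#' @param alpha Weighting exponent in `(0, 1]`.
#' @param learning_rate Initial AdaGrad step size.
#' @param n_epochs Number of passes over the nonzero pairs.
#' @param seed Integer seed controlling initialization and pair shuffling.
#' @param init_scale Half-width of the uniform initialization interval;
#'   defaults to `0.5 / n_properties`.
#' @return A list of class `glove_config`.
#' @export
glove_config <- function(n_properties = 100, x_max = 100, alpha = 0.75,
                         learning_rate = 0.05, n_epochs = 50, seed = 1,
                         init_scale = NULL) {
  if (is.null(init_scale)) init_scale <- 0.5 / n_properties
  stopifnot(n_properties >= 1, x_max > 0, alpha > 0, alpha <= 1,
            learning_rate > 0, n_epochs >= 1, init_scale > 0)
  structure(
    list(n_properties = as.integer(n_properties), x_max = x_max, alpha = alpha,
         learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
         seed = as.integer(seed), init_scale = init_scale),
    class = "glove_config"
  )
}

#' GloVe weighting function
#'
#' `f(x) = (x / x_max)^alpha` for `x < x_max`, and 1 otherwise. Rare pairs
#' are down-weighted; the cap keeps very frequent pairs from dominating.
#'
#' @param x Non-negative co-occurrence count(s).
#' @param x_max,alpha See [glove_config()].
#' @return Weights in `[0, 1]`, same length as `x`.
#' @export
glove_weight <- function(x, x_max = 100, alpha = 0.75) {
  if (any(x < 0)) stop("co-occurrence counts must be non-negative", call. = FALSE)
  ifelse(x < x_max, (x / x_max)^alpha, 1)
}

glove_pairs <- function(cooc) {
  up <- which(upper.tri(cooc$X) & cooc$X > 0, arr.ind = TRUE)
  list(i = up[, 1], j = up[, 2], x = cooc$X[up])
}

#' Train a GloVe embedding over ASVs
#'
#' Factorizes the log co-occurrence counts: learns per-ASV main vectors
#' `w_i`, context vectors `w~_j` and biases such that
#' `w_i . w~_j + b_i + b~_j ~ log X[i, j]`, minimizing the weighted squared
#' error with weights [glove_weight()]. Optimization is AdaGrad stochastic
#' descent over the nonzero unordered pairs, each visited in both directions
#' per epoch in a seeded shuffled order; results are bitwise-reproducible
#' for a fixed `(cooc, config)`.
#'
#' @param cooc A [build_cooccurrence()] result with at least one nonzero
#'   off-diagonal entry.
#' @param config A [glove_config()].
#' @return An object of class `glove_model`: main/context vectors (`w`,
#'   `w_tilde`; ASV x property), biases (`b`, `b_tilde`), `loss_history`
#'   (objective value after each epoch), `asv_ids` and `config`.
#' @seealso [finalize_vectors()] to extract the embedding matrix.
#' @export
train_glove <- function(cooc, config = glove_config()) {
  stopifnot(inherits(cooc, "cooccurrence"), inherits(config, "glove_config"))
  pr <- glove_pairs(cooc)
  if (length(pr$x) == 0) {
    stop("co-occurrence matrix has no nonzero off-diagonal entry", call. = FALSE)
  }
  n <- ncol(cooc$X)
  d <- config$n_properties
  s <- config$init_scale
  set.seed(config$seed)
  w <- matrix(stats::runif(n * d, -s, s), n, d)
  wt <- matrix(stats::runif(n * d, -s, s), n, d)
  b <- stats::runif(n, -s, s)
  bt <- stats::runif(n, -s, s)
  fit <- .glove_train_cpp(pr$i - 1L, pr$j - 1L, pr$x, w, wt, b, bt,
                          config$x_max, config$alpha, config$learning_rate,
                          config$n_epochs)
  if (fit$diverged_epoch > 0) {
    stop("GloVe training diverged (non-finite loss) at epoch ",
         fit$diverged_epoch, "; lower the learning rate", call. = FALSE)
  }
  ids <- colnames(cooc$X)
  rownames(fit$w) <- rownames(fit$w_tilde) <- ids
  structure(
    list(w = fit$w, w_tilde = fit$w_tilde,
         b = stats::setNames(fit$b, ids), b_tilde = stats::setNames(fit$b_tilde, ids),
         loss_history = fit$loss_history, asv_ids = ids, config = config),
    class = "glove_model"
  )
}

#' @export
print.glove_model <- function(x, ...) {
  cat(sprintf(
    "<glove_model> %d ASVs, %d properties, %d epochs (final loss %.4g)\n",
    length(x$asv_ids), x$config$n_properties, length(x$loss_history),
    x$loss_history[length(x$loss_history)]
  ))
  invisible(x)
}

#' GloVe objective and analytic gradient at arbitrary parameters
#'
#' `glove_objective()` evaluates the training objective
#' `sum over ordered pairs (i, j), X[i,j] > 0 of
#'  f(X[i,j]) * (w_i . w~_j + b_i + b~_j - log X[i,j])^2`
#' at an arbitrary parameter point; `glove_gradient()` returns its exact
#' gradient with the same shapes as the parameters. Both are plain
#' (vectorized) R and serve verification, line searches and full-batch
#' descent; training itself uses the stochastic AdaGrad kernel.
#'
#' @param params List with matrices `w`, `w_tilde` (ASV x property) and
#'   vectors `b`, `b_tilde`.
#' @param cooc A [build_cooccurrence()] result.
#' @param x_max,alpha Weighting parameters, see [glove_weight()].
#' @return `glove_objective()`: a single non-negative number.
#'   `glove_gradient()`: list `w`, `w_tilde`, `b`, `b_tilde`.
#' @export
glove_objective <- function(params, cooc, x_max = 100, alpha = 0.75) {
  pr <- glove_pairs(cooc)
  i <- c(pr$i, pr$j); j <- c(pr$j, pr$i); x <- c(pr$x, pr$x)
  f <- glove_weight(x, x_max, alpha)
  diff <- rowSums(params$w[i, , drop = FALSE] * params$w_tilde[j, , drop = FALSE]) +
    params$b[i] + params$b_tilde[j] - log(x)
  sum(f * diff^2)
}

#' @rdname glove_objective
#' @export
glove_gradient <- function(params, cooc, x_max = 100, alpha = 0.75) {
  pr <- glove_pairs(cooc)
  i <- c(pr$i, pr$j); j <- c(pr$j, pr$i); x <- c(pr$x, pr$x)
  f <- glove_weight(x, x_max, alpha)
  diff <- rowSums(params$w[i, , drop = FALSE] * params$w_tilde[j, , drop = FALSE]) +
    params$b[i] + params$b_tilde[j] - log(x)
  n <- nrow(params$w)
  fd <- 2 * f * diff
  gw <- rowsum(fd * params$w_tilde[j, , drop = FALSE], i, reorder = FALSE)
  gwt <- rowsum(fd * params$w[i, , drop = FALSE], j, reorder = FALSE)
  gb <- rowsum(fd, i, reorder = FALSE)
  gbt <- rowsum(fd, j, reorder = FALSE)
  out <- list(
    w = matrix(0, n, ncol(params$w)), w_tilde = matrix(0, n, ncol(params$w)),
    b = numeric(n), b_tilde = numeric(n)
  )
  out$w[as.integer(rownames(gw)), ] <- gw
  out$w_tilde[as.integer(rownames(gwt)), ] <- gwt
  out$b[as.integer(rownames(gb))] <- gb
  out$b_tilde[as.integer(rownames(gbt))] <- gbt
  out
}

#' Training objective of a fitted model
#'
#' @param model A [train_glove()] result.
#' @param cooc The co-occurrence matrix it was trained on.
#' @inheritParams glove_objective
#' @return The objective value at the fitted parameters.
#' @export
glove_loss <- function(model, cooc, x_max = model$config$x_max,
                       alpha = model$config$alpha) {
  stopifnot(inherits(model, "glove_model"))
  glove_objective(model, cooc, x_max = x_max, alpha = alpha)
}

#' Extract the embedding (transformation) matrix from a fitted model
#'
#' The per-ASV property vector is the sum of main and context vectors
#' (`mode = "sum"`, the canonical GloVe recommendation for a symmetric
#' co-occurrence matrix) or the main vector alone (`mode = "main"`). Biases
#' are dropped.
#'
#' @param model A [train_glove()] result.
#' @param mode `"sum"` (default) or `"main"`.
#' @return An [asv_embedding()] with property columns `P1..Pk`.
#' @export
finalize_vectors <- function(model, mode = c("sum", "main")) {
  stopifnot(inherits(model, "glove_model"))
  mode <- match.arg(mode)
  v <- if (mode == "sum") model$w + model$w_tilde else model$w
  rownames(v) <- model$asv_ids
  colnames(v) <- paste0("P", seq_len(ncol(v)))
  asv_embedding(v)
}

#' Learn an embedding straight from a count table
#'
#' Convenience pipeline: optionally subset a seeded fraction of samples
#' (embeddings are typically learned on 85% of samples, leaving the rest
#' untouched for classifier testing), binarize to presence/absence, count
#' co-occurrences, train GloVe and return the embedding matrix.
#'
#' @param table A [sample_table()] (already filtered; see [filter_table()]).
#' @param config A [glove_config()].
#' @param train_fraction Optional fraction of samples (by count) used for
#'   co-occurrence counting; the split is by samples and seeded by
#'   `config$seed`. `NULL` uses all samples.
#' @param mode Passed to [finalize_vectors()].
#' @return List with `embedding` ([asv_embedding()]), `model`
#'   (`glove_model`), `cooccurrence`, and `training_samples` (IDs used).
#' @export
embed_table <- function(table, config = glove_config(), train_fraction = NULL,
                        mode = "sum") {
  stopifnot(inherits(table, "sample_table"))
  ids <- sample_ids(table)
  if (!is.null(train_fraction)) {
    stopifnot(train_fraction > 0, train_fraction <= 1)
    set.seed(config$seed)
    keep <- sort(sample.int(length(ids), round(train_fraction * length(ids))))
    table <- sample_table(table$counts[keep, , drop = FALSE])
    ids <- ids[keep]
  }
  cooc <- build_cooccurrence(to_presence(table))
  model <- train_glove(cooc, config)
  list(embedding = finalize_vectors(model, mode), model = model,
       cooccurrence = cooc, training_samples = ids)
}

#' @method tidy glove_model
#' @export
tidy.glove_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @method glance glove_model
#' @export
glance.glove_model <- function(x, ...) {
  tibble::tibble(
    n_asvs = length(x$asv_ids), n_properties = x$config$n_properties,
    n_epochs = length(x$loss_history),
    final_loss = x$loss_history[length(x$loss_history)],
    x_max = x$config$x_max, alpha = x$config$alpha,
    learning_rate = x$config$learning_rate, seed = x$config$seed
  )
}

#' Within- vs between-block cosine similarity of embedding vectors
#'
#' Summary used to assess structure recovery on communities with known
#' block membership: ASVs sharing a latent block should sit closer in
#' property space than ASVs from different blocks.
#'
#' @param embedding An [asv_embedding()].
#' @param blocks Block assignment, named by ASV ID (e.g. from
#'   [generate_community_table()]).
#' @return A one-row tibble with `within`, `between` (mean pairwise cosine
#'   similarities) and `gap = within - between`.
#' @export
block_cosine_separation <- function(embedding, blocks) {
  v <- unclass(embedding)
  blk <- blocks[rownames(v)]
  if (anyNA(blk)) stop("`blocks` must cover every embedding ASV", call. = FALSE)
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- 1
  sim <- tcrossprod(v / nrm)
  up <- upper.tri(sim)
  same <- outer(blk, blk, "==")
  tibble::tibble(
    within = mean(sim[same & up]),
    between = mean(sim[!same & up]),
    gap = mean(sim[same & up]) - mean(sim[!same & up])
  )
}
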