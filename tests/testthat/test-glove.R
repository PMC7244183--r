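test_that("weighting function caps at 1 and follows the power law", {
  expect_equal(glove_weight(100, x_max = 100), 1)
  expect_equal(glove_weight(250, x_max = 100), 1)
  expect_equal(glove_weight(0), 0)
  expect_equal(glove_weight(100 / 16, x_max = 100, alpha = 0.75), 16^(-0.75))
  expect_error(glove_weight(-1), "non-negative")
})

test_that("objective has the stated closed forms on single-pair instances", {
  one_pair <- function(x) {
    p <- matrix(0, 1, 2, dimnames = list("s1", c("a", "b")))
    cooc <- build_cooccurrence(p)
    cooc$X["a", "b"] <- cooc$X["b", "a"] <- x
    cooc$occ[] <- 1
    cooc
  }
  zero <- list(w = matrix(0, 2, 2), w_tilde = matrix(0, 2, 2),
               b = c(0, 0), b_tilde = c(0, 0))
  # X = 1: log 1 = 0, all parameters 0 -> loss 0
  expect_equal(glove_objective(zero, one_pair(1)), 0)
  # X = e: residual is exactly 1 per direction, so loss = 2 * f(e)
  expect_equal(glove_objective(zero, one_pair(exp(1))),
               2 * glove_weight(exp(1)))
})

test_that("objective equals a term-by-term brute-force sum", {
  cooc <- small_cooc(8, 25, seed = 5)
  pr <- random_params(8, 3, seed = 11)
  brute <- 0
  for (i in 1:8) {
    for (j in 1:8) {
      if (i == j || cooc$X[i, j] == 0) next
      diff <- sum(pr$w[i, ] * pr$w_tilde[j, ]) + pr$b[i] + pr$b_tilde[j] -
        log(cooc$X[i, j])
      brute <- brute + glove_weight(cooc$X[i, j]) * diff^2
    }
  }
  expect_equal(glove_objective(pr, cooc), brute, tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  cooc <- small_cooc(10, 30, seed = 3)
  eps <- 1e-6
  for (seed in 1:4) {
    pr <- random_params(10, 4, seed = seed)
    gr <- glove_gradient(pr, cooc)
    # probe a handful of coordinates in each parameter block
    set.seed(seed)
    for (probe in 1:5) {
      i <- sample(10, 1); d <- sample(4, 1)
      for (block in c("w", "w_tilde", "b", "b_tilde")) {
        up <- pr; dn <- pr
        if (block %in% c("w", "w_tilde")) {
          up[[block]][i, d] <- up[[block]][i, d] + eps
          dn[[block]][i, d] <- dn[[block]][i, d] - eps
          g <- gr[[block]][i, d]
        } else {
          up[[block]][i] <- up[[block]][i] + eps
          dn[[block]][i] <- dn[[block]][i] - eps
          g <- gr[[block]][i]
        }
        fd <- (glove_objective(up, cooc) - glove_objective(dn, cooc)) / (2 * eps)
        expect_equal(g, fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("full-batch gradient descent monotonically decreases the objective", {
  cooc <- small_cooc(10, 40, seed = 7)
  pr <- random_params(10, 4, seed = 2, scale = 0.1)
  losses <- numeric(40)
  step <- 1e-3
  for (it in seq_along(losses)) {
    losses[it] <- glove_objective(pr, cooc)
    g <- glove_gradient(pr, cooc)
    pr$w <- pr$w - step * g$w
    pr$w_tilde <- pr$w_tilde - step * g$w_tilde
    pr$b <- pr$b - step * g$b
    pr$b_tilde <- pr$b_tilde - step * g$b_tilde
  }
  expect_true(all(diff(losses) <= 0))
})

test_that("training is bitwise reproducible for a fixed seed and config", {
  cooc <- small_cooc(12, 40, seed = 8)
  cfg <- glove_config(n_properties = 5, n_epochs = 8, seed = 42)
  m1 <- train_glove(cooc, cfg)
  m2 <- train_glove(cooc, cfg)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$w_tilde, m2$w_tilde)
  expect_identical(m1$b, m2$b)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_length(m1$loss_history, 8)
  # a different seed gives different parameters
  m3 <- train_glove(cooc, glove_config(n_properties = 5, n_epochs = 8, seed = 43))
  expect_false(identical(m1$w, m3$w))
})

test_that("reported loss history matches the standalone objective", {
  cooc <- small_cooc(10, 30, seed = 4)
  model <- train_glove(cooc, glove_config(n_properties = 4, n_epochs = 6, seed = 1))
  expect_equal(glove_loss(model, cooc), model$loss_history[6], tolerance = 1e-12)
})

test_that("a 2-ASV single-pair instance is driven to near-zero loss", {
  p <- matrix(c(1, 1), 1, 2, dimnames = list("s1", c("a", "b")))
  cooc <- build_cooccurrence(p)
  cooc$X["a", "b"] <- cooc$X["b", "a"] <- 7
  cooc$occ[] <- 7
  model <- train_glove(cooc, glove_config(n_properties = 2, n_epochs = 300,
                                          learning_rate = 0.1, seed = 3))
  expect_lt(glove_loss(model, cooc), 1e-4)
})

test_that("objective is invariant to a joint permutation of ASVs", {
  cooc <- small_cooc(9, 30, seed = 6)
  pr <- random_params(9, 3, seed = 5)
  set.seed(1)
  perm <- sample(9)
  cooc_p <- cooc
  cooc_p$X <- cooc$X[perm, perm]
  cooc_p$occ <- cooc$occ[perm]
  pr_p <- list(w = pr$w[perm, ], w_tilde = pr$w_tilde[perm, ],
               b = pr$b[perm], b_tilde = pr$b_tilde[perm])
  expect_equal(glove_objective(pr, cooc), glove_objective(pr_p, cooc_p),
               tolerance = 1e-12)
})

test_that("finalized vectors follow the mode contract", {
  cooc <- small_cooc(6, 20, seed = 2)
  model <- train_glove(cooc, glove_config(n_properties = 3, n_epochs = 3, seed = 1))
  emb_sum <- finalize_vectors(model, "sum")
  emb_main <- finalize_vectors(model, "main")
  expect_equal(unclass(emb_sum), unname(model$w + model$w_tilde),
               ignore_attr = TRUE)
  expect_equal(unclass(emb_main), unname(model$w), ignore_attr = TRUE)
  expect_equal(nrow(emb_sum), ncol(cooc$X))
  expect_equal(colnames(emb_sum), c("P1", "P2", "P3"))
})

test_that("training rejects empty co-occurrence and records config", {
  p <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  cooc <- build_cooccurrence(p)  # never co-occur
  expect_error(train_glove(cooc, glove_config(n_properties = 2)),
               "no nonzero off-diagonal")
})

test_that("embedding a table on a seeded sample subset is reproducible", {
  cfg <- synth_config(n_samples = 60, n_asvs = 30, seed = 5)
  tab <- generate_community_table(cfg)$table
  r1 <- embed_table(tab, glove_config(n_properties = 4, n_epochs = 4, seed = 9),
                    train_fraction = 0.85)
  r2 <- embed_table(tab, glove_config(n_properties = 4, n_epochs = 4, seed = 9),
                    train_fraction = 0.85)
  expect_identical(r1$training_samples, r2$training_samples)
  expect_length(r1$training_samples, round(0.85 * 60))
  expect_identical(unclass(r1$embedding), unclass(r2$embedding))
})
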