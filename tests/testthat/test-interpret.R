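make_embedding_from <- function(m, asvs = NULL) {
  m <- as.matrix(m)
  if (!is.null(asvs)) rownames(m) <- asvs
  asv_embedding(m)
}

test_that("a property equal to a pathway indicator correlates at r = 1", {
  set.seed(1)
  n <- 40
  asvs <- sprintf("a%03d", 1:n)
  pw <- matrix(rbinom(n * 3, 1, 0.5), n, 3,
               dimnames = list(asvs, c("ko00001", "ko00002", "ko00003")))
  storage.mode(pw) <- "double"
  emb <- make_embedding_from(cbind(P1 = pw[, 2], P2 = rnorm(n)), asvs)
  r <- property_pathway_correlations(emb, pw)
  expect_equal(r["P1", "ko00002"], 1)
  expect_lt(abs(r["P2", "ko00002"]), 0.5)
})

test_that("constant pathway columns are flagged and scored 0", {
  n <- 20
  asvs <- sprintf("a%03d", 1:n)
  set.seed(2)
  pw <- cbind(ko1 = rep(1, n), ko2 = rbinom(n, 1, 0.5))
  rownames(pw) <- asvs
  emb <- random_embedding(n, 2)
  rownames(emb) <- asvs
  r <- property_pathway_correlations(emb, pw)
  expect_equal(unname(r[, "ko1"]), c(0, 0))
  expect_equal(attr(r, "constant_pathways"), "ko1")
})

test_that("permutation p-values respect the add-one floor", {
  # engineered observed max correlation of 1: no permutation ties it
  set.seed(3)
  n <- 60
  asvs <- sprintf("a%03d", 1:n)
  pwcol <- rbinom(n, 1, 0.5)
  pw <- cbind(ko1 = pwcol, ko2 = rbinom(n, 1, 0.5))
  rownames(pw) <- asvs
  emb <- make_embedding_from(cbind(P1 = pwcol), asvs)
  res <- max_correlation_permutation_test(emb, pw, n_permutations = 200, seed = 4)
  expect_equal(res$summary$p_value, 1 / 201)
  expect_true(all(res$summary$p_value >= 1 / 201 & res$summary$p_value <= 1))
})

test_that("the permutation test is calibrated when pathways are independent", {
  cfg <- synth_config(n_asvs = 200, n_samples = 2, n_pathways = 15,
                      pathway_block_fidelity = 0.5, seed = 11)
  blocks <- rep(1:2, length.out = 200)
  names(blocks) <- sprintf("a%03d", 1:200)
  pw <- generate_pathway_table(blocks, cfg)$pathways
  set.seed(12)
  k <- 40
  emb <- asv_embedding(matrix(rnorm(200 * k), 200, k,
                              dimnames = list(names(blocks), paste0("P", 1:k))))
  res <- max_correlation_permutation_test(emb, pw, n_permutations = 200, seed = 13)
  frac <- mean(res$summary$p_value <= 0.05)
  # exact binomial 99% band around 0.05 for k = 40 properties
  band <- qbinom(c(0.005, 0.995), k, 0.05) / k
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("permutation test is invariant to pathway column relabeling", {
  set.seed(5)
  n <- 50
  asvs <- sprintf("a%03d", 1:n)
  pw <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
               dimnames = list(asvs, paste0("ko", 1:4)))
  emb <- random_embedding(n, 3, seed = 6)
  rownames(emb) <- asvs
  r1 <- max_correlation_permutation_test(emb, pw, 100, seed = 7)
  r2 <- max_correlation_permutation_test(emb, pw[, c(3, 1, 4, 2)], 100, seed = 7)
  expect_equal(r1$summary$p_value, r2$summary$p_value)
  expect_equal(r1$summary$max_r, r2$summary$max_r)
})

test_that("variance explained is exact for linear properties and near the
           null expectation for noise", {
  set.seed(8)
  n <- 1000
  asvs <- sprintf("a%04d", 1:n)
  p <- 10
  pw <- matrix(rbinom(n * p, 1, 0.5), n, p,
               dimnames = list(asvs, paste0("ko", 1:p)))
  beta <- rnorm(p)
  exact <- drop(pw %*% beta) + 2
  noise <- rnorm(n)
  emb <- make_embedding_from(cbind(P1 = exact, P2 = noise), asvs)
  ve <- variance_explained(emb, pw)
  expect_equal(ve$r_squared[ve$property == "P1"], 1, tolerance = 1e-10)
  # null r^2 concentrates near p / (n - 1)
  expect_lt(abs(ve$r_squared[ve$property == "P2"] - p / (n - 1)), 4 * sqrt(2 * p) / n)
})

test_that("zero-variance properties give NA r^2 with a warning", {
  n <- 30
  asvs <- sprintf("a%03d", 1:n)
  set.seed(9)
  pw <- matrix(rbinom(n * 2, 1, 0.5), n, 2, dimnames = list(asvs, c("k1", "k2")))
  emb <- make_embedding_from(cbind(P1 = rep(2, n), P2 = rnorm(n)), asvs)
  expect_warning(ve <- variance_explained(emb, pw), "zero-variance")
  expect_true(is.na(ve$r_squared[ve$property == "P1"]))
  expect_false(is.na(ve$r_squared[ve$property == "P2"]))
})

test_that("Mantel test: identity gives r = 1 at the p floor; r agrees with
           vegan's implementation", {
  set.seed(10)
  d <- as.matrix(dist(matrix(rnorm(30), 10)))
  res <- mantel_test(d, d, n_permutations = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / 100)

  d2 <- as.matrix(dist(matrix(rnorm(30), 10)))
  ours <- mantel_test(d, d2, n_permutations = 999, seed = 2)
  veg <- vegan::mantel(d, d2, permutations = 999)
  expect_equal(ours$statistic, unname(veg$statistic), tolerance = 1e-12)
  # same statistic when arguments swap
  expect_equal(mantel_test(d2, d, 9, seed = 3)$statistic, ours$statistic)
  expect_error(mantel_test(d, d2[1:5, 1:5]), "size mismatch")
  dbad <- d; dbad[1, 2] <- dbad[1, 2] + 1
  expect_error(mantel_test(d, dbad), "symmetric")
})

test_that("Mantel p-values are calibrated under independence", {
  set.seed(11)
  pvals <- replicate(100, {
    d1 <- as.matrix(dist(matrix(rnorm(36), 12)))
    d2 <- as.matrix(dist(matrix(rnorm(36), 12)))
    mantel_test(d1, d2, n_permutations = 99,
                seed = sample.int(1e6, 1))$p_value
  })
  # P(p <= 0.05) is exactly 5/100 under exchangeability
  hits <- sum(pvals <= 0.05)
  band <- qbinom(c(0.005, 0.995), 100, 0.05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("property distances feed the Mantel comparison of the two
           property views", {
  cfg <- synth_config(n_samples = 120, n_asvs = 80, n_pathways = 12,
                      pathway_block_fidelity = 0.95, seed = 14)
  com <- generate_community_table(cfg)
  pw <- generate_pathway_table(com$block_assignment, cfg)$pathways
  emb <- embed_table(com$table,
                     glove_config(n_properties = 6, n_epochs = 10, seed = 14))$embedding
  d_asv <- property_distance(emb)
  d_pw <- property_distance(emb, pw, type = "pathway_correlation")
  expect_equal(dim(d_asv), c(6, 6))
  expect_equal(diag(d_pw), rep(0, 6), ignore_attr = TRUE)
  res <- mantel_test(d_asv, d_pw, n_permutations = 199, seed = 5)
  expect_gt(res$statistic, 0)  # shared block structure links the two views
})

test_that("association scores recover a single informative feature and
           reverse under label inversion", {
  set.seed(15)
  n <- 250
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(paste0("s", 1:n), paste0("P", 1:5)))
  y <- as.integer(x[, 3] + rnorm(n, 0, 0.5) > 0)
  sc <- association_score(x, y, n_folds = 3, n_trees = 40, seed = 1)
  expect_gt(sc$score[sc$property == "P3"], 0)
  expect_equal(max(abs(sc$score)), abs(sc$score[sc$property == "P3"]))
  expect_true(all(abs(sc$score) <= sc$n_trees_support * 3))

  inv <- association_score(x, 1L - y, n_folds = 3, n_trees = 40, seed = 1)
  expect_lt(inv$score[inv$property == "P3"], 0)
  expect_lt(cor(sc$score, inv$score), -0.9)

  # same forests, opposite orientation: near-exact mirror
  opp <- association_score(x, y, n_folds = 3, n_trees = 40, seed = 1,
                           case_class = "0")
  expect_lt(opp$score[opp$property == "P3"], 0)
})

test_that("a depth-1 stump splitting one feature scores +1 per case path", {
  # two clusters far apart: a 1-tree forest of depth 1 splits P1 once and
  # sends the high side to the case leaf
  x <- matrix(c(rep(0, 30), rep(10, 30)), ncol = 1,
              dimnames = list(paste0("s", 1:60), "P1"))
  y <- rep(c(0L, 1L), each = 30)
  rf <- ranger::ranger(x = as.data.frame(x), y = factor(y, levels = 0:1),
                       num.trees = 1, max.depth = 1, probability = TRUE,
                       seed = 1, num.threads = 1)
  ti <- ranger::treeInfo(rf, 1)
  bt <- taxaprop:::backtrace_tree(ti, "P1")
  expect_equal(unname(bt$score), 1)
})

test_that("pathway importance counts consistent properties per pathway", {
  corr <- structure(list(
    significant = list(P1 = c("ko1", "ko2"), P2 = c("ko1"), P3 = c("ko1", "ko3")),
    summary = tibble::tibble(property = c("P1", "P2", "P3"))
  ), class = "pathway_correlation")
  s1 <- structure(tibble::tibble(property = c("P1", "P2", "P3"),
                                 score = c(10, 9, -12),
                                 n_trees_support = c(5, 5, 5)),
                  class = c("association_score", class(tibble::tibble())))
  s2 <- structure(tibble::tibble(property = c("P1", "P2", "P3"),
                                 score = c(11, 3, -9),
                                 n_trees_support = c(5, 5, 5)),
                  class = c("association_score", class(tibble::tibble())))
  # consistent at threshold 8 in both datasets: P1 (+), P3 (-); P2 fails in s2
  out <- pathway_importance(list(s1, s2), corr, score_threshold = 8,
                            min_properties = 2)
  expect_equal(out$pathway, "ko1")
  expect_equal(out$n_properties, 2L)
  expect_setequal(out$properties[[1]], c("P1", "P3"))
  # min_properties = 1 admits the singletons
  out1 <- pathway_importance(list(s1, s2), corr, 8, min_properties = 1)
  expect_setequal(out1$pathway, c("ko1", "ko2", "ko3"))
  # nothing consistent -> empty with warning
  expect_warning(
    none <- pathway_importance(list(s1, s2), corr, score_threshold = 100),
    "no consistently predictive"
  )
  expect_equal(nrow(none), 0L)
})
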