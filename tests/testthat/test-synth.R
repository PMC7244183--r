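test_that("generators are pure functions of the config seed", {
  cfg <- synth_config(n_samples = 40, n_asvs = 20, seed = 3)
  c1 <- generate_community_table(cfg)
  c2 <- generate_community_table(cfg)
  expect_identical(c1$table$counts, c2$table$counts)
  expect_identical(c1$activity, c2$activity)
  expect_identical(generate_pathway_table(c1$block_assignment, cfg)$pathways,
                   generate_pathway_table(c2$block_assignment, cfg)$pathways)
  expect_identical(generate_labels(c1$activity, cfg),
                   generate_labels(c2$activity, cfg))
  expect_identical(ape::write.tree(generate_tree(c1$block_assignment, cfg)),
                   ape::write.tree(generate_tree(c2$block_assignment, cfg)))
  c3 <- generate_community_table(synth_config(n_samples = 40, n_asvs = 20, seed = 4))
  expect_false(identical(c1$table$counts, c3$table$counts))
})

test_that("generated tables satisfy the consuming type contracts", {
  cfg <- synth_config(n_samples = 50, n_asvs = 24, n_pathways = 8, seed = 7)
  com <- generate_community_table(cfg)
  expect_s3_class(com$table, "sample_table")
  expect_true(all(com$table$counts >= 0))
  expect_true(all(com$table$counts == floor(com$table$counts)))
  pw <- generate_pathway_table(com$block_assignment, cfg)
  expect_true(all(pw$pathways %in% 0:1))
  labels <- generate_labels(com$activity, cfg)
  expect_true(all(labels %in% 0:1))
  expect_equal(names(labels), sample_ids(com$table))
  tree <- generate_tree(com$block_assignment, cfg)
  expect_setequal(tree$tip.label, asv_ids(com$table))
  expect_true(all(tree$edge.length >= 0))
})

test_that("within-block co-occurrence exceeds between-block, matching the
           analytic expectation within 3 sigma", {
  cfg <- synth_config(n_samples = 400, n_asvs = 60, seed = 9)
  com <- generate_community_table(cfg)
  p <- to_presence(com$table)
  cooc <- build_cooccurrence(p)
  blk <- com$block_assignment
  same <- outer(blk, blk, "==") & upper.tri(cooc$X)
  diff <- outer(blk, blk, "!=") & upper.tri(cooc$X)
  rate_within <- mean(cooc$X[same]) / cfg$n_samples
  rate_between <- mean(cooc$X[diff]) / cfg$n_samples
  expect_gt(rate_within, rate_between)
  # analytic joint-presence probability for a pair sharing a block:
  # act * w^2 + (1 - act) * b^2, and for pairs in different blocks the four
  # activation combinations of the two blocks
  act <- cfg$block_activity_prob
  w <- cfg$within_block_presence_prob
  b <- cfg$between_block_presence_prob
  exp_within <- act * w^2 + (1 - act) * b^2
  exp_between <- (act * w + (1 - act) * b)^2
  # pair rates share samples, so the binding noise scale is the per-sample
  # binomial error, not the (much smaller) per-pair one
  se_w <- sqrt(exp_within * (1 - exp_within) / cfg$n_samples)
  se_b <- sqrt(exp_between * (1 - exp_between) / cfg$n_samples)
  expect_lt(abs(rate_within - exp_within), 3 * se_w)
  expect_lt(abs(rate_between - exp_between), 3 * se_b)
})

test_that("no-signal configurations carry no block information", {
  cfg <- synth_config(n_samples = 200, n_asvs = 40,
                      within_block_presence_prob = 0.3,
                      between_block_presence_prob = 0.3, seed = 11)
  com <- generate_community_table(cfg)
  p <- to_presence(com$table)
  blk <- com$block_assignment
  # presence rates are indistinguishable across blocks
  r1 <- mean(p[, blk == 1])
  r2 <- mean(p[, blk == 2])
  expect_lt(abs(r1 - r2), 0.02)
})

test_that("pathway fidelity interpolates from block indicator to noise", {
  blocks <- stats::setNames(rep(1:2, each = 25), sprintf("a%03d", 1:50))
  cfg1 <- synth_config(n_asvs = 50, n_pathways = 4,
                       pathway_block_fidelity = 1, seed = 5)
  pw1 <- generate_pathway_table(blocks, cfg1)
  for (p in colnames(pw1$pathways)) {
    expect_equal(unname(pw1$pathways[, p]),
                 as.numeric(blocks == pw1$pathway_block[p]))
  }
  cfg05 <- synth_config(n_asvs = 50, n_pathways = 40,
                        pathway_block_fidelity = 0.5, seed = 5)
  pw05 <- generate_pathway_table(blocks, cfg05)
  # correlation with the block indicator centers on zero
  cors <- apply(pw05$pathways, 2, function(v) suppressWarnings(cor(v, blocks == 1)))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.1)
})

test_that("label generation responds to the effect size as contracted", {
  cfg0 <- synth_config(n_samples = 600, n_asvs = 40, label_effect_size = 0,
                       seed = 13)
  com0 <- generate_community_table(cfg0)
  lab0 <- generate_labels(com0$activity, cfg0)
  expect_gt(mean(lab0), 0.4)
  expect_lt(mean(lab0), 0.6)
  # the latent score carries no signal for the labels
  expect_lt(auroc(com0$activity[, 1], lab0), 0.58)

  cfg_big <- synth_config(n_samples = 600, n_asvs = 40,
                          label_effect_size = 50, label_noise = 0, seed = 13)
  lab_big <- generate_labels(com0$activity, cfg_big)
  # labels become a near-deterministic threshold of block activity
  expect_gt(auroc(com0$activity[, 1], lab_big), 0.99)
})

test_that("tree leakage 0 makes blocks perfect clades; leakage 1 decouples
           the topology", {
  cfg <- synth_config(n_samples = 10, n_asvs = 30, tree_leakage = 0, seed = 15)
  blocks <- stats::setNames(rep(1:2, length.out = 30), sprintf("ASV%04d", 1:30))
  tr <- generate_tree(blocks, cfg)
  expect_true(ape::is.monophyletic(tr, names(blocks)[blocks == 1]))
  expect_true(ape::is.monophyletic(tr, names(blocks)[blocks == 2]))

  cfg1 <- synth_config(n_samples = 10, n_asvs = 30, tree_leakage = 1, seed = 16)
  tr1 <- generate_tree(blocks, cfg1)
  expect_setequal(tr1$tip.label, names(blocks))
  expect_false(ape::is.monophyletic(tr1, names(blocks)[blocks == 1]) &&
                 ape::is.monophyletic(tr1, names(blocks)[blocks == 2]))
})

test_that("counts conditional on presence are heavy-tailed positive integers", {
  cfg <- synth_config(n_samples = 100, n_asvs = 50, seed = 17)
  com <- generate_community_table(cfg)
  pos <- com$table$counts[com$table$counts > 0]
  expect_true(all(pos >= 1))
  expect_gt(max(pos), 10 * stats::median(pos))  # long right tail
})

test_that("generated sequences are valid nucleotides and seed-stable", {
  s1 <- generate_asv_sequences(c("x", "y"), length = 80, seed = 4)
  s2 <- generate_asv_sequences(c("x", "y"), length = 80, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(grepl("^[ACGT]{80}$", s1)))
})
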