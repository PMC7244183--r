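#' Configuration for the synthetic community generator
#'
#' Generates sample-by-ASV tables with latent block (community) structure:
#' each sample independently activates each block with probability
#' `block_activity_prob` (0.4 by default, giving overlapping communities
#' rather than pure clusters); ASVs of an active block are present with
#' probability `within_block_presence_prob`, all others with
#' `between_block_presence_prob`. Counts conditional on presence follow a
#' truncated log-series distribution (`count_theta`), the classic
#' heavy-tailed shape of amplicon abundances. A pathway table, phenotype
#' labels and a phylogeny can be generated with matching, tunable coupling
#' to the same blocks.
#'
#' @param n_samples,n_asvs,n_blocks Table dimensions and number of latent
#'   blocks.
#' @param within_block_presence_prob,between_block_presence_prob Presence
#'   probabilities for ASVs of active vs inactive/other blocks; signal
#'   configurations need within > between (defaults 0.9 / 0.05).
#' @param block_activity_prob Probability a sample activates a block.
#' @param n_pathways Number of pathways in [generate_pathway_table()].
#' @param pathway_block_fidelity Probability a pathway's presence follows
#'   its assigned block (0.5 = independent of block structure).
#' @param label_effect_size Log-odds of the case label per standard
#'   deviation of the latent disease-block activity score.
#' @param label_noise Standard deviation of extra Gaussian noise on the
#'   label log-odds.
#' @param tree_leakage Probability an ASV's tree position ignores its block
#'   (0 = blocks are perfect clades, 1 = topology unrelated to blocks).
#' @param count_theta Log-series parameter of counts given presence.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 500, n_asvs = 300, n_blocks = 2,
                         within_block_presence_prob = 0.9,
                         between_block_presence_prob = 0.05,
                         block_activity_prob = 0.4,
                         n_pathways = 30, pathway_block_fidelity = 0.9,
                         label_effect_size = 2, label_noise = 0.5,
                         tree_leakage = 0.2, count_theta = 0.95, seed = 1) {
  stopifnot(
    n_samples >= 2, n_asvs >= 2, n_blocks >= 1,
    within_block_presence_prob >= 0, within_block_presence_prob <= 1,
    between_block_presence_prob >= 0, between_block_presence_prob <= 1,
    block_activity_prob >= 0, block_activity_prob <= 1,
    pathway_block_fidelity >= 0, pathway_block_fidelity <= 1,
    tree_leakage >= 0, tree_leakage <= 1,
    count_theta > 0, count_theta < 1
  )
  structure(
    list(n_samples = as.integer(n_samples), n_asvs = as.integer(n_asvs),
         n_blocks = as.integer(n_blocks),
         within_block_presence_prob = within_block_presence_prob,
         between_block_presence_prob = between_block_presence_prob,
         block_activity_prob = block_activity_prob,
         n_pathways = as.integer(n_pathways),
         pathway_block_fidelity = pathway_block_fidelity,
         label_effect_size = label_effect_size, label_noise = label_noise,
         tree_leakage = tree_leakage, count_theta = count_theta,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# log-series counts on 1..kmax via inverse-CDF sampling
rlogseries <- function(n, theta, kmax = 10000L) {
  k <- seq_len(kmax)
  p <- theta^k / k
  cdf <- cumsum(p) / sum(p)
  findInterval(stats::runif(n), cdf) + 1L
}

#' Generate a synthetic community table with latent block structure
#'
#' @param config A [synth_config()].
#' @return A list of class `synthetic_community`: `table` (a
#'   [sample_table()]), `block_assignment` (named integer, ASV -> block),
#'   `active` (binary samples x blocks activation matrix), and `activity`
#'   (continuous samples x blocks latent scores: the realized fraction of
#'   each block's ASVs present in the sample).
#' @export
generate_community_table <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_asvs
  blocks <- rep(seq_len(config$n_blocks), length.out = m)
  asvs <- sprintf("ASV%04d", seq_len(m))
  samples <- sprintf("S%04d", seq_len(n))
  names(blocks) <- asvs

  active <- matrix(stats::rbinom(n * config$n_blocks, 1, config$block_activity_prob),
                   n, config$n_blocks,
                   dimnames = list(samples, paste0("block", seq_len(config$n_blocks))))
  p <- matrix(config$between_block_presence_prob, n, m, dimnames = list(samples, asvs))
  for (b in seq_len(config$n_blocks)) {
    on <- active[, b] == 1
    p[on, blocks == b] <- config$within_block_presence_prob
  }
  presence <- matrix(stats::rbinom(n * m, 1, p), n, m, dimnames = list(samples, asvs))
  counts <- presence
  npos <- sum(presence)
  counts[presence == 1] <- rlogseries(npos, config$count_theta)

  activity <- vapply(seq_len(config$n_blocks), function(b) {
    rowMeans(presence[, blocks == b, drop = FALSE])
  }, numeric(n))
  dimnames(activity) <- dimnames(active)

  structure(
    list(table = sample_table(counts), block_assignment = blocks,
         active = active, activity = activity, config = config),
    class = "synthetic_community"
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("<synthetic_community> %d samples x %d ASVs in %d blocks\n",
              nrow(x$table$counts), ncol(x$table$counts), x$config$n_blocks))
  invisible(x)
}

#' Generate a pathway table coupled to the community blocks
#'
#' Each pathway is assigned to a block; an ASV carries the pathway with
#' probability `pathway_block_fidelity` when it belongs to that block and
#' `1 - fidelity` otherwise. Fidelity 1 makes the pathway column the block
#' indicator exactly; fidelity 0.5 makes it independent of the blocks.
#'
#' @param block_assignment Named integer vector (ASV -> block), from
#'   [generate_community_table()].
#' @param config A [synth_config()].
#' @return A list: `pathways` (binary ASV x pathway matrix) and
#'   `pathway_block` (named integer, pathway -> block).
#' @export
generate_pathway_table <- function(block_assignment, config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  m <- length(block_assignment)
  pw_block <- rep(seq_len(config$n_blocks), length.out = config$n_pathways)
  pw_ids <- sprintf("ko%05d", seq_len(config$n_pathways))
  names(pw_block) <- pw_ids
  fid <- config$pathway_block_fidelity
  prob <- outer(block_assignment, pw_block,
                function(ab, pb) ifelse(ab == pb, fid, 1 - fid))
  presence <- matrix(stats::rbinom(length(prob), 1, prob), m, config$n_pathways,
                     dimnames = list(names(block_assignment), pw_ids))
  storage.mode(presence) <- "double"
  list(pathways = presence, pathway_block = pw_block)
}

#' Generate phenotype labels from latent block activity
#'
#' The designated disease block's activity column is standardized; the
#' case probability is `plogis(label_effect_size * z + label_noise * e)`
#' with `e ~ N(0, 1)`, and labels are Bernoulli draws. Effect size 0 gives
#' labels independent of the community; a large effect with no noise makes
#' the label an almost deterministic threshold of block activity.
#'
#' @param activity Continuous samples x blocks activity matrix from
#'   [generate_community_table()].
#' @param config A [synth_config()].
#' @param disease_block Column index of the designated disease block.
#' @return Named integer 0/1 labels with the disease block recorded in
#'   `attr(, "disease_block")`.
#' @export
generate_labels <- function(activity, config = synth_config(),
                            disease_block = 1) {
  stopifnot(inherits(config, "synth_config"),
            disease_block >= 1, disease_block <= ncol(activity))
  set.seed(config$seed + 2L)
  a <- activity[, disease_block]
  z <- if (stats::sd(a) > 0) (a - mean(a)) / stats::sd(a) else a * 0
  logit <- config$label_effect_size * z +
    config$label_noise * stats::rnorm(length(a))
  labels <- stats::rbinom(length(a), 1, stats::plogis(logit))
  names(labels) <- rownames(activity)
  attr(labels, "disease_block") <- disease_block
  labels
}

#' Generate a phylogeny that tracks the blocks imperfectly
#'
#' Builds a coalescent-style random subtree per block (unit height) and
#' joins the blocks on a backbone with long branches, so ASVs of a block
#' coalesce early. With probability `tree_leakage` an ASV's position is
#' drawn from a random block instead of its own: leakage 0 makes blocks
#' perfect clades, leakage 1 makes the topology unrelated to the true
#' assignment.
#'
#' @param block_assignment Named integer vector (ASV -> block).
#' @param config A [synth_config()].
#' @return An [ape::phylo] tree with one leaf per ASV.
#' @export
generate_tree <- function(block_assignment, config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 3L)
  eff <- block_assignment
  flip <- stats::runif(length(eff)) < config$tree_leakage
  eff[flip] <- sample(seq_len(config$n_blocks), sum(flip), replace = TRUE)
  sub_newick <- character(0)
  for (b in seq_len(config$n_blocks)) {
    tips <- names(eff)[eff == b]
    if (length(tips) == 0) next
    if (length(tips) == 1) {
      sub_newick <- c(sub_newick, sprintf("%s:1", tips))
    } else {
      tr <- ape::rcoal(length(tips), tip.label = sample(tips))
      tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
      nw <- ape::write.tree(tr)
      sub_newick <- c(sub_newick, sub(";$", ":1", nw))
    }
  }
  if (length(sub_newick) == 1) {
    full <- sub(":1$", ";", sub_newick)
  } else {
    full <- sub_newick[1]
    for (k in seq_along(sub_newick)[-1]) {
      full <- sprintf("(%s,%s):1", full, sub_newick[k])
    }
    full <- sub(":1$", ";", full)
  }
  ape::read.tree(text = full)
}

#' Random ASV representative sequences
#'
#' Uniform random nucleotide sequences, one per ASV, for exercising the
#' sequence-matching path on synthetic data.
#'
#' @param asv_ids Character vector of ASV IDs.
#' @param length Sequence length in nt (V4 amplicons are ~250 nt; tests use
#'   shorter).
#' @param seed Integer seed.
#' @return Named character vector of sequences.
#' @export
generate_asv_sequences <- function(asv_ids, length = 150, seed = 1) {
  set.seed(seed)
  seqs <- vapply(asv_ids, function(id) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- asv_ids
  seqs
}
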