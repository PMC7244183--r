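#' Hierarchical-clustering tree over ASVs in property space
#'
#' Computes pairwise cosine (default) or Euclidean distances between ASV
#' property vectors, clusters agglomeratively (average or complete
#' linkage), and returns the dendrogram as a rooted `phylo` tree whose node
#' depths are the merge heights: each leaf branch has length equal to its
#' parent's merge height and each internal branch the difference of merge
#' heights, so the tree is ultrametric and branch scores against it are
#' well defined. ASVs are ordered by ID before clustering, making the
#' output deterministic regardless of input row order (duplicate rows have
#' distance 0 and merge in ID order).
#'
#' @param embedding An [asv_embedding()] with at least 3 ASVs.
#' @param metric `"cosine"` (the usual convention for embedding vectors) or
#'   `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return An [ape::phylo] object with one leaf per ASV.
#' @export
property_tree <- function(embedding, metric = c("cosine", "euclidean"),
                          linkage = c("average", "complete")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  v <- unclass(embedding)
  if (nrow(v) < 3) stop("at least 3 ASVs required", call. = FALSE)
  v <- v[order(rownames(v)), , drop = FALSE]
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(v^2))
    nrm[nrm == 0] <- 1
    sim <- tcrossprod(v / nrm)
    d <- stats::as.dist(pmax(1 - sim, 0))
  } else {
    d <- stats::dist(v)
  }
  hc <- stats::hclust(d, method = linkage)
  hclust_to_phylo(hc)
}

# Dendrogram -> rooted phylo: node depth = merge height, leaf branch length
# = parent merge height, internal branch = difference of merge heights.
hclust_to_phylo <- function(hc) {
  n <- length(hc$labels)
  n_int <- n - 1L
  # merge m -> phylo node id: root (last merge) gets n+1, earlier merges
  # get increasing ids so that ids are unique in [n+1, 2n-1]
  merge_node <- (2L * n) - seq_len(n_int)   # merge 1 -> 2n-1, merge n-1 -> n+1
  edges <- matrix(0L, 2L * n_int, 2L)
  lengths <- numeric(2L * n_int)
  e <- 0L
  for (m in seq_len(n_int)) {
    for (side in 1:2) {
      child <- hc$merge[m, side]
      e <- e + 1L
      edges[e, 1] <- merge_node[m]
      if (child < 0) {
        edges[e, 2] <- -child
        lengths[e] <- hc$height[m]
      } else {
        edges[e, 2] <- merge_node[child]
        lengths[e] <- hc$height[m] - hc$height[child]
      }
    }
  }
  tr <- structure(
    list(edge = edges, edge.length = pmax(lengths, 0),
         Nnode = n_int, tip.label = hc$labels),
    class = "phylo"
  )
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

check_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  bad <- which(is.na(tree$edge.length))
  if (length(bad) > 0) {
    stop(sprintf("missing branch length on edge %d -> %d",
                 tree$edge[bad[1], 1], tree$edge[bad[1], 2]), call. = FALSE)
  }
}

#' Tip-to-tip path-length distances
#'
#' Sum of branch lengths along the path between every pair of leaves.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A symmetric leaf x leaf matrix with zero diagonal.
#' @export
tip_to_tip_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  check_branch_lengths(tree)
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

check_same_leaves <- function(t1, t2) {
  d1 <- sort(setdiff(t1$tip.label, t2$tip.label))
  d2 <- sort(setdiff(t2$tip.label, t1$tip.label))
  if (length(d1) > 0 || length(d2) > 0) {
    stop("leaf sets differ: only in first tree: {",
         paste(d1, collapse = ", "), "}; only in second tree: {",
         paste(d2, collapse = ", "), "}", call. = FALSE)
  }
}

#' Branch score (Kuhner-Felsenstein) distance between two trees
#'
#' Over the union of leaf bipartitions of both trees, sums the squared
#' differences of the associated branch lengths (0 for a bipartition a tree
#' lacks) and returns the square root. Identical trees give 0; the same
#' topology with one branch length perturbed by `delta` gives `delta`.
#'
#' @param t1,t2 `phylo` trees on identical leaf sets, with branch lengths.
#' @return A non-negative number.
#' @export
branch_score_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  check_branch_lengths(t1)
  check_branch_lengths(t2)
  as.numeric(phangorn::KF.dist(t1, t2, check.labels = TRUE))
}

#' Symmetric (Robinson-Foulds) distance between two trees
#'
#' Counts the nontrivial leaf bipartitions present in exactly one of the
#' two trees; always an even number for binary trees, bounded by
#' `2 * (n - 3)` on `n` shared leaves.
#'
#' @param t1,t2 `phylo` trees on identical leaf sets.
#' @return An even non-negative integer.
#' @export
symmetric_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Leaf-permutation test of tree similarity
#'
#' Computes the branch score and symmetric distances between a phylogenetic
#' tree and a (fixed) property tree, then builds null distributions by
#' shuffling the leaf labels of the phylogenetic tree `n_permutations`
#' times and recomputing both distances; branch lengths and topology stay
#' fixed, only labels move. Small distances mean similar trees, so the
#' one-sided p-value is the lower-tail add-one count
#' `p = (#\{null <= observed\} + 1) / (n_permutations + 1)`.
#'
#' @param phylo Phylogenetic `phylo` tree.
#' @param prop_tree Property-derived `phylo` tree ([property_tree()]) on
#'   the same leaves.
#' @param n_permutations Number of label shuffles (1000 is the standard
#'   protocol).
#' @param seed Integer seed.
#' @return An object of class `tree_distance_test`: list with
#'   `branch_score`, `symmetric`, `null_branch_scores`, `null_symmetric`,
#'   `p_branch`, `p_symmetric`, `n_permutations`.
#' @export
leaf_permutation_test <- function(phylo, prop_tree, n_permutations = 1000,
                                  seed = 1) {
  check_same_leaves(phylo, prop_tree)
  obs_bs <- branch_score_distance(phylo, prop_tree)
  obs_rf <- symmetric_distance(phylo, prop_tree)
  set.seed(seed)
  null_bs <- numeric(n_permutations)
  null_rf <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- phylo
    perm$tip.label <- sample(phylo$tip.label)
    null_bs[b] <- phangorn::KF.dist(perm, prop_tree, check.labels = TRUE)
    null_rf[b] <- phangorn::RF.dist(perm, prop_tree, check.labels = TRUE)
  }
  structure(
    list(branch_score = obs_bs, symmetric = obs_rf,
         null_branch_scores = null_bs, null_symmetric = null_rf,
         p_branch = (sum(null_bs <= obs_bs) + 1) / (n_permutations + 1),
         p_symmetric = (sum(null_rf <= obs_rf) + 1) / (n_permutations + 1),
         n_permutations = n_permutations),
    class = "tree_distance_test"
  )
}

#' @export
print.tree_distance_test <- function(x, ...) {
  cat(sprintf(
    "<tree_distance_test> branch score %.4g (p = %.3g), symmetric %d (p = %.3g); %d permutations\n",
    x$branch_score, x$p_branch, x$symmetric, x$p_symmetric, x$n_permutations
  ))
  invisible(x)
}

#' @method tidy tree_distance_test
#' @export
tidy.tree_distance_test <- function(x, ...) {
  tibble::tibble(
    distance = c("branch_score", "symmetric"),
    observed = c(x$branch_score, x$symmetric),
    null_mean = c(mean(x$null_branch_scores), mean(x$null_symmetric)),
    p_value = c(x$p_branch, x$p_symmetric),
    n_permutations = x$n_permutations
  )
}
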