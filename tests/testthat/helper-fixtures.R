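# Small builders shared across test files. Everything is generated in code;
# no fixture files.

toy_counts <- function() {
  matrix(c(0, 3, 1,
           2, 0, 5),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("S1", "S2"), c("A1", "A2", "A3")))
}

toy_table <- function() sample_table(toy_counts())

random_presence <- function(n_samples, n_asvs, p = 0.4, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_samples * n_asvs, 1, p), n_samples, n_asvs,
              dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                              sprintf("a%03d", seq_len(n_asvs))))
  m
}

# brute-force co-occurrence oracle: explicit double loop over ASV pairs and
# samples
brute_cooccurrence <- function(presence) {
  m <- ncol(presence)
  X <- matrix(0, m, m, dimnames = list(colnames(presence), colnames(presence)))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      for (s in seq_len(nrow(presence))) {
        if (presence[s, i] == 1 && presence[s, j] == 1) X[i, j] <- X[i, j] + 1
      }
    }
  }
  X
}

random_params <- function(n, d, seed = 1, scale = 0.5) {
  set.seed(seed)
  list(w = matrix(runif(n * d, -scale, scale), n, d),
       w_tilde = matrix(runif(n * d, -scale, scale), n, d),
       b = runif(n, -scale, scale),
       b_tilde = runif(n, -scale, scale))
}

small_cooc <- function(n_asvs = 10, n_samples = 30, seed = 2) {
  build_cooccurrence(random_presence(n_samples, n_asvs, p = 0.5, seed = seed))
}

random_embedding <- function(n_asvs = 12, k = 4, seed = 1) {
  set.seed(seed)
  asv_embedding(matrix(rnorm(n_asvs * k), n_asvs, k,
                       dimnames = list(sprintf("a%03d", seq_len(n_asvs)),
                                       paste0("P", seq_len(k)))))
}

# leaf bipartitions of an unrooted tree as canonical strings, with the
# branch length subtending each; brute force via edge removal
brute_bipartitions <- function(tree, nontrivial_only = TRUE) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  n <- length(tips)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    desc <- if (child <= n) tree$tip.label[child] else {
      tree$tip.label[phangorn::Descendants(tree, child, "tips")[[1]]]
    }
    side <- sort(desc)
    other <- setdiff(tips, side)
    if (nontrivial_only && (length(side) < 2 || length(other) < 2)) next
    key <- paste(sort(c(paste(side, collapse = ","),
                        paste(other, collapse = ",")))[1], collapse = "|")
    len <- if (is.null(tree$edge.length)) NA_real_ else tree$edge.length[e]
    out[[key]] <- sum(c(out[[key]], len))
  }
  out
}

brute_rf_distance <- function(t1, t2) {
  b1 <- names(brute_bipartitions(t1))
  b2 <- names(brute_bipartitions(t2))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

brute_branch_score <- function(t1, t2) {
  b1 <- brute_bipartitions(t1, nontrivial_only = FALSE)
  b2 <- brute_bipartitions(t2, nontrivial_only = FALSE)
  keys <- union(names(b1), names(b2))
  sq <- vapply(keys, function(k) {
    l1 <- if (is.null(b1[[k]])) 0 else b1[[k]]
    l2 <- if (is.null(b2[[k]])) 0 else b2[[k]]
    (l1 - l2)^2
  }, numeric(1))
  sqrt(sum(sq))
}

# brute-force tip-to-tip distance by path enumeration on the edge graph
brute_tip_distances <- function(tree) {
  n_nodes <- max(tree$edge)
  adj <- lapply(seq_len(n_nodes), function(i) list())
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- c(adj[[a]], list(c(b, w)))
    adj[[b]] <- c(adj[[b]], list(c(a, w)))
  }
  n <- length(tree$tip.label)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (start in seq_len(n)) {
    dist <- rep(NA_real_, n_nodes)
    dist[start] <- 0
    queue <- start
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (nb in adj[[u]]) {
        v <- nb[1]
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + nb[2]
          queue <- c(queue, v)
        }
      }
    }
    d[start, ] <- dist[seq_len(n)]
  }
  d
}
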