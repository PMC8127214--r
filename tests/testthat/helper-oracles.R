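# Independent reference implementations used to check the package against.
# These deliberately use the most literal/brute-force formulation available
# and share no code with the implementation under test.

# Brute-force BH step-up: find the largest k with p_(k) <= k * alpha / m by
# scanning all k, for every alpha on a fine grid; returned as adjusted
# values via the direct min-over-tail formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) {
    # adjusted value of the r-th smallest: min over j >= r of p_(j) * m / j
    vals <- vapply(r:m, function(j) p[o[j]] * m / j, 1)
    adj[o[r]] <- min(1, min(vals))
  }
  adj
}

# Literal stop rule: enumerate every root-to-leaf path and walk it from the
# root, computing U from scratch at every node.
oracle_propose <- function(tree, stats, t, p_thresh = 0.05) {
  u_of <- function(i) {
    B <- branch_set(tree, i)
    q <- ifelse(!is.na(stats$p[B]) & stats$p[B] <= t, stats$direction[B], 0L)
    abs(sum(q)) / length(B)
  }
  paths_to <- function(leaf) {
    path <- leaf
    while (!is.na(tree$parent[path[1L]])) path <- c(tree$parent[path[1L]], path)
    path
  }
  termini <- integer(0)
  for (leaf in seq_len(tree$K)) {
    path <- paths_to(leaf)
    stopped <- FALSE
    for (v in path) {
      p_v <- stats$p[v]
      if (u_of(v) == 1 && !is.na(p_v) && p_v < p_thresh) {
        termini <- c(termini, v)
        stopped <- TRUE
        break
      }
    }
    if (!stopped) termini <- c(termini, leaf)
  }
  sort(unique(termini))
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments.
oracle_ranksum <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  ranks <- rank(vals)
  obs <- sum(ranks[seq_along(x)])
  idx <- utils::combn(n, length(x))
  sums <- apply(idx, 2L, function(ii) sum(ranks[ii]))
  mu <- mean(sums)
  min(1, mean(abs(sums - mu) >= abs(obs - mu) - 1e-9))
}

# Random node stats for a tree: uniform p, random non-zero signs.
random_stats <- function(tree, feature = "abundance") {
  treepin:::new_node_stats(
    seq_len(tree$M), tree$labels, feature,
    p = runif(tree$M),
    direction = sample(c(-1L, 1L), tree$M, replace = TRUE))
}

# Hand-built node stats from explicit vectors.
make_stats <- function(tree, p, direction, feature = "abundance") {
  treepin:::new_node_stats(seq_len(tree$M), tree$labels, feature,
                           p = p, direction = as.integer(direction))
}

# Symmetric-Dirichlet control parameters over the leaves of a tree.
random_dm <- function(tree, theta = 0.02, depths = seq(10000, 50000, 1000)) {
  K <- tree$K
  pi <- rgamma(K, 2, 1)
  pi <- pi / sum(pi)
  names(pi) <- tree$labels[seq_len(K)]
  dm_params(pi, theta, depths)
}

# A branch pair whose masses differ enough to give a clear fold change;
# used where tests need coherent detectable signal rather than a random
# (possibly near-null) swap.
strong_branch_pair <- function(tree, params, min_leaves = 5, max_leaves = 10,
                               min_abs_log_r = 0.5) {
  pi <- treepin:::leaf_pi(tree, params)
  internal <- (tree$K + 1L):tree$M
  sizes <- lengths(tree$b[internal])
  ok <- internal[sizes >= min_leaves & sizes <= max_leaves]
  best <- NULL
  best_lr <- 0
  for (a in ok) for (b in ok) {
    if (a == b || any(tree$b[[a]] %in% tree$b[[b]])) next
    lr <- abs(log(sum(pi[tree$b[[b]]]) / sum(pi[tree$b[[a]]])))
    if (lr > best_lr) { best <- list(A = a, B = b); best_lr <- lr }
  }
  if (is.null(best) || best_lr < min_abs_log_r)
    stop("no strongly imbalanced branch pair in this tree draw")
  best
}
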