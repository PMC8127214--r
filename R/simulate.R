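# Dirichlet-multinomial (DM) count simulation with tree-located signal.
# Counts in a sample with depth n are drawn as p ~ Dirichlet(alpha),
# x ~ Multinomial(n, p), with alpha_k = pi_k * (1 - theta) / theta, where pi
# is the expected proportion vector over the K leaves and theta in (0, 1)
# controls overdispersion (theta -> 0 recovers the multinomial). Signal is
# introduced by modifying pi between a control and a treatment group on two
# selected branches, so that the relative abundance of unaffected leaves is
# unchanged; three scenarios are provided: BS (balanced: one fold change per
# branch), US (unbalanced: heterogeneous per-leaf fold changes in a shared
# direction), and SS (sporadic: only a subset of each branch changes).
#
# All random draws use R's global RNG; call set.seed() for reproducibility.

#' Dirichlet-multinomial parameters
#'
#' @param pi proportion vector over leaves (nonnegative, sums to 1; names are
#'   leaf labels).
#' @param theta overdispersion in (0, 1).
#' @param depths pool of candidate per-sample totals, resampled with
#'   replacement at simulation time.
#' @return An object of class `tpn_dm` with elements `pi`, `theta`, `alpha`,
#'   `depths`.
#' @export
dm_params <- function(pi, theta, depths) {
  nm <- names(pi)
  pi <- as.numeric(pi)
  names(pi) <- nm
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("`pi` must be nonnegative and sum to 1")
  if (theta <= 0 || theta >= 1) stop("`theta` must lie in (0, 1)")
  if (!length(depths) || any(depths < 0)) stop("invalid depth pool")
  structure(list(pi = pi, theta = theta,
                 alpha = pi * (1 - theta) / theta,
                 depths = as.numeric(depths)),
            class = "tpn_dm")
}

dm_loglik <- function(counts, alpha) {
  s <- sum(alpha)
  n <- colSums(counts)
  sum(lgamma(s) - lgamma(n + s)) +
    sum(lgamma(counts + alpha) - lgamma(alpha))
}

#' Estimate Dirichlet-multinomial parameters from a count table
#'
#' Maximum likelihood via the standard fixed-point iteration on the
#' alpha parameterization, started from moment estimates; convergence is
#' declared when successive log-likelihoods differ by less than `tol`.
#' The estimated overdispersion is clamped to `[1e-6, 1 - 1e-6]`: data with
#' no replicate variability drive theta to the lower clamp.
#'
#' @param counts K x J count matrix (rownames are leaf labels); every column
#'   must have a positive total.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return A `tpn_dm` whose depth pool is the observed column totals.
#' @export
estimate_dm <- function(counts, tol = 1e-8, max_iter = 500L) {
  stopifnot(is.matrix(counts))
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least 2 leaves and 2 samples")
  n <- colSums(counts)
  if (any(n == 0)) stop("every sample must have a positive total count")
  props <- sweep(counts, 2L, n, "/")
  pi0 <- rowMeans(props)
  pi0 <- pmax(pi0, 1e-10); pi0 <- pi0 / sum(pi0)
  # moment-based starting overdispersion from the proportion variances
  vk <- apply(props, 1L, stats::var)
  denom <- pi0 * (1 - pi0)
  theta0 <- stats::median(vk[denom > 0] / denom[denom > 0], na.rm = TRUE)
  theta0 <- min(max(theta0, 1e-4), 0.5)
  s <- (1 - theta0) / theta0
  alpha <- pi0 * s

  ll <- dm_loglik(counts, alpha)
  s_max <- (1 - 1e-6) / 1e-6
  for (it in seq_len(max_iter)) {
    s <- sum(alpha)
    num <- rowSums(digamma(counts + alpha)) - ncol(counts) * digamma(alpha)
    den <- sum(digamma(n + s)) - ncol(counts) * digamma(s)
    alpha_new <- alpha * num / den
    alpha_new[!is.finite(alpha_new) | alpha_new <= 0] <- 1e-10
    if (sum(alpha_new) > s_max) alpha_new <- alpha_new * s_max / sum(alpha_new)
    ll_new <- dm_loglik(counts, alpha_new)
    alpha <- alpha_new
    if (is.finite(ll_new) && abs(ll_new - ll) < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  s <- sum(alpha)
  theta <- min(max(1 / (1 + s), 1e-6), 1 - 1e-6)
  dm_params(alpha / s, theta, n)
}

#' Draw one Dirichlet-multinomial count vector
#'
#' `p ~ Dirichlet(alpha)` then `x ~ Multinomial(n, p)`; the result sums to
#' `n`. Reproducible under [set.seed()].
#'
#' @param n total count (nonnegative integer).
#' @param params a `tpn_dm`.
#' @return Integer count vector over the leaves (named like `params$pi`).
#' @export
sample_dm <- function(n, params) {
  stopifnot(inherits(params, "tpn_dm"))
  if (n < 0) stop("total count n must be nonnegative")
  K <- length(params$pi)
  if (n == 0) return(stats::setNames(integer(K), names(params$pi)))
  g <- stats::rgamma(K, shape = params$alpha, rate = 1)
  if (sum(g) == 0) g[which.max(params$alpha)] <- 1
  x <- as.integer(stats::rmultinom(1L, size = n, prob = g / sum(g)))
  stats::setNames(x, names(params$pi))
}

#' Pick two non-nested signal branches
#'
#' Samples uniformly among pairs of internal nodes that satisfy the leaf
#' count constraints, carry at least `min_prop` proportion mass, and have
#' disjoint leaf sets.
#'
#' @param tree a `tpn_tree`.
#' @param params a `tpn_dm` over the tree leaves.
#' @param min_leaves,max_leaves admissible branch sizes (in leaves).
#' @param min_prop minimum total proportion mass of a branch.
#' @return List with integer node ids `A` and `B`.
#' @export
pick_signal_branches <- function(tree, params, min_leaves = 5L,
                                 max_leaves = 10L, min_prop = 0) {
  stopifnot(inherits(tree, "tpn_tree"), inherits(params, "tpn_dm"))
  pi <- leaf_pi(tree, params)
  internal <- (tree$K + 1L):tree$M
  sizes <- lengths(tree$b[internal])
  mass <- vapply(tree$b[internal], function(b) sum(pi[b]), 1)
  ok <- internal[sizes >= min_leaves & sizes <= max_leaves & mass >= min_prop]
  if (length(ok) < 2L)
    stop("no feasible branch pair: fewer than 2 internal nodes with ",
         min_leaves, "-", max_leaves, " leaves and mass >= ", min_prop)
  pairs <- utils::combn(ok, 2L)
  disjoint <- apply(pairs, 2L, function(pr)
    !any(tree$b[[pr[1L]]] %in% tree$b[[pr[2L]]]))
  if (!any(disjoint))
    stop("no feasible branch pair: all admissible branches are nested")
  pick <- pairs[, sample(which(disjoint), 1L)]
  list(A = pick[1L], B = pick[2L])
}

# proportions aligned to leaf ids 1..K (pi may be named by leaf label)
leaf_pi <- function(tree, params) {
  pi <- params$pi
  if (!is.null(names(pi))) {
    idx <- match(tree$labels[seq_len(tree$K)], names(pi))
    if (anyNA(idx)) stop("`params$pi` names do not cover the tree leaves")
    pi <- pi[idx]
  } else if (length(pi) != tree$K) {
    stop("`params$pi` length does not match the number of leaves")
  }
  stats::setNames(as.numeric(pi), tree$labels[seq_len(tree$K)])
}

scenario_spec <- function(scenario, A, B, truth, extra = list()) {
  structure(c(list(scenario = scenario, A = A, B = B, truth = truth), extra),
            class = "tpn_scenario")
}

#' Balanced-signal (BS) scenario: swap branch proportions
#'
#' The treatment proportions multiply branch A by `r = mass(B) / mass(A)`
#' and divide branch B by the same `r`, swapping the total mass of the two
#' branches while leaving every other leaf untouched; every leaf within a
#' branch has the same fold change.
#'
#' @param params control `tpn_dm`.
#' @param A,B internal node ids of two disjoint branches.
#' @param tree a `tpn_tree`.
#' @return List with `params` (treatment `tpn_dm`) and `spec` (a
#'   `tpn_scenario` whose `truth` is a data.frame of leaf id, label and
#'   direction; empty when `r = 1`).
#' @export
apply_bs <- function(params, A, B, tree) {
  pi <- leaf_pi(tree, params)
  bA <- tree$b[[A]]; bB <- tree$b[[B]]
  if (length(intersect(bA, bB))) stop("branches A and B must be disjoint")
  mA <- sum(pi[bA]); mB <- sum(pi[bB])
  if (mA <= 0 || mB <= 0) stop("both branches must carry positive mass")
  r <- mB / mA
  piT <- pi
  piT[bA] <- pi[bA] * r
  piT[bB] <- pi[bB] / r
  dirA <- as.integer(sign(log(r)))
  truth_leaves <- if (r == 1) integer(0) else c(bA, bB)
  truth <- data.frame(
    leaf = truth_leaves,
    label = tree$labels[truth_leaves],
    direction = c(rep(dirA, if (r == 1) 0 else length(bA)),
                  rep(-dirA, if (r == 1) 0 else length(bB))),
    stringsAsFactors = FALSE)
  list(params = dm_params(piT, params$theta, params$depths),
       spec = scenario_spec("BS", A, B, truth, list(fold_change = r)))
}

#' Unbalanced-signal (US) scenario: heterogeneous fold changes
#'
#' Like [apply_bs()], but every leaf in a branch gets its own multiplier:
#' raw multipliers are drawn log-uniformly within one log unit of the
#' branch-level fold change and then rescaled so that the total mass moved
#' between the branches equals the balanced swap. Leaves in the same branch
#' share a direction whenever the rescaled multipliers stay on one side of
#' 1; directions are recorded from the realized multipliers.
#'
#' @inheritParams apply_bs
#' @return As [apply_bs()]; the scenario records the realized per-leaf
#'   multipliers.
#' @export
apply_us <- function(params, A, B, tree) {
  pi <- leaf_pi(tree, params)
  bA <- tree$b[[A]]; bB <- tree$b[[B]]
  if (length(intersect(bA, bB))) stop("branches A and B must be disjoint")
  mA <- sum(pi[bA]); mB <- sum(pi[bB])
  if (mA <= 0 || mB <= 0) stop("both branches must carry positive mass")
  r <- mB / mA
  draw <- function(base_log_fc, leaves, target_mass) {
    m <- exp(stats::runif(length(leaves), base_log_fc - 1, base_log_fc + 1))
    m * target_mass / sum(m * pi[leaves])
  }
  mAvec <- draw(log(r), bA, mB)    # branch A takes over B's mass
  mBvec <- draw(-log(r), bB, mA)   # and vice versa
  piT <- pi
  piT[bA] <- pi[bA] * mAvec
  piT[bB] <- pi[bB] * mBvec
  truth <- data.frame(
    leaf = c(bA, bB),
    label = tree$labels[c(bA, bB)],
    direction = as.integer(sign(log(c(mAvec, mBvec)))),
    stringsAsFactors = FALSE)
  truth <- truth[truth$direction != 0L, , drop = FALSE]
  list(params = dm_params(piT, params$theta, params$depths),
       spec = scenario_spec("US", A, B, truth,
                            list(multipliers = c(mAvec, mBvec),
                                 fold_change = r)))
}

#' Sporadic-signal (SS) scenario: only subsets of the branches change
#'
#' Random subsets of the two branches (a `fraction` of each, rounded up) are
#' selected and their mass is swapped exactly as in [apply_bs()] restricted
#' to the subsets; all other leaves, including the unselected leaves inside
#' A and B, keep their control proportions exactly. With `fraction = 1` the
#' output equals [apply_bs()].
#'
#' @inheritParams apply_bs
#' @param fraction share of each branch's leaves that changes, in (0, 1].
#' @return As [apply_bs()]; `truth` contains only the affected subsets.
#' @export
apply_ss <- function(params, A, B, tree, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must lie in (0, 1]")
  pi <- leaf_pi(tree, params)
  bA <- tree$b[[A]]; bB <- tree$b[[B]]
  if (length(intersect(bA, bB))) stop("branches A and B must be disjoint")
  nA <- ceiling(fraction * length(bA)); nB <- ceiling(fraction * length(bB))
  if (nA < 1L || nB < 1L) stop("affected subset is empty")
  sA <- sort(sample(bA, nA)); sB <- sort(sample(bB, nB))
  mA <- sum(pi[sA]); mB <- sum(pi[sB])
  if (mA <= 0 || mB <= 0) stop("selected subsets must carry positive mass")
  r <- mB / mA
  piT <- pi
  piT[sA] <- pi[sA] * r
  piT[sB] <- pi[sB] / r
  dirA <- as.integer(sign(log(r)))
  truth_leaves <- if (r == 1) integer(0) else c(sA, sB)
  truth <- data.frame(
    leaf = truth_leaves,
    label = tree$labels[truth_leaves],
    direction = c(rep(dirA, if (r == 1) 0 else length(sA)),
                  rep(-dirA, if (r == 1) 0 else length(sB))),
    stringsAsFactors = FALSE)
  list(params = dm_params(piT, params$theta, params$depths),
       spec = scenario_spec("SS", A, B, truth,
                            list(S_A = sA, S_B = sB, fold_change = r,
                                 fraction = fraction)))
}

#' Simulate a two-group count dataset
#'
#' Draws `nC` control and `nT` treatment samples from the control and
#' treatment DM parameters, with per-sample depths resampled with
#' replacement from the control depth pool.
#'
#' @param tree a `tpn_tree` (provides leaf labels and count ordering).
#' @param params_c control `tpn_dm`.
#' @param scenario output of [apply_bs()], [apply_us()] or [apply_ss()] (its
#'   `params` element is used for the treatment group), or `NULL` for a null
#'   dataset (treatment = control).
#' @param nC,nT samples per group.
#' @return List with `counts` (K x (nC+nT) matrix, leaf labels as rownames),
#'   `groups` (factor with levels C, T), and `truth` (data.frame of DA
#'   leaves; empty for a null dataset).
#' @export
simulate_dataset <- function(tree, params_c, scenario = NULL, nC = 10L, nT = 10L) {
  stopifnot(inherits(tree, "tpn_tree"), inherits(params_c, "tpn_dm"))
  piC <- leaf_pi(tree, params_c)
  pC <- dm_params(piC, params_c$theta, params_c$depths)
  pT <- if (is.null(scenario)) pC else {
    piT <- leaf_pi(tree, scenario$params)
    dm_params(piT, scenario$params$theta, params_c$depths)
  }
  J <- nC + nT
  depths <- sample(params_c$depths, J, replace = TRUE)
  counts <- matrix(0L, nrow = tree$K, ncol = J,
                   dimnames = list(tree$labels[seq_len(tree$K)],
                                   c(paste0("C", seq_len(nC)),
                                     paste0("T", seq_len(nT)))))
  for (j in seq_len(nC)) counts[, j] <- sample_dm(depths[j], pC)
  for (j in seq_len(nT)) counts[, nC + j] <- sample_dm(depths[nC + j], pT)
  truth <- if (is.null(scenario))
    data.frame(leaf = integer(0), label = character(0),
               direction = integer(0), stringsAsFactors = FALSE)
  else scenario$spec$truth
  list(counts = counts,
       groups = factor(rep(c("C", "T"), c(nC, nT)), levels = c("C", "T")),
       truth = truth)
}

#' Random binary tree by sequential coalescence
#'
#' Starts from K labeled leaves and repeatedly joins two uniformly chosen
#' active roots until one root remains, giving a random binary topology with
#' `M = 2K - 1` nodes. Reproducible under [set.seed()].
#'
#' @param K number of leaves (at least 2).
#' @param labels optional leaf labels; default `leaf_1..leaf_K`.
#' @return A `tpn_tree`.
#' @export
synthetic_tree <- function(K, labels = NULL) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("K must be at least 2")
  if (is.null(labels)) labels <- paste0("leaf_", seq_len(K))
  stopifnot(length(labels) == K)
  M <- 2L * K - 1L
  parent <- rep(NA_integer_, M)
  active <- seq_len(K)
  nxt <- K
  while (length(active) > 1L) {
    pair <- sample(active, 2L)
    nxt <- nxt + 1L
    parent[pair] <- nxt
    active <- c(setdiff(active, pair), nxt)
  }
  labs <- c(labels, paste0("node_", (K + 1L):M))
  new_tree(parent, labs,
           label_auto = c(rep(FALSE, K), rep(TRUE, M - K)))
}
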