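# Candidate proposal. For a tuning value t in [0, 1], each node k gets a
# signed significance score q_k(t) = sign(theta_k) * I(p_k <= t) and each
# node i a coherence score U_i(t) = |sum of q over B(i)| / |B(i)|. U_i(t)
# reaches 1 exactly when every node in the branch below (and including) i is
# significant at t with one shared direction. A candidate at t is obtained
# by climbing from the root toward the leaves and stopping, on each path, at
# the first node with U_i(t) = 1 and p_i below an admission threshold
# (default 0.05), or at the leaf.

check_t <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("tuning value t must be a single number in [0, 1]")
  t
}

#' Signed significance score q
#'
#' `q = direction * I(p <= t)`; a missing p-value yields 0. Vectorized over
#' `p` and `direction`.
#'
#' @param p p-value(s) in \[0, 1\] (NA allowed).
#' @param direction direction sign(s) in \{-1, 0, +1\}.
#' @param t tuning value in \[0, 1\].
#' @return Integer vector of scores in \{-1, 0, +1\}.
#' @export
q_score <- function(p, direction, t) {
  check_t(t)
  ifelse(!is.na(p) & p <= t, as.integer(direction), 0L)
}

#' Branch coherence score U
#'
#' `U_i(t) = |sum over k in B(i) of q_k(t)| / |B(i)|`. Equals 1 iff every
#' node in the branch set B(i) has p <= t and all share one non-zero
#' direction; a single leaf with p <= t and non-zero sign scores 1. Nodes
#' with missing statistics contribute q = 0 but still count in |B(i)|, which
#' keeps U below 1 on branches with unusable nodes.
#'
#' @param tree a `tpn_tree`.
#' @param stats node stats for a single feature (data.frame covering all M
#'   nodes).
#' @param i node id.
#' @param t tuning value in \[0, 1\].
#' @return U score in \[0, 1\].
#' @export
u_score <- function(tree, stats, i, t) {
  stopifnot(inherits(tree, "tpn_tree"))
  s <- stats_by_feature(stats, tree)
  if (length(s) != 1L) stop("u_score expects stats for a single feature")
  s <- s[[1L]]
  B <- branch_set(tree, i)
  q <- q_score(s$p[B], s$direction[B], t)
  abs(sum(q)) / length(B)
}

#' Propose the candidate at tuning value t
#'
#' Depth-first climb from the root: on every root-to-leaf path the terminus
#' is the first node i with `U_i(t) = 1` and `p_i < p_thresh`, or the leaf if
#' no such node appears. The termini are mutually non-nested and their
#' descendant-leaf sets partition the leaves. The admission threshold on the
#' node's own p-value keeps candidates near the leaf level in branches
#' without signal: a three-leaf null branch is represented by its internal
#' node with probability about 0.25 * p_thresh.
#'
#' @param tree a `tpn_tree`.
#' @param stats node stats for a single feature.
#' @param t tuning value in \[0, 1\].
#' @param p_thresh admission threshold for an internal terminus (default
#'   0.05, a fixed constant of the method).
#' @return An object of class `tpn_candidate`: list with `t`, `nodes`
#'   (terminus ids), `feature`, and `provenance` (data.frame feature x node).
#' @export
propose_candidate <- function(tree, stats, t, p_thresh = 0.05) {
  check_t(t)
  stopifnot(inherits(tree, "tpn_tree"))
  s <- stats_by_feature(stats, tree)
  if (length(s) != 1L) stop("propose_candidate expects stats for a single feature")
  feature <- names(s)
  s <- s[[1L]]

  q <- q_score(s$p, s$direction, t)
  # subtree sums of q in one postorder sweep; U_i = 1 iff |sum| == |B(i)|
  qsum <- numeric(tree$M)
  nB <- lengths(tree$B)
  for (v in tree$postorder) {
    kids <- tree$children[[v]]
    qsum[v] <- q[v] + if (length(kids)) sum(qsum[kids]) else 0
  }
  u_is_one <- abs(qsum) == nB
  ok_p <- !is.na(s$p) & s$p < p_thresh

  termini <- integer(0)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= tree$K || (u_is_one[v] && ok_p[v])) {
      termini <- c(termini, v)
    } else {
      stack <- c(stack, tree$children[[v]])
    }
  }
  termini <- sort(termini)
  structure(list(t = t, nodes = termini, feature = feature,
                 provenance = data.frame(feature = feature, node_id = termini,
                                         stringsAsFactors = FALSE)),
            class = "tpn_candidate")
}

#' @export
print.tpn_candidate <- function(x, ...) {
  cat(sprintf("Candidate at t = %g (%s): %d termini\n",
              x$t, paste(unique(x$provenance$feature), collapse = "+"),
              nrow(x$provenance)))
  invisible(x)
}

#' Default grid of tuning values
#'
#' `{0, 0.01, 0.02, 0.03, 0.04}` followed by `0.05, 0.10, ..., 1` — a fixed,
#' strictly increasing 25-value grid. t = 0 (which proposes the leaf-level
#' candidate whenever all p-values are positive) and t = 1 are always
#' included.
#'
#' @return Numeric vector of tuning values.
#' @export
default_t_grid <- function() {
  c(0, 0.01, 0.02, 0.03, 0.04, seq(0.05, 1, by = 0.05))
}

#' Pool per-feature candidates into a global candidate
#'
#' In differential-state analysis each feature climbs the tree independently;
#' the global candidate at t is the union of the per-feature termini, with
#' provenance recording which nodes terminate which feature. The pooled node
#' set may contain nested nodes across features; each per-feature list stays
#' non-nested.
#'
#' @param per_feature list of `tpn_candidate` objects sharing the same t.
#' @return A pooled `tpn_candidate` with feature tag `"global"`.
#' @export
pool_candidates <- function(per_feature) {
  stopifnot(length(per_feature) >= 1L,
            all(vapply(per_feature, inherits, TRUE, "tpn_candidate")))
  ts <- vapply(per_feature, function(cd) cd$t, 1)
  if (length(unique(ts)) != 1L)
    stop("all candidates must share the same tuning value t")
  prov <- do.call(rbind, lapply(per_feature, function(cd) cd$provenance))
  rownames(prov) <- NULL
  structure(list(t = ts[[1L]], nodes = sort(unique(prov$node_id)),
                 feature = "global", provenance = prov),
            class = "tpn_candidate")
}
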