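# Leaf-level confusion metrics and the repetition-level benchmarking loop.
# Every rejected internal node is expanded to its descendant leaves before
# scoring, so methods reporting at different resolutions are compared on a
# common footing.

#' Leaf-level confusion summary
#'
#' Expands a selection (or an explicit set of called leaves) to leaf level
#' and scores it against a set of truly differential leaves. The FDR of an
#' empty call set is defined as 0, matching the convention used for methods
#' that reject nothing.
#'
#' @param result a `tpn_selection`, or an integer/character vector of called
#'   leaves (ids or labels).
#' @param truth integer/character vector of truly differential leaves.
#' @param tree a `tpn_tree`.
#' @return data.frame with columns `TP`, `FP`, `FN`, `TPR`, `FDR` (one row).
#'   `TPR` is `NA` when `truth` is empty.
#' @export
leaf_confusion <- function(result, truth, tree) {
  stopifnot(inherits(tree, "tpn_tree"))
  as_leaf_ids <- function(x) {
    if (is.character(x)) return(match_leaves(tree, x))
    x <- as.integer(x)
    if (any(is.na(x) | x < 1L | x > tree$K))
      stop("leaf ids must lie in 1..K")
    x
  }
  called <- if (inherits(result, "tpn_selection"))
    result$rejected_leaves else as_leaf_ids(result)
  truth <- as_leaf_ids(truth)
  called <- unique(called); truth <- unique(truth)
  TP <- length(intersect(called, truth))
  FP <- length(setdiff(called, truth))
  FN <- length(setdiff(truth, called))
  data.frame(TP = TP, FP = FP, FN = FN,
             TPR = if (length(truth)) TP / (TP + FN) else NA_real_,
             FDR = if (length(called)) FP / (TP + FP) else 0)
}

#' Leaf-level BH comparator
#'
#' The tree-free baseline: BH correction applied to the leaf p-values only,
#' rejecting leaves with adjusted p at most alpha.
#'
#' @param stats node stats for a single feature.
#' @param tree a `tpn_tree`.
#' @param alpha nominal FDR.
#' @return Integer vector of rejected leaf ids.
#' @export
bh_leaf_calls <- function(stats, tree, alpha = 0.05) {
  s <- stats_by_feature(stats, tree)
  if (length(s) != 1L) stop("bh_leaf_calls expects stats for a single feature")
  s <- s[[1L]]
  leaf_p <- s$p[seq_len(tree$K)]
  adj <- bh_adjust(leaf_p)
  which(!is.na(adj) & adj <= alpha)
}

#' Benchmark tree-climbing against leaf-level BH on simulated data
#'
#' Runs `reps` independent repetitions of: simulate a two-group DM dataset
#' under the requested scenario, analyze it with the full tree-climbing
#' pipeline and with leaf-level BH at each FDR cutoff, and score both at leaf
#' level against the simulated truth. Per-repetition seeds are derived
#' deterministically from `seed`, so the output table is reproducible
#' bit-for-bit.
#'
#' @param tree a `tpn_tree`.
#' @param params_c control `tpn_dm`.
#' @param scenario `"BS"`, `"US"`, `"SS"`, or `"null"` (no signal).
#' @param reps number of repetitions (0 gives an empty table).
#' @param nC,nT samples per group.
#' @param alphas FDR cutoffs to impose.
#' @param engine node-test engine passed to [treeclimb_run()].
#' @param seed master seed.
#' @param min_leaves,max_leaves signal-branch size constraints.
#' @param fraction affected share for the SS scenario.
#' @param fixed_branches optional list with ids `A`, `B` to reuse across
#'   repetitions instead of sampling new branches each time.
#' @param scoring_tree optional `tpn_tree` used for the analysis in place of
#'   the simulation tree (with the same leaf labels); supplying an unrelated
#'   random tree turns any scenario into an uninformative-tree negative
#'   control where the signal leaves are scattered.
#' @return List with `results` (long-format data.frame: rep, method, alpha,
#'   TP, FP, FN, TPR, FDR) and `summary` (per method x alpha means with
#'   Monte-Carlo standard errors).
#' @export
benchmark <- function(tree, params_c, scenario = c("BS", "US", "SS", "null"),
                      reps = 50L, nC = 10L, nT = 10L, alphas = 0.05,
                      engine = "nb", seed = 1L, min_leaves = 5L,
                      max_leaves = 10L, fraction = 0.5,
                      fixed_branches = NULL, scoring_tree = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(tree, "tpn_tree"), inherits(params_c, "tpn_dm"))
  analysis_tree <- if (is.null(scoring_tree)) tree else scoring_tree
  rows <- list()
  for (rep_i in seq_len(reps)) {
    set.seed(seed + 7919L * rep_i)
    sc <- if (scenario == "null") NULL else {
      br <- if (is.null(fixed_branches))
        pick_signal_branches(tree, params_c, min_leaves, max_leaves)
      else fixed_branches
      switch(scenario,
             BS = apply_bs(params_c, br$A, br$B, tree),
             US = apply_us(params_c, br$A, br$B, tree),
             SS = apply_ss(params_c, br$A, br$B, tree, fraction = fraction))
    }
    dat <- simulate_dataset(tree, params_c, sc, nC = nC, nT = nT)
    truth_labels <- dat$truth$label
    agg <- aggregate_da(analysis_tree, dat$counts, fun = "sum")
    stats <- if (engine == "nb")
      nb_glm_node_test(agg, dat$groups)
    else wilcoxon_node_test(agg, dat$groups, normalize = TRUE)
    by_feat <- stats_by_feature(stats, analysis_tree)[[1L]]
    for (a in alphas) {
      evals <- lapply(default_t_grid(), function(t)
        evaluate_candidate(propose_candidate(analysis_tree, by_feat, t),
                           stats, analysis_tree, alpha = a))
      sel <- select_candidate(evals)
      called_tc <- analysis_tree$labels[sel$rejected_leaves]
      called_bh <- analysis_tree$labels[bh_leaf_calls(stats, analysis_tree, a)]
      for (meth in c("treeclimb", "BH")) {
        called <- if (meth == "treeclimb") called_tc else called_bh
        cs <- leaf_confusion(if (length(called)) called else integer(0),
                             truth_labels, analysis_tree)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(rep = rep_i, method = meth, alpha = a,
                           stringsAsFactors = FALSE), cs)
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows)
  else data.frame(rep = integer(0), method = character(0), alpha = numeric(0),
                  TP = integer(0), FP = integer(0), FN = integer(0),
                  TPR = numeric(0), FDR = numeric(0))
  summary <- if (nrow(results)) {
    ag <- stats::aggregate(cbind(TPR, FDR) ~ method + alpha, data = results,
                           FUN = mean, na.action = stats::na.omit)
    se <- stats::aggregate(cbind(TPR, FDR) ~ method + alpha, data = results,
                           FUN = function(v) stats::sd(v) / sqrt(length(v)),
                           na.action = stats::na.omit)
    names(ag)[3:4] <- c("mean_TPR", "mean_FDR")
    ag$se_TPR <- se$TPR; ag$se_FDR <- se$FDR
    ag
  } else NULL
  list(results = results, summary = summary)
}
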