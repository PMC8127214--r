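# Candidate evaluation and selection. Each candidate is corrected for
# multiplicity on its own (BH within the candidate), rejected internal nodes
# propagate to all their descendant leaves, and the tuning value t is
# restricted to [0, 2 * alpha * (r_hat - 1)] where r_hat estimates the mean
# signal-branch size (in leaves) from the candidate's own rejections. Among
# admissible candidates the winner maximizes the number of rejected leaves,
# then minimizes the number of rejected nodes, then takes the smallest t.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjusted values (monotone, capped at 1); rejecting hypotheses with
#' adjusted value at most alpha controls the FDR at alpha. Missing p-values
#' are returned as missing and do not count toward the number of hypotheses.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Upper bound of the admissible tuning range
#'
#' `2 * alpha * (r - 1)`, clipped at 1, where r is the mean size in leaves of
#' the signal branches detected at FDR alpha. At r = 1 signals do not cluster
#' on the tree and the bound collapses to 0: only the leaf level is
#' admissible.
#'
#' @param alpha nominal FDR, in (0, 1).
#' @param r mean signal-branch size, at least 1.
#' @return Upper bound for t, in \[0, 1\].
#' @export
t_upper <- function(alpha, r) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(r) || is.na(r) || r < 1)
    stop("mean signal-branch size r must be >= 1")
  min(2 * alpha * (r - 1), 1)
}

#' Evaluate a candidate at FDR level alpha
#'
#' Applies BH across the candidate's hypothesis list (node-feature pairs for
#' pooled candidates, so the FDR is controlled globally across features) and
#' summarizes the rejections: `m` testable hypotheses, `R` rejected
#' hypotheses, `R_L` unique descendant leaves of rejected nodes, `s` distinct
#' rejected nodes, `l` unique descendant leaves of those nodes, and
#' `r_hat = l / s` (defined as 1 when nothing is rejected). The candidate is
#' admissible when `t <= 2 * alpha * (r_hat - 1)`; t = 0 is always
#' admissible. Hypotheses with missing p-values (possible for leaf termini
#' under an incomplete external engine) are never rejected and do not count
#' in `m`.
#'
#' @param candidate a `tpn_candidate`.
#' @param stats node stats covering the candidate's features.
#' @param tree a `tpn_tree`.
#' @param alpha nominal FDR in (0, 1).
#' @return An object of class `tpn_evaluation`.
#' @export
evaluate_candidate <- function(candidate, stats, tree, alpha = 0.05) {
  stopifnot(inherits(candidate, "tpn_candidate"), inherits(tree, "tpn_tree"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  by_feat <- stats_by_feature(stats, tree)
  prov <- candidate$provenance
  missing_feat <- setdiff(unique(prov$feature), names(by_feat))
  if (length(missing_feat))
    stop("no node stats for feature(s): ", paste(missing_feat, collapse = ", "))
  p <- mapply(function(g, i) by_feat[[g]]$p[i], prov$feature, prov$node_id)
  dir <- mapply(function(g, i) by_feat[[g]]$direction[i], prov$feature, prov$node_id)
  adj <- bh_adjust(p)
  rej <- !is.na(adj) & adj <= alpha

  rej_nodes <- unique(prov$node_id[rej])
  rej_leaves <- if (length(rej_nodes))
    sort(unique(unlist(tree$b[rej_nodes], use.names = FALSE))) else integer(0)
  s <- length(rej_nodes)
  l <- length(rej_leaves)
  r_hat <- if (s == 0L) 1 else l / s
  admissible <- candidate$t == 0 ||
    candidate$t <= t_upper(alpha, r_hat)

  structure(
    list(candidate = candidate, alpha = alpha,
         m = sum(!is.na(p)), R = sum(rej), R_L = l, s = s, l = l,
         r_hat = r_hat, admissible = admissible,
         rejected = data.frame(feature = prov$feature[rej],
                               node_id = prov$node_id[rej],
                               label = tree$labels[prov$node_id[rej]],
                               p = p[rej], adj_p = adj[rej],
                               direction = as.integer(dir[rej]),
                               stringsAsFactors = FALSE),
         rejected_leaves = rej_leaves,
         table = data.frame(feature = prov$feature, node_id = prov$node_id,
                            label = tree$labels[prov$node_id],
                            p = p, adj_p = adj, rejected = rej,
                            stringsAsFactors = FALSE)),
    class = "tpn_evaluation")
}

#' @export
print.tpn_evaluation <- function(x, ...) {
  cat(sprintf(
    "Candidate t = %g: m = %d, R = %d, R_L = %d, s = %d, r_hat = %.3g, %s\n",
    x$candidate$t, x$m, x$R, x$R_L, x$s, x$r_hat,
    if (x$admissible) "admissible" else "not admissible"))
  invisible(x)
}

#' Select the best candidate
#'
#' Three ordered criteria: (i) keep only admissible candidates (those whose t
#' lies inside the FDR-motivated bound; the leaf-level candidate at t = 0 is
#' always admissible); (ii) among them maximize the number of rejected
#' leaves; (iii) break ties by the smallest number of rejected nodes.
#' Remaining ties go to the smallest t, favoring resolutions closer to the
#' leaves. The selection does not depend on the order of the input list.
#'
#' @param evaluations list of `tpn_evaluation` objects computed at a common
#'   alpha over the tuning grid (the t = 0 evaluation should be present).
#' @return An object of class `tpn_selection`: the winning evaluation plus an
#'   evaluation table (columns `t`, `m`, `R`, `R_L`, `s`, `r_hat`,
#'   `admissible`) mirroring the per-candidate summaries.
#' @export
select_candidate <- function(evaluations) {
  if (!length(evaluations)) stop("empty evaluation list")
  stopifnot(all(vapply(evaluations, inherits, TRUE, "tpn_evaluation")))
  alphas <- vapply(evaluations, function(e) e$alpha, 1)
  if (length(unique(alphas)) != 1L)
    stop("evaluations were computed at different alpha levels")
  tab <- data.frame(
    t = vapply(evaluations, function(e) e$candidate$t, 1),
    m = vapply(evaluations, function(e) e$m, 1),
    R = vapply(evaluations, function(e) e$R, 1),
    R_L = vapply(evaluations, function(e) e$R_L, 1),
    s = vapply(evaluations, function(e) e$s, 1),
    r_hat = vapply(evaluations, function(e) e$r_hat, 1),
    admissible = vapply(evaluations, function(e) e$admissible, TRUE))
  ok <- which(tab$admissible)
  if (!length(ok))
    stop("no admissible candidate; include t = 0 in the grid")
  ord <- ok[order(-tab$R_L[ok], tab$s[ok], tab$t[ok])]
  win <- evaluations[[ord[1L]]]
  structure(
    list(winner = win, alpha = alphas[[1L]], t = win$candidate$t,
         rejected = win$rejected, rejected_leaves = win$rejected_leaves,
         evaluation_table = tab[order(tab$t), , drop = FALSE]),
    class = "tpn_selection")
}

#' @export
print.tpn_selection <- function(x, ...) {
  cat(sprintf("Selected candidate: t = %g (alpha = %g)\n", x$t, x$alpha))
  cat(sprintf("  rejected nodes: %d; rejected leaves: %d\n",
              length(unique(x$rejected$node_id)), length(x$rejected_leaves)))
  invisible(x)
}

#' Run the full tree-climbing analysis
#'
#' End-to-end pipeline: aggregate the data to all tree nodes, test every node
#' (per feature in DS mode), propose one candidate per tuning value (pooled
#' across features in DS mode), evaluate each candidate at FDR alpha, and
#' select the best one. Deterministic given the inputs and engine.
#'
#' @param tree a `tpn_tree`.
#' @param data for `mode = "da"`, a K x J count matrix with entity rownames;
#'   for `mode = "ds"`, a cell-level data.frame as for [aggregate_ds()].
#' @param groups factor of length J (DA) or one entry per sample (DS, named
#'   by sample id or in the sample order of `data`) with exactly 2 levels.
#' @param mode `"da"` (differential abundance) or `"ds"` (differential
#'   state).
#' @param alpha nominal leaf-level FDR.
#' @param engine `"nb"` (negative-binomial GLM, default for DA counts) or
#'   `"wilcoxon"` (default for DS values).
#' @param fun aggregation function; defaults to `"sum"` for DA and
#'   `"median"` for DS.
#' @param t_grid tuning grid; defaults to [default_t_grid()].
#' @param p_thresh internal-terminus admission threshold (default 0.05).
#' @param normalize for the Wilcoxon engine in DA mode: test library-size
#'   normalized values (default `TRUE`).
#' @return A `tpn_selection` with additional elements `stats` (the node
#'   stats) and `mode`.
#' @export
treeclimb_run <- function(tree, data, groups, mode = c("da", "ds"),
                          alpha = 0.05, engine = NULL, fun = NULL,
                          t_grid = default_t_grid(), p_thresh = 0.05,
                          normalize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "tpn_tree"))
  if (mode == "da") {
    if (is.null(engine)) engine <- "nb"
    if (is.null(fun)) fun <- "sum"
    agg <- aggregate_da(tree, data, fun = fun)
    stats <- switch(engine,
      nb = nb_glm_node_test(agg, groups),
      wilcoxon = wilcoxon_node_test(agg, groups, normalize = normalize),
      stop("unknown engine: ", engine))
  } else {
    if (is.null(engine)) engine <- "wilcoxon"
    if (is.null(fun)) fun <- "median"
    agg <- aggregate_ds(tree, data, fun = fun)
    samples <- colnames(agg[[1L]])
    g <- if (!is.null(names(groups))) {
      if (!all(samples %in% names(groups)))
        stop("`groups` is missing entries for samples: ",
             paste(setdiff(samples, names(groups)), collapse = ", "))
      groups[samples]
    } else groups
    stats <- do.call(rbind, lapply(names(agg), function(gname) {
      switch(engine,
        wilcoxon = wilcoxon_node_test(agg[[gname]], g, feature = gname),
        stop("unsupported DS engine: ", engine))
    }))
    groups <- g
  }

  feats <- unique(stats$feature)
  by_feat <- stats_by_feature(stats, tree)
  evaluations <- lapply(sort(unique(t_grid)), function(t) {
    cands <- lapply(feats, function(gname)
      propose_candidate(tree, by_feat[[gname]], t, p_thresh = p_thresh))
    cand <- if (length(cands) == 1L) cands[[1L]] else pool_candidates(cands)
    evaluate_candidate(cand, stats, tree, alpha = alpha)
  })
  sel <- select_candidate(evaluations)
  sel$stats <- stats
  sel$mode <- mode
  sel
}

#' Result table of a selection
#'
#' One row per rejected (feature, node) pair of the winning candidate, with
#' descendant-leaf counts; suitable for writing as TSV.
#'
#' @param selection a `tpn_selection`.
#' @param tree the tree the analysis was run on.
#' @return data.frame with columns `feature`, `node_id`, `label`, `p`,
#'   `adjusted_p`, `direction`, `n_descendant_leaves`, `selected_t`.
#' @export
results_table <- function(selection, tree) {
  stopifnot(inherits(selection, "tpn_selection"), inherits(tree, "tpn_tree"))
  rej <- selection$rejected
  data.frame(feature = rej$feature, node_id = rej$node_id, label = rej$label,
             p = rej$p, adjusted_p = rej$adj_p, direction = rej$direction,
             n_descendant_leaves = lengths(tree$b[rej$node_id]),
             selected_t = rep(selection$t, nrow(rej)),
             stringsAsFactors = FALSE)
}
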