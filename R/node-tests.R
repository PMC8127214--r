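# Node-level differential testing. Every operation returns "node stats": a
# data.frame with one row per (node, feature) carrying a raw p-value, an
# estimated direction of change in {-1, 0, +1}, and an optional effect size
# (log fold change). Any external testing engine can be plugged in through
# attach_external_stats().

new_node_stats <- function(node_id, label, feature, p, direction, effect = NA_real_) {
  stopifnot(all(direction %in% c(-1L, 0L, 1L)))
  direction[is.na(p)] <- 0L
  data.frame(node_id = as.integer(node_id), label = label,
             feature = feature, p = as.numeric(p),
             direction = as.integer(direction), effect = as.numeric(effect),
             stringsAsFactors = FALSE)
}

check_groups <- function(groups, J) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("`groups` must be a factor with exactly 2 levels, got ",
         nlevels(groups))
  if (length(groups) != J)
    stop("`groups` length does not match the number of samples")
  groups
}

#' Wilcoxon rank-sum test at every tree node
#'
#' Two-sided rank-sum test per node comparing the two sample groups; the
#' direction is the sign of (mean of the second group level minus mean of the
#' first). The exact null distribution is used when both groups have at most
#' 10 non-missing samples and there are no ties; otherwise the normal
#' approximation with tie correction is used. Nodes where either group has
#' fewer than 2 non-missing samples get a missing p-value (direction 0), as
#' do nodes with identical values in both groups (p = 1).
#'
#' @param values M x J node value matrix ([aggregate_da()] or one element of
#'   [aggregate_ds()]).
#' @param groups factor of length J with exactly 2 levels; the second level
#'   is treated as the treatment group for the direction sign.
#' @param normalize if `TRUE`, divide each sample by its leaf-level library
#'   size (taken from the `lib_sizes` attribute) before testing; intended for
#'   count data analyzed non-parametrically.
#' @param feature feature tag written into the result (default `"abundance"`).
#' @return Node stats data.frame (columns `node_id`, `label`, `feature`, `p`,
#'   `direction`, `effect`).
#' @export
wilcoxon_node_test <- function(values, groups, normalize = FALSE,
                               feature = "abundance") {
  stopifnot(is.matrix(values))
  groups <- check_groups(groups, ncol(values))
  if (normalize) {
    ls <- attr(values, "lib_sizes")
    if (is.null(ls)) stop("`normalize = TRUE` requires a lib_sizes attribute")
    values <- sweep(values, 2L, ls, "/")
  }
  g2 <- groups == levels(groups)[2L]
  M <- nrow(values)
  p <- rep(NA_real_, M); dir <- rep(0L, M); eff <- rep(NA_real_, M)
  for (i in seq_len(M)) {
    x <- values[i, !g2]; y <- values[i, g2]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) next
    d <- mean(y) - mean(x)
    if (all(c(x, y) == c(x, y)[1L])) { p[i] <- 1; dir[i] <- 0L; next }
    exact <- length(x) <= 10L && length(y) <= 10L &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(y, x, alternative = "two.sided", exact = exact))
    p[i] <- min(wt$p.value, 1)
    dir[i] <- as.integer(sign(d))
    eff[i] <- d
  }
  lab <- rownames(values)
  if (is.null(lab)) lab <- as.character(seq_len(M))
  new_node_stats(seq_len(M), lab, feature, p, dir, eff)
}

#' Negative-binomial GLM test at every tree node
#'
#' Fits, per node, a negative-binomial log-linear model with a group effect
#' to aggregated counts (edgeR dispersion estimation followed by the
#' quasi-likelihood F-test, which keeps the type I error calibrated at small
#' sample sizes), using the leaf-level library sizes as offsets so that
#' aggregated rows are compared on the scale of relative abundance. The
#' direction is the sign of the fitted group log fold change. Nodes with
#' all-zero counts get a missing p-value.
#'
#' @param counts M x J matrix of aggregated counts ([aggregate_da()] with
#'   `fun = "sum"`); values must be integers.
#' @param groups factor of length J with exactly 2 levels.
#' @param lib_sizes per-sample leaf-level totals; defaults to the `lib_sizes`
#'   attribute attached by [aggregate_da()].
#' @param feature feature tag written into the result.
#' @return Node stats data.frame as for [wilcoxon_node_test()]; `effect` is
#'   the fitted log2 fold change.
#' @export
nb_glm_node_test <- function(counts, groups, lib_sizes = NULL,
                             feature = "abundance") {
  stopifnot(is.matrix(counts))
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("`counts` must be integer-valued aggregated counts")
  groups <- check_groups(groups, ncol(counts))
  if (is.null(lib_sizes)) lib_sizes <- attr(counts, "lib_sizes")
  if (is.null(lib_sizes))
    stop("leaf-level library sizes are required (lib_sizes attribute or argument)")
  design <- stats::model.matrix(~groups)
  y <- edgeR::DGEList(counts = counts, lib.size = as.numeric(lib_sizes))
  y <- edgeR::estimateDisp(y, design)
  fit <- suppressWarnings(edgeR::glmQLFit(y, design))
  qlt <- edgeR::glmQLFTest(fit, coef = 2L)
  p <- qlt$table$PValue
  lfc <- qlt$table$logFC
  dir <- as.integer(sign(lfc))
  zero <- rowSums(counts) == 0
  p[zero] <- NA_real_
  dir[zero] <- 0L
  lfc[zero] <- NA_real_
  lab <- rownames(counts)
  if (is.null(lab)) lab <- as.character(seq_len(nrow(counts)))
  new_node_stats(seq_len(nrow(counts)), lab, feature, p, dir, lfc)
}

#' Attach externally computed node statistics
#'
#' Integration point for any differential-testing engine: supply a table of
#' p-values and directions keyed by node label (and feature), and get back a
#' complete node-stats object covering all M nodes. Nodes absent from the
#' table get a missing p-value and direction 0; such nodes can never become
#' candidate termini but climbing proceeds past them.
#'
#' @param tree a `tpn_tree`.
#' @param table data.frame with columns `label`, `p`, `direction`, and
#'   optionally `feature` (default feature tag `"stat"`) and `effect`.
#' @return Node stats data.frame covering every (node, feature) pair.
#' @export
attach_external_stats <- function(tree, table) {
  stopifnot(inherits(tree, "tpn_tree"), is.data.frame(table))
  if (!all(c("label", "p", "direction") %in% names(table)))
    stop("`table` must have columns label, p, direction")
  if (!"feature" %in% names(table)) table$feature <- "stat"
  if (!"effect" %in% names(table)) table$effect <- NA_real_
  idx <- match(as.character(table$label), tree$labels)
  if (anyNA(idx))
    stop("unknown node labels: ",
         paste(unique(table$label[is.na(idx)]), collapse = ", "))
  bad_p <- !is.na(table$p) & (table$p < 0 | table$p > 1)
  if (any(bad_p)) stop("p-values outside [0, 1]")
  if (!all(table$direction %in% c(-1, 0, 1)))
    stop("directions must be in {-1, 0, +1}")
  out <- do.call(rbind, lapply(unique(table$feature), function(g) {
    sub <- table[table$feature == g, , drop = FALSE]
    sidx <- match(seq_len(tree$M), idx[table$feature == g])
    if (anyDuplicated(idx[table$feature == g]))
      stop("duplicate (label, feature) rows in `table`")
    new_node_stats(seq_len(tree$M), tree$labels,
                   g,
                   p = sub$p[sidx],
                   direction = ifelse(is.na(sidx), 0L, sub$direction[sidx]),
                   effect = sub$effect[sidx])
  }))
  rownames(out) <- NULL
  out
}

# split node stats by feature, validating shape against a tree
stats_by_feature <- function(stats, tree) {
  stopifnot(is.data.frame(stats))
  feats <- unique(stats$feature)
  if (length(feats) == 1L) {
    # fast path: single feature, typically already in node order
    s <- if (identical(stats$node_id, seq_len(tree$M))) stats
    else stats[order(stats$node_id), , drop = FALSE]
    if (!identical(s$node_id, seq_len(tree$M)))
      stop("node stats must cover all ", tree$M, " nodes exactly once per feature")
    return(stats::setNames(list(s), feats))
  }
  out <- split(stats, stats$feature)
  lapply(out, function(s) {
    s <- s[order(s$node_id), , drop = FALSE]
    if (!identical(s$node_id, seq_len(tree$M)))
      stop("node stats must cover all ", tree$M, " nodes exactly once per feature")
    s
  })
}
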