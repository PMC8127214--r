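# Aggregation of leaf-level (DA) or cell-level (DS) observations to every
# node of the tree. A node's value in a sample is a summary (sum, mean or
# median) of the values of its descendant leaves (DA) or of the cells mapped
# below it (DS).

agg_fun <- function(fun) {
  switch(fun, sum = sum, mean = mean, median = stats::median,
         stop("unknown aggregation fun: ", fun))
}

#' Aggregate a leaf count table to all tree nodes (DA)
#'
#' For every node i and sample j the output is `fun` applied to the counts of
#' the descendant leaves b(i) in sample j. With `fun = "sum"` (the default
#' for count data) the root row equals the per-sample library sizes and the
#' value at any internal node equals the sum over its children.
#'
#' @param tree a `tpn_tree`.
#' @param counts numeric matrix, entities x samples, with rownames matching
#'   the tree leaf labels (a bijection is required) and colnames giving
#'   sample ids. Counts must be finite and nonnegative.
#' @param fun one of `"sum"`, `"mean"`, `"median"`.
#' @return An M x J matrix with rownames equal to the node labels, carrying
#'   attributes `fun` and `lib_sizes` (leaf-level per-sample totals).
#' @export
aggregate_da <- function(tree, counts, fun = c("sum", "mean", "median")) {
  fun <- match.arg(fun)
  stopifnot(inherits(tree, "tpn_tree"), is.matrix(counts))
  if (is.null(rownames(counts))) stop("`counts` must have entity rownames")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  leaf_labels <- tree$labels[seq_len(tree$K)]
  missing_in_counts <- setdiff(leaf_labels, rownames(counts))
  missing_in_tree <- setdiff(rownames(counts), leaf_labels)
  if (length(missing_in_counts) || length(missing_in_tree))
    stop("entity labels and tree leaves do not match; missing in counts: [",
         paste(missing_in_counts, collapse = ", "), "]; missing in tree: [",
         paste(missing_in_tree, collapse = ", "), "]")
  leaf_mat <- counts[leaf_labels, , drop = FALSE]

  out <- matrix(NA_real_, nrow = tree$M, ncol = ncol(counts),
                dimnames = list(tree$labels, colnames(counts)))
  out[seq_len(tree$K), ] <- leaf_mat
  f <- agg_fun(fun)
  if (fun == "sum") {
    for (i in (tree$K + 1L):tree$M)
      out[i, ] <- colSums(leaf_mat[tree$b[[i]], , drop = FALSE])
  } else {
    for (i in (tree$K + 1L):tree$M)
      out[i, ] <- apply(leaf_mat[tree$b[[i]], , drop = FALSE], 2L, f)
  }
  attr(out, "fun") <- fun
  attr(out, "lib_sizes") <- colSums(leaf_mat)
  out
}

#' Aggregate a cell-level table to all tree nodes (DS)
#'
#' For every feature g, node i and sample j the output is `fun` applied to
#' the feature values of the cells that belong to sample j and are mapped to
#' a leaf in b(i). The default `fun = "median"` matches the usual treatment
#' of transformed state-marker intensities. Node x sample combinations with
#' no contributing cell are `NA` and are excluded from downstream testing.
#'
#' @param tree a `tpn_tree`.
#' @param cells data.frame with columns `cell_id`, `leaf_label`, `sample_id`
#'   followed by one numeric column per feature.
#' @param fun one of `"median"`, `"mean"`, `"sum"`.
#' @return Named list of M x J matrices, one per feature, each carrying the
#'   attribute `n_cells` (an M x J matrix of contributing cell counts).
#' @export
aggregate_ds <- function(tree, cells, fun = c("median", "mean", "sum")) {
  fun <- match.arg(fun)
  stopifnot(inherits(tree, "tpn_tree"), is.data.frame(cells))
  need <- c("cell_id", "leaf_label", "sample_id")
  if (!all(need %in% names(cells)))
    stop("`cells` must have columns ", paste(need, collapse = ", "))
  feat_cols <- setdiff(names(cells), need)
  if (!length(feat_cols)) stop("`cells` has no feature columns (G >= 1 required)")
  leaf_idx <- match_leaves(tree, as.character(cells$leaf_label))
  samples <- unique(as.character(cells$sample_id))
  J <- length(samples)
  samp_idx <- match(as.character(cells$sample_id), samples)
  f <- agg_fun(fun)

  # cells contributing to node i in sample j: leaf in b(i) and sample j
  n_cells <- matrix(0L, nrow = tree$M, ncol = J,
                    dimnames = list(tree$labels, samples))
  out <- vector("list", length(feat_cols))
  names(out) <- feat_cols
  for (g in feat_cols) {
    vals <- as.numeric(cells[[g]])
    m <- matrix(NA_real_, nrow = tree$M, ncol = J,
                dimnames = list(tree$labels, samples))
    for (i in seq_len(tree$M)) {
      in_b <- leaf_idx %in% tree$b[[i]]
      for (j in seq_len(J)) {
        sel <- in_b & samp_idx == j
        n <- sum(sel)
        if (g == feat_cols[[1]]) n_cells[i, j] <- n
        if (n > 0L) m[i, j] <- f(vals[sel])
      }
    }
    attr(m, "fun") <- fun
    attr(m, "n_cells") <- n_cells
    out[[g]] <- m
  }
  out
}
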