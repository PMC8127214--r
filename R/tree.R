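# Rooted-tree container used throughout the package.
#
# Nodes are integers 1..M with leaves 1..K and internal nodes K+1..M; the
# root carries the largest id when the tree comes from `parse_newick()`.
# Descendant-leaf sets b(i) and branch sets B(i) = {i} plus all descendants
# are precomputed so that downstream modules query them in O(1).

#' Construct a rooted tree from a parent map
#'
#' Low-level constructor behind [parse_newick()], [tree_from_linkage()] and
#' [synthetic_tree()]. Most users never call it directly.
#'
#' @param parent integer vector of length M; `parent[i]` is the parent node of
#'   node `i`, `NA` for the root. Leaves must occupy ids `1..K`, internal
#'   nodes `K+1..M`, and every internal id must be larger than all ids in its
#'   subtree (children-before-parent numbering).
#' @param labels character vector of length M with node labels; leaf labels
#'   must be unique and non-empty.
#' @param brlen optional numeric vector of length M with the length of the
#'   edge above each node (`NA` for the root or when absent).
#' @param label_auto logical vector marking labels that were generated rather
#'   than supplied; auto labels are omitted when writing Newick.
#'
#' @return An object of class `tpn_tree`: a list with elements `K`, `M`,
#'   `root`, `parent`, `children`, `labels`, `brlen`, `postorder`, and the
#'   precomputed sets `b` (descendant leaves) and `B` (branch sets).
#' @export
new_tree <- function(parent, labels, brlen = NULL, label_auto = NULL) {
  M <- length(parent)
  stopifnot(is.numeric(parent), length(labels) == M)
  parent <- as.integer(parent)
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root (one NA in `parent`)")
  if (any(parent[-root] < 1L | parent[-root] > M, na.rm = TRUE))
    stop("`parent` contains out-of-range node ids")

  children <- vector("list", M)
  for (i in seq_len(M)) children[[i]] <- integer(0)
  for (i in seq_len(M)[-root]) {
    p <- parent[i]
    children[[p]] <- c(children[[p]], i)
  }
  is_leaf <- vapply(children, length, 1L) == 0L
  K <- sum(is_leaf)
  if (K < 2L) stop("tree must have at least 2 leaves (K >= 2)")
  if (!all(which(is_leaf) == seq_len(K)))
    stop("leaves must be numbered 1..K and internal nodes K+1..M")

  leaf_labels <- labels[seq_len(K)]
  if (anyNA(leaf_labels) || any(!nzchar(leaf_labels)))
    stop("leaf labels must be non-empty")
  if (anyDuplicated(leaf_labels))
    stop("duplicate leaf labels: ",
         paste(unique(leaf_labels[duplicated(leaf_labels)]), collapse = ", "))

  # iterative DFS establishing connectivity/acyclicity and a postorder
  post <- integer(0)
  stack <- root
  seen <- logical(M)
  order_out <- integer(M)
  n_out <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) stop("tree contains a cycle")
    seen[v] <- TRUE
    n_out <- n_out + 1L
    order_out[n_out] <- v
    kids <- children[[v]]
    if (length(kids)) stack <- c(stack, kids)
  }
  if (!all(seen)) stop("tree is not connected: unreachable nodes exist")
  post <- rev(order_out)  # children before parents

  b <- vector("list", M)
  B <- vector("list", M)
  for (v in post) {
    kids <- children[[v]]
    if (!length(kids)) {
      b[[v]] <- v
      B[[v]] <- v
    } else {
      b[[v]] <- sort(unlist(b[kids], use.names = FALSE))
      B[[v]] <- sort(c(v, unlist(B[kids], use.names = FALSE)))
    }
  }

  if (is.null(brlen)) brlen <- rep(NA_real_, M)
  stopifnot(length(brlen) == M)
  if (any(brlen < 0, na.rm = TRUE)) stop("branch lengths must be nonnegative")
  if (is.null(label_auto)) label_auto <- rep(FALSE, M)

  structure(
    list(K = K, M = M, root = root, parent = parent, children = children,
         labels = as.character(labels), brlen = as.numeric(brlen),
         label_auto = label_auto, postorder = post, b = b, B = B),
    class = "tpn_tree")
}

#' @export
print.tpn_tree <- function(x, ...) {
  cat(sprintf("Rooted tree: %d leaves, %d internal nodes (%d total), root = node %d\n",
              x$K, x$M - x$K, x$M, x$root))
  cat("Leaf labels: ", paste(utils::head(x$labels[seq_len(x$K)], 6), collapse = ", "),
      if (x$K > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Convert an ape "phylo" object: tips keep ids 1..K, internal nodes are
# renumbered in postorder so the root becomes node M.
tree_from_phylo <- function(phy) {
  K <- length(phy$tip.label)
  if (K < 2L) stop("tree must have at least 2 leaves (K >= 2)")
  n_int <- phy$Nnode
  M <- K + n_int
  kids_ph <- vector("list", M)
  for (i in seq_len(M)) kids_ph[[i]] <- integer(0)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; c0 <- phy$edge[e, 2L]
    kids_ph[[p]] <- c(kids_ph[[p]], c0)
  }
  root_ph <- setdiff(unique(phy$edge[, 1L]), phy$edge[, 2L])
  if (length(root_ph) != 1L) stop("malformed tree: root is not unique")

  # postorder over internal phylo ids
  stack <- root_ph
  order_out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order_out <- c(order_out, v)
    stack <- c(stack, kids_ph[[v]])
  }
  post_ph <- rev(order_out)
  internal_post <- post_ph[post_ph > K]
  new_id <- integer(M)
  new_id[seq_len(K)] <- seq_len(K)
  new_id[internal_post] <- K + seq_along(internal_post)

  parent <- rep(NA_integer_, M)
  brlen <- rep(NA_real_, M)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; c0 <- phy$edge[e, 2L]
    parent[new_id[c0]] <- new_id[p]
    if (!is.null(phy$edge.length)) brlen[new_id[c0]] <- phy$edge.length[e]
  }

  labels <- character(M)
  label_auto <- rep(FALSE, M)
  labels[seq_len(K)] <- phy$tip.label
  node_lab <- phy$node.label
  for (j in seq_len(n_int)) {
    ph_id <- K + j
    lab <- if (!is.null(node_lab) && j <= length(node_lab)) node_lab[j] else ""
    if (is.na(lab) || !nzchar(lab)) {
      labels[new_id[ph_id]] <- paste0("node_", new_id[ph_id])
      label_auto[new_id[ph_id]] <- TRUE
    } else {
      labels[new_id[ph_id]] <- lab
    }
  }
  new_tree(parent, labels, brlen, label_auto)
}

# Convert back to ape "phylo" (internal ids renumbered root-first as ape
# expects). Auto-generated internal labels are dropped.
tree_to_phylo <- function(tree) {
  K <- tree$K; M <- tree$M
  new_int <- integer(M)
  new_int[seq_len(K)] <- seq_len(K)
  # preorder over internal nodes, root first
  stack <- tree$root
  ctr <- K
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v > K) {
      ctr <- ctr + 1L
      new_int[v] <- ctr
      pre <- c(pre, v)
    }
    stack <- c(stack, rev(tree$children[[v]]))
  }
  edge <- matrix(0L, nrow = M - 1L, ncol = 2L)
  elen <- numeric(M - 1L)
  row <- 0L
  walk <- function(v) {
    for (c0 in tree$children[[v]]) {
      row <<- row + 1L
      edge[row, ] <<- c(new_int[v], new_int[c0])
      elen[row] <<- tree$brlen[c0]
      walk(c0)
    }
  }
  walk(tree$root)
  node_label <- character(M - K)
  for (v in (seq_len(M))[(K + 1):M]) {
    node_label[new_int[v] - K] <- if (tree$label_auto[v]) "" else tree$labels[v]
  }
  phy <- list(edge = edge, Nnode = M - K,
              tip.label = tree$labels[seq_len(K)])
  if (any(!is.na(elen))) {
    elen[is.na(elen)] <- 0
    phy$edge.length <- elen
  }
  if (any(nzchar(node_label))) phy$node.label <- node_label
  class(phy) <- "phylo"
  phy
}

#' Parse a Newick string into a rooted tree
#'
#' Leaves are numbered `1..K` in order of first appearance in the string,
#' internal nodes `K+1..M` in postorder (so the root is node `M`). Branch
#' lengths and internal labels are preserved; unlabeled internal nodes get
#' synthetic labels `"node_<id>"`.
#'
#' @param text a Newick string (must end with `;`).
#' @return A `tpn_tree`.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' tr$K  # 3 leaves
#' descendant_leaves(tr, 4)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    # locate first structurally suspicious position for the error message
    bal <- cumsum((strsplit(text, "")[[1]] == "(") -
                  (strsplit(text, "")[[1]] == ")"))
    pos <- if (any(bal < 0)) which(bal < 0)[1] else nchar(text)
    stop(sprintf("malformed Newick string (near position %d)", pos))
  }
  tree_from_phylo(phy)
}

#' Serialize a tree to Newick
#'
#' Round trips with [parse_newick()]: topology, leaf labels, user-supplied
#' internal labels, and branch lengths are preserved. Branch lengths are
#' written with up to 10 significant digits.
#'
#' @param tree a `tpn_tree`.
#' @return A single Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "tpn_tree"))
  phy <- tree_to_phylo(tree)
  ape::write.tree(phy, digits = 10)
}

#' Build a tree by hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering (via [stats::hclust()]) of labeled items, as used
#' to organize cell clusters by their median marker expression. The resulting
#' dendrogram is returned as a binary tree with `M = 2K - 1` nodes and merge
#' heights stored as branch lengths.
#'
#' @param d square symmetric nonnegative matrix with zero diagonal; row or
#'   column names are used as leaf labels (items are named `item_<k>` when
#'   absent).
#' @param method linkage method passed to [stats::hclust()]; default
#'   `"complete"`.
#' @return A `tpn_tree` with `K = nrow(d)` leaves.
#' @export
tree_from_linkage <- function(d, method = "complete") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  if (nrow(d) < 2L) stop("need at least 2 items")
  if (any(d < 0)) stop("dissimilarities must be nonnegative")
  if (any(abs(d - t(d)) > 1e-8)) stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  labs <- rownames(d)
  if (is.null(labs)) labs <- colnames(d)
  if (is.null(labs)) labs <- paste0("item_", seq_len(nrow(d)))
  rownames(d) <- colnames(d) <- labs
  hc <- stats::hclust(stats::as.dist(d), method = method)
  tree_from_phylo(ape::as.phylo(hc))
}

#' Descendant leaves of a node
#'
#' Returns b(i), the set of leaf ids below node `i` (for a leaf, the node
#' itself). Sibling sets are disjoint and the root covers all leaves.
#'
#' @param tree a `tpn_tree`.
#' @param i node id in `1..M`.
#' @return Sorted integer vector of leaf ids.
#' @export
descendant_leaves <- function(tree, i) {
  stopifnot(inherits(tree, "tpn_tree"))
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > tree$M)
    stop("unknown node id: ", i)
  tree$b[[i]]
}

#' Branch set of a node
#'
#' Returns B(i) = node `i` together with all its descendants, internal and
#' leaf. `|B(i)|` is the branch size n_B used by the U score.
#'
#' @inheritParams descendant_leaves
#' @return Sorted integer vector of node ids.
#' @export
branch_set <- function(tree, i) {
  stopifnot(inherits(tree, "tpn_tree"))
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > tree$M)
    stop("unknown node id: ", i)
  tree$B[[i]]
}

#' Node annotation table
#'
#' @param tree a `tpn_tree`.
#' @return data.frame with columns `node_id`, `label`, `is_leaf`, `parent_id`.
#' @export
node_table <- function(tree) {
  stopifnot(inherits(tree, "tpn_tree"))
  data.frame(node_id = seq_len(tree$M),
             label = tree$labels,
             is_leaf = seq_len(tree$M) <= tree$K,
             parent_id = tree$parent,
             stringsAsFactors = FALSE)
}

# leaf ids for a vector of leaf labels, with validation
match_leaves <- function(tree, labels) {
  idx <- match(labels, tree$labels[seq_len(tree$K)])
  if (anyNA(idx))
    stop("labels not found among tree leaves: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}
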