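# File readers/writers and the command-line entry point. TSV is the
# canonical tabular dialect (tab-separated, UTF-8, header row); CSV is
# accepted on read by sniffing the header line. Readers validate rather than
# coerce: malformed input is rejected with file context.

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a leaf count table
#'
#' Entities as rows (first column holds the entity labels), samples as
#' columns. Tab- or comma-separated, sniffed from the header.
#'
#' @param path file path.
#' @return Numeric matrix with entity rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop(path, ": need an entity column plus at least 2 sample columns")
  labels <- trimws(as.character(df[[1L]]))
  if (anyDuplicated(labels))
    stop(path, ": duplicate entity labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  num <- df[, -1L, drop = FALSE]
  bad <- !vapply(num, is.numeric, TRUE)
  if (any(bad))
    stop(path, ": non-numeric count column(s): ",
         paste(names(num)[bad], collapse = ", "))
  m <- as.matrix(num)
  rownames(m) <- labels
  if (any(!is.finite(m)) || any(m < 0))
    stop(path, ": counts must be finite and nonnegative")
  m
}

#' Read sample metadata
#'
#' Requires columns `sample_id` and `group`, with exactly two group levels.
#'
#' @param path file path.
#' @return Factor of group assignments named by sample id.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop(path, ": metadata must have columns sample_id, group")
  ids <- trimws(as.character(df$sample_id))
  if (anyDuplicated(ids)) stop(path, ": duplicate sample ids")
  g <- factor(trimws(as.character(df$group)))
  if (nlevels(g) != 2L)
    stop(path, ": expected exactly 2 groups, found ", nlevels(g))
  names(g) <- ids
  g
}

#' Read a cell-level table (DS mode)
#'
#' Requires columns `cell_id`, `leaf_label`, `sample_id`, followed by one
#' numeric column per feature.
#'
#' @param path file path.
#' @return data.frame suitable for [aggregate_ds()].
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_id", "leaf_label", "sample_id")
  if (!all(need %in% names(df)))
    stop(path, ": cell table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(trimws(as.character(df$cell_id))))
    stop(path, ": duplicate cell ids")
  feat <- setdiff(names(df), need)
  if (!length(feat)) stop(path, ": no feature columns found")
  bad <- !vapply(df[feat], is.numeric, TRUE)
  if (any(bad))
    stop(path, ": non-numeric feature column(s): ",
         paste(feat[bad], collapse = ", "))
  df$leaf_label <- trimws(as.character(df$leaf_label))
  df$sample_id <- trimws(as.character(df$sample_id))
  df
}

#' Read a tree from a Newick file
#'
#' @param path file path.
#' @return A `tpn_tree`.
#' @export
read_tree_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `run-da` (counts + tree + metadata -> results and evaluation
#' tables), `simulate` (write a simulated dataset: counts, metadata, Newick
#' tree, truth), and `benchmark` (repetition-level TPR/FDR table). Every run
#' writes a plain-text manifest echoing the configuration and seed. Intended
#' to be wrapped in a two-line Rscript; see `system.file("scripts",
#' "treepin", package = "treepin")`.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Exit status, 0 on success (invisibly).
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: treepin <subcommand> [options]",
    "  run-da    --counts F --tree F --meta F --out DIR [--alpha 0.05]",
    "            [--engine nb|wilcoxon]",
    "  simulate  --scenario BS|US|SS|null --k K --out DIR [--seed S]",
    "            [--theta 0.02] [--nc 10] [--nt 10]",
    "  benchmark --scenario BS|US|SS|null --reps N --k K --out DIR",
    "            [--seed S] [--alpha 0.05] [--n-per-group 10]",
    sep = "\n")
  fail <- function(msg) {
    message(msg, "\n", usage)
    return(invisible(1L))
  }
  if (!length(argv)) return(fail("no subcommand given"))
  sub <- argv[[1L]]
  opts <- list()
  rest <- argv[-1L]
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[[i]]
    if (!startsWith(a, "--")) return(fail(paste("unexpected argument:", a)))
    if (i + 1L > length(rest)) return(fail(paste("missing value for", a)))
    opts[[substring(a, 3L)]] <- rest[[i + 1L]]
    i <- i + 2L
  }
  get <- function(name, default = NULL) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }
  known <- c("counts", "tree", "meta", "out", "alpha", "engine", "scenario",
             "k", "seed", "theta", "nc", "nt", "reps", "n-per-group",
             "min-leaves", "max-leaves", "fraction")
  unknown <- setdiff(names(opts), known)
  if (length(unknown))
    return(fail(paste("unknown flag(s):", paste0("--", unknown, collapse = ", "))))

  out_dir <- get("out")
  if (is.null(out_dir)) return(fail("--out is required"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(paste("subcommand:", sub),
                vapply(names(opts), function(n)
                  paste0(n, ": ", opts[[n]]), ""),
                paste("package_version:", as.character(utils::packageVersion("treepin"))))

  status <- tryCatch({
    if (sub == "run-da") {
      for (req in c("counts", "tree", "meta"))
        if (is.null(get(req))) stop("--", req, " is required for run-da")
      counts <- read_counts(get("counts"))
      tree <- read_tree_file(get("tree"))
      meta <- read_metadata(get("meta"))
      if (!all(colnames(counts) %in% names(meta)))
        stop("metadata is missing samples: ",
             paste(setdiff(colnames(counts), names(meta)), collapse = ", "))
      groups <- meta[colnames(counts)]
      sel <- treeclimb_run(tree, counts, groups, mode = "da",
                           alpha = as.numeric(get("alpha", "0.05")),
                           engine = get("engine", "nb"))
      write_tsv(results_table(sel, tree), file.path(out_dir, "results.tsv"))
      write_tsv(sel$evaluation_table, file.path(out_dir, "evaluation.tsv"))
      0L
    } else if (sub == "simulate") {
      seed <- as.integer(get("seed", "1"))
      set.seed(seed)
      K <- as.integer(get("k", "100"))
      tree <- synthetic_tree(K)
      pi <- as.numeric(stats::rgamma(K, 2, 1)); pi <- pi / sum(pi)
      names(pi) <- tree$labels[seq_len(K)]
      params <- dm_params(pi, as.numeric(get("theta", "0.02")),
                          depths = seq(10000L, 50000L, by = 1000L))
      scen_name <- get("scenario", "BS")
      sc <- if (scen_name == "null") NULL else {
        br <- pick_signal_branches(tree, params,
                                   as.integer(get("min-leaves", "5")),
                                   as.integer(get("max-leaves", "10")))
        switch(scen_name,
               BS = apply_bs(params, br$A, br$B, tree),
               US = apply_us(params, br$A, br$B, tree),
               SS = apply_ss(params, br$A, br$B, tree,
                             fraction = as.numeric(get("fraction", "0.5"))),
               stop("unknown scenario: ", scen_name))
      }
      dat <- simulate_dataset(tree, params, sc,
                              nC = as.integer(get("nc", "10")),
                              nT = as.integer(get("nt", "10")))
      write_tsv(data.frame(entity = rownames(dat$counts), dat$counts,
                           check.names = FALSE),
                file.path(out_dir, "counts.tsv"))
      write_tsv(data.frame(sample_id = colnames(dat$counts),
                           group = as.character(dat$groups)),
                file.path(out_dir, "metadata.tsv"))
      writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))
      truth <- dat$truth
      truth$scenario <- scen_name
      write_tsv(truth, file.path(out_dir, "truth.tsv"))
      0L
    } else if (sub == "benchmark") {
      seed <- as.integer(get("seed", "1"))
      set.seed(seed)
      K <- as.integer(get("k", "100"))
      tree <- synthetic_tree(K)
      pi <- as.numeric(stats::rgamma(K, 2, 1)); pi <- pi / sum(pi)
      names(pi) <- tree$labels[seq_len(K)]
      params <- dm_params(pi, as.numeric(get("theta", "0.02")),
                          depths = seq(10000L, 50000L, by = 1000L))
      n <- as.integer(get("n-per-group", "10"))
      alphas <- as.numeric(strsplit(get("alpha", "0.05"), ",")[[1L]])
      bm <- benchmark(tree, params, scenario = get("scenario", "BS"),
                      reps = as.integer(get("reps", "10")),
                      nC = n, nT = n, alphas = alphas, seed = seed)
      write_tsv(bm$results, file.path(out_dir, "benchmark.tsv"))
      if (!is.null(bm$summary))
        write_tsv(bm$summary, file.path(out_dir, "benchmark_summary.tsv"))
      0L
    } else {
      stop("unknown subcommand: ", sub)
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  if (identical(status, 0L))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(status)
}
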