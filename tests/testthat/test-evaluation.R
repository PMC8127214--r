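# BH correction, candidate evaluation (m, R, R_L, r_hat, Eq.-style t bound),
# selection criteria, and the end-to-end runner.

test_that("bh_adjust reproduces hand computations and the brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (rep_i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("t_upper implements the admissible range bound", {
  expect_equal(t_upper(0.05, 3), 0.2)
  expect_identical(t_upper(0.05, 1), 0)   # leaf level when r = 1
  expect_equal(t_upper(0.5, 100), 1)      # clipped
  expect_error(t_upper(0.05, 0.5), ">= 1")
  expect_error(t_upper(1.5, 2), "alpha")
})

test_that("evaluate_candidate summarizes rejections and admissibility", {
  set.seed(8)
  tr <- synthetic_tree(12)
  # find two disjoint internal nodes; give them tiny p so both are rejected
  internal <- (tr$K + 1L):tr$M
  sizes <- lengths(tr$b[internal])
  two <- NULL
  for (a in internal) for (b in internal) {
    if (a != b && !any(tr$b[[a]] %in% tr$b[[b]]) &&
        length(tr$b[[a]]) > 1 && length(tr$b[[b]]) > 1) { two <- c(a, b); break }
    if (!is.null(two)) break
  }
  p <- rep(0.5, tr$M); dir <- rep(1L, tr$M)
  p[two] <- 1e-6
  st <- make_stats(tr, p, dir)
  cand <- structure(list(t = 0.2, nodes = two, feature = "abundance",
                         provenance = data.frame(feature = "abundance",
                                                 node_id = two)),
                    class = "tpn_candidate")
  ev <- evaluate_candidate(cand, st, tr, alpha = 0.05)
  la <- length(tr$b[[two[1]]]); lb <- length(tr$b[[two[2]]])
  expect_equal(ev$s, 2L)
  expect_equal(ev$l, la + lb)
  expect_equal(ev$r_hat, (la + lb) / 2)
  expect_equal(ev$R_L, la + lb)
  expect_equal(ev$admissible, 0.2 <= 2 * 0.05 * (ev$r_hat - 1))

  # no rejections: r_hat = 1, admissible only at t = 0
  st_null <- make_stats(tr, rep(0.9, tr$M), rep(1L, tr$M))
  ev0 <- evaluate_candidate(cand, st_null, tr, alpha = 0.05)
  expect_equal(ev0$s, 0L)
  expect_equal(ev0$r_hat, 1)
  expect_false(ev0$admissible)
  cand0 <- structure(c(cand[-1], list(t = 0)), class = "tpn_candidate")
  expect_true(evaluate_candidate(cand0, st_null, tr, alpha = 0.05)$admissible)

  # leaf-level candidate with everything rejected: r_hat = 1
  leaves <- seq_len(tr$K)
  cl <- structure(list(t = 0, nodes = leaves, feature = "abundance",
                       provenance = data.frame(feature = "abundance",
                                               node_id = leaves)),
                  class = "tpn_candidate")
  stl <- make_stats(tr, rep(1e-6, tr$M), rep(1L, tr$M))
  evl <- evaluate_candidate(cl, stl, tr, alpha = 0.05)
  expect_equal(evl$r_hat, 1)
  expect_equal(evl$R_L, tr$K)
})

test_that("selection applies the three criteria in order", {
  tr <- synthetic_tree(10)
  fake_eval <- function(t, R_L, s, admissible) {
    structure(list(candidate = structure(list(t = t, nodes = integer(0),
                                              feature = "abundance",
                                              provenance = data.frame()),
                                         class = "tpn_candidate"),
                   alpha = 0.05, m = 10L, R = s, R_L = R_L, s = s, l = R_L,
                   r_hat = 1, admissible = admissible,
                   rejected = data.frame(), rejected_leaves = integer(0)),
              class = "tpn_evaluation")
  }
  # R_L tie broken by fewer nodes (the C2-vs-C3 configuration)
  evals <- list(fake_eval(0, 6, 6, TRUE), fake_eval(0.05, 6, 4, TRUE),
                fake_eval(0.1, 6, 3, TRUE))
  expect_equal(select_candidate(evals)$t, 0.1)
  # higher R_L wins regardless of node count
  evals2 <- list(fake_eval(0, 10, 10, TRUE), fake_eval(0.05, 8, 1, TRUE))
  expect_equal(select_candidate(evals2)$t, 0)
  # inadmissible candidates are filtered first
  evals3 <- list(fake_eval(0, 2, 2, TRUE), fake_eval(0.05, 50, 1, FALSE))
  expect_equal(select_candidate(evals3)$t, 0)
  # invariant to input order; remaining ties -> smallest t
  evals4 <- list(fake_eval(0.3, 6, 3, TRUE), fake_eval(0.1, 6, 3, TRUE))
  expect_equal(select_candidate(evals4)$t, 0.1)
  expect_equal(select_candidate(rev(evals4))$t, 0.1)
  expect_error(select_candidate(list()), "empty")
})

test_that("treeclimb_run finds a coherent signal branch as a branch node", {
  set.seed(501)
  tree <- synthetic_tree(60)
  params <- random_dm(tree, theta = 0.005)
  br <- strong_branch_pair(tree, params, 4, 10, min_abs_log_r = 0.4)
  sc <- apply_bs(params, br$A, br$B, tree)
  dat <- simulate_dataset(tree, params, sc, nC = 10, nT = 10)
  sel <- treeclimb_run(tree, dat$counts, dat$groups, mode = "da", alpha = 0.05)
  cs <- leaf_confusion(sel, dat$truth$label, tree)
  bh <- leaf_confusion(tree$labels[bh_leaf_calls(sel$stats, tree, 0.05)],
                       dat$truth$label, tree)
  expect_gte(cs$TPR, bh$TPR)
  # at least one rejected node is internal (the climb aggregated something)
  expect_true(any(sel$rejected$node_id > tree$K))
})

test_that("treeclimb_run on null data rejects nothing or almost nothing", {
  set.seed(502)
  tree <- synthetic_tree(50)
  params <- random_dm(tree, theta = 0.02)
  hits <- 0L
  for (i in 1:5) {
    dat <- simulate_dataset(tree, params, NULL, nC = 8, nT = 8)
    sel <- treeclimb_run(tree, dat$counts, dat$groups, mode = "da", alpha = 0.05)
    hits <- hits + (length(sel$rejected_leaves) > 0L)
  }
  expect_lte(hits, 1L)
})

test_that("DS mode lets different features stop at different branches", {
  set.seed(503)
  tree <- parse_newick("(((A,B),(C,D)),((E,F),(G,H)));")
  ab_cd <- which(vapply(tree$b, function(b) identical(b, 1:4), TRUE))
  ef_gh <- which(vapply(tree$b, function(b) identical(b, 5:8), TRUE))
  n_per <- 12
  samples <- paste0("s", 1:16)
  groups <- factor(rep(c("C", "T"), each = 8)); names(groups) <- samples
  mk_cells <- function() {
    do.call(rbind, lapply(samples, function(s) {
      shift <- if (groups[[s]] == "T") 3 else 0
      data.frame(
        cell_id = paste0(s, "_", 1:(8 * n_per)),
        leaf_label = rep(LETTERS[1:8], each = n_per),
        sample_id = s,
        # g1: coherent shift on leaves A-D; g2: coherent shift on E-H
        g1 = rnorm(8 * n_per) + rep(c(shift, 0), each = 4 * n_per),
        g2 = rnorm(8 * n_per) + rep(c(0, shift), each = 4 * n_per))
    }))
  }
  cells <- mk_cells()
  sel <- treeclimb_run(tree, cells, groups, mode = "ds", alpha = 0.05)
  rej <- sel$rejected
  g1_leaves <- sort(unique(unlist(tree$b[rej$node_id[rej$feature == "g1"]])))
  g2_leaves <- sort(unique(unlist(tree$b[rej$node_id[rej$feature == "g2"]])))
  expect_true(all(g1_leaves %in% 1:4))
  expect_true(all(g2_leaves %in% 5:8))
  expect_gt(length(g1_leaves), 0)
  expect_gt(length(g2_leaves), 0)
})

test_that("results_table mirrors the winning rejections", {
  set.seed(504)
  tree <- synthetic_tree(30)
  params <- random_dm(tree, theta = 0.005)
  br <- strong_branch_pair(tree, params, 3, 8, min_abs_log_r = 0.3)
  sc <- apply_bs(params, br$A, br$B, tree)
  dat <- simulate_dataset(tree, params, sc, nC = 8, nT = 8)
  sel <- treeclimb_run(tree, dat$counts, dat$groups, mode = "da")
  rt <- results_table(sel, tree)
  expect_equal(nrow(rt), nrow(sel$rejected))
  if (nrow(rt)) {
    expect_true(all(rt$adjusted_p <= 0.05))
    expect_equal(rt$n_descendant_leaves, lengths(tree$b[rt$node_id]))
    expect_true(all(rt$selected_t == sel$t))
  }
})
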