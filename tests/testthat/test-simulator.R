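# Dirichlet-multinomial sampling, parameter estimation, and the three
# tree-located signal scenarios.

test_that("dm_params validates and derives alpha", {
  p <- dm_params(c(a = 0.25, b = 0.75), theta = 0.2, depths = 100)
  expect_equal(unname(p$alpha), c(0.25, 0.75) * 0.8 / 0.2)
  expect_error(dm_params(c(0.5, 0.6), 0.2, 100), "sum to 1")
  expect_error(dm_params(c(0.5, 0.5), 0, 100), "theta")
  expect_error(dm_params(c(0.5, 0.5), 1, 100), "theta")
})

test_that("sample_dm respects the total count and is seed-reproducible", {
  p <- dm_params(c(0.3, 0.7), theta = 0.1, depths = 100)
  expect_equal(unname(sample_dm(0, p)), c(0L, 0L))
  set.seed(1); a <- sample_dm(500, p)
  set.seed(1); b <- sample_dm(500, p)
  expect_identical(a, b)
  expect_equal(sum(a), 500)
  expect_error(sample_dm(-1, p), "nonnegative")
})

test_that("DM moments match the closed forms", {
  set.seed(600)
  p <- dm_params(c(0.5, 0.5), theta = 0.5, depths = 100)
  n <- 100L
  draws <- matrix(0L, nrow = 1e5, ncol = 2)
  for (i in seq_len(nrow(draws))) draws[i, ] <- sample_dm(n, p)
  x <- draws[, 1]
  mu <- n * 0.5
  v <- n * 0.5 * 0.5 * (1 + (n - 1) * 0.5)
  se_mean <- sqrt(v / length(x))
  expect_lt(abs(mean(x) - mu), 3 * se_mean)
  # variance of the sample variance via the empirical fourth moment
  m4 <- mean((x - mean(x))^4)
  se_var <- sqrt((m4 - var(x)^2) / length(x))
  expect_lt(abs(var(x) - v), 3 * se_var)
})

test_that("estimate_dm recovers pi and theta from simulated data", {
  set.seed(601)
  K <- 50; J <- 150
  pi <- rgamma(K, 2); pi <- pi / sum(pi)
  truth <- dm_params(pi, theta = 0.02, depths = 20000)
  counts <- vapply(seq_len(J), function(j) sample_dm(20000, truth),
                   integer(K))
  rownames(counts) <- paste0("otu", seq_len(K))
  est <- estimate_dm(counts)
  expect_lt(max(abs(est$pi - pi)), 0.01)
  expect_lt(abs(est$theta - 0.02), 0.01)
  expect_equal(est$depths, rep(20000, J), ignore_attr = TRUE)
})

test_that("estimate_dm hits the boundary on multinomial-like data", {
  set.seed(602)
  K <- 20; J <- 60
  pi <- rep(1 / K, K)
  counts <- stats::rmultinom(J, 5000, pi)   # no overdispersion
  rownames(counts) <- paste0("otu", seq_len(K))
  est <- estimate_dm(counts)
  expect_lte(est$theta, 0.005)

  # two identical samples repeated: no replicate variability at all
  one <- stats::rmultinom(1, 5000, pi)[, 1]
  twin <- matrix(rep(one, 6), ncol = 6,
                 dimnames = list(paste0("otu", seq_len(K)), NULL))
  est2 <- estimate_dm(twin)
  expect_lte(est2$theta, 1e-4)
  expect_error(estimate_dm(cbind(one, 0 * one)), "positive total")
})

test_that("pick_signal_branches respects constraints and the seed", {
  set.seed(603)
  tree <- synthetic_tree(100)
  params <- random_dm(tree)
  br <- pick_signal_branches(tree, params, min_leaves = 2, max_leaves = 10)
  for (node in c(br$A, br$B)) {
    expect_gte(length(descendant_leaves(tree, node)), 2)
    expect_lte(length(descendant_leaves(tree, node)), 10)
  }
  expect_length(intersect(descendant_leaves(tree, br$A),
                          descendant_leaves(tree, br$B)), 0)
  set.seed(603)
  tree2 <- synthetic_tree(100)
  params2 <- random_dm(tree2)
  br2 <- pick_signal_branches(tree2, params2, min_leaves = 2, max_leaves = 10)
  expect_identical(br, br2)
  expect_error(pick_signal_branches(tree, params, min_leaves = 101,
                                    max_leaves = 200), "feasible")
})

test_that("the balanced swap moves exactly the branch masses", {
  # two cherries with masses 0.1 and 0.2; the rest of the mass sits on e
  tree <- parse_newick("((a,b),((c,d),e));")
  pi <- c(a = 0.04, b = 0.06, c = 0.15, d = 0.05, e = 0.7)
  params <- dm_params(pi, theta = 0.1, depths = 1000)
  A <- which(vapply(tree$b, function(b) setequal(tree$labels[b], c("a", "b")), TRUE))
  B <- which(vapply(tree$b, function(b) setequal(tree$labels[b], c("c", "d")), TRUE))
  sc <- apply_bs(params, A, B, tree)
  piT <- treepin:::leaf_pi(tree, sc$params)
  expect_equal(sc$spec$fold_change, 2)
  expect_equal(sum(piT[c("a", "b")]), 0.2)   # A doubled
  expect_equal(sum(piT[c("c", "d")]), 0.1)   # B halved
  expect_equal(unname(piT["e"]), 0.7)        # untouched leaf is exact
  expect_equal(sum(piT), 1, tolerance = 1e-12)
  expect_equal(sort(sc$spec$truth$direction[sc$spec$truth$label %in% c("a", "b")]),
               c(1L, 1L))
  expect_equal(sort(sc$spec$truth$direction[sc$spec$truth$label %in% c("c", "d")]),
               c(-1L, -1L))
})

test_that("a null swap between equal-mass branches changes nothing", {
  tree <- parse_newick("((a,b),(c,d));")
  params <- dm_params(c(a = 0.2, b = 0.3, c = 0.1, d = 0.4), 0.1, 1000)
  A <- which(vapply(tree$b, function(b) setequal(tree$labels[b], c("a", "b")), TRUE))
  B <- which(vapply(tree$b, function(b) setequal(tree$labels[b], c("c", "d")), TRUE))
  sc <- apply_bs(params, A, B, tree)  # both masses are 0.5
  expect_equal(treepin:::leaf_pi(tree, sc$params),
               treepin:::leaf_pi(tree, params))
  expect_equal(nrow(sc$spec$truth), 0L)
})

test_that("scenarios conserve mass and leave non-truth leaves untouched", {
  set.seed(604)
  for (rep_i in 1:5) {
    tree <- synthetic_tree(40)
    params <- random_dm(tree)
    br <- pick_signal_branches(tree, params, 3, 8)
    pi0 <- treepin:::leaf_pi(tree, params)
    for (scen in c("BS", "US", "SS")) {
      sc <- switch(scen,
                   BS = apply_bs(params, br$A, br$B, tree),
                   US = apply_us(params, br$A, br$B, tree),
                   SS = apply_ss(params, br$A, br$B, tree, fraction = 0.5))
      piT <- treepin:::leaf_pi(tree, sc$params)
      expect_equal(sum(piT), 1, tolerance = 1e-12)
      truth_set <- sc$spec$truth$leaf
      outside <- setdiff(seq_len(tree$K),
                         union(descendant_leaves(tree, br$A),
                               descendant_leaves(tree, br$B)))
      expect_identical(piT[outside], pi0[outside])
      if (scen == "SS") {
        # unaffected leaves inside the branches keep pi exactly too
        inside_untouched <- setdiff(union(descendant_leaves(tree, br$A),
                                          descendant_leaves(tree, br$B)),
                                    truth_set)
        expect_identical(piT[inside_untouched], pi0[inside_untouched])
      }
      expect_true(all(truth_set %in% union(descendant_leaves(tree, br$A),
                                           descendant_leaves(tree, br$B))))
    }
  }
})

test_that("US multipliers are heterogeneous, seed-stable, and mass-swapping", {
  set.seed(605)
  tree <- synthetic_tree(30)
  params <- random_dm(tree)
  br <- pick_signal_branches(tree, params, 3, 8)
  set.seed(42); us1 <- apply_us(params, br$A, br$B, tree)
  set.seed(42); us2 <- apply_us(params, br$A, br$B, tree)
  expect_identical(us1$spec$multipliers, us2$spec$multipliers)
  mult_A <- us1$spec$multipliers[seq_along(tree$b[[br$A]])]
  expect_gt(stats::sd(mult_A), 0)      # unequal per-leaf fold changes
  pi0 <- treepin:::leaf_pi(tree, params)
  piT <- treepin:::leaf_pi(tree, us1$params)
  expect_equal(sum(piT[tree$b[[br$A]]]), sum(pi0[tree$b[[br$B]]]),
               tolerance = 1e-12)     # mass swap preserved
  expect_equal(sum(piT[tree$b[[br$B]]]), sum(pi0[tree$b[[br$A]]]),
               tolerance = 1e-12)
})

test_that("SS with fraction 1 reduces exactly to the balanced swap", {
  set.seed(606)
  tree <- synthetic_tree(25)
  params <- random_dm(tree)
  br <- pick_signal_branches(tree, params, 3, 6)
  bs <- apply_bs(params, br$A, br$B, tree)
  ss <- apply_ss(params, br$A, br$B, tree, fraction = 1)
  expect_identical(treepin:::leaf_pi(tree, ss$params),
                   treepin:::leaf_pi(tree, bs$params))
  expect_setequal(ss$spec$truth$leaf, bs$spec$truth$leaf)
  # fraction 0.5 on 4-leaf branches touches exactly 2 leaves per branch
  tr4 <- parse_newick("(((a,b),(c,d)),((e,f),(g,h)));")
  p4 <- dm_params(setNames(rep(0.125, 8), letters[1:8]), 0.1, 1000)
  A <- which(vapply(tr4$b, function(b) identical(b, 1:4), TRUE))
  B <- which(vapply(tr4$b, function(b) identical(b, 5:8), TRUE))
  ss4 <- apply_ss(p4, A, B, tr4, fraction = 0.5)
  expect_length(intersect(ss4$spec$S_A, 1:4), 2L)
  expect_length(intersect(ss4$spec$S_B, 5:8), 2L)
})

test_that("simulate_dataset draws reproducible tables with pooled depths", {
  set.seed(607)
  tree <- synthetic_tree(100)
  params <- random_dm(tree, depths = seq(10000, 50000, by = 1000))
  set.seed(1); d1 <- simulate_dataset(tree, params, NULL, nC = 10, nT = 10)
  set.seed(1); d2 <- simulate_dataset(tree, params, NULL, nC = 10, nT = 10)
  expect_identical(d1$counts, d2$counts)
  expect_equal(dim(d1$counts), c(100L, 20L))
  expect_true(all(colSums(d1$counts) %in% params$depths))
  expect_equal(levels(d1$groups), c("C", "T"))
  expect_equal(nrow(d1$truth), 0L)
})

test_that("null leaf-level rank-sum p-values are uniform across repetitions", {
  set.seed(608)
  tree <- synthetic_tree(50)
  params <- random_dm(tree, theta = 0.02)
  pvals <- c()
  for (i in 1:20) {
    dat <- simulate_dataset(tree, params, NULL, nC = 8, nT = 8)
    agg <- aggregate_da(tree, dat$counts)
    st <- wilcoxon_node_test(agg, dat$groups, normalize = TRUE)
    pvals <- c(pvals, st$p[seq_len(tree$K)])
  }
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 900)
  # exact rank-sum p-values are discrete (two-sided atoms push the mean a
  # little above 0.5); compare to the uniform via mean and tail mass
  expect_lt(abs(mean(pvals) - 0.5), 0.06)
  expect_lt(abs(mean(pvals <= 0.1) - 0.1), 0.03)
})

test_that("synthetic_tree builds valid binary trees", {
  set.seed(609)
  expect_equal(synthetic_tree(2)$M, 3L)
  big <- synthetic_tree(100)
  expect_equal(big$M, 199L)
  expect_equal(big$K, 100L)
  set.seed(4); a <- synthetic_tree(20)
  set.seed(4); b <- synthetic_tree(20)
  expect_identical(a$parent, b$parent)
  expect_error(synthetic_tree(1), "at least 2")
})
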