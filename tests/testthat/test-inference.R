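test_that("the two-taxon branch-length MLE matches the JC closed form", {
  # 1000 sites, 400 differing: p-hat = 0.4
  aln <- dna_alignment(c(
    A = strrep("A", 1000),
    B = paste0(strrep("A", 600), strrep("C", 400))
  ))
  tr <- parse_newick("(A:0.1,B:0.1);")
  fit <- optimize_branch_lengths(tr, aln, substitution_model(),
    tol = 1e-10, edge_tol = 1e-11
  )
  expect_equal(sum(fit$tree$edge.length),
    -3 / 4 * log(1 - 4 / 3 * 0.4),
    tolerance = 1e-8
  )
})

test_that("branch-length optimization is monotone and idempotent", {
  withr::with_seed(20, {
    tr <- random_blen_tree(6)
    m <- random_gtr_model()
    aln <- simulate_alignment(tr, m, L = 500)
    start <- tr
    start$edge.length <- rep(0.3, nrow(tr$edge))
    lnl0 <- tree_log_likelihood(start, aln, m)$total
    fit1 <- optimize_branch_lengths(start, aln, m)
    expect_gte(fit1$lnL, lnl0)
    fit2 <- optimize_branch_lengths(fit1$tree, aln, m)
    expect_lt(abs(fit2$lnL - fit1$lnL), 1e-5)
  })
})

test_that("branch lengths are recovered from long simulated alignments", {
  withr::with_seed(21, {
    tr <- random_blen_tree(6)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.4)
    m <- substitution_model(
      exch = c(1.5, 4, 0.9, 1.1, 4.5, 1),
      base_freq = c(0.3, 0.2, 0.2, 0.3)
    )
    aln <- simulate_alignment(tr, m, L = 5000)
    fit <- optimize_branch_lengths(tr, aln, m)
    # compare edge by edge: topology (and hence edge order) is unchanged
    expect_equal(fit$tree$edge.length, tr$edge.length, tolerance = 0.15)
  })
})

test_that("model parameters are recovered at the stated tolerances", {
  withr::with_seed(22, {
    tr <- random_blen_tree(8)
    gen <- substitution_model(
      exch = c(1.5, 4, 0.9, 1.1, 4.5, 1),
      base_freq = c(0.3, 0.2, 0.2, 0.3),
      gamma_shape = 0.5, p_inv = 0
    )
    aln <- simulate_alignment(tr, gen, L = 10000)
    fit <- optimize_model_parameters(tr, aln, family = "GTR+G+I")
    expect_gte(fit$model$gamma_shape, 0.35)
    expect_lte(fit$model$gamma_shape, 0.70)
    expect_lt(fit$model$p_inv, 0.05) # generated without invariable sites
    # transition exchangeabilities dominate transversions (HKY-like truth)
    expect_gt(min(fit$model$exch[c(2, 5)]), max(fit$model$exch[c(1, 3, 4)]))
  })
})

test_that("nni_neighbors produces the two other quartet resolutions", {
  t0 <- ape::unroot(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"))
  e <- internal_edge_of(t0)
  nb <- nni_neighbors(t0, e)
  expect_length(nb, 2)
  keys <- vapply(nb, function(t) bipartition_set(t)[1], "")
  expect_setequal(keys, c(
    bipartition_set(parse_newick("((A,C),(B,D));"))[1],
    bipartition_set(parse_newick("((A,D),(B,C));"))[1]
  ))
})

test_that("NNI moves are rf-2 involutions on random trees", {
  withr::with_seed(23, {
    for (i in 1:8) {
      tr <- ape::unroot(random_blen_tree(8))
      edges <- which(tr$edge[, 2] > length(tr$tip.label))
      e <- sample(edges, 1)
      nb <- nni_neighbors(tr, e)
      for (t2 in nb) expect_identical(rf_distance(tr, t2), 2L)
      # applying the same swap twice restores the topology
      cn <- attr(nb[[1]], "central")
      e2 <- which(nb[[1]]$edge[, 1] %in% cn & nb[[1]]$edge[, 2] %in% cn)[1]
      back <- nni_neighbors(nb[[1]], e2)
      expect_true(any(vapply(back, topologies_equal, TRUE, t1 = tr)))
    }
  })
})

test_that("nni_neighbors rejects terminal edges and rooted trees", {
  tr <- ape::unroot(random_blen_tree(6, seed = 2))
  tip_edge <- which(tr$edge[, 2] <= 6)[1]
  expect_error(nni_neighbors(tr, tip_edge), "terminal")
  rooted <- ape::root(random_blen_tree(6, seed = 2),
    outgroup = "t1", resolve.root = TRUE
  )
  expect_error(nni_neighbors(rooted, 1), "unrooted")
})

test_that("ml_search recovers a strong-signal quartet from every seed", {
  truth <- quartet_tree(internal = 0.3)
  m <- substitution_model()
  withr::with_seed(24, {
    ok <- vapply(1:10, function(i) {
      aln <- simulate_alignment(truth, m, L = 2000)
      res <- ml_search(aln, m, seed = i, optimize_model = FALSE)
      topologies_equal(res$tree, truth)
    }, TRUE)
    expect_identical(sum(ok), 10L)
  })
})

test_that("the search trace is monotone and the final lnL is its maximum", {
  withr::with_seed(25, {
    truth <- random_blen_tree(7)
    m <- random_gtr_model(gamma = FALSE, inv = FALSE)
    aln <- simulate_alignment(truth, m, L = 800)
    res <- ml_search(aln, m, seed = 1, optimize_model = FALSE)
    expect_true(all(diff(res$trace$lnL) >= -1e-9))
    expect_equal(res$lnL, max(res$trace$lnL), tolerance = 1e-9)
    expect_gte(res$lnL, res$trace$lnL[1])
    # a search started from the recovered tree makes no topology move
    res2 <- ml_search(aln, m, start = res$tree, seed = 1, optimize_model = FALSE)
    expect_identical(sum(res2$trace$move == "nni"), 0L)
  })
})

test_that("AIC is recomputable, nested and order-invariant", {
  withr::with_seed(26, {
    truth <- random_blen_tree(6)
    m <- substitution_model()
    aln <- simulate_alignment(truth, m, L = 1200)
    cands <- c("JC", "HKY+G", "GTR+G+I")
    sel <- aic_select(aln, truth, cands)
    expect_equal(sel$table$AIC, 2 * sel$table$K - 2 * sel$table$lnL, tolerance = 1e-9)
    # nesting: richer models never fit worse on the same data/topology
    lnl <- stats::setNames(sel$table$lnL, sel$table$model)
    expect_gte(lnl[["GTR+G+I"]] + 1e-4, lnl[["JC"]])
    # candidate order does not change the winner
    sel_rev <- aic_select(aln, truth, rev(cands))
    expect_identical(sel$selected, sel_rev$selected)
    expect_error(aic_select(aln, truth, character(0)), "empty")
  })
})

test_that("JC-generated data do not elect a saturated model", {
  withr::with_seed(27, {
    truth <- random_blen_tree(6)
    aln <- simulate_alignment(truth, substitution_model(), L = 5000)
    sel <- aic_select(aln, truth, c("JC", "JC+G", "GTR+G+I"))
    expect_true(sel$selected %in% c("JC", "JC+G"))
  })
})

test_that("bootstrap supports are proportions, deterministic and signal-sensitive", {
  truth <- quartet_tree(internal = 0.3)
  m <- substitution_model()
  withr::with_seed(28, {
    aln <- simulate_alignment(truth, m, L = 2000)
  })
  ml <- ml_search(aln, m, seed = 1, optimize_model = FALSE)
  bs <- bootstrap_support(aln, m, ml$tree, n_reps = 20, seed = 5)
  expect_true(all(bs$support >= 0 & bs$support <= 1))
  expect_gte(bs$support[[bipartition_set(truth)[1]]], 0.95)
  bs2 <- bootstrap_support(aln, m, ml$tree, n_reps = 20, seed = 5)
  expect_identical(bs$support, bs2$support)
  expect_false(is.null(bs$tree$node.label))
})
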