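test_that("constrained trees mirror the host topology by construction", {
  # all taxa mapped: the constraint is the host topology with virus labels
  host <- simulate_host_tree(7, seed = 100)
  vt <- simulate_virus_tree(host, n_switches = 2, seed = 101)
  assoc <- attr(vt, "association")
  con <- build_constrained_tree(vt, host, assoc)
  expect_true(topologies_equal(map_and_prune(con, assoc), host))

  # already congruent input: the constraint is the input topology
  vt0 <- simulate_virus_tree(host, n_switches = 0, seed = 102)
  con0 <- build_constrained_tree(vt0, host, attr(vt0, "association"))
  expect_true(topologies_equal(con0, vt0))
})

test_that("constrained trees keep outgroup splits untouched", {
  withr::with_seed(103, {
    host <- simulate_host_tree(7, seed = 104)
    vt <- simulate_virus_tree(host, n_switches = 2, seed = 105)
    assoc <- attr(vt, "association")
    # attach an outgroup cherry midway along the edge above virus03
    og <- structure(
      list(
        edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
        tip.label = c("out1", "out2"), Nnode = 1L,
        edge.length = c(0.3, 0.3),
        root.edge = 0.1
      ),
      class = "phylo"
    )
    tip3 <- which(vt$tip.label == "virus03")
    stalk <- vt$edge.length[which(vt$edge[, 2] == tip3)]
    aug <- ape::bind.tree(vt, og, where = tip3, position = stalk / 2)
    con <- build_constrained_tree(aug, host, assoc)
    expect_setequal(con$tip.label, aug$tip.label)
    expect_true(topologies_equal(map_and_prune(con, assoc), host))
    # the outgroup pair survives as a split (canonical key: the side not
    # containing the lexicographically smallest leaf)
    key_for <- function(tree, side) {
      labs <- tree$tip.label
      if (sort(labs)[1] %in% side) side <- setdiff(labs, side)
      paste(sort(side), collapse = "|")
    }
    expect_true(key_for(con, c("out1", "out2")) %in% bipartition_set(con))
    expect_error(
      build_constrained_tree(vt, host, host_association("virusXX", "host01")),
      "absent from ml_tree"
    )
    expect_error(
      build_constrained_tree(vt, host, host_association("virus01", "hostXX")),
      "missing mapped host"
    )
  })
})

test_that("the SH test is null on identical topologies and detects switches", {
  fx <- make_fixture(cophylogeny_scenario(n_hosts = 7, n_switches = 0, seed = 110), L = 500)
  m <- default_fixture_model()
  bl <- optimize_branch_lengths(fx$virus_tree, fx$alignment, m)
  same <- sh_test(fx$alignment, m, list(bl$tree, bl$tree),
    n_rell = 200, seed = 1, optimize = FALSE
  )
  expect_equal(same$sh_delta, 0)
  expect_equal(same$sh_p, 1)
  expect_error(sh_test(fx$alignment, m, list(bl$tree), n_rell = 200), "two candidate")
  expect_error(sh_test(fx$alignment, m, list(bl$tree, bl$tree), n_rell = 10), ">= 100")

  # a 3-switch tree is firmly rejected against the truth
  fx3 <- make_fixture(cophylogeny_scenario(n_hosts = 7, n_switches = 3, seed = 111), L = 2000)
  con <- build_constrained_tree(fx3$virus_tree, fx3$host_tree, fx3$assoc)
  sh <- sh_test(fx3$alignment, default_fixture_model(), list(fx3$virus_tree, con), seed = 2)
  expect_gt(sh$sh_delta, 0)
  expect_lt(sh$sh_p, 0.05)
  # determinism given the seed
  sh2 <- sh_test(fx3$alignment, default_fixture_model(), list(fx3$virus_tree, con), seed = 2)
  expect_identical(sh$table, sh2$table)
})

test_that("sh_test rejects topologies on different taxon sets", {
  t1 <- random_blen_tree(5, seed = 1)
  t2 <- random_topology(letters[1:5], seed = 2)
  aln <- simulate_alignment(t1, substitution_model(), L = 50, seed = 3)
  expect_error(
    sh_test(aln, substitution_model(), list(t1, t2), n_rell = 100),
    "different taxon sets"
  )
})

test_that("posterior match proportion counts exact unrooted matches", {
  host <- simulate_host_tree(6, seed = 120)
  vt <- simulate_virus_tree(host, n_switches = 0, seed = 121)
  assoc <- attr(vt, "association")
  other <- random_topology(vt$tip.label, seed = 122)
  ps <- posterior_sample(
    c(replicate(7, vt, simplify = FALSE), list(other)),
    burnin_applied = TRUE
  )
  res <- posterior_match_proportion(ps, host, assoc)
  expect_equal(res$n, 8)
  expect_gte(res$matches, 7)
  expect_equal(res$proportion, res$matches / 8)
  expect_error(
    posterior_match_proportion(posterior_sample(list(), burnin_applied = TRUE), host, assoc),
    "empty"
  )
  # invariance to rerooting of posterior trees and host
  rr <- ape::root(vt, outgroup = vt$tip.label[4], resolve.root = TRUE)
  host_rr <- ape::root(host, outgroup = host$tip.label[2], resolve.root = TRUE)
  res2 <- posterior_match_proportion(
    posterior_sample(list(rr), burnin_applied = TRUE), host_rr, assoc
  )
  expect_equal(res2$proportion, 1)
})

test_that("a host-identical posterior yields an RF-null fraction of zero", {
  host <- simulate_host_tree(7, seed = 130)
  vt <- simulate_virus_tree(host, n_switches = 0, seed = 131)
  assoc <- attr(vt, "association")
  ps <- posterior_sample(replicate(5, vt, simplify = FALSE), burnin_applied = TRUE)
  res <- rf_null_test(ps, host, assoc, n_random = 500, seed = 7)
  expect_identical(res$rf_null_fraction, 0)
  expect_true(all(res$posterior_rf == 0L))
  expect_length(res$null_rf, 500)
})

test_that("the RF null fraction agrees with exhaustive 7-leaf enumeration", {
  host <- simulate_host_tree(7, seed = 140)
  assoc <- host_association(paste0("virus0", 1:7), paste0("host0", 1:7))
  # a "posterior" of uniformly random topologies
  post <- withr::with_seed(141, {
    replicate(200, random_topology(paste0("virus0", 1:7)), simplify = FALSE)
  })
  ps <- posterior_sample(post, burnin_applied = TRUE)
  res <- rf_null_test(ps, host, assoc, n_random = 10000, seed = 142)

  all945 <- enumerate_topologies(host$tip.label)
  expect_length(all945, 945)
  host_cmp <- host
  host_cmp$edge.length <- NULL
  exact_rf <- vapply(all945, function(nwk) {
    rf_distance(parse_newick(nwk), host_cmp)
  }, 0L)
  d_star <- mean(res$posterior_rf)
  exact_fraction <- mean(exact_rf < d_star)
  se <- sqrt(exact_fraction * (1 - exact_fraction) / 10000)
  expect_lt(abs(res$rf_null_fraction - exact_fraction), 4 * se + 1e-9)
  # both summaries are reported
  expect_true(is.finite(res$fraction_median))
})

test_that("congruence reports round-trip through their serialized form", {
  rep <- structure(
    list(
      sh_delta = 12.5, sh_p = 0.021, match_proportion = 0.4,
      match_count = 4L, posterior_size = 10L,
      rf_null_fraction = 0.02, rf_null_fraction_mean = 0.02,
      rf_null_fraction_median = 0.015,
      posterior_rf_distribution = c(0L, 2L, 2L, 4L),
      null_rf_distribution = c(8L, 6L, 8L, 4L, 8L),
      selected_model = "GTR+G+I", ml_lnL = -1234.5,
      settings = list(
        n_rell = 1000L, n_random = 100L, summary = "mean",
        seed = 3L, candidates = c("JC", "GTR+G+I")
      )
    ),
    class = "congruence_report"
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_congruence_report(rep, path)
  back <- read_congruence_report(path)
  expect_equal(unclass(back), unclass(rep), tolerance = 1e-12)
})

test_that("the full congruence suite distinguishes cospeciation from switching", {
  # small, fast settings: the pattern (not the precision) is the point
  fx <- make_fixture(cophylogeny_scenario(n_hosts = 6, n_switches = 0, seed = 150), L = 800)
  cfg <- list(
    candidates = c("HKY+G"), n_rell = 500, n_random = 500,
    mcmc = mcmc_config(generations = 6000, sample_every = 30, seed = 151),
    seed = 152
  )
  rep0 <- run_congruence_suite(fx$alignment, fx$host_tree, fx$assoc, cfg)
  expect_gt(rep0$sh_p, 0.05)
  expect_gte(rep0$match_proportion, 0.9)
  # at most the share of random 6-leaf topologies identical to the host
  expect_lte(rep0$rf_null_fraction, 0.05)

  fx3 <- make_fixture(cophylogeny_scenario(n_hosts = 6, n_switches = 3, seed = 153), L = 800)
  rep3 <- run_congruence_suite(fx3$alignment, fx3$host_tree, fx3$assoc, cfg)
  expect_lt(rep3$sh_p, 0.05)
  expect_equal(rep3$match_proportion, 0)
  expect_gt(rep3$sh_delta, rep0$sh_delta)
})

test_that("an external posterior can replace the built-in sampler", {
  fx <- make_fixture(cophylogeny_scenario(n_hosts = 6, n_switches = 0, seed = 160), L = 300)
  trees <- replicate(10, fx$virus_tree, simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".t")
  write_nexus_trees(posterior_sample(trees, burnin_applied = TRUE), path)
  cfg <- list(
    candidates = c("JC"), n_rell = 200, n_random = 200,
    posterior = read_nexus_trees(path), seed = 161
  )
  rep <- run_congruence_suite(fx$alignment, fx$host_tree, fx$assoc, cfg)
  # burn-in is applied to the ingested sample: 10 trees keep 8
  expect_equal(rep$posterior_size, 8)
  expect_equal(rep$match_proportion, 1)
})
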