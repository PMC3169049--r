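test_that("parse_newick reads labels, lengths and rootedness", {
  tr <- parse_newick("((A:1,B:1):0.5,C:1);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_true(ape::is.rooted(tr))
  expect_equal(sort(tr$edge.length), c(0.5, 1, 1, 1))

  star <- parse_newick("(A,B,C);")
  expect_false(ape::is.rooted(star))
  expect_null(star$edge.length)
})

test_that("parse_newick rejects malformed input with a useful message", {
  expect_error(parse_newick("((A,B,C);"), "unbalanced")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate leaf label.*A")
})

test_that("parse/write round-trip preserves topology and branch lengths", {
  for (i in 1:20) {
    tr <- random_blen_tree(10, seed = 100 + i)
    back <- parse_newick(write_newick(tr))
    expect_true(topologies_equal(tr, back))
    # branch lengths compared via the sorted multiset (node numbering may
    # differ between serializations)
    expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  }
})

test_that("bipartition sets have the expected size and canonical form", {
  expect_length(bipartition_set(parse_newick("((A,B),(C,D));")), 1)
  expect_length(bipartition_set(parse_newick("(A,B,C);")), 0)
  t7 <- random_topology(letters[1:7], seed = 3)
  expect_length(bipartition_set(t7), 4) # n - 3

  # same split read from either side yields one canonical key
  a <- parse_newick("((A,B),(C,D));")
  b <- parse_newick("((C,D),(A,B));")
  expect_identical(bipartition_set(a), bipartition_set(b))
})

test_that("bipartition sets are invariant to rooting", {
  for (i in 1:10) {
    tr <- random_topology(letters[1:8], seed = 200 + i)
    rooted <- ape::root(tr, outgroup = "a", resolve.root = TRUE)
    expect_setequal(bipartition_set(tr), bipartition_set(rooted))
  }
})

test_that("rf_distance matches the brute-force oracle and phangorn", {
  skip_if_not_installed("phangorn")
  attained <- integer(0)
  for (i in 1:50) {
    t1 <- random_topology(paste0("s", 1:8), seed = 300 + i)
    t2 <- random_topology(paste0("s", 1:8), seed = 400 + i)
    d <- rf_distance(t1, t2)
    expect_identical(d, brute_rf(t1, t2))
    expect_identical(d, rf_distance(t2, t1))
    expect_equal(d, as.integer(phangorn::RF.dist(t1, t2)))
    expect_true(d >= 0 && d <= 2 * (8 - 3))
    attained <- c(attained, d)
  }
  t <- random_topology(paste0("s", 1:8), seed = 1)
  expect_identical(rf_distance(t, t), 0L)
})

test_that("RF behaves as a metric on sampled triples", {
  for (i in 1:15) {
    a <- random_topology(letters[1:7], seed = 500 + i)
    b <- random_topology(letters[1:7], seed = 600 + i)
    c <- random_topology(letters[1:7], seed = 700 + i)
    expect_true(rf_distance(a, c) <= rf_distance(a, b) + rf_distance(b, c))
    expect_identical(rf_distance(a, b) == 0L, topologies_equal(a, b))
  }
})

test_that("rf_distance reports the leaf-set difference on mismatch", {
  t1 <- random_topology(letters[1:5], seed = 1)
  t2 <- random_topology(letters[2:6], seed = 1)
  expect_error(rf_distance(t1, t2), "only in first.*a.*only in second.*f")
})

test_that("normalized RF divides by 2(n-3)", {
  t1 <- random_topology(letters[1:8], seed = 11)
  t2 <- random_topology(letters[1:8], seed = 12)
  expect_equal(
    rf_distance(t1, t2, normalized = TRUE),
    rf_distance(t1, t2) / 10
  )
})

test_that("random_topology draws uniformly (chi-square at alpha = 0.01)", {
  # n = 4: the three topologies should be equifrequent over 9999 draws
  taxa <- c("A", "B", "C", "D")
  refs <- lapply(
    c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
    parse_newick
  )
  ref_keys <- vapply(refs, function(t) bipartition_set(t)[1], "")
  draws <- withr::with_seed(42, replicate(9999, bipartition_set(random_topology(taxa))[1]))
  counts <- table(factor(draws, levels = ref_keys))
  expect_true(all(counts > 0))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("random_topology covers all 15 five-leaf topologies", {
  keys <- withr::with_seed(7, replicate(10000, {
    paste(sort(bipartition_set(random_topology(letters[1:5]))), collapse = ";")
  }))
  expect_identical(length(unique(keys)), 15L)
  expect_gt(stats::chisq.test(table(keys))$p.value, 0.01)
})

test_that("random_topology is deterministic given a seed and validates input", {
  a <- random_topology(letters[1:9], seed = 99)
  b <- random_topology(letters[1:9], seed = 99)
  expect_true(topologies_equal(a, b))
  expect_error(random_topology(c("A", "B")), "at least 3")
  expect_error(random_topology(c("A", "A", "B")), "unique")
})

test_that("map_and_prune prunes, relabels and drops lengths", {
  vt <- random_blen_tree(10, seed = 5)
  assoc <- host_association(paste0("t", 1:7), paste0("h", 1:7))
  pruned <- map_and_prune(vt, assoc)
  expect_setequal(pruned$tip.label, paste0("h", 1:7))
  expect_null(pruned$edge.length)

  # restriction property: the pruned splits are the original splits cut
  # down to the mapped leaf set
  keep <- paste0("t", 1:7)
  expected <- unique(unlist(lapply(brute_splits(vt), function(k) {
    tips <- intersect(strsplit(k, "|", fixed = TRUE)[[1]], keep)
    if (length(tips) <= 1 || length(tips) >= 6) {
      return(character(0))
    }
    ref <- sort(keep)[1]
    if (ref %in% tips) tips <- sort(setdiff(keep, tips))
    paste(sort(tips), collapse = "|")
  })))
  got <- vapply(bipartition_set(pruned), function(k) {
    tips <- strsplit(k, "|", fixed = TRUE)[[1]]
    paste(sort(sub("^h", "t", tips)), collapse = "|")
  }, "")
  # note: relabelled back to t-names; canonical reference taxon is shared
  expect_setequal(unname(got), setdiff(expected, NA))

  expect_error(
    map_and_prune(vt, host_association("t99", "h99")),
    "absent from the tree: t99"
  )
})

test_that("map_and_prune over all leaves is a relabelling", {
  vt <- random_blen_tree(6, seed = 8)
  assoc <- host_association(paste0("t", 1:6), paste0("h", 1:6))
  pruned <- map_and_prune(vt, assoc)
  relab <- vt
  relab$tip.label <- paste0("h", 1:6)
  expect_true(topologies_equal(pruned, relab))
})

test_that("topologies_equal ignores rooting and child order", {
  tr <- random_blen_tree(7, seed = 21)
  rerooted <- ape::root(tr, outgroup = tr$tip.label[3], resolve.root = TRUE)
  expect_true(topologies_equal(tr, rerooted))

  nwk <- "((A,B),(C,(D,E)));"
  swapped <- "(((E,D),C),(B,A));"
  expect_true(topologies_equal(parse_newick(nwk), parse_newick(swapped)))

  # one NNI apart is never equal
  t0 <- ape::unroot(random_blen_tree(6, seed = 31))
  nb <- nni_neighbors(t0, internal_edge_of(t0))
  expect_false(topologies_equal(t0, nb[[1]]))
  expect_identical(rf_distance(t0, nb[[1]]), 2L)
})

test_that("NEXUS posterior samples read through the translate table", {
  nex <- paste(
    "#NEXUS",
    "begin trees;",
    "  translate",
    "    1 A,",
    "    2 B,",
    "    3 C,",
    "    4 D;",
    "  tree gen.100 = ((1:0.1,2:0.1):0.05,(3:0.1,4:0.1):0.05);",
    "  tree gen.200 = ((1:0.1,3:0.1):0.05,(2:0.1,4:0.1):0.05);",
    "end;",
    sep = "\n"
  )
  ps <- read_nexus_trees(nex)
  expect_s3_class(ps, "posterior_sample")
  expect_length(ps, 2)
  expect_false(ps$burnin_applied)
  expect_setequal(ps$trees[[1]]$tip.label, c("A", "B", "C", "D"))
  expect_false(topologies_equal(ps$trees[[1]], ps$trees[[2]]))

  # dialect tolerance: no translate table, named tips
  nex2 <- paste(
    "#NEXUS",
    "begin trees;",
    "  tree one = ((A:1,B:1):1,(C:1,D:1):1);",
    "end;",
    sep = "\n"
  )
  ps2 <- read_nexus_trees(nex2)
  expect_length(ps2, 1)
  expect_true(topologies_equal(ps2$trees[[1]], ps$trees[[1]]))
})

test_that("posterior samples round-trip through the NEXUS writer", {
  trees <- lapply(1:5, function(i) random_blen_tree(6, seed = 800 + i))
  ps <- posterior_sample(trees, burnin_applied = TRUE)
  path <- withr::local_tempfile(fileext = ".t")
  write_nexus_trees(ps, path)
  back <- read_nexus_trees(path)
  expect_length(back, 5)
  for (i in 1:5) expect_true(topologies_equal(back$trees[[i]], trees[[i]]))
})

test_that("apply_burnin drops the leading fraction", {
  trees <- lapply(1:8, function(i) random_blen_tree(5, seed = 900 + i))
  ps <- apply_burnin(posterior_sample(trees), fraction = 0.25)
  expect_length(ps, 6)
  expect_true(ps$burnin_applied)
  expect_true(topologies_equal(ps$trees[[1]], trees[[3]]))
})

test_that("association tables validate and round-trip through TSV", {
  expect_error(host_association(c("v1", "v1"), c("h1", "h2")), "duplicate parasite")
  expect_error(host_association(c("v1", "v2"), c("h1", "h1")), "not injective")
  assoc <- host_association(paste0("v", 1:4), paste0("h", 1:4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_association(assoc, path)
  writeLines(c("# comment line", readLines(path)), path)
  back <- read_association(path)
  expect_identical(
    as.character(back[names(assoc)]),
    as.character(assoc)
  )
})
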