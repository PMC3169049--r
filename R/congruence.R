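#' Build a host-constrained virus topology
#'
#' Rearranges the mapped virus leaves of an ML tree so that their induced
#' topology mirrors the host tree, while leaving unmapped (outgroup) taxa
#' in their original arrangement. The host-shaped subtree is grafted at the
#' attachment point of the lexicographically smallest mapped leaf, so by
#' construction `map_and_prune(result)` equals the host topology. Branch
#' lengths are dropped; re-optimize them before computing likelihoods.
#'
#' @param ml_tree the unconstrained virus tree (a `phylo`).
#' @param host_tree the host tree (a `phylo`; extra hosts are pruned).
#' @param assoc a [host_association].
#' @return a topology-only `phylo` on `ml_tree`'s full leaf set.
#' @export
build_constrained_tree <- function(ml_tree, host_tree, assoc) {
  assoc <- as_host_association(assoc)
  mapped <- names(assoc)
  missing_v <- setdiff(mapped, ml_tree$tip.label)
  if (length(missing_v)) {
    stop_ct("mapped virus taxa absent from ml_tree: ", paste(missing_v, collapse = ", "))
  }
  missing_h <- setdiff(unname(assoc), host_tree$tip.label)
  if (length(missing_h)) {
    stop_ct("host tree is missing mapped host taxa: ", paste(missing_h, collapse = ", "))
  }
  # host topology restricted to the mapped hosts, relabelled to virus names
  hsub <- ape::keep.tip(host_tree, unname(assoc))
  inv <- stats::setNames(names(assoc), unname(assoc))
  hsub$tip.label <- unname(inv[hsub$tip.label])
  hsub$edge.length <- NULL
  hsub$node.label <- NULL

  unmapped <- setdiff(ml_tree$tip.label, mapped)
  if (!length(unmapped)) {
    out <- hsub
  } else {
    anchor <- sort(mapped)[1]
    backbone <- ape::drop.tip(ml_tree, setdiff(mapped, anchor))
    backbone$edge.length <- NULL
    backbone$node.label <- NULL
    where <- which(backbone$tip.label == anchor)
    grafted <- ape::bind.tree(backbone, hsub, where = where)
    out <- grafted
  }
  out$edge.length <- NULL
  # construction invariant: the induced topology on mapped taxa is the host's
  chk <- map_and_prune(out, assoc)
  if (!topologies_equal(chk, {
    h <- ape::keep.tip(host_tree, unname(assoc))
    h$edge.length <- NULL
    h
  })) {
    stop_ct("internal error: constrained tree does not mirror the host topology")
  }
  out
}

#' Shimodaira-Hasegawa test of candidate topologies
#'
#' Compares the likelihoods of candidate topologies (here: the ML tree and
#' the host-constrained tree) using RELL resampling of per-site
#' log-likelihoods. For each topology, branch lengths are optimized on the
#' supplied alignment under the supplied model; the observed statistic for
#' a topology is the log-likelihood gap to the best topology. Replicates
#' resample site columns with replacement; per-topology replicate sums are
#' centred by their own mean, and the replicate statistic is the
#' max-over-topologies centred value minus the topology's centred value.
#' The p-value is the fraction of replicates at least as extreme as the
#' observed gap — the standard conservative SH recipe.
#'
#' @param aln a [dna_alignment].
#' @param model a [substitution_model()] (typically the ML fit).
#' @param topologies list of `phylo` objects on the same taxa; the first is
#'   conventionally the ML tree and the second the constrained tree.
#' @param n_rell number of RELL bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @param optimize if `TRUE` (default) branch lengths of every candidate
#'   are re-optimized before the test.
#' @return list of class `sh_test`: `table` (per-topology lnL, delta, p),
#'   `sh_delta` (2 * lnL gap of topology 2, the constrained one), `sh_p`
#'   (its p-value), `n_rell`, `seed`.
#' @export
sh_test <- function(aln, model, topologies, n_rell = 1000, seed = NULL,
                    optimize = TRUE) {
  if (n_rell < 100) stop_ct("n_rell must be >= 100")
  if (length(topologies) < 2) stop_ct("need at least two candidate topologies")
  taxa0 <- sort(topologies[[1]]$tip.label)
  for (t in topologies[-1]) {
    if (!identical(sort(t$tip.label), taxa0)) {
      stop_ct("candidate topologies have different taxon sets")
    }
  }
  sitemat <- sapply(topologies, function(tr) {
    if (optimize) {
      tr <- optimize_branch_lengths(tr, aln, model, tol = 1e-6, max_sweeps = 30)$tree
    }
    tree_log_likelihood(tr, aln, model)$site_lnl
  })
  totals <- colSums(sitemat)
  best <- which.max(totals)
  delta_obs <- totals[best] - totals
  L <- nrow(sitemat)
  ntop <- length(topologies)
  with_seed(seed, {
    reps <- matrix(0, n_rell, ntop)
    for (b in seq_len(n_rell)) {
      cols <- sample.int(L, L, replace = TRUE)
      reps[b, ] <- colSums(sitemat[cols, , drop = FALSE])
    }
    centred <- sweep(reps, 2, colMeans(reps))
    repmax <- apply(centred, 1, max)
    pvals <- vapply(seq_len(ntop), function(i) {
      mean((repmax - centred[, i]) >= delta_obs[i])
    }, 0)
    structure(
      list(
        table = data.frame(
          topology = seq_len(ntop), lnL = totals,
          delta = delta_obs, p = pvals
        ),
        sh_delta = 2 * delta_obs[2],
        sh_p = pvals[2],
        n_rell = n_rell, seed = seed
      ),
      class = "sh_test"
    )
  })
}

#' @export
print.sh_test <- function(x, ...) {
  cat(
    "SH test: 2*delta(lnL) =", format(x$sh_delta, digits = 6),
    ", p =", format(x$sh_p, digits = 4),
    "(", x$n_rell, "RELL replicates )\n"
  )
  invisible(x)
}

#' Proportion of posterior virus topologies matching the host tree
#'
#' Every sampled tree is restricted to the mapped taxa, relabelled to host
#' names ([map_and_prune()]) and compared to the host topology unrooted.
#'
#' @param sample a [posterior_sample] with burn-in applied.
#' @param host_tree the host `phylo` (extra hosts are pruned).
#' @param assoc a [host_association].
#' @return list with `proportion`, `matches` and `n`.
#' @export
posterior_match_proportion <- function(sample, host_tree, assoc) {
  stopifnot(inherits(sample, "posterior_sample"))
  if (!length(sample$trees)) stop_ct("posterior sample is empty")
  if (!sample$burnin_applied) {
    warning("posterior sample has burn-in not applied; applying none")
  }
  assoc <- as_host_association(assoc)
  host <- ape::keep.tip(host_tree, unname(assoc))
  host_keys <- bipartition_set(host)
  matches <- vapply(sample$trees, function(tr) {
    pr <- map_and_prune(tr, assoc)
    setequal(bipartition_set(pr), host_keys)
  }, logical(1))
  list(
    proportion = mean(matches), matches = sum(matches),
    n = length(matches)
  )
}

#' Robinson-Foulds random-topology null test
#'
#' Is the posterior sample of virus topologies closer to the host topology
#' than random trees are? The posterior RF distribution is summarized (mean
#' by default; median optional) and compared with the RF distances of
#' `n_random` uniformly random binary topologies on the host leaf set: the
#' reported fraction is the share of random topologies strictly closer to
#' the host tree than the posterior summary.
#'
#' @param sample a [posterior_sample].
#' @param host_tree the host `phylo`.
#' @param assoc a [host_association].
#' @param n_random number of random topologies (default 10000).
#' @param summary `"mean"` (default) or `"median"`.
#' @param seed optional integer seed.
#' @return list of class `rf_null`: `rf_null_fraction`, the fraction under
#'   the alternate summary (`fraction_mean`, `fraction_median`),
#'   `posterior_rf` and `null_rf` (integer distributions), `summary`,
#'   `n_random`, `seed`.
#' @export
rf_null_test <- function(sample, host_tree, assoc, n_random = 10000,
                         summary = c("mean", "median"), seed = NULL) {
  stopifnot(inherits(sample, "posterior_sample"))
  if (!length(sample$trees)) stop_ct("posterior sample is empty")
  if (n_random < 100) stop_ct("n_random must be >= 100")
  summary <- match.arg(summary)
  assoc <- as_host_association(assoc)
  host <- ape::keep.tip(host_tree, unname(assoc))
  host$edge.length <- NULL
  host_keys <- bipartition_set(host)
  post_rf <- vapply(sample$trees, function(tr) {
    keys <- bipartition_set(map_and_prune(tr, assoc))
    length(setdiff(keys, host_keys)) + length(setdiff(host_keys, keys))
  }, 0L)
  with_seed(seed, {
    null_rf <- vapply(seq_len(n_random), function(i) {
      keys <- bipartition_set(random_topology(host$tip.label))
      length(setdiff(keys, host_keys)) + length(setdiff(host_keys, keys))
    }, 0L)
    d_mean <- mean(post_rf)
    d_median <- stats::median(post_rf)
    fr_mean <- mean(null_rf < d_mean)
    fr_median <- mean(null_rf < d_median)
    structure(
      list(
        rf_null_fraction = if (summary == "mean") fr_mean else fr_median,
        fraction_mean = fr_mean, fraction_median = fr_median,
        posterior_rf = post_rf, null_rf = null_rf,
        summary = summary, n_random = n_random, seed = seed
      ),
      class = "rf_null"
    )
  })
}

#' @export
print.rf_null <- function(x, ...) {
  cat(
    "RF null test:", format(100 * x$rf_null_fraction, digits = 3),
    "% of", x$n_random, "random topologies are closer to the host tree",
    "than the posterior", x$summary,
    "RF (", format(mean(x$posterior_rf), digits = 4), ")\n"
  )
  invisible(x)
}

#' Run the full host-virus congruence test battery
#'
#' The complete pipeline: ML tree search with AIC model selection, the SH
#' test against the host-constrained topology, a Bayesian posterior sample
#' (run here, or supplied externally), the posterior topology-matching
#' proportion, and the Robinson-Foulds random-topology null.
#'
#' @param aln virus gene alignment (a [dna_alignment]).
#' @param host_tree host `phylo`.
#' @param assoc a [host_association].
#' @param config list of settings; recognized entries (with defaults):
#'   `candidates` (model ladder for AIC, default [default_candidates()]),
#'   `n_rell` (1000), `n_random` (10000), `summary` ("mean"),
#'   `mcmc` (an [mcmc_config()]; default 50000 generations sampled every
#'   50, 25 per cent burn-in), `posterior` (an external [posterior_sample]
#'   to use instead of running MCMC), `seed` (master seed, default 1).
#' @return an object of class `congruence_report`.
#' @export
run_congruence_suite <- function(aln, host_tree, assoc, config = list()) {
  assoc <- as_host_association(assoc)
  seed <- config$seed %||% 1L
  n_rell <- config$n_rell %||% 1000L
  n_random <- config$n_random %||% 10000L
  summary <- config$summary %||% "mean"
  candidates <- config$candidates %||% default_candidates()
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_ct("congruence stage '", what, "' failed: ", conditionMessage(e))
    })
  }
  ml0 <- stage("ml_search", ml_search(aln, substitution_model(),
    seed = seed, optimize_model = FALSE
  ))
  sel <- stage("aic_select", aic_select(aln, ml0$tree, candidates))
  ml <- stage("ml_refit", ml_search(aln, sel$model,
    start = sel$tree,
    seed = seed, optimize_model = TRUE
  ))
  constrained <- stage(
    "build_constrained_tree",
    build_constrained_tree(ml$tree, host_tree, assoc)
  )
  sh <- stage("sh_test", sh_test(aln, ml$model,
    list(ml$tree, constrained),
    n_rell = n_rell, seed = seed + 1L
  ))
  post <- config$posterior
  if (is.null(post)) {
    mc <- config$mcmc %||% mcmc_config(
      generations = 50000, sample_every = 50,
      burnin_frac = 0.25
    )
    if (is.null(mc$seed)) mc$seed <- seed + 2L
    post <- stage("mcmc_sample", mcmc_sample(aln,
      family = ml$family %||% "GTR+G+I",
      config = mc
    ))
  } else if (!post$burnin_applied) {
    post <- apply_burnin(post)
  }
  match <- stage(
    "posterior_match_proportion",
    posterior_match_proportion(post, host_tree, assoc)
  )
  rfnull <- stage("rf_null_test", rf_null_test(post, host_tree, assoc,
    n_random = n_random, summary = summary, seed = seed + 3L
  ))
  structure(
    list(
      sh_delta = sh$sh_delta,
      sh_p = sh$sh_p,
      match_proportion = match$proportion,
      match_count = match$matches,
      posterior_size = match$n,
      rf_null_fraction = rfnull$rf_null_fraction,
      rf_null_fraction_mean = rfnull$fraction_mean,
      rf_null_fraction_median = rfnull$fraction_median,
      posterior_rf_distribution = as.integer(rfnull$posterior_rf),
      null_rf_distribution = as.integer(rfnull$null_rf),
      selected_model = sel$selected,
      ml_lnL = ml$lnL,
      settings = list(
        n_rell = n_rell, n_random = n_random, summary = summary,
        seed = seed, candidates = candidates
      )
    ),
    class = "congruence_report"
  )
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("Host-virus congruence report\n")
  cat("  selected model:   ", x$selected_model, "\n")
  cat(
    "  SH test:           2*delta(lnL) =", format(x$sh_delta, digits = 6),
    ", p =", format(x$sh_p, digits = 4), "\n"
  )
  cat(
    "  posterior match:  ", x$match_count, "/", x$posterior_size,
    "topologies match the host tree (proportion",
    format(x$match_proportion, digits = 4), ")\n"
  )
  cat(
    "  RF null:          ", format(100 * x$rf_null_fraction, digits = 3),
    "% of random topologies closer than the posterior", x$settings$summary,
    "\n"
  )
  invisible(x)
}

#' Serialize / restore a congruence report
#'
#' The report (statistics, settings, and both RF distributions as integer
#' lists) round-trips losslessly through a JSON document.
#'
#' @param report a `congruence_report`.
#' @param path file path.
#' @return `read_congruence_report` returns the restored report.
#' @export
write_congruence_report <- function(report, path) {
  stopifnot(inherits(report, "congruence_report"))
  jsonlite::write_json(unclass(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_congruence_report
#' @export
read_congruence_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$posterior_rf_distribution <- as.integer(x$posterior_rf_distribution)
  x$null_rf_distribution <- as.integer(x$null_rf_distribution)
  class(x) <- "congruence_report"
  x
}
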