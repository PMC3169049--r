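#' Cophylogeny simulation scenario
#'
#' The generative hypothesis the congruence tests are calibrated against: a
#' Yule host tree, a virus tree that starts as an exact copy (strict
#' cospeciation) and is then perturbed by a configurable number of
#' host-switch events, each modelled as a subtree-prune-regraft move.
#'
#' @param n_hosts number of host species (>= 3).
#' @param yule_rate speciation rate per lineage per unit time (default 1).
#' @param n_switches number of host-switch (SPR) events applied to the
#'   virus tree; must be `<= n_hosts - 3` so each move stays meaningful.
#' @param virus_rate_scale multiplier converting host branch lengths
#'   (time) to virus branch lengths (substitutions/site), default 0.3.
#' @param seed integer seed driving the whole scenario.
#' @return a list of class `cophylogeny_scenario`.
#' @export
cophylogeny_scenario <- function(n_hosts = 8, yule_rate = 1, n_switches = 0,
                                 virus_rate_scale = 0.3, seed = 1) {
  stopifnot(n_hosts >= 3, yule_rate > 0, virus_rate_scale > 0)
  if (n_switches < 0 || n_switches > n_hosts - 3) {
    stop_ct("n_switches must be in [0, n_hosts - 3], got ", n_switches)
  }
  structure(
    list(
      n_hosts = as.integer(n_hosts), yule_rate = yule_rate,
      n_switches = as.integer(n_switches),
      virus_rate_scale = virus_rate_scale, seed = as.integer(seed)
    ),
    class = "cophylogeny_scenario"
  )
}

#' Simulate a Yule (pure-birth) host tree
#'
#' Starting from two lineages, waiting times between speciations are
#' exponential with rate `k * yule_rate` among `k` extant lineages and the
#' splitting lineage is chosen uniformly; growth stops on reaching `n`
#' lineages, so the tree is ultrametric with height equal to the time taken
#' to grow from 2 to `n` lineages.
#'
#' @param n number of tips (>= 3).
#' @param yule_rate speciation rate per lineage per unit time.
#' @param seed optional integer seed.
#' @param labels tip labels (default `host01`, `host02`, ...).
#' @return a rooted ultrametric `phylo`.
#' @export
simulate_host_tree <- function(n, yule_rate = 1, seed = NULL, labels = NULL) {
  if (n < 3) stop_ct("need at least 3 host taxa, got ", n)
  if (is.null(labels)) labels <- sprintf("host%02d", seq_len(n))
  stopifnot(length(labels) == n)
  with_seed(seed, {
    # active lineages are edges-in-progress: (parent node id, start time)
    root <- n + 1L
    next_internal <- n + 2L
    act_parent <- c(root, root)
    act_start <- c(0, 0)
    t_now <- 0
    edge <- matrix(0L, 0L, 2L)
    elen <- numeric(0)
    while (length(act_parent) < n) {
      k <- length(act_parent)
      t_now <- t_now + stats::rexp(1, rate = k * yule_rate)
      i <- sample.int(k, 1L)
      node <- next_internal
      next_internal <- next_internal + 1L
      edge <- rbind(edge, c(act_parent[i], node))
      elen <- c(elen, t_now - act_start[i])
      act_parent[i] <- node
      act_start[i] <- t_now
      act_parent <- c(act_parent, node)
      act_start <- c(act_start, t_now)
    }
    height <- t_now + stats::rexp(1, rate = n * yule_rate)
    for (i in seq_along(act_parent)) {
      edge <- rbind(edge, c(act_parent[i], i))
      elen <- c(elen, height - act_start[i])
    }
    phy <- list(
      edge = edge, edge.length = elen,
      Nnode = n - 1L, tip.label = labels
    )
    class(phy) <- "phylo"
    ape::reorder.phylo(phy, "cladewise")
  })
}

#' Derive a virus tree from a host tree by host switching
#'
#' The host tree is copied, leaves are relabelled (`hostXX` to `virusXX`,
#' or prefixed `v.` for other label schemes), branch lengths are rescaled
#' from time to expected substitutions/site, and `n_switches` random
#' subtree-prune-regraft moves are applied. The pruned subtree and the
#' regraft edge are chosen uniformly; the edge freed by the prune is
#' excluded as a target, so every move changes the topology.
#'
#' @param host_tree a rooted `phylo`.
#' @param n_switches number of SPR events (0 keeps the host topology).
#' @param virus_rate_scale branch-length multiplier.
#' @param seed optional integer seed.
#' @return a rooted `phylo` with virus tip labels; the association between
#'   its tips and the host tips is returned in attribute `"association"`.
#' @export
simulate_virus_tree <- function(host_tree, n_switches = 0,
                                virus_rate_scale = 0.3, seed = NULL) {
  n <- length(host_tree$tip.label)
  if (n_switches > n - 3) {
    stop_ct("n_switches must be <= n_hosts - 3 = ", n - 3, ", got ", n_switches)
  }
  vlabels <- sub("^host", "virus", host_tree$tip.label)
  untouched <- vlabels == host_tree$tip.label
  vlabels[untouched] <- paste0("v.", vlabels[untouched])
  vt <- host_tree
  vt$tip.label <- vlabels
  vt$edge.length <- vt$edge.length * virus_rate_scale
  vt <- with_seed(seed, {
    if (n_switches > 0) {
      for (s in seq_len(n_switches)) vt <- spr_move(vt)
    }
    vt
  })
  attr(vt, "association") <- host_association(vlabels, host_tree$tip.label)
  vt
}

# One random SPR move on a rooted binary tree, guaranteed to change the
# unrooted topology: the pruned edge is uniform over non-root edges whose
# removal leaves >= 3 remaining leaves; the regraft edge is uniform over
# remaining edges except the edge freed by suppressing the pruned node
# (regrafting there would restore the original topology).
spr_move <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop_ct("SPR needs at least 4 leaves")
  root <- ntip + 1L
  repeat {
    cand <- which(tree$edge[, 1L] != root)
    e <- cand[sample.int(length(cand), 1L)]
    p <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    adj <- phylo_to_adj(tree)
    # detach subtree at ch
    ip <- match(ch, adj$nbr[[p]])
    stalk <- adj$len[[p]][ip]
    adj$nbr[[p]] <- adj$nbr[[p]][-ip]
    adj$len[[p]] <- adj$len[[p]][-ip]
    # suppress p (now degree 2): join its two remaining neighbours
    stopifnot(length(adj$nbr[[p]]) == 2L)
    u <- adj$nbr[[p]][1]
    v <- adj$nbr[[p]][2]
    lu <- adj$len[[p]][1]
    lv <- adj$len[[p]][2]
    iu <- match(p, adj$nbr[[u]])
    adj$nbr[[u]][iu] <- v
    adj$len[[u]][iu] <- lu + lv
    iv <- match(p, adj$nbr[[v]])
    adj$nbr[[v]][iv] <- u
    adj$len[[v]][iv] <- lu + lv
    adj$nbr[[p]] <- integer(0)
    adj$len[[p]] <- numeric(0)
    # remaining edges reachable from root side, excluding the merged (u,v)
    in_pruned <- subtree_nodes(adj_list_edges(adj), ch)
    edges_left <- adj_list_edges(adj)
    keep <- !(edges_left[, 1] %in% in_pruned | edges_left[, 2] %in% in_pruned)
    keep <- keep & !((edges_left[, 1] == u & edges_left[, 2] == v) |
      (edges_left[, 1] == v & edges_left[, 2] == u))
    targets <- which(keep)
    if (!length(targets)) next # e.g. pruning next to a 3-leaf remainder
    tgt <- targets[sample.int(length(targets), 1L)]
    a <- edges_left[tgt, 1]
    b <- edges_left[tgt, 2]
    lab <- adj$len[[a]][match(b, adj$nbr[[a]])]
    # insert new node m in the middle of (a, b), attach ch with its stalk
    m <- p # reuse the suppressed node id
    adj$nbr[[a]][match(b, adj$nbr[[a]])] <- m
    adj$len[[a]][match(m, adj$nbr[[a]])] <- lab / 2
    adj$nbr[[b]][match(a, adj$nbr[[b]])] <- m
    adj$len[[b]][match(m, adj$nbr[[b]])] <- lab / 2
    adj$nbr[[m]] <- c(a, b, ch)
    adj$len[[m]] <- c(lab / 2, lab / 2, stalk)
    adj$nbr[[ch]][match(p, adj$nbr[[ch]])] <- m # p == m: already consistent
    new_root <- if (root %in% c(p)) m else root
    if (length(adj$nbr[[root]]) < 2L) new_root <- m
    return(adj_to_phylo(adj, root = new_root))
  }
}

# helper: all (undirected, deduplicated) edges of an adjacency list
adj_list_edges <- function(adj) {
  rows <- list()
  for (a in seq_along(adj$nbr)) {
    for (b in adj$nbr[[a]]) {
      if (a < b) rows[[length(rows) + 1L]] <- c(a, b)
    }
  }
  do.call(rbind, rows)
}

# nodes in the component containing `start` of the given edge list
subtree_nodes <- function(edges, start) {
  seen <- start
  repeat {
    hit <- edges[, 1] %in% seen | edges[, 2] %in% seen
    grow <- unique(c(edges[hit, 1], edges[hit, 2]))
    if (all(grow %in% seen)) {
      return(seen)
    }
    seen <- unique(c(seen, grow))
  }
}

#' Simulate a nucleotide alignment along a tree
#'
#' Each site is invariable with probability `p_inv` (state drawn from the
#' stationary frequencies, constant across the tree); otherwise it draws a
#' gamma rate category, a root state from the stationary frequencies, and
#' evolves down the tree with the model's transition probabilities.
#'
#' @param tree a `phylo` with branch lengths.
#' @param model a [substitution_model()].
#' @param L number of sites.
#' @param seed optional integer seed.
#' @return a [dna_alignment] over the tree's tips.
#' @export
simulate_alignment <- function(tree, model, L, seed = NULL) {
  stopifnot(L >= 1)
  if (is.null(tree$edge.length)) stop_ct("tree needs branch lengths to simulate on")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    rates <- model_rates(model)
    k <- length(rates)
    # site classes: 0 = invariable, 1..k = gamma category
    cls <- ifelse(stats::runif(L) < model$p_inv, 0L, sample.int(k, L, replace = TRUE))
    states <- matrix(0L, nnode, L)
    root <- ntip + 1L
    states[root, ] <- sample.int(4L, L, replace = TRUE, prob = model$base_freq)
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (i in seq_len(nrow(pre$edge))) {
      par <- pre$edge[i, 1L]
      ch <- pre$edge[i, 2L]
      t <- pre$edge.length[i]
      states[ch, ] <- states[par, ]
      for (c in seq_len(k)) {
        sel <- which(cls == c)
        if (!length(sel)) next
        P <- transition_probabilities(model, t, rates[c])
        for (s0 in 1:4) {
          sub <- sel[states[par, sel] == s0]
          if (length(sub)) {
            states[ch, sub] <- sample.int(4L, length(sub),
              replace = TRUE, prob = P[s0, ]
            )
          }
        }
      }
    }
    mat <- matrix(DNA_STATES[states[seq_len(ntip), , drop = FALSE]], ntip, L)
    rownames(mat) <- tree$tip.label
    dna_alignment(mat)
  })
}

#' Generate a complete cophylogeny fixture
#'
#' Simulates a host tree, a virus tree under the scenario, and an alignment
#' evolved on the virus tree; optionally writes the bundle (host Newick,
#' virus Newick, FASTA, association TSV, JSON provenance) to a directory.
#' Re-invocation with the same scenario reproduces byte-identical files.
#'
#' @param scenario a [cophylogeny_scenario()].
#' @param model a [substitution_model()] (default: the package's reference
#'   GTR+G+I fixture model, [default_fixture_model()]).
#' @param L alignment length (default 2000).
#' @param dir output directory, or `NULL` to keep the bundle in memory.
#' @return a list of class `fixture_bundle`: `host_tree`, `virus_tree`,
#'   `alignment`, `assoc`, `scenario`, `model`, `L`, and `paths` when
#'   written.
#' @export
make_fixture <- function(scenario, model = default_fixture_model(),
                         L = 2000, dir = NULL) {
  stopifnot(inherits(scenario, "cophylogeny_scenario"))
  host <- simulate_host_tree(scenario$n_hosts, scenario$yule_rate,
    seed = scenario$seed
  )
  virus <- simulate_virus_tree(host, scenario$n_switches,
    scenario$virus_rate_scale,
    seed = scenario$seed + 1L
  )
  assoc <- attr(virus, "association")
  aln <- simulate_alignment(virus, model, L, seed = scenario$seed + 2L)
  bundle <- structure(
    list(
      host_tree = host, virus_tree = virus, alignment = aln,
      assoc = assoc, scenario = scenario, model = model, L = L
    ),
    class = "fixture_bundle"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) {
      ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop_ct("cannot create output directory ", dir)
    }
    paths <- list(
      host = file.path(dir, "host.nwk"),
      virus = file.path(dir, "virus_true.nwk"),
      alignment = file.path(dir, "alignment.fasta"),
      association = file.path(dir, "association.tsv"),
      provenance = file.path(dir, "provenance.json")
    )
    writeLines(write_newick(host), paths$host)
    writeLines(write_newick(virus), paths$virus)
    write_fasta_alignment(aln, paths$alignment)
    write_association(assoc, paths$association)
    jsonlite::write_json(
      list(
        scenario = unclass(scenario),
        model = unclass(model), L = L
      ),
      paths$provenance,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    bundle$paths <- paths
  }
  bundle
}

#' The reference substitution model for shipped fixtures
#'
#' GTR+G+I with transition rates about four times the transversion rates,
#' mildly AT-rich base frequencies, strong rate heterogeneity
#' (`alpha = 0.5`) and 10 per cent invariable sites — the parameter regime
#' typical of a divergent viral polymerase alignment.
#'
#' @return a [substitution_model()].
#' @export
default_fixture_model <- function() {
  substitution_model(
    exch = c(1.5, 4.0, 0.9, 1.1, 4.5, 1),
    base_freq = c(0.30, 0.20, 0.20, 0.30),
    gamma_shape = 0.5, p_inv = 0.1, k = 4L
  )
}

#' Load a fixture bundle from disk
#'
#' Reads a bundle written by [make_fixture()]. The two scenarios shipped
#' with the package are `"cospeciation-8taxa"` (strict codivergence) and
#' `"switch3-8taxa"` (three host switches).
#'
#' @param name a shipped fixture name, or a directory containing a bundle.
#' @return a `fixture_bundle` (without the generating scenario's RNG state;
#'   the provenance file records its parameters).
#' @export
load_fixture <- function(name) {
  dir <- if (dir.exists(name)) {
    name
  } else {
    system.file("extdata", name, package = "cophylotest")
  }
  if (!nzchar(dir) || !dir.exists(dir)) {
    stop_ct("no fixture directory found for '", name, "'")
  }
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"), simplifyVector = TRUE)
  structure(
    list(
      host_tree = parse_newick(file.path(dir, "host.nwk")),
      virus_tree = parse_newick(file.path(dir, "virus_true.nwk")),
      alignment = read_fasta_alignment(file.path(dir, "alignment.fasta")),
      assoc = read_association(file.path(dir, "association.tsv")),
      scenario = prov$scenario,
      model = do.call(substitution_model, prov$model[c(
        "exch", "base_freq", "gamma_shape", "p_inv", "k"
      )]),
      L = prov$L,
      paths = NULL
    ),
    class = "fixture_bundle"
  )
}
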