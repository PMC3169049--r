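#' The two nearest-neighbour-interchange rearrangements of an internal edge
#'
#' For an internal edge of an unrooted binary tree, the four subtrees
#' hanging off its endpoints can be swapped across the edge in two distinct
#' ways; each resulting topology differs from the input by a
#' Robinson-Foulds distance of exactly 2, and applying the same swap twice
#' restores the original tree.
#'
#' @param tree an unrooted binary `phylo`.
#' @param edge row index into `tree$edge` of an internal edge (both
#'   endpoints internal nodes).
#' @return list of two `phylo` objects.
#' @export
nni_neighbors <- function(tree, edge) {
  ntip <- length(tree$tip.label)
  if (ape::is.rooted(tree)) {
    stop_ct("nni_neighbors expects an unrooted tree (use ape::unroot)")
  }
  if (edge < 1 || edge > nrow(tree$edge)) stop_ct("edge index out of range")
  p <- tree$edge[edge, 1L]
  ch <- tree$edge[edge, 2L]
  if (ch <= ntip) {
    stop_ct("edge ", edge, " is terminal (leads to tip '", tree$tip.label[ch], "')")
  }
  adj <- phylo_to_adj(tree)
  a_b <- adj_neighbors(adj, ch, except = p)
  d_e <- adj_neighbors(adj, p, except = ch)
  if (length(a_b) != 2L || length(d_e) != 2L) {
    stop_ct("tree is not binary around edge ", edge)
  }
  a <- a_b[1]
  lapply(d_e, function(x) {
    new <- adj
    # swap subtree a (neighbour of ch) with subtree x (neighbour of p);
    # each subtree keeps its own stalk length
    ia <- match(a, new$nbr[[ch]])
    ix <- match(x, new$nbr[[p]])
    la <- new$len[[ch]][ia]
    lx <- new$len[[p]][ix]
    new$nbr[[ch]][ia] <- x
    new$len[[ch]][ia] <- lx
    new$nbr[[p]][ix] <- a
    new$len[[p]][ix] <- la
    new$nbr[[a]][match(ch, new$nbr[[a]])] <- p
    new$nbr[[x]][match(p, new$nbr[[x]])] <- ch
    out <- adj_to_phylo(new, root = p)
    nm <- attr(out, "node_map")
    # new ids of the swapped edge's endpoints, for callers that want to
    # re-optimize the branches around the rearrangement
    attr(out, "central") <- c(nm[p], nm[ch])
    out
  })
}

internal_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  which(tree$edge[, 2L] > ntip)
}

# Greedy distance-based starting tree: neighbour joining on
# Jukes-Cantor-corrected pairwise distances.
start_tree_nj <- function(aln) {
  n <- length(aln$taxa)
  mat <- aln$mat
  D <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] %in% DNA_STATES & mat[j, ] %in% DNA_STATES
      p <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0
      d <- if (p >= 0.745) 3 else -0.75 * log(1 - 4 * p / 3)
      D[i, j] <- D[j, i] <- d
    }
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  ape::unroot(tr)
}

#' Maximum-likelihood tree search by nearest-neighbour interchange
#'
#' Hill-climbing heuristic: starting from a supplied tree or a
#' neighbour-joining tree on Jukes-Cantor distances, all NNI rearrangements
#' of every internal edge are scored (with a quick re-optimization of the
#' five branch lengths around the swapped edge); the best improving move is
#' accepted, followed by a full branch-length sweep; the search stops when
#' no rearrangement improves the log-likelihood. Optionally finishes with a
#' full model-parameter optimization.
#'
#' @param aln a [dna_alignment] with at least 4 taxa.
#' @param model a [substitution_model()] used during the search.
#' @param start a `phylo`, or `"auto"` for the distance start tree.
#' @param seed optional integer seed (tie-breaks and any randomized start
#'   resolution).
#' @param optimize_model if `TRUE` (default), re-fit the model's free
#'   parameters on the final topology.
#' @param tol lnL improvement required to accept a move (default 1e-6).
#' @return an object of class `ml_result`: list with `tree` (optimized
#'   branch lengths), `model`, `lnL`, `n_free_parameters` and `trace`
#'   (data frame of accepted moves).
#' @export
ml_search <- function(aln, model = substitution_model(), start = "auto",
                      seed = NULL, optimize_model = TRUE, tol = 1e-6) {
  if (length(aln$taxa) < 4L) {
    stop_ct("ML search needs at least 4 taxa, got ", length(aln$taxa))
  }
  with_seed(seed, {
    tree <- if (inherits(start, "phylo")) {
      t0 <- start
      if (ape::is.rooted(t0)) t0 <- ape::unroot(t0)
      if (!ape::is.binary(t0)) t0 <- ape::multi2di(t0)
      ensure_lengths(t0)
    } else {
      start_tree_nj(aln)
    }
    bl <- optimize_branch_lengths(tree, aln, model, tol = 1e-5, max_sweeps = 10)
    tree <- bl$tree
    cur <- bl$lnL
    trace <- list(list(move = "start", lnL = cur))
    repeat {
      best <- NULL
      best_lnl <- cur
      cp <- lik_context(tree, aln)$cp
      for (e in internal_edges(tree)) {
        for (nb in nni_neighbors(tree, e)) {
          cand <- quick_branch_opt(nb, aln, model,
            nodes = attr(nb, "central"), cp = cp
          )
          if (cand$lnL > best_lnl + tol) {
            best <- cand
            best_lnl <- cand$lnL
          }
        }
      }
      if (is.null(best)) break
      bl <- optimize_branch_lengths(best$tree, aln, model, tol = 1e-5, max_sweeps = 5)
      tree <- bl$tree
      cur <- bl$lnL
      trace <- c(trace, list(list(move = "nni", lnL = cur)))
    }
    fam_free <- 0L
    if (optimize_model) {
      fit <- optimize_model_parameters(tree, aln, model)
      tree <- fit$tree
      model <- fit$model
      cur <- fit$lnL
      fam_free <- fit$n_free_parameters - nrow(tree$edge)
      trace <- c(trace, list(list(move = "model", lnL = cur)))
    } else {
      bl <- optimize_branch_lengths(tree, aln, model, tol = 1e-6, max_sweeps = 20)
      tree <- bl$tree
      cur <- bl$lnL
    }
    structure(
      list(
        tree = tree, model = model, lnL = cur,
        n_free_parameters = fam_free + nrow(tree$edge),
        family = if (optimize_model) fit$family else NULL,
        trace = do.call(rbind, lapply(trace, as.data.frame))
      ),
      class = "ml_result"
    )
  })
}

# One-pass Brent optimization of selected edges (cheap scoring of NNI
# candidates before the full sweep on acceptance). `nodes` restricts the
# pass to edges incident to those node ids (the five edges around a swap).
quick_branch_opt <- function(tree, aln, model, nodes = NULL, cp = NULL) {
  ctx <- lik_context(tree, aln, cp = cp)
  eg <- model_eigen(model)
  rates <- model_rates(model)
  elen <- ctx$po$edge.length
  cur <- lik_eval(ctx, elen, model, eg, rates)
  rows <- if (is.null(nodes)) {
    seq_along(elen)
  } else {
    which(ctx$po$edge[, 1L] %in% nodes | ctx$po$edge[, 2L] %in% nodes)
  }
  for (i in rows) {
    f <- function(t) {
      e <- elen
      e[i] <- t
      lik_eval(ctx, e, model, eg, rates)
    }
    opt <- stats::optimize(f, c(1e-9, 10), maximum = TRUE, tol = 1e-5)
    if (opt$objective > cur) {
      elen[i] <- opt$maximum
      cur <- opt$objective
    }
  }
  out <- ctx$po
  out$edge.length <- elen
  list(tree = ape::reorder.phylo(out, "cladewise"), lnL = cur)
}

#' @export
print.ml_result <- function(x, ...) {
  cat(
    "ML tree:", length(x$tree$tip.label), "taxa, lnL =", x$lnL, "(",
    x$n_free_parameters, "free parameters,",
    sum(x$trace$move == "nni"), "NNI moves )\n"
  )
  invisible(x)
}

#' Substitution-model selection by AIC
#'
#' Fits each candidate family on a fixed topology (branch lengths
#' re-optimized per candidate) and ranks them by `AIC = 2K - 2 lnL`, where
#' `K` counts branch lengths plus the family's free model parameters. Ties
#' break toward fewer parameters, then alphabetically, so the selection is
#' invariant to candidate order.
#'
#' @param aln a [dna_alignment].
#' @param tree the topology to fit on (a `phylo`).
#' @param candidates character vector of family names; default is the
#'   16-member ladder JC/K80/HKY/GTR, each plain, `+G`, `+I`, `+G+I`.
#' @return an object of class `model_selection`: data frame `table`
#'   (model, lnL, K, AIC), the `selected` family name, and the fitted
#'   `model` and `tree` of the winner.
#' @export
aic_select <- function(aln, tree, candidates = default_candidates()) {
  if (!length(candidates)) stop_ct("candidate list is empty")
  fits <- lapply(candidates, function(fname) {
    fit <- tryCatch(
      optimize_model_parameters(tree, aln, family = fname),
      error = function(e) stop_ct("fitting candidate '", fname, "': ", conditionMessage(e))
    )
    fit
  })
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "family"),
    lnL = vapply(fits, `[[`, 0, "lnL"),
    K = vapply(fits, `[[`, 0L, "n_free_parameters"),
    stringsAsFactors = FALSE
  )
  tab$AIC <- 2 * tab$K - 2 * tab$lnL
  ord <- order(tab$AIC, tab$K, tab$model)
  sel <- ord[1]
  structure(
    list(
      table = tab[order(tab$AIC), ],
      selected = tab$model[sel],
      model = fits[[sel]]$model,
      tree = fits[[sel]]$tree,
      lnL = fits[[sel]]$lnL
    ),
    class = "model_selection"
  )
}

#' The default 16-family candidate ladder for [aic_select()]
#' @return character vector of family names.
#' @export
default_candidates <- function() {
  as.vector(outer(
    c("JC", "K80", "HKY", "GTR"),
    c("", "+G", "+I", "+G+I"), paste0
  ))
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection by AIC; selected:", x$selected, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Non-parametric bootstrap support for the splits of an ML tree
#'
#' Columns are resampled with replacement `n_reps` times; each replicate
#' alignment is re-searched (started from the ML tree, model fixed), and
#' the support of every internal split of the ML tree is the fraction of
#' replicate trees containing it.
#'
#' @param aln a [dna_alignment].
#' @param model the [substitution_model()] to search under.
#' @param ml_tree the tree whose splits are assessed.
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed; replicates are reproducible given it.
#' @return list with `support` (named numeric in `[0,1]`, keyed by split),
#'   and `tree`, a copy of `ml_tree` with node labels carrying supports.
#' @export
bootstrap_support <- function(aln, model, ml_tree, n_reps = 100, seed = NULL) {
  stopifnot(n_reps >= 1)
  splits <- bipartition_set(ml_tree)
  counts <- stats::setNames(numeric(length(splits)), splits)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      rep_aln <- resample_columns(aln)
      res <- ml_search(rep_aln, model,
        start = ml_tree,
        optimize_model = FALSE
      )
      hits <- intersect(splits, bipartition_set(res$tree))
      counts[hits] <- counts[hits] + 1
    }
  })
  support <- counts / n_reps
  list(support = support, tree = annotate_support(ml_tree, support))
}

# write per-split supports into node labels of the tree that owns them
annotate_support <- function(tree, support) {
  ntip <- length(tree$tip.label)
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  po <- ape::reorder.phylo(tree, "postorder")
  below <- matrix(FALSE, ntip + tree$Nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  node_lab <- rep("", tree$Nnode)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    below[p, ] <- below[p, ] | below[ch, ]
    if (ch > ntip) {
      side <- below[ch, ]
      k <- sum(side)
      if (k > 1L && k < ntip - 1L) {
        if (side[match(ref, labs)]) side <- !side
        key <- paste(sort(labs[side]), collapse = "|")
        if (key %in% names(support)) {
          node_lab[ch - ntip] <- format(support[[key]], digits = 3)
        }
      }
    }
  }
  tree$node.label <- node_lab
  tree
}
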