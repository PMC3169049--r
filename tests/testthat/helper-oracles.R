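# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: splits are found by graph bisection, the
# likelihood by exhaustive enumeration of internal-node states with
# series-based matrix exponentials.

# --- split / RF oracle --------------------------------------------------

# all non-trivial splits of a tree by literally cutting each edge and
# flooding one side of the resulting graph
brute_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  keys <- character(0)
  ref <- sort(tree$tip.label)[1]
  for (e in seq_len(nrow(edges))) {
    rest <- edges[-e, , drop = FALSE]
    side <- edges[e, 2]
    repeat {
      hit <- rest[, 1] %in% side | rest[, 2] %in% side
      grow <- unique(c(rest[hit, 1], rest[hit, 2], side))
      if (length(grow) == length(side)) break
      side <- grow
    }
    tips <- sort(tree$tip.label[side[side <= ntip]])
    if (length(tips) <= 1 || length(tips) >= ntip - 1) next
    if (ref %in% tips) tips <- sort(setdiff(tree$tip.label, tips))
    keys <- c(keys, paste(tips, collapse = "|"))
  }
  unique(keys)
}

brute_rf <- function(t1, t2) {
  s1 <- brute_splits(t1)
  s2 <- brute_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# --- likelihood oracle --------------------------------------------------

# matrix exponential by scaling-and-squaring of a Taylor series — an
# implementation independent of the package's eigendecomposition
expm_series <- function(M) {
  n <- 20L
  s <- 2^8
  X <- M / s
  E <- diag(4)
  term <- diag(4)
  for (i in seq_len(n)) {
    term <- term %*% X / i
    E <- E + term
  }
  for (i in 1:8) E <- E %*% E
  E
}

# site likelihood by summing over every assignment of internal-node states
brute_site_lik <- function(tree, chars, model) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  Q <- build_rate_matrix(model)
  rates <- if (is.na(model$gamma_shape)) 1 else discrete_gamma_rates(model$gamma_shape, model$k)
  pi <- model$base_freq
  lut <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  tipstate <- unname(lut[chars[tree$tip.label]])
  lik_cat <- vapply(rates, function(r) {
    P <- lapply(seq_len(nrow(tree$edge)), function(e) {
      expm_series(Q * tree$edge.length[e] * r)
    })
    total <- 0
    for (assign_idx in seq_len(4^nint) - 1L) {
      st <- integer(ntip + nint)
      st[seq_len(ntip)] <- tipstate
      rem <- assign_idx
      for (j in seq_len(nint)) {
        st[ntip + j] <- rem %% 4L + 1L
        rem <- rem %/% 4L
      }
      p <- pi[st[ntip + 1L]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- p * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      }
      total <- total + p
    }
    total
  }, 0)
  mixed <- mean(lik_cat)
  if (model$p_inv > 0) {
    constant <- length(unique(tipstate)) == 1L
    invp <- if (constant) pi[tipstate[1]] else 0
    mixed <- model$p_inv * invp + (1 - model$p_inv) * mixed
  }
  mixed
}

brute_lnl <- function(tree, aln, model) {
  sum(vapply(seq_len(aln$L), function(s) {
    chars <- stats::setNames(aln$mat[, s], rownames(aln$mat))
    log(brute_site_lik(tree, chars, model))
  }, 0))
}

# --- topology enumeration ----------------------------------------------

# every labelled unrooted binary topology on the given taxa, as Newick
# strings, by exhaustive sequential insertion (independent of the
# package's tree machinery)
enumerate_topologies <- function(taxa) {
  n <- length(taxa)
  stopifnot(n >= 3)
  # edge lists over node ids: tips 1..n, internals n+1...
  grow <- function(edges, next_id, k) {
    if (k > n) {
      return(list(edges))
    }
    out <- list()
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]
      b <- edges[e, 2]
      m <- next_id
      new_edges <- rbind(edges[-e, , drop = FALSE], c(a, m), c(m, b), c(m, k))
      out <- c(out, grow(new_edges, next_id + 1L, k + 1L))
    }
    out
  }
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), 3, 2, byrow = TRUE)
  all_edges <- grow(base, n + 2L, 4L)
  vapply(all_edges, function(edges) edgelist_to_newick(edges, taxa), "")
}

edgelist_to_newick <- function(edges, taxa) {
  n <- length(taxa)
  nbr <- list()
  for (i in seq_len(max(edges))) nbr[[i]] <- integer(0)
  for (e in seq_len(nrow(edges))) {
    nbr[[edges[e, 1]]] <- c(nbr[[edges[e, 1]]], edges[e, 2])
    nbr[[edges[e, 2]]] <- c(nbr[[edges[e, 2]]], edges[e, 1])
  }
  sub <- function(node, parent) {
    if (node <= n) {
      return(taxa[node])
    }
    kids <- setdiff(nbr[[node]], parent)
    paste0("(", paste(vapply(kids, function(kk) sub(kk, node), ""), collapse = ","), ")")
  }
  # root the string at internal node n+1
  kids <- nbr[[n + 1L]]
  paste0("(", paste(vapply(kids, function(k) sub(k, n + 1L), ""), collapse = ","), ");")
}

# --- shared fixtures ----------------------------------------------------

quartet_tree <- function(internal = 0.3, tip = 0.1) {
  parse_newick(sprintf(
    "((A:%g,B:%g):%g,C:%g,D:%g);",
    tip, tip, internal, tip, tip
  ))
}

random_gtr_model <- function(gamma = TRUE, inv = TRUE) {
  ex <- stats::runif(6, 0.3, 4)
  ex <- ex / ex[6]
  bf <- stats::runif(4, 0.5, 2)
  bf <- bf / sum(bf)
  substitution_model(
    exch = ex, base_freq = bf,
    gamma_shape = if (gamma) stats::runif(1, 0.3, 2) else NA_real_,
    p_inv = if (inv) stats::runif(1, 0, 0.3) else 0
  )
}

random_blen_tree <- function(n, seed = NULL) {
  tr <- random_topology(paste0("t", seq_len(n)), seed = seed)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.6)
  tr
}

internal_edge_of <- function(tree) {
  ntip <- length(tree$tip.label)
  which(tree$edge[, 2] > ntip)[1]
}
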