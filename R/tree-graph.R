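# Internal undirected-graph view of a phylo object.
#
# Several operations (NNI, SPR, random topology growth, subtree grafting)
# are awkward on ape's parent/child edge matrix but trivial on an adjacency
# list.  Node ids follow ape's convention: tips 1..ntip, internal nodes
# above.  Ids need not be contiguous after editing; adj_to_phylo renumbers.

phylo_to_adj <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  nbr <- vector("list", nnode)
  len <- vector("list", nnode)
  has_len <- !is.null(phy$edge.length)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]
    b <- phy$edge[i, 2L]
    l <- if (has_len) phy$edge.length[i] else NA_real_
    nbr[[a]] <- c(nbr[[a]], b)
    len[[a]] <- c(len[[a]], l)
    nbr[[b]] <- c(nbr[[b]], a)
    len[[b]] <- c(len[[b]], l)
  }
  list(nbr = nbr, len = len, ntip = ntip, tip.label = phy$tip.label)
}

# Rebuild a phylo from an adjacency list.  `root` picks the node the edge
# matrix is traversed from (an internal node; defaults to the first one with
# degree > 1).  Traversal is preorder, giving a cladewise edge matrix.
adj_to_phylo <- function(adj, root = NULL) {
  ntip <- adj$ntip
  deg <- lengths(adj$nbr)
  if (is.null(root)) {
    root <- which(deg > 1L)[1]
  }
  n_internal <- sum(deg > 1L)
  n_edges <- ntip + n_internal - 1L
  new_id <- integer(length(adj$nbr))
  new_id[seq_len(ntip)] <- seq_len(ntip)

  edge <- matrix(0L, n_edges, 2L)
  elen <- numeric(n_edges)
  # explicit stack of (node, parent) pairs; ids assigned on first visit
  next_int <- ntip + 1L
  row <- 0L
  new_id[root] <- next_int
  next_int <- next_int + 1L
  stack_node <- c(root)
  stack_par <- c(0L)
  while (length(stack_node)) {
    k <- length(stack_node)
    node <- stack_node[k]
    par <- stack_par[k]
    stack_node <- stack_node[-k]
    stack_par <- stack_par[-k]
    nbs <- adj$nbr[[node]]
    lns <- adj$len[[node]]
    keep <- nbs != par
    nbs <- nbs[keep]
    lns <- lns[keep]
    # reverse so that the first neighbour is emitted first (stack is LIFO)
    for (j in rev(seq_along(nbs))) {
      stack_node <- c(stack_node, nbs[j])
      stack_par <- c(stack_par, node)
    }
    for (j in seq_along(nbs)) {
      ch <- nbs[j]
      if (deg[ch] > 1L && new_id[ch] == 0L) {
        new_id[ch] <- next_int
        next_int <- next_int + 1L
      }
    }
  }
  # second pass to emit edges in preorder with ids fixed
  stack_node <- c(root)
  stack_par <- c(0L)
  while (length(stack_node)) {
    k <- length(stack_node)
    node <- stack_node[k]
    par <- stack_par[k]
    stack_node <- stack_node[-k]
    stack_par <- stack_par[-k]
    nbs <- adj$nbr[[node]]
    lns <- adj$len[[node]]
    keep <- nbs != par
    nbs <- nbs[keep]
    lns <- lns[keep]
    for (j in rev(seq_along(nbs))) {
      stack_node <- c(stack_node, nbs[j])
      stack_par <- c(stack_par, node)
    }
    for (j in seq_along(nbs)) {
      row <- row + 1L
      edge[row, ] <- c(new_id[node], new_id[nbs[j]])
      elen[row] <- lns[j]
    }
  }
  # preorder emission above pushes children right-to-left but rows were
  # appended parent-first per node, so the matrix is cladewise per node
  # grouping; reorder rows to true preorder (parent row before child rows).
  phy <- list(
    edge = edge,
    Nnode = n_internal,
    tip.label = adj$tip.label
  )
  if (!all(is.na(elen))) phy$edge.length <- elen
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "node_map") <- new_id # old id -> new id
  phy
}

# First-visit parent lookup for one node: returns the neighbour ids of
# `node` excluding `except`.
adj_neighbors <- function(adj, node, except = 0L) {
  nbs <- adj$nbr[[node]]
  nbs[nbs != except]
}

# Replace neighbour `old` of `node` with `new`, keeping the stalk length
# stored on the moved subtree's side.
adj_swap_neighbor <- function(adj, node, old, new) {
  i <- match(old, adj$nbr[[node]])
  adj$nbr[[node]][i] <- new
  adj
}
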