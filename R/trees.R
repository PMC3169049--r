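#' Parse a Newick string into a phylogenetic tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Branch lengths and
#' internal-node (support) labels are preserved; the tree is flagged rooted
#' when the basal node has exactly two children.
#'
#' @param text a Newick string (one tree, terminated by `;`), or a path to a
#'   file containing one if `text` does not contain `(`.
#' @return an object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,C:1);")
#' tr$tip.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("(", text, fixed = TRUE)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop_ct(
      "unbalanced parentheses in Newick string: ",
      n_open, " '(' vs ", n_close, "')'"
    )
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop_ct("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(phy)) stop_ct("Newick parse error: no tree found in input")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup)) {
    stop_ct("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0)) {
    stop_ct("negative branch length in input tree")
  }
  phy
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths (default 10, enough
#'   for a lossless parse/write round trip at double precision scales used
#'   here).
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Read a posterior tree sample from a NEXUS trees block
#'
#' Accepts the MrBayes-style `.t` dialect: a `translate` table mapping tip
#' numbers to names, followed by numbered `tree` statements. Files without a
#' translate table (named tips) are also accepted. Burn-in is *not* applied;
#' see [apply_burnin()].
#'
#' @param x path to a NEXUS file, or the file contents as a character string
#'   (detected by an embedded newline or `#NEXUS` header).
#' @return a [posterior_sample] with `burnin_applied = FALSE`.
#' @export
read_nexus_trees <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  path <- x
  if (grepl("\n", x) || grepl("^#NEXUS", x, ignore.case = TRUE)) {
    path <- tempfile(fileext = ".nex")
    on.exit(unlink(path), add = TRUE)
    writeLines(x, path)
  }
  trees <- tryCatch(
    ape::read.nexus(path),
    error = function(e) stop_ct("NEXUS parse error: ", conditionMessage(e))
  )
  if (inherits(trees, "phylo")) {
    trees <- structure(list(trees), class = "multiPhylo")
  }
  bad <- vapply(trees, function(t) anyNA(t$tip.label) ||
    any(grepl("^[0-9]+$", t$tip.label)), logical(1))
  if (any(bad)) {
    nums <- unique(unlist(lapply(trees[bad], function(t) {
      t$tip.label[grepl("^[0-9]+$", t$tip.label)]
    })))
    stop_ct(
      "tip number(s) without a Translate entry: ",
      paste(nums, collapse = ", ")
    )
  }
  posterior_sample(trees, burnin_applied = FALSE, provenance = list(source = "nexus"))
}

#' Construct a posterior tree sample
#'
#' An ordered collection of sampled topologies with burn-in metadata,
#' optionally carrying a parameter trace (one row per retained sample).
#'
#' @param trees a `multiPhylo` (or list of `phylo`) in chain order.
#' @param burnin_applied has burn-in already been discarded?
#' @param params optional data frame of sampled parameters.
#' @param provenance list of seeds/settings that produced the sample.
#' @return an object of class `posterior_sample`.
#' @export
posterior_sample <- function(trees, burnin_applied = FALSE, params = NULL,
                             provenance = list()) {
  if (!inherits(trees, "multiPhylo")) {
    trees <- structure(trees, class = "multiPhylo")
  }
  structure(
    list(
      trees = trees, burnin_applied = burnin_applied,
      params = params, provenance = provenance
    ),
    class = "posterior_sample"
  )
}

#' @export
length.posterior_sample <- function(x) length(x$trees)

#' @export
print.posterior_sample <- function(x, ...) {
  cat(
    "Posterior sample:", length(x$trees), "trees;",
    if (x$burnin_applied) "burn-in applied" else "burn-in NOT applied", "\n"
  )
  invisible(x)
}

#' Discard a burn-in fraction from a posterior sample
#'
#' @param sample a [posterior_sample].
#' @param fraction fraction of initial samples to drop (default 0.25).
#' @return the trimmed [posterior_sample] with `burnin_applied = TRUE`.
#' @export
apply_burnin <- function(sample, fraction = 0.25) {
  stopifnot(inherits(sample, "posterior_sample"), fraction >= 0, fraction < 1)
  n <- length(sample$trees)
  drop <- floor(n * fraction)
  keep <- seq.int(drop + 1L, n)
  sample$trees <- structure(sample$trees[keep], class = "multiPhylo")
  if (!is.null(sample$params)) sample$params <- sample$params[keep, , drop = FALSE]
  sample$burnin_applied <- TRUE
  sample$provenance$burnin_fraction <- fraction
  sample
}

#' Write a posterior sample as a NEXUS trees block
#'
#' Emits a `translate` table plus numbered tree statements, the dialect
#' consumed by [read_nexus_trees()].
#'
#' @param sample a [posterior_sample].
#' @param path output file path.
#' @export
write_nexus_trees <- function(sample, path) {
  stopifnot(inherits(sample, "posterior_sample"))
  ape::write.nexus(sample$trees, file = path, translate = TRUE)
  invisible(path)
}

#' Canonical non-trivial bipartitions of a tree
#'
#' Each internal edge splits the leaves in two; the canonical form is the
#' side *not* containing the reference taxon (the lexicographically smallest
#' leaf label), so identical splits read off either side or either rooting
#' collapse to the same key. Trivial splits (one leaf versus the rest) are
#' excluded, as is the duplicate split induced by a degree-2 root.
#'
#' @param tree a `phylo` object.
#' @return a character vector of split keys (leaf names sorted, joined by
#'   `"|"`), empty for trees with fewer than 4 leaves.
#' @export
bipartition_set <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) {
    return(character(0))
  }
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    c <- po$edge[i, 2L]
    below[p, ] <- below[p, ] | below[c, ]
  }
  keys <- character(0)
  for (i in seq_len(nrow(po$edge))) {
    side <- below[po$edge[i, 2L], ]
    k <- sum(side)
    if (k <= 1L || k >= ntip - 1L) next
    if (side[match(ref, labs)]) side <- !side
    keys <- c(keys, paste(sort(labs[side]), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric-difference count of non-trivial bipartitions: the number of
#' splits found in one tree but not the other. Comparison is unrooted;
#' branch lengths are ignored. Polytomous trees are accepted (their fewer
#' splits are simply counted).
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @param normalized if `TRUE`, divide by the maximum `2*(n-3)` attainable
#'   by two binary trees on `n` leaves.
#' @return a non-negative count (or fraction if `normalized`).
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  check_same_leaves(t1$tip.label, t2$tip.label)
  s1 <- bipartition_set(t1)
  s2 <- bipartition_set(t2)
  d <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (normalized) {
    n <- length(t1$tip.label)
    if (n <= 3L) {
      return(0)
    }
    return(d / (2 * (n - 3)))
  }
  d
}

check_same_leaves <- function(a, b) {
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  if (length(only_a) || length(only_b)) {
    stop_ct(
      "leaf sets differ; only in first: {",
      paste(only_a, collapse = ", "), "}; only in second: {",
      paste(only_b, collapse = ", "), "}"
    )
  }
  invisible(TRUE)
}

#' Are two trees the same unrooted topology?
#'
#' True when the unrooted bipartition sets coincide (equivalently
#' `rf_distance == 0`). Root placement, child order and branch lengths are
#' ignored.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return logical.
#' @export
topologies_equal <- function(t1, t2) {
  check_same_leaves(t1$tip.label, t2$tip.label)
  setequal(bipartition_set(t1), bipartition_set(t2))
}

#' Draw a uniformly random unrooted binary topology
#'
#' Sequential random attachment: grow from the 3-leaf star by attaching each
#' further leaf to an edge chosen uniformly at random, which yields the
#' uniform distribution over the `(2n-5)!!` labelled unrooted binary
#' topologies. No branch lengths are assigned.
#'
#' @param taxa character vector of at least 3 unique leaf labels.
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#' @return a `phylo` object without branch lengths.
#' @export
random_topology <- function(taxa, seed = NULL) {
  taxa <- as.character(taxa)
  if (length(taxa) < 3L) stop_ct("need at least 3 taxa, got ", length(taxa))
  if (anyDuplicated(taxa)) stop_ct("taxa labels must be unique")
  with_seed(seed, {
    n <- length(taxa)
    # edges as a growing 2-column matrix of node ids
    edges <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), 3L, 2L, byrow = TRUE)
    next_internal <- n + 2L
    if (n > 3L) {
      for (i in 4:n) {
        e <- sample.int(nrow(edges), 1L)
        a <- edges[e, 1L]
        b <- edges[e, 2L]
        m <- next_internal
        next_internal <- next_internal + 1L
        edges[e, ] <- c(a, m)
        edges <- rbind(edges, c(m, b), c(m, i))
      }
    }
    adj <- edgelist_to_adj(edges, ntip = n, tip_label = taxa)
    adj_to_phylo(adj, root = n + 1L)
  })
}

edgelist_to_adj <- function(edges, ntip, tip_label, lengths = NULL) {
  nnode <- max(edges)
  nbr <- vector("list", nnode)
  len <- vector("list", nnode)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]
    b <- edges[i, 2L]
    l <- if (is.null(lengths)) NA_real_ else lengths[i]
    nbr[[a]] <- c(nbr[[a]], b)
    len[[a]] <- c(len[[a]], l)
    nbr[[b]] <- c(nbr[[b]], a)
    len[[b]] <- c(len[[b]], l)
  }
  list(nbr = nbr, len = len, ntip = ntip, tip.label = tip_label)
}

#' Restrict a parasite tree to mapped taxa and relabel with host names
#'
#' Leaves absent from the association (outgroups) are pruned, the degree-2
#' nodes this creates are suppressed, remaining leaves are renamed to their
#' host taxa, and branch lengths are dropped: the result is directly
#' comparable to the host topology.
#'
#' @param virus_tree a `phylo` whose tips include all mapped parasite taxa.
#' @param assoc a [host_association].
#' @return a topology-only `phylo` with host leaf labels.
#' @export
map_and_prune <- function(virus_tree, assoc) {
  assoc <- as_host_association(assoc)
  mapped <- names(assoc)
  missing <- setdiff(mapped, virus_tree$tip.label)
  if (length(missing)) {
    stop_ct(
      "mapped taxa absent from the tree: ",
      paste(missing, collapse = ", ")
    )
  }
  pruned <- ape::keep.tip(virus_tree, mapped)
  pruned$tip.label <- unname(assoc[pruned$tip.label])
  pruned$edge.length <- NULL
  pruned$node.label <- NULL
  pruned
}

#' Virus-to-host association table
#'
#' A named character vector mapping parasite taxon (name) to host taxon
#' (value). The mapping must be injective over the parasite leaves used in
#' the congruence analysis; parasite taxa left out are treated as outgroups
#' and pruned by [map_and_prune()].
#'
#' @param virus character vector of parasite taxon names.
#' @param host character vector of host taxon names, same length.
#' @return a named character vector of class `host_association`.
#' @export
host_association <- function(virus, host) {
  virus <- as.character(virus)
  host <- as.character(host)
  stopifnot(length(virus) == length(host))
  if (anyDuplicated(virus)) {
    stop_ct(
      "duplicate parasite taxa in association: ",
      paste(unique(virus[duplicated(virus)]), collapse = ", ")
    )
  }
  if (anyDuplicated(host)) {
    stop_ct(
      "association is not injective; duplicated host taxa: ",
      paste(unique(host[duplicated(host)]), collapse = ", ")
    )
  }
  structure(stats::setNames(host, virus), class = "host_association")
}

as_host_association <- function(x) {
  if (inherits(x, "host_association")) {
    return(x)
  }
  if (is.character(x) && !is.null(names(x))) {
    return(host_association(names(x), unname(x)))
  }
  stop_ct("cannot interpret object as a host association")
}

#' Read a virus-to-host association from a two-column TSV
#'
#' Tab-delimited, UTF-8, `#` comment lines allowed, columns
#' `virus_taxon<TAB>host_taxon`. A header line is detected and skipped when
#' its first field is literally `virus_taxon`.
#'
#' @param path file path.
#' @return a [host_association].
#' @export
read_association <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop_ct("line ", bad[1], " of ", path, " does not have two tab-separated fields")
  }
  virus <- trimws(vapply(parts, `[[`, "", 1L))
  host <- trimws(vapply(parts, `[[`, "", 2L))
  if (length(virus) && virus[1] == "virus_taxon") {
    virus <- virus[-1]
    host <- host[-1]
  }
  host_association(virus, host)
}

#' Write an association table as TSV
#' @param assoc a [host_association].
#' @param path output file path.
#' @export
write_association <- function(assoc, path) {
  assoc <- as_host_association(assoc)
  writeLines(
    c("virus_taxon\thost_taxon", paste(names(assoc), unname(assoc), sep = "\t")),
    path
  )
  invisible(path)
}
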