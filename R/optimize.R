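# Likelihood evaluation context: everything that survives across repeated
# evaluations on one topology (postorder edge matrix, compressed patterns,
# pattern weights). The optimizers and the MCMC live on these.

lik_context <- function(tree, aln, cp = NULL) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  if (is.null(cp)) cp <- compress_patterns(aln, po$tip.label)
  list(
    po = po, ntip = ntip, nnode = ntip + tree$Nnode, root = ntip + 1L,
    cp = cp, w = tabulate(cp$index, cp$npat)
  )
}

model_rates <- function(model) {
  if (is.na(model$gamma_shape)) 1 else discrete_gamma_rates(model$gamma_shape, model$k)
}

lik_eval <- function(ctx, elen, model, eg = NULL, rates = NULL, inv = NULL) {
  if (ctx$cp$npat == 0L) {
    return(0)
  }
  if (is.null(eg)) eg <- model_eigen(model)
  if (is.null(rates)) rates <- model_rates(model)
  if (is.null(inv)) {
    inv <- if (model$p_inv > 0) {
      as.numeric(model$base_freq %*% ctx$cp$prod_part)
    } else {
      numeric(ctx$cp$npat)
    }
  }
  pp <- pruning_loglik_cpp(
    ctx$po$edge, elen, ctx$ntip, ctx$nnode, ctx$root,
    ctx$cp$tip_part, eg$A, eg$B, eg$lambda,
    rates, model$base_freq, model$p_inv, inv
  )
  sum(pp * ctx$w)
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise Brent optimization of each edge length in turn, sweeping
#' until the total log-likelihood improves by less than `tol` per sweep (or
#' `max_sweeps` is reached). The log-likelihood never decreases across
#' sweeps.
#'
#' @param tree a `phylo`; edges without a length start at 0.1.
#' @param aln a [dna_alignment].
#' @param model a [substitution_model()].
#' @param tol lnL convergence tolerance per sweep (default 1e-6).
#' @param max_sweeps maximum sweeps (default 50).
#' @param min_len,max_len search bracket for each branch length.
#' @param edge_tol Brent x-tolerance per edge (default 1e-9).
#' @return list with `tree` (updated lengths), `lnL` and `sweeps`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    max_sweeps = 50, min_len = 1e-9,
                                    max_len = 10, edge_tol = 1e-9) {
  tree <- ensure_lengths(tree)
  ctx <- lik_context(tree, aln)
  eg <- model_eigen(model)
  rates <- model_rates(model)
  elen <- ctx$po$edge.length
  cur <- lik_eval(ctx, elen, model, eg, rates)
  if (!is.finite(cur)) {
    stop_ct(
      "log-likelihood is not finite at the starting state; ",
      "check that the alignment matches the model and tree"
    )
  }
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    before <- cur
    for (i in seq_along(elen)) {
      f <- function(t) {
        e <- elen
        e[i] <- t
        lik_eval(ctx, e, model, eg, rates)
      }
      opt <- stats::optimize(f, c(min_len, max_len), maximum = TRUE, tol = edge_tol)
      if (opt$objective > cur) {
        elen[i] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - before < tol || sweeps >= max_sweeps) break
  }
  out <- ctx$po
  out$edge.length <- elen
  list(tree = ape::reorder.phylo(out, "cladewise"), lnL = cur, sweeps = sweeps)
}

ensure_lengths <- function(tree, default = 0.1) {
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(default, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- default
    tree$edge.length[tree$edge.length < 0] <- 1e-8
  }
  tree
}

# ---- model families ---------------------------------------------------

FAMILY_BASES <- c(JC = 0L, K80 = 1L, HKY = 4L, GTR = 8L)

parse_family <- function(name) {
  up <- toupper(gsub("\\s", "", name))
  parts <- strsplit(up, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  if (!base %in% names(FAMILY_BASES)) {
    stop_ct(
      "unknown model family '", name,
      "' (expected JC, K80, HKY or GTR, optionally +G and/or +I)"
    )
  }
  flags <- parts[-1]
  if (!all(flags %in% c("G", "I"))) {
    stop_ct("unknown model flag in '", name, "' (only +G and +I are supported)")
  }
  list(
    name = paste(c(base, intersect(c("G", "I"), flags)), collapse = "+"),
    base = base,
    gamma = "G" %in% flags,
    inv = "I" %in% flags,
    n_free = unname(FAMILY_BASES[base]) + ("G" %in% flags) + ("I" %in% flags)
  )
}

# Free-parameter packing. All parameters are mapped to the real line:
# log rates, log-ratio frequencies (vs T), log alpha, logit p_inv.
pack_model <- function(model, fam) {
  th <- numeric(0)
  if (fam$base == "K80" || fam$base == "HKY") th <- c(th, log(model$exch[2]))
  if (fam$base == "GTR") th <- c(th, log(pmax(model$exch[1:5], 1e-8)))
  if (fam$base %in% c("HKY", "GTR")) {
    th <- c(th, log(model$base_freq[1:3] / model$base_freq[4]))
  }
  if (fam$gamma) th <- c(th, log(model$gamma_shape))
  if (fam$inv) th <- c(th, stats::qlogis(min(max(model$p_inv, 1e-6), 0.99)))
  th
}

unpack_model <- function(th, fam, template) {
  i <- 0L
  take <- function(n) {
    v <- th[i + seq_len(n)]
    i <<- i + n
    v
  }
  exch <- rep(1, 6)
  if (fam$base %in% c("K80", "HKY")) {
    kappa <- exp(take(1))
    exch <- c(1, kappa, 1, 1, kappa, 1)
  } else if (fam$base == "GTR") {
    exch <- c(exp(take(5)), 1)
  }
  bf <- rep(0.25, 4)
  if (fam$base %in% c("HKY", "GTR")) {
    lr <- take(3)
    u <- c(exp(lr), 1)
    bf <- u / sum(u)
  } else if (!is.null(template)) {
    bf <- rep(0.25, 4) # JC / K80 assume equal frequencies
  }
  alpha <- if (fam$gamma) exp(take(1)) else NA_real_
  pinv <- if (fam$inv) stats::plogis(take(1)) else 0
  substitution_model(
    exch = pmin(exch, 1e4), base_freq = bf,
    gamma_shape = if (!is.na(alpha)) min(max(alpha, 0.02), 100) else NA_real_,
    p_inv = min(pinv, 0.99),
    k = if (is.null(template)) 4L else template$k
  )
}

family_start_model <- function(fam, aln, k = 4L) {
  bf <- if (fam$base %in% c("HKY", "GTR")) base_frequencies(aln) else rep(0.25, 4)
  bf <- pmax(bf, 1e-3)
  bf <- bf / sum(bf)
  exch <- if (fam$base %in% c("K80", "HKY")) c(1, 2, 1, 1, 2, 1) else rep(1, 6)
  substitution_model(
    exch = exch, base_freq = bf,
    gamma_shape = if (fam$gamma) 1 else NA_real_,
    p_inv = if (fam$inv) 0.1 else 0, k = k
  )
}

#' Optimize substitution-model parameters (with branch-length sweeps)
#'
#' Maximizes the log-likelihood over the free parameters of a model family
#' (exchangeabilities, base frequencies on the simplex via an unconstrained
#' log-ratio transform, gamma shape, invariable proportion), interleaved
#' with coordinate-wise branch-length sweeps. The log-likelihood is
#' non-decreasing across rounds.
#'
#' @param tree a `phylo` with (or without) branch lengths.
#' @param aln a [dna_alignment].
#' @param model starting [substitution_model()]; also defines the family
#'   when `family` is `NULL` (gamma/invariable parts are optimized when set
#'   in the model).
#' @param family optional family string such as `"GTR+G+I"`, `"HKY+G"`,
#'   `"JC"`; overrides `model`'s structure.
#' @param max_rounds maximum model/branch interleavings (default 12).
#' @param tol lnL convergence tolerance between rounds (default 1e-3; the
#'   profile over the gamma-shape/invariable-proportion ridge is extremely
#'   flat, and tighter tolerances only crawl along it).
#' @return list with `model`, `tree`, `lnL`, `n_free_parameters` and
#'   `converged`.
#' @export
optimize_model_parameters <- function(tree, aln, model = NULL, family = NULL,
                                      max_rounds = 12, tol = 1e-3) {
  if (is.null(family)) {
    if (is.null(model)) stop_ct("supply a model, a family, or both")
    base <- if (all(model$exch == 1)) {
      if (all(abs(model$base_freq - 0.25) < 1e-12)) "JC" else "HKY"
    } else {
      "GTR"
    }
    family <- paste(c(
      base, if (!is.na(model$gamma_shape)) "G",
      if (model$p_inv > 0) "I"
    ), collapse = "+")
  }
  fam <- parse_family(family)
  if (is.null(model)) model <- family_start_model(fam, aln)
  tree <- ensure_lengths(tree)

  bl <- optimize_branch_lengths(tree, aln, model,
    tol = 1e-4, max_sweeps = 3, edge_tol = 1e-6
  )
  tree <- bl$tree
  cur <- bl$lnL
  converged <- FALSE
  if (fam$n_free > 0) {
    for (round in seq_len(max_rounds)) {
      ctx <- lik_context(tree, aln)
      elen <- ctx$po$edge.length
      th0 <- pack_model(model, fam)
      negll <- function(th) {
        m <- unpack_model(th, fam, model)
        v <- lik_eval(ctx, elen, m)
        if (!is.finite(v)) {
          return(1e10)
        }
        -v
      }
      opt <- if (length(th0) == 1L) {
        # single free parameter: bounded Brent on the transformed scale
        stats::optim(th0, negll,
          method = "Brent",
          lower = th0 - 8, upper = th0 + 8
        )
      } else {
        stats::optim(th0, negll,
          method = "Nelder-Mead",
          control = list(
            maxit = if (round == 1L) 1500 else 500,
            reltol = 1e-10
          )
        )
      }
      cand <- unpack_model(opt$par, fam, model)
      if (-opt$value > cur) model <- cand
      bl <- optimize_branch_lengths(tree, aln, model,
        tol = 1e-5, edge_tol = 1e-7,
        max_sweeps = if (round < max_rounds) 3 else 10
      )
      tree <- bl$tree
      if (bl$lnL - cur < tol) {
        cur <- max(cur, bl$lnL)
        converged <- TRUE
        break
      }
      cur <- bl$lnL
    }
    if (!converged) {
      warning("model-parameter optimization stopped at max_rounds; returning best so far")
    }
  } else {
    bl <- optimize_branch_lengths(tree, aln, model, tol = 1e-6, max_sweeps = 20)
    tree <- bl$tree
    cur <- bl$lnL
    converged <- TRUE
  }
  list(
    model = model, tree = tree, lnL = cur,
    n_free_parameters = fam$n_free + nrow(tree$edge),
    family = fam$name, converged = converged
  )
}
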