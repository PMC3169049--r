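#' Nucleotide alignment
#'
#' Equal-length sequences keyed by unique taxon names, stored as an
#' uppercase character matrix (taxa x sites). IUPAC ambiguity codes, `-`
#' and `N`/`?` are allowed; `U` is normalized to `T`.
#'
#' @param seqs named character vector of sequences, or a character matrix
#'   with taxon rownames.
#' @return an object of class `dna_alignment` with elements `mat` (character
#'   matrix), `taxa` and `L`.
#' @export
dna_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    taxa <- rownames(mat)
  } else {
    taxa <- names(seqs)
    if (is.null(taxa)) stop_ct("sequences must be named by taxon")
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop_ct(
        "sequences have unequal lengths: ",
        paste(unique(lens), collapse = ", ")
      )
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    if (length(seqs) && lens[1] == 0L) mat <- matrix(character(0), length(seqs), 0L)
    rownames(mat) <- taxa
  }
  if (anyDuplicated(taxa)) {
    stop_ct(
      "duplicate taxon names: ",
      paste(unique(taxa[duplicated(taxa)]), collapse = ", ")
    )
  }
  mat[mat == "U"] <- "T"
  bad <- setdiff(unique(as.vector(mat)), names(IUPAC_PARTIALS))
  if (length(bad)) stop_ct("unsupported characters in alignment: ", paste(bad, collapse = " "))
  structure(list(mat = mat, taxa = taxa, L = ncol(mat)), class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", length(x$taxa), "taxa x", x$L, "sites\n")
  invisible(x)
}

# partial-likelihood vectors for every accepted character
IUPAC_PARTIALS <- list(
  A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
  R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0), W = c(1, 0, 0, 1),
  K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
  B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1), V = c(1, 1, 1, 0),
  N = c(1, 1, 1, 1), `-` = c(1, 1, 1, 1), `?` = c(1, 1, 1, 1)
)

#' Read a FASTA alignment
#'
#' Wrapped lines are concatenated, case is folded to upper, `U` becomes
#' `T`. All sequences must have equal length.
#'
#' @param path FASTA file path.
#' @return a [dna_alignment].
#' @export
read_fasta_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop_ct(path, ": not FASTA (no leading '>' header)")
  idx <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_) # first token is the taxon name
  seqs <- vapply(
    split(lines[!hdr], idx[!hdr]),
    function(x) gsub("\\s", "", paste(x, collapse = "")), ""
  )
  dna_alignment(stats::setNames(unname(seqs), names_))
}

#' Write an alignment as FASTA
#' @param aln a [dna_alignment].
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @export
write_fasta_alignment <- function(aln, path, width = 70) {
  stopifnot(inherits(aln, "dna_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$taxa)) {
    writeLines(paste0(">", aln$taxa[i]), con)
    s <- paste(aln$mat[i, ], collapse = "")
    if (nchar(s)) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Resample alignment columns with replacement
#'
#' The bootstrap/RELL primitive: taxa and length are preserved.
#'
#' @param aln a [dna_alignment].
#' @param seed optional integer seed.
#' @return a [dna_alignment] of the same dimensions.
#' @export
resample_columns <- function(aln, seed = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  with_seed(seed, {
    cols <- sample.int(aln$L, aln$L, replace = TRUE)
    dna_alignment(aln$mat[, cols, drop = FALSE])
  })
}

# Compress an alignment into unique site patterns for the given taxon
# order. Returns the pattern matrix, the per-original-column pattern index
# and the per-taxon 4 x npat tip partial block used by the C++ kernel.
compress_patterns <- function(aln, taxa) {
  miss <- setdiff(taxa, aln$taxa)
  if (length(miss)) {
    stop_ct("leaf without a sequence: ", paste(miss, collapse = ", "))
  }
  mat <- aln$mat[taxa, , drop = FALSE]
  if (ncol(mat) == 0L) {
    return(list(
      index = integer(0), npat = 0L,
      tip_part = matrix(0, 4, 0), inv_contrib = numeric(0)
    ))
  }
  keys <- apply(mat, 2, paste, collapse = "")
  uk <- unique(keys)
  index <- match(keys, uk)
  first <- match(uk, keys)
  pat <- mat[, first, drop = FALSE]
  npat <- length(uk)
  ntaxa <- length(taxa)
  tip_part <- matrix(0, 4, ntaxa * npat)
  prod_part <- matrix(1, 4, npat)
  lut <- do.call(cbind, IUPAC_PARTIALS)
  for (i in seq_len(ntaxa)) {
    block <- lut[, pat[i, ], drop = FALSE]
    tip_part[, (i - 1) * npat + seq_len(npat)] <- block
    prod_part <- prod_part * block
  }
  list(
    index = index, npat = npat, tip_part = tip_part,
    prod_part = prod_part
  )
}

#' Observed base frequencies of an alignment
#'
#' Unambiguous A/C/G/T counts only; used for empirical starting values.
#'
#' @param aln a [dna_alignment].
#' @return numeric length 4 summing to 1.
#' @export
base_frequencies <- function(aln) {
  tab <- table(factor(as.vector(aln$mat), levels = DNA_STATES))
  f <- as.numeric(tab)
  if (sum(f) == 0) {
    return(rep(0.25, 4))
  }
  f / sum(f)
}
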