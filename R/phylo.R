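# Distance phylogeny from the single-copy supermatrix: p-distances,
# neighbor joining (ape), column-resampling bootstrap with bipartition
# supports.

supermatrixMatrix <- function(sm) {
  stopifnot(is(sm, "Supermatrix"))
  do.call(rbind, strsplit(as.character(sm@sequences), ""))
}

pDistFromMatrix <- function(M) {
  sp <- rownames(M)
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    comparable <- M[i, ] != "-" & M[j, ] != "-"
    nc <- sum(comparable)
    if (nc == 0)
      stop("no comparable columns between ", sp[i], " and ", sp[j])
    D[i, j] <- D[j, i] <- 1 - sum(M[i, comparable] == M[j, comparable]) / nc
  }
  D
}

#' p-distance matrix of a supermatrix
#'
#' d(i, j) = 1 - (identical residues) / (comparable columns), where a
#' column is comparable when both rows are non-gap. A species pair with no
#' comparable columns is an error.
#'
#' @param sm a [Supermatrix-class] (>= 3 species).
#' @return symmetric numeric matrix with zero diagonal, species as
#'   dimnames.
#' @export
pDistances <- function(sm) {
  M <- supermatrixMatrix(sm)
  if (nrow(M) < 3) stop("need at least 3 species")
  pDistFromMatrix(M)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Q-criterion, Saitou-Nei branch lengths) via
#' [ape::nj()], with taxa pre-sorted by label so the result is invariant
#' to input order. Negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param D symmetric distance matrix with species dimnames (or `dist`).
#' @return unrooted `phylo`.
#' @export
njTree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(nrow(D) >= 3, !is.null(rownames(D)))
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  tr <- ape::nj(stats::as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap supports for the NJ supermatrix tree
#'
#' Builds the NJ tree from the full supermatrix, then resamples
#' supermatrix columns with replacement `nReps` times, rebuilds the NJ
#' tree per replicate, and scores each internal bipartition of the
#' original tree by the percentage of replicate trees containing it
#' (unrooted bipartitions, [ape::prop.clades()]). Deterministic given
#' `seed`; supports are invariant to supermatrix column order.
#'
#' @param sm a [Supermatrix-class].
#' @param nReps bootstrap replicates (default 100).
#' @param seed RNG seed for the resampling substream.
#' @return `phylo` with `node.label` holding supports (0-100; empty at
#'   the root), plus attribute `replicates` = nReps.
#' @export
bootstrapTree <- function(sm, nReps = 100L, seed = 1L) {
  stopifnot(nReps >= 1)
  M <- supermatrixMatrix(sm)
  if (nrow(M) < 3) stop("need at least 3 species")
  base <- njTree(pDistFromMatrix(M))
  # p-distances depend only on the multiset of columns; sorting columns by
  # their site pattern makes the resampled replicates (hence the supports)
  # invariant to supermatrix column order
  M <- M[, order(apply(M, 2, paste, collapse = "")), drop = FALSE]
  L <- ncol(M)
  reps <- withSeed(substreamSeed(seed, "bootstrap"), {
    lapply(seq_len(nReps), function(r) {
      idx <- sample.int(L, L, replace = TRUE)
      suppressWarnings(njTree(pDistFromMatrix(M[, idx, drop = FALSE])))
    })
  })
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / nReps)
  lab <- as.character(support)
  # the root "bipartition" of an unrooted tree is not an internal edge
  lab[1] <- ""
  base$node.label <- lab
  attr(base, "replicates") <- as.integer(nReps)
  base
}

#' Export a distance matrix in square PHYLIP layout
#'
#' @param D symmetric distance matrix with species dimnames.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePhylipDist <- function(D, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Test two trees for identical unrooted topology
#'
#' TRUE when both trees share the same tip set and their unrooted
#' Robinson-Foulds distance is zero.
#'
#' @param t1,t2 `phylo` objects.
#' @return logical.
#' @export
sameUnrootedTopology <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  d <- tryCatch(ape::dist.topo(ape::unroot(t1), ape::unroot(t2),
                               method = "PH85"),
                error = function(e) NA)
  isTRUE(as.numeric(d) == 0)
}
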