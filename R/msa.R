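# Progressive multiple alignment: average-linkage guide tree on pairwise
# global-alignment distances, then profile-profile merges with sum-of-pairs
# scoring and affine gaps. The DP kernel lives in src/align.cpp; columns are
# never reordered.

encodeResidues <- function(s) {
  idx <- match(strsplit(s, "")[[1]], AA20_VEC)
  if (anyNA(idx)) stop("non-canonical residue in sequence")
  idx
}

# gapped integer row (0 = gap) back to a string
decodeRow <- function(v) {
  paste(c("-", AA20_VEC)[v + 1L], collapse = "")
}

#' Global alignment of two protein sequences
#'
#' Needleman-Wunsch with Gotoh affine gaps (gap of length k costs
#' `gapOpen + k * gapExtend`). Used for guide-tree distances and as the
#' two-sequence base case of [progressiveMSA()].
#'
#' @param a,b protein sequences (character).
#' @param matrix substitution matrix name or matrix (default BLOSUM62).
#' @param gapOpen,gapExtend positive gap penalties (defaults 11, 1).
#' @return list: `score`, aligned strings `a` and `b`, `identity`
#'   (matches / alignment length).
#' @export
alignGlobal <- function(a, b, matrix = "BLOSUM62", gapOpen = 11,
                        gapExtend = 1) {
  sub <- getSubstitutionMatrix(matrix)
  ca <- strsplit(as.character(a), "")[[1]]
  cb <- strsplit(as.character(b), "")[[1]]
  S <- sub[ca, cb, drop = FALSE]
  res <- .affineAlignGlobal(S, gapOpen, gapExtend)
  p1 <- res$path1; p2 <- res$path2
  a_aln <- ifelse(p1 == 0L, "-", ca[pmax(p1, 1L)])
  b_aln <- ifelse(p2 == 0L, "-", cb[pmax(p2, 1L)])
  matches <- sum(p1 > 0 & p2 > 0 & a_aln == b_aln)
  list(score = res$score,
       a = paste(a_aln, collapse = ""), b = paste(b_aln, collapse = ""),
       identity = matches / length(p1))
}

# residue count profile (20 x L) of a gapped integer matrix
profileCounts <- function(rows) {
  L <- ncol(rows)
  P <- matrix(0, 20L, L)
  for (i in seq_len(nrow(rows))) {
    v <- rows[i, ]
    nz <- which(v > 0L)
    P[cbind(v[nz], nz)] <- P[cbind(v[nz], nz)] + 1
  }
  P
}

# merge two sub-alignments (integer matrices) by profile-profile DP
mergeProfiles <- function(A, B, sub20, gapOpen, gapExtend) {
  PA <- profileCounts(A)
  PB <- profileCounts(B)
  S <- crossprod(PA, sub20 %*% PB) # (L1 x L2) summed pair scores
  nn <- nrow(A) * nrow(B)
  res <- .affineAlignGlobal(S, gapOpen * nn, gapExtend * nn)
  p1 <- res$path1; p2 <- res$path2
  L <- length(p1)
  out <- matrix(0L, nrow(A) + nrow(B), L)
  out[seq_len(nrow(A)), p1 > 0L] <- A[, p1[p1 > 0L], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), p2 > 0L] <- B[, p2[p2 > 0L], drop = FALSE]
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by average-linkage clustering of pairwise
#' global-alignment distances (1 - identity), then merges sub-alignments
#' bottom-up with profile-profile sum-of-pairs scoring under affine gaps
#' (penalties scaled by the number of sequence pairs crossing the merge).
#' A single sequence is returned as-is; two sequences reduce to
#' [alignGlobal()]. Row order of the result follows the input.
#'
#' @param seqs [Biostrings::AAStringSet] (or named character vector).
#' @param matrix,gapOpen,gapExtend scoring scheme (defaults BLOSUM62,
#'   11, 1).
#' @return [Biostrings::AAStringSet] of equal-width aligned sequences.
#' @examples
#' progressiveMSA(Biostrings::AAStringSet(c(a = "HEAGAWGHEE",
#'                                          b = "HEAGAWGHEE")))
#' @export
progressiveMSA <- function(seqs, matrix = "BLOSUM62", gapOpen = 11,
                           gapExtend = 1) {
  seqs <- Biostrings::AAStringSet(seqs)
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (n == 0) stop("no sequences")
  if (n == 1) return(seqs)
  sub <- getSubstitutionMatrix(matrix)
  sub20 <- sub[AA20_VEC, AA20_VEC]
  chr <- as.character(seqs)

  if (n == 2) {
    al <- alignGlobal(chr[1], chr[2], sub, gapOpen, gapExtend)
    out <- Biostrings::AAStringSet(c(al$a, al$b))
    names(out) <- names(seqs)
    return(out)
  }

  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    al <- alignGlobal(chr[i], chr[j], sub, gapOpen, gapExtend)
    D[i, j] <- D[j, i] <- 1 - al$identity
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  enc <- lapply(chr, function(s) {
    m <- matrix(encodeResidues(s), nrow = 1L)
    m
  })
  for (i in seq_len(n)) rownames(enc[[i]]) <- names(seqs)[i]

  nodes <- vector("list", nrow(hc$merge))
  getAln <- function(k) if (k < 0) enc[[-k]] else nodes[[k]]
  for (m in seq_len(nrow(hc$merge))) {
    A <- getAln(hc$merge[m, 1])
    B <- getAln(hc$merge[m, 2])
    nodes[[m]] <- mergeProfiles(A, B, sub20, gapOpen, gapExtend)
  }
  final <- nodes[[nrow(hc$merge)]]
  final <- final[names(seqs), , drop = FALSE]
  out <- Biostrings::AAStringSet(apply(final, 1, decodeRow))
  names(out) <- names(seqs)
  out
}

#' Sum-of-pairs score of an alignment
#'
#' Total substitution score over all residue pairs in every column, minus
#' affine gap costs per pairwise projection (each pairwise alignment's
#' gaps are charged `gapOpen + k * gapExtend`; columns where both rows are
#' gapped are ignored for that pair).
#'
#' @param aln equal-width [Biostrings::AAStringSet].
#' @param matrix,gapOpen,gapExtend scoring scheme.
#' @return numeric score.
#' @export
sumOfPairsScore <- function(aln, matrix = "BLOSUM62", gapOpen = 11,
                            gapExtend = 1) {
  sub <- getSubstitutionMatrix(matrix)
  rows <- strsplit(as.character(aln), "")
  n <- length(rows)
  total <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- rows[[i]]; b <- rows[[j]]
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    both <- a != "-" & b != "-"
    total <- total + sum(sub[cbind(a[both], b[both])])
    for (g in list(a == "-", b == "-")) {
      r <- rle(g)
      gl <- r$lengths[r$values]
      total <- total - sum(gapOpen + gl * gapExtend)
    }
  }
  total
}

#' Read an aligned FASTA file
#'
#' All rows must have equal length; a ragged row is an error naming the
#' offending record. Every row must retain at least one non-gap column.
#'
#' @param path aligned FASTA path.
#' @return [Biostrings::AAStringSet].
#' @export
readAlignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) stop("no records in ", path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1) {
    bad <- names(ss)[which(w != w[1])[1]]
    stop("ragged alignment: record '", bad, "' has length ",
         w[w != w[1]][1], ", expected ", w[1])
  }
  gapOnly <- Biostrings::letterFrequency(ss, "-") == w
  if (any(gapOnly))
    stop("record '", names(ss)[which(gapOnly)[1]], "' is all gaps")
  ss
}

#' Write an alignment as aligned FASTA
#'
#' @param aln [Biostrings::AAStringSet].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln, path, width = 60L)
  invisible(path)
}
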