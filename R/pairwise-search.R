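#' Keep the longest isoform per gene
#'
#' Collapses splice isoforms so that each gene is represented by exactly
#' one sequence: the longest isoform, ties broken by the lexicographically
#' smaller isoform id. Records without an isoform tag pass through
#' unchanged. After filtering, sequence ids equal gene ids.
#'
#' @param pset a [ProteomeSet-class].
#' @return a [ProteomeSet-class] with one sequence per gene.
#' @export
filterLongestIsoform <- function(pset) {
  stopifnot(is(pset, "ProteomeSet"))
  gi <- as.data.frame(pset@geneInfo)
  gi$len <- Biostrings::width(pset@sequences)
  iso <- ifelse(is.na(gi$isoform), "", gi$isoform)
  ord <- order(gi$gene_id, -gi$len, iso)
  keep <- ord[!duplicated(gi$gene_id[ord])]
  keep <- sort(keep)
  seqs <- pset@sequences[keep]
  names(seqs) <- gi$gene_id[keep]
  out <- gi[keep, c("gene_id", "species", "family")]
  new("ProteomeSet", sequences = seqs,
      geneInfo = DataFrame(seq_id = out$gene_id, gene_id = out$gene_id,
                           species = out$species, isoform = NA_character_,
                           family = out$family))
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman/Gotoh local alignment under affine gap penalties (a gap
#' of length k costs `gapOpen + k * gapExtend`), computed with
#' [Biostrings::pairwiseAlignment()]. Returns the raw score, the fraction
#' of identical positions over the local alignment, and the alignment
#' length (gapped columns included). When no residue pair scores
#' positively the optimal local alignment is empty: score 0, identity 0,
#' length 0.
#'
#' @param a,b protein sequences (character or `AAString`).
#' @param matrix substitution matrix name (from Biostrings) or a matrix;
#'   default BLOSUM62.
#' @param gapOpen,gapExtend positive gap penalties (defaults 11 and 1).
#' @param onUnknown `"error"` rejects residues absent from the matrix;
#'   `"min"` scores them as the matrix minimum against everything.
#' @return list with `score`, `identity`, `alignedLength`.
#' @examples
#' alignLocal("HEAGAWGHEE", "HEAGAWGHEE")$identity
#' @export
alignLocal <- function(a, b, matrix = "BLOSUM62", gapOpen = 11,
                       gapExtend = 1, onUnknown = c("error", "min")) {
  onUnknown <- match.arg(onUnknown)
  stopifnot(gapOpen > 0, gapExtend > 0)
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  sub <- getSubstitutionMatrix(matrix)
  letters <- unique(strsplit(paste0(a, b), "")[[1]])
  unknown <- setdiff(letters, rownames(sub))
  if (length(unknown)) {
    if (onUnknown == "error")
      stop("unknown residue letter(s): ", paste(unknown, collapse = ""))
    sub <- augmentMatrix(sub, unknown)
  }
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = sub,
                                      gapOpening = gapOpen,
                                      gapExtension = gapExtend,
                                      scoreOnly = FALSE)
  sc <- Biostrings::score(pa)
  if (sc <= 0)
    return(list(score = 0, identity = 0, alignedLength = 0L))
  len <- Biostrings::nchar(pa)
  list(score = sc,
       identity = Biostrings::nmatch(pa) / len,
       alignedLength = len)
}

augmentMatrix <- function(sub, unknown) {
  mn <- min(sub)
  all <- c(rownames(sub), unknown)
  out <- matrix(mn, length(all), length(all), dimnames = list(all, all))
  out[rownames(sub), colnames(sub)] <- sub
  out
}

#' Karlin-Altschul E-value
#'
#' E = K * m * n * exp(-lambda * S) for a raw local alignment score S and
#' search space m x n. Strictly decreasing in S, increasing in m * n.
#'
#' @param score raw alignment score.
#' @param m,n query and subject lengths (>= 1).
#' @param K,lambda positive Karlin-Altschul parameters; defaults are the
#'   standard gapped BLOSUM62 constants (K = 0.041, lambda = 0.267).
#' @return the E-value.
#' @export
evalueKA <- function(score, m, n, K = 0.041, lambda = 0.267) {
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive")
  stopifnot(m >= 1, n >= 1)
  K * m * n * exp(-lambda * score)
}

bitScore <- function(score, K = 0.041, lambda = 0.267) {
  (lambda * score - log(K)) / log(2)
}

#' All-against-all protein similarity search
#'
#' Evaluates every ordered gene pair (within and across species, self-pairs
#' skipped) and keeps hits with E below the threshold. Two backends:
#' `"builtin"` runs exhaustive Smith-Waterman/Gotoh locally with
#' Karlin-Altschul E-values — exact but only sensible for small inputs;
#' `"blast"` shells out to the BLAST+ tools (`makeblastdb`/`blastp`,
#' 12-column tabular output) for larger sets, reading the result back with
#' [readHits()].
#'
#' @param pset a [ProteomeSet-class] (isoform-filtered; see
#'   [filterLongestIsoform()]).
#' @param evalueThreshold keep hits with E strictly below this (default
#'   1e-5).
#' @param matrix,gapOpen,gapExtend scoring scheme, as [alignLocal()].
#' @param K,lambda Karlin-Altschul constants for the builtin backend.
#' @param method `"builtin"` or `"blast"`.
#' @return a [HitTable-class].
#' @export
allAgainstAll <- function(pset, evalueThreshold = 1e-5,
                          matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                          K = 0.041, lambda = 0.267,
                          method = c("builtin", "blast")) {
  method <- match.arg(method)
  stopifnot(is(pset, "ProteomeSet"))
  if (length(unique(pset@geneInfo$species)) < 2)
    stop("need at least 2 proteomes")
  if (any(Biostrings::width(pset@sequences) == 0)) stop("empty sequence")
  if (method == "blast")
    return(allAgainstAllBlast(pset, evalueThreshold))

  seqs <- pset@sequences
  n <- length(seqs)
  ids <- names(seqs)
  lens <- Biostrings::width(seqs)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      al <- alignLocal(as.character(seqs[[i]]), as.character(seqs[[j]]),
                       matrix = matrix, gapOpen = gapOpen,
                       gapExtend = gapExtend, onUnknown = "min")
      if (al$alignedLength == 0) next
      E <- evalueKA(al$score, lens[i], lens[j], K = K, lambda = lambda)
      if (E >= evalueThreshold) next
      bs <- bitScore(al$score, K, lambda)
      mism <- round(al$alignedLength * (1 - al$identity))
      # both directions share score and E (symmetric search space)
      rows[[length(rows) + 1L]] <- data.frame(
        query = c(ids[i], ids[j]), subject = c(ids[j], ids[i]),
        pident = round(100 * al$identity, 3), length = al$alignedLength,
        mismatch = mism, gapopen = 0L,
        qstart = 1L, qend = c(lens[i], lens[j]),
        sstart = 1L, send = c(lens[j], lens[i]),
        evalue = E, bitscore = round(bs, 1),
        stringsAsFactors = FALSE)
    }
  }
  h <- if (length(rows)) do.call(rbind, rows) else emptyHits()
  h <- h[order(h$query, h$subject), , drop = FALSE]
  rownames(h) <- NULL
  new("HitTable", hits = h, threshold = evalueThreshold)
}

emptyHits <- function() {
  df <- data.frame(query = character(), subject = character(),
                   pident = numeric(), length = integer(),
                   mismatch = integer(), gapopen = integer(),
                   qstart = integer(), qend = integer(),
                   sstart = integer(), send = integer(),
                   evalue = numeric(), bitscore = numeric(),
                   stringsAsFactors = FALSE)
  df
}

allAgainstAllBlast <- function(pset, evalueThreshold) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "")
    stop("BLAST+ (blastp/makeblastdb) not found on PATH")
  td <- tempfile("aaa_blast_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fa <- file.path(td, "all.faa")
  Biostrings::writeXStringSet(pset@sequences, fa, width = 60L)
  db <- file.path(td, "db")
  out <- file.path(td, "hits.tsv")
  run <- function(cmd, args) {
    st <- system2(cmd, args, stdout = file.path(td, "log"), stderr =
                  file.path(td, "log"))
    if (st != 0)
      stop(cmd, " failed (status ", st, "): ",
           paste(readLines(file.path(td, "log")), collapse = "\n"))
  }
  run("makeblastdb", c("-in", fa, "-dbtype", "prot", "-out", db))
  run("blastp", c("-query", fa, "-db", db, "-outfmt", "6",
                  "-evalue", format(evalueThreshold, scientific = TRUE),
                  "-num_threads", "1", "-max_target_seqs", "500",
                  "-out", out))
  readHits(out, threshold = evalueThreshold)
}

#' Read a 12-column tabular hit file
#'
#' Parses the standard 12-column tab-separated hit layout (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, E-value, bit score; no header), applies the E-value
#' threshold, drops self-hits, floors zero E-values at 1e-200 and
#' collapses duplicate (query, subject) rows to the best by E-value (ties
#' by bit score). Malformed lines are rejected with their line number.
#'
#' @param path input path.
#' @param threshold E-value threshold; hits with E >= threshold are
#'   dropped (default 1e-5).
#' @return a [HitTable-class].
#' @export
readHits <- function(path, threshold = 1e-5) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(new("HitTable", hits = emptyHits(), threshold = threshold))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop("line ", bad, ": expected 12 tab-separated columns, found ",
         nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop("line ", bad, ": unparsable numeric field")
  }
  h <- data.frame(query = m[, 1], subject = m[, 2],
                  pident = num[, 1], length = as.integer(num[, 2]),
                  mismatch = as.integer(num[, 3]),
                  gapopen = as.integer(num[, 4]),
                  qstart = as.integer(num[, 5]), qend = as.integer(num[, 6]),
                  sstart = as.integer(num[, 7]), send = as.integer(num[, 8]),
                  evalue = num[, 9], bitscore = num[, 10],
                  stringsAsFactors = FALSE)
  h$evalue[h$evalue <= 0] <- 1e-200
  h <- h[h$query != h$subject, , drop = FALSE]
  h <- h[h$evalue < threshold, , drop = FALSE]
  ord <- order(h$query, h$subject, h$evalue, -h$bitscore)
  h <- h[ord, , drop = FALSE]
  key <- paste(h$query, h$subject, sep = "\r")
  h <- h[!duplicated(key), , drop = FALSE]
  rownames(h) <- NULL
  new("HitTable", hits = h, threshold = threshold)
}

#' Write a HitTable in 12-column tabular layout
#'
#' @param ht a [HitTable-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeHits <- function(ht, path) {
  stopifnot(is(ht, "HitTable"))
  h <- ht@hits[order(ht@hits$query, ht@hits$subject), , drop = FALSE]
  utils::write.table(h, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
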