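#' Extract conserved blocks from a protein MSA
#'
#' Column-classification block extraction in the classic conserved-block
#' style, controlled by four parameters over an alignment of n rows:
#'
#' * `b1` — minimum rows sharing the majority residue for a column to be
#'   *conserved* (must exceed n/2; default `floor(n/2) + 1`).
#' * `b2` — minimum for *highly conserved* (default
#'   `max(b1, ceiling(0.85 n))`).
#' * `b3` — longest tolerated stretch of contiguous nonconserved columns
#'   (default 8); longer stretches are rejected and break blocks.
#' * `b4` — minimum retained columns per block (default 10).
#'
#' Procedure: each column's majority residue is the most frequent non-gap
#' residue (ties by alphabetical residue); columns with majority count
#' below `b1` are nonconserved. Under the default `gapPolicy = "none"`,
#' any column containing a gap is nonconserved and can never be retained;
#' `"half"` only forces columns with gaps in more than half the rows;
#' `"all"` ignores gaps. Runs of more than `b3` contiguous nonconserved
#' columns are rejected; the remaining candidate segments are trimmed from
#' both ends until flanked by highly conserved columns; blocks retaining
#' fewer than `b4` columns are dropped.
#'
#' @param aln equal-width [Biostrings::AAStringSet] (>= 2 rows).
#' @param b1,b2,b3,b4 rule parameters, see above.
#' @param gapPolicy `"none"` (default), `"half"`, or `"all"`.
#' @param rowInfo optional [S4Vectors::DataFrame] with `gene_id`,
#'   `species` per row; derived from pipe-delimited names when absent.
#' @return a [BlockedAlignment-class].
#' @export
extractBlocks <- function(aln, b1 = NULL, b2 = NULL, b3 = 8L, b4 = 10L,
                          gapPolicy = c("none", "half", "all"),
                          rowInfo = NULL) {
  gapPolicy <- match.arg(gapPolicy)
  n <- length(aln)
  stopifnot(n >= 2)
  L <- unique(Biostrings::width(aln))
  stopifnot(length(L) == 1)
  if (is.null(b1)) b1 <- floor(n / 2) + 1L
  if (is.null(b2)) b2 <- max(b1, ceiling(0.85 * n))
  if (b1 <= n / 2) stop("b1 must exceed n/2")
  if (b2 < b1) stop("b2 must be >= b1")
  if (b3 < 1) stop("b3 must be >= 1")
  if (b4 < 2) stop("b4 must be >= 2")

  M <- do.call(rbind, strsplit(as.character(aln), ""))
  nGaps <- colSums(M == "-")
  majCount <- integer(L)
  for (j in seq_len(L)) {
    col <- M[, j]
    col <- col[col != "-"]
    if (!length(col)) { majCount[j] <- 0L; next }
    tab <- table(col)
    # ties by alphabetical residue: table() is already alphabetical, max
    # count taken directly (the residue identity only affects records)
    majCount[j] <- max(tab)
  }
  excluded <- switch(gapPolicy,
    none = nGaps > 0L,
    half = nGaps > n / 2,
    all = rep(FALSE, L))
  status <- ifelse(excluded | majCount < b1, "nonconserved",
                   ifelse(majCount < b2, "conserved", "highly"))

  nc <- status == "nonconserved"
  rejected <- logical(L)
  r <- rle(nc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths))
    if (r$values[k] && r$lengths[k] > b3)
      rejected[starts[k]:ends[k]] <- TRUE

  keepable <- !rejected
  blocksStart <- integer(0); blocksEnd <- integer(0)
  retained <- integer(0)
  r2 <- rle(keepable)
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  for (k in seq_along(r2$lengths)) {
    if (!r2$values[k]) next
    s <- starts2[k]; e <- ends2[k]
    while (s <= e && status[s] != "highly") s <- s + 1L
    while (e >= s && status[e] != "highly") e <- e - 1L
    if (s > e) next
    cols <- s:e
    cols <- cols[!excluded[cols]]
    if (length(cols) < b4) next
    blocksStart <- c(blocksStart, s)
    blocksEnd <- c(blocksEnd, e)
    retained <- c(retained, cols)
  }

  if (is.null(rowInfo)) rowInfo <- rowInfoFromNames(names(aln))
  new("BlockedAlignment", alignment = aln, rowInfo = rowInfo,
      retained = as.integer(retained),
      blocks = IRanges::IRanges(start = blocksStart, end = blocksEnd),
      params = list(b1 = b1, b2 = b2, b3 = as.integer(b3),
                    b4 = as.integer(b4), gapPolicy = gapPolicy))
}

rowInfoFromNames <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  DataFrame(gene_id = ids,
            species = vapply(parts, `[`, character(1), 1))
}

#' Align selected groups and extract their common blocks
#'
#' For each selected ortholog group holding exactly one gene per analyzed
#' species, aligns the members ([progressiveMSA()], unless a precomputed
#' alignment is supplied) and extracts conserved blocks on the full
#' alignment — so every species pair is subsequently compared on the same
#' retained columns. Groups missing a species are dropped with a message
#' and reported in the `dropped` attribute.
#'
#' @param pset isoform-filtered [ProteomeSet-class].
#' @param ogs [OrthologGroupSet-class].
#' @param groupIds groups to process (e.g. from [selectSingleCopy()]).
#' @param species the analyzed species (default: the whole universe).
#' @param alignments optional named list of precomputed equal-width
#'   [Biostrings::AAStringSet] alignments (names = group ids); these take
#'   precedence over the built-in aligner.
#' @param ... block parameters passed to [extractBlocks()].
#' @return named list of [BlockedAlignment-class], with attribute
#'   `dropped` (character vector of skipped group ids).
#' @export
commonBlocks <- function(pset, ogs, groupIds, species = NULL,
                         alignments = NULL, ...) {
  stopifnot(is(pset, "ProteomeSet"), is(ogs, "OrthologGroupSet"))
  if (is.null(species)) species <- ogs@speciesUniverse
  m <- ogs@membership
  out <- list()
  dropped <- character(0)
  for (g in sort(groupIds)) {
    mem <- m[m$group_id == g & m$species %in% species, , drop = FALSE]
    if (!setequal(unique(mem$species), species) ||
        nrow(mem) != length(species) ||
        !all(mem$gene_id %in% names(pset@sequences))) {
      dropped <- c(dropped, g)
      next
    }
    mem <- mem[order(mem$species), ]
    aln <- if (!is.null(alignments) && g %in% names(alignments)) {
      alignments[[g]]
    } else {
      progressiveMSA(pset@sequences[mem$gene_id])
    }
    out[[g]] <- extractBlocks(
      aln, ...,
      rowInfo = DataFrame(gene_id = mem$gene_id, species = mem$species))
  }
  if (length(dropped))
    message(length(dropped), " group(s) dropped for missing species: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  attr(out, "dropped") <- dropped
  out
}

#' Concatenate retained blocks into a supermatrix
#'
#' Concatenates the retained columns of each group's alignment, one row
#' per species, in deterministic lexicographic group-id order, recording
#' per-group partition offsets. Groups with an empty retained set
#' contribute zero columns but still get a (width-0) partition.
#'
#' @param blockedList named list of [BlockedAlignment-class] (one row per
#'   species each, identical species sets).
#' @return a [Supermatrix-class].
#' @export
concatenateBlocks <- function(blockedList) {
  stopifnot(length(blockedList) >= 1, !is.null(names(blockedList)))
  ord <- order(names(blockedList))
  blockedList <- blockedList[ord]
  spRef <- sort(as.character(blockedList[[1]]@rowInfo$species))
  pieces <- stats::setNames(
    rep(list(character(0)), length(spRef)), spRef)
  starts <- integer(0); widths <- integer(0)
  pos <- 0L
  for (g in names(blockedList)) {
    ba <- blockedList[[g]]
    sp <- as.character(ba@rowInfo$species)
    if (!setequal(sp, spRef))
      stop("group ", g, " has a different species set")
    rows <- as.character(ba@alignment)
    names(rows) <- sp
    w <- length(ba@retained)
    for (s in spRef) {
      piece <- if (w) paste(strsplit(rows[[s]], "")[[1]][ba@retained],
                            collapse = "") else ""
      pieces[[s]] <- c(pieces[[s]], piece)
    }
    starts <- c(starts, pos + 1L)
    widths <- c(widths, w)
    pos <- pos + w
  }
  seqs <- Biostrings::AAStringSet(
    vapply(pieces, paste, character(1), collapse = ""))
  names(seqs) <- spRef
  new("Supermatrix", sequences = seqs,
      partitions = IRanges::IRanges(start = starts, width = widths,
                                    names = names(blockedList)))
}

#' Write retained blocks report
#'
#' Tab-separated, one row per block: group, block start, block end
#' (0-based, half-open on original alignment columns), retained column
#' count.
#'
#' @param blockedList named list of [BlockedAlignment-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeBlocksReport <- function(blockedList, path) {
  rows <- list()
  for (g in sort(names(blockedList))) {
    ba <- blockedList[[g]]
    bl <- ba@blocks
    if (!length(bl)) next
    inBlock <- vapply(seq_along(bl), function(k)
      sum(ba@retained >= IRanges::start(bl)[k] &
          ba@retained <= IRanges::end(bl)[k]), integer(1))
    rows[[g]] <- data.frame(
      group_id = g,
      block_start0 = IRanges::start(bl) - 1L,
      block_end0 = IRanges::end(bl), # half-open
      retained = inBlock, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = character(), block_start0 = integer(),
               block_end0 = integer(), retained = integer())
  rownames(df) <- NULL
  writeTsv(df, path)
}
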