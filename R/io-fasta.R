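#' Read per-species protein FASTA files into a ProteomeSet
#'
#' Each file holds one proteome; the species label is taken from the file
#' name (without extension) unless `species` is supplied. Headers are
#' truncated at the first whitespace. A trailing pipe-delimited field
#' matching `iso<k>` marks a splice isoform of the gene named by the
#' preceding fields (see [ProteomeSet-class] for the dialect). CRLF input
#' is handled transparently.
#'
#' @param paths character vector of FASTA paths.
#' @param species optional species labels, parallel to `paths`.
#' @param strict when TRUE (default) duplicate record ids and letters
#'   outside the canonical alphabet plus `X` are errors; when FALSE
#'   duplicates are deduplicated with a numeric suffix and a message.
#' @return a [ProteomeSet-class].
#' @export
readProteomes <- function(paths, species = NULL, strict = TRUE) {
  if (is.null(species))
    species <- sub("\\.(fa|faa|fasta)$", "", basename(paths))
  stopifnot(length(paths) == length(species))
  seqs <- list(); info <- list()
  for (i in seq_along(paths)) {
    ss <- Biostrings::readAAStringSet(paths[i])
    if (!length(ss)) stop("no records in ", paths[i])
    ids <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(ids)) {
      if (strict)
        stop("duplicate record id '", ids[duplicated(ids)][1], "' in ",
             paths[i])
      message("deduplicating ", sum(duplicated(ids)), " record ids in ",
              paths[i])
      ids <- make.unique(ids, sep = "_dup")
    }
    names(ss) <- ids
    checkProteinAlphabet(ss, paths[i], strict = strict)
    parts <- strsplit(ids, "|", fixed = TRUE)
    last <- vapply(parts, function(p) p[length(p)], character(1))
    isIso <- grepl("^iso[0-9]+$", last) & lengths(parts) > 1L
    gene <- ifelse(isIso,
                   vapply(parts, function(p)
                     paste(p[-length(p)], collapse = "|"), character(1)),
                   ids)
    seqs[[i]] <- ss
    info[[i]] <- data.frame(seq_id = ids, gene_id = gene,
                            species = species[i],
                            isoform = ifelse(isIso, last, NA_character_),
                            family = NA_character_,
                            stringsAsFactors = FALSE)
  }
  gi <- do.call(rbind, info)
  new("ProteomeSet", sequences = do.call(c, seqs), geneInfo = DataFrame(gi))
}

checkProteinAlphabet <- function(ss, label, strict = TRUE) {
  freq <- Biostrings::alphabetFrequency(ss)
  allowed <- c(AA20_VEC, "X")
  bad <- setdiff(colnames(freq)[colSums(freq) > 0], allowed)
  if (length(bad)) {
    msg <- paste0("letters outside the protein alphabet in ", label, ": ",
                  paste(bad, collapse = ""))
    if (strict) stop(msg) else message(msg)
  }
  nX <- sum(freq[, "X"])
  if (nX > 0) message(label, ": ", nX, " ambiguous 'X' residues")
  invisible(TRUE)
}

#' Write a ProteomeSet as per-species FASTA files
#'
#' @param pset a [ProteomeSet-class].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeProteomes <- function(pset, dir) {
  stopifnot(is(pset, "ProteomeSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (sp in speciesNames(pset)) {
    p <- file.path(dir, paste0(sp, ".faa"))
    Biostrings::writeXStringSet(proteome(pset, sp), p, width = 60L)
    paths <- c(paths, p)
  }
  invisible(paths)
}
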