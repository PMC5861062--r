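#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Multi-species protein sequence set
#'
#' Container for one or more proteomes: an [Biostrings::AAStringSet] of
#' protein sequences together with a per-sequence table of gene metadata
#' (gene identifier, species, optional isoform tag and ground-truth family).
#'
#' Sequence names follow a pipe-delimited dialect: a plain identifier, or
#' `<gene_id>|iso<k>` when a record is one splice isoform of gene
#' `<gene_id>`. Simulated genes use `<species>|<family>|g<k>` as the gene
#' identifier (the whole string; the trailing field never matches `iso<k>`).
#'
#' @slot sequences [Biostrings::AAStringSet] of protein sequences, named by
#'   the full record identifier.
#' @slot geneInfo [S4Vectors::DataFrame] with one row per sequence and
#'   columns `seq_id`, `gene_id`, `species`, `isoform` (NA when the record
#'   is not isoform-tagged) and `family` (NA when unknown).
#' @seealso [readProteomes()], [filterLongestIsoform()]
#' @export
setClass("ProteomeSet",
  slots = c(sequences = "AAStringSet", geneInfo = "DataFrame"))

setValidity("ProteomeSet", function(object) {
  gi <- object@geneInfo
  need <- c("seq_id", "gene_id", "species", "isoform", "family")
  if (!all(need %in% colnames(gi)))
    return(paste("geneInfo must have columns", paste(need, collapse = ", ")))
  if (length(object@sequences) != nrow(gi))
    return("sequences and geneInfo disagree in length")
  if (length(object@sequences) &&
      !identical(names(object@sequences), as.character(gi$seq_id)))
    return("names(sequences) must equal geneInfo$seq_id")
  if (anyDuplicated(names(object@sequences)))
    return("duplicate sequence identifiers")
  TRUE
})

#' Thresholded table of pairwise similarity hits
#'
#' Directed pairwise similarity records in the 12-column tabular hit layout
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, E-value, bit score), with the E-value
#' threshold that was applied. At most one row is stored per ordered
#' (query, subject) pair — the best by E-value, ties broken by bit score —
#' and self-hits are excluded.
#'
#' @slot hits data.frame with the 12 standard columns.
#' @slot threshold numeric E-value threshold; all stored hits satisfy
#'   `evalue < threshold`.
#' @seealso [allAgainstAll()], [readHits()]
#' @export
setClass("HitTable",
  slots = c(hits = "data.frame", threshold = "numeric"))

setValidity("HitTable", function(object) {
  h <- object@hits
  if (!all(HIT_COLUMNS %in% colnames(h)))
    return(paste("hits must have columns", paste(HIT_COLUMNS, collapse = ", ")))
  if (length(object@threshold) != 1L || object@threshold <= 0)
    return("threshold must be a single positive number")
  if (nrow(h)) {
    if (any(h$evalue <= 0)) return("E-values must be > 0")
    if (any(h$evalue >= object@threshold))
      return("all stored hits must satisfy evalue < threshold")
    if (any(h$query == h$subject)) return("self-hits are not allowed")
    if (anyDuplicated(paste(h$query, h$subject, sep = "\r")))
      return("at most one hit per ordered (query, subject) pair")
  }
  TRUE
})

#' Ortholog groups from Markov clustering
#'
#' A partition of genes into ortholog groups over a declared species
#' universe, with optional per-group category labels (assigned by
#' [classifyGroups()]) and the lineage subset used by the
#' lineage-restricted category rule.
#'
#' @slot membership data.frame with columns `group_id`, `gene_id`,
#'   `species`; every clustered gene appears exactly once.
#' @slot speciesUniverse character vector of all analyzed species.
#' @slot lineage character vector, subset of the species universe.
#' @slot labels named character vector of category labels per group
#'   (possibly NA before classification).
#' @slot converged logical; FALSE when Markov clustering hit its iteration
#'   cap before the matrix stabilised.
#' @seealso [mclCluster()], [classifyGroups()], [categoryCounts()]
#' @export
setClass("OrthologGroupSet",
  slots = c(membership = "data.frame", speciesUniverse = "character",
            lineage = "character", labels = "character",
            converged = "logical"))

setValidity("OrthologGroupSet", function(object) {
  m <- object@membership
  if (!all(c("group_id", "gene_id", "species") %in% colnames(m)))
    return("membership needs columns group_id, gene_id, species")
  if (anyDuplicated(m$gene_id))
    return("groups must partition the gene set (duplicate gene_id)")
  if (!all(m$species %in% object@speciesUniverse))
    return("membership species outside the species universe")
  if (!all(object@lineage %in% object@speciesUniverse))
    return("lineage must be a subset of the species universe")
  if (length(object@labels) &&
      !all(names(object@labels) %in% unique(m$group_id)))
    return("labels named by unknown group ids")
  TRUE
})

#' Protein MSA with retained conserved-block columns
#'
#' A multiple sequence alignment plus the ordered set of alignment columns
#' retained by conserved-block extraction, the block extents on the
#' original coordinate system, and the parameters used.
#'
#' Retained columns are stored 1-based (R convention); tabular reports are
#' written 0-based, half-open.
#'
#' @slot alignment [Biostrings::AAStringSet], all rows of equal width,
#'   gap character `-`.
#' @slot rowInfo [S4Vectors::DataFrame] with columns `gene_id`, `species`.
#' @slot retained integer vector of retained columns, strictly increasing.
#' @slot blocks [IRanges::IRanges] of block extents on original columns.
#' @slot params list of extraction parameters (b1, b2, b3, b4, gapPolicy).
#' @seealso [extractBlocks()], [concatenateBlocks()]
#' @export
setClass("BlockedAlignment",
  slots = c(alignment = "AAStringSet", rowInfo = "DataFrame",
            retained = "integer", blocks = "ANY", params = "list"))

setValidity("BlockedAlignment", function(object) {
  w <- unique(Biostrings::width(object@alignment))
  if (length(w) > 1) return("alignment rows differ in length")
  r <- object@retained
  if (length(r)) {
    if (is.unsorted(r, strictly = TRUE)) return("retained not strictly increasing")
    if (min(r) < 1L || max(r) > w) return("retained columns out of range")
  }
  if (nrow(object@rowInfo) != length(object@alignment))
    return("rowInfo and alignment disagree in length")
  TRUE
})

#' Concatenated single-copy supermatrix
#'
#' Species-indexed concatenation of the retained block columns of many
#' single-copy ortholog groups, with per-group partition offsets.
#'
#' @slot sequences [Biostrings::AAStringSet] named by species, all of equal
#'   width equal to the total retained length.
#' @slot partitions [IRanges::IRanges] named by group id, giving each
#'   group's column extent in the supermatrix (1-based).
#' @seealso [concatenateBlocks()], [pDistances()], [bootstrapTree()]
#' @export
setClass("Supermatrix",
  slots = c(sequences = "AAStringSet", partitions = "ANY"))

setValidity("Supermatrix", function(object) {
  w <- unique(Biostrings::width(object@sequences))
  if (length(w) > 1) return("supermatrix rows differ in length")
  total <- sum(IRanges::width(object@partitions))
  if (length(w) == 1 && w != total)
    return("supermatrix width must equal the sum of partition widths")
  TRUE
})

#' Ground-truthed synthetic proteome set
#'
#' Output of the proteome evolution simulator: the species tree, the family
#' specifications (category and per-species copy number), every emitted
#' gene with its sequence, and the simulation parameters.
#'
#' @slot tree species tree (`phylo`), branch lengths in expected
#'   replacements per site.
#' @slot families data.frame with columns `family_id`, `category`.
#' @slot copyNumber integer matrix, families x species.
#' @slot sequences [Biostrings::AAStringSet] of all simulated genes, named
#'   `<species>|<family>|g<k>`.
#' @slot geneInfo [S4Vectors::DataFrame] with columns `gene_id`, `species`,
#'   `family_id`, `category`.
#' @slot params list: `rootLength`, `pi` (named 20-vector), `seed`.
#' @seealso [simulateProteomes()], [writeTruthSet()]
#' @export
setClass("TruthSet",
  slots = c(tree = "ANY", families = "data.frame", copyNumber = "matrix",
            sequences = "AAStringSet", geneInfo = "DataFrame",
            params = "list"))

setValidity("TruthSet", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  if (!setequal(colnames(object@copyNumber), object@tree$tip.label))
    return("copyNumber columns must match tree tips")
  if (anyDuplicated(object@geneInfo$gene_id)) return("duplicate gene ids")
  bad <- !as.character(object@geneInfo$family_id) %in% object@families$family_id
  if (any(bad)) return("gene assigned to unknown family")
  letters_ok <- all(Biostrings::alphabetFrequency(object@sequences)[,
    setdiff(colnames(Biostrings::alphabetFrequency(object@sequences)),
            strsplit(AA20, "")[[1]]), drop = FALSE] == 0)
  if (!letters_ok) return("sequences contain non-canonical letters")
  TRUE
})
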