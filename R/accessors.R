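#' @rdname ProteomeSet-class
#' @param object,x a `ProteomeSet` (or other package object, per method)
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname ProteomeSet-class
#' @export
setMethod("geneInfo", "ProteomeSet", function(x) x@geneInfo)

#' @rdname ProteomeSet-class
#' @export
setGeneric("aaSequences", function(x) standardGeneric("aaSequences"))

#' @rdname ProteomeSet-class
#' @export
setMethod("aaSequences", "ProteomeSet", function(x) x@sequences)

#' @rdname ProteomeSet-class
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname ProteomeSet-class
#' @export
setMethod("speciesNames", "ProteomeSet",
          function(x) sort(unique(as.character(x@geneInfo$species))))

#' @rdname ProteomeSet-class
#' @param species single species label
#' @export
proteome <- function(x, species) {
  stopifnot(is(x, "ProteomeSet"))
  x@sequences[as.character(x@geneInfo$species) == species]
}

setMethod("show", "ProteomeSet", function(object) {
  sp <- speciesNames(object)
  cat("ProteomeSet:", length(object@sequences), "sequences,",
      length(unique(object@geneInfo$gene_id)), "genes,",
      length(sp), "species\n")
  cat("  species:", paste(sp, collapse = ", "), "\n")
})

#' @rdname HitTable-class
#' @param x a `HitTable`
#' @export
hits <- function(x) { stopifnot(is(x, "HitTable")); x@hits }

#' @rdname HitTable-class
#' @export
evalueThreshold <- function(x) { stopifnot(is(x, "HitTable")); x@threshold }

setMethod("show", "HitTable", function(object) {
  cat("HitTable:", nrow(object@hits), "hits at E <",
      format(object@threshold), "\n")
})

#' @rdname OrthologGroupSet-class
#' @param x an `OrthologGroupSet`
#' @export
groupMembership <- function(x) { stopifnot(is(x, "OrthologGroupSet")); x@membership }

#' @rdname OrthologGroupSet-class
#' @export
groupLabels <- function(x) { stopifnot(is(x, "OrthologGroupSet")); x@labels }

#' @rdname OrthologGroupSet-class
#' @export
speciesUniverse <- function(x) { stopifnot(is(x, "OrthologGroupSet")); x@speciesUniverse }

#' Per-group, per-species copy-count matrix
#'
#' Tallies group members per species over the declared species universe.
#'
#' @param x an `OrthologGroupSet`
#' @return integer matrix, groups x species (all species of the universe).
#' @export
copyNumberMatrix <- function(x) {
  stopifnot(is(x, "OrthologGroupSet"))
  m <- x@membership
  tab <- table(factor(m$group_id, levels = sort(unique(m$group_id))),
               factor(m$species, levels = x@speciesUniverse))
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  mat
}

setMethod("show", "OrthologGroupSet", function(object) {
  ng <- length(unique(object@membership$group_id))
  cat("OrthologGroupSet:", ng, "groups over",
      nrow(object@membership), "genes,",
      length(object@speciesUniverse), "species\n")
  if (length(object@labels) && !all(is.na(object@labels))) {
    tab <- table(object@labels)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!object@converged)
    cat("  warning: Markov clustering did not converge\n")
})

#' @rdname BlockedAlignment-class
#' @param x a `BlockedAlignment`
#' @export
retainedColumns <- function(x) { stopifnot(is(x, "BlockedAlignment")); x@retained }

#' @rdname BlockedAlignment-class
#' @export
blockRanges <- function(x) { stopifnot(is(x, "BlockedAlignment")); x@blocks }

#' @rdname BlockedAlignment-class
#' @export
alignedSequences <- function(x) { stopifnot(is(x, "BlockedAlignment")); x@alignment }

#' @rdname BlockedAlignment-class
#' @export
alignmentRowInfo <- function(x) { stopifnot(is(x, "BlockedAlignment")); x@rowInfo }

setMethod("show", "BlockedAlignment", function(object) {
  cat("BlockedAlignment:", length(object@alignment), "rows x",
      if (length(object@alignment)) Biostrings::width(object@alignment)[1] else 0,
      "columns;", length(object@retained), "retained in",
      length(object@blocks), "blocks\n")
})

#' @rdname Supermatrix-class
#' @param x a `Supermatrix`
#' @export
supermatrixSequences <- function(x) { stopifnot(is(x, "Supermatrix")); x@sequences }

#' @rdname Supermatrix-class
#' @export
partitionRanges <- function(x) { stopifnot(is(x, "Supermatrix")); x@partitions }

setMethod("show", "Supermatrix", function(object) {
  cat("Supermatrix:", length(object@sequences), "species x",
      if (length(object@sequences)) Biostrings::width(object@sequences)[1] else 0,
      "columns in", length(object@partitions), "partitions\n")
})

#' @rdname TruthSet-class
#' @param x a `TruthSet`
#' @export
truthGenes <- function(x) { stopifnot(is(x, "TruthSet")); x@geneInfo }

#' @rdname TruthSet-class
#' @export
truthFamilies <- function(x) { stopifnot(is(x, "TruthSet")); x@families }

#' @rdname TruthSet-class
#' @export
truthCopyNumber <- function(x) { stopifnot(is(x, "TruthSet")); x@copyNumber }

#' @rdname TruthSet-class
#' @export
setMethod("aaSequences", "TruthSet", function(x) x@sequences)

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@families), "families,",
      length(object@sequences), "genes,",
      length(object@tree$tip.label), "species\n")
  tab <- table(object@families$category)
  cat("  categories:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})
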