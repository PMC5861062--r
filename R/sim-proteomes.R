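#' Parse and validate a species tree in newick format
#'
#' Reads a rooted species tree with mandatory branch lengths and validates
#' it for use by the simulator: unique leaf labels, non-negative branch
#' lengths, at least three leaves. Light lexical checks run before parsing
#' so that malformed input is rejected with the offending character
#' position.
#'
#' @param text newick string, or a path to a file containing one tree.
#' @return an [ape::read.tree()] `phylo` object.
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parseNewick <- function(text) {
  if (length(text) == 1 && !grepl(";", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "")
  stopifnot(is.character(text), length(text) == 1)

  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' at end of input")
  if (!grepl(";", text))
    stop("malformed newick: missing terminating ';' at position ",
         nchar(text))

  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL)
  if (is.null(tree))
    stop("malformed newick: not parseable as a tree")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("malformed newick: branch lengths are mandatory on every edge")
  if (anyNA(tree$edge.length))
    stop("malformed newick: missing branch length")
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    stop("negative branch length ", tree$edge.length[bad],
         " on edge ", bad)
  }
  if (anyDuplicated(tree$tip.label)) {
    d <- tree$tip.label[duplicated(tree$tip.label)][1]
    stop("duplicate leaf label '", d, "'")
  }
  if (length(tree$tip.label) < 3)
    stop("species tree must have at least 3 leaves")
  tree
}

#' Write a tree in newick format
#'
#' @param tree a `phylo` object.
#' @param file optional output path; when NULL the newick string is
#'   returned.
#' @return the newick string, invisibly when written to file.
#' @export
writeNewick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

# path distance between two leaves, in expected replacements per site
leafPathDistance <- function(tree, a, b) {
  d <- ape::cophenetic.phylo(tree)
  d[a, b]
}

#' Sample gene-family specifications from a category mixture
#'
#' Draws `nFamilies` family specifications whose per-species copy-count
#' vectors realise a declared mixture of orthology categories (universal
#' single-copy, universal multi-copy, lineage-only, species-specific,
#' present-at-half, patchy). Every generated copy-count vector is checked
#' against [classifyCopyNumber()]; generation fails rather than emit a
#' family that the category rules would label differently.
#'
#' `homology-only` cannot be requested: it is a property of downstream
#' clustering (a gene with hits but no group), not of a family's copy
#' structure.
#'
#' @param tree species tree (`phylo`); tips define the species universe.
#' @param proportions named numeric vector of category proportions, summing
#'   to 1 (tolerance 1e-9).
#' @param nFamilies number of families to draw.
#' @param lineage character vector of lineage species (needed by the
#'   lineage-only category; must have >= 3 members to realise it).
#' @param maxCopies largest per-species copy count for duplicated
#'   categories (default 3).
#' @param seed master seed; per-family substreams are derived by stable
#'   hashing of the family id, so family k is reproducible in isolation.
#' @return list with elements `families` (data.frame: family_id, category)
#'   and `copyNumber` (integer matrix, families x species).
#' @examples
#' tr <- parseNewick("((A:.1,B:.1):.1,(C:.1,D:.1):.1);")
#' fs <- sampleFamilies(tr, c("universal-single" = 1), 5,
#'                      lineage = c("A", "B"), seed = 1)
#' fs$copyNumber
#' @export
sampleFamilies <- function(tree, proportions, nFamilies,
                           lineage = character(), maxCopies = 3L,
                           seed = 1L) {
  stopifnot(nFamilies >= 1)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("category proportions must sum to 1")
  bad <- setdiff(names(proportions), setdiff(CATEGORIES, c("homology-only", "none")))
  if (length(bad))
    stop("unsupported category for generation: ", paste(bad, collapse = ", "))
  species <- sort(tree$tip.label)
  S <- length(species)
  lineage <- sort(lineage)
  if (!all(lineage %in% species))
    stop("lineage must be a subset of the tree's species")
  if ("lineage-only" %in% names(proportions) &&
      proportions[["lineage-only"]] > 0 && length(lineage) < 3)
    stop("lineage-only families need a lineage of >= 3 species")

  ids <- sprintf("F%04d", seq_len(nFamilies))
  cats <- withSeed(substreamSeed(seed, "family-categories"),
    sample(names(proportions), nFamilies, replace = TRUE, prob = proportions))

  cn <- matrix(0L, nFamilies, S, dimnames = list(ids, species))
  for (k in seq_len(nFamilies)) {
    cn[k, ] <- withSeed(substreamSeed(seed, ids[k]),
      drawCopyNumber(cats[k], species, lineage, maxCopies))
    got <- classifyCopyNumber(cn[k, ], species, lineage)
    if (got != cats[k])
      stop("internal error: generated family classifies as ", got,
           " instead of ", cats[k])
  }
  list(families = data.frame(family_id = ids, category = cats,
                             stringsAsFactors = FALSE),
       copyNumber = cn)
}

# one copy-count vector realising a category (called inside a substream)
drawCopyNumber <- function(category, species, lineage, maxCopies) {
  S <- length(species)
  cn <- stats::setNames(integer(S), species)
  half <- ceiling(S / 2)
  switch(category,
    "universal-single" = { cn[] <- 1L },
    "universal-multi" = {
      cn[] <- 1L
      dup <- sample(species, 2L)
      cn[dup] <- cn[dup] + sample(seq_len(maxCopies - 1L), 2L, replace = TRUE)
    },
    "species-specific" = {
      # at least two copies, so the family is recoverable as a cluster
      # (a lone gene with no homologs can never form a group downstream)
      cn[sample(species, 1L)] <- if (maxCopies > 2L)
        sample(2:maxCopies, 1L) else 2L
    },
    "lineage-only" = {
      k <- if (length(lineage) == 3L) 3L else sample(3:length(lineage), 1L)
      if (S - length(lineage) < 2L && k >= S - 1L)
        stop("lineage-only not realisable: family would be universal")
      cn[sample(lineage, k)] <- 1L
    },
    "present-at-half" = {
      if (half > S - 2L)
        stop("present-at-half not realisable for ", S, " species")
      k <- if (half == S - 2L) half else sample(half:(S - 2L), 1L)
      outside <- setdiff(species, lineage)
      # at least one non-lineage species so the lineage-only rule cannot
      # fire; fill the rest uniformly
      first <- if (length(outside)) sample(outside, 1L) else character()
      rest <- sample(setdiff(species, first), k - length(first))
      cn[c(first, rest)] <- 1L
    },
    "patchy" = {
      if (half <= 2L)
        stop("patchy not realisable for ", S, " species (any 2-species ",
             "presence already reaches half)")
      k <- if (half - 1L == 2L) 2L else sample(2:(half - 1L), 1L)
      outside <- setdiff(species, lineage)
      # avoid the lineage-only rule: include a non-lineage species when the
      # pattern would otherwise sit inside the lineage with >= 3 members
      first <- if (length(outside) && k >= 3L) sample(outside, 1L) else character()
      rest <- sample(setdiff(species, first), k - length(first))
      cn[c(first, rest)] <- 1L
    },
    stop("unsupported category: ", category)
  )
  cn
}

# apply the Poisson replacement model along one branch: each site is hit by
# >= 1 event with probability 1 - exp(-d); a hit site is redrawn from pi
# (possibly to the same residue)
mutateSequence <- function(seq, d, pi) {
  if (d == 0) return(seq)
  hit <- stats::runif(length(seq)) < (1 - exp(-d))
  if (any(hit))
    seq[hit] <- sample(AA20_VEC, sum(hit), replace = TRUE, prob = pi)
  seq
}

#' Evolve one gene family along a species tree
#'
#' Simulates protein sequences for a single family under the stationary
#' Poisson replacement model: along a branch of length d (expected
#' replacements per site) each site is hit by at least one event with
#' probability 1 - exp(-d), and a hit site is redrawn from the stationary
#' amino-acid frequencies `pi` (possibly unchanged). Under this model two
#' sequences at path distance D match at a site with probability
#' exp(-D) + (1 - exp(-D)) * sum(pi^2), which the test suite uses as a
#' closed-form oracle.
#'
#' Species with copy count c > 1 duplicate at the midpoint of their
#' terminal branch: the lineage evolves to the midpoint once, then c copies
#' evolve independently over the remaining half branch.
#'
#' @param tree species tree (`phylo`) with branch lengths.
#' @param familyId family identifier (used in gene ids and for the RNG
#'   substream).
#' @param copyNumber named integer vector of per-species copy counts
#'   (names = tip labels; absent species may be omitted or 0).
#' @param pi stationary amino-acid frequencies: named or unnamed 20-vector
#'   summing to 1, in alphabetical residue order when unnamed.
#' @param rootLength length of the root sequence (>= 1).
#' @param seed master seed (combined with the family id hash).
#' @return [Biostrings::AAStringSet] named `<species>|<family>|g<k>`.
#' @examples
#' tr <- parseNewick("((A:0,B:0):0,C:0);")
#' evolveFamily(tr, "F1", c(A = 1, B = 1, C = 1), rootLength = 10, seed = 1)
#' @export
evolveFamily <- function(tree, familyId, copyNumber,
                         pi = rep(1 / 20, 20), rootLength = 300L,
                         seed = 1L) {
  stopifnot(rootLength >= 1)
  pi <- validatePi(pi)
  species <- tree$tip.label
  copyNumber <- fullCopyVector(copyNumber, species)

  withSeed(substreamSeed(seed, paste0("evolve:", familyId)), {
    root <- sample(AA20_VEC, rootLength, replace = TRUE, prob = pi)
    tr <- ape::reorder.phylo(tree, "cladewise")
    nTips <- length(species)
    rootNode <- nTips + 1L
    states <- vector("list", nTips + tr$Nnode)
    states[[rootNode]] <- root
    out <- list()
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      d <- tr$edge.length[e]
      if (child > nTips) {
        states[[child]] <- mutateSequence(states[[parent]], d, pi)
      } else {
        sp <- species[child]
        c_k <- copyNumber[sp]
        if (c_k == 0L) next
        if (c_k == 1L) {
          out[[paste(sp, familyId, "g1", sep = "|")]] <-
            mutateSequence(states[[parent]], d, pi)
        } else {
          mid <- mutateSequence(states[[parent]], d / 2, pi)
          for (k in seq_len(c_k))
            out[[paste(sp, familyId, paste0("g", k), sep = "|")]] <-
              mutateSequence(mid, d / 2, pi)
        }
      }
    }
    Biostrings::AAStringSet(vapply(out, paste, character(1), collapse = ""))
  })
}

validatePi <- function(pi) {
  if (length(pi) != 20 || any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be a 20-vector of non-negative frequencies summing to 1")
  if (!is.null(names(pi))) pi <- pi[AA20_VEC]
  unname(pi)
}

fullCopyVector <- function(copyNumber, species) {
  cn <- stats::setNames(integer(length(species)), species)
  if (is.null(names(copyNumber))) {
    stopifnot(length(copyNumber) == length(species))
    names(copyNumber) <- species
  }
  extra <- setdiff(names(copyNumber), species)
  if (length(extra)) stop("copy counts for unknown species: ",
                          paste(extra, collapse = ", "))
  cn[names(copyNumber)] <- as.integer(copyNumber)
  if (any(cn < 0)) stop("copy counts must be non-negative")
  if (sum(cn) == 0) stop("at least one species must have a copy")
  cn
}

#' Simulate ground-truthed proteomes for a family set
#'
#' Runs [evolveFamily()] for every family of a [sampleFamilies()] draw and
#' assembles the result into a [TruthSet-class].
#'
#' @inheritParams evolveFamily
#' @param familySet result of [sampleFamilies()] (or a list with elements
#'   `families` and `copyNumber`).
#' @return a [TruthSet-class].
#' @export
simulateProteomes <- function(tree, familySet, pi = rep(1 / 20, 20),
                              rootLength = 300L, seed = 1L) {
  pi <- validatePi(pi)
  fams <- familySet$families
  cn <- familySet$copyNumber
  seqs <- list()
  info <- list()
  for (k in seq_len(nrow(fams))) {
    fid <- fams$family_id[k]
    ss <- evolveFamily(tree, fid, cn[fid, ], pi = pi,
                       rootLength = rootLength, seed = seed)
    seqs[[fid]] <- ss
    parts <- strsplit(names(ss), "|", fixed = TRUE)
    info[[fid]] <- data.frame(
      gene_id = names(ss),
      species = vapply(parts, `[`, character(1), 1),
      family_id = fid,
      category = fams$category[k],
      stringsAsFactors = FALSE)
  }
  allSeqs <- do.call(c, unname(seqs))
  gi <- do.call(rbind, info)
  rownames(gi) <- NULL
  new("TruthSet", tree = tree, families = fams, copyNumber = cn,
      sequences = allSeqs, geneInfo = DataFrame(gi),
      params = list(rootLength = as.integer(rootLength),
                    pi = stats::setNames(pi, AA20_VEC), seed = seed))
}

#' Write a simulated truth set to disk
#'
#' Writes one protein FASTA per species (60-column wrapped, headers
#' `<species>|<family>|g<k>`), a tab-separated truth table
#' (gene, species, family, category), the species tree in newick and the
#' simulation parameters in a key:value file. A species with zero copies
#' of every family still gets an (empty) FASTA only if it has genes;
#' absence is preserved.
#'
#' @param truth a [TruthSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeTruthSet <- function(truth, dir) {
  stopifnot(is(truth, "TruthSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gi <- as.data.frame(truth@geneInfo)
  paths <- character()
  for (sp in sort(unique(gi$species))) {
    p <- file.path(dir, paste0(sp, ".faa"))
    Biostrings::writeXStringSet(truth@sequences[gi$species == sp], p,
                                width = 60L)
    paths <- c(paths, p)
  }
  tt <- gi[order(gi$gene_id), c("gene_id", "species", "family_id", "category")]
  ttPath <- file.path(dir, "truth.tsv")
  writeTsv(tt, ttPath)
  nwk <- file.path(dir, "tree.nwk")
  writeNewick(truth@tree, nwk)
  par <- file.path(dir, "params.yaml")
  yaml::write_yaml(list(rootLength = truth@params$rootLength,
                        pi = as.list(truth@params$pi),
                        seed = truth@params$seed), par)
  invisible(c(paths, ttPath, nwk, par))
}

#' Read a written truth table back
#'
#' @param dir directory written by [writeTruthSet()].
#' @return data.frame with columns gene_id, species, family_id, category.
#' @export
readTruthTable <- function(dir) {
  readTsv(file.path(dir, "truth.tsv"))
}

#' Convert a truth set to a ProteomeSet
#'
#' Direct in-memory handoff from the simulator to the pipeline (no disk
#' round trip).
#'
#' @param truth a [TruthSet-class].
#' @return a [ProteomeSet-class].
#' @export
asProteomeSet <- function(truth) {
  stopifnot(is(truth, "TruthSet"))
  gi <- as.data.frame(truth@geneInfo)
  new("ProteomeSet", sequences = truth@sequences,
      geneInfo = DataFrame(seq_id = gi$gene_id, gene_id = gi$gene_id,
                           species = gi$species, isoform = NA_character_,
                           family = gi$family_id))
}
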