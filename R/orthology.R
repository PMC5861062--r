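#' Build the reciprocal-hit similarity graph
#'
#' Nodes are all genes of the proteome (isolated genes included); an
#' undirected edge joins genes u and v only when both directed hits u->v
#' and v->u passed the E-value threshold. The edge weight is the mean of
#' the two -log10 E-values, with each E floored at 1e-200 so weights are
#' capped at 200.
#'
#' @param ht a [HitTable-class].
#' @param pset the [ProteomeSet-class] the hits were computed from
#'   (supplies the node set and species labels).
#' @return an [igraph::graph] with vertex attributes `name` (gene id) and
#'   `species`, and edge attribute `weight`.
#' @export
buildSimilarityGraph <- function(ht, pset) {
  stopifnot(is(ht, "HitTable"), is(pset, "ProteomeSet"))
  gi <- as.data.frame(pset@geneInfo)
  ids <- sort(gi$gene_id)
  sp <- gi$species[match(ids, gi$gene_id)]
  h <- ht@hits
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "species", value = sp)
  if (!nrow(h)) return(g)
  unknown <- setdiff(unique(c(h$query, h$subject)), ids)
  if (length(unknown))
    stop("hits reference genes absent from the proteome: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  mlog <- pmin(-log10(pmax(h$evalue, 1e-200)), 200)
  a <- pmin(h$query, h$subject)
  b <- pmax(h$query, h$subject)
  key <- paste(a, b, sep = "\r")
  dirTag <- ifelse(h$query < h$subject, "f", "r")
  tab <- tapply(seq_len(nrow(h)), key, identity, simplify = FALSE)
  keep <- vapply(tab, function(idx) length(unique(dirTag[idx])) == 2L,
                 logical(1))
  recip <- tab[keep]
  if (!length(recip)) return(g)
  w <- vapply(recip, function(idx) min(mean(mlog[idx]), 200), numeric(1))
  pairKeys <- names(recip)
  ab <- strsplit(pairKeys, "\r", fixed = TRUE)
  ea <- vapply(ab, `[`, character(1), 1)
  eb <- vapply(ab, `[`, character(1), 2)
  ord <- order(ea, eb)
  edges <- rbind(ea, eb)[, ord, drop = FALSE]
  g <- igraph::add_edges(g, as.vector(edges), weight = unname(w[ord]))
  g
}

#' Markov clustering of the similarity graph into ortholog groups
#'
#' Runs MCL on each connected component of the weighted similarity graph:
#' self-loops are added at each node's maximum incident weight, columns are
#' normalised to a stochastic matrix, then expansion (matrix squaring) and
#' inflation (elementwise power + renormalisation) alternate, pruning
#' entries below `pruneEps`, until the matrix changes by less than 1e-8 or
#' `maxIter` is reached. Clusters are read off the attractor rows of the
#' limit matrix. The procedure is deterministic: nodes are processed in
#' sorted gene-id order.
#'
#' @param graph similarity graph from [buildSimilarityGraph()].
#' @param inflation inflation exponent, > 1 (default 1.5).
#' @param maxIter iteration cap (default 100); non-convergence is recorded
#'   on the result and warned about.
#' @param pruneEps entries below this are zeroed each iteration (default
#'   1e-5).
#' @param speciesUniverse,lineage species context recorded on the result;
#'   defaults to the graph's species.
#' @return an [OrthologGroupSet-class] partitioning all graph nodes; group
#'   ids are assigned in order of each cluster's smallest member gene id.
#' @export
mclCluster <- function(graph, inflation = 1.5, maxIter = 100L,
                       pruneEps = 1e-5, speciesUniverse = NULL,
                       lineage = character()) {
  stopifnot(inflation > 1)
  ids <- igraph::V(graph)$name
  sp <- igraph::V(graph)$species
  if (is.null(sp))
    sp <- rep(if (length(speciesUniverse)) speciesUniverse[1] else "unknown",
              length(ids))
  if (is.null(speciesUniverse)) speciesUniverse <- sort(unique(sp))
  comp <- igraph::components(graph)$membership
  clusters <- list()
  allConverged <- TRUE
  for (ci in sort(unique(comp))) {
    nodes <- which(comp == ci)
    nodes <- nodes[order(ids[nodes])]
    if (length(nodes) == 1L) {
      clusters[[length(clusters) + 1L]] <- ids[nodes]
      next
    }
    sub <- igraph::induced_subgraph(graph, nodes)
    A <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    ord <- order(rownames(A))
    A <- A[ord, ord, drop = FALSE]
    res <- withCallingHandlers(
      mclDenseTracked(A, inflation, maxIter, pruneEps),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!res$converged) allConverged <- FALSE
    for (cl in res$clusters)
      clusters[[length(clusters) + 1L]] <- rownames(A)[cl]
  }
  clusters <- clusters[order(vapply(clusters, min, character(1)))]
  gid <- sprintf("OG%05d", seq_along(clusters))
  membership <- data.frame(
    group_id = rep(gid, lengths(clusters)),
    gene_id = unlist(clusters),
    stringsAsFactors = FALSE)
  membership$species <- sp[match(membership$gene_id, ids)]
  if (!allConverged)
    warning("Markov clustering hit the iteration cap before convergence")
  new("OrthologGroupSet", membership = membership,
      speciesUniverse = speciesUniverse, lineage = sort(lineage),
      labels = stats::setNames(rep(NA_character_, length(gid)), gid),
      converged = allConverged)
}

mclDenseTracked <- function(A, inflation, maxIter, pruneEps) {
  n <- nrow(A)
  mx <- apply(A, 2, max)
  diag(A) <- ifelse(mx > 0, mx, 1)
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    Mexp <- M %*% M
    Minf <- Mexp^inflation
    Minf <- sweep(Minf, 2, colSums(Minf), "/")
    Minf[Minf < pruneEps] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Minf <- sweep(Minf, 2, cs, "/")
    if (max(abs(Minf - M)) < 1e-8) { M <- Minf; converged <- TRUE; break }
    M <- Minf
  }
  attrRows <- which(diag(M) > 0)
  if (!length(attrRows)) attrRows <- seq_len(n)
  covered <- integer(0)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in attrRows) {
    nodes <- union(which(M[r, ] > 0), r)
    covered <- union(covered, nodes)
    root <- findRoot(nodes[1])
    for (x in nodes[-1]) {
      rx <- findRoot(x)
      if (rx != root) parent[rx] <- root
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  clusters <- split(seq_len(n), roots)
  list(clusters = unname(lapply(clusters, sort)), converged = converged)
}

#' Classify a copy-count vector into an orthology category
#'
#' Applies the category rules over the declared species universe with a
#' fixed precedence: species-specific (all members in one species), then
#' universal single-copy (exactly one copy everywhere, tolerating absence
#' or duplication in at most one genome), then universal multi-copy
#' (presence in all but at most one genome), then lineage-only (presence
#' confined to the lineage subset, in at least three of its genomes), then
#' present-at-half (presence in at least ceiling(S/2) genomes), then
#' patchy.
#'
#' @param counts named integer vector of per-species copy counts, or
#'   unnamed parallel to `speciesUniverse`.
#' @param speciesUniverse all analyzed species (length S).
#' @param lineage lineage subset of the species universe.
#' @return a single category label.
#' @examples
#' sp <- paste0("s", 1:12)
#' classifyCopyNumber(setNames(c(0, rep(1, 11)), sp), sp, sp[1:4])
#' @export
classifyCopyNumber <- function(counts, speciesUniverse,
                               lineage = character()) {
  S <- length(speciesUniverse)
  if (!all(lineage %in% speciesUniverse))
    stop("lineage must be a subset of the species universe")
  cn <- stats::setNames(integer(S), speciesUniverse)
  if (is.null(names(counts))) {
    stopifnot(length(counts) == S)
    names(counts) <- speciesUniverse
  }
  cn[names(counts)] <- as.integer(counts)
  present <- names(cn)[cn > 0]
  nPresent <- length(present)
  if (nPresent == 0) return("none")
  if (nPresent == 1) return("species-specific")
  deviating <- sum(cn != 1L)
  if (deviating <= 1L) return("universal-single")
  if (nPresent >= S - 1L) return("universal-multi")
  if (length(lineage) && all(present %in% lineage) && nPresent >= 3L)
    return("lineage-only")
  if (nPresent >= ceiling(S / 2)) return("present-at-half")
  "patchy"
}

#' Label every ortholog group with its category
#'
#' Multi-gene groups are labelled by [classifyCopyNumber()]; single-gene
#' groups are left for [flagHomologyOnly()] (their label here is
#' `"species-specific"` only when they carry more than one gene in one
#' species, otherwise NA pending the homology check).
#'
#' @param ogs an [OrthologGroupSet-class].
#' @param lineage lineage subset; defaults to the one stored on the
#'   object.
#' @return the [OrthologGroupSet-class] with `labels` filled for all
#'   multi-gene groups.
#' @export
classifyGroups <- function(ogs, lineage = NULL) {
  stopifnot(is(ogs, "OrthologGroupSet"))
  if (!is.null(lineage)) ogs@lineage <- sort(lineage)
  cn <- copyNumberMatrix(ogs)
  sizes <- rowSums(cn)
  lab <- stats::setNames(rep(NA_character_, nrow(cn)), rownames(cn))
  multi <- rownames(cn)[sizes > 1L]
  for (g in multi)
    lab[g] <- classifyCopyNumber(cn[g, ], ogs@speciesUniverse, ogs@lineage)
  ogs@labels <- lab
  ogs
}

#' Flag unclustered genes with residual homology
#'
#' Genes that are not members of any multi-gene group but still have at
#' least one retained hit are `homology-only`; unclustered genes with no
#' hits at all are `none`.
#'
#' @param ogs an [OrthologGroupSet-class].
#' @param ht the [HitTable-class] used for clustering.
#' @return named character vector (`homology-only`/`none`) over all
#'   unclustered (singleton-group) genes.
#' @export
flagHomologyOnly <- function(ogs, ht) {
  stopifnot(is(ogs, "OrthologGroupSet"), is(ht, "HitTable"))
  m <- ogs@membership
  sizes <- table(m$group_id)
  singleGenes <- m$gene_id[m$group_id %in% names(sizes)[sizes == 1L]]
  withHits <- unique(c(ht@hits$query, ht@hits$subject))
  stats::setNames(
    ifelse(singleGenes %in% withHits, "homology-only", "none"),
    singleGenes)
}

#' Per-species gene counts by orthology category
#'
#' Tallies genes per species and category. Multi-gene groups use their
#' classified label; singleton-group genes are counted under
#' `homology-only` or `none` via [flagHomologyOnly()]. Row sums equal the
#' proteome sizes.
#'
#' @param ogs a classified [OrthologGroupSet-class] (see
#'   [classifyGroups()]).
#' @param ht the [HitTable-class] used for clustering.
#' @return integer matrix, species x category.
#' @export
categoryCounts <- function(ogs, ht) {
  stopifnot(is(ogs, "OrthologGroupSet"))
  m <- ogs@membership
  lab <- ogs@labels[m$group_id]
  single <- flagHomologyOnly(ogs, ht)
  idx <- match(m$gene_id, names(single))
  lab[!is.na(idx)] <- single[idx[!is.na(idx)]]
  if (anyNA(lab))
    stop("unlabelled group(s): run classifyGroups() first")
  tab <- table(factor(m$species, levels = ogs@speciesUniverse),
               factor(lab, levels = CATEGORIES))
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

#' Select single-copy ortholog groups
#'
#' Strict mode keeps groups with exactly one copy in every species of the
#' subset; tolerant mode applies the universal single-copy rule on the
#' subset (at most one genome may deviate by absence or duplication).
#' Copies outside the subset are ignored (projection).
#'
#' @param ogs an [OrthologGroupSet-class].
#' @param speciesSubset species to require (default: the whole universe).
#' @param strict logical (default TRUE).
#' @return character vector of selected group ids.
#' @export
selectSingleCopy <- function(ogs, speciesSubset = NULL, strict = TRUE) {
  stopifnot(is(ogs, "OrthologGroupSet"))
  if (is.null(speciesSubset)) speciesSubset <- ogs@speciesUniverse
  if (!length(speciesSubset)) stop("empty species subset")
  if (!all(speciesSubset %in% ogs@speciesUniverse))
    stop("subset outside the species universe")
  cn <- copyNumberMatrix(ogs)[, speciesSubset, drop = FALSE]
  if (strict) {
    keep <- rowSums(cn == 1L) == length(speciesSubset)
  } else {
    keep <- rowSums(cn != 1L) <= 1L & rowSums(cn > 0) >= 1L &
      rowSums(cn) > 1L
  }
  sort(rownames(cn)[keep])
}

#' Write ortholog groups as a three-column table
#'
#' Layout: `group_id <tab> species <tab> gene_id`, sorted by group, then
#' species, then gene.
#'
#' @param ogs an [OrthologGroupSet-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGroups <- function(ogs, path) {
  m <- ogs@membership[, c("group_id", "species", "gene_id")]
  m <- m[order(m$group_id, m$species, m$gene_id), ]
  writeTsv(m, path)
}
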