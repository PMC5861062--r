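#' Assemble a pipeline configuration
#'
#' Collects every stage parameter (with the package defaults) into a
#' validated list. The configuration is fully serialised into the run
#' manifest, and a single master seed drives named per-stage substreams,
#' so any stage can be re-run in isolation reproducibly.
#'
#' @param proteomes named character vector of FASTA paths (names =
#'   species), or NULL when `truth` is given.
#' @param truth optional [TruthSet-class] used directly as input.
#' @param species the species universe; default: all input species.
#' @param lineage lineage subset for the lineage-only category.
#' @param focal,pairA,pairB species of the three-way comparison; defaults
#'   to NULL (stage skipped unless all three are set).
#' @param evalueThreshold,searchMethod all-against-all settings.
#' @param inflation,pruneEps,maxIter Markov clustering settings.
#' @param strictSingleCopy selection mode for the supermatrix genes.
#' @param b1,b2,b3,b4,gapPolicy conserved-block settings (NULL = derived
#'   defaults, see [extractBlocks()]).
#' @param restrictBlocks compute identities on retained blocks (TRUE) or
#'   whole alignments.
#' @param tieEps,lowessFrac,lowessIters three-way comparison settings.
#' @param bootstrapReps bootstrap replicates.
#' @param seed master seed.
#' @return a validated config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(proteomes = NULL, truth = NULL, species = NULL,
                           lineage = character(), focal = NULL,
                           pairA = NULL, pairB = NULL,
                           evalueThreshold = 1e-5,
                           searchMethod = c("builtin", "blast"),
                           inflation = 1.5, pruneEps = 1e-5,
                           maxIter = 100L, strictSingleCopy = TRUE,
                           b1 = NULL, b2 = NULL, b3 = 8L, b4 = 10L,
                           gapPolicy = "none", restrictBlocks = TRUE,
                           tieEps = 0, lowessFrac = 2 / 3,
                           lowessIters = 3L, bootstrapReps = 100L,
                           seed = 1L) {
  searchMethod <- match.arg(searchMethod)
  if (is.null(proteomes) && is.null(truth))
    stop("either proteomes or truth must be supplied")
  cfg <- list(proteomes = proteomes, truth = truth, species = species,
              lineage = lineage, focal = focal, pairA = pairA,
              pairB = pairB, evalueThreshold = evalueThreshold,
              searchMethod = searchMethod, inflation = inflation,
              pruneEps = pruneEps, maxIter = maxIter,
              strictSingleCopy = strictSingleCopy,
              b1 = b1, b2 = b2, b3 = b3, b4 = b4, gapPolicy = gapPolicy,
              restrictBlocks = restrictBlocks, tieEps = tieEps,
              lowessFrac = lowessFrac, lowessIters = lowessIters,
              bootstrapReps = bootstrapReps, seed = seed)
  class(cfg) <- "pipelineConfig"
  cfg
}

validateConfig <- function(cfg, pset) {
  have <- speciesNames(pset)
  universe <- cfg$species %||% have
  missing <- setdiff(universe, have)
  if (length(missing))
    stop("config references species absent from inputs: ",
         paste(missing, collapse = ", "))
  if (!all(cfg$lineage %in% universe))
    stop("lineage outside the species universe")
  for (s in c(cfg$focal, cfg$pairA, cfg$pairB))
    if (!is.null(s) && !s %in% universe)
      stop("config references species absent from inputs: ", s)
  if (cfg$evalueThreshold <= 0) stop("evalueThreshold must be positive")
  if (cfg$inflation <= 1) stop("inflation must exceed 1")
  if (cfg$bootstrapReps < 1) stop("bootstrapReps must be >= 1")
  universe
}

#' Run the full comparative pipeline
#'
#' Executes the stages in order — isoform filter, all-against-all hits,
#' reciprocal similarity graph, Markov clustering, category
#' classification, single-copy selection, multiple alignment, conserved
#' blocks, block-restricted identity, three-way comparison with lowess,
#' supermatrix concatenation, NJ tree with bootstrap — writing every
#' artifact plus a JSON manifest (parameters, seed, input checksums,
#' per-stage in/out counts) into `outdir`. Tabular outputs are sorted on
#' documented keys, so identical configurations produce byte-identical
#' runs. Any stage error halts with the stage name, recorded in
#' `status.json`.
#'
#' @param cfg a [pipelineConfig()].
#' @param outdir run directory (created; must not contain a previous
#'   manifest).
#' @return invisibly, a list with the main in-memory results
#'   (`proteomes`, `hits`, `groups`, `categories`, `singleCopy`,
#'   `blocked`, `identity`, `comparison`, `supermatrix`, `tree`).
#' @export
runPipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- list(parameters = cfg[setdiff(names(cfg), c("truth"))],
                   stages = list())
  status <- list(state = "running", stage = NA_character_)
  writeStatus <- function() {
    jsonlite::write_json(status, file.path(outdir, "status.json"),
                         auto_unbox = TRUE, null = "null")
  }
  fail <- function(stage, e) {
    status$state <<- "failed"; status$stage <<- stage
    status$message <<- conditionMessage(e)
    writeStatus()
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) fail(name, e))
  }
  res <- list()

  # 01 input + isoform filter
  res$proteomes <- stage("proteomes", {
    pset <- if (!is.null(cfg$truth)) asProteomeSet(cfg$truth)
            else readProteomes(unname(cfg$proteomes), names(cfg$proteomes))
    universe <- validateConfig(cfg, pset)
    nIn <- length(pset@sequences)
    pset <- filterLongestIsoform(pset)
    manifest$stages$proteomes <- list(
      sequences_in = nIn, genes_kept = length(pset@sequences),
      isoforms_removed = nIn - length(pset@sequences),
      species = universe)
    if (!is.null(cfg$proteomes))
      manifest$input_checksums <- as.list(tools::md5sum(unname(cfg$proteomes)))
    writeProteomes(pset, file.path(outdir, "01_proteomes"))
    attr(pset, "universe") <- universe
    pset
  })
  universe <- attr(res$proteomes, "universe")

  # 02 all-against-all hits
  res$hits <- stage("hits", {
    ht <- allAgainstAll(res$proteomes, evalueThreshold = cfg$evalueThreshold,
                        method = cfg$searchMethod)
    writeHits(ht, file.path(outdir, "02_hits.tsv"))
    manifest$stages$hits <- list(n_hits = nrow(ht@hits),
                                  threshold = cfg$evalueThreshold,
                                  method = cfg$searchMethod)
    ht
  })

  # 03 similarity graph
  graph <- stage("graph", {
    g <- buildSimilarityGraph(res$hits, res$proteomes)
    el <- igraph::as_data_frame(g, what = "edges")
    colnames(el) <- c("gene_a", "gene_b", "weight")
    el <- el[order(el$gene_a, el$gene_b), , drop = FALSE]
    writeTsv(el, file.path(outdir, "03_graph.tsv"))
    manifest$stages$graph <- list(n_nodes = igraph::vcount(g),
                                   n_edges = igraph::ecount(g))
    g
  })

  # 04 Markov clustering
  res$groups <- stage("mcl", {
    ogs <- mclCluster(graph, inflation = cfg$inflation,
                      maxIter = cfg$maxIter, pruneEps = cfg$pruneEps,
                      speciesUniverse = universe, lineage = cfg$lineage)
    writeGroups(ogs, file.path(outdir, "04_groups.tsv"))
    sizes <- table(ogs@membership$group_id)
    manifest$stages$mcl <- list(n_groups = length(sizes),
                                 n_multigene = sum(sizes > 1),
                                 converged = ogs@converged)
    ogs
  })

  # 05 classification + category counts
  res$categories <- stage("classify", {
    res$groups <- classifyGroups(res$groups)
    counts <- categoryCounts(res$groups, res$hits)
    df <- data.frame(species = rownames(counts),
                     as.data.frame.matrix(counts), check.names = FALSE)
    writeTsv(df, file.path(outdir, "05_categories.tsv"))
    manifest$stages$classify <- list(
      per_category = as.list(colSums(counts)))
    counts
  })

  # 06 single-copy selection
  res$singleCopy <- stage("single_copy", {
    sc <- selectSingleCopy(res$groups, universe,
                           strict = cfg$strictSingleCopy)
    writeLines(sc, file.path(outdir, "06_single_copy.txt"))
    manifest$stages$single_copy <- list(
      n_selected = length(sc), strict = cfg$strictSingleCopy)
    sc
  })

  # 07-08 alignment + conserved blocks
  res$blocked <- stage("blocks", {
    bl <- commonBlocks(res$proteomes, res$groups, res$singleCopy,
                       species = universe, b1 = cfg$b1, b2 = cfg$b2,
                       b3 = cfg$b3, b4 = cfg$b4,
                       gapPolicy = cfg$gapPolicy)
    alnDir <- file.path(outdir, "07_alignments")
    dir.create(alnDir, showWarnings = FALSE)
    for (g in names(bl))
      writeAlignment(bl[[g]]@alignment,
                     file.path(alnDir, paste0(g, ".afa")))
    writeBlocksReport(bl, file.path(outdir, "08_blocks.tsv"))
    manifest$stages$blocks <- list(
      n_groups_aligned = length(bl),
      n_dropped_missing_species = length(attr(bl, "dropped")),
      total_retained = sum(vapply(bl, function(b) length(b@retained),
                                  integer(1))))
    bl
  })

  # 09 identity records
  res$identity <- stage("identity", {
    rec <- identityTable(res$blocked, restrictBlocks = cfg$restrictBlocks)
    writeIdentityRecords(rec, file.path(outdir, "09_identity.tsv"))
    manifest$stages$identity <- list(n_records = nrow(rec))
    rec
  })

  # 10 three-way comparison + lowess + distribution summaries
  res$comparison <- stage("compare", {
    if (is.null(cfg$focal) || is.null(cfg$pairA) || is.null(cfg$pairB)) {
      manifest$stages$compare <- list(skipped = TRUE)
      NULL
    } else {
      cmp <- threeWayCompare(res$identity, cfg$focal, cfg$pairA,
                             cfg$pairB, tieEps = cfg$tieEps,
                             frac = cfg$lowessFrac,
                             robustIters = cfg$lowessIters)
      writeTsv(cmp$table, file.path(outdir, "10_comparison.tsv"))
      if (!is.null(cmp$lowess))
        writeTsv(data.frame(x = cmp$lowess$x, fitted = cmp$lowess$fitted),
                 file.path(outdir, "10_lowess.tsv"))
      summaries <- lapply(
        unique(res$identity[, c("species_a", "species_b")]) |>
          split(seq_len(nrow(unique(res$identity[, c("species_a",
                                                     "species_b")])))),
        function(p) summarizeIdentity(res$identity,
                                      c(p$species_a, p$species_b)))
      jsonlite::write_json(
        list(counts = as.list(cmp$counts),
             fractions = as.list(cmp$fractions),
             lowess_r2 = if (is.null(cmp$lowess)) NULL else cmp$lowess$r2,
             distributions = unname(summaries)),
        file.path(outdir, "10_summary.json"), auto_unbox = TRUE,
        digits = NA)
      manifest$stages$compare <- list(
        counts = as.list(cmp$counts), n_excluded = cmp$nExcluded)
      cmp
    }
  })

  # 11 supermatrix
  res$supermatrix <- stage("supermatrix", {
    if (!length(res$blocked)) stop("no aligned groups to concatenate")
    sm <- concatenateBlocks(res$blocked)
    writeAlignment(sm@sequences, file.path(outdir, "11_supermatrix.fasta"))
    part <- data.frame(group_id = names(sm@partitions),
                       start0 = IRanges::start(sm@partitions) - 1L,
                       end0 = IRanges::end(sm@partitions))
    writeTsv(part, file.path(outdir, "11_partitions.tsv"))
    manifest$stages$supermatrix <- list(
      width = if (length(sm@sequences)) Biostrings::width(sm@sequences)[1]
              else 0L,
      n_partitions = length(sm@partitions))
    sm
  })

  # 12 distance tree + bootstrap
  res$tree <- stage("tree", {
    D <- pDistances(res$supermatrix)
    writePhylipDist(D, file.path(outdir, "12_distances.phy"))
    tr <- bootstrapTree(res$supermatrix, nReps = cfg$bootstrapReps,
                        seed = substreamSeed(cfg$seed, "tree"))
    writeLines(ape::write.tree(tr), file.path(outdir, "12_tree.nwk"))
    manifest$stages$tree <- list(
      bootstrap_reps = cfg$bootstrapReps,
      min_support = if (length(tr$node.label) > 1)
        min(as.numeric(tr$node.label[-1])) else NA)
    tr
  })

  status$state <- "ok"; status$stage <- "done"
  writeStatus()
  manifest$package_version <- as.character(utils::packageVersion("orthopipe"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
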