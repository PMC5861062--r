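# Similarity graph, Markov clustering, category rules.

# HitTable straight from a data.frame of (query, subject, evalue)
hitTableFrom <- function(df, threshold = 1e-5) {
  n <- nrow(df)
  h <- data.frame(query = df$query, subject = df$subject,
                  pident = 90, length = 100L, mismatch = 10L,
                  gapopen = 0L, qstart = 1L, qend = 100L,
                  sstart = 1L, send = 100L, evalue = df$evalue,
                  bitscore = 100, stringsAsFactors = FALSE)
  new("HitTable", hits = h, threshold = threshold)
}

psetFrom <- function(genes, species) {
  seqs <- Biostrings::AAStringSet(
    stats::setNames(rep("MKLV", length(genes)), genes))
  new("ProteomeSet", sequences = seqs,
      geneInfo = S4Vectors::DataFrame(
        seq_id = genes, gene_id = genes, species = species,
        isoform = NA_character_, family = NA_character_))
}

test_that("buildSimilarityGraph applies reciprocity, weighting and the cap", {
  ps <- psetFrom(c("a1", "b1", "b2", "c1"), c("A", "B", "B", "C"))
  ht <- hitTableFrom(data.frame(
    query = c("a1", "b1", "a1", "b2", "c1"),
    subject = c("b1", "a1", "b2", "a1", "a1"),
    evalue = c(1e-10, 1e-20, 1e-50, 1e-300, 1e-8)))
  g <- buildSimilarityGraph(ht, ps)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 2L)
  w <- igraph::E(g)$weight
  ends <- apply(igraph::ends(g, igraph::E(g)), 1, paste, collapse = "-")
  expect_equal(w[ends == "a1-b1"], 15) # (10 + 20) / 2
  # 1e-300 floored at 1e-200 -> (50 + 200)/2 = 125
  expect_equal(w[ends == "a1-b2"], 125)
  # c1 -> a1 has no reciprocal: no edge; c1 is isolated
  expect_equal(unname(igraph::degree(g, "c1")), 0)

  # both floored: capped at 200
  ht2 <- hitTableFrom(data.frame(query = c("a1", "b1"),
                                 subject = c("b1", "a1"),
                                 evalue = c(1e-250, 1e-220)))
  g2 <- buildSimilarityGraph(ht2, ps)
  expect_equal(igraph::E(g2)$weight, 200)
})

test_that("mclCluster separates disconnected components and singletons", {
  ps <- psetFrom(sprintf("g%d", 1:7), rep(c("A", "B"), length.out = 7))
  tri <- function(a, b, c) {
    expand <- expand.grid(q = c(a, b, c), s = c(a, b, c),
                          stringsAsFactors = FALSE)
    expand <- expand[expand$q != expand$s, ]
    data.frame(query = expand$q, subject = expand$s, evalue = 1e-20)
  }
  ht <- hitTableFrom(rbind(tri("g1", "g2", "g3"), tri("g4", "g5", "g6")))
  g <- buildSimilarityGraph(ht, ps)
  ogs <- mclCluster(g)
  mem <- groupMembership(ogs)
  expect_equal(length(unique(mem$group_id)), 3L) # 2 triangles + isolated g7
  byGroup <- split(mem$gene_id, mem$group_id)
  expect_true(list(c("g1", "g2", "g3")) %in% lapply(byGroup, sort) ||
                any(vapply(byGroup, function(x)
                  setequal(x, c("g1", "g2", "g3")), logical(1))))
  expect_true(any(vapply(byGroup, function(x)
    identical(sort(x), "g7"), logical(1))))
  # partition: every gene exactly once
  expect_setequal(mem$gene_id, sprintf("g%d", 1:7))
  expect_false(anyDuplicated(mem$gene_id) > 0)
})

test_that("mclCluster matches the naive reference implementation", {
  set.seed(2024)
  for (rep in 1:50) {
    n <- sample(6:15, 1)
    ids <- sprintf("n%02d", seq_len(n))
    # random sparse weighted graph
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    nEdges <- sample(n:(2 * n), 1)
    for (e in seq_len(nEdges)) {
      ij <- sample(n, 2)
      A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- stats::runif(1, 1, 100)
    }
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    ogs <- suppressWarnings(
      mclCluster(g, speciesUniverse = "X",
                 lineage = character()))
    mem <- stats::setNames(groupMembership(ogs)$group_id,
                           groupMembership(ogs)$gene_id)
    ref <- oracleMCL(A)
    names(ref) <- ids
    expect_identical(partitionCanonical(mem[ids]),
                     partitionCanonical(ref),
                     info = paste("graph", rep))
  }
})

test_that("classifyCopyNumber reproduces the worked category examples", {
  sp12 <- sprintf("s%02d", 1:12)
  lin <- sp12[1:4]
  v <- function(...) stats::setNames(c(...), sp12)
  # absence in one genome tolerated by single-copy
  expect_equal(classifyCopyNumber(v(0, rep(1, 11)), sp12, lin),
               "universal-single")
  # duplication in two genomes: universal multi-copy
  expect_equal(classifyCopyNumber(v(2, 2, rep(1, 10)), sp12, lin),
               "universal-multi")
  # lineage presence in 3 of 4, absent elsewhere
  expect_equal(classifyCopyNumber(v(1, 1, 1, rep(0, 9)), sp12, lin),
               "lineage-only")
  # exactly half (6 of 12) spanning both lineages
  expect_equal(
    classifyCopyNumber(v(1, 1, 1, 0, 1, 1, 1, 0, 0, 0, 0, 0), sp12, lin),
    "present-at-half")
  # 5 of 12: patchy
  expect_equal(
    classifyCopyNumber(v(1, 1, 0, 0, 1, 1, 1, 0, 0, 0, 0, 0), sp12, lin),
    "patchy")
  expect_equal(classifyCopyNumber(v(3, rep(0, 11)), sp12, lin),
               "species-specific")
  expect_error(classifyCopyNumber(v(rep(1, 12)), sp12, c("sZZ")),
               "subset")
})

test_that("classifyCopyNumber equals the brute-force rule table", {
  sp12 <- sprintf("s%02d", 1:12)
  lin <- sp12[1:4]
  set.seed(99)
  for (k in 1:2000) {
    cn <- stats::setNames(
      sample(0:3, 12, replace = TRUE, prob = c(.45, .35, .15, .05)), sp12)
    expect_identical(classifyCopyNumber(cn, sp12, lin),
                     oracleCategory(cn, sp12, lin),
                     info = paste(cn, collapse = ","))
  }
})

test_that("homology-only flags singleton genes with hits, none without", {
  ps <- psetFrom(c("a1", "a2", "b1", "b2", "b3", "c1"),
                 c("A", "A", "B", "B", "B", "C"))
  # a1<->b1 reciprocal (one group); a2 has a one-way hit only; c1 nothing
  ht <- hitTableFrom(data.frame(
    query = c("a1", "b1", "a2", "b2", "b3"),
    subject = c("b1", "a1", "b1", "b3", "b2"),
    evalue = rep(1e-20, 5)))
  g <- buildSimilarityGraph(ht, ps)
  ogs <- mclCluster(g)
  flags <- flagHomologyOnly(ogs, ht)
  expect_equal(unname(flags["a2"]), "homology-only")
  expect_equal(unname(flags["c1"]), "none")
  # members of multi-gene groups are not flagged
  expect_false("a1" %in% names(flags))
  expect_false("b2" %in% names(flags))
})

test_that("categoryCounts conserves proteome sizes", {
  tr <- parseNewick("((A:.1,B:.1):.1,(C:.1,D:.1):.1);")
  fs <- sampleFamilies(tr, c("universal-single" = 0.7,
                             "species-specific" = 0.3), 15, seed = 12)
  truth <- simulateProteomes(tr, fs, rootLength = 150, seed = 12)
  ps <- asProteomeSet(truth)
  ht <- allAgainstAll(ps)
  ogs <- classifyGroups(mclCluster(buildSimilarityGraph(ht, ps)))
  counts <- categoryCounts(ogs, ht)
  gi <- as.data.frame(truthGenes(truth))
  expect_equal(rowSums(counts)[sort(unique(gi$species))],
               table(gi$species)[sort(unique(gi$species))] |>
                 as.vector() |> stats::setNames(sort(unique(gi$species))))
  # perfect clustering: counts match the truth tallies
  truthTab <- table(factor(gi$species, rownames(counts)),
                    factor(gi$category, colnames(counts)))
  expect_equal(unclass(counts)[, c("universal-single", "species-specific")],
               unclass(truthTab)[, c("universal-single", "species-specific")],
               ignore_attr = TRUE)
})

test_that("selectSingleCopy distinguishes strict from tolerant", {
  mk <- function(cnList) {
    rows <- list()
    for (g in names(cnList)) {
      cn <- cnList[[g]]
      for (sp in names(cn)) {
        if (cn[sp] > 0)
          rows[[length(rows) + 1]] <- data.frame(
            group_id = g,
            gene_id = paste0(sp, "_", g, "_", seq_len(cn[sp])),
            species = sp)
      }
    }
    new("OrthologGroupSet", membership = do.call(rbind, rows),
        speciesUniverse = c("A", "B", "C", "D"), lineage = character(),
        labels = character(), converged = TRUE)
  }
  ogs <- mk(list(
    g1 = c(A = 1, B = 1, C = 1, D = 1),
    g2 = c(A = 1, B = 1, C = 1, D = 0),
    g3 = c(A = 1, B = 2, C = 1, D = 1)))
  expect_equal(selectSingleCopy(ogs, strict = TRUE), "g1")
  expect_setequal(selectSingleCopy(ogs, strict = FALSE),
                  c("g1", "g2", "g3"))
  expect_error(selectSingleCopy(ogs, character(0)), "empty")
  expect_error(selectSingleCopy(ogs, c("A", "Z")), "universe")
})
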