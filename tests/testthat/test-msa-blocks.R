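# Progressive alignment, conserved-block extraction, concatenation.

aaset <- function(...) Biostrings::AAStringSet(c(...))

test_that("identical sequences align gap-free to themselves", {
  s <- "MKTAYIAKQRQISFVK"
  aln <- progressiveMSA(aaset(a = s, b = s, c = s))
  expect_equal(as.character(aln), c(a = s, b = s, c = s))
})

test_that("two sequences reduce to the pairwise global alignment", {
  a <- "HEAGAWGHEE"; b <- "PAWHEAE"
  aln <- progressiveMSA(aaset(x = a, y = b))
  pw <- alignGlobal(a, b)
  expect_equal(as.character(aln[["x"]]), pw$a)
  expect_equal(as.character(aln[["y"]]), pw$b)
  # and the pairwise global score equals the independent oracle
  set.seed(33)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:15) {
    p <- paste(sample(aa, sample(4:9, 1), TRUE), collapse = "")
    q <- paste(sample(aa, sample(4:9, 1), TRUE), collapse = "")
    expect_equal(alignGlobal(p, q)$score, oracleGlobalScore(p, q),
                 info = paste(p, q))
  }
})

test_that("gap-free optima are found exactly for three sequences", {
  # substitution-only triples: the optimal alignment is gap-free, with
  # sum-of-pairs score equal to the summed column scores of the inputs
  set.seed(44)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:10) {
    base <- sample(aa, 12, TRUE)
    mut <- function(s) {
      i <- sample(12, 2)
      s[i] <- sample(aa, 2, TRUE)
      s
    }
    seqs <- aaset(a = paste(base, collapse = ""),
                  b = paste(mut(base), collapse = ""),
                  c = paste(mut(base), collapse = ""))
    aln <- progressiveMSA(seqs)
    expect_equal(Biostrings::width(aln), rep(12L, 3), info = k)
    direct <- 0
    rows <- lapply(as.character(seqs), function(s) strsplit(s, "")[[1]])
    for (i in 1:2) for (j in (i + 1):3)
      direct <- direct + sum(blosum62[cbind(rows[[i]], rows[[j]])])
    expect_equal(sumOfPairsScore(aln), direct, info = k)
  }
})

test_that("readAlignment validates shape and round-trips", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "aln.afa")
  aln <- aaset(r1 = "MK-LV", r2 = "MKALV", r3 = "MKA-V", r4 = "MKALV")
  writeAlignment(aln, p)
  back <- readAlignment(p)
  expect_identical(as.character(back), as.character(aln))
  expect_equal(unique(Biostrings::width(back)), 5L)

  writeLines(c(">a", "MKLVAAAAX-", ">b", "MKLVAAAA-"), p)
  expect_error(readAlignment(p), "ragged.*'b'")
})

test_that("extractBlocks reproduces the hand-worked toy column set", {
  ba <- extractBlocks(toyMSA(), b1 = 3, b2 = 4, b3 = 2, b4 = 3)
  expect_equal(retainedColumns(ba),
               c(7L, 8L, 9L, 10L, 11L, 12L, 14L, 21L, 22L, 23L))
  expect_equal(IRanges::start(blockRanges(ba)), c(7L, 21L))
  expect_equal(IRanges::end(blockRanges(ba)), c(14L, 23L))
})

test_that("fully conserved gap-free input is retained wholesale", {
  s <- paste(rep("MKTAYIAKQR", 5), collapse = "")
  aln <- aaset(a = s, b = s, c = s, d = s)
  ba <- extractBlocks(aln)
  expect_equal(retainedColumns(ba), 1:50)
  expect_equal(length(blockRanges(ba)), 1L)

  # shorter than b4: nothing retained
  short <- aaset(a = "MKTAYIA", b = "MKTAYIA")
  expect_length(retainedColumns(extractBlocks(short, b4 = 10)), 0L)

  expect_error(extractBlocks(aln, b1 = 2), "b1")
  expect_error(extractBlocks(aln, b1 = 3, b2 = 2), "b2")
})

test_that("tightening parameters never grows the retained set", {
  set.seed(55)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  randomMSA <- function() {
    n <- sample(4:8, 1)
    L <- sample(25:60, 1)
    base <- sample(aa, L, TRUE)
    rows <- vapply(seq_len(n), function(i) {
      s <- base
      nm <- sample(0:floor(L / 2), 1)
      if (nm) {
        idx <- sample(L, nm)
        s[idx] <- sample(c(aa, "-"), nm, TRUE)
      }
      paste(s, collapse = "")
    }, character(1))
    Biostrings::AAStringSet(stats::setNames(rows, paste0("r", seq_len(n))))
  }
  for (k in 1:100) {
    aln <- randomMSA()
    n <- length(aln)
    b1 <- floor(n / 2) + 1L
    b2 <- n # fixed so parameter effects are isolated
    base <- retainedColumns(extractBlocks(aln, b1, b2, b3 = 6, b4 = 4))
    tighterB1 <- retainedColumns(
      extractBlocks(aln, min(b1 + 1L, n), b2, b3 = 6, b4 = 4))
    smallerB3 <- retainedColumns(extractBlocks(aln, b1, b2, b3 = 3, b4 = 4))
    biggerB4 <- retainedColumns(extractBlocks(aln, b1, b2, b3 = 6, b4 = 8))
    expect_true(all(tighterB1 %in% base), info = k)
    expect_true(all(smallerB3 %in% base), info = k)
    expect_true(all(biggerB4 %in% base), info = k)
  }
})

test_that("commonBlocks shares one column set per group and drops gaps in species", {
  tr <- parseNewick("((A:.05,B:.05):.05,C:.1);")
  fs <- sampleFamilies(tr, c("universal-single" = 1), 4, seed = 8)
  truth <- simulateProteomes(tr, fs, rootLength = 80, seed = 8)
  ps <- asProteomeSet(truth)
  ht <- allAgainstAll(ps)
  ogs <- classifyGroups(mclCluster(buildSimilarityGraph(ht, ps)))
  sc <- selectSingleCopy(ogs)
  bl <- commonBlocks(ps, ogs, sc)
  expect_length(bl, length(sc))
  for (g in names(bl)) {
    # one row per species, one shared retained set (gap-free input: equals
    # full-alignment extraction)
    expect_setequal(as.character(alignmentRowInfo(bl[[g]])$species),
                    c("A", "B", "C"))
    direct <- extractBlocks(alignedSequences(bl[[g]]))
    expect_equal(retainedColumns(bl[[g]]), retainedColumns(direct))
  }
  # a group missing one species is dropped and reported
  sub <- ogs
  mem <- groupMembership(ogs)
  drop1 <- mem$gene_id[mem$group_id == sc[1] & mem$species == "C"]
  keep <- setdiff(names(aaSequences(ps)), drop1)
  ps2 <- new("ProteomeSet", sequences = aaSequences(ps)[keep],
             geneInfo = geneInfo(ps)[match(keep, geneInfo(ps)$seq_id), ])
  expect_message(bl2 <- commonBlocks(ps2, ogs, sc), "dropped")
  expect_equal(attr(bl2, "dropped"), sc[1])
})

test_that("concatenateBlocks is additive, canonical and tolerates empties", {
  mkBlocked <- function(seqA, seqB, retain) {
    aln <- aaset(A = seqA, B = seqB)
    bl <- if (length(retain))
      IRanges::IRanges(start = min(retain), end = max(retain))
    else IRanges::IRanges()
    new("BlockedAlignment", alignment = aln,
        rowInfo = S4Vectors::DataFrame(gene_id = c("gA", "gB"),
                                       species = c("A", "B")),
        retained = as.integer(retain), blocks = bl, params = list())
  }
  b1 <- mkBlocked(strrep("M", 12), strrep("K", 12), 1:10)
  b2 <- mkBlocked(strrep("R", 20), strrep("W", 20), 1:15)
  sm <- concatenateBlocks(list(g2 = b2, g1 = b1))
  expect_equal(Biostrings::width(supermatrixSequences(sm)), c(25L, 25L))
  # canonical lexicographic order regardless of input order
  sm2 <- concatenateBlocks(list(g1 = b1, g2 = b2))
  expect_identical(as.character(supermatrixSequences(sm)),
                   as.character(supermatrixSequences(sm2)))
  expect_equal(names(partitionRanges(sm)), c("g1", "g2"))
  expect_equal(as.character(supermatrixSequences(sm)[["A"]]),
               paste0(strrep("M", 10), strrep("R", 15)))

  empty <- mkBlocked(strrep("M", 5), strrep("K", 5), integer(0))
  sm3 <- concatenateBlocks(list(g1 = b1, g0 = empty))
  expect_equal(IRanges::width(partitionRanges(sm3)),
               stats::setNames(c(0L, 10L), NULL))
  expect_equal(Biostrings::width(supermatrixSequences(sm3)), c(10L, 10L))
})
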