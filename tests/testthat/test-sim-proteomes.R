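# Simulator: newick handling, family sampling, Poisson replacement model.

test_that("parseNewick parses, validates, and round-trips", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  # root children are the AB clade and the tip C
  expect_equal(leafDist <- ape::cophenetic.phylo(tr)["A", "B"], 2)
  expect_equal(ape::cophenetic.phylo(tr)["A", "C"], 4)

  rt <- parseNewick(writeNewick(tr))
  expect_true(sameUnrootedTopology(rt, tr))
  expect_equal(sort(rt$edge.length), sort(tr$edge.length))

  expect_error(parseNewick("((A:1,B:1):1,C:-2);"), "negative branch length")
  expect_error(parseNewick("((A:1,B:1:1,C:2);"), "unclosed")
  expect_error(parseNewick("(A:1,B:1)):1;"), "position 10")
  expect_error(parseNewick("((A:1,A:1):1,C:2);"), "duplicate leaf")
  expect_error(parseNewick("((A:1,B:1):1,C:2)"), "';'")
  expect_error(parseNewick("((A,B):1,C:2);"), "branch length")
})

test_that("sampleFamilies realises pure categories exactly", {
  tr <- parseNewick("((A:.1,B:.1):.1,(C:.1,D:.1):.1);")
  us <- sampleFamilies(tr, c("universal-single" = 1), 10, seed = 1)
  expect_equal(nrow(us$families), 10)
  expect_true(all(us$copyNumber == 1L))

  ss <- sampleFamilies(tr, c("species-specific" = 1), 5, seed = 1)
  expect_true(all(rowSums(ss$copyNumber > 0) == 1L))

  expect_error(
    sampleFamilies(tr, c("homology-only" = 1), 3, seed = 1),
    "unsupported")
  expect_error(
    sampleFamilies(tr, c("universal-single" = 0.7), 3, seed = 1),
    "sum to 1")
  expect_error(
    sampleFamilies(tr, c("lineage-only" = 1), 3, lineage = c("A", "B"),
                   seed = 1),
    ">= 3 species")
})

test_that("sampleFamilies category frequencies track the mixture", {
  tr <- parseNewick("((A:.1,B:.1):.1,(C:.1,D:.1):.1);")
  p <- c("universal-single" = 0.5, "universal-multi" = 0.5)
  fs <- sampleFamilies(tr, p, 1000, seed = 42)
  nUS <- sum(fs$families$category == "universal-single")
  se <- sqrt(1000 * 0.5 * 0.5)
  expect_lt(abs(nUS - 500), 3 * se)
  # deterministic given the seed
  fs2 <- sampleFamilies(tr, p, 1000, seed = 42)
  expect_identical(fs$families, fs2$families)
  expect_identical(fs$copyNumber, fs2$copyNumber)
})

test_that("generated families always satisfy their declared category", {
  tr8 <- parseNewick(paste0("(((A:.1,B:.1):.1,(C:.1,D:.1):.1):.1,",
                            "((E:.1,F:.1):.1,(G:.1,H:.1):.1):.1);"))
  p <- c("universal-single" = .2, "universal-multi" = .2,
         "lineage-only" = .2, "species-specific" = .1,
         "present-at-half" = .15, "patchy" = .15)
  fs <- sampleFamilies(tr8, p, 200, lineage = c("A", "B", "C", "D"),
                       seed = 9)
  sp <- sort(tr8$tip.label)
  for (k in seq_len(200)) {
    expect_identical(
      classifyCopyNumber(fs$copyNumber[k, sp], sp, c("A", "B", "C", "D")),
      fs$families$category[k])
  }
})

test_that("zero branch lengths leave sequences identical to the root", {
  tr <- parseNewick("((A:0,B:0):0,C:0);")
  ss <- evolveFamily(tr, "F1", c(A = 1, B = 1, C = 1), rootLength = 50,
                     seed = 3)
  expect_length(ss, 3)
  expect_equal(length(unique(as.character(ss))), 1L)
})

test_that("mean identity matches the closed form at path distance 1", {
  # two effective leaves at distance 1; closed form with uniform pi:
  # exp(-1) + (1 - exp(-1)) / 20
  tr <- parseNewick("(A:0.5,B:0.5,C:0.01);")
  nFam <- 60; L <- 300
  matches <- 0L
  for (k in seq_len(nFam)) {
    ss <- evolveFamily(tr, paste0("F", k), c(A = 1, B = 1, C = 1),
                       rootLength = L, seed = 11)
    a <- strsplit(as.character(ss[[paste0("A|F", k, "|g1")]]), "")[[1]]
    b <- strsplit(as.character(ss[[paste0("B|F", k, "|g1")]]), "")[[1]]
    matches <- matches + sum(a == b)
  }
  p <- exp(-1) + (1 - exp(-1)) / 20
  phat <- matches / (nFam * L)
  se <- sqrt(p * (1 - p) / (nFam * L))
  expect_lt(abs(phat - p), 3 * se)
})

test_that("evolveFamily is deterministic and duplicates at the branch midpoint", {
  tr <- parseNewick("((A:0.4,B:0.4):0.1,C:0.5);")
  s1 <- evolveFamily(tr, "Fx", c(A = 3, B = 1, C = 1), seed = 5)
  s2 <- evolveFamily(tr, "Fx", c(A = 3, B = 1, C = 1), seed = 5)
  expect_identical(as.character(s1), as.character(s2))
  expect_setequal(names(s1), c("A|Fx|g1", "A|Fx|g2", "A|Fx|g3",
                               "B|Fx|g1", "C|Fx|g1"))
  expect_error(evolveFamily(tr, "Fy", c(A = 1), rootLength = 0), "rootLength")
  expect_error(evolveFamily(tr, "Fy", c(A = 1), pi = rep(0.1, 10)), "pi")
})

test_that("identity decreases with path distance (ladder check)", {
  ids <- vapply(c(0.1, 0.5, 1.0, 2.0), function(D) {
    tr <- parseNewick(sprintf("(A:%f,B:%f,C:0.01);", D / 2, D / 2))
    m <- 0L
    for (k in 1:20) {
      ss <- evolveFamily(tr, paste0("L", k), c(A = 1, B = 1, C = 1),
                         rootLength = 300, seed = 21)
      a <- strsplit(as.character(ss[[1]]), "")[[1]]
      b <- strsplit(as.character(ss[[paste0("B|L", k, "|g1")]]), "")[[1]]
      m <- m + sum(a == b)
    }
    m / (20 * 300)
  }, numeric(1))
  expect_true(all(diff(ids) < 0))
})

test_that("writeTruthSet round-trips sequences and preserves absences", {
  tr <- parseNewick("((A:.1,B:.1):.1,C:.2);")
  fs <- list(families = data.frame(family_id = c("F001", "F002"),
                                   category = c("universal-single",
                                                "species-specific")),
             copyNumber = matrix(c(1L, 1L, 1L, 2L, 0L, 0L), nrow = 2,
                                 byrow = TRUE,
                                 dimnames = list(c("F001", "F002"),
                                                 c("A", "B", "C"))))
  truth <- simulateProteomes(tr, fs, rootLength = 40, seed = 2)
  dir <- withr::local_tempdir()
  writeTruthSet(truth, dir)
  expect_setequal(list.files(dir, pattern = "faa$"),
                  c("A.faa", "B.faa", "C.faa"))
  tt <- readTruthTable(dir)
  expect_equal(nrow(tt), length(truth@sequences))
  # F002 is A-only: no records for B or C
  expect_equal(sum(tt$family_id == "F002" & tt$species != "A"), 0L)

  ps <- readProteomes(file.path(dir, c("A.faa", "B.faa", "C.faa")))
  expect_setequal(names(aaSequences(ps)), names(aaSequences(truth)))
  expect_identical(
    as.character(aaSequences(ps))[sort(names(aaSequences(ps)))],
    as.character(aaSequences(truth))[sort(names(aaSequences(truth)))])
})
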