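# Internal helpers: alphabet, RNG substreams, TSV conventions.

# canonical amino-acid alphabet, alphabetical order
AA20 <- "ACDEFGHIKLMNPQRSTVWY"
AA20_VEC <- strsplit(AA20, "")[[1]]

HIT_COLUMNS <- c("query", "subject", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

CATEGORIES <- c("universal-single", "universal-multi", "lineage-only",
                "species-specific", "present-at-half", "patchy",
                "homology-only", "none")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable 31-bit string hash (polynomial rolling mod the Mersenne prime
# 2^31 - 1), used to derive per-family / per-stage RNG substreams from the
# master seed so results are invariant to processing order. Exact in double
# arithmetic: intermediate values stay below 2^53.
stableHash <- function(x) {
  p <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% p
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# seed for a named substream, always a valid 32-bit integer
substreamSeed <- function(seed, label) {
  as.integer((as.numeric(seed) + stableHash(label)) %% 2147483647)
}

# evaluate code under a temporary RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# tab-separated writer/reader with a single '#'-prefixed header line
writeTsv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(colnames(df), collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop("expected a '#'-prefixed header line in ", path)
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  df
}

# shared substitution matrix lookup (Biostrings ships the standard series)
getSubstitutionMatrix <- function(name = "BLOSUM62") {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}
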