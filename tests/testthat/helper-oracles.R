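# Independent oracles, deliberately written with different machinery than
# the package implementations they check.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# --- local alignment -------------------------------------------------------

# plain-R three-state Smith-Waterman/Gotoh, scalar loops, H-matrix form;
# gap of length k costs open + k * ext
oracleLocalScore <- function(a, b, sub = blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1) # gap in a (moving along b)
  F <- matrix(-Inf, n + 1, m + 1) # gap in b
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + sub[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# complete enumeration of local alignments for very short sequences:
# every substring pair, every monotone alignment path, affine-scored
enumLocalScore <- function(a, b, sub = blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- 0
  scorePath <- function(ops, ai, bi) {
    # ops: vector of "M","I","D"
    s <- 0; run <- ""
    for (op in ops) {
      if (op == "M") {
        s <- s + sub[A[ai], B[bi]]; ai <- ai + 1; bi <- bi + 1; run <- ""
      } else {
        s <- s - ext - if (run == op) 0 else open
        run <- op
        if (op == "I") bi <- bi + 1 else ai <- ai + 1
      }
    }
    s
  }
  recurse <- function(ops, ai, bi, na, nb) {
    if (na == 0 && nb == 0) {
      if (length(ops)) best <<- max(best, scorePath(ops, ai0, bi0))
      return()
    }
    if (na > 0 && nb > 0) recurse(c(ops, "M"), ai, bi, na - 1, nb - 1)
    if (na > 0) recurse(c(ops, "D"), ai, bi, na - 1, nb)
    if (nb > 0) recurse(c(ops, "I"), ai, bi, na, nb - 1)
  }
  for (ai0 in seq_along(A)) for (la in 1:(length(A) - ai0 + 1)) {
    for (bi0 in seq_along(B)) for (lb in 1:(length(B) - bi0 + 1)) {
      recurse(character(), ai0, bi0, la, lb)
    }
  }
  best
}

# --- global alignment ------------------------------------------------------

oracleGlobalScore <- function(a, b, sub = blosum62, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) E[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) F[i, 1] <- -open - (i - 1) * ext
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(M[i, j - 1] - open - ext, F[i, j - 1] - open - ext,
                   E[i, j - 1] - ext)
    F[i, j] <- max(M[i - 1, j] - open - ext, E[i - 1, j] - open - ext,
                   F[i - 1, j] - ext)
    M[i, j] <- max(M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) +
      sub[A[i - 1], B[j - 1]]
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
}

# --- Markov clustering -----------------------------------------------------

# naive whole-graph dense reference: explicit column loops, cluster readout
# as connected components of the limit matrix's nonzero pattern
oracleMCL <- function(adj, inflation = 1.5, maxIter = 100, pruneEps = 1e-5) {
  n <- nrow(adj)
  A <- adj
  for (k in seq_len(n)) {
    mx <- max(A[, k])
    A[k, k] <- if (mx > 0) mx else 1
  }
  M <- A
  for (k in seq_len(n)) M[, k] <- A[, k] / sum(A[, k])
  for (it in seq_len(maxIter)) {
    Mexp <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      Mexp[i, j] <- sum(M[i, ] * M[, j])
    Mnew <- Mexp^inflation
    for (k in seq_len(n)) Mnew[, k] <- Mnew[, k] / sum(Mnew[, k])
    Mnew[Mnew < pruneEps] <- 0
    for (k in seq_len(n)) {
      s <- sum(Mnew[, k])
      if (s > 0) Mnew[, k] <- Mnew[, k] / s
    }
    if (max(abs(Mnew - M)) < 1e-8) { M <- Mnew; break }
    M <- Mnew
  }
  reach <- (M + t(M)) > 0
  diag(reach) <- TRUE
  # connected components by BFS over the nonzero pattern
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(reach[v, ] & is.na(comp)))
    }
  }
  comp
}

# canonical form of a partition for comparison (list of sorted member sets)
partitionCanonical <- function(members) {
  cl <- split(names(members), members)
  cl <- lapply(cl, sort)
  unname(cl[order(vapply(cl, `[`, character(1), 1))])
}

# --- orthology category rule table -----------------------------------------

# direct boolean re-statement of the category rules, evaluated in fixed
# precedence order; independent of the package's control flow
oracleCategory <- function(cn, universe, lineage) {
  present <- universe[cn > 0]
  S <- length(universe)
  if (length(present) == 0) return("none")
  isSpecific <- length(present) == 1
  if (isSpecific) return("species-specific")
  isUnivSingle <- sum(cn != 1) <= 1
  if (isUnivSingle) return("universal-single")
  isUniv <- length(present) >= S - 1
  if (isUniv) return("universal-multi")
  isLineage <- length(lineage) > 0 && all(present %in% lineage) &&
    length(present) >= 3
  if (isLineage) return("lineage-only")
  if (length(present) >= ceiling(S / 2)) return("present-at-half")
  "patchy"
}

# --- locally weighted regression -------------------------------------------

# from-scratch transcription of the classic lowess algorithm: tricube
# weights over the ns nearest neighbours, local linear fit, bisquare
# robustness weights scaled by six times the median absolute residual
oracleLowess <- function(x, y, f = 2 / 3, nsteps = 3L) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  ns <- max(2L, min(n, as.integer(f * n + 1e-7)))
  rw <- numeric(n)
  ys <- numeric(n)
  rng <- x[n] - x[1]

  fitAt <- function(i, nleft, nright, userw) {
    xs <- x[i]
    h <- max(xs - x[nleft], x[nright] - xs)
    h9 <- 0.999 * h; h1 <- 0.001 * h
    w <- numeric(n)
    a <- 0
    j <- nleft
    while (j <= n) {
      r <- abs(x[j] - xs)
      if (r <= h9) {
        w[j] <- if (r <= h1) 1 else (1 - (r / h)^3)^3
        if (userw) w[j] <- w[j] * rw[j]
        a <- a + w[j]
      } else if (x[j] > xs) break
      j <- j + 1L
    }
    nrt <- j - 1L
    if (a <= 0) return(list(ok = FALSE))
    idx <- nleft:nrt
    w[idx] <- w[idx] / a
    if (h > 0) {
      a <- sum(w[idx] * x[idx])
      b <- xs - a
      cc <- sum(w[idx] * (x[idx] - a)^2)
      if (sqrt(cc) > 0.001 * rng) {
        b <- b / cc
        w[idx] <- w[idx] * (b * (x[idx] - a) + 1)
      }
    }
    list(ok = TRUE, ys = sum(w[idx] * y[idx]))
  }

  for (iteration in seq_len(nsteps + 1L)) {
    nleft <- 1L; nright <- ns
    last <- 0L; i <- 1L
    repeat {
      while (nright < n) {
        d1 <- x[i] - x[nleft]
        d2 <- x[nright + 1L] - x[i]
        if (d1 <= d2) break
        nleft <- nleft + 1L; nright <- nright + 1L
      }
      r <- fitAt(i, nleft, nright, iteration > 1L)
      ys[i] <- if (r$ok) r$ys else y[i]
      last <- i
      # delta = 0: still copy fits across tied x values
      i <- last + 1L
      while (i <= n && x[i] == x[last]) {
        ys[i] <- ys[last]
        last <- i
        i <- i + 1L
      }
      if (last >= n) break
    }
    if (iteration > nsteps) break
    res <- y - ys
    absr <- sort(abs(res))
    m1 <- floor(n / 2) + 1L
    m2 <- n - m1 + 1L
    cmad <- 3 * (absr[m1] + absr[m2])
    if (cmad < 1e-7 * (sum(abs(res)) / n)) break
    c9 <- 0.999 * cmad; c1 <- 0.001 * cmad
    r <- abs(res)
    rw <- ifelse(r <= c1, 1, ifelse(r <= c9, (1 - (r / cmad)^2)^2, 0))
  }
  list(x = x, y = ys)
}

# --- trees ------------------------------------------------------------------

# random additive tree distances: random topology with exponential branch
# lengths, patristic distances as the matrix
randomAdditiveDistances <- function(nTaxa) {
  tr <- ape::rtree(nTaxa, br = function(k) stats::rexp(k, 5) + 0.02)
  tr$tip.label <- sort(tr$tip.label)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
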