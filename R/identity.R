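#' Block-restricted percent identity between two alignment rows
#'
#' Identity = 100 * matching columns / comparable columns, where the
#' comparable columns are the retained conserved-block columns at which
#' both rows are non-gap. Returns the comparable-column count alongside;
#' zero comparable columns yields no record (NA identity).
#'
#' @param ba a [BlockedAlignment-class].
#' @param i,j row indices or gene/species names (distinct).
#' @param restrictBlocks when FALSE, all alignment columns are used
#'   instead of the retained set.
#' @return list with `identity` (percent) and `nColumns`.
#' @export
pairwiseIdentity <- function(ba, i, j, restrictBlocks = TRUE) {
  stopifnot(is(ba, "BlockedAlignment"))
  idx <- function(k) {
    if (is.character(k)) {
      hit <- match(k, ba@rowInfo$gene_id)
      if (is.na(hit)) hit <- match(k, ba@rowInfo$species)
      if (is.na(hit)) stop("no alignment row '", k, "'")
      hit
    } else as.integer(k)
  }
  i <- idx(i); j <- idx(j)
  stopifnot(i != j)
  a <- strsplit(as.character(ba@alignment[[i]]), "")[[1]]
  b <- strsplit(as.character(ba@alignment[[j]]), "")[[1]]
  cols <- if (restrictBlocks) ba@retained else seq_along(a)
  if (!length(cols)) return(list(identity = NA_real_, nColumns = 0L))
  a <- a[cols]; b <- b[cols]
  comparable <- a != "-" & b != "-"
  nc <- sum(comparable)
  if (nc == 0L) return(list(identity = NA_real_, nColumns = 0L))
  list(identity = 100 * sum(a[comparable] == b[comparable]) / nc,
       nColumns = nc)
}

#' Per-group, per-species-pair identity records
#'
#' Computes block-restricted percent identity for every unordered species
#' pair of every group. Pairs with zero comparable columns are skipped
#' with a message.
#'
#' @param blockedList named list of [BlockedAlignment-class] (one row per
#'   species).
#' @param restrictBlocks see [pairwiseIdentity()].
#' @return data.frame: `group_id`, `species_a`, `species_b`
#'   (alphabetical within pair), `identity`, `n_columns`.
#' @export
identityTable <- function(blockedList, restrictBlocks = TRUE) {
  rows <- list()
  skipped <- 0L
  for (g in sort(names(blockedList))) {
    ba <- blockedList[[g]]
    sp <- sort(as.character(ba@rowInfo$species))
    for (i in seq_len(length(sp) - 1)) for (j in seq(i + 1, length(sp))) {
      r <- pairwiseIdentity(ba, sp[i], sp[j], restrictBlocks)
      if (r$nColumns == 0L) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = g, species_a = sp[i], species_b = sp[j],
        identity = r$identity, n_columns = r$nColumns,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped) message(skipped, " pair(s) skipped: no comparable columns")
  if (!length(rows))
    return(data.frame(group_id = character(), species_a = character(),
                      species_b = character(), identity = numeric(),
                      n_columns = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise an identity distribution for one species pair
#'
#' Boxplot-style summary: quartiles by linear interpolation (quantile
#' type 7) and a notch half-width of `1.58 * IQR / sqrt(n)` on each side
#' of the median.
#'
#' @param records data.frame from [identityTable()].
#' @param pair character vector of the two species.
#' @return list: `species_a`, `species_b`, `n`, `q1`, `median`, `q3`,
#'   `notch`.
#' @export
summarizeIdentity <- function(records, pair) {
  stopifnot(length(pair) == 2)
  pair <- sort(pair)
  x <- records$identity[records$species_a == pair[1] &
                        records$species_b == pair[2]]
  if (!length(x)) stop("no records for pair ", paste(pair, collapse = "/"))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(species_a = pair[1], species_b = pair[2], n = length(x),
       q1 = q[1], median = q[2], q3 = q[3],
       notch = 1.58 * (q[3] - q[1]) / sqrt(length(x)))
}

#' Robust locally weighted regression (lowess) with a smoother R-squared
#'
#' Fits the classic lowess smoother — local linear regression with tricube
#' weights over the `ceiling(frac * n)` nearest neighbours and
#' `robustIters` bisquare re-weighting passes — via [stats::lowess()]
#' (with `delta = 0`, so every point is fitted exactly). The coefficient
#' of determination is computed from the fitted values at the observed x:
#' `R2 = 1 - SS_res / SS_tot`. Degenerate inputs: when all x are equal the
#' fit is `mean(y)` everywhere, with R2 = 1 if y is constant and 0
#' otherwise.
#'
#' @param x,y numeric vectors (n >= 3).
#' @param frac neighbourhood fraction in (0, 1] (default 2/3).
#' @param robustIters robustifying iterations (default 3).
#' @return list: `x` (sorted), `fitted` (at sorted x), `fittedAt`
#'   (fitted values in input order) and `r2`.
#' @examples
#' f <- lowessFit(1:10, 2 * (1:10) + 1)
#' f$r2
#' @export
lowessFit <- function(x, y, frac = 2 / 3, robustIters = 3L) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            frac > 0, frac <= 1, robustIters >= 0)
  if (length(unique(x)) == 1L) {
    fit <- rep(mean(y), length(y))
    r2 <- if (isTRUE(all.equal(stats::var(y), 0)) || stats::var(y) == 0) 1 else 0
    return(list(x = x, fitted = fit, fittedAt = fit, r2 = r2))
  }
  lw <- stats::lowess(x, y, f = frac, iter = robustIters, delta = 0)
  ord <- order(x)
  fittedAt <- numeric(length(x))
  fittedAt[ord] <- lw$y
  ssRes <- sum((y - fittedAt)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot == 0) {
    # constant y: perfect fit up to numerical noise counts as 1
    if (ssRes <= 1e-10 * (1 + sum(y^2))) 1 else 0
  } else 1 - ssRes / ssTot
  list(x = lw$x, fitted = lw$y, fittedAt = fittedAt, r2 = r2)
}

#' Three-way closest-relative comparison
#'
#' For every ortholog group with identity records for both (focal, a) and
#' (focal, b), labels the group `closer-a` when
#' `id(focal, a) - id(focal, b) > tieEps`, `closer-b` symmetrically, and
#' `tie` otherwise. Groups missing either record are excluded and
#' counted. A lowess smoother of `id(focal, b)` against `id(focal, a)` is
#' fitted with [lowessFit()].
#'
#' @param records data.frame from [identityTable()].
#' @param focal,a,b species labels.
#' @param tieEps non-negative tie tolerance in identity percpoints
#'   (default 0).
#' @param frac,robustIters smoother settings, see [lowessFit()].
#' @return list: `table` (data.frame group_id, id_a, id_b, label),
#'   `counts`, `fractions` (over non-tie labels and ties reported
#'   separately), `nExcluded`, `lowess` (the [lowessFit()] result),
#'   `focal`, `a`, `b`.
#' @export
threeWayCompare <- function(records, focal, a, b, tieEps = 0,
                            frac = 2 / 3, robustIters = 3L) {
  stopifnot(tieEps >= 0)
  getPair <- function(s1, s2) {
    p <- sort(c(s1, s2))
    r <- records[records$species_a == p[1] & records$species_b == p[2], ]
    stats::setNames(r$identity, r$group_id)
  }
  ia <- getPair(focal, a)
  ib <- getPair(focal, b)
  common <- intersect(names(ia), names(ib))
  nExcluded <- length(union(names(ia), names(ib))) - length(common)
  common <- sort(common)
  diff <- ia[common] - ib[common]
  label <- ifelse(diff > tieEps, "closer-a",
                  ifelse(diff < -tieEps, "closer-b", "tie"))
  tab <- data.frame(group_id = common, id_a = unname(ia[common]),
                    id_b = unname(ib[common]), label = unname(label),
                    stringsAsFactors = FALSE)
  counts <- c(`closer-a` = sum(label == "closer-a"),
              `closer-b` = sum(label == "closer-b"),
              tie = sum(label == "tie"))
  fractions <- counts / max(sum(counts), 1L)
  lw <- if (nrow(tab) >= 3)
    lowessFit(tab$id_a, tab$id_b, frac = frac, robustIters = robustIters)
  else NULL
  list(table = tab, counts = counts, fractions = fractions,
       nExcluded = nExcluded, lowess = lw, focal = focal, a = a, b = b)
}

#' Write identity records
#'
#' Layout: `group <tab> speciesA <tab> speciesB <tab> identity <tab>
#' n_columns`, sorted by group then pair.
#'
#' @param records data.frame from [identityTable()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeIdentityRecords <- function(records, path) {
  r <- records[order(records$group_id, records$species_a,
                     records$species_b), ]
  writeTsv(r, path)
}
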