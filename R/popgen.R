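#' Windowed nucleotide diversity per group
#'
#' Per block and group, pi per bp = sum over sites of
#' 2 p (1 - p) n / (n - 1), divided by the block length in bp, where p is
#' the group's ALT frequency at the site and n its non-missing allele
#' count (the n/(n-1) factor is the unbiased sample-size correction).
#' Sites with fewer than 2 observed alleles in the group are skipped.
#'
#' @param gm a [GenotypeMatrix-class] with a group map.
#' @param grid block `GRanges` from [sliceBlocks()].
#' @param groups group names to score (default: all groups with >= 2
#'   accessions is required; a singleton group is an error).
#' @return data.frame: `chrom`, `start`, `end`, `block`, `group`, `pi`
#'   (per bp), `n_sites`.
#' @export
nucleotideDiversity <- function(gm, grid, groups = NULL) {
  gmap <- groupMap(gm)
  if (is.null(gmap)) stop("genotype matrix needs a group map")
  if (is.null(groups)) groups <- unique(gmap)
  dos <- dosage(gm)
  blockOf <- siteBlocks(gm, grid)
  res <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    members <- names(gmap)[gmap == g]
    if (length(members) < 2L)
      stop("group '", g, "' has fewer than 2 accessions")
    sub <- dos[, members, drop = FALSE]
    n <- 2 * rowSums(!is.na(sub))
    p <- ifelse(n > 0, rowSums(sub, na.rm = TRUE) / n, NA_real_)
    term <- ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)
    pi <- vapply(seq_along(grid), function(b) {
      idx <- which(blockOf == b & !is.na(term))
      if (!length(idx)) return(NA_real_)
      sum(term[idx]) / width(grid)[b]
    }, numeric(1))
    nsites <- vapply(seq_along(grid), function(b)
      sum(blockOf == b & !is.na(term), na.rm = TRUE), numeric(1))
    res[[gi]] <- data.frame(chrom = as.character(seqnames(grid)),
                            start = start(grid), end = end(grid),
                            block = seq_along(grid), group = g,
                            pi = pi, n_sites = as.integer(nsites))
  }
  do.call(rbind, res)
}

#' Windowed Hudson Fst between two groups
#'
#' Ratio-of-averages Hudson estimator: per site,
#' `N = (pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)` and
#' `D = pA(1-pB) + pB(1-pA)` with allele counts nA, nB; per block,
#' `Fst = sum(N) / sum(D)`.  Sites need at least 2 observed alleles in
#' each group; a block with `sum(D) = 0` (no polymorphism) is `NA`.
#'
#' @param gm a [GenotypeMatrix-class] with a group map.
#' @param grid block `GRanges`.
#' @param groupA,groupB the two groups (each >= 2 accessions).
#' @return data.frame: `chrom`, `start`, `end`, `block`, `fst`,
#'   `n_sites`.
#' @export
hudsonFst <- function(gm, grid, groupA, groupB) {
  gmap <- groupMap(gm)
  if (is.null(gmap)) stop("genotype matrix needs a group map")
  dos <- dosage(gm)
  freqCount <- function(g) {
    members <- names(gmap)[gmap == g]
    if (length(members) < 2L)
      stop("group '", g, "' has fewer than 2 accessions")
    sub <- dos[, members, drop = FALSE]
    n <- 2 * rowSums(!is.na(sub))
    list(p = ifelse(n > 0, rowSums(sub, na.rm = TRUE) / n, NA_real_), n = n)
  }
  A <- freqCount(groupA); B <- freqCount(groupB)
  ok <- A$n >= 2 & B$n >= 2
  N <- (A$p - B$p)^2 - A$p * (1 - A$p) / (A$n - 1) -
    B$p * (1 - B$p) / (B$n - 1)
  D <- A$p * (1 - B$p) + B$p * (1 - A$p)
  blockOf <- siteBlocks(gm, grid)
  fst <- nsites <- rep(NA_real_, length(grid))
  for (b in seq_along(grid)) {
    idx <- which(blockOf == b & ok)
    nsites[b] <- length(idx)
    if (!length(idx)) next
    den <- sum(D[idx])
    fst[b] <- if (den > 0) sum(N[idx]) / den else NA_real_
  }
  data.frame(chrom = as.character(seqnames(grid)),
             start = start(grid), end = end(grid),
             block = seq_along(grid), fst = fst,
             n_sites = as.integer(nsites))
}
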