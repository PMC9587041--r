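#' Classify introgressed accessions from a block tree
#'
#' An accession whose whole-genome group is `recipient` is called
#' introgressed from `donor` in this block when two conditions hold:
#' (i) among its k nearest non-self leaves by patristic distance —
#' candidates restricted to members of the donor and recipient groups —
#' strictly more than k/2 belong to the donor group, and (ii) its median
#' patristic distance to donor members is strictly smaller than to the
#' other members of its own group.  The median confirmation makes the
#' call robust to label contamination: in a block where introgressed
#' recipients genuinely carry donor haplotypes, those carriers sit next
#' to the donor clade and would otherwise drag honest donor accessions
#' into spurious reverse-direction calls, while a median over the
#' (mostly uncontaminated) groups is unaffected below 50% contamination.
#' Distance ties are broken by lexicographic leaf name, so the rule is
#' deterministic; on a star tree (all distances equal) no accession is
#' called.  k defaults to `min(5, donor group size)`.
#'
#' @param tree a `phylo` whose tips are accession ids (e.g. from
#'   [njTree()]).
#' @param groups named character vector, accession -> whole-genome group.
#' @param recipient,donor group names (roles: donor -> recipient).
#' @param k neighbourhood size; strict majority of k is required.
#' @return data.frame of calls with columns `accession`, `donor_group`,
#'   `recipient_group` (zero rows when nothing is called).
#' @examples
#' tr <- ape::read.tree(text =
#'   "(((A1:0.01,B1:0.01):0.01,(B2:0.01,B3:0.01):0.01):0.2,(A2:0.01,A3:0.01):0.2);")
#' gmap <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B", B3 = "B")
#' classifyIntrogression(tr, gmap, recipient = "A", donor = "B", k = 3)
#' @export
classifyIntrogression <- function(tree, groups, recipient, donor, k = NULL) {
  if (recipient == donor) stop("donor and recipient must differ")
  tips <- tree$tip.label
  donors <- intersect(tips, names(groups)[groups == donor])
  recips <- intersect(tips, names(groups)[groups == recipient])
  if (is.null(k)) k <- min(5L, length(donors))
  if (length(donors) < k || length(recips) < 2L)
    stop("tree needs >= k donor leaves and >= 2 recipient leaves")
  pd <- patristicDistance(tree)
  called <- character()
  for (x in recips) {
    cand <- setdiff(c(donors, recips), x)
    o <- order(pd[x, cand], cand)     # distance, then name
    nearest <- cand[o][seq_len(k)]
    majority <- sum(nearest %in% donors) > k / 2
    ownOthers <- setdiff(recips, x)
    medianCloser <- stats::median(pd[x, donors]) <
      stats::median(pd[x, ownOthers])
    if (majority && medianCloser) called <- c(called, x)
  }
  data.frame(accession = sort(called),
             donor_group = rep(donor, length(called)),
             recipient_group = rep(recipient, length(called)))
}

#' Block-wise phylogenetic-tree introgression scan
#'
#' For every block of the grid: count polymorphic sites; with fewer than
#' `minSnps` the block is NO_CALL (matching the grey
#' insufficient-polymorphism areas of a painted-genome track).  Otherwise
#' build the allele-sharing distance matrix over all accessions, a
#' neighbor-joining tree, and classify every ordered donor -> recipient
#' pair with [classifyIntrogression()].  A block in which some accession
#' pair shares no genotyped site is also NO_CALL.
#'
#' @param gm a [GenotypeMatrix-class] with a group map.
#' @param grid block `GRanges` from [sliceBlocks()].
#' @param pairs data.frame with columns `donor`, `recipient` (ordered
#'   pairs to classify).
#' @param minSnps minimum polymorphic sites for a callable block
#'   (default 10).
#' @param k neighbourhood size passed to [classifyIntrogression()].
#' @return an [IntrogressionScan-class].
#' @export
scanBlocks <- function(gm, grid, pairs, minSnps = 10L, k = NULL) {
  gmap <- groupMap(gm)
  if (is.null(gmap)) stop("genotype matrix needs a group map")
  stopifnot(all(c("donor", "recipient") %in% names(pairs)))
  pairs <- as.data.frame(pairs)[, c("donor", "recipient")]
  dos <- dosage(gm)
  blockOf <- siteBlocks(gm, grid)
  nb <- length(grid)
  noCall <- logical(nb)
  counts <- matrix(NA_real_, nrow(pairs), nb)
  calls <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    recips <- sort(names(gmap)[gmap == pairs$recipient[p]])
    calls[[p]] <- matrix(NA, length(recips), nb,
                         dimnames = list(recips, NULL))
  }
  names(calls) <- .pairKey(pairs$donor, pairs$recipient)
  for (b in seq_len(nb)) {
    idx <- which(blockOf == b)
    sub <- dos[idx, , drop = FALSE]
    poly <- 0L
    if (length(idx)) {
      mn <- suppressWarnings(apply(sub, 1L, min, na.rm = TRUE))
      mx <- suppressWarnings(apply(sub, 1L, max, na.rm = TRUE))
      poly <- sum(is.finite(mn) & is.finite(mx) & mx > mn)
    }
    if (poly < minSnps) { noCall[b] <- TRUE; next }
    d <- tryCatch(alleleSharingDistance(gm[idx, ]),
                  introScan_no_shared_sites = function(e) NULL)
    if (is.null(d)) { noCall[b] <- TRUE; next }
    tr <- njTree(d)
    for (p in seq_len(nrow(pairs))) {
      res <- classifyIntrogression(tr, gmap, recipient = pairs$recipient[p],
                                   donor = pairs$donor[p], k = k)
      cm <- calls[[p]]
      cm[, b] <- rownames(cm) %in% res$accession
      calls[[p]] <- cm
      counts[p, b] <- nrow(res)
    }
  }
  new("IntrogressionScan", grid = grid, pairs = pairs, calls = calls,
      counts = counts, noCall = noCall, minSnps = as.integer(minSnps),
      groups = gmap)
}

## merge adjacent significant blocks of one grid into regions
.mergeBlocks <- function(grid, which) {
  if (!length(which)) return(GRanges(seqlengths = seqlengths(grid)))
  reduce(granges(grid[sort(which)]), min.gapwidth = 1L)
}

#' Permutation-based significant introgression regions
#'
#' Builds a genome-wide null by independently permuting, for every
#' recipient accession, its per-block call vector across all called
#' blocks — each accession's genome-wide introgression load is preserved
#' exactly.  The test statistic is the per-block introgressed-accession
#' count; the genome-wide threshold is the (1 - alpha) quantile of the
#' maximum per-permutation count, giving family-wise error control.
#' Blocks whose observed count strictly exceeds the threshold are
#' significant; adjacent significant blocks are merged into regions.
#'
#' @param scan an [IntrogressionScan-class].
#' @param donor,recipient the ordered pair to test.
#' @param nPerm number of permutations (>= 100).
#' @param alpha family-wise error level; must be >= 1/nPerm.
#' @param seed integer seed for the permutations.
#' @return list with `regions` (`GRanges`), `significantBlocks` (integer
#'   indices into the grid), `threshold` (the null quantile) and
#'   `maxNull` (the permutation max-count distribution).
#' @export
permutationSignificantRegions <- function(scan, donor, recipient,
                                          nPerm = 1000L, alpha = 0.05,
                                          seed = 1L) {
  if (nPerm < 100L) stop("use at least 100 permutations")
  if (alpha < 1 / nPerm)
    stop("alpha below the permutation resolution 1/nPerm")
  cm <- callMatrix(scan, donor, recipient)
  calledBlocks <- which(!scan@noCall)
  if (!length(calledBlocks)) stop("no called block in this scan")
  cmc <- cm[, calledBlocks, drop = FALSE]
  obs <- colSums(cmc)
  tot <- rowSums(cmc)
  m <- length(calledBlocks)
  set.seed(seed)
  maxNull <- vapply(seq_len(nPerm), function(i) {
    cnt <- integer(m)
    for (t in tot[tot > 0]) {
      idx <- sample.int(m, t)
      cnt[idx] <- cnt[idx] + 1L
    }
    max(cnt)
  }, numeric(1))
  threshold <- stats::quantile(maxNull, 1 - alpha, type = 1, names = FALSE)
  sig <- calledBlocks[obs > threshold]
  list(regions = .mergeBlocks(scan@grid, sig),
       significantBlocks = sig, threshold = threshold, maxNull = maxNull)
}

#' Correlation between the two directions of introgression
#'
#' Pearson correlation, OLS slope and a two-sided p-value between the
#' per-block counts of donor -> recipient and recipient -> donor calls,
#' over blocks called in both directions.  Under unidirectional gene flow
#' the two tracks should be uncorrelated.
#'
#' @param scan an [IntrogressionScan-class] containing both directions.
#' @param groupA,groupB the two groups.
#' @return list with `r`, `slope`, `p`, `n` (blocks used).  With zero
#'   variance in either track the correlation is undefined and `r`, `p`
#'   are `NA` with a message in `$note`.
#' @export
directionCorrelation <- function(scan, groupA, groupB) {
  x <- callCounts(scan, donor = groupA, recipient = groupB)
  y <- callCounts(scan, donor = groupB, recipient = groupA)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 jointly called blocks")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, slope = NA_real_, p = NA_real_, n = sum(ok),
                note = "zero variance in a direction track"))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate),
       slope = unname(stats::coef(stats::lm(y ~ x))[2L]),
       p = ct$p.value, n = sum(ok))
}

#' Chi-square enrichment of introgression in annotated regions
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2 x 2 table
#' of (introgression calls, non-calls) x (blocks overlapping the
#' annotation, other blocks), where a block overlaps when any base pair
#' intersects.  Also callable on a prebuilt 2 x 2 matrix.
#'
#' @param x an [IntrogressionScan-class], or a 2 x 2 numeric matrix of
#'   observed counts.
#' @param donor,recipient pair to test (scan input only).
#' @param annotation `GRanges` of annotated intervals (e.g. high-repeat
#'   regions), scan input only.
#' @return list with `statistic`, `p`, `table`.  A zero margin leaves the
#'   test undefined: `statistic`/`p` are `NA` with a `$note`.
#' @export
enrichmentTest <- function(x, donor = NULL, recipient = NULL,
                           annotation = NULL) {
  if (is.matrix(x)) {
    tbl <- x
  } else {
    stopifnot(is(x, "IntrogressionScan"), !is.null(annotation))
    called <- which(!x@noCall)
    cnt <- callCounts(x, donor, recipient)[called]
    nrecip <- nrow(callMatrix(x, donor, recipient))
    inAnn <- overlapsAny(x@grid[called], annotation)
    tbl <- rbind(calls = c(sum(cnt[inAnn]), sum(cnt[!inAnn])),
                 noncalls = c(sum(nrecip - cnt[inAnn]),
                              sum(nrecip - cnt[!inAnn])))
    colnames(tbl) <- c("annotated", "other")
  }
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0))
    return(list(statistic = NA_real_, p = NA_real_, table = tbl,
                note = "zero margin: test undefined"))
  ct <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value, table = tbl)
}
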