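#' Per-site allele frequencies for the four D-statistic roles
#'
#' For each role population (P1, P2, P3, O) the ALT-allele frequency at a
#' site is the dosage sum over its members divided by twice the number of
#' non-missing genotypes.  A site is usable only when all four roles have
#' at least one non-missing genotype.
#'
#' @param gm a [GenotypeMatrix-class] with a group map.
#' @param roles named character vector `c(P1 = ..., P2 = ..., P3 = ...,
#'   O = ...)` mapping roles to group names (four distinct, non-empty
#'   groups; the motivating design sets tropical japonica as P1,
#'   temperate japonica as P2, indica as P3 and African cultivated rice
#'   as the outgroup O).
#' @param polarizeByOutgroup when `TRUE`, sites where the outgroup ALT
#'   frequency exceeds 0.5 are flipped (p -> 1 - p in all four roles) so
#'   the outgroup major allele plays the ancestral role; default `FALSE`
#'   (ALT dosage used directly).
#' @return list with `p` (sites x 4 matrix, columns P1, P2, P3, O),
#'   `nObs` (non-missing genotype counts) and `usable` (logical per
#'   site).
#' @export
groupAlleleFrequencies <- function(gm, roles, polarizeByOutgroup = FALSE) {
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(roles)))
  roles <- roles[c("P1", "P2", "P3", "O")]
  if (anyDuplicated(roles)) stop("the four role groups must be distinct")
  gmap <- groupMap(gm)
  if (is.null(gmap)) stop("genotype matrix needs a group map")
  dos <- dosage(gm)
  p <- matrix(NA_real_, nrow(dos), 4L,
              dimnames = list(NULL, names(roles)))
  nObs <- matrix(0L, nrow(dos), 4L, dimnames = dimnames(p))
  for (r in names(roles)) {
    members <- names(gmap)[gmap == roles[[r]]]
    if (!length(members)) stop("role ", r, " maps to an empty group")
    sub <- dos[, members, drop = FALSE]
    n <- rowSums(!is.na(sub))
    p[, r] <- ifelse(n > 0, rowSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
    nObs[, r] <- n
  }
  usable <- rowSums(nObs > 0) == 4L
  if (polarizeByOutgroup) {
    flip <- usable & p[, "O"] > 0.5
    p[flip, ] <- 1 - p[flip, ]
  }
  list(p = p, nObs = nObs, usable = usable)
}

#' ABBA-BABA D statistic from allele frequencies
#'
#' With per-site frequencies p1, p2, p3, p4 in the populations P1, P2, P3
#' and the outgroup O,
#' `abba = sum (1-p1) p2 p3 (1-p4)`, `baba = sum p1 (1-p2) p3 (1-p4)` and
#' `D = (abba - baba) / (abba + baba)`.  D > 0 marks excess P2-P3
#' sharing, D < 0 excess P1-P3 sharing; a zero denominator leaves D
#' undefined (`NA`, never coerced to 0).  Sites with p3 = 0 or p4 = 1
#' contribute nothing to either sum.
#'
#' @param p1,p2,p3,p4 numeric vectors of per-site frequencies in \[0,1\]
#'   (equal length).
#' @return list with `abba`, `baba`, `D`, `nSites`.
#' @examples
#' dStatistic(0, 1, 1, 0)$D   #  1, pure ABBA
#' dStatistic(1, 0, 1, 0)$D   # -1, pure BABA
#' @export
dStatistic <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == length(p2), length(p1) == length(p3),
            length(p1) == length(p4))
  abba <- sum((1 - p1) * p2 * p3 * (1 - p4))
  baba <- sum(p1 * (1 - p2) * p3 * (1 - p4))
  den <- abba + baba
  list(abba = abba, baba = baba,
       D = if (den > 0) (abba - baba) / den else NA_real_,
       nSites = length(p1))
}

## per-site ABBA/BABA terms for jackknifing
.abbaBabaTerms <- function(p) {
  list(a = (1 - p[, "P1"]) * p[, "P2"] * p[, "P3"] * (1 - p[, "O"]),
       b = p[, "P1"] * (1 - p[, "P2"]) * p[, "P3"] * (1 - p[, "O"]))
}

## delete-one-group jackknife Z for a ratio statistic D = (A-B)/(A+B)
## given per-group sums of the a and b terms
.jackknifeZ <- function(aSums, bSums) {
  A <- sum(aSums); B <- sum(bSums)
  if (A + B <= 0) return(NA_real_)
  D <- (A - B) / (A + B)
  m <- length(aSums)
  if (m < 10L) return(NA_real_)
  num <- (A - aSums) - (B - bSums)
  den <- (A - aSums) + (B - bSums)
  ok <- den > 0
  if (sum(ok) < 10L) return(NA_real_)
  Dj <- num[ok] / den[ok]
  mm <- sum(ok)
  u <- (Dj - mean(Dj))^2
  se <- sqrt((mm - 1) / mm * sum(u))
  if (se == 0) return(if (D >= 0) Inf else -Inf)
  t <- D / se
  # A few high-weight sites can dominate a window, making the jackknife
  # SE itself noisy and D/SE heavier-tailed than normal.  Calibrate via a
  # Student-t reference with Satterthwaite effective degrees of freedom
  # from the jackknife deviations, mapped back to the normal scale.
  dfEff <- sum(u)^2 / sum(u^2)
  logp <- stats::pt(abs(t), df = dfEff, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  sign(t) * z
}

#' Windowed D-statistic scan with jackknife Z scores
#'
#' Computes the ABBA-BABA D statistic in every block of the grid (the
#' 500 kb tree-scan grid by default, enabling a direct overlap comparison
#' between the two detection methods).  The per-window Z score is a
#' delete-one-site jackknife within the window (sites are treated as
#' exchangeable; at least 10 usable sites are required, otherwise `NA`);
#' an SE of exactly zero is flagged as `Inf` with the sign of D, never as
#' a number.
#'
#' @param gm a [GenotypeMatrix-class] with a group map.
#' @param grid block `GRanges` from [sliceBlocks()].
#' @param roles role map, see [groupAlleleFrequencies()].
#' @param polarizeByOutgroup see [groupAlleleFrequencies()].
#' @return data.frame per window: `chrom`, `start`, `end`, `block`,
#'   `n_sites`, `abba`, `baba`, `D`, `Z`.
#' @export
dstatScan <- function(gm, grid, roles, polarizeByOutgroup = FALSE) {
  fr <- groupAlleleFrequencies(gm, roles, polarizeByOutgroup)
  blockOf <- siteBlocks(gm, grid)
  terms <- .abbaBabaTerms(fr$p)
  out <- data.frame(chrom = as.character(seqnames(grid)),
                    start = start(grid), end = end(grid),
                    block = seq_along(grid),
                    n_sites = 0L, abba = 0, baba = 0,
                    D = NA_real_, Z = NA_real_)
  for (b in seq_along(grid)) {
    idx <- which(blockOf == b & fr$usable)
    if (!length(idx)) next
    a <- terms$a[idx]; bb <- terms$b[idx]
    A <- sum(a); B <- sum(bb)
    out$n_sites[b] <- length(idx)
    out$abba[b] <- A
    out$baba[b] <- B
    if (A + B > 0) out$D[b] <- (A - B) / (A + B)
    out$Z[b] <- .jackknifeZ(a, bb)
  }
  out
}

#' Genome-wide D with block jackknife
#'
#' One D over all usable sites, with a standard error from a
#' delete-one-block jackknife over groups of `windowsPerBlock` consecutive
#' grid windows (default 5, i.e. 2.5 Mb on the 500 kb grid, damping local
#' correlation).
#'
#' @inheritParams dstatScan
#' @param windowsPerBlock consecutive windows pooled into one jackknife
#'   block.
#' @return list with `D`, `Z`, `se`, `abba`, `baba`, `nSites`,
#'   `nJackknifeBlocks`.
#' @export
genomeDstat <- function(gm, grid, roles, windowsPerBlock = 5L,
                        polarizeByOutgroup = FALSE) {
  fr <- groupAlleleFrequencies(gm, roles, polarizeByOutgroup)
  blockOf <- siteBlocks(gm, grid)
  terms <- .abbaBabaTerms(fr$p)
  usable <- fr$usable & !is.na(blockOf)
  jb <- paste(as.character(seqnames(grid))[blockOf[usable]],
              (blockOf[usable] - 1L) %/% as.integer(windowsPerBlock))
  aSums <- tapply(terms$a[usable], jb, sum)
  bSums <- tapply(terms$b[usable], jb, sum)
  A <- sum(aSums); B <- sum(bSums)
  z <- .jackknifeZ(as.numeric(aSums), as.numeric(bSums))
  D <- if (A + B > 0) (A - B) / (A + B) else NA_real_
  list(D = D, Z = z,
       se = if (!is.na(z) && is.finite(z) && z != 0) D / z else NA_real_,
       abba = A, baba = B, nSites = sum(usable),
       nJackknifeBlocks = length(aSums))
}

#' Call D-statistic peaks
#'
#' Windows with |Z| at or above the threshold are merged when adjacent;
#' each region is annotated with the direction implied by the sign of D
#' (negative: excess P1-P3 sharing, e.g. donor -> P1 introgression under
#' the motivating role assignment).
#'
#' @param windows data.frame from [dstatScan()].
#' @param grid the matching block `GRanges`.
#' @param zThreshold |Z| threshold, default 3.
#' @return `GRanges` of peak regions with metadata columns `direction`
#'   (`"P1-P3"` or `"P2-P3"`) and `maxAbsZ`.
#' @export
callPeaks <- function(windows, grid, zThreshold = 3) {
  pass <- which(!is.na(windows$Z) & abs(windows$Z) >= zThreshold)
  if (!length(pass))
    return(GRanges(seqlengths = seqlengths(grid)))
  regions <- .mergeBlocks(grid, pass)
  hits <- findOverlaps(grid[pass], regions, select = "first")
  direction <- vapply(seq_along(regions), function(i) {
    dmean <- mean(windows$D[pass[hits == i]], na.rm = TRUE)
    if (dmean < 0) "P1-P3" else "P2-P3"
  }, character(1))
  maxAbsZ <- vapply(seq_along(regions), function(i)
    max(abs(windows$Z[pass[hits == i]])), numeric(1))
  mcols(regions)$direction <- direction
  mcols(regions)$maxAbsZ <- maxAbsZ
  regions
}
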