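#' Site filtering by minor allele frequency and missing rate
#'
#' Keeps sites whose minor allele frequency, computed over non-missing
#' alleles only, is strictly greater than `mafMin`, and whose missing
#' genotype fraction is strictly smaller than `missingMax`.  Both
#' inequalities are strict by design (a site at MAF exactly 5% or
#' missingness exactly 40% is dropped); sites with all genotypes missing
#' have no defined MAF and are dropped.  Filtering is idempotent.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param mafMin minimum (exclusive) minor allele frequency, default 0.05.
#' @param missingMax maximum (exclusive) missing fraction, default 0.40.
#' @return the filtered [GenotypeMatrix-class].
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:2, width = 1))
#' g <- matrix(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L), 2,
#'             dimnames = list(NULL, paste0("a", 1:4)))
#' filterSites(GenotypeMatrix(g, sites))   # site 1 is monomorphic
#' @export
filterSites <- function(gm, mafMin = 0.05, missingMax = 0.40) {
  stopifnot(mafMin >= 0, mafMin <= 0.5, missingMax >= 0, missingMax <= 1)
  d <- dosage(gm)
  nonmiss <- rowSums(!is.na(d))
  altsum <- rowSums(d, na.rm = TRUE)
  p <- ifelse(nonmiss > 0, altsum / (2 * nonmiss), NA_real_)
  maf <- pmin(p, 1 - p)
  missFrac <- 1 - nonmiss / ncol(d)
  keep <- !is.na(maf) & maf > mafMin & missFrac < missingMax
  gm[keep, ]
}

#' Partition the genome into fixed-width non-overlapping blocks
#'
#' Blocks tile each chromosome from its first base in `blockSizeBp` steps;
#' the last block is truncated at the chromosome end.  A site at 1-based
#' position p belongs to block `floor((p - 1) / blockSizeBp)` of its
#' chromosome.  The default 500 kb is the tree/D scan grid; admixture
#' mapping uses 200 kb.
#'
#' @param x a [GenotypeMatrix-class], a `GRanges` of sites, or `NULL`
#'   (then `chromLengths` must be given).
#' @param blockSizeBp block width in bp.
#' @param chromLengths named numeric of chromosome lengths; defaults to
#'   the `seqlengths` of `x` and falls back to the last site position.
#' @return a `GRanges` grid, one range per block in genome order, with
#'   metadata column `block` (ordinal index, 1-based).
#' @examples
#' sliceBlocks(NULL, 5e5, c(chr1 = 1.2e6))
#' @export
sliceBlocks <- function(x, blockSizeBp = 5e5, chromLengths = NULL) {
  stopifnot(blockSizeBp > 0)
  if (is.null(chromLengths)) {
    sites <- if (is(x, "GenotypeMatrix")) siteRanges(x) else x
    if (is.null(sites)) stop("need 'x' or 'chromLengths'")
    sl <- seqlengths(sites)
    if (!length(sl) || any(is.na(sl)))
      sl <- vapply(split(end(sites), as.character(seqnames(sites))), max,
                   numeric(1))
    chromLengths <- sl
  }
  pieces <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    starts <- seq(1, len, by = blockSizeBp)
    GRanges(ch, IRanges(starts, pmin(starts + blockSizeBp - 1, len)))
  })
  grid <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlevels(grid) <- names(chromLengths)
  seqlengths(grid) <- chromLengths
  mcols(grid)$block <- seq_along(grid)
  grid
}

#' Map sites onto a block grid
#'
#' @param sites a `GRanges` of width-1 sites (or a
#'   [GenotypeMatrix-class]).
#' @param grid block grid from [sliceBlocks()].
#' @return integer vector: for each site, the 1-based index of its block
#'   in `grid` (`NA` if outside the grid).
#' @export
siteBlocks <- function(sites, grid) {
  if (is(sites, "GenotypeMatrix")) sites <- siteRanges(sites)
  hits <- findOverlaps(sites, grid, select = "first")
  as.integer(hits)
}
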