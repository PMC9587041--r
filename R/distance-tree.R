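#' Allele-sharing distance between accessions
#'
#' d(i, j) = sum_s |g_is - g_js| / (2 * n_ij), summed over the sites where
#' both accessions are genotyped (n_ij of them).  This is the standard
#' dosage dissimilarity in \[0, 1\]; its complement 1 - d is the kinship
#' reported alongside.  Computed by cross-products of dosage indicator
#' matrices, so it is exact and fast even with missing data.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param block optional `GRanges`; when given, only sites overlapping it
#'   are used.
#' @return symmetric numeric matrix with zero diagonal and attributes
#'   `nSites` (pairwise non-missing site counts) and `kinship` (1 - d).
#'   A pair of accessions with no jointly genotyped site is an error
#'   (condition class `introScan_no_shared_sites`), which the block scan
#'   converts into a NO_CALL block.
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:3, width = 1))
#' g <- cbind(a = c(0L, 2L, 2L), b = c(2L, 2L, 0L))
#' alleleSharingDistance(GenotypeMatrix(g, sites))["a", "b"]  # 2/3
#' @export
alleleSharingDistance <- function(gm, block = NULL) {
  d <- dosage(gm)
  if (!is.null(block))
    d <- d[overlapsAny(siteRanges(gm), block), , drop = FALSE]
  ok <- !is.na(d)
  a0 <- (d == 0L & ok); a0[is.na(a0)] <- FALSE; storage.mode(a0) <- "double"
  a1 <- (d == 1L & ok); a1[is.na(a1)] <- FALSE; storage.mode(a1) <- "double"
  a2 <- (d == 2L & ok); a2[is.na(a2)] <- FALSE; storage.mode(a2) <- "double"
  m <- ok; storage.mode(m) <- "double"
  n01 <- crossprod(a0, a1)
  n12 <- crossprod(a1, a2)
  n02 <- crossprod(a0, a2)
  num <- n01 + t(n01) + n12 + t(n12) + 2 * (n02 + t(n02))
  nshared <- crossprod(m)
  off <- upper.tri(nshared) | lower.tri(nshared)
  if (any(nshared[off] == 0))
    stop(structure(
      list(message = "accession pair with no jointly genotyped site",
           call = sys.call()),
      class = c("introScan_no_shared_sites", "error", "condition")))
  dist <- num / (2 * nshared)
  diag(dist) <- 0
  dimnames(dist) <- list(colnames(d), colnames(d))
  attr(dist, "nSites") <- nshared
  attr(dist, "kinship") <- 1 - dist
  dist
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`) followed by phylip-style
#' cleanup of negative branch lengths: each negative branch is clamped to
#' zero and its deficit transferred to the sister branch, so patristic
#' distances through the joined node are preserved as far as possible.
#'
#' @param d symmetric distance matrix with row/column names (e.g. from
#'   [alleleSharingDistance()]), or a `dist`.
#' @return an unrooted `phylo` tree.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 leaves")
  tr <- ape::nj(d)
  for (pass in seq_len(length(tr$edge.length))) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1L]
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sib))
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Patristic (tree-path) distances between leaves
#'
#' @param tree a `phylo`.
#' @return symmetric matrix of summed branch lengths between leaf pairs.
#' @export
patristicDistance <- function(tree) stats::cophenetic(tree)
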