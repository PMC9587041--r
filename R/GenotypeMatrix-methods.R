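#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix, sites x accessions, of ALT-allele dosages
#'   in 0:2 with `NA` for missing genotypes.  Column names are accession
#'   ids (required, unique); row order must follow `sites`.
#' @param sites `GRanges` of width-1 SNP positions (1-based, as in VCF),
#'   sorted, with optional `ref`/`alt` metadata columns (defaulted to
#'   `"A"`/`"C"` when absent — the dosage codes, not the letters, carry the
#'   information).
#' @param groups optional named character vector or factor mapping
#'   accession id to group name; stored in `colData(x)$group`.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1))
#' g <- matrix(c(0L, 2L, 1L, NA), 2, dimnames = list(NULL, c("a1", "b1")))
#' gm <- GenotypeMatrix(g, sites, groups = c(a1 = "A", b1 = "B"))
#' dosage(gm)
#' @export
GenotypeMatrix <- function(dosage, sites, groups = NULL) {
  if (!is.matrix(dosage))
    stop("'dosage' must be a matrix (sites x accessions)")
  if (is.null(colnames(dosage)))
    stop("'dosage' must carry accession ids as column names")
  storage.mode(dosage) <- "integer"
  if (!is(sites, "GRanges"))
    stop("'sites' must be a GRanges")
  if (length(sites) != nrow(dosage))
    stop("nrow(dosage) must equal length(sites)")
  if (is.null(mcols(sites)$ref)) mcols(sites)$ref <- "A"
  if (is.null(mcols(sites)$alt)) mcols(sites)$alt <- "C"
  cd <- DataFrame(row.names = colnames(dosage))
  if (!is.null(groups)) {
    groups <- as.character(groups)[match(colnames(dosage), names(groups))] |>
      stats::setNames(colnames(dosage))
    if (anyNA(groups))
      stop("every accession must be present in 'groups'")
    cd$group <- unname(groups)
  }
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowRanges = sites, colData = cd)
  new("GenotypeMatrix", se)
}

#' @rdname GenotypeMatrix
#' @param x,object a `GenotypeMatrix`.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeMatrix
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) assay(x, "dosage"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("accessionIds", function(x) standardGeneric("accessionIds"))

#' @rdname GenotypeMatrix
#' @export
setMethod("accessionIds", "GenotypeMatrix", function(x) colnames(x))

#' @rdname GenotypeMatrix
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' @rdname GenotypeMatrix
#' @export
setMethod("siteRanges", "GenotypeMatrix", function(x) rowRanges(x))

#' @rdname GenotypeMatrix
#' @export
setGeneric("groupMap", function(x) standardGeneric("groupMap"))

#' @rdname GenotypeMatrix
#' @export
setMethod("groupMap", "GenotypeMatrix", function(x) {
  g <- colData(x)$group
  if (is.null(g)) return(NULL)
  stats::setNames(as.character(g), colnames(x))
})

#' @rdname GenotypeMatrix
#' @param value named character vector, accession -> group.
#' @export
setGeneric("groupMap<-", function(x, value) standardGeneric("groupMap<-"))

#' @rdname GenotypeMatrix
#' @export
setMethod("groupMap<-", "GenotypeMatrix", function(x, value) {
  v <- as.character(value)[match(colnames(x), names(value))]
  if (anyNA(v))
    stop("every accession must be present in the replacement group map")
  colData(x)$group <- v
  validObject(x)
  x
})

#' Accessions belonging to one group
#' @param x a `GenotypeMatrix`.
#' @param group group name.
#' @return character vector of accession ids.
#' @export
groupMembers <- function(x, group) {
  gm <- groupMap(x)
  if (is.null(gm)) stop("no group map attached to this GenotypeMatrix")
  names(gm)[gm == group]
}

setMethod("show", "GenotypeMatrix", function(object) {
  d <- assay(object, "dosage")
  miss <- if (length(d)) mean(is.na(d)) else 0
  cat(sprintf("GenotypeMatrix: %d sites x %d accessions (%.1f%% missing)\n",
              nrow(object), ncol(object), 100 * miss))
  g <- groupMap(object)
  if (!is.null(g)) {
    tab <- table(g)
    cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  sl <- seqlengths(object)
  if (length(sl) && !all(is.na(sl)))
    cat("chromosomes:", paste(seqlevels(object), collapse = ", "), "\n")
})

setMethod("show", "IntrogressionScan", function(object) {
  cat(sprintf("IntrogressionScan: %d blocks (%d NO_CALL), %d group pair(s)\n",
              length(object@grid), sum(object@noCall), nrow(object@pairs)))
  for (i in seq_len(nrow(object@pairs))) {
    cnt <- object@counts[i, ]
    cat(sprintf("  %s -> %s: %d calls over %d called blocks\n",
                object@pairs$donor[i], object@pairs$recipient[i],
                sum(cnt, na.rm = TRUE), sum(!is.na(cnt))))
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d groups, %d chrom x %g bp x %d sites, seed %d\n",
    length(object@nPerGroup), object@nChromosomes, object@chromLengthBp,
    object@nSitesPerChrom, object@seed))
  cat("  groups:", paste(sprintf("%s n=%d F=%.3g", names(object@nPerGroup),
                                 object@nPerGroup,
                                 object@fstBranch[names(object@nPerGroup)]),
                         collapse = "; "), "\n")
})

setMethod("show", "SimulatedDataset", function(object) {
  show(object@genotypes)
  cat(sprintf("planted tracts: %d; phenotype: %s\n",
              length(object@truthTracts),
              if (length(object@phenotype)) "yes" else "no"))
})

#' Accessors for simulated datasets
#'
#' @param x a [SimulatedDataset-class].
#' @return `genotypes()` the [GenotypeMatrix-class]; `truthTracts()` the
#'   planted-tract `GRanges`; `phenotype()` the named phenotype vector (or
#'   `NULL`); `causalBlock()` the causal block `GRanges`.
#' @name SimulatedDataset-accessors
NULL

#' @rdname SimulatedDataset-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname SimulatedDataset-accessors
#' @export
setMethod("genotypes", "SimulatedDataset", function(x) x@genotypes)

#' @rdname SimulatedDataset-accessors
#' @export
setGeneric("truthTracts", function(x) standardGeneric("truthTracts"))

#' @rdname SimulatedDataset-accessors
#' @export
setMethod("truthTracts", "SimulatedDataset", function(x) x@truthTracts)

#' @rdname SimulatedDataset-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname SimulatedDataset-accessors
#' @export
setMethod("phenotype", "SimulatedDataset", function(x)
  if (length(x@phenotype)) x@phenotype else NULL)

#' @rdname SimulatedDataset-accessors
#' @export
setGeneric("causalBlock", function(x) standardGeneric("causalBlock"))

#' @rdname SimulatedDataset-accessors
#' @export
setMethod("causalBlock", "SimulatedDataset", function(x) x@causalBlock)

#' Accessors for introgression scans
#'
#' @param x an [IntrogressionScan-class].
#' @param donor,recipient group names selecting one ordered pair.
#' @return `blockGrid()` the block `GRanges`; `callCounts()` the per-block
#'   introgressed-accession counts for one pair (`NA` on NO_CALL blocks);
#'   `callMatrix()` the logical recipient-accession x block call matrix;
#'   `noCallBlocks()` the logical NO_CALL mask.
#' @name IntrogressionScan-accessors
NULL

.pairKey <- function(donor, recipient) paste0(donor, "->", recipient)

.pairIndex <- function(scan, donor, recipient) {
  i <- which(scan@pairs$donor == donor & scan@pairs$recipient == recipient)
  if (!length(i))
    stop("pair ", .pairKey(donor, recipient), " not present in this scan")
  i
}

#' @rdname IntrogressionScan-accessors
#' @export
setGeneric("blockGrid", function(x) standardGeneric("blockGrid"))

#' @rdname IntrogressionScan-accessors
#' @export
setMethod("blockGrid", "IntrogressionScan", function(x) x@grid)

#' @rdname IntrogressionScan-accessors
#' @export
callCounts <- function(x, donor, recipient)
  x@counts[.pairIndex(x, donor, recipient), ]

#' @rdname IntrogressionScan-accessors
#' @export
callMatrix <- function(x, donor, recipient)
  x@calls[[.pairIndex(x, donor, recipient)]]

#' @rdname IntrogressionScan-accessors
#' @export
noCallBlocks <- function(x) x@noCall
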