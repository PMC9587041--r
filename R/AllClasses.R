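#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps reduce granges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges colData rowRanges<- colData<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames<-
NULL

#' Diploid SNP genotypes with site coordinates and group labels
#'
#' `GenotypeMatrix` is the package's universal substrate: a
#' [SummarizedExperiment::RangedSummarizedExperiment] whose single assay
#' `"dosage"` holds ALT-allele dosage codes (0, 1, 2; `NA` = missing) for
#' biallelic SNPs.  Rows are sites (a `GRanges` with `ref`/`alt` metadata
#' columns, 1-based positions as in VCF), columns are accessions, and the
#' optional `group` column of `colData` carries the subpopulation label of
#' each accession (e.g. indica, temperate japonica, tropical japonica,
#' outgroup).
#'
#' @slot .Data inherited `RangedSummarizedExperiment` structure.
#' @seealso [GenotypeMatrix()], [readGenotypeVcf()], [filterSites()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- NULL
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosage codes must be 0, 1, 2 or NA")
  }
  ids <- colnames(object)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "accession ids (colnames) must be present and unique")
  rr <- rowRanges(object)
  if (length(rr)) {
    if (!all(c("ref", "alt") %in% colnames(mcols(rr))))
      msg <- c(msg, "site ranges need 'ref' and 'alt' metadata columns")
    o <- order(rr)
    if (!identical(o, seq_along(rr)))
      msg <- c(msg, "sites must be sorted by (chrom, pos)")
    if (any(duplicated(paste(seqnames(rr), start(rr)))))
      msg <- c(msg, "site positions must be unique within a chromosome")
  }
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the Balding-Nichols population simulator
#'
#' Describes a multi-group diploid SNP simulation with nested divergence:
#' ancestral allele frequencies are Beta(`ancestralBeta`) draws, each branch
#' or group frequency is a Balding-Nichols draw
#' Beta(p(1-F)/F, (1-p)(1-F)/F) around its parent's frequency, with the
#' drift parameter F taken from `fstBranch` (groups) or `branchFst`
#' (internal branches named in `groupParent`).  Groups whose name is absent
#' from `groupParent` hang directly off the root.
#'
#' @slot nPerGroup named integer, accessions per group (>= 2 each).
#' @slot nChromosomes,chromLengthBp,nSitesPerChrom genome dimensions.
#' @slot fstBranch named numeric in (0,1), per-group drift F.
#' @slot branchFst named numeric in (0,1), drift F of internal branches.
#' @slot groupParent named character mapping group -> internal branch.
#' @slot ancestralBeta length-2 shape parameters of the ancestral Beta.
#' @slot missingRate per-entry missing-genotype probability in [0,1).
#' @slot seed integer random seed; identical config => identical output.
#' @seealso [simulationConfig()], [simulateDataset()]
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nPerGroup = "integer",
  nChromosomes = "integer",
  chromLengthBp = "numeric",
  nSitesPerChrom = "integer",
  fstBranch = "numeric",
  branchFst = "numeric",
  groupParent = "character",
  ancestralBeta = "numeric",
  missingRate = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  n <- object@nPerGroup
  if (!length(n) || is.null(names(n)) || any(names(n) == ""))
    msg <- c(msg, "nPerGroup must be a named vector")
  if (any(n < 2L))
    msg <- c(msg, "each group needs at least 2 accessions")
  f <- c(object@fstBranch, object@branchFst)
  if (any(f <= 0 | f >= 1))
    msg <- c(msg, "drift parameters F must lie strictly in (0,1)")
  if (!all(names(n) %in% names(object@fstBranch)))
    msg <- c(msg, "every group needs an entry in fstBranch")
  if (length(object@groupParent) &&
      !all(object@groupParent %in% names(object@branchFst)))
    msg <- c(msg, "groupParent values must name branches in branchFst")
  if (object@nChromosomes < 1L || object@nSitesPerChrom < 1L)
    msg <- c(msg, "need >= 1 chromosome and >= 1 site per chromosome")
  if (object@nSitesPerChrom > object@chromLengthBp)
    msg <- c(msg, "more sites than base pairs on a chromosome")
  if (length(object@ancestralBeta) != 2L || any(object@ancestralBeta <= 0))
    msg <- c(msg, "ancestralBeta must be two positive shape parameters")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0,1)")
  if (is.null(msg)) TRUE else msg
})

#' Simulated dataset with ground truth
#'
#' Bundles simulated genotypes with the planted-introgression truth needed
#' to benchmark the detectors: the tract table (a `GRanges` with donor
#' group, recipient group and carrier accessions), and optionally a
#' quantitative phenotype driven by local ancestry at a causal block.
#'
#' @slot genotypes a [GenotypeMatrix-class].
#' @slot truthTracts `GRanges` of planted tracts; metadata columns
#'   `donor_group`, `recipient_group`, `carriers` (comma-joined accession
#'   ids) and `n_sites`.
#' @slot phenotype named numeric (length 0 when absent).
#' @slot causalBlock `GRanges` of length 0 or 1.
#' @slot config the generating [SimulationConfig-class].
#' @seealso [simulateDataset()], [simulatePhenotype()]
#' @exportClass SimulatedDataset
setClass("SimulatedDataset", representation(
  genotypes = "GenotypeMatrix",
  truthTracts = "GRanges",
  phenotype = "numeric",
  causalBlock = "GRanges",
  config = "SimulationConfig"
))

setValidity("SimulatedDataset", function(object) {
  msg <- NULL
  if (length(object@phenotype) &&
      is.null(names(object@phenotype)))
    msg <- c(msg, "phenotype must be named by accession")
  if (length(object@phenotype) && length(object@causalBlock) == 0L)
    msg <- c(msg, "phenotype requires a causalBlock")
  if (length(object@causalBlock) > 1L)
    msg <- c(msg, "at most one causal block")
  if (is.null(msg)) TRUE else msg
})

#' Result of the block-wise phylogenetic-tree introgression scan
#'
#' Holds, for every ordered donor->recipient group pair, the per-accession
#' introgression calls on a fixed block grid, together with per-block call
#' counts and the NO_CALL mask for blocks with too few polymorphic sites.
#'
#' @slot grid the block `GRanges` (one range per block, genome order).
#' @slot pairs data.frame with columns `donor`, `recipient`.
#' @slot calls named list (one element per pair, `"donor->recipient"`) of
#'   logical matrices, recipient accessions x blocks.
#' @slot counts numeric matrix, pairs x blocks, of introgressed-accession
#'   counts (`NA` on NO_CALL blocks).
#' @slot noCall logical per block: too few polymorphic sites to build a
#'   tree (or a pair of accessions with no shared genotyped site).
#' @slot minSnps the polymorphic-site threshold used.
#' @slot groups named character, accession -> whole-genome group.
#' @seealso [scanBlocks()], [permutationSignificantRegions()]
#' @exportClass IntrogressionScan
setClass("IntrogressionScan", representation(
  grid = "GRanges",
  pairs = "data.frame",
  calls = "list",
  counts = "matrix",
  noCall = "logical",
  minSnps = "integer",
  groups = "character"
))

setValidity("IntrogressionScan", function(object) {
  msg <- NULL
  nb <- length(object@grid)
  if (ncol(object@counts) != nb || length(object@noCall) != nb)
    msg <- c(msg, "counts/noCall dimensions must match the grid")
  if (nrow(object@pairs) != length(object@calls))
    msg <- c(msg, "one call matrix per group pair required")
  if (is.null(msg)) TRUE else msg
})
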