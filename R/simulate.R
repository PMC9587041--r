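#' Default simulation configuration
#'
#' Builds a [SimulationConfig-class].  The defaults describe a desk-scale
#' rice-like panel with nested divergence — an outgroup far from everything
#' (F = 0.7, standing in for African cultivated rice, a distinct species),
#' indica versus a japonica branch (F = 0.3 each, mirroring the strong
#' indica-japonica differentiation of cultivated rice), and temperate
#' versus tropical japonica inside that branch (F = 0.1 each, a modest
#' within-japonica split) — at 3 chromosomes x 5 Mb x
#' 2500 SNPs and 40 accessions per group, sized so that a full two-method
#' scan runs in seconds while every downstream stage still has power.
#'
#' @param nPerGroup named integer vector of group sizes.
#' @param nChromosomes,chromLengthBp,nSitesPerChrom genome dimensions.
#' @param fstBranch named numeric, per-group Balding-Nichols drift F.
#' @param branchFst named numeric, drift F of internal branches.
#' @param groupParent named character, group -> internal branch (groups not
#'   listed descend straight from the root).
#' @param ancestralBeta shape parameters of the ancestral-frequency Beta.
#' @param missingRate per-genotype missing probability.
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 7)
#' cfg
#' @export
simulationConfig <- function(
    nPerGroup = c(indica = 40L, temperate_japonica = 40L,
                  tropical_japonica = 40L, african = 40L),
    nChromosomes = 3L,
    chromLengthBp = 5e6,
    nSitesPerChrom = 2500L,
    fstBranch = c(indica = 0.30, temperate_japonica = 0.10,
                  tropical_japonica = 0.10, african = 0.70),
    branchFst = c(japonica = 0.30),
    groupParent = c(temperate_japonica = "japonica",
                    tropical_japonica = "japonica"),
    ancestralBeta = c(1, 1),
    missingRate = 0.02,
    seed = 1L) {
  new("SimulationConfig",
      nPerGroup = stats::setNames(as.integer(nPerGroup), names(nPerGroup)),
      nChromosomes = as.integer(nChromosomes),
      chromLengthBp = as.numeric(chromLengthBp),
      nSitesPerChrom = as.integer(nSitesPerChrom),
      fstBranch = fstBranch,
      branchFst = branchFst,
      groupParent = groupParent,
      ancestralBeta = as.numeric(ancestralBeta),
      missingRate = as.numeric(missingRate),
      seed = as.integer(seed))
}

## Balding-Nichols draw: daughter frequency around parent p with drift F.
## Sites fixed in the parent stay fixed (the Beta degenerates there).
.bnDraw <- function(p, F) {
  out <- p
  seg <- p > 0 & p < 1
  if (any(seg)) {
    scale <- (1 - F) / F
    out[seg] <- stats::rbeta(sum(seg), p[seg] * scale, (1 - p[seg]) * scale)
  }
  out
}

#' Simulate per-group allele frequencies under nested Balding-Nichols drift
#'
#' Ancestral frequencies are Beta(a, b) draws per site; each internal
#' branch named in `groupParent` gets a Balding-Nichols draw around the
#' ancestral frequency with its `branchFst`, and each group a draw around
#' its parent (branch or root) with its `fstBranch`.  Sites are placed
#' uniformly without replacement along each chromosome.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `sites` (a sorted `GRanges` with seqlengths),
#'   `ancestral` (numeric per site) and `freq` (numeric matrix, sites x
#'   groups).
#' @export
simulateFrequencies <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nchr <- config@nChromosomes
  nper <- config@nSitesPerChrom
  len <- config@chromLengthBp
  chroms <- sprintf("chr%d", seq_len(nchr))
  pos <- lapply(seq_len(nchr), function(i) sort(sample.int(len, nper)))
  sites <- GRanges(rep(chroms, each = nper),
                   IRanges(unlist(pos), width = 1L),
                   seqlengths = stats::setNames(rep(len, nchr), chroms))
  ntot <- length(sites)
  anc <- stats::rbeta(ntot, config@ancestralBeta[1], config@ancestralBeta[2])
  branchFreq <- lapply(config@branchFst, function(F) .bnDraw(anc, F))
  groups <- names(config@nPerGroup)
  freq <- vapply(groups, function(g) {
    parent <- if (g %in% names(config@groupParent))
      branchFreq[[config@groupParent[[g]]]] else anc
    .bnDraw(parent, config@fstBranch[[g]])
  }, numeric(ntot))
  list(sites = sites, ancestral = anc, freq = freq)
}

#' Simulate diploid genotypes from group allele frequencies
#'
#' Each genotype is an independent Binomial(2, p_group) dosage draw;
#' missing entries are then masked independently at `missingRate`.
#' Accessions are named `<group>_<i>` with zero-padded indices so that
#' lexicographic tie-breaking downstream is well defined.
#'
#' @param freqs output of [simulateFrequencies()].
#' @param config the same [SimulationConfig-class].
#' @return a [GenotypeMatrix-class] with the group map attached.
#' @export
simulateGenotypes <- function(freqs, config) {
  validObject(config)
  if (any(freqs$freq < 0 | freqs$freq > 1))
    stop("allele frequencies must lie in [0,1]")
  set.seed(config@seed + 1L)
  nsite <- length(freqs$sites)
  groups <- names(config@nPerGroup)
  cols <- lapply(groups, function(g) {
    n <- config@nPerGroup[[g]]
    matrix(stats::rbinom(nsite * n, 2L, rep(freqs$freq[, g], n)),
           nrow = nsite, ncol = n,
           dimnames = list(NULL, sprintf("%s_%03d", g, seq_len(n))))
  })
  dos <- do.call(cbind, cols)
  if (config@missingRate > 0)
    dos[stats::runif(length(dos)) < config@missingRate] <- NA_integer_
  gmap <- stats::setNames(rep(groups, config@nPerGroup[groups]),
                          colnames(dos))
  GenotypeMatrix(dos, freqs$sites, groups = gmap)
}

#' Build a planted-tract table
#'
#' @param chrom,startBp,endBp tract interval (1-based inclusive
#'   coordinates, as `GRanges`); vectors recycle.
#' @param donorGroup,recipientGroup group names (must differ).
#' @param replacementFraction fraction of recipient accessions that carry
#'   the tract.
#' @return data.frame understood by [plantIntrogression()].
#' @export
plantedTract <- function(chrom, startBp, endBp, donorGroup, recipientGroup,
                         replacementFraction = 0.3) {
  if (any(donorGroup == recipientGroup))
    stop("donor and recipient group must differ")
  if (any(endBp < startBp))
    stop("tract end before start")
  data.frame(chrom = chrom, start = startBp, end = endBp,
             donor_group = donorGroup, recipient_group = recipientGroup,
             replacement_fraction = replacementFraction)
}

#' Plant homozygous introgression tracts into a genotype matrix
#'
#' For each tract, a `replacement_fraction` share of the recipient group's
#' accessions is sampled as carriers, and every carrier's dosages at all
#' sites inside the tract are replaced by fresh Binomial(2, f_donor) draws
#' from the donor group's allele frequencies — a whole-tract replacement
#' emulating a homozygous introgressed segment.  Carriers and covered-site
#' counts are recorded as ground truth.
#'
#' @param gm a [GenotypeMatrix-class] with a group map.
#' @param tracts data.frame from [plantedTract()] (columns `chrom`,
#'   `start`, `end`, `donor_group`, `recipient_group`,
#'   `replacement_fraction`), or a `GRanges` with those metadata columns.
#' @param freqs the [simulateFrequencies()] output the genotypes came from.
#' @param seed integer seed for carrier sampling and replacement draws.
#' @return list with `genotypes` (modified [GenotypeMatrix-class]) and
#'   `truth` (`GRanges` of tracts with `donor_group`, `recipient_group`,
#'   `carriers` — comma-joined ids — and `n_sites`).
#' @export
plantIntrogression <- function(gm, tracts, freqs, seed = 1L) {
  if (is(tracts, "GRanges")) {
    tracts <- data.frame(chrom = as.character(seqnames(tracts)),
                         start = start(tracts), end = end(tracts),
                         donor_group = mcols(tracts)$donor_group,
                         recipient_group = mcols(tracts)$recipient_group,
                         replacement_fraction =
                           mcols(tracts)$replacement_fraction)
  }
  set.seed(seed)
  dos <- dosage(gm)
  sites <- siteRanges(gm)
  gmap <- groupMap(gm)
  if (is.null(gmap)) stop("genotype matrix needs a group map")
  truth <- vector("list", nrow(tracts))
  for (i in seq_len(nrow(tracts))) {
    tr <- tracts[i, ]
    if (tr$donor_group == tr$recipient_group)
      stop("donor and recipient group must differ")
    idx <- which(as.character(seqnames(sites)) == tr$chrom &
                 start(sites) >= tr$start & start(sites) <= tr$end)
    recip <- names(gmap)[gmap == tr$recipient_group]
    ncar <- round(tr$replacement_fraction * length(recip))
    carriers <- if (ncar > 0) sort(sample(recip, ncar)) else character()
    if (!length(idx)) {
      warning("tract ", i, " overlaps no site; recorded with zero sites")
    } else if (length(carriers)) {
      f <- freqs$freq[idx, tr$donor_group]
      for (acc in carriers)
        dos[idx, acc] <- stats::rbinom(length(idx), 2L, f)
    }
    truth[[i]] <- GRanges(tr$chrom, IRanges(tr$start, tr$end),
                          donor_group = tr$donor_group,
                          recipient_group = tr$recipient_group,
                          carriers = paste(carriers, collapse = ","),
                          n_sites = length(idx))
  }
  truth <- suppressWarnings(do.call(c, truth))
  GenomeInfoDb::seqlevels(truth) <- GenomeInfoDb::seqlevels(sites)
  seqlengths(truth) <- seqlengths(sites)
  gm2 <- GenotypeMatrix(dos, sites, groups = gmap)
  list(genotypes = gm2, truth = truth)
}

#' Per-accession truth of donor ancestry
#'
#' @param truth planted-tract `GRanges` as returned by
#'   [plantIntrogression()].
#' @param accessions character vector of all accession ids.
#' @param region `GRanges` (e.g. one block): an accession scores 1 when it
#'   carries a tract overlapping the region.
#' @return numeric 0/1 vector named by accession.
#' @export
truthAncestryDosage <- function(truth, accessions, region) {
  z <- stats::setNames(numeric(length(accessions)), accessions)
  if (!length(truth)) return(z)
  hit <- overlapsAny(truth, region)
  for (i in which(hit)) {
    cars <- strsplit(mcols(truth)$carriers[i], ",", fixed = TRUE)[[1]]
    cars <- cars[cars %in% accessions]
    z[cars] <- 1
  }
  z
}

#' Simulate an ancestry-linked quantitative phenotype
#'
#' phenotype = effectSize * z + confounderCoef * a + Normal(0, noiseSd),
#' where z is the true donor-ancestry dosage at the causal block (1 for
#' tract carriers, 0 otherwise) and a is the accession's genome-wide
#' donor-ancestry fraction (bp carried / genome length) acting as a
#' global-ancestry confounder (coefficient 0 by default).
#'
#' @param truth planted-tract `GRanges` ([plantIntrogression()] output).
#' @param accessions accession ids to score.
#' @param causalBlock length-1 `GRanges`.
#' @param effectSize,noiseSd,confounderCoef model parameters.
#' @param genomeLengthBp total genome length used for the global-ancestry
#'   fraction.
#' @param seed integer seed for the noise draw.
#' @return named numeric phenotype vector.
#' @export
simulatePhenotype <- function(truth, accessions, causalBlock,
                              effectSize = 1, noiseSd = 1,
                              confounderCoef = 0,
                              genomeLengthBp = NULL, seed = 1L) {
  set.seed(seed)
  z <- truthAncestryDosage(truth, accessions, causalBlock)
  glob <- stats::setNames(numeric(length(accessions)), accessions)
  if (length(truth)) {
    if (is.null(genomeLengthBp))
      genomeLengthBp <- sum(as.numeric(seqlengths(truth)), na.rm = TRUE)
    for (i in seq_along(truth)) {
      cars <- strsplit(mcols(truth)$carriers[i], ",", fixed = TRUE)[[1]]
      cars <- cars[cars %in% accessions]
      glob[cars] <- glob[cars] + width(truth)[i] / genomeLengthBp
    }
  }
  effectSize * z + confounderCoef * glob +
    stats::rnorm(length(accessions), 0, noiseSd)
}

#' One-call simulation of a full benchmark dataset
#'
#' Runs [simulateFrequencies()], [simulateGenotypes()],
#' [plantIntrogression()] and (when a causal block is given)
#' [simulatePhenotype()], returning a [SimulatedDataset-class] whose truth
#' slots drive the package's benchmarks.
#'
#' @param config a [SimulationConfig-class].
#' @param tracts optional planted-tract data.frame ([plantedTract()]).
#' @param causalBlock optional length-1 `GRanges`; phenotype is simulated
#'   iff present (its carriers come from the tract table).
#' @param effectSize,noiseSd,confounderCoef passed to
#'   [simulatePhenotype()].
#' @return a [SimulatedDataset-class].
#' @examples
#' cfg <- simulationConfig(seed = 42)
#' tr <- plantedTract("chr1", 2000001, 2500000, "indica",
#'                    "tropical_japonica", 0.3)
#' sim <- simulateDataset(cfg, tracts = tr)
#' sim
#' @export
simulateDataset <- function(config, tracts = NULL, causalBlock = NULL,
                            effectSize = 1, noiseSd = 1,
                            confounderCoef = 0) {
  validObject(config)
  freqs <- simulateFrequencies(config)
  gm <- simulateGenotypes(freqs, config)
  truth <- GRanges()
  if (!is.null(tracts) && NROW(tracts)) {
    planted <- plantIntrogression(gm, tracts, freqs,
                                  seed = config@seed + 2L)
    gm <- planted$genotypes
    truth <- planted$truth
  }
  pheno <- numeric()
  cb <- GRanges()
  if (!is.null(causalBlock) && length(causalBlock)) {
    cb <- causalBlock
    pheno <- simulatePhenotype(truth, accessionIds(gm), cb,
                               effectSize = effectSize, noiseSd = noiseSd,
                               confounderCoef = confounderCoef,
                               genomeLengthBp =
                                 config@nChromosomes * config@chromLengthBp,
                               seed = config@seed + 3L)
  }
  new("SimulatedDataset", genotypes = gm, truthTracts = truth,
      phenotype = pheno, causalBlock = cb, config = config)
}
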