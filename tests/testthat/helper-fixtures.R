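# Fixtures shared across test files.  Everything is generated in code at
# test time; the heavier simulated dataset is cached per session.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# small genotype matrix straight from dosage codes
toyGm <- function(dos, positions = NULL, chrom = "chr1", groups = NULL,
                  chromLength = NA) {
  if (is.null(positions)) positions <- seq_len(nrow(dos)) * 100L
  sl <- if (is.na(chromLength)) NULL else
    stats::setNames(chromLength, chrom)
  sites <- GRanges(chrom, IRanges(positions, width = 1L), seqlengths = sl)
  GenotypeMatrix(dos, sites, groups = groups)
}

# default planted-tract benchmark: indica -> tropical japonica tract at
# chr1:2,000,001-3,000,000 (blocks 5-6 of the 500 kb grid), 30% carriers
plantedBenchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(nSitesPerChrom = 10000L, seed = 2024L)
      tr <- plantedTract("chr1", 2000001, 3000000,
                         "indica", "tropical_japonica", 0.3)
      sim <- simulateDataset(cfg, tracts = tr)
      gm <- filterSites(genotypes(sim))
      grid <- sliceBlocks(gm, 5e5)
      pairs <- data.frame(donor = c("indica", "tropical_japonica"),
                          recipient = c("tropical_japonica", "indica"))
      scan <- scanBlocks(gm, grid, pairs)
      cache <<- list(sim = sim, gm = gm, grid = grid, scan = scan,
                     plantedBlocks = which(overlapsAny(grid, truthTracts(sim))))
    }
    cache
  }
})

# wrap a bare call matrix (accessions x blocks) as an IntrogressionScan so
# the permutation machinery can be exercised directly
scanFromCalls <- function(calls, donor = "A", recipient = "B",
                          blockSize = 5e5) {
  nb <- ncol(calls)
  grid <- sliceBlocks(NULL, blockSize, c(chr1 = nb * blockSize))
  counts <- matrix(colSums(calls), 1L, nb)
  rownames(calls) <- sprintf("%s_%03d", recipient, seq_len(nrow(calls)))
  groups <- c(stats::setNames(rep(recipient, nrow(calls)), rownames(calls)),
              stats::setNames(donor, paste0(donor, "_001")))
  methods::new("IntrogressionScan", grid = grid,
               pairs = data.frame(donor = donor, recipient = recipient),
               calls = stats::setNames(list(calls),
                                       paste0(donor, "->", recipient)),
               counts = counts, noCall = logical(nb), minSnps = 10L,
               groups = groups)
}

# random additive distance matrix: random binary topology with branch
# lengths bounded away from zero, so the generating tree is the unique
# additive topology
randomAdditive <- function(n) {
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1)
  d <- stats::cophenetic(tr)
  o <- order(rownames(d))
  list(tree = tr, d = d[o, o])
}

# least-squares branch-length fit of a topology to a distance matrix;
# exhaustive-enumeration oracle for neighbor joining
lsRss <- function(topology, d) {
  labs <- rownames(d)
  tr <- topology
  n <- length(tr$tip.label)
  pairs <- t(utils::combn(n, 2))
  nb <- nrow(tr$edge)
  X <- matrix(0, nrow(pairs), nb)
  dv <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    path <- ape::nodepath(tr, i, j)
    for (s in seq_len(length(path) - 1L)) {
      e <- which((tr$edge[, 1] == path[s] & tr$edge[, 2] == path[s + 1]) |
                 (tr$edge[, 2] == path[s] & tr$edge[, 1] == path[s + 1]))
      X[r, e] <- 1
    }
    dv[r] <- d[tr$tip.label[i], tr$tip.label[j]]
  }
  fit <- stats::lm.fit(X, dv)
  sum(fit$residuals^2)
}

bestTopologyByEnumeration <- function(d) {
  labs <- rownames(d)
  tops <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  rss <- vapply(tops, lsRss, numeric(1), d = d)
  tops[[which.min(rss)]]
}

sameTopology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
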