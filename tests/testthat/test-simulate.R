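test_that("Balding-Nichols frequencies respect the drift parameter", {
  # no-drift limit: group frequencies hug the ancestral frequency
  cfgLow <- simulationConfig(nPerGroup = c(A = 5L, B = 5L),
                             fstBranch = c(A = 1e-4, B = 1e-4),
                             branchFst = numeric(), groupParent = character(),
                             nChromosomes = 1L, nSitesPerChrom = 2000L,
                             missingRate = 0, seed = 11L)
  frLow <- simulateFrequencies(cfgLow)
  expect_lt(mean(abs(frLow$freq[, "A"] - frLow$ancestral)), 0.01)

  # strong drift: most sites near fixation
  cfgHi <- simulationConfig(nPerGroup = c(A = 5L, B = 5L),
                            fstBranch = c(A = 0.99, B = 0.99),
                            branchFst = numeric(), groupParent = character(),
                            nChromosomes = 1L, nSitesPerChrom = 10000L,
                            chromLengthBp = 2e7,
                            missingRate = 0, seed = 12L)
  frHi <- simulateFrequencies(cfgHi)
  extreme <- mean(frHi$freq[, "A"] < 0.01 | frHi$freq[, "A"] > 0.99)
  expect_gt(extreme, 0.9)

  # invalid drift rejected
  expect_error(simulationConfig(nPerGroup = c(A = 5L, B = 5L),
                                fstBranch = c(A = 1.2, B = 0.1),
                                branchFst = numeric(),
                                groupParent = character()),
               "strictly in")
})

test_that("simulation is a deterministic function of the config", {
  cfg <- simulationConfig(nPerGroup = c(A = 4L, B = 4L),
                          fstBranch = c(A = 0.2, B = 0.2),
                          branchFst = numeric(), groupParent = character(),
                          nChromosomes = 1L, nSitesPerChrom = 200L,
                          chromLengthBp = 1e6, seed = 5L)
  f1 <- simulateFrequencies(cfg)
  f2 <- simulateFrequencies(cfg)
  expect_identical(f1, f2)
  expect_identical(dosage(simulateGenotypes(f1, cfg)),
                   dosage(simulateGenotypes(f2, cfg)))
})

test_that("genotype draws follow the group frequencies", {
  cfg <- simulationConfig(nPerGroup = c(A = 2000L, B = 2L),
                          fstBranch = c(A = 0.2, B = 0.2),
                          branchFst = numeric(), groupParent = character(),
                          nChromosomes = 1L, nSitesPerChrom = 3L,
                          chromLengthBp = 1e4, missingRate = 0, seed = 3L)
  fr <- simulateFrequencies(cfg)
  fr$freq[, "A"] <- c(1, 0.5, 0)    # pinned frequencies
  gm <- simulateGenotypes(fr, cfg)
  dosA <- dosage(gm)[, groupMembers(gm, "A")]
  expect_true(all(dosA[1, ] == 2L))          # fixed ALT
  expect_true(all(dosA[3, ] == 0L))          # fixed REF
  expect_false(anyNA(dosage(gm)))            # missingRate = 0
  pHat <- mean(dosA[2, ]) / 2
  expect_lt(abs(pHat - 0.5), 0.03)           # binomial bound at n = 2000
})

test_that("missing genotypes appear at the configured rate", {
  cfg <- simulationConfig(nPerGroup = c(A = 50L, B = 50L),
                          fstBranch = c(A = 0.2, B = 0.2),
                          branchFst = numeric(), groupParent = character(),
                          nChromosomes = 1L, nSitesPerChrom = 500L,
                          chromLengthBp = 1e6, missingRate = 0.1, seed = 4L)
  gm <- simulateGenotypes(simulateFrequencies(cfg), cfg)
  expect_lt(abs(mean(is.na(dosage(gm))) - 0.1), 0.01)
})

test_that("planted tracts replace carrier genotypes with donor draws", {
  cfg <- simulationConfig(nPerGroup = c(A = 10L, B = 10L),
                          fstBranch = c(A = 0.2, B = 0.2),
                          branchFst = numeric(), groupParent = character(),
                          nChromosomes = 1L, nSitesPerChrom = 10L,
                          chromLengthBp = 1e4, missingRate = 0, seed = 6L)
  fr <- simulateFrequencies(cfg)
  fr$freq[, "A"] <- 1   # donor fixed for ALT
  fr$freq[, "B"] <- 0   # recipient fixed for REF
  gm <- simulateGenotypes(fr, cfg)

  # replacement_fraction = 0 leaves everything untouched
  tr0 <- plantedTract("chr1", 1, 1e4, "A", "B", 0)
  out0 <- plantIntrogression(gm, tr0, fr, seed = 1)
  expect_identical(dosage(out0$genotypes), dosage(gm))

  # fixed-difference case: carriers become homozygous ALT at all 10 sites
  tr <- plantedTract("chr1", 1, 1e4, "A", "B", 0.5)
  out <- plantIntrogression(gm, tr, fr, seed = 1)
  carriers <- strsplit(S4Vectors::mcols(out$truth)$carriers, ",")[[1]]
  expect_length(carriers, 5L)
  expect_true(all(dosage(out$genotypes)[, carriers] == 2L))
  nonCarriers <- setdiff(groupMembers(gm, "B"), carriers)
  expect_true(all(dosage(out$genotypes)[, nonCarriers] == 0L))

  # a tract with no overlapping site warns and records zero sites
  trEmpty <- plantedTract("chr9", 1, 100, "A", "B", 0.5)
  expect_warning(outE <- plantIntrogression(gm, trEmpty, fr, seed = 1),
                 "zero sites")
  expect_identical(S4Vectors::mcols(outE$truth)$n_sites, 0L)
})

test_that("carriers are closer to the donor group inside the tract", {
  fix <- plantedBenchmark()
  sim <- fix$sim
  tract <- truthTracts(sim)
  carriers <- strsplit(S4Vectors::mcols(tract)$carriers, ",")[[1]]
  gm <- genotypes(sim)
  d <- alleleSharingDistance(gm, block = tract)
  donor <- groupMembers(gm, "indica")
  own <- setdiff(groupMembers(gm, "tropical_japonica"), carriers)
  toDonor <- mean(d[carriers, donor])
  toOwn <- mean(d[carriers, own])
  expect_lt(toDonor, toOwn)
})

test_that("phenotype reflects causal ancestry as configured", {
  fix <- plantedBenchmark()
  sim <- fix$sim
  acc <- accessionIds(genotypes(sim))
  cb <- truthTracts(sim)[1]
  z <- truthAncestryDosage(truthTracts(sim), acc, cb)
  expect_setequal(unique(z), c(0, 1))

  # zero effect: phenotype independent of local ancestry
  y0 <- simulatePhenotype(truthTracts(sim), acc, cb, effectSize = 0,
                          noiseSd = 1, seed = 21)
  expect_gt(stats::cor.test(y0, z)$p.value, 0.01)

  # zero noise, no confounder: exact affine function of dosage
  y1 <- simulatePhenotype(truthTracts(sim), acc, cb, effectSize = 2,
                          noiseSd = 0, seed = 22)
  expect_true(all(abs(y1 - 2 * z) < 1e-12))

  # effect 1, noise 1: R^2 in the variance-decomposition window
  y2 <- simulatePhenotype(truthTracts(sim), acc, cb, effectSize = 1,
                          noiseSd = 1, seed = 23)
  r2 <- stats::cor(y2, z)^2
  expect_gt(r2, 0.02)
  expect_lt(r2, 0.9)
})
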