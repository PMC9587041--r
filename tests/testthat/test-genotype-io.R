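test_that("VCF genotype fields map onto dosage codes", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"),
           "chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/1\t./.\t1|1",
           "chr1\t200\t.\tG\tT\t.\tPASS\t.\tGT\t0/0\t1/1\t./1",
           "chr1\t300\t.\tG\tT,A\t.\tPASS\t.\tGT\t0/0\t1/1\t2/2")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_warning(gm <- readGenotypeVcf(f), "multiallelic")
  expect_equal(nrow(gm), 2L)                       # multiallelic skipped
  expect_identical(dosage(gm)[1, ], c(s1 = 1L, s2 = NA_integer_, s3 = 2L))
  expect_identical(dosage(gm)[2, ], c(s1 = 0L, s2 = 2L, s3 = NA_integer_))
  expect_identical(S4Vectors::mcols(siteRanges(gm))$ref, c("A", "G"))
})

test_that("VCF round-trip preserves dosage, positions and missingness", {
  cfg <- simulationConfig(nPerGroup = c(A = 6L, B = 6L),
                          fstBranch = c(A = 0.2, B = 0.2),
                          branchFst = numeric(), groupParent = character(),
                          nChromosomes = 2L, nSitesPerChrom = 80L,
                          chromLengthBp = 1e6, missingRate = 0.1, seed = 8L)
  gm <- simulateGenotypes(simulateFrequencies(cfg), cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypeVcf(gm, f)
  back <- readGenotypeVcf(f)
  expect_identical(dosage(back), dosage(gm))
  expect_identical(GenomicRanges::start(siteRanges(back)),
                   GenomicRanges::start(siteRanges(gm)))
  expect_identical(as.character(GenomicRanges::seqnames(siteRanges(back))),
                   as.character(GenomicRanges::seqnames(siteRanges(gm))))
})

test_that("groups, phenotype and BED tables round-trip", {
  g <- c(a1 = "indica", a2 = "japonica")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  writeGroups(g, f1)
  expect_identical(readGroups(f1), g)

  ph <- c(a1 = 1.25, a2 = -0.5)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writePhenotype(ph, f2)
  expect_equal(readPhenotype(f2), ph)

  gr <- GRanges("chr2", IRanges(1001, 2000))
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeBed(gr, f3)
  bedLine <- readLines(f3)
  expect_identical(bedLine, "chr2\t1000\t2000")    # 0-based half-open
  expect_true(identical(GenomicRanges::granges(readBed(f3)), gr))
})

test_that("site filters apply strict MAF and missingness boundaries", {
  # 50 diploid accessions (100 alleles); six sites engineered to MAFs
  # 0, 0.04, 0.05, 0.10, 0.25, 0.50 with no missing data: under the
  # strict MAF > 0.05 rule exactly 3 survive
  nAcc <- 50L
  mk <- function(nAlt) {
    al <- c(rep(1L, nAlt), rep(0L, 2 * nAcc - nAlt))
    vapply(seq_len(nAcc), function(i) al[2 * i - 1] + al[2 * i], integer(1))
  }
  dos <- rbind(mk(0), mk(4), mk(5), mk(10), mk(25), mk(50))
  colnames(dos) <- sprintf("a%02d", seq_len(nAcc))
  gm <- toyGm(dos)
  kept <- filterSites(gm)
  expect_equal(nrow(kept), 3L)
  mafs <- rowSums(dosage(kept)) / (2 * nAcc)
  expect_true(all(pmin(mafs, 1 - mafs) > 0.05))

  # missing fraction exactly at the threshold is dropped (strict <)
  dos2 <- matrix(c(rep(NA_integer_, 4), rep(1L, 6)), 1, 10,
                 dimnames = list(NULL, sprintf("b%02d", 1:10)))
  expect_equal(nrow(filterSites(toyGm(dos2), missingMax = 0.40)), 0L)
  expect_equal(nrow(filterSites(toyGm(dos2), missingMax = 0.41)), 1L)

  # all-missing site has undefined MAF and is dropped
  dos3 <- matrix(NA_integer_, 1, 10,
                 dimnames = list(NULL, sprintf("c%02d", 1:10)))
  expect_equal(nrow(filterSites(toyGm(dos3))), 0L)

  # idempotence
  expect_identical(dosage(filterSites(kept)), dosage(kept))
})

test_that("block grids tile chromosomes and assign sites uniquely", {
  grid <- sliceBlocks(NULL, 5e5, c(chr1 = 1200000))
  expect_length(grid, 3L)
  expect_equal(GenomicRanges::start(grid), c(1, 500001, 1000001))
  expect_equal(GenomicRanges::end(grid), c(500000, 1000000, 1200000))

  # a site at pos 500000 (1-based) belongs to the first block
  s <- GRanges("chr1", IRanges(500000, width = 1))
  expect_equal(siteBlocks(s, grid), 1L)
  expect_equal(siteBlocks(GRanges("chr1", IRanges(500001, width = 1)), grid),
               2L)

  # partition property on a simulated site table
  cfg <- simulationConfig(nPerGroup = c(A = 2L, B = 2L),
                          fstBranch = c(A = 0.2, B = 0.2),
                          branchFst = numeric(), groupParent = character(),
                          nChromosomes = 1L, nSitesPerChrom = 2500L,
                          chromLengthBp = 5e6, seed = 9L)
  fr <- simulateFrequencies(cfg)
  g10 <- sliceBlocks(fr$sites, 5e5)
  assign <- siteBlocks(fr$sites, g10)
  expect_false(anyNA(assign))
  expect_equal(sum(table(assign)), 2500L)
  expect_length(g10, 10L)
})
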