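test_that("classification follows the nearest-leaf majority rule", {
  gmap <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B", B3 = "B")

  # hand-worked case: A1 nests inside the B clade -> only A1 is called
  tr <- ape::read.tree(text = paste0(
    "(((A1:0.01,B1:0.01):0.01,(B2:0.01,B3:0.01):0.01):0.2,",
    "(A2:0.01,A3:0.01):0.2);"))
  res <- classifyIntrogression(tr, gmap, recipient = "A", donor = "B", k = 3)
  expect_identical(res$accession, "A1")

  # perfectly separated clades: nothing called in either direction
  tr2 <- ape::read.tree(text =
    "((A1:0.1,(A2:0.1,A3:0.1):0.1):0.5,(B1:0.1,(B2:0.1,B3:0.1):0.1):0.5);")
  expect_equal(nrow(classifyIntrogression(tr2, gmap, "A", "B", k = 3)), 0L)
  expect_equal(nrow(classifyIntrogression(tr2, gmap, "B", "A", k = 3)), 0L)

  # star tree (all distances equal): strict rules yield no call
  tr3 <- ape::read.tree(text = "(A1:1,A2:1,A3:1,B1:1,B2:1,B3:1);")
  expect_equal(nrow(classifyIntrogression(tr3, gmap, "A", "B", k = 3)), 0L)
})

test_that("classification is label-symmetric", {
  set.seed(41)
  tr <- ape::unroot(ape::rtree(12))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr$tip.label <- c(sprintf("A%02d", 1:6), sprintf("B%02d", 1:6))
  gmap <- stats::setNames(rep(c("A", "B"), each = 6), tr$tip.label)
  swapped <- stats::setNames(rep(c("B", "A"), each = 6), tr$tip.label)
  orig <- classifyIntrogression(tr, gmap, recipient = "A", donor = "B")
  swap <- classifyIntrogression(tr, swapped, recipient = "B", donor = "A")
  expect_identical(orig$accession, swap$accession)
})

test_that("block scan localizes the planted tract and stays unidirectional", {
  fix <- plantedBenchmark()
  fwd <- callCounts(fix$scan, "indica", "tropical_japonica")
  rev <- callCounts(fix$scan, "tropical_japonica", "indica")

  # the planted blocks carry the call maximum
  expect_true(which.max(fwd) %in% fix$plantedBlocks)
  expect_gt(min(fwd[fix$plantedBlocks]), 5)
  expect_true(all(fwd[-fix$plantedBlocks] <= 2, na.rm = TRUE))

  # reverse direction at background level inside the planted blocks
  bg95 <- stats::quantile(rev[-fix$plantedBlocks], 0.95, na.rm = TRUE)
  expect_true(all(rev[fix$plantedBlocks] <= bg95))

  # conservation: counts are column sums of the call matrices
  cm <- callMatrix(fix$scan, "indica", "tropical_japonica")
  called <- !noCallBlocks(fix$scan)
  expect_equal(unname(colSums(cm[, called])), unname(fwd[called]))
  expect_equal(sum(cm[, called]), sum(fwd, na.rm = TRUE))
})

test_that("blocks without polymorphism are NO_CALL", {
  set.seed(42)
  # 30 constant sites in block 1, 30 polymorphic in block 2
  dosConst <- matrix(1L, 30, 12)
  dosPoly <- matrix(sample(0:2, 30 * 12, replace = TRUE), 30, 12)
  dos <- rbind(dosConst, dosPoly)
  colnames(dos) <- c(sprintf("A%02d", 1:6), sprintf("B%02d", 1:6))
  gmap <- stats::setNames(rep(c("A", "B"), each = 6), colnames(dos))
  gm <- toyGm(dos, positions = c(seq(100, by = 10, length.out = 30),
                                 seq(1e5 + 100, by = 10, length.out = 30)),
              groups = gmap, chromLength = 2e5)
  grid <- sliceBlocks(gm, 1e5)
  scan <- scanBlocks(gm, grid, data.frame(donor = "A", recipient = "B"),
                     minSnps = 10L)
  expect_identical(noCallBlocks(scan), c(TRUE, FALSE))
  expect_true(is.na(callCounts(scan, "A", "B")[1]))
})

test_that("permutation null respects accession loads and alpha monotonicity", {
  set.seed(43)
  calls <- matrix(stats::runif(40 * 30) < 0.05, 40, 30)
  scan <- scanFromCalls(calls)

  perm <- permutationSignificantRegions(scan, "A", "B", nPerm = 200,
                                        alpha = 0.05, seed = 7)
  # an all-zero track can never be significant
  scan0 <- scanFromCalls(matrix(FALSE, 40, 30))
  perm0 <- permutationSignificantRegions(scan0, "A", "B", nPerm = 200,
                                         alpha = 0.05, seed = 7)
  expect_length(perm0$regions, 0L)
  expect_equal(perm0$threshold, 0)

  # threshold is monotone nonincreasing in alpha
  thr <- vapply(c(0.01, 0.05, 0.2), function(a)
    permutationSignificantRegions(scan, "A", "B", nPerm = 200, alpha = a,
                                  seed = 7)$threshold, numeric(1))
  expect_true(all(diff(thr) <= 0))

  # alpha below the permutation resolution is rejected
  expect_error(permutationSignificantRegions(scan, "A", "B", nPerm = 100,
                                             alpha = 0.001, seed = 7),
               "resolution")
})

test_that("the planted region is significant; its blocks match truth", {
  fix <- plantedBenchmark()
  perm <- permutationSignificantRegions(fix$scan, "indica",
                                        "tropical_japonica",
                                        nPerm = 500, alpha = 0.05, seed = 99)
  expect_setequal(perm$significantBlocks, fix$plantedBlocks)
  expect_true(all(overlapsAny(perm$regions, truthTracts(fix$sim))))
})

test_that("direction correlation behaves on degenerate and exact inputs", {
  calls <- matrix(stats::runif(20 * 12) < 0.3, 20, 12)
  cnt <- colSums(calls)
  mkScan <- function(x, y) {
    nb <- length(x)
    grid <- sliceBlocks(NULL, 5e5, c(chr1 = nb * 5e5))
    methods::new("IntrogressionScan", grid = grid,
                 pairs = data.frame(donor = c("A", "B"),
                                    recipient = c("B", "A")),
                 calls = list("A->B" = calls, "B->A" = calls),
                 counts = rbind(x, y), noCall = logical(nb),
                 minSnps = 10L, groups = c(a = "A", b = "B"))
  }
  same <- directionCorrelation(mkScan(cnt, cnt), "A", "B")
  expect_equal(same$r, 1)
  neg <- directionCorrelation(mkScan(cnt, max(cnt) - cnt), "A", "B")
  expect_equal(neg$r, -1)
  expect_equal(neg$slope, -1)
  flat <- directionCorrelation(mkScan(cnt, rep(2, length(cnt))), "A", "B")
  expect_true(is.na(flat$r))
  expect_match(flat$note, "zero variance")
})

test_that("independent null direction tracks are uncorrelated", {
  set.seed(44)
  hits <- 0L
  for (r in 1:50) {
    x <- stats::rbinom(40, 10, 0.1)
    y <- stats::rbinom(40, 10, 0.1)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    p <- stats::cor.test(x, y)$p.value
    hits <- hits + (p > 0.05)
  }
  expect_gte(hits, 45L)
})

test_that("chi-square enrichment matches the Pearson formula", {
  # proportional rows: exact independence
  res0 <- enrichmentTest(matrix(c(10, 30, 20, 60), 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  # hand-computed Pearson chi-square, no continuity correction
  tbl <- matrix(c(20, 10, 10, 20), 2)
  E <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  expect_equal(enrichmentTest(tbl)$statistic, sum((tbl - E)^2 / E))

  # zero margin: undefined
  resU <- enrichmentTest(matrix(c(5, 3, 0, 0), 2))
  expect_true(is.na(resU$statistic))
  expect_match(resU$note, "zero margin")

  # scan interface: annotation covering every block has a zero margin
  fix <- plantedBenchmark()
  allBlocks <- GRanges(c("chr1", "chr2", "chr3"), IRanges(1, 5e6))
  resAll <- enrichmentTest(fix$scan, "indica", "tropical_japonica",
                           annotation = allBlocks)
  expect_true(is.na(resAll$statistic))

  # partial annotation gives a defined test on the real scan
  ann <- GRanges("chr1", IRanges(1, 2.5e6))
  resPart <- enrichmentTest(fix$scan, "indica", "tropical_japonica",
                            annotation = ann)
  expect_false(is.na(resPart$statistic))
  expect_true(resPart$p >= 0 && resPart$p <= 1)
})
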