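#' Jaccard overlap between two sets of genomic regions
#'
#' Base-pair Jaccard index |A intersect B| / |A union B|.
#'
#' @param a,b `GRanges`.
#' @return numeric in \[0, 1\]; `NA` when both are empty.
#' @export
regionJaccard <- function(a, b) {
  a <- reduce(granges(a)); b <- reduce(granges(b))
  sl <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  a <- GRanges(as.character(seqnames(a)), IRanges(start(a), end(a)),
               seqinfo = GenomeInfoDb::Seqinfo(sl))
  b <- GRanges(as.character(seqnames(b)), IRanges(start(b), end(b)),
               seqinfo = GenomeInfoDb::Seqinfo(sl))
  u <- sum(as.numeric(width(GenomicRanges::union(a, b))))
  if (u == 0) return(NA_real_)
  i <- sum(as.numeric(width(GenomicRanges::intersect(a, b))))
  i / u
}

## tiny polynomial rolling hash of a deparsed object, for provenance headers
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

.provenance <- function(seed, hash) {
  sprintf("# introScan %s; seed=%d; config_hash=%s",
          as.character(utils::packageVersion("introScan")), seed, hash)
}

.writeTsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full introgression-detection pipeline
#'
#' Orchestrates simulate (or load) -> site filtering -> tree-method block
#' scan with permutation-significant regions -> D-statistic scan with
#' peak calling -> diversity and Fst tracks -> optional admixture
#' mapping, writing TSV/BED outputs plus a `summary.tsv` that includes
#' the base-pair Jaccard overlap between the tree-method significant
#' regions and the D-statistic peaks (the two-method consistency check).
#' Every output starts with a provenance header line (package version,
#' seed, config hash), and the whole run is a deterministic function of
#' the config.
#'
#' @param config named list (or path to a YAML file with the same keys):
#'   `sim` (a [SimulationConfig-class]; default [simulationConfig()]),
#'   `tracts` (planted-tract data.frame, or `NULL`), `vcf`/`groups` (to
#'   load data instead of simulating), `donor`, `recipient`, `roles`
#'   (named vector for [dstatScan()]), `blockSizeTree` (500000),
#'   `blockSizeAdmix` (200000), `mafMin` (0.05), `missingMax` (0.40),
#'   `minSnps` (10), `nPerm` (1000), `alpha` (0.05), `zThreshold` (3),
#'   `phenotype` (named vector or TSV path; enables admixture mapping).
#' @param outDir output directory (created).
#' @param seed integer seed controlling permutations (and the simulation
#'   when `config$sim` is absent).
#' @return invisibly, a list with the main in-memory results:
#'   `genotypes`, `scan`, `treeRegions`, `dWindows`, `dPeaks`,
#'   `jaccard`, `diversity`, `fst`, `association` (or `NULL`), and
#'   `summary` (the key-value summary data.frame).
#' @export
runPipeline <- function(config = list(), outDir, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  hdr <- .provenance(as.integer(seed), hash)
  logf <- file.path(outDir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(line)
    cat(line, "\n", file = logf, append = TRUE)
  }
  cfg <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }

  donor <- cfg("donor", "indica")
  recipient <- cfg("recipient", "tropical_japonica")
  roles <- cfg("roles", c(P1 = "tropical_japonica",
                          P2 = "temperate_japonica",
                          P3 = "indica", O = "african"))
  truth <- GRanges()
  if (!is.null(config$vcf)) {
    logmsg("loading genotypes from ", config$vcf)
    gm <- readGenotypeVcf(config$vcf, groups = config$groups)
  } else {
    simCfg <- cfg("sim", simulationConfig(seed = as.integer(seed)))
    logmsg("simulating dataset (seed ", simCfg@seed, ")")
    sim <- simulateDataset(simCfg, tracts = config$tracts)
    gm <- genotypes(sim)
    truth <- truthTracts(sim)
    writeGenotypeVcf(gm, file.path(outDir, "simulated.vcf"))
    writeGroups(groupMap(gm), file.path(outDir, "groups.tsv"))
    if (length(truth))
      writeBed(truth, file.path(outDir, "truth_tracts.bed"),
               name = paste0(mcols(truth)$donor_group, ">",
                             mcols(truth)$recipient_group))
  }
  logmsg("filtering sites (MAF > ", cfg("mafMin", 0.05),
         ", missing < ", cfg("missingMax", 0.40), ")")
  nBefore <- nrow(gm)
  gm <- filterSites(gm, cfg("mafMin", 0.05), cfg("missingMax", 0.40))
  logmsg(nBefore, " sites -> ", nrow(gm), " after filtering")

  grid <- sliceBlocks(gm, cfg("blockSizeTree", 5e5))
  pairs <- data.frame(donor = c(donor, recipient),
                      recipient = c(recipient, donor))
  logmsg("tree-method scan over ", length(grid), " blocks")
  scan <- scanBlocks(gm, grid, pairs, minSnps = cfg("minSnps", 10L))
  perm <- permutationSignificantRegions(scan, donor, recipient,
                                        nPerm = cfg("nPerm", 1000L),
                                        alpha = cfg("alpha", 0.05),
                                        seed = as.integer(seed) + 10L)
  cntTab <- data.frame(chrom = as.character(seqnames(grid)),
                       start = start(grid), end = end(grid))
  for (p in seq_len(nrow(pairs)))
    cntTab[[.pairKey(pairs$donor[p], pairs$recipient[p])]] <- scan@counts[p, ]
  cntTab$no_call <- scan@noCall
  .writeTsv(cntTab, file.path(outDir, "tree_block_counts.tsv"), hdr)
  if (length(perm$regions))
    writeBed(perm$regions, file.path(outDir, "tree_significant_regions.bed"))
  logmsg(length(perm$regions), " significant tree-method region(s), ",
         "threshold ", perm$threshold)

  logmsg("D-statistic scan (P1=", roles[["P1"]], ", P2=", roles[["P2"]],
         ", P3=", roles[["P3"]], ", O=", roles[["O"]], ")")
  dWin <- dstatScan(gm, grid, roles)
  .writeTsv(dWin, file.path(outDir, "dstat_windows.tsv"), hdr)
  dPeaks <- callPeaks(dWin, grid, cfg("zThreshold", 3))
  if (length(dPeaks))
    writeBed(dPeaks, file.path(outDir, "dstat_peaks.bed"),
             name = mcols(dPeaks)$direction)
  jac <- regionJaccard(perm$regions, dPeaks)
  logmsg(length(dPeaks), " D peak(s); tree/D Jaccard = ",
         format(jac, digits = 3))

  div <- nucleotideDiversity(gm, grid)
  .writeTsv(div, file.path(outDir, "diversity.tsv"), hdr)
  fst <- hudsonFst(gm, grid, donor, recipient)
  .writeTsv(fst, file.path(outDir, "fst.tsv"), hdr)

  assoc <- NULL
  pheno <- config$phenotype
  if (!is.null(pheno)) {
    if (is.character(pheno) && length(pheno) == 1L) pheno <- readPhenotype(pheno)
    gridA <- sliceBlocks(gm, cfg("blockSizeAdmix", 2e5))
    logmsg("admixture mapping over ", length(gridA), " blocks")
    anc <- estimateBlockAncestry(gm, gridA, panelA = donor,
                                 panelB = recipient,
                                 targets = sort(names(pheno)))
    assoc <- associateAncestry(anc, pheno, grid = gridA)
    .writeTsv(assoc, file.path(outDir, "admixture_association.tsv"), hdr)
  }

  summary <- data.frame(
    key = c("seed", "config_hash", "n_sites", "n_accessions",
            "n_blocks", "n_no_call", "tree_significant_regions",
            "tree_threshold", "d_peaks", "tree_d_jaccard",
            if (!is.null(assoc)) c("admix_min_p", "admix_lambda")),
    value = c(seed, hash, nrow(gm), ncol(gm), length(grid),
              sum(scan@noCall), length(perm$regions), perm$threshold,
              length(dPeaks), jac,
              if (!is.null(assoc)) c(min(assoc$p, na.rm = TRUE),
                                     attr(assoc, "lambda"))))
  .writeTsv(summary, file.path(outDir, "summary.tsv"), hdr)
  logmsg("done")
  invisible(list(genotypes = gm, truth = truth, scan = scan,
                 treeRegions = perm$regions, treeThreshold = perm$threshold,
                 dWindows = dWin, dPeaks = dPeaks, jaccard = jac,
                 diversity = div, fst = fst, association = assoc,
                 summary = summary))
}
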