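#' Read diploid biallelic genotypes from a VCF file
#'
#' Parses a VCF (4.x, plain or gzipped) with `vcfR` and converts the GT
#' field to ALT-allele dosages.  Any genotype containing `.` becomes
#' missing; phased (`|`) and unphased (`/`) separators are both accepted.
#' Multiallelic records (ALT containing a comma) are skipped with a
#' warning, matching an upstream pipeline that emits biallelic SNPs only.
#'
#' @param path VCF file path.
#' @param groups optional named character vector (or path to a groups TSV,
#'   see [readGroups()]) attaching group labels.
#' @return a [GenotypeMatrix-class].
#' @seealso [writeGenotypeVcf()]
#' @export
readGenotypeVcf <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = list(NULL, colnames(gt)))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  hit <- clean %in% names(known)
  dos[hit] <- known[clean[hit]]
  bad <- !hit & !grepl(".", clean, fixed = TRUE) & !is.na(clean)
  if (any(bad))
    stop("unparseable GT value(s), e.g. ", utils::head(gt[bad], 1))
  sites <- GRanges(fix[, "CHROM"],
                   IRanges(as.integer(fix[, "POS"]), width = 1L),
                   ref = fix[, "REF"], alt = fix[, "ALT"])
  o <- order(sites)
  gm <- GenotypeMatrix(dos[o, , drop = FALSE], sites[o])
  if (!is.null(groups)) {
    if (is.character(groups) && length(groups) == 1L && file.exists(groups))
      groups <- readGroups(groups)
    groupMap(gm) <- groups
  }
  gm
}

#' Write a GenotypeMatrix as a minimal VCF 4.2
#'
#' GT-only records; missing genotypes are written `./.` and dosage 1 as
#' `0/1` (phase is not modelled).  Contig header lines carry the
#' chromosome lengths when `seqlengths` are known.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path (plain text).
#' @return invisibly, `path`.
#' @export
writeGenotypeVcf <- function(gm, path) {
  sites <- siteRanges(gm)
  dos <- dosage(gm)
  sl <- seqlengths(sites)
  contig <- if (length(sl) && !all(is.na(sl)))
    sprintf("##contig=<ID=%s,length=%d>", names(sl), sl) else
    sprintf("##contig=<ID=%s>", seqlevels(sites))
  hdr <- c("##fileformat=VCFv4.2",
           contig,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(dos)), collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  gtxt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gtxt[ok] <- code[dos[ok] + 1L]
  body <- paste(as.character(seqnames(sites)), start(sites), ".",
                mcols(sites)$ref, mcols(sites)$alt, ".", "PASS", ".", "GT",
                apply(gtxt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write accession-to-group tables
#'
#' Two-column tab-separated files, `accession<TAB>group`, no header.
#'
#' @param path file path.
#' @return `readGroups()` a named character vector (accession -> group).
#' @export
readGroups <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("accession", "group"),
                          colClasses = "character")
  stats::setNames(df$group, df$accession)
}

#' @rdname readGroups
#' @param groups named character vector, accession -> group.
#' @export
writeGroups <- function(groups, path) {
  utils::write.table(data.frame(names(groups), unname(groups)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write phenotype tables
#'
#' Two-column tab-separated files, `accession<TAB>value`, no header.
#'
#' @param path file path.
#' @return `readPhenotype()` a named numeric vector.
#' @export
readPhenotype <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("accession", "value"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$value, df$accession)
}

#' @rdname readPhenotype
#' @param pheno named numeric vector.
#' @export
writePhenotype <- function(pheno, path) {
  utils::write.table(data.frame(names(pheno), unname(pheno)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open on disk; in memory intervals are `GRanges`
#' (1-based closed), so `start` gains 1 on read and loses 1 on write.
#'
#' @param path file path.
#' @return `readBed()` a `GRanges`.
#' @export
readBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  gr <- GRanges(as.character(df[[1]]), IRanges(df[[2]] + 1L, df[[3]]))
  if (ncol(df) >= 4) mcols(gr)$name <- as.character(df[[4]])
  gr
}

#' @rdname readBed
#' @param gr a `GRanges`.
#' @param name optional character vector written as the 4th column.
#' @export
writeBed <- function(gr, path, name = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(name)) df$name <- name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
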