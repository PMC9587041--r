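#' Supervised per-block local-ancestry estimation
#'
#' For each target accession and block, the donor-ancestry dosage q in
#' \[0, 1\] maximizes the supervised binomial likelihood
#' `prod_s Binom(g_s; 2, q f_A,s + (1-q) f_B,s)` over the block's sites,
#' where f_A and f_B are the two reference panels' allele frequencies
#' (recomputed leaving the target out whenever it belongs to a panel).
#' The maximization combines a bounded 1-D golden-section search
#' (tolerance 1e-4) with explicit evaluation of both boundaries, so fixed
#' differences resolve exactly to q = 0 or 1.  Mixture frequencies are
#' clamped away from 0/1 by 1e-9 to keep the log-likelihood finite.
#'
#' @param gm a [GenotypeMatrix-class] with a group map.
#' @param grid block `GRanges` (the 200 kb admixture grid by default
#'   convention).
#' @param panelA,panelB reference group names (A is the "donor" whose
#'   dosage q reports; each panel needs >= 5 accessions).
#' @param targets accessions to score (default: all).
#' @param minSnps minimum number of sites with data in both panels for a
#'   callable block (default 5); otherwise `NA`.
#' @param tol search tolerance on q.
#' @return numeric matrix, targets x blocks, of q estimates; block grid
#'   attached as attribute `grid`.
#' @export
estimateBlockAncestry <- function(gm, grid, panelA, panelB,
                                  targets = NULL, minSnps = 5L,
                                  tol = 1e-4) {
  gmap <- groupMap(gm)
  if (is.null(gmap)) stop("genotype matrix needs a group map")
  membersA <- names(gmap)[gmap == panelA]
  membersB <- names(gmap)[gmap == panelB]
  if (length(membersA) < 5L || length(membersB) < 5L)
    stop("each reference panel needs at least 5 accessions")
  if (is.null(targets)) targets <- accessionIds(gm)
  dos <- dosage(gm)
  blockOf <- siteBlocks(gm, grid)
  eps <- 1e-9
  panelStats <- function(members) {
    sub <- dos[, members, drop = FALSE]
    list(sum = rowSums(sub, na.rm = TRUE), n = rowSums(!is.na(sub)))
  }
  A <- panelStats(membersA); B <- panelStats(membersB)
  q <- matrix(NA_real_, length(targets), length(grid),
              dimnames = list(targets, NULL))
  for (b in seq_along(grid)) {
    idx <- which(blockOf == b)
    if (!length(idx)) next
    for (ti in seq_along(targets)) {
      tg <- targets[ti]
      g <- dos[idx, tg]
      sA <- A$sum[idx]; nA <- A$n[idx]
      sB <- B$sum[idx]; nB <- B$n[idx]
      gobs <- !is.na(g)
      if (tg %in% membersA) {     # leave-one-out panel frequencies
        sA <- sA - ifelse(gobs, g, 0); nA <- nA - gobs
      }
      if (tg %in% membersB) {
        sB <- sB - ifelse(gobs, g, 0); nB <- nB - gobs
      }
      use <- gobs & nA > 0 & nB > 0
      if (sum(use) < minSnps) next
      fA <- sA[use] / (2 * nA[use])
      fB <- sB[use] / (2 * nB[use])
      gg <- g[use]
      ll <- function(qq) {
        m <- pmin(pmax(qq * fA + (1 - qq) * fB, eps), 1 - eps)
        sum(gg * log(m) + (2 - gg) * log1p(-m))
      }
      opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = tol)
      cand <- c(0, opt$maximum, 1)
      vals <- c(ll(0), opt$objective, ll(1))
      q[ti, b] <- cand[which.max(vals)]
    }
  }
  attr(q, "grid") <- grid
  q
}

#' Admixture association mapping
#'
#' Per block, ordinary least squares
#' `phenotype ~ intercept + block ancestry dosage + global mean ancestry
#' (+ covariates)`, with a two-sided t-test on the dosage coefficient.
#' The accession's mean ancestry across all blocks is always included to
#' control for genome-wide structure confounding.  The genomic inflation
#' factor lambda (median association chi-square over its null median) is
#' reported as an attribute.
#'
#' @param ancestry targets x blocks q matrix from
#'   [estimateBlockAncestry()] (or an externally produced matrix with
#'   accession rownames).
#' @param phenotype named numeric vector.
#' @param covariates optional numeric matrix/data.frame with accession
#'   rownames.
#' @param grid optional block `GRanges` (defaults to `attr(ancestry,
#'   "grid")`) used to annotate the result rows.
#' @param minN minimum accessions with data per block (default 10).
#' @return data.frame per block: `block`, `beta`, `se`, `t`, `p`, `n`
#'   (plus `chrom`, `start`, `end` when a grid is known), with attribute
#'   `lambda`.  Blocks with constant dosage or a rank-deficient design
#'   give `NA` rows.
#' @export
associateAncestry <- function(ancestry, phenotype, covariates = NULL,
                              grid = NULL, minN = 10L) {
  if (is.null(grid)) grid <- attr(ancestry, "grid")
  common <- intersect(rownames(ancestry), names(phenotype))
  if (length(common) < minN)
    stop("fewer than ", minN, " accessions with ancestry and phenotype")
  qm <- ancestry[common, , drop = FALSE]
  y <- phenotype[common]
  cv <- NULL
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[common, , drop = FALSE]
  }
  qbar <- rowMeans(qm, na.rm = TRUE)
  nb <- ncol(qm)
  out <- data.frame(block = seq_len(nb), beta = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_, n = NA_integer_)
  for (b in seq_len(nb)) {
    qb <- qm[, b]
    ok <- !is.na(qb) & !is.na(y) & !is.na(qbar)
    if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
    if (sum(ok) < minN) next
    out$n[b] <- sum(ok)
    if (stats::var(qb[ok]) == 0) next
    X <- cbind(1, qb[ok], qbar[ok], if (!is.null(cv)) cv[ok, , drop = FALSE])
    fit <- stats::lm.fit(X, y[ok])
    if (is.na(fit$coefficients[2L])) {
      warning("rank-deficient design at block ", b)
      next
    }
    rk <- fit$rank
    df <- sum(ok) - rk
    if (df < 1L) next
    piv <- fit$qr$pivot[seq_len(rk)]
    j <- match(2L, piv)
    if (is.na(j)) next
    rss <- sum(fit$residuals^2)
    XtXinv <- tryCatch(chol2inv(chol(crossprod(X[, piv, drop = FALSE]))),
                       error = function(e) NULL)
    if (is.null(XtXinv)) next
    sigma2 <- rss / df
    se <- sqrt(sigma2 * XtXinv[j, j])
    beta <- fit$coefficients[2L]
    tv <- beta / se
    out$beta[b] <- beta
    out$se[b] <- se
    out$t[b] <- tv
    out$p[b] <- 2 * stats::pt(-abs(tv), df)
  }
  if (!is.null(grid) && length(grid) == nb) {
    out$chrom <- as.character(seqnames(grid))
    out$start <- start(grid)
    out$end <- end(grid)
  }
  chi <- stats::qchisq(out$p, df = 1, lower.tail = FALSE)
  attr(out, "lambda") <-
    stats::median(chi, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
  out
}
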