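## Linear mixed model association engine: an exact, desk-scale analog of
## the infinitesimal-model LMM used by large-cohort GWAS tools. Variance
## components are estimated by REML via one eigendecomposition of the
## genetic relationship matrix and a bounded 1-D search on the variance
## ratio; per-SNP effects are generalized-least-squares Wald tests under
## the fitted covariance, with leave-one-chromosome-out (LOCO) relatedness
## by default.

#' Genetic relationship matrix
#'
#' `K = Z Z' / M` over the `M` SNPs passing the MAF filter, where `Z`
#' standardizes each dosage column to mean 0 and (Hardy-Weinberg) variance
#' 1: `z = (x - 2p) / sqrt(2 p (1 - p))` with `p` the sample ALT
#' frequency.
#'
#' @param panel a [GenotypePanel-class].
#' @param mafFilter minimum folded MAF for a SNP to enter the GRM.
#' @return an n x n symmetric matrix with attributes `snps` (SNP ids used)
#'   and `M`.
#' @export
computeGRM <- function(panel, mafFilter = 0.01) {
  d <- dosages(panel)
  p <- colMeans(d) / 2
  v <- colMeans(d^2) - (2 * p)^2
  keep <- pmin(p, 1 - p) >= pmax(mafFilter, 1e-12) & v > 0
  if (sum(keep) < 1)
    stop("no polymorphic SNPs left after the MAF filter")
  Z <- .standardizedDosage(d[, keep, drop = FALSE], p[keep])
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(d), rownames(d))
  attr(K, "snps") <- colnames(d)[keep]
  attr(K, "M") <- ncol(Z)
  K
}

.standardizedDosage <- function(d, p = colMeans(d) / 2) {
  sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
}

#' Ancestral principal components
#'
#' Top-k eigenvectors of the GRM, sign-fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param x a Kinship matrix from [computeGRM()] or a
#'   [GenotypePanel-class].
#' @param k number of components (`k < n`).
#' @return n x k matrix of component scores.
#' @export
computePCs <- function(x, k = 10L) {
  K <- if (is(x, "GenotypePanel")) computeGRM(x) else x
  if (k >= nrow(K)) stop("k must be smaller than the number of subjects")
  e <- eigen(K, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Greedy LD pruning
#'
#' Walks each chromosome in position order and keeps a SNP only if its
#' squared correlation with every already-kept SNP within the window is
#' below the threshold. The pruned set is the standard input for
#' ancestry principal components, which would otherwise load on
#' individual LD blocks at small panel sizes.
#'
#' @param panel a [GenotypePanel-class].
#' @param r2Threshold prune threshold on r-squared (default 0.2).
#' @param windowBp comparison window in base pairs (default 1 Mb).
#' @return character vector of retained SNP ids.
#' @export
ldPrune <- function(panel, r2Threshold = 0.2, windowBp = 1e6) {
  info <- snpInfo(panel)
  d <- dosages(panel)
  keep <- character(0)
  for (c1 in unique(info$chrom)) {
    sel <- which(info$chrom == c1)
    sel <- sel[order(info$pos[sel])]
    kept <- integer(0)
    for (j in sel) {
      near <- kept[info$pos[j] - info$pos[kept] <= windowBp]
      ok <- TRUE
      if (length(near)) {
        sj <- stats::sd(d[, j])
        if (sj == 0) next
        r2 <- (stats::cor(d[, j], d[, near, drop = FALSE]))^2
        ok <- all(r2 < r2Threshold, na.rm = TRUE)
      }
      if (ok) kept <- c(kept, j)
    }
    keep <- c(keep, info$snp[kept])
  }
  keep
}

## Restricted log-likelihood machinery in the GRM eigenbasis.
## w_i = gamma * D_i + 1 (V = sigmaE2 * (gamma K + I), gamma = sg2/se2).
.remlProfile <- function(logGamma, D, tY, tX) {
  w <- exp(logGamma) * D + 1
  sw <- 1 / sqrt(w)
  Xw <- tX * sw
  yw <- tY * sw
  XtX <- crossprod(Xw)
  b <- solve(XtX, crossprod(Xw, yw))
  r <- yw - Xw %*% b
  q <- ncol(tX)
  n <- length(tY)
  se2 <- sum(r^2) / (n - q)
  ll <- -0.5 * ((n - q) * log(se2) + sum(log(w)) +
                  determinant(XtX, logarithm = TRUE)$modulus +
                  (n - q) * (1 + log(2 * pi)))
  list(ll = as.numeric(ll), se2 = se2)
}

#' REML fit of the null mixed model
#'
#' Fits `y = X beta + g + e` with `g ~ N(0, sigmaG2 K)` and
#' `e ~ N(0, sigmaE2 I)` by restricted maximum likelihood: one
#' eigendecomposition of `K` and a bounded scalar search on
#' `log(sigmaG2 / sigmaE2)` over `[-10, 10]` (tolerance 1e-8). When the
#' optimum sits at the lower boundary the genetic variance is reported as
#' exactly zero and the model reduces to ordinary least squares.
#'
#' @param y trait vector.
#' @param X covariate matrix (full rank, including the intercept).
#' @param K kinship matrix (positive semidefinite within tolerance).
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)`.
#' @return list with `sigmaG2`, `sigmaE2`, `loglik`, `gamma` and the
#'   eigendecomposition used (`eig`).
#' @export
remlFitNull <- function(y, X, K, eig = NULL) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), nrow(X) >= ncol(X) + 2)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  D <- eig$values
  if (min(D) < -1e-6 * max(abs(D)))
    stop("kinship matrix is not positive semidefinite within tolerance")
  D <- pmax(D, 0)
  tY <- as.vector(crossprod(eig$vectors, y))
  tX <- crossprod(eig$vectors, X)
  opt <- stats::optimize(function(lg) .remlProfile(lg, D, tY, tX)$ll,
                         interval = c(-10, 10), maximum = TRUE, tol = 1e-8)
  lg <- opt$maximum
  atBoundary <- lg <= -10 + 1e-3
  pr0 <- .remlProfile(if (atBoundary) -Inf else lg, D, tY, tX)
  gamma <- if (atBoundary) 0 else exp(lg)
  list(sigmaG2 = gamma * pr0$se2, sigmaE2 = pr0$se2,
       loglik = pr0$ll, gamma = gamma, eig = eig)
}

## Shared multi-trait scan. Y: n x t named trait matrix. Returns long
## data.frame. LOCO: the GRM for SNPs on chromosome c excludes that
## chromosome's SNPs.
.lmmScanCore <- function(Y, X, panel, loco = TRUE, mafFilter = 0.01,
                         verbose = FALSE, XByGroup = NULL) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(ncol(Y)))
  info <- snpInfo(panel)
  d <- dosages(panel)
  n <- nrow(d)
  p <- colMeans(d) / 2
  v <- colMeans(d^2) - (2 * p)^2
  poly <- pmin(p, 1 - p) >= pmax(mafFilter, 1e-12) & v > 0
  if (sum(poly) < 2) stop("fewer than 2 testable SNPs")
  Z <- .standardizedDosage(d[, poly, drop = FALSE], p[poly])
  ZZt <- tcrossprod(Z)
  M <- ncol(Z)
  chrPoly <- info$chrom[poly]
  groups <- if (loco) unique(info$chrom) else "all"

  out <- vector("list", length(groups) * ncol(Y))
  oi <- 0L
  for (g in groups) {
    if (loco) {
      inC <- chrPoly == g
      Mout <- M - sum(inC)
      K <- if (Mout >= 2) {
        Zc <- Z[, inC, drop = FALSE]
        (ZZt - tcrossprod(Zc)) / Mout
      } else ZZt / M
      snpSel <- which(info$chrom == g)
    } else {
      K <- ZZt / M
      snpSel <- seq_len(nrow(info))
    }
    Xg <- if (!is.null(XByGroup)) cbind(X, XByGroup[[g]]) else X
    eig <- eigen(K, symmetric = TRUE)
    Ut <- t(eig$vectors)
    tX <- Ut %*% Xg
    tG <- Ut %*% d[, snpSel, drop = FALSE]
    testable <- poly[snpSel]
    for (tr in colnames(Y)) {
      fit <- remlFitNull(Y[, tr], Xg, K, eig = eig)
      w <- fit$gamma * pmax(eig$values, 0) + 1
      sw <- 1 / sqrt(w)
      Xw <- tX * sw
      yw <- as.vector(Ut %*% Y[, tr]) * sw
      Q <- qr.Q(qr(Xw))
      yr <- yw - Q %*% crossprod(Q, yw)
      Gw <- tG * sw
      Gr <- Gw - Q %*% crossprod(Q, Gw)
      xx <- colSums(Gr^2)
      xy <- as.vector(crossprod(Gr, yr))
      beta <- ifelse(testable, xy / xx, 0)
      se <- ifelse(testable, sqrt(fit$sigmaE2 / xx), NA_real_)
      chisq <- ifelse(testable, beta^2 / (fit$sigmaE2 / xx), 0)
      pv <- ifelse(testable,
                   pmax(stats::pchisq(chisq, 1, lower.tail = FALSE), 1e-300),
                   1)
      oi <- oi + 1L
      out[[oi]] <- data.frame(
        snp = info$snp[snpSel], chrom = info$chrom[snpSel],
        pos = info$pos[snpSel], ref = info$ref[snpSel],
        alt = info$alt[snpSel], af = p[snpSel], trait = tr,
        beta = beta, se = se, chisq = chisq, pvalue = pv,
        tested = testable, row.names = NULL)
    }
    if (verbose) message("scanned ", g, " (", length(snpSel), " SNPs, ",
                         ncol(Y), " traits)")
  }
  res <- do.call(rbind, out)
  res[order(match(res$trait, colnames(Y)), match(res$snp, info$snp)), ,
      drop = FALSE]
}

#' Mixed-model association scan for one trait
#'
#' Per-SNP generalized-least-squares effect and Wald chi-square (1 df)
#' under the REML-fitted covariance `V = sigmaG2 K + sigmaE2 I`, with
#' covariates projected out of both trait and dosages under the V-metric.
#' With `loco = TRUE` the kinship used for a SNP excludes its chromosome.
#' SNPs failing the MAF filter are reported untested with `beta = 0` and
#' `p = 1`. P-values are floored at 1e-300.
#'
#' @param y trait vector aligned with the panel's subjects.
#' @param X covariate matrix (intercept included).
#' @param panel a [GenotypePanel-class].
#' @param loco leave-one-chromosome-out kinship (default `TRUE`).
#' @param mafFilter minimum MAF for testing (default 0.01).
#' @return an association `data.frame` with columns `snp, chrom, pos, ref,
#'   alt, af, trait, beta, se, chisq, pvalue, tested`.
#' @export
assocScan <- function(y, X, panel, loco = TRUE, mafFilter = 0.01) {
  Y <- matrix(y, ncol = 1, dimnames = list(NULL, "y"))
  .lmmScanCore(Y, as.matrix(X), panel, loco = loco, mafFilter = mafFilter)
}

#' GWAS of every phenotype column, separately per eye
#'
#' Runs one mixed-model scan per trait per eye with age, sex and the top
#' ancestral principal components as covariates. The two eyes are never
#' meta-analyzed; downstream selection intersects their results.
#'
#' @param phenosLeft,phenosRight subjects x traits matrices (rownames =
#'   subject ids, in any order; must cover the panel's subjects).
#' @param covars `data.frame` with columns `id`, `age`, `sex`.
#' @param panel a [GenotypePanel-class].
#' @param nPCs number of GRM principal components used as covariates.
#' @param loco,mafFilter passed to the scan.
#' @param verbose log per-chromosome progress.
#' @return list with association tables `left` and `right` (columns as in
#'   [assocScan()] plus `eye`).
#' @export
runEndophenotypeGWAS <- function(phenosLeft, phenosRight, covars, panel,
                                 nPCs = 10L, loco = TRUE, mafFilter = 0.01,
                                 verbose = FALSE) {
  ids <- subjectIds(panel)
  for (nm in c("phenosLeft", "phenosRight")) {
    ph <- get(nm)
    bad <- setdiff(ids, rownames(ph))
    if (length(bad))
      stop(nm, " is missing subjects present in the panel: ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
  }
  bad <- setdiff(ids, covars$id)
  if (length(bad))
    stop("covariates are missing subjects: ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!identical(colnames(phenosLeft), colnames(phenosRight)))
    stop("left and right phenotype matrices must share trait names")
  cv <- covars[match(ids, covars$id), ]
  ## Ancestry PCs are computed from an LD-pruned SNP set and, under LOCO,
  ## excluding the test SNP's chromosome. At desk-scale panel sizes the
  ## top eigenvectors of an unpruned (or all-chromosome) GRM are
  ## individual LD-block factors, and projecting them out absorbs causal
  ## signal; at biobank panel sizes the same leakage is negligible, so
  ## this is the exact analog of genome-wide PC adjustment.
  pruned <- ldPrune(panel, r2Threshold = 0.2, windowBp = 1e6)
  dp <- dosages(panel[pruned, ])
  pp <- colMeans(dp) / 2
  keep <- pmin(pp, 1 - pp) >= pmax(mafFilter, 1e-12)
  Zp <- .standardizedDosage(dp[, keep, drop = FALSE], pp[keep])
  prChrom <- snpInfo(panel[pruned, ])$chrom[keep]
  ZZp <- tcrossprod(Zp)
  k <- min(nPCs, nrow(ZZp) - 2L)
  pcFrom <- function(Kpc) computePCs(Kpc, k = k)
  XByGroup <- NULL
  if (loco) {
    XByGroup <- lapply(unique(snpInfo(panel)$chrom), function(g) {
      inC <- prChrom == g
      Mout <- sum(!inC)
      if (Mout < k + 2L) return(pcFrom(ZZp / ncol(Zp)))
      pcFrom((ZZp - tcrossprod(Zp[, inC, drop = FALSE])) / Mout)
    })
    names(XByGroup) <- unique(snpInfo(panel)$chrom)
    X <- cbind(intercept = 1, age = cv$age, sex = cv$sex)
  } else {
    X <- cbind(intercept = 1, age = cv$age, sex = cv$sex,
               pcFrom(ZZp / ncol(Zp)))
  }
  out <- list()
  for (eye in c("left", "right")) {
    ph <- if (eye == "left") phenosLeft else phenosRight
    res <- .lmmScanCore(ph[ids, , drop = FALSE], X, panel, loco = loco,
                        mafFilter = mafFilter, verbose = verbose,
                        XByGroup = XByGroup)
    res$eye <- eye
    out[[eye]] <- res
  }
  out
}

#' Genomic inflation factor
#'
#' `lambda_GC`: the median association chi-square (1 df) implied by the
#' p-values, divided by the null median 0.4549364.
#'
#' @param pvalues p-values in `(0, 1]`.
#' @return scalar `lambda_GC`.
#' @export
genomicInflation <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("no p-values supplied")
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Split an embedding matrix into per-eye phenotype matrices
#'
#' Takes the first image per subject per eye.
#'
#' @param emb an [EmbeddingMatrix-class].
#' @return list of two subjects x d matrices, `left` and `right`.
#' @export
embeddingPhenotypes <- function(emb) {
  Z <- embeddings(emb)
  colnames(Z) <- paste0("e", seq_len(ncol(Z)))
  ids <- embeddingSubjects(emb)
  eyes <- embeddingEyes(emb)
  out <- list()
  for (eye in c("left", "right")) {
    sel <- which(eyes == eye)
    sel <- sel[!duplicated(ids[sel])]
    m <- Z[sel, , drop = FALSE]
    rownames(m) <- ids[sel]
    out[[eye]] <- m
  }
  out
}

#' Split retina-color phenotypes into per-eye matrices
#'
#' @param colors output of [extractRetinaColors()].
#' @return list of two subjects x 3 matrices (`mean_red`, `mean_green`,
#'   `mean_blue`), `left` and `right`.
#' @export
colorPhenotypes <- function(colors) {
  out <- list()
  for (eye in c("left", "right")) {
    cc <- colors[colors$eye == eye, ]
    cc <- cc[!duplicated(cc$subject_id), ]
    m <- as.matrix(cc[, c("mean_red", "mean_green", "mean_blue")])
    rownames(m) <- cc$subject_id
    out[[eye]] <- m
  }
  out
}
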