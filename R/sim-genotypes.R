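#' Simulate block-LD genotypes
#'
#' Draws a diploid biallelic panel from a Gaussian copula: each haplotype's
#' latent variables follow an AR(1) process within LD blocks (correlation
#' `withinBlockR` between adjacent SNPs, blocks independent) and are
#' thresholded at the Hardy-Weinberg quantile of the SNP's drawn allele
#' frequency, so genotype frequencies are `(1-p)^2, 2p(1-p), p^2`. SNPs are
#' split across `nChrom` chromosomes in contiguous chunks; positions are
#' 1-based multiples of `posStride`. The stored `maf` is the folded sample
#' allele frequency.
#'
#' @param config a [SimConfig-class].
#' @return a [GenotypePanel-class]; deterministic given `config@seed`.
#' @examples
#' panel <- simulateGenotypes(simConfig(nSubjects = 100, nSnps = 50, seed = 1))
#' dim(dosages(panel))
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  n <- config@nSubjects
  m <- config@nSnps
  r <- config@withinBlockR
  withSeed(substreamSeed(config@seed, "genotypes"), {
    maf <- runif(m, config@mafRange[1], config@mafRange[2])
    q <- qnorm(1 - maf)                      # latent > q  <=>  alt allele
    ## chromosome assignment: contiguous near-equal chunks
    chromIdx <- floor((seq_len(m) - 1) * config@nChrom / m) + 1L
    chrom <- paste0("chr", chromIdx)
    pos <- integer(m)
    for (c1 in unique(chromIdx)) {
      sel <- chromIdx == c1
      pos[sel] <- seq_len(sum(sel)) * config@posStride
    }
    ## blocks never straddle a chromosome boundary
    block <- integer(m)
    nb <- 0L
    for (c1 in unique(chromIdx)) {
      sel <- which(chromIdx == c1)
      b <- (seq_along(sel) - 1) %/% config@ldBlockSize + 1L
      block[sel] <- b + nb
      nb <- nb + max(b)
    }
    dos <- matrix(0L, n, m)
    for (hap in 1:2) {
      Z <- matrix(0, n, m)
      for (b in unique(block)) {
        cols <- which(block == b)
        E <- matrix(rnorm(n * length(cols)), n)
        Z[, cols[1]] <- E[, 1]
        if (length(cols) > 1)
          for (j in 2:length(cols))
            Z[, cols[j]] <- r * Z[, cols[j - 1]] + sqrt(1 - r^2) * E[, j]
      }
      dos <- dos + (Z > rep(q, each = n))
    }
    storage.mode(dos) <- "integer"
    af <- colMeans(dos) / 2
    fold <- pmin(af, 1 - af)
    rownames(dos) <- sprintf("S%05d", seq_len(n))
    colnames(dos) <- sprintf("rs%06d", seq_len(m))
    ref <- rep(c("A", "C", "G", "T"), length.out = m)
    alt <- rep(c("G", "T", "A", "C"), length.out = m)
    GenotypePanel(dos, chrom, pos, ref, alt, fold)
  })
}

#' Simulate subject covariates and latent traits
#'
#' Each latent trait is an additive genetic score plus environmental noise:
#' `trait = sum_k beta_k z_k + e`, where `z_k` is the column-standardized
#' dosage of a causal SNP, `beta_k = sqrt(varExplained_k)`, and the noise
#' variance tops the total up to 1. Age is uniform on `config@ageRange`, sex
#' is Bernoulli(0.5), and the diabetic-retinopathy grade is a fixed
#' monotone thresholding of the vessel trait (grades 0-4).
#'
#' @param panel a [GenotypePanel-class].
#' @param config the [SimConfig-class] used to generate `panel` (its
#'   `causalMap` defines the genetic architecture).
#' @return a `data.frame` with columns `id, age, sex, pigment, vessel,
#'   dr_grade`; deterministic given the seed.
#' @export
simulateSubjects <- function(panel, config) {
  stopifnot(is(panel, "GenotypePanel"), is(config, "SimConfig"))
  cm <- config@causalMap
  if (nrow(cm) && any(cm$snp > nrow(panel)))
    stop("configuration error: causalMap indices exceed the panel")
  if (nrow(cm)) {
    ve <- tapply(cm$varExplained, cm$trait, sum)
    if (any(ve >= 1)) stop("configuration error: variance budget exceeded")
  }
  d <- dosages(panel)
  n <- nrow(d)
  withSeed(substreamSeed(config@seed, "subjects"), {
    traits <- c("pigment", "vessel")
    out <- data.frame(id = rownames(d),
                      age = round(runif(n, config@ageRange[1],
                                        config@ageRange[2]), 1),
                      sex = rbinom(n, 1, 0.5))
    for (tr in traits) {
      rows <- if (nrow(cm)) which(cm$trait == tr) else integer()
      Zc <- NULL
      veSum <- 0
      beta <- numeric(0)
      for (k in rows) {
        x <- d[, cm$snp[k]]
        s <- sd(x)
        if (s == 0) next                     # monomorphic: no signal
        Zc <- cbind(Zc, (x - mean(x)) / s)
        beta <- c(beta, sqrt(cm$varExplained[k]))
        veSum <- veSum + cm$varExplained[k]
      }
      e <- rnorm(n)
      if (!is.null(Zc)) {
        ## calibrate the realized variance split exactly: the noise is
        ## residualized in-sample against the causal predictors and both
        ## components are rescaled, so each SNP's realized variance
        ## explained equals its nominal value up to O(1/n) LD leakage
        ## instead of fluctuating by Op(1/sqrt(n))
        g <- as.vector(Zc %*% beta)
        e <- stats::resid(stats::lm.fit(cbind(1, Zc), e))
        out[[tr]] <- g * sqrt(veSum) / sd(g) + e * sqrt(1 - veSum) / sd(e)
      } else {
        out[[tr]] <- e
      }
    }
    ## disease grade: monotone thresholds on the vessel trait
    out$dr_grade <- findInterval(out$vessel, qnorm(c(0.55, 0.75, 0.9, 0.97)))
    out
  })
}
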