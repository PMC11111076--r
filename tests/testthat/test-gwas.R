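test_that("GRM matches closed forms and the two-loop oracle", {
  ## one SNP, dosages {0, 2}: standardized +/- sqrt(2)
  pan <- GenotypePanel(matrix(c(0L, 2L, 1L, 1L), 2, 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))),
                       chrom = c("chr1", "chr1"), pos = c(1L, 2L),
                       ref = c("A", "A"), alt = c("G", "G"),
                       maf = c(0.5, 0.5))
  K1 <- computeGRM(pan, mafFilter = 0)
  ## s2 is monomorphic and drops out; only the {0,2} SNP remains
  expect_equal(unname(K1), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  cfg <- simConfig(nSubjects = 40, nSnps = 25, nChrom = 2, seed = 6)
  panel <- simulateGenotypes(cfg)
  K <- computeGRM(panel)
  d <- dosages(panel)[, attr(K, "snps"), drop = FALSE]
  p <- colMeans(d) / 2
  Z <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  Kor <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40)
    Kor[i, j] <- sum(Z[i, ] * Z[j, ]) / ncol(Z)
  expect_equal(unname(K), Kor, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mean(diag(K)), 1, tolerance = 0.2)

  ## duplicated subjects share their diagonal value off-diagonal
  d2 <- dosages(panel)[c(1, 1, 2:10), ]
  rownames(d2) <- paste0("r", 1:11)
  info <- snpInfo(panel)
  K2 <- computeGRM(GenotypePanel(d2, info$chrom, info$pos, info$ref,
                                 info$alt, info$maf))
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)

  mono <- GenotypePanel(matrix(1L, 5, 3,
                               dimnames = list(paste0("s", 1:5),
                                               paste0("m", 1:3))),
                        chrom = rep("chr1", 3), pos = 1:3,
                        ref = rep("A", 3), alt = rep("G", 3),
                        maf = rep(0.5, 3))
  expect_error(computeGRM(mono), "no polymorphic")
})

test_that("principal components recover structure and match the dense solver", {
  set.seed(2)
  v <- rnorm(30)
  K <- tcrossprod(v)
  pc <- computePCs(K, 1)
  expect_equal(abs(stats::cor(pc[, 1], v)), 1, tolerance = 1e-8)
  expect_gt(pc[which.max(abs(pc[, 1])), 1], 0)   # sign fix

  A <- crossprod(matrix(rnorm(900), 30))
  e <- eigen(A, symmetric = TRUE)
  pc2 <- computePCs(A, 5)
  for (j in 1:5)
    expect_equal(abs(stats::cor(pc2[, j], e$vectors[, j])), 1,
                 tolerance = 1e-8)
  expect_error(computePCs(A, 30), "smaller")
})

test_that("REML reduces to OLS at zero genetic variance and recovers components", {
  cfg <- simConfig(nSubjects = 300, nSnps = 300, seed = 7)
  panel <- simulateGenotypes(cfg)
  K <- computeGRM(panel)
  eig <- eigen(K, symmetric = TRUE)
  X <- cbind(1, rnorm(300))

  set.seed(1)
  X <- cbind(1, rnorm(300))
  y0 <- X %*% c(1, 0.5) + rnorm(300)       # no genetic component
  f0 <- remlFitNull(y0, X, K, eig = eig)
  expect_identical(f0$sigmaG2, 0)
  ols <- stats::lm.fit(X, y0)$coefficients
  w <- f0$gamma * pmax(eig$values, 0) + 1
  tX <- crossprod(eig$vectors, X) / sqrt(w)
  ty <- crossprod(eig$vectors, y0) / sqrt(w)
  bg <- solve(crossprod(tX), crossprod(tX, ty))
  expect_equal(as.vector(bg), unname(ols), tolerance = 1e-6)

  ## variance-component recovery, 20 seeds
  L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)))
  set.seed(11)
  est <- replicate(20, {
    y <- as.vector(L %*% rnorm(300)) * sqrt(0.5) + rnorm(300, sd = sqrt(0.5))
    f <- remlFitNull(y, X, K, eig = eig)
    c(f$sigmaG2, f$sigmaE2)
  })
  expect_equal(mean(est[1, ]), 0.5, tolerance = 0.15)
  expect_equal(mean(est[2, ]), 0.5, tolerance = 0.15)

  ## the REML optimum dominates random ratio values
  set.seed(12)
  y <- as.vector(L %*% rnorm(300)) * 0.8 + rnorm(300, sd = 0.6)
  f <- remlFitNull(y, X, K, eig = eig)
  D <- pmax(eig$values, 0)
  tY <- as.vector(crossprod(eig$vectors, y))
  tX2 <- crossprod(eig$vectors, X)
  for (lg in runif(20, -10, 10))
    expect_gte(f$loglik + 1e-6,
               fundusGWAS:::.remlProfile(lg, D, tY, tX2)$ll)

  expect_error(remlFitNull(y, X, -K), "positive semidefinite")
})

test_that("the association scan equals dense GLS on small instances", {
  cfg <- simConfig(nSubjects = 20, nSnps = 30, nChrom = 2, seed = 6,
                   mafRange = c(0.2, 0.5))
  panel <- simulateGenotypes(cfg)
  d <- dosages(panel)
  set.seed(3)
  y <- rnorm(20)
  X <- cbind(1, rnorm(20))
  for (loco in c(FALSE, TRUE)) {
    res <- assocScan(y, X, panel, loco = loco, mafFilter = 0.05)
    info <- snpInfo(panel)
    p <- colMeans(d) / 2
    poly <- pmin(p, 1 - p) >= 0.05
    Z <- sweep(sweep(d[, poly, drop = FALSE], 2, 2 * p[poly]), 2,
               sqrt(2 * p[poly] * (1 - p[poly])), "/")
    ZZt <- tcrossprod(Z)
    for (j in which(res$tested)) {
      ch <- res$chrom[j]
      Kj <- if (loco) {
        inC <- info$chrom[poly] == ch
        (ZZt - tcrossprod(Z[, inC, drop = FALSE])) / sum(!inC)
      } else ZZt / ncol(Z)
      fit <- remlFitNull(y, X, Kj)
      V <- fit$sigmaG2 * Kj + fit$sigmaE2 * diag(20)
      Vi <- solve(V)
      A <- cbind(X, d[, res$snp[j]])
      bhat <- solve(t(A) %*% Vi %*% A, t(A) %*% Vi %*% y)
      se <- sqrt(solve(t(A) %*% Vi %*% A)[3, 3])
      expect_equal(res$beta[j], bhat[3], tolerance = 1e-8)
      expect_equal(res$se[j], se, tolerance = 1e-8)
      expect_equal(res$chisq[j], (bhat[3] / se)^2, tolerance = 1e-6)
    }
  }
})

test_that("swapping ref and alt alleles flips beta and preserves chi-square", {
  cfg <- simConfig(nSubjects = 150, nSnps = 12, nChrom = 2, seed = 9,
                   mafRange = c(0.2, 0.5))
  panel <- simulateGenotypes(cfg)
  info <- snpInfo(panel)
  swapped <- GenotypePanel(2L - dosages(panel), info$chrom, info$pos,
                           info$alt, info$ref, info$maf)
  set.seed(4)
  y <- rnorm(150); X <- matrix(1, 150)
  a <- assocScan(y, X, panel, loco = FALSE, mafFilter = 0.05)
  b <- assocScan(y, X, swapped, loco = FALSE, mafFilter = 0.05)
  expect_equal(a$beta, -b$beta, tolerance = 1e-6)
  expect_equal(a$chisq, b$chisq, tolerance = 1e-6)
})

test_that("monomorphic SNPs are reported untested with p = 1", {
  d <- cbind(s1 = c(0L, 1L, 2L, 1L, 0L, 2L), s2 = rep(1L, 6),
             s3 = c(2L, 0L, 1L, 2L, 1L, 0L))
  rownames(d) <- paste0("i", 1:6)
  pan <- GenotypePanel(d, rep("chr1", 3), 1:3, rep("A", 3), rep("G", 3),
                       rep(0.5, 3))
  res <- assocScan(rnorm(6), matrix(1, 6), pan, loco = FALSE, mafFilter = 0)
  i <- which(res$snp == "s2")
  expect_false(res$tested[i])
  expect_identical(res$pvalue[i], 1)
  expect_identical(res$beta[i], 0)
})

test_that("per-eye GWAS validates alignment and scans every trait", {
  sc <- smallCohort()
  ids <- sc$subjects$id
  ph <- matrix(rnorm(24), 12, 2, dimnames = list(ids, c("t1", "t2")))
  gw <- runEndophenotypeGWAS(ph, ph, sc$subjects[, c("id", "age", "sex")],
                             sc$panel, nPCs = 2)
  expect_equal(nrow(gw$left), 2 * nrow(sc$panel))
  expect_identical(gw$left$pvalue, gw$right$pvalue)  # identical phenotypes
  expect_identical(unique(gw$left$eye), "left")

  expect_error(runEndophenotypeGWAS(ph[1:5, ], ph,
                                    sc$subjects[, c("id", "age", "sex")],
                                    sc$panel, nPCs = 2),
               "missing subjects")
})

test_that("the genomic inflation factor has its defining properties", {
  expect_equal(genomicInflation(rep(0.5, 11)), 1)
  ## doubling every chi-square doubles lambda
  set.seed(5)
  chi <- rchisq(400, 1)
  p1 <- stats::pchisq(chi, 1, lower.tail = FALSE)
  p2 <- stats::pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomicInflation(p2), 2 * genomicInflation(p1),
               tolerance = 1e-10)
  set.seed(6)
  expect_equal(genomicInflation(runif(10000)), 1, tolerance = 0.05)
  expect_error(genomicInflation(numeric(0)), "no p-values")
})
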