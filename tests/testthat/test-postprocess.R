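test_that("dual-eye intersection keeps only variants replicating in both eyes", {
  tab <- function(p) data.frame(snp = "rs1", chrom = "chr1", pos = 100L,
                                trait = "t1", pvalue = p)
  expect_equal(intersectEyes(tab(1e-9), tab(2e-8))$reported_p, 1e-9)
  expect_equal(nrow(intersectEyes(tab(1e-9), tab(6e-8))), 0)

  bad <- rbind(tab(1e-9), transform(tab(1e-9), snp = "rs2"))
  expect_error(intersectEyes(bad, tab(1e-9)), "symmetric difference")

  ## brute-force double-loop oracle on random tables
  pair <- randomAssocPair(nSnp = 25, nTrait = 4, seed = 77)
  thr <- 1e-4
  got <- intersectEyes(pair$left, pair$right, threshold = thr)
  want <- character()
  for (s in unique(pair$left$snp)) {
    pl <- min(pair$left$pvalue[pair$left$snp == s])
    pr <- min(pair$right$pvalue[pair$right$snp == s])
    if (pl < thr && pr < thr) want <- c(want, s)
  }
  expect_setequal(got$snp, want)
  for (i in seq_len(nrow(got)))
    expect_equal(got$reported_p[i],
                 min(pair$left$pvalue[pair$left$snp == got$snp[i]],
                     pair$right$pvalue[pair$right$snp == got$snp[i]]))

  ## monotone in the threshold
  lo <- intersectEyes(pair$left, pair$right, threshold = 1e-5)
  expect_true(all(lo$snp %in% got$snp))
})

test_that("pairwise hits require the same trait to replicate", {
  pair <- randomAssocPair(nSnp = 15, nTrait = 3, seed = 5)
  thr <- 1e-3
  got <- pairwiseHits(pair$left, pair$right, threshold = thr)
  key <- paste(pair$left$snp, pair$left$trait)
  rk <- paste(pair$right$snp, pair$right$trait)
  want <- key[pair$left$pvalue < thr &
                pair$right$pvalue[match(key, rk)] < thr]
  expect_setequal(paste(got$snp, got$trait), want)

  one <- data.frame(snp = "rs1", chrom = "chr1", pos = 1L, trait = "t1",
                    pvalue = 1e-9)
  expect_equal(nrow(pairwiseHits(one, transform(one, pvalue = 0.5))), 0)
  expect_equal(nrow(pairwiseHits(one, one)), 1)
})

test_that("LD r-squared matches the textbook formula and flags monomorphics", {
  cfg <- simConfig(nSubjects = 200, nSnps = 12, nChrom = 1, seed = 15)
  panel <- simulateGenotypes(cfg)
  r2 <- ldR2Matrix(panel)
  d <- dosages(panel)
  for (i in 1:12) for (j in 1:12)
    expect_equal(r2[i, j], stats::cor(d[, i], d[, j])^2, tolerance = 1e-12)

  ## duplicated SNP column
  d2 <- cbind(d[, 1:2], dup = d[, 1])
  pan2 <- GenotypePanel(d2, rep("chr1", 3), c(1L, 2L, 3L), rep("A", 3),
                        rep("G", 3), rep(0.3, 3))
  expect_equal(ldR2Matrix(pan2)[1, 3], 1)

  d3 <- cbind(d[, 1, drop = FALSE], mono = rep(1L, 200))
  pan3 <- GenotypePanel(d3, rep("chr1", 2), c(1L, 2L), rep("A", 2),
                        rep("G", 2), c(0.3, 0.5))
  expect_warning(r3 <- ldR2Matrix(pan3), "monomorphic")
  expect_equal(r3["mono", 1], 0)
  expect_equal(diag(r3), c(1, 1), ignore_attr = TRUE)
})

test_that("independent SNPs have near-zero off-diagonal r-squared", {
  cfg <- simConfig(nSubjects = 5000, nSnps = 20, withinBlockR = 0,
                   nChrom = 20, seed = 16)
  r2 <- ldR2Matrix(simulateGenotypes(cfg))
  expect_lt(mean(r2[upper.tri(r2)]), 0.01)
})

test_that("clumping merges by LD or distance with transitive closure", {
  mkVar <- function(snp, chrom, pos, p) data.frame(snp = snp, chrom = chrom,
                                                   pos = pos,
                                                   reported_p = p)
  ## independent dosages so LD never merges; distances drive everything
  set.seed(20)
  d <- matrix(rbinom(400 * 3, 2, 0.4), 400)
  colnames(d) <- c("a", "b", "c"); rownames(d) <- paste0("s", 1:400)

  pan2 <- GenotypePanel(d[, 1:2], c("chr1", "chr1"), c(1L, 300001L),
                        c("A", "A"), c("G", "G"), c(0.4, 0.4))
  v2 <- mkVar(c("a", "b"), "chr1", c(1L, 300001L), c(1e-9, 1e-10))
  expect_equal(nrow(clumpLoci(v2, pan2)), 2)

  ## chain: a-b 200 kb, b-c 200 kb, a-c 400 kb -> one locus
  pan3 <- GenotypePanel(d, rep("chr1", 3), c(1L, 200001L, 400001L),
                        rep("A", 3), rep("G", 3), rep(0.4, 3))
  v3 <- mkVar(c("a", "b", "c"), "chr1", c(1L, 200001L, 400001L),
              c(1e-9, 1e-8, 1e-10))
  loci <- clumpLoci(v3, pan3)
  expect_equal(nrow(loci), 1)
  expect_identical(loci$lead_snp, "c")
  expect_equal(loci$n_snps, 3)

  ## distinct chromosomes never merge
  pan4 <- GenotypePanel(d, c("chr1", "chr2", "chr3"), rep(1L, 3),
                        rep("A", 3), rep("G", 3), rep(0.4, 3))
  v4 <- mkVar(c("a", "b", "c"), c("chr1", "chr2", "chr3"), rep(1L, 3),
              rep(1e-9, 3))
  expect_equal(nrow(clumpLoci(v4, pan4)), 3)

  expect_equal(nrow(clumpLoci(v4[0, ], pan4)), 0)
})

test_that("clumping equals the brute-force closure on random instances", {
  closureOracle <- function(v, r2, r2thr, dthr) {
    n <- nrow(v)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      adj[i, j] <- i == j || (v$chrom[i] == v$chrom[j] &&
        (r2[v$snp[i], v$snp[j]] > r2thr || abs(v$pos[i] - v$pos[j]) <= dthr))
    reach <- adj
    for (k in seq_len(n))                     # Floyd-Warshall closure
      reach <- reach | (reach[, k] %o% reach[k, ] > 0)
    comp <- apply(reach, 1, function(r) min(which(r)))
    split(v$snp, comp)
  }
  set.seed(30)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    m <- sample(150:250, 1)
    d <- matrix(rbinom(m * n, 2, runif(1, 0.2, 0.5)), m)
    colnames(d) <- paste0("v", seq_len(n))
    rownames(d) <- paste0("s", seq_len(m))
    ## duplicate some columns to create real LD edges
    if (n > 2 && runif(1) < 0.5) d[, n] <- d[, 1]
    chrom <- paste0("chr", sample(1:2, n, replace = TRUE))
    pos <- sample.int(1e6, n)
    o <- order(chrom, pos)
    pan <- GenotypePanel(d[, o, drop = FALSE], chrom[o], pos[o],
                         rep("A", n), rep("G", n), rep(0.3, n))
    v <- data.frame(snp = colnames(d)[o], chrom = chrom[o], pos = pos[o],
                    reported_p = 10^runif(n, -12, -8))
    ## present the variants in scrambled order: output must not care
    vs <- v[sample(n), ]
    loci <- clumpLoci(vs, pan, r2Threshold = 0.2, distThreshold = 250000)
    r2 <- suppressWarnings(ldR2Matrix(pan, v$snp))
    want <- closureOracle(v, r2, 0.2, 250000)
    got <- lapply(strsplit(loci$members, ","), sort)
    expect_setequal(got, lapply(want, sort))
    expect_true(all(loci$min_p < 5e-8))
  }
})

test_that("LD scores equal the windowed double-loop oracle", {
  cfg <- simConfig(nSubjects = 300, nSnps = 30, ldBlockSize = 5,
                   nChrom = 2, seed = 21)
  panel <- simulateGenotypes(cfg)
  expect_equal(unname(computeLdScores(panel, windowBp = 0)), rep(1, 30))

  l <- computeLdScores(panel, windowBp = 20000)
  info <- snpInfo(panel)
  d <- dosages(panel)
  for (j in 1:30) {
    lj <- 0
    for (k in 1:30)
      if (info$chrom[j] == info$chrom[k] &&
          abs(info$pos[j] - info$pos[k]) <= 20000)
        lj <- lj + stats::cor(d[, j], d[, k])^2
    expect_equal(unname(l[j]), lj, tolerance = 1e-12)
  }
  expect_true(all(l >= 1))
})

test_that("LD-score regression recovers heritability", {
  set.seed(22)
  l <- runif(2000, 1, 10)
  N <- 1000; M <- 2000
  ## noiseless line: exact recovery
  f <- ldscH2(1 + N * 0.3 * l / M, l, N, M)
  expect_equal(f$h2, 0.3, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)

  ## null: no heritability
  est0 <- replicate(20, ldscH2(rchisq(M, 1), l, N, M)$h2)
  expect_lt(abs(mean(est0)), 0.05)

  ## model recovery
  mu <- 1 + N * 0.3 * l / M
  est <- replicate(50, ldscH2(mu * rchisq(M, 1), l, N, M)$h2)
  expect_equal(mean(est), 0.3, tolerance = 0.05)
  expect_true(f$h2_se >= 0)

  expect_error(ldscH2(rchisq(10, 1), rep(2, 10), 100, 10), "constant")
})

test_that("genetic correlation regression behaves at its reference points", {
  set.seed(23)
  M <- 1500; N <- 800
  l <- runif(M, 1, 10)
  ## construct z-scores from the generating model with shared effects
  mkz <- function(rhoShared) {
    base <- sqrt(N * 0.3 * l / M)
    u <- rnorm(M)
    z1 <- base * u + rnorm(M)
    z2 <- base * (rhoShared * u + sqrt(1 - rhoShared^2) * rnorm(M)) + rnorm(M)
    list(z1 = z1, z2 = z2)
  }
  ## identical summary statistics: rg = 1 with self-consistent h2
  z <- mkz(1)
  h2 <- ldscH2(z$z1^2, l, N, M)$h2
  expect_equal(ldscRg(z$z1, z$z1, l, N, N, M, h2, h2)$rg, 1,
               tolerance = 0.05)

  rg0 <- replicate(20, { z <- mkz(0)
    h1 <- ldscH2(z$z1^2, l, N, M)$h2; h2b <- ldscH2(z$z2^2, l, N, M)$h2
    ldscRg(z$z1, z$z2, l, N, N, M, max(h1, 0.01), max(h2b, 0.01))$rg })
  expect_lt(abs(mean(rg0)), 0.1)

  rg1 <- replicate(20, { z <- mkz(1)
    h1 <- ldscH2(z$z1^2, l, N, M)$h2; h2b <- ldscH2(z$z2^2, l, N, M)$h2
    ldscRg(z$z1, z$z2, l, N, N, M, max(h1, 0.01), max(h2b, 0.01))$rg })
  expect_gt(mean(rg1), 0.8)

  expect_error(ldscRg(rnorm(10), rnorm(10), runif(10, 1, 3), 100, 100, 10,
                      0, 0.3), "non-positive")
})

test_that("endophenotype descriptives order correlations and flag constants", {
  set.seed(24)
  Z <- matrix(rnorm(500 * 6), 500)
  Z[, 6] <- Z[, 1]                          # duplicated trait
  colnames(Z) <- paste0("e", 1:6)
  de <- endophenotypeDescriptives(Z)
  A <- de$correlation
  expect_true(isSymmetric(A))
  expect_equal(unname(diag(A)), rep(1, 6))
  expect_equal(A["e1", "e6"], 1)
  ## duplicated traits end up adjacent after clustering
  expect_equal(abs(diff(match(c("e1", "e6"), rownames(A)))), 1)
  offd <- A[upper.tri(A)]
  expect_lt(mean(offd[offd < 0.99]), 0.2)

  Zc <- cbind(Z[, 1:2], const = 1)
  expect_warning(dc <- endophenotypeDescriptives(Zc), "constant")
  expect_equal(dc$correlation["const", "e1"], 0)
  expect_length(de$histograms, 6)
})

test_that("catalog range queries use closed intervals per chromosome", {
  loci <- data.frame(locus = 1:2, chrom = c("chr1", "chr2"),
                     start = c(500000L, 100000L), end = c(600000L, 100000L),
                     lead_snp = c("rs1", "rs2"))
  cat1 <- data.frame(CHR = c("chr1", "chr1", "chr1", "chr2"),
                     BP = c(250000, 249999, 850001, 350000),
                     TRAIT = c("edge", "outside", "outside2", "edge2"),
                     PMID = "1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(cat1, f, sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- catalogRangeQuery(loci, f, flank = 250000)
  ## 250000 == start - flank exactly: included; 249999: excluded
  expect_setequal(hits$TRAIT, c("edge", "edge2"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  write.table(cat1[0, ], empty, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(catalogRangeQuery(loci, empty)), 0)

  ## brute-force interval oracle on random instances
  set.seed(26)
  for (rep in 1:20) {
    nl <- sample(1:5, 1); nc <- sample(5:30, 1)
    loci2 <- data.frame(locus = seq_len(nl),
                        chrom = paste0("chr", sample(1:3, nl, TRUE)),
                        start = sample.int(1e6, nl), lead_snp = "x")
    loci2$end <- loci2$start + sample.int(2e5, nl)
    cat2 <- data.frame(CHR = paste0("chr", sample(1:3, nc, TRUE)),
                       BP = sample.int(1.5e6, nc),
                       TRAIT = paste0("t", seq_len(nc)), PMID = "1")
    f2 <- tempfile(fileext = ".tsv")
    write.table(cat2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    got <- catalogRangeQuery(loci2, f2, flank = 50000)
    want <- 0L
    for (i in seq_len(nl)) for (j in seq_len(nc))
      if (cat2$CHR[j] == loci2$chrom[i] &&
          cat2$BP[j] >= loci2$start[i] - 50000 &&
          cat2$BP[j] <= loci2$end[i] + 50000) want <- want + 1L
    expect_equal(nrow(got), want)
    unlink(f2)
  }
})
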