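## Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## A small rendered cohort: 12 subjects with genotypes, traits and image
## pairs at 64 x 64.
smallCohort <- function() {
  fixture("smallCohort", function() {
    cfg <- simConfig(nSubjects = 12, nSnps = 30, ldBlockSize = 5,
                     nChrom = 2, imageSize = c(64, 64), seed = 42)
    panel <- simulateGenotypes(cfg)
    subjects <- simulateSubjects(panel, cfg)
    images <- list()
    for (i in seq_len(nrow(subjects)))
      images <- c(images, renderFundusPair(subjects[i, ], cfg,
                                           seed = 1000 + i))
    list(cfg = cfg, panel = panel, subjects = subjects, images = images)
  })
}

## A labeled quality corpus plus a trained scorer.
qualityFixture <- function() {
  fixture("quality", function() {
    cfg <- simConfig(nSubjects = 5, nSnps = 10, imageSize = c(64, 64),
                     seed = 7)
    corpus <- makeQualityCorpus(120, 120, cfg, seed = 11)
    model <- trainQualityScorer(corpus, epochs = 150, seed = 3)
    list(cfg = cfg, corpus = corpus, model = model)
  })
}

## Random unit-row matrix.
randUnit <- function(n, d) {
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

## Random association-table pair over a shared SNP universe, for
## intersection / pairwise brute-force checks.
randomAssocPair <- function(nSnp, nTrait, seed) {
  set.seed(seed)
  mk <- function() {
    expand.grid(snp = sprintf("rs%03d", seq_len(nSnp)),
                trait = paste0("t", seq_len(nTrait)),
                stringsAsFactors = FALSE) |>
      transform(chrom = "chr1", pos = match(snp, unique(snp)) * 1000L,
                pvalue = 10^runif(nSnp * nTrait, -10, 0))
  }
  list(left = mk(), right = mk())
}
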