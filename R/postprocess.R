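## Post-processing of per-eye association tables: dual-eye intersection
## replication, LD computation, locus clumping by single-link closure,
## LD scores, simplified LD-score regression, descriptive statistics and
## local catalog range queries.

.checkUniverse <- function(left, right) {
  dl <- setdiff(unique(left$snp), unique(right$snp))
  dr <- setdiff(unique(right$snp), unique(left$snp))
  if (length(dl) || length(dr))
    stop("SNP universes differ between eyes; symmetric difference: ",
         paste(utils::head(c(dl, dr), 10), collapse = ", "))
}

#' Dual-eye intersection replication
#'
#' Per SNP, takes the minimum p-value over traits within each eye; a
#' variant is selected iff both minima pass the threshold, and the smaller
#' of the two minima is reported.
#'
#' @param left,right association tables from [runEndophenotypeGWAS()]
#'   (same SNP universe).
#' @param threshold genome-wide significance threshold (default 5e-8).
#' @return `data.frame` of selected variants: `snp, chrom, pos,
#'   min_p_left, min_p_right, reported_p, best_trait_left,
#'   best_trait_right`.
#' @export
intersectEyes <- function(left, right, threshold = 5e-8) {
  .checkUniverse(left, right)
  minBy <- function(tab) {
    o <- order(tab$snp, tab$pvalue)
    t1 <- tab[o, ]
    t1[!duplicated(t1$snp), c("snp", "chrom", "pos", "pvalue", "trait")]
  }
  L <- minBy(left); R <- minBy(right)
  R <- R[match(L$snp, R$snp), ]
  sel <- L$pvalue < threshold & R$pvalue < threshold
  data.frame(snp = L$snp[sel], chrom = L$chrom[sel], pos = L$pos[sel],
             min_p_left = L$pvalue[sel], min_p_right = R$pvalue[sel],
             reported_p = pmin(L$pvalue[sel], R$pvalue[sel]),
             best_trait_left = L$trait[sel], best_trait_right = R$trait[sel],
             row.names = NULL)
}

#' SNP-trait pairs significant in both eyes
#'
#' @param left,right association tables (same SNP and trait universe).
#' @param threshold significance threshold.
#' @return `data.frame` of `(snp, trait)` pairs with both per-eye p-values.
#' @export
pairwiseHits <- function(left, right, threshold = 5e-8) {
  .checkUniverse(left, right)
  key <- function(tab) paste(tab$snp, tab$trait, sep = "\r")
  R <- right[match(key(left), key(right)), ]
  sel <- left$pvalue < threshold & R$pvalue < threshold
  sel[is.na(sel)] <- FALSE
  data.frame(snp = left$snp[sel], trait = left$trait[sel],
             p_left = left$pvalue[sel], p_right = R$pvalue[sel],
             row.names = NULL)
}

#' Pairwise LD (r-squared) matrix
#'
#' Squared Pearson correlation between dosage columns. Monomorphic SNPs
#' get r-squared 0 against everything (with a warning); the diagonal is 1.
#'
#' @param panel a [GenotypePanel-class].
#' @param snpSubset SNP ids (default: all).
#' @return symmetric r-squared matrix.
#' @export
ldR2Matrix <- function(panel, snpSubset = NULL) {
  d <- dosages(panel)
  if (!is.null(snpSubset)) {
    stopifnot(length(snpSubset) > 0)
    miss <- setdiff(snpSubset, colnames(d))
    if (length(miss)) stop("unknown SNPs: ", paste(miss, collapse = ", "))
    d <- d[, snpSubset, drop = FALSE]
  }
  sds <- apply(d, 2, stats::sd)
  mono <- sds == 0
  if (any(mono))
    warning("monomorphic SNP(s): r-squared set to 0 for ",
            paste(colnames(d)[mono], collapse = ", "))
  r2 <- matrix(0, ncol(d), ncol(d), dimnames = list(colnames(d), colnames(d)))
  if (any(!mono)) {
    cc <- stats::cor(d[, !mono, drop = FALSE])^2
    r2[!mono, !mono] <- cc
  }
  diag(r2) <- 1
  r2
}

## Union-find with path compression.
.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Merge selected variants into independent loci
#'
#' Same-chromosome variants are merged (single-link, transitively closed
#' via union-find) whenever their genotypes are in LD (`r2 >
#' r2Threshold`) or they lie within `distThreshold` base pairs of each
#' other. The lead SNP of a locus has the smallest reported p-value, ties
#' broken by smaller position.
#'
#' @param variants output of [intersectEyes()] (needs `snp, chrom, pos,
#'   reported_p`).
#' @param panel the [GenotypePanel-class] for LD computation.
#' @param r2Threshold LD merge threshold (default 0.2).
#' @param distThreshold distance merge threshold in bp (default 250000).
#' @return `data.frame` of loci: `locus, chrom, start, end, n_snps,
#'   lead_snp, min_p, members` (comma-separated SNP ids).
#' @export
clumpLoci <- function(variants, panel, r2Threshold = 0.2,
                      distThreshold = 250000) {
  if (nrow(variants) == 0)
    return(data.frame(locus = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), lead_snp = character(),
                      min_p = numeric(), members = character()))
  v <- variants[order(variants$chrom, variants$pos), ]
  n <- nrow(v)
  r2 <- suppressWarnings(ldR2Matrix(panel, v$snp))
  parent <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (v$chrom[i] != v$chrom[j]) next
      if (r2[i, j] > r2Threshold ||
          abs(v$pos[i] - v$pos[j]) <= distThreshold) {
        ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) .ufFind(parent, i), 0L)
  out <- lapply(split(seq_len(n), comp), function(ii) {
    vv <- v[ii, ]
    lead <- vv[order(vv$reported_p, vv$pos), ][1, ]
    data.frame(chrom = vv$chrom[1], start = min(vv$pos), end = max(vv$pos),
               n_snps = nrow(vv), lead_snp = lead$snp,
               min_p = lead$reported_p,
               members = paste(vv$snp, collapse = ","))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), ]
  data.frame(locus = seq_len(nrow(out)), out, row.names = NULL)
}

#' Per-SNP LD scores
#'
#' `l_j = sum_k r2_jk` over SNPs `k` within `windowBp` of SNP `j` on the
#' same chromosome, including the self term (so `windowBp = 0` gives
#' `l_j = 1`).
#'
#' @param panel a [GenotypePanel-class], sorted by position.
#' @param windowBp window half-width in base pairs (default 1 Mb).
#' @return named numeric vector of LD scores.
#' @export
computeLdScores <- function(panel, windowBp = 1e6) {
  info <- snpInfo(panel)
  d <- dosages(panel)
  l <- setNames(rep(1, nrow(info)), info$snp)
  for (c1 in unique(info$chrom)) {
    sel <- which(info$chrom == c1)
    if (length(sel) < 2) next
    r2 <- suppressWarnings(ldR2Matrix(panel, info$snp[sel]))
    dd <- abs(outer(info$pos[sel], info$pos[sel], "-"))
    r2[dd > windowBp] <- 0
    diag(r2) <- 1
    l[sel] <- rowSums(r2)
  }
  l
}

.jackknifeSE <- function(x, estimator, nBlocks = 20L) {
  n <- length(x)
  nBlocks <- min(nBlocks, n)
  blk <- floor((seq_len(n) - 1) * nBlocks / n) + 1L
  est <- vapply(seq_len(nBlocks), function(b) estimator(blk != b), 0)
  sqrt((nBlocks - 1) / nBlocks * sum((est - mean(est))^2))
}

#' LD-score regression heritability
#'
#' Regresses per-SNP chi-square on LD scores under
#' `E[chi2_j] = 1 + N h2 l_j / M` with a free intercept (unit weights);
#' `h2 = slope * M / N`. Standard errors by block jackknife.
#'
#' @param chi2 per-SNP association chi-square (1 df).
#' @param l aligned LD scores.
#' @param N GWAS sample size.
#' @param M number of SNPs the heritability is spread over.
#' @param nBlocks jackknife blocks (default 20).
#' @return list (`LdscResult`) with `h2`, `intercept`, `h2_se`,
#'   `intercept_se`, `M`, `N`.
#' @export
ldscH2 <- function(chi2, l, N, M, nBlocks = 20L) {
  stopifnot(length(chi2) == length(l), N > 0, M > 0)
  if (stats::sd(l) == 0)
    stop("LD scores are constant; the regression slope is undefined")
  fit <- function(keep) {
    cf <- stats::coef(stats::lm(chi2[keep] ~ l[keep]))
    unname(cf[2] * M / N)
  }
  cf <- stats::coef(stats::lm(chi2 ~ l))
  structure(list(h2 = unname(cf[2] * M / N), intercept = unname(cf[1]),
                 h2_se = .jackknifeSE(chi2, fit, nBlocks),
                 intercept_se = .jackknifeSE(chi2, function(keep)
                   unname(stats::coef(stats::lm(chi2[keep] ~ l[keep]))[1]),
                   nBlocks),
                 M = M, N = N), class = "LdscResult")
}

#' LD-score regression genetic correlation
#'
#' Regresses the z-score product on LD scores under
#' `E[z1 z2] = sqrt(N1 N2) rho_g l / M + intercept`;
#' `rg = rho_g / sqrt(h2_1 h2_2)`, clipped to `[-1.25, 1.25]` with a
#' warning.
#'
#' @param z1,z2 aligned per-SNP z-scores of the two traits.
#' @param l aligned LD scores.
#' @param N1,N2 sample sizes.
#' @param M SNP count.
#' @param h2_1,h2_2 heritabilities of the two traits (must be positive).
#' @param nBlocks jackknife blocks.
#' @return list (`LdscResult`) with `rg`, `rhoG`, `intercept`, `rg_se`.
#' @export
ldscRg <- function(z1, z2, l, N1, N2, M, h2_1, h2_2, nBlocks = 20L) {
  stopifnot(length(z1) == length(z2), length(z1) == length(l))
  if (h2_1 <= 0 || h2_2 <= 0)
    stop("genetic correlation undefined for non-positive heritability")
  if (stats::sd(l) == 0) stop("LD scores are constant")
  zz <- z1 * z2
  rhoOf <- function(keep) {
    cf <- stats::coef(stats::lm(zz[keep] ~ l[keep]))
    unname(cf[2] * M / sqrt(N1 * N2))
  }
  cf <- stats::coef(stats::lm(zz ~ l))
  rhoG <- unname(cf[2] * M / sqrt(N1 * N2))
  rg <- rhoG / sqrt(h2_1 * h2_2)
  if (abs(rg) > 1.25) {
    warning("rg = ", round(rg, 3), " clipped to [-1.25, 1.25]")
    rg <- clamp(rg, -1.25, 1.25)
  }
  structure(list(rg = rg, rhoG = rhoG, intercept = unname(cf[1]),
                 rg_se = .jackknifeSE(zz, function(keep)
                   rhoOf(keep) / sqrt(h2_1 * h2_2), nBlocks),
                 M = M, N = sqrt(N1 * N2)), class = "LdscResult")
}

#' Descriptive statistics of the endophenotypes
#'
#' Per-trait histograms and the absolute Pearson correlation matrix,
#' ordered by average-linkage hierarchical clustering on `1 - |r|`.
#' Constant traits get correlation 0 with a warning.
#'
#' @param emb an [EmbeddingMatrix-class] or a numeric matrix (columns =
#'   traits).
#' @param file optional path; if given the ordered correlation matrix is
#'   written as TSV.
#' @return list with `correlation` (ordered absolute correlations),
#'   `order`, and `histograms` (per trait: `breaks`, `counts`).
#' @export
endophenotypeDescriptives <- function(emb, file = NULL) {
  Z <- if (is(emb, "EmbeddingMatrix")) embeddings(emb) else as.matrix(emb)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("e", seq_len(ncol(Z)))
  stopifnot(ncol(Z) >= 2)
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0))
    warning("constant trait(s), correlation set to 0: ",
            paste(colnames(Z)[sds == 0], collapse = ", "))
  A <- matrix(0, ncol(Z), ncol(Z), dimnames = list(colnames(Z), colnames(Z)))
  ok <- sds > 0
  if (sum(ok) >= 2) A[ok, ok] <- abs(stats::cor(Z[, ok, drop = FALSE]))
  diag(A) <- 1
  ord <- if (ncol(Z) > 2)
    stats::hclust(stats::as.dist(1 - A), method = "average")$order else
      seq_len(ncol(Z))
  A <- A[ord, ord]
  hists <- lapply(colnames(Z), function(tr) {
    h <- graphics::hist(Z[, tr], breaks = 30, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  })
  names(hists) <- colnames(Z)
  if (!is.null(file))
    utils::write.table(cbind(trait = rownames(A), as.data.frame(A)), file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(correlation = A, order = ord, histograms = hists)
}

#' Range query of loci against a local association catalog
#'
#' For each locus, returns catalog entries on the same chromosome with
#' position in the closed interval `[start - flank, end + flank]`.
#'
#' @param loci output of [clumpLoci()].
#' @param catalogFile TSV with columns `CHR`, `BP`, `TRAIT` (and
#'   optionally `PMID`).
#' @param flank flanking width in bp (default 250000).
#' @return `data.frame` of overlaps: locus id plus the catalog columns.
#' @export
catalogRangeQuery <- function(loci, catalogFile, flank = 250000) {
  cat <- utils::read.delim(catalogFile, colClasses = "character")
  names(cat) <- toupper(names(cat))
  stopifnot(all(c("CHR", "BP", "TRAIT") %in% names(cat)))
  cat$BP <- as.numeric(cat$BP)
  hits <- lapply(seq_len(nrow(loci)), function(i) {
    sel <- cat$CHR == loci$chrom[i] &
      cat$BP >= loci$start[i] - flank & cat$BP <= loci$end[i] + flank
    if (!any(sel)) return(NULL)
    data.frame(locus = loci$locus[i], lead_snp = loci$lead_snp[i],
               cat[sel, , drop = FALSE], row.names = NULL)
  })
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (!length(hits))
    return(data.frame(locus = integer(), lead_snp = character(),
                      CHR = character(), BP = numeric(), TRAIT = character()))
  do.call(rbind, hits)
}
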