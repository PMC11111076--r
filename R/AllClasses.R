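#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic genotype-to-image generator. Genotypes are
#' drawn from a Gaussian copula with AR(1) correlation within LD blocks,
#' thresholded at Hardy-Weinberg quantiles of the drawn allele frequency.
#' Latent subject traits (pigmentation, vessel density) receive additive
#' genetic effects from the SNPs listed in `causalMap` and environmental
#' noise topping the variance up to 1.
#'
#' @slot nSubjects number of subjects.
#' @slot nSnps number of SNPs.
#' @slot ldBlockSize SNPs per LD block.
#' @slot withinBlockR latent AR(1) correlation between adjacent SNPs of a
#'   block, in `[0, 1)`.
#' @slot mafRange interval in `(0, 0.5]` from which per-SNP minor allele
#'   frequencies are drawn uniformly.
#' @slot causalMap `data.frame` with columns `snp` (1-based SNP index),
#'   `trait` (trait name) and `varExplained` (per-SNP fraction of trait
#'   variance, in `[0, 1)`).
#' @slot imageSize `c(rows, cols)` of rendered images.
#' @slot nChrom number of chromosomes the SNPs are split across.
#' @slot posStride base-pair distance between adjacent SNPs (positions are
#'   1-based multiples of the stride within each chromosome).
#' @slot ageRange age range (years) for the uniform age draw.
#' @slot seed master seed of the generator.
#' @export
setClass("SimConfig", representation(
  nSubjects = "integer", nSnps = "integer", ldBlockSize = "integer",
  withinBlockR = "numeric", mafRange = "numeric", causalMap = "data.frame",
  imageSize = "integer", nChrom = "integer", posStride = "integer",
  ageRange = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be positive")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be positive")
  if (object@ldBlockSize < 1L) msg <- c(msg, "ldBlockSize must be positive")
  if (object@withinBlockR < 0 || object@withinBlockR >= 1)
    msg <- c(msg, "withinBlockR must be in [0, 1)")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || diff(object@mafRange) < 0)
    msg <- c(msg, "mafRange must be an interval within (0, 0.5]")
  cm <- object@causalMap
  if (nrow(cm)) {
    if (!all(c("snp", "trait", "varExplained") %in% names(cm)))
      msg <- c(msg, "causalMap needs columns snp, trait, varExplained")
    else {
      if (any(cm$snp < 1 | cm$snp > object@nSnps))
        msg <- c(msg, "causalMap snp indices out of range")
      ve <- tapply(cm$varExplained, cm$trait, sum)
      if (any(cm$varExplained < 0) || any(ve >= 1))
        msg <- c(msg, "variance explained per trait must sum to < 1")
    }
  }
  if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
    msg <- c(msg, "imageSize must be c(rows, cols), both >= 16")
  if (object@nChrom < 1L || object@nChrom > object@nSnps)
    msg <- c(msg, "nChrom must be in [1, nSnps]")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nSubjects,nSnps cohort and panel size.
#' @param ldBlockSize,withinBlockR LD block structure: block length in SNPs
#'   and the latent AR(1) correlation between adjacent SNPs.
#' @param mafRange uniform sampling interval for minor allele frequencies.
#' @param causalMap `data.frame(snp, trait, varExplained)`; may be empty.
#' @param imageSize rendered image size, `c(rows, cols)`.
#' @param nChrom number of chromosomes.
#' @param posStride base pairs between adjacent SNPs.
#' @param ageRange uniform age range in years.
#' @param seed master seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSubjects = 50, nSnps = 40, seed = 7)
#' cfg
#' @export
simConfig <- function(nSubjects = 500L, nSnps = 2000L, ldBlockSize = 10L,
                      withinBlockR = 0.8, mafRange = c(0.05, 0.5),
                      causalMap = data.frame(snp = integer(),
                                             trait = character(),
                                             varExplained = numeric()),
                      imageSize = c(128L, 128L), nChrom = 5L,
                      posStride = 5000L, ageRange = c(40, 70), seed = 1L) {
  if (nSubjects < 1 || nSnps < 1)
    stop("configuration error: counts must be positive")
  new("SimConfig",
      nSubjects = as.integer(nSubjects), nSnps = as.integer(nSnps),
      ldBlockSize = as.integer(ldBlockSize),
      withinBlockR = as.numeric(withinBlockR),
      mafRange = as.numeric(mafRange), causalMap = causalMap,
      imageSize = as.integer(imageSize), nChrom = as.integer(nChrom),
      posStride = as.integer(posStride), ageRange = as.numeric(ageRange),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSubjects, "subjects x", object@nSnps, "SNPs,",
      object@nChrom, "chromosomes\n")
  cat("  LD blocks of", object@ldBlockSize, "SNPs, within-block r =",
      object@withinBlockR, "\n")
  cat("  MAF ~ U(", object@mafRange[1], ",", object@mafRange[2], "), stride",
      object@posStride, "bp\n")
  cat("  images", object@imageSize[1], "x", object@imageSize[2],
      "| causal SNPs:", nrow(object@causalMap), "| seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## GenotypePanel
## ---------------------------------------------------------------------------

#' Genotype panel
#'
#' A `RangedSummarizedExperiment` subclass holding a diploid biallelic
#' dosage matrix (SNPs x subjects in the assay; use [dosages()] for the
#' subjects x SNPs orientation) with per-SNP genomic coordinates, alleles
#' and folded minor allele frequency in `rowRanges`.
#'
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!all(d %in% 0:2)) msg <- c(msg, "dosages must be in {0, 1, 2}")
  rr <- SummarizedExperiment::rowRanges(object)
  if (!all(c("ref", "alt", "maf") %in% names(S4Vectors::mcols(rr))))
    msg <- c(msg, "rowRanges needs ref, alt, maf metadata columns")
  else {
    maf <- S4Vectors::mcols(rr)$maf
    if (any(maf < 0 | maf > 0.5)) msg <- c(msg, "maf must lie in [0, 0.5]")
    pos <- GenomicRanges::start(rr)
    chr <- as.character(GenomicRanges::seqnames(rr))
    for (c1 in unique(chr)) {
      p <- pos[chr == c1]
      if (any(diff(p) <= 0)) {
        msg <- c(msg, "positions must be strictly increasing per chromosome")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a genotype panel
#'
#' @param dosages subjects x SNPs integer matrix with values in `{0, 1, 2}`;
#'   rownames are subject ids, colnames SNP ids.
#' @param chrom per-SNP chromosome labels.
#' @param pos per-SNP 1-based base-pair positions.
#' @param ref,alt reference / alternate allele characters.
#' @param maf per-SNP folded minor allele frequency.
#' @return a [GenotypePanel-class].
#' @export
GenotypePanel <- function(dosages, chrom, pos, ref, alt, maf) {
  stopifnot(is.matrix(dosages), length(chrom) == ncol(dosages))
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               ref = ref, alt = alt, maf = maf)
  names(rr) <- colnames(dosages)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosages)), rowRanges = rr)
  colnames(se) <- rownames(dosages)
  new("GenotypePanel", se)
}

#' @describeIn GenotypePanel subjects x SNPs dosage matrix.
#' @param panel a [GenotypePanel-class].
#' @export
dosages <- function(panel) t(SummarizedExperiment::assay(panel, "dosage"))

#' @describeIn GenotypePanel per-SNP metadata as a `data.frame` with columns
#'   `snp`, `chrom`, `pos`, `ref`, `alt`, `maf`.
#' @export
snpInfo <- function(panel) {
  rr <- SummarizedExperiment::rowRanges(panel)
  data.frame(snp = names(rr),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = S4Vectors::mcols(rr)$ref, alt = S4Vectors::mcols(rr)$alt,
             maf = S4Vectors::mcols(rr)$maf, row.names = NULL)
}

#' @describeIn GenotypePanel subject identifiers.
#' @export
subjectIds <- function(panel) colnames(panel)

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", ncol(object), "subjects x", nrow(object), "SNPs on",
      length(unique(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(object))))), "chromosomes\n")
  maf <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))$maf
  cat("  MAF range [", round(min(maf), 3), ",", round(max(maf), 3), "]\n")
})

## ---------------------------------------------------------------------------
## FundusImage
## ---------------------------------------------------------------------------

#' A simulated fundus photograph
#'
#' RGB raster with subject id, eye side, an optional quality label, and the
#' per-image nuisance parameters that were applied at render time.
#'
#' @slot pixels rows x cols x 3 array with values in `[0, 255]`.
#' @slot subjectId subject identifier.
#' @slot eye `"left"` or `"right"`.
#' @slot qualityLabel `"good"`, `"bad"` or `"unlabeled"`.
#' @slot nuisance named numeric vector `rotation` (degrees),
#'   `illumination` (multiplicative scale), `blur` (Gaussian sigma, pixels).
#' @export
setClass("FundusImage", representation(
  pixels = "array", subjectId = "character", eye = "character",
  qualityLabel = "character", nuisance = "numeric"
))

setValidity("FundusImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be a rows x cols x 3 array")
  else if (min(object@pixels) < 0 || max(object@pixels) > 255)
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (!object@eye %in% c("left", "right"))
    msg <- c(msg, "eye must be 'left' or 'right'")
  if (!object@qualityLabel %in% c("good", "bad", "unlabeled"))
    msg <- c(msg, "qualityLabel must be good/bad/unlabeled")
  if (length(msg)) msg else TRUE
})

#' Construct a FundusImage
#'
#' @param pixels rows x cols x 3 array in `[0, 255]`.
#' @param subjectId subject identifier.
#' @param eye `"left"` or `"right"`.
#' @param qualityLabel `"good"`, `"bad"` or `"unlabeled"`.
#' @param nuisance named numeric vector (rotation, illumination, blur).
#' @return a [FundusImage-class].
#' @export
FundusImage <- function(pixels, subjectId, eye,
                        qualityLabel = "unlabeled",
                        nuisance = c(rotation = 0, illumination = 1,
                                     blur = 0)) {
  new("FundusImage", pixels = pixels, subjectId = as.character(subjectId),
      eye = eye, qualityLabel = qualityLabel, nuisance = nuisance)
}

#' @describeIn FundusImage pixel array accessor.
#' @param x a [FundusImage-class].
#' @export
imagePixels <- function(x) x@pixels

#' @describeIn FundusImage eye side accessor.
#' @export
imageEye <- function(x) x@eye

#' @describeIn FundusImage subject id accessor.
#' @export
imageSubject <- function(x) x@subjectId

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat("FundusImage", object@subjectId, sprintf("(%s eye)", object@eye),
      d[1], "x", d[2], "px, quality:", object@qualityLabel, "\n")
  cat(sprintf("  nuisance: rotation %.1f deg, illumination x%.2f, blur %.2f\n",
              object@nuisance[["rotation"]], object@nuisance[["illumination"]],
              object@nuisance[["blur"]]))
})

## ---------------------------------------------------------------------------
## EmbeddingMatrix
## ---------------------------------------------------------------------------

#' Endophenotype embedding matrix
#'
#' Images x d matrix of unit-length endophenotype vectors, with the subject
#' id and eye side of each row.
#'
#' @slot embeddings images x d numeric matrix, rows unit length.
#' @slot subjectId per-row subject identifier.
#' @slot eye per-row eye side.
#' @export
setClass("EmbeddingMatrix", representation(
  embeddings = "matrix", subjectId = "character", eye = "character"
))

setValidity("EmbeddingMatrix", function(object) {
  msg <- character()
  n <- nrow(object@embeddings)
  if (length(object@subjectId) != n || length(object@eye) != n)
    msg <- c(msg, "subjectId and eye must have one entry per row")
  nrm <- sqrt(rowSums(object@embeddings^2))
  if (n > 0 && any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "embedding rows must have unit Euclidean norm")
  if (length(msg)) msg else TRUE
})

#' Construct an EmbeddingMatrix
#'
#' @param embeddings images x d matrix (rows are unit-normalized if not
#'   already).
#' @param subjectId,eye per-row metadata.
#' @return an [EmbeddingMatrix-class].
#' @export
EmbeddingMatrix <- function(embeddings, subjectId, eye) {
  new("EmbeddingMatrix", embeddings = unitRows(embeddings),
      subjectId = as.character(subjectId), eye = as.character(eye))
}

#' @describeIn EmbeddingMatrix numeric matrix accessor.
#' @param x an [EmbeddingMatrix-class].
#' @export
embeddings <- function(x) x@embeddings

#' @describeIn EmbeddingMatrix per-row subject ids.
#' @export
embeddingSubjects <- function(x) x@subjectId

#' @describeIn EmbeddingMatrix per-row eye sides.
#' @export
embeddingEyes <- function(x) x@eye

setMethod("show", "EmbeddingMatrix", function(object) {
  cat("EmbeddingMatrix:", nrow(object@embeddings), "images x",
      ncol(object@embeddings), "endophenotypes,",
      length(unique(object@subjectId)), "subjects\n")
})

## ---------------------------------------------------------------------------
## Model classes
## ---------------------------------------------------------------------------

#' Image quality scoring model
#'
#' A small multilayer perceptron over pooled-intensity and sharpness image
#' features, trained with cross-entropy and early stopping; maps an RGB
#' image to a quality score in `[0, 1]` (1 = good).
#'
#' @slot W1,b1,W2,b2 network weights.
#' @slot center,scale feature standardization statistics.
#' @slot meta list with training metadata (epochs run, seed, loss history).
#' @export
setClass("QualityModel", representation(
  W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
  center = "numeric", scale = "numeric", meta = "list"
))

setMethod("show", "QualityModel", function(object) {
  cat("QualityModel:", ncol(object@W1), "features ->", nrow(object@W1),
      "hidden units; trained", object@meta$epochsRun, "epochs (seed",
      object@meta$seed, ")\n")
})

#' Self-supervised contrastive phenotyper
#'
#' A lightweight convolutional feature encoder (fixed pooled-intensity and
#' gradient feature maps) with a trained linear embedding head, plus the
#' per-subject template bank learned jointly under the additive
#' angular-margin loss.
#'
#' @slot W d x p linear embedding head.
#' @slot auxW grade-classification head (0 x 0 matrix when disabled).
#' @slot center,scale feature standardization statistics.
#' @slot templates subjects x d unit-row template bank (rownames = ids).
#' @slot config the training configuration (an `ArcFaceConfig` list).
#' @slot history list of per-epoch train / held-out losses.
#' @export
setClass("PhenotyperModel", representation(
  W = "matrix", auxW = "matrix", center = "numeric", scale = "numeric",
  templates = "matrix", config = "list", history = "list"
))

setValidity("PhenotyperModel", function(object) {
  if (nrow(object@templates) > 0) {
    nrm <- sqrt(rowSums(object@templates^2))
    if (any(abs(nrm - 1) > 1e-6))
      return("templates must have unit Euclidean norm")
  }
  TRUE
})

setMethod("show", "PhenotyperModel", function(object) {
  cat("PhenotyperModel: d =", nrow(object@W), "embedding over",
      ncol(object@W), "features;", nrow(object@templates),
      "subject templates\n")
  h <- object@history
  if (length(h$val))
    cat(sprintf("  held-out loss: epoch0 %.4f -> best %.4f (epoch %d)\n",
                h$val[1], min(h$val), which.min(h$val) - 1L))
})
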