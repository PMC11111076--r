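## Self-supervised contrastive phenotyper: an additive angular-margin
## (ArcFace-style) template softmax over per-subject templates, trained
## jointly with a linear embedding head on fixed convolutional features.
## Both eyes of one subject are pulled toward the subject's template on the
## unit sphere; other subjects' templates are pushed at least the angular
## margin away.

#' Phenotyper training configuration
#'
#' @param d embedding dimension (the number of endophenotypes).
#' @param s inverse-temperature scale on the cosine logits.
#' @param m angular margin in radians, in `[0, pi)`.
#' @param auxWeightRatio contrastive-to-classification weight ratio of the
#'   auxiliary retinopathy-grade task (10 means the auxiliary cross-entropy
#'   enters with weight 1/10).
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param nAug rotation-augmented variants precomputed per image (variant 1
#'   is unrotated; the rest use angles uniform in +/-15 degrees).
#' @param valFraction fraction of subjects held out for model selection.
#' @param seed training seed.
#' @return a validated `ArcFaceConfig` list.
#' @export
arcfaceConfig <- function(d = 128L, s = 30, m = 0.5, auxWeightRatio = 10,
                          lr = 1e-4, epochs = 50L, batchSize = 64L,
                          nAug = 4L, valFraction = 0.2, seed = 1L) {
  stopifnot(d >= 2, s > 0, m >= 0, m < pi, auxWeightRatio > 0, lr > 0,
            epochs >= 0, nAug >= 1)
  structure(list(d = as.integer(d), s = s, m = m,
                 auxWeightRatio = auxWeightRatio, lr = lr,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 nAug = as.integer(nAug), valFraction = valFraction,
                 seed = as.integer(seed)), class = "ArcFaceConfig")
}

.asTemplateMatrix <- function(templates) {
  if (is(templates, "PhenotyperModel")) templates <- templates@templates
  stopifnot(is.matrix(templates), !is.null(rownames(templates)))
  templates
}

#' Additive angular-margin template loss
#'
#' Mean negative log of the margin-softmax probability of each sample's own
#' template: the target logit is `s * cos(theta_target + m)` and every
#' other subject's template contributes a logit `s * cos(theta_j)`. With
#' `m = 0` this is plain softmax cross-entropy over the template logits.
#'
#' @param emb images x d embedding matrix (unit rows; non-unit rows are
#'   normalized with a warning).
#' @param ids per-row subject ids; each must appear in `templates`.
#' @param templates subjects x d template matrix with subject-id rownames
#'   (or a [PhenotyperModel-class]).
#' @param cfg an [arcfaceConfig()] list (fields `s` and `m` are used).
#' @return a nonnegative scalar loss.
#' @export
arcfaceLoss <- function(emb, ids, templates, cfg = arcfaceConfig()) {
  templates <- .asTemplateMatrix(templates)
  if (is(emb, "EmbeddingMatrix")) {
    if (missing(ids)) ids <- embeddingSubjects(emb)
    emb <- embeddings(emb)
  }
  if (any(abs(sqrt(rowSums(emb^2)) - 1) > 1e-6)) {
    warning("embeddings are not unit length; normalizing")
    emb <- unitRows(emb)
  }
  if (any(abs(sqrt(rowSums(templates^2)) - 1) > 1e-6)) {
    warning("templates are not unit length; normalizing")
    templates <- unitRows(templates)
  }
  yi <- match(as.character(ids), rownames(templates))
  if (anyNA(yi)) stop("unknown subject id(s): ",
                      paste(unique(ids[is.na(yi)]), collapse = ", "))
  COS <- emb %*% t(templates)
  .arcfaceLossFromCos(COS, yi, cfg$s, cfg$m)$loss
}

## Core loss from a cosine matrix; also returns the softmax and the
## derivative of the target logit wrt its cosine (for backprop).
.arcfaceLossFromCos <- function(COS, yi, s, m) {
  n <- nrow(COS)
  tgt <- cbind(seq_len(n), yi)
  ct <- clamp(COS[tgt], -1 + 1e-7, 1 - 1e-7)
  logits <- s * COS
  logits[tgt] <- s * (ct * cos(m) - sqrt(1 - ct^2) * sin(m))
  mx <- apply(logits, 1, max)
  P <- exp(logits - mx)
  P <- P / rowSums(P)
  loss <- -mean(log(pmax(P[tgt], 1e-300)))
  dTarget <- s * (cos(m) + sin(m) * ct / sqrt(1 - ct^2))
  list(loss = loss, P = P, tgt = tgt, dTarget = dTarget)
}

## One backprop pass. Fb: batch features (n x p), yi: template index,
## W: d x p, V: raw template params (C x d), auxW: (5 x d) or NULL,
## grades: 0-4 per sample or NULL. Returns loss and gradients.
.phenotyperGrads <- function(Fb, yi, W, V, auxW, grades, cfg) {
  n <- nrow(Fb)
  U <- Fb %*% t(W)
  nu <- pmax(sqrt(rowSums(U^2)), 1e-12)
  Z <- U / nu
  Tm <- unitRows(V)
  COS <- Z %*% t(Tm)
  lf <- .arcfaceLossFromCos(COS, yi, cfg$s, cfg$m)
  Gl <- lf$P / n
  Gl[lf$tgt] <- Gl[lf$tgt] - 1 / n
  Gc <- Gl * cfg$s
  Gc[lf$tgt] <- Gl[lf$tgt] * lf$dTarget
  dZ <- Gc %*% Tm
  dT <- t(Gc) %*% Z
  loss <- lf$loss
  gAux <- NULL
  if (!is.null(auxW)) {
    w <- 1 / cfg$auxWeightRatio
    LA <- Z %*% t(auxW)
    LA <- LA - apply(LA, 1, max)
    PA <- exp(LA); PA <- PA / rowSums(PA)
    oneHot <- matrix(0, n, nrow(auxW))
    oneHot[cbind(seq_len(n), grades + 1L)] <- 1
    loss <- loss + w * (-mean(log(pmax(PA[oneHot == 1], 1e-300))))
    GA <- w * (PA - oneHot) / n
    dZ <- dZ + GA %*% auxW
    gAux <- t(GA) %*% Z
  }
  GU <- (dZ - rowSums(dZ * Z) * Z) / nu
  nv <- pmax(sqrt(rowSums(V^2)), 1e-12)
  GV <- (dT - rowSums(dT * Tm) * Tm) / nv
  list(loss = loss, gW = t(GU) %*% Fb, gV = GV, gAux = gAux)
}

.flipIfRight <- function(img) {
  px <- imagePixels(img)
  if (imageEye(img) == "right") px <- px[, rev(seq_len(dim(px)[2])), ,
                                         drop = FALSE]
  px
}

#' Train the self-supervised phenotyper
#'
#' Right-eye images are horizontally flipped in preprocessing, rotation
#' augmentation is applied during training, and the linear embedding head
#' and the per-subject template bank are optimized jointly with Adam under
#' the angular-margin loss; when retinopathy grades are supplied, an
#' auxiliary grade-classification head is trained with cross-entropy at
#' weight `1/auxWeightRatio`. Subjects are split 80/20; the held-out loss
#' (a template-free pair version: each held-out subject's left-eye
#' embedding serves as their template for the right-eye sample) is tracked
#' per epoch and the weights with the lowest held-out loss are retained.
#'
#' @param images list of good-quality [FundusImage-class]; at least 2
#'   subjects, each contributing at least one image.
#' @param drGrades optional named vector of grades 0-4 (names = subject
#'   ids) enabling the auxiliary task.
#' @param cfg an [arcfaceConfig()].
#' @return a [PhenotyperModel-class]; deterministic given `cfg$seed`.
#' @export
trainPhenotyper <- function(images, drGrades = NULL, cfg = arcfaceConfig()) {
  ids <- vapply(images, imageSubject, "")
  eyes <- vapply(images, imageEye, "")
  subs <- unique(ids)
  if (length(subs) < 2L)
    stop("contrastive loss is degenerate with a single subject; refusing")
  nImg <- length(images)
  trainedSize <- dim(imagePixels(images[[1]]))[1:2]

  ## precompute augmented feature variants (variant 1 = unrotated)
  augSeed <- substreamSeed(cfg$seed, "augment")
  Faug <- vector("list", cfg$nAug)
  base <- lapply(images, .flipIfRight)
  Faug[[1]] <- t(vapply(base, imageFeatures, numeric(832)))
  if (cfg$nAug > 1) {
    for (a in 2:cfg$nAug) {
      angles <- withSeed(substreamSeed(augSeed, paste0("a", a)),
                         runif(nImg, -15, 15))
      Faug[[a]] <- t(vapply(seq_len(nImg), function(i)
        imageFeatures(.applyNuisance(base[[i]], rotation = angles[i])),
        numeric(832)))
    }
  }

  withSeed(substreamSeed(cfg$seed, "train"), {
    valSub <- if (cfg$valFraction > 0 && length(subs) >= 5)
      sample(subs, max(1L, floor(cfg$valFraction * length(subs)))) else
        character()
    trIdx <- which(!ids %in% valSub)
    vlIdx <- which(ids %in% valSub)
    st <- .standardizeFit(Faug[[1]][trIdx, , drop = FALSE])
    Fz <- lapply(Faug, .standardizeApply, stats = st)

    trSubs <- unique(ids[trIdx])
    yi <- match(ids, trSubs)
    p <- ncol(Fz[[1]])
    W <- matrix(rnorm(cfg$d * p, sd = 0.05), cfg$d, p)
    V <- matrix(rnorm(length(trSubs) * cfg$d), length(trSubs), cfg$d)
    useAux <- !is.null(drGrades)
    auxW <- if (useAux) matrix(rnorm(5 * cfg$d, sd = 0.05), 5, cfg$d) else
      matrix(0, 0, 0)
    grades <- if (useAux) as.integer(drGrades[ids]) else NULL

    embedNow <- function(Wc, idx) unitRows(Fz[[1]][idx, , drop = FALSE] %*%
                                             t(Wc))
    heldOutLoss <- function(Wc) {
      if (length(vlIdx)) {
        vs <- ids[vlIdx]
        lefts <- vlIdx[eyes[vlIdx] == "left"]
        rights <- vlIdx[eyes[vlIdx] == "right"]
        lsub <- ids[lefts]; rsub <- ids[rights]
        common <- intersect(lsub, rsub)
        if (length(common) >= 2) {
          TL <- embedNow(Wc, lefts[match(common, lsub)])
          rownames(TL) <- common
          ZR <- embedNow(Wc, rights[match(common, rsub)])
          return(.arcfaceLossFromCos(ZR %*% t(TL),
                                     seq_along(common), cfg$s, cfg$m)$loss)
        }
      }
      ## fallback: training loss against current templates
      .arcfaceLossFromCos(embedNow(W, trIdx) %*% t(unitRows(V)),
                          yi[trIdx], cfg$s, cfg$m)$loss
    }

    params <- if (useAux) list(W, V, auxW) else list(W, V)
    adam <- .adamInit(lapply(params, dim))
    valHist <- heldOutLoss(W)
    trainHist <- numeric(0)
    best <- list(W = W, V = V, auxW = auxW); bestLoss <- valHist[1]
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(trIdx)
      aug <- sample.int(cfg$nAug, length(ord), replace = TRUE)
      epLoss <- 0; nb <- 0
      for (b in split(seq_along(ord), ceiling(seq_along(ord) / cfg$batchSize))) {
        ii <- ord[b]
        Fb <- do.call(rbind, lapply(seq_along(ii), function(k)
          Fz[[aug[b[k]]]][ii[k], , drop = FALSE]))
        gr <- .phenotyperGrads(Fb, yi[ii], params[[1]], params[[2]],
                               if (useAux) params[[3]] else NULL,
                               if (useAux) grades[ii] else NULL, cfg)
        gl <- if (useAux) list(gr$gW, gr$gV, gr$gAux) else list(gr$gW, gr$gV)
        upd <- .adamStep(adam, params, gl, cfg$lr)
        adam <- upd$state; params <- upd$params
        epLoss <- epLoss + gr$loss; nb <- nb + 1
      }
      trainHist <- c(trainHist, epLoss / nb)
      W <- params[[1]]; V <- params[[2]]
      vloss <- heldOutLoss(W)
      valHist <- c(valHist, vloss)
      if (vloss < bestLoss) {
        bestLoss <- vloss
        best <- list(W = W, V = V,
                     auxW = if (useAux) params[[3]] else auxW)
      }
    }
    Tm <- unitRows(best$V)
    rownames(Tm) <- trSubs
    new("PhenotyperModel", W = best$W, auxW = best$auxW,
        center = st$center, scale = st$scale, templates = Tm,
        config = c(unclass(cfg), list(trainedSize = trainedSize)),
        history = list(train = trainHist, val = valHist))
  })
}

#' Embed images as endophenotypes
#'
#' Applies the same preprocessing as training (right-eye horizontal flip,
#' feature standardization) but no augmentation, and unit-normalizes each
#' embedding row.
#'
#' @param model a [PhenotyperModel-class].
#' @param images list of [FundusImage-class].
#' @return an [EmbeddingMatrix-class] with one row per image.
#' @export
embedImages <- function(model, images) {
  stopifnot(is(model, "PhenotyperModel"))
  sz <- model@config$trainedSize
  d1 <- dim(imagePixels(images[[1]]))[1:2]
  if (!is.null(sz) && any(d1 != sz))
    warning("image size ", d1[1], "x", d1[2],
            " differs from the training size ", sz[1], "x", sz[2],
            "; pooled features are resolution-independent, proceeding")
  F <- t(vapply(lapply(images, .flipIfRight), imageFeatures, numeric(832)))
  Fz <- .standardizeApply(F, list(center = model@center, scale = model@scale))
  EmbeddingMatrix(Fz %*% t(model@W),
                  vapply(images, imageSubject, ""),
                  vapply(images, imageEye, ""))
}

#' Matched-pair vs random-pair similarity diagnostics
#'
#' Computes cosine similarities of matched pairs (the left and right image
#' of each subject) and of random cross-subject pairs, then the
#' Jensen-Shannon distance (base 2, square root of the divergence) and the
#' Jaccard index (intersection over union of area) between the two
#' distributions on a fixed 80-bin histogram over `[-1, 1]`. Kernel
#' density curves (Scott bandwidth times 0.5) are attached for plotting.
#'
#' @param emb an [EmbeddingMatrix-class] covering at least 2 subjects with
#'   both eyes.
#' @param nRandomPairs random pairs to sample (without replacement when
#'   possible; with replacement plus a warning otherwise).
#' @param seed sampling seed.
#' @return a `PairStats` list: `matched`, `random` (similarity samples),
#'   `jsDistance`, `jaccard`, `meanRandom`, `kde`.
#' @export
pairSimilarityStats <- function(emb, nRandomPairs = 1000L, seed = 1L) {
  stopifnot(is(emb, "EmbeddingMatrix"))
  Z <- embeddings(emb)
  ids <- embeddingSubjects(emb)
  eyes <- embeddingEyes(emb)
  lefts <- which(eyes == "left"); rights <- which(eyes == "right")
  common <- intersect(ids[lefts], ids[rights])
  if (length(common) < 2)
    stop("need at least 2 subjects with both eyes")
  li <- lefts[match(common, ids[lefts])]
  ri <- rights[match(common, ids[rights])]
  matched <- rowSums(Z[li, , drop = FALSE] * Z[ri, , drop = FALSE])

  n <- nrow(Z)
  cross <- which(outer(ids, ids, "!=") & upper.tri(matrix(0, n, n)),
                 arr.ind = TRUE)
  rnd <- withSeed(substreamSeed(seed, "random-pairs"), {
    if (nRandomPairs > nrow(cross)) {
      warning("requested more random pairs than available; ",
              "sampling with replacement")
      cross[sample.int(nrow(cross), nRandomPairs, replace = TRUE), ,
            drop = FALSE]
    } else cross[sample.int(nrow(cross), nRandomPairs), , drop = FALSE]
  })
  random <- rowSums(Z[rnd[, 1], , drop = FALSE] * Z[rnd[, 2], , drop = FALSE])

  breaks <- seq(-1, 1, length.out = 81)
  p <- graphics::hist(clamp(matched, -1, 1), breaks = breaks,
                      plot = FALSE)$counts
  q <- graphics::hist(clamp(random, -1, 1), breaks = breaks,
                      plot = FALSE)$counts
  p <- p / sum(p); q <- q / sum(q)
  mm <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  js <- sqrt(0.5 * kl(p, mm) + 0.5 * kl(q, mm))
  jac <- sum(pmin(p, q)) / sum(pmax(p, q))
  kde <- function(x) if (length(unique(x)) > 1)
    stats::density(x, bw = 0.5 * stats::bw.nrd(x)) else NULL
  structure(list(matched = matched, random = random, jsDistance = js,
                 jaccard = jac, meanRandom = mean(random),
                 kde = list(matched = kde(matched), random = kde(random))),
            class = "PairStats")
}
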