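## Image quality control: a small neural scorer in [0, 1], top-quality
## subset selection, and threshold classification metrics.

.adamInit <- function(shapes) {
  list(m = lapply(shapes, function(s) array(0, s)),
       v = lapply(shapes, function(s) array(0, s)), t = 0)
}

.adamStep <- function(state, params, grads, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(params)) {
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * grads[[i]]
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - b1^state$t)
    vhat <- state$v[[i]] / (1 - b2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

.qualityForward <- function(W1, b1, W2, b2, F) {
  H <- tanh(F %*% t(W1) + rep(as.vector(b1), each = nrow(F)))   # n x h
  as.vector(stats::plogis(H %*% t(W2) + as.vector(b2)))
}

#' Train the image quality scorer
#'
#' A single-hidden-layer network over sharpness / intensity / pooled
#' grayscale features, trained with cross-entropy (full-batch Adam) and
#' early stopping (patience 5) on a seeded 80/20 held-out split. The score
#' is in `[0, 1]`, 1 meaning good quality.
#'
#' @param corpus list of labeled [FundusImage-class] (labels `"good"` /
#'   `"bad"`; both classes required).
#' @param epochs maximum training epochs; `epochs = 0` returns the
#'   untrained (initialized) model, which still scores in `[0, 1]`.
#' @param seed training seed (initialization and split).
#' @param hidden hidden-layer width.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience in epochs.
#' @return a [QualityModel-class].
#' @export
trainQualityScorer <- function(corpus, epochs = 200L, seed = 1L,
                               hidden = 8L, lr = 0.05, patience = 5L) {
  labels <- vapply(corpus, function(im) im@qualityLabel, "")
  if (!all(labels %in% c("good", "bad")))
    stop("corpus must be fully labeled good/bad")
  y <- as.numeric(labels == "good")
  if (length(unique(y)) < 2L)
    stop("corpus contains a single class; cannot train a scorer")
  F <- t(vapply(corpus, qualityFeatures, numeric(70)))
  st <- .standardizeFit(F)
  Fz <- .standardizeApply(F, st)
  p <- ncol(Fz)

  withSeed(substreamSeed(seed, "quality-train"), {
    n <- nrow(Fz)
    val <- sample(n, max(1L, floor(0.2 * n)))
    if (length(unique(y[-val])) < 2L) val <- val[-1]   # keep both classes
    W1 <- matrix(rnorm(hidden * p, sd = 0.1), hidden, p)
    b1 <- numeric(hidden)
    W2 <- matrix(rnorm(hidden, sd = 0.1), 1, hidden)
    b2 <- 0
    params <- list(W1, b1, W2, b2)
    adam <- .adamInit(lapply(params, function(x) dim(as.array(x))))
    best <- params
    bestLoss <- Inf; wait <- 0L; hist <- numeric(0); ran <- 0L
    ce <- function(pr, yy) -mean(yy * log(pmax(pr, 1e-12)) +
                                   (1 - yy) * log(pmax(1 - pr, 1e-12)))
    for (ep in seq_len(epochs)) {
      W1 <- params[[1]]; b1 <- params[[2]]; W2 <- params[[3]]; b2 <- params[[4]]
      Ftr <- Fz[-val, , drop = FALSE]; ytr <- y[-val]
      H <- tanh(Ftr %*% t(W1) + rep(as.vector(b1), each = nrow(Ftr)))
      pr <- as.vector(stats::plogis(H %*% t(W2) + as.vector(b2)))
      dz <- (pr - ytr) / length(ytr)                 # d loss / d logit
      gW2 <- matrix(colSums(dz * H), 1)
      gb2 <- sum(dz)
      dH <- outer(dz, as.vector(W2)) * (1 - H^2)
      gW1 <- t(dH) %*% Ftr
      gb1 <- colSums(dH)
      upd <- .adamStep(adam, params, list(gW1, gb1, gW2, gb2), lr)
      adam <- upd$state; params <- upd$params
      vloss <- ce(.qualityForward(params[[1]], params[[2]], params[[3]],
                                  params[[4]], Fz[val, , drop = FALSE]),
                  y[val])
      hist <- c(hist, vloss); ran <- ep
      if (vloss < bestLoss - 1e-6) {
        bestLoss <- vloss; best <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    new("QualityModel", W1 = best[[1]], b1 = as.numeric(best[[2]]),
        W2 = best[[3]], b2 = as.numeric(best[[4]]),
        center = st$center, scale = st$scale,
        meta = list(epochsRun = ran, seed = seed, valLoss = hist))
  })
}

#' Score image quality
#'
#' @param model a [QualityModel-class].
#' @param images list of [FundusImage-class] or pixel arrays.
#' @return numeric scores in `[0, 1]`, one per image, in input order.
#' @export
scoreQuality <- function(model, images) {
  stopifnot(is(model, "QualityModel"))
  if (is(images, "FundusImage") || (is.array(images) &&
                                    length(dim(images)) == 3L))
    images <- list(images)
  F <- t(vapply(seq_along(images), function(i) {
    tryCatch(qualityFeatures(images[[i]]),
             error = function(e) stop("image ", i, ": ", conditionMessage(e)))
  }, numeric(70)))
  .qualityForward(model@W1, model@b1, model@W2, model@b2,
                  .standardizeApply(F, list(center = model@center,
                                            scale = model@scale)))
}

#' Select the top-quality image subset
#'
#' Keeps images with `score > scoreFloor`, ranked by descending score with
#' a stable tie-break by input order, truncated to `maxN`.
#'
#' @param images list of images (any type; returned as a subset).
#' @param scores aligned numeric quality scores.
#' @param scoreFloor strict lower bound on the score (default 0.95, the
#'   top-quality training cut; 0.5 is the plain good/bad cut).
#' @param maxN maximum subset size.
#' @return list with `images`, `scores` and the selected `indices`.
#' @export
selectTopQuality <- function(images, scores, scoreFloor = 0.95, maxN = Inf) {
  stopifnot(length(images) == length(scores))
  keep <- which(scores > scoreFloor)
  keep <- keep[orderByScoreDesc(scores[keep])]
  if (length(keep) > maxN) keep <- keep[seq_len(maxN)]
  list(images = images[keep], scores = scores[keep], indices = keep)
}

#' Threshold classification metrics of a scorer
#'
#' AUROC by the rank (Mann-Whitney) statistic with ties counted 0.5, and
#' PPV / NPV / sensitivity / specificity from the 2x2 table at
#' `score > threshold`.
#'
#' @param scores numeric scores.
#' @param labels 0/1 or `"bad"`/`"good"` labels (1/good = positive).
#' @param threshold decision threshold (default 0.5).
#' @return list with `auroc`, `ppv`, `npv`, `sensitivity`, `specificity`.
#' @export
classificationMetrics <- function(scores, labels, threshold = 0.5) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.numeric(as.character(labels) == "good")
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: a single class is present")
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.numeric(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  safe <- function(a, b) if (b == 0) NA_real_ else a / b
  list(auroc = auroc, ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
       sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp))
}
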