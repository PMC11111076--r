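## Fixed convolutional feature maps shared by the quality scorer and the
## phenotyper encoder: block-average pooling of each color channel plus
## pooled gradient magnitude of the grayscale image. Pooling uses 16 (or 8)
## near-equal contiguous bins per axis, so the feature dimension is
## independent of the input resolution (inputs must be >= 16 x 16).

.pixelArray <- function(x, what = "image") {
  px <- if (is(x, "FundusImage")) imagePixels(x) else x
  d <- dim(px)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || any(d[1:2] < 16L))
    stop("malformed ", what, ": expected a rows x cols x 3 array, >= 16x16")
  px
}

.grayGradient <- function(gray) {
  nr <- nrow(gray); nc <- ncol(gray)
  gx <- cbind(gray[, -1] - gray[, -nc], 0)
  gy <- rbind(gray[-1, ] - gray[-nr, ], 0)
  sqrt(gx^2 + gy^2)
}

## Embedding features: 16x16 pooled means per channel (768) + 8x8 pooled
## gradient magnitude (64); length 832.
imageFeatures <- function(x) {
  px <- .pixelArray(x) / 255
  nr <- dim(px)[1]; nc <- dim(px)[2]
  A16r <- poolOperator(nr, 16L); A16c <- t(poolOperator(nc, 16L))
  A8r <- poolOperator(nr, 8L); A8c <- t(poolOperator(nc, 8L))
  pooled <- vapply(1:3, function(k) as.vector(A16r %*% px[, , k] %*% A16c),
                   numeric(256))
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  gm <- A8r %*% .grayGradient(gray) %*% A8c
  c(as.vector(pooled), as.vector(gm))
}

## Quality features: global sharpness (variance of the discrete Laplacian),
## intensity statistics, clipping fractions, and an 8x8 pooled grayscale
## map; length 70.
qualityFeatures <- function(x) {
  px <- .pixelArray(x) / 255
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  nr <- nrow(gray); nc <- ncol(gray)
  core <- gray[2:(nr - 1), 2:(nc - 1)]
  lap <- gray[1:(nr - 2), 2:(nc - 1)] + gray[3:nr, 2:(nc - 1)] +
    gray[2:(nr - 1), 1:(nc - 2)] + gray[2:(nr - 1), 3:nc] - 4 * core
  A8r <- poolOperator(nr, 8L); A8c <- t(poolOperator(nc, 8L))
  c(log1p(stats::var(as.vector(lap)) * 1e4),
    mean(gray), stats::sd(as.vector(gray)),
    mean(gray > 0.94), mean(gray < 0.06),
    mean(.grayGradient(gray)),
    as.vector(A8r %*% gray %*% A8c))
}

## Standardize a feature matrix; zero-variance columns are left centered.
.standardizeFit <- function(F) {
  ctr <- colMeans(F)
  scl <- apply(F, 2, stats::sd)
  scl[scl < 1e-8] <- 1
  list(center = ctr, scale = scl)
}

.standardizeApply <- function(F, stats) {
  sweep(sweep(F, 2, stats$center), 2, stats$scale, "/")
}
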