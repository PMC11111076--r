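## Internal helpers: seed substreams, RNG scoping, pooling operators,
## conversions between the package's pixel arrays and EBImage objects.

#' Derive a reproducible substream seed from a master seed and a label
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so that adding or reordering stages never perturbs the draws
#' of another stage.
#'
#' @param seed master integer seed.
#' @param name substream label, e.g. `"genotypes"` or `"nuisance-S0001-left"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  mod <- 2147483647
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% mod
  as.integer((abs(as.numeric(seed)) * 69069 + h) %% mod)
}

## Evaluate `expr` under `seed` without clobbering the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## k x n row-group averaging operator: groups the n positions into k
## near-equal contiguous bins and averages within each bin.
poolOperator <- function(n, k) {
  grp <- floor((seq_len(n) - 1) * k / n) + 1L
  A <- matrix(0, k, n)
  A[cbind(grp, seq_len(n))] <- 1
  A / rowSums(A)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## rows x cols x 3 array in [0,255]  <->  EBImage Image ([x, y, c] in [0,1])
toEBImage <- function(pixels) {
  EBImage::Image(aperm(pixels, c(2, 1, 3)) / 255, colormode = "Color")
}

fromEBImage <- function(img) {
  aperm(EBImage::imageData(img), c(2, 1, 3)) * 255
}

## Unit-normalize the rows of a matrix; zero rows are left untouched.
unitRows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

## Stable descending order by score, ties broken by original position.
orderByScoreDesc <- function(scores) {
  order(-scores, seq_along(scores))
}
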