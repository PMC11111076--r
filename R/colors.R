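#' Extract retina-color phenotypes from the central foveal patch
#'
#' Right-eye images are horizontally mirrored first. For a 1536 x 2048
#' image the half-open, 0-based pixel window rows `[600, 1000)`, columns
#' `[800, 1200)` (a 400 x 400 patch around the fovea) is used verbatim;
#' for any other size the same fractional window (`600/1536` to
#' `1000/1536` of the rows, `800/2048` to `1200/2048` of the columns,
#' floor-rounded) is used, preserving the window's slight offset from the
#' geometric center. The per-channel arithmetic means of the patch are the
#' three color phenotypes.
#'
#' @param image a [FundusImage-class] (or a rows x cols x 3 array, treated
#'   as a left eye).
#' @return a one-row `data.frame`: `subject_id`, `eye`, `mean_red`,
#'   `mean_green`, `mean_blue`.
#' @examples
#' px <- array(100, dim = c(96, 128, 3))
#' extractRetinaColor(px)$mean_red   # 100
#' @export
extractRetinaColor <- function(image) {
  if (is(image, "FundusImage")) {
    px <- imagePixels(image)
    id <- image@subjectId
    eye <- image@eye
  } else {
    px <- image
    id <- NA_character_
    eye <- "left"
  }
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  if (eye == "right")
    px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  nr <- dim(px)[1]; nc <- dim(px)[2]
  r0 <- floor(600 / 1536 * nr); r1 <- floor(1000 / 1536 * nr)
  c0 <- floor(800 / 2048 * nc); c1 <- floor(1200 / 2048 * nc)
  if (r1 <= r0 || c1 <= c0)
    stop("color patch window is empty after rounding for a ", nr, "x", nc,
         " image")
  patch <- px[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
  data.frame(subject_id = id, eye = eye,
             mean_red = mean(patch[, , 1]),
             mean_green = mean(patch[, , 2]),
             mean_blue = mean(patch[, , 3]))
}

#' Retina-color phenotypes for a set of images
#'
#' @param images list of [FundusImage-class].
#' @return a `data.frame` with one row per image (columns as in
#'   [extractRetinaColor()]).
#' @export
extractRetinaColors <- function(images) {
  do.call(rbind, lapply(images, extractRetinaColor))
}
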