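## Procedural fundus rendering: a circular field of view whose background
## color tracks the pigmentation trait, a recursive bifurcating vessel tree
## whose branch count tracks the vessel-density trait (subject-seeded so
## both eyes share topology), an optic disc, a foveal dark spot, and
## grade-dependent lesions. The right eye is the horizontal mirror of the
## subject's base rendering; per-image nuisance (rotation, illumination,
## optional blur) is applied independently afterwards.

.renderBase <- function(subject, config, topoSeed) {
  nr <- config@imageSize[1]; nc <- config@imageSize[2]
  rowM <- matrix(seq_len(nr), nr, nc)
  colM <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  rad <- 0.48 * min(nr, nc)
  dist <- sqrt((rowM - cy)^2 + (colM - cx)^2)

  ## background: higher pigment -> darker and relatively redder; linear in
  ## the trait (clamped at the extremes) so the central-patch color is a
  ## near-lossless readout of pigmentation
  sh <- clamp(0.5 + 0.22 * subject$pigment, 0.03, 0.97)
  base <- c(230 - 130 * sh, 140 - 85 * sh, 80 - 50 * sh)
  vig <- pmax(1 - 0.30 * (dist / rad)^2, 0)          # radial illumination
  fov <- 1 - 0.30 * exp(-dist^2 / (2 * (0.09 * min(nr, nc))^2))
  ch <- lapply(1:3, function(k) base[k] * vig * fov)

  ## optic disc (temporal side of the base/left rendering)
  dy <- cy; dx <- cx + 0.55 * rad
  dd <- sqrt((rowM - dy)^2 + (colM - dx)^2)
  w <- pmax(1 - (dd / (0.16 * rad))^2, 0)
  disc <- c(245, 215, 160)
  for (k in 1:3) ch[[k]] <- ch[[k]] * (1 - w) + disc[k] * w

  withSeed(topoSeed, {
    ## vessel tree: branch count is a monotone function of the vessel trait
    nTrunk <- max(2L, round(5 + 1.8 * subject$vessel))
    vcol <- c(0.42 * base[1], 0.30 * base[2], 0.35 * base[3])
    aim <- atan2(cy - dy, cx - dx)
    drawSeg <- function(y0, x0, ang, len, depth) {
      t <- seq(0, len, by = 0.6)
      py <- round(y0 + t * sin(ang)); px <- round(x0 + t * cos(ang))
      ok <- py >= 1 & py <= nr & px >= 1 & px <= nc &
        (py - cy)^2 + (px - cx)^2 > (0.3 * rad)^2   # foveal avascular zone
      if (any(ok)) {
        idx <- cbind(py[ok], px[ok])
        for (k in 1:3)
          ch[[k]][idx] <<- ch[[k]][idx] * 0.35 + vcol[k] * 0.65
        if (depth == 0L) {                   # thicker trunks
          idx2 <- cbind(pmin(py[ok] + 1L, nr), px[ok])
          for (k in 1:3)
            ch[[k]][idx2] <<- ch[[k]][idx2] * 0.5 + vcol[k] * 0.5
        }
      }
      if (depth < 2L) {
        for (s in c(-1, 1))
          drawSeg(y0 + len * sin(ang), x0 + len * cos(ang),
                  ang + s * runif(1, 0.25, 0.7), len * 0.72, depth + 1L)
      }
    }
    ## trunks arc around the macula (the fovea is avascular): aim away from
    ## the straight line to the image center
    for (i in seq_len(nTrunk))
      drawSeg(dy, dx, aim + sample(c(-1, 1), 1) * runif(1, 0.35, 1.2),
              0.38 * rad, 0L)

    ## lesions scale with disease grade
    g <- subject$dr_grade
    if (g > 0) {
      for (i in seq_len(3L * g)) {
        repeat {                             # lesions spare the fovea
          ly <- cy + runif(1, -0.75, 0.75) * rad
          lx <- cx + runif(1, -0.75, 0.75) * rad
          if ((ly - cy)^2 + (lx - cx)^2 > (0.3 * rad)^2) break
        }
        sig <- 0.018 * min(nr, nc)
        lw <- exp(-((rowM - ly)^2 + (colM - lx)^2) / (2 * sig^2))
        tgt <- if (g >= 3 && i %% 2 == 0) c(60, 12, 12) else c(235, 235, 190)
        for (k in 1:3) ch[[k]] <- ch[[k]] * (1 - lw) + tgt[k] * lw
      }
    }
  })

  ## circular field of view with a soft edge and dark surround
  edge <- clamp((rad - dist) / 1.5, 0, 1)
  out <- array(0, dim = c(nr, nc, 3))
  for (k in 1:3) out[, , k] <- clamp(ch[[k]] * edge, 0, 255)
  out
}

.applyNuisance <- function(pixels, rotation = 0, illumination = 1, blur = 0) {
  if (rotation != 0) {
    img <- EBImage::rotate(toEBImage(pixels), rotation,
                           output.dim = c(dim(pixels)[2], dim(pixels)[1]),
                           bg.col = "black")
    pixels <- fromEBImage(img)
  }
  if (blur > 0)
    pixels <- fromEBImage(EBImage::gblur(toEBImage(pixels), sigma = blur))
  clamp(pixels * illumination, 0, 255)
}

#' Render the left/right fundus image pair of one subject
#'
#' Both eyes share the subject's trait-driven content (background color,
#' vessel topology, lesions) because the base rendering is drawn from a
#' subject-seeded generator; the right image is the horizontal mirror of
#' the base. Per-image nuisance (rotation within +/-15 degrees,
#' illumination scale, occasional blur) is applied independently to each
#' eye. With `nuisance = FALSE` the right image is exactly the flipped
#' left image.
#'
#' @param subject one row of [simulateSubjects()] output (or any list with
#'   `id`, `pigment`, `vessel`, `dr_grade`).
#' @param config a [SimConfig-class] (image size >= 64x64 recommended).
#' @param seed seed for this rendering; topology and nuisance substreams
#'   are derived from it and the subject id.
#' @param nuisance logical; apply per-image nuisance?
#' @return a list with elements `left` and `right`, both [FundusImage-class].
#' @export
renderFundusPair <- function(subject, config, seed = config@seed,
                             nuisance = TRUE) {
  stopifnot(is(config, "SimConfig"))
  id <- as.character(subject$id)
  base <- .renderBase(subject, config, substreamSeed(seed, paste0("topo-", id)))
  sides <- list(left = base, right = base[, rev(seq_len(dim(base)[2])), ,
                                          drop = FALSE])
  out <- list()
  for (eye in c("left", "right")) {
    px <- sides[[eye]]
    nu <- c(rotation = 0, illumination = 1, blur = 0)
    if (nuisance) {
      nu <- withSeed(substreamSeed(seed, paste0("nuis-", id, "-", eye)), {
        c(rotation = runif(1, -15, 15),
          illumination = runif(1, 0.95, 1.05),
          blur = if (runif(1) < 0.7) 0 else runif(1, 0.3, 1))
      })
      px <- .applyNuisance(px, nu[["rotation"]], nu[["illumination"]],
                           nu[["blur"]])
    }
    out[[eye]] <- FundusImage(px, id, eye, nuisance = nu)
  }
  out
}

## Random subjects with standard-normal traits, for corpora that need no
## genotypes.
.randomSubjects <- function(n, seed, prefix = "Q") {
  withSeed(seed, {
    data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
               age = round(runif(n, 40, 70), 1), sex = rbinom(n, 1, 0.5),
               pigment = rnorm(n), vessel = rnorm(n),
               dr_grade = findInterval(rnorm(n),
                                       qnorm(c(0.55, 0.75, 0.9, 0.97))))
  })
}

#' Generate a labeled good/bad quality image corpus
#'
#' Good images are clean renderings with mild nuisance; bad images are the
#' same renderings degraded by heavy blur, severe under- or
#' over-illumination, or occlusion of half the field of view. Labels are
#' recorded on each image.
#'
#' @param nGood,nBad number of good / bad images (non-negative, not both 0).
#' @param config a [SimConfig-class] (controls image size).
#' @param seed corpus seed.
#' @return list of [FundusImage-class], the `nGood` good images first.
#' @export
makeQualityCorpus <- function(nGood, nBad, config, seed = config@seed) {
  stopifnot(nGood >= 0, nBad >= 0, nGood + nBad > 0)
  n <- nGood + nBad
  subs <- .randomSubjects(n, substreamSeed(seed, "quality-subjects"))
  out <- vector("list", n)
  degSeed <- substreamSeed(seed, "quality-degrade")
  for (i in seq_len(n)) {
    eye <- if (i %% 2 == 0) "right" else "left"
    img <- renderFundusPair(subs[i, ], config,
                            seed = substreamSeed(seed, paste0("qc-", i)))[[eye]]
    if (i <= nGood) {
      img@qualityLabel <- "good"
    } else {
      ## bad images are defocused (as in real bad-quality fundus photos),
      ## optionally with a second defect on top
      px <- withSeed(substreamSeed(degSeed, paste0("deg-", i)), {
        p <- fromEBImage(EBImage::gblur(toEBImage(imagePixels(img)),
                                        sigma = runif(1, 2.5, 6)))
        extra <- sample(c("none", "dark", "bright", "occlusion"), 1)
        switch(extra,
          none = p,
          dark = p * runif(1, 0.06, 0.22),
          bright = clamp(p * runif(1, 2.6, 4), 0, 255),
          occlusion = {
            cut <- sample(floor(nrow(p) * 0.4):ceiling(nrow(p) * 0.6), 1)
            p[seq_len(cut), , ] <- 0
            p
          })
      })
      img <- FundusImage(clamp(px, 0, 255), img@subjectId, img@eye,
                         qualityLabel = "bad", nuisance = img@nuisance)
    }
    out[[i]] <- img
  }
  out
}
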