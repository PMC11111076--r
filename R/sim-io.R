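## Dataset serialization: VCF 4.2 (GT only) for genotypes, TSV for
## covariates/traits, PNG per image, plus a manifest TSV.

.writeVcf <- function(panel, path) {
  info <- snpInfo(panel)
  d <- dosages(panel)
  gtcode <- c("0/0", "0/1", "1/1")
  gt <- matrix(gtcode[d + 1L], nrow(d), ncol(d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  body <- cbind(info$chrom, info$pos, info$snp, info$ref, info$alt, ".",
                "PASS", ".", "GT", t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

.readVcfPanel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- matrix(match(gt, c("0/0", "0/1", "1/1")) - 1L, nrow(gt),
                dimnames = dimnames(gt))
  if (anyNA(dos)) stop("unsupported genotype codes in ", path)
  dos <- t(dos)                              # subjects x SNPs
  fix <- vcfR::getFIX(v)
  af <- colMeans(dos) / 2
  GenotypePanel(dos, chrom = fix[, "CHROM"],
                pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                alt = fix[, "ALT"], maf = pmin(af, 1 - af))
}

#' Write a simulated dataset to disk
#'
#' Writes `genotypes.vcf` (VCF 4.2, GT fields), `covariates.tsv`
#' (id, age, sex, pigment, vessel, dr_grade), one PNG per image named
#' `{subject}_{eye}.png` under `images/`, and `manifest.tsv` listing every
#' image with its subject, eye, quality label and path. A round-trip read
#' with [readDataset()] reproduces the dosage matrix exactly.
#'
#' @param panel a [GenotypePanel-class].
#' @param subjects the [simulateSubjects()] data.frame.
#' @param images list of [FundusImage-class] (may be empty).
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest `data.frame`.
#' @export
writeDataset <- function(panel, subjects, images, outDir) {
  if (!setequal(subjects$id, subjectIds(panel)))
    stop("id mismatch between subjects table and genotype panel")
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  .writeVcf(panel, file.path(outDir, "genotypes.vcf"))
  utils::write.table(subjects, file.path(outDir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rows <- lapply(images, function(img) {
    rel <- file.path("images",
                     sprintf("%s_%s.png", img@subjectId, img@eye))
    png::writePNG(imagePixels(img) / 255, file.path(outDir, rel))
    data.frame(subject_id = img@subjectId, eye = img@eye,
               quality_label = img@qualityLabel, path = rel)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), eye = character(),
               quality_label = character(), path = character())
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @param loadImages logical; read the PNGs listed in the manifest? A
#'   missing image file raises an error naming the subject and eye.
#' @return list with `panel`, `subjects`, `manifest` and (if requested)
#'   `images`.
#' @export
readDataset <- function(dir, loadImages = TRUE) {
  panel <- .readVcfPanel(file.path(dir, "genotypes.vcf"))
  subjects <- utils::read.delim(file.path(dir, "covariates.tsv"))
  subjects$id <- as.character(subjects$id)
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                colClasses = "character")
  out <- list(panel = panel, subjects = subjects, manifest = manifest)
  if (loadImages && nrow(manifest)) {
    out$images <- lapply(seq_len(nrow(manifest)), function(i) {
      f <- file.path(dir, manifest$path[i])
      if (!file.exists(f))
        stop(sprintf("missing image file for subject %s, %s eye: %s",
                     manifest$subject_id[i], manifest$eye[i], f))
      FundusImage(png::readPNG(f) * 255, manifest$subject_id[i],
                  manifest$eye[i], qualityLabel = manifest$quality_label[i])
    })
  }
  out
}
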