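## End-to-end orchestration: simulate -> quality control -> contrastive
## phenotyper -> embeddings -> retina colors -> per-eye mixed-model GWAS
## (endophenotypes and colors) -> dual-eye intersection -> locus clumping
## -> LD-score regression -> report. Every stage is deterministic given
## the master seed; numeric TSV artifacts are rounded to 6 significant
## digits so that re-runs are checksum-identical.

#' Default pipeline configuration
#'
#' Nested configuration of all stages with every analysis constant
#' surfaced as a named key: quality thresholds 0.5 / 0.95, the 5e-8
#' dual-eye significance threshold, the r2 > 0.2 / 250 kb locus-merge
#' rule, and the phenotyper loss parameters (s, m, auxiliary weight
#' ratio). Cohort and model sizes default to a desk-scale toy run
#' (120 subjects, 200 SNPs, 64 x 64 images, 16 endophenotypes) so a full
#' pipeline completes in minutes; scale them up as needed.
#'
#' @param seed master seed; all stage substreams derive from it.
#' @return a nested configuration list (class `RunConfig`).
#' @export
pipelineConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    sim = list(nSubjects = 120L, nSnps = 200L, ldBlockSize = 8L,
               withinBlockR = 0.8, mafRange = c(0.1, 0.5), nChrom = 4L,
               posStride = 5000L, imageSize = c(64L, 64L),
               causalMap = data.frame(
                 snp = c(10L, 60L, 110L, 160L),
                 trait = c("pigment", "pigment", "vessel", "vessel"),
                 varExplained = c(0.15, 0.15, 0.1, 0.1)),
               writeImages = FALSE),
    quality = list(nGood = 60L, nBad = 60L, epochs = 100L,
                   goodThreshold = 0.5, topThreshold = 0.95),
    phenotyper = list(d = 16L, s = 30, m = 0.5, auxWeightRatio = 10,
                      lr = 0.01, epochs = 10L, batchSize = 64L, nAug = 2L),
    gwas = list(nPCs = 10L, loco = TRUE, mafFilter = 0.01,
                threshold = 5e-8, r2Threshold = 0.2,
                distThreshold = 250000),
    ldsc = list(windowBp = 1e6, nBlocks = 20L),
    stages = c(simulate = TRUE, quality = TRUE, phenotyper = TRUE,
               embed = TRUE, colors = TRUE, gwas = TRUE, intersect = TRUE,
               ldsc = TRUE, report = TRUE)
  ), class = "RunConfig")
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.assocOut <- function(tab) {
  data.frame(SNP = tab$snp, CHR = tab$chrom, BP = tab$pos, REF = tab$ref,
             ALT = tab$alt, ALTFREQ = tab$af, TRAIT = tab$trait,
             BETA = tab$beta, SE = tab$se, CHISQ = tab$chisq,
             P = tab$pvalue)
}

.assocIn <- function(path) {
  t1 <- utils::read.delim(path)
  data.frame(snp = t1$SNP, chrom = t1$CHR, pos = t1$BP, ref = t1$REF,
             alt = t1$ALT, af = t1$ALTFREQ, trait = t1$TRAIT,
             beta = t1$BETA, se = t1$SE, chisq = t1$CHISQ, pvalue = t1$P,
             tested = !is.na(t1$SE))
}

.need <- function(path, stage) {
  if (!file.exists(path))
    stop("missing upstream artifact ", basename(path),
         "; enable stage '", stage, "'")
  path
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, each stage reading only artifacts
#' of prior stages; disabled stages reuse artifacts already present in
#' `outDir` (an error names the stage to enable when one is missing).
#' Writes per-stage TSV artifacts, a config echo (`config.yaml`), a text
#' log with stage timings and seeds, and `manifest.tsv` listing every TSV
#' artifact with its MD5 checksum. A re-run from the same configuration
#' and seed reproduces all TSV artifacts bit-identically.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory.
#' @return invisibly, the manifest `data.frame` (file, stage, md5).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  logLines <- c(sprintf("master seed: %d", config$seed))
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    logLines <<- c(logLines, sprintf("%-12s %7.2fs", stage,
                                     as.numeric(Sys.time() - t0,
                                                units = "secs")))
    res
  }
  art <- character(0)  # artifact -> stage
  emit <- function(df, name, stage) {
    .writeTsv(df, file.path(outDir, name))
    art[name] <<- stage
  }

  simCfg <- do.call(simConfig, c(config$sim[setdiff(names(config$sim),
                                                    "writeImages")],
                                 list(seed = config$seed)))

  ## -- simulate ------------------------------------------------------------
  if (st[["simulate"]]) {
    panel <- tick("simulate", simulateGenotypes(simCfg))
    subjects <- simulateSubjects(panel, simCfg)
    .writeVcf(panel, file.path(outDir, "genotypes.vcf"))
    emit(subjects, "covariates.tsv", "simulate")
  } else {
    panel <- .readVcfPanel(.need(file.path(outDir, "genotypes.vcf"),
                                 "simulate"))
    subjects <- utils::read.delim(.need(file.path(outDir, "covariates.tsv"),
                                        "simulate"))
    subjects$id <- as.character(subjects$id)
  }
  ## cohort images are deterministic given the seed; render (or re-render)
  images <- tick("render", {
    im <- list()
    for (i in seq_len(nrow(subjects))) {
      pr <- renderFundusPair(subjects[i, ], simCfg,
                             seed = substreamSeed(config$seed,
                                                  paste0("img-",
                                                         subjects$id[i])))
      im <- c(im, pr)
    }
    im
  })
  if (isTRUE(config$sim$writeImages))
    writeDataset(panel, subjects, images, outDir)

  ## -- quality -------------------------------------------------------------
  if (st[["quality"]]) {
    tick("quality", {
      corpus <- makeQualityCorpus(config$quality$nGood, config$quality$nBad,
                                  simCfg,
                                  seed = substreamSeed(config$seed, "qc"))
      qm <- trainQualityScorer(corpus, epochs = config$quality$epochs,
                               seed = substreamSeed(config$seed, "qc-train"))
      scores <- scoreQuality(qm, images)
      emit(data.frame(subject_id = vapply(images, imageSubject, ""),
                      eye = vapply(images, imageEye, ""),
                      score = scores), "quality_scores.tsv", "quality")
      cm <- classificationMetrics(scoreQuality(qm, corpus),
                                  vapply(corpus, function(x) x@qualityLabel,
                                         ""),
                                  threshold = config$quality$goodThreshold)
      emit(as.data.frame(cm), "quality_metrics.tsv", "quality")
    })
  }
  qs <- utils::read.delim(.need(file.path(outDir, "quality_scores.tsv"),
                                "quality"))
  keep <- which(qs$score > config$quality$goodThreshold)
  if (length(keep) < 4L) keep <- seq_along(images)   # degenerate scorer

  ## -- phenotyper ----------------------------------------------------------
  acfg <- do.call(arcfaceConfig,
                  c(config$phenotyper,
                    list(seed = substreamSeed(config$seed, "phenotyper"))))
  if (st[["phenotyper"]] || st[["embed"]]) {
    model <- tick("phenotyper", {
      gr <- setNames(subjects$dr_grade, subjects$id)
      trainPhenotyper(images[keep], drGrades = gr, cfg = acfg)
    })
    if (st[["phenotyper"]])
      emit(data.frame(epoch = seq_along(model@history$val) - 1L,
                      val_loss = model@history$val),
           "phenotyper_history.tsv", "phenotyper")
  }

  ## -- embed ---------------------------------------------------------------
  if (st[["embed"]]) {
    emb <- tick("embed", embedImages(model, images))
    Z <- embeddings(emb)
    colnames(Z) <- paste0("e", seq_len(ncol(Z)))
    emit(data.frame(subject_id = embeddingSubjects(emb),
                    eye = embeddingEyes(emb), Z),
         "embeddings.tsv", "embed")
  }
  et <- utils::read.delim(.need(file.path(outDir, "embeddings.tsv"), "embed"))

  ## -- colors --------------------------------------------------------------
  if (st[["colors"]]) {
    emit(tick("colors", extractRetinaColors(images)), "colors.tsv", "colors")
  }
  ct <- utils::read.delim(.need(file.path(outDir, "colors.tsv"), "colors"))
  ct$subject_id <- as.character(ct$subject_id)

  ## -- gwas ----------------------------------------------------------------
  if (st[["gwas"]]) {
    tick("gwas", {
      ecols <- grep("^e[0-9]+$", names(et), value = TRUE)
      mkMat <- function(df, eye, cols) {
        dd <- df[df$eye == eye, ]
        dd <- dd[!duplicated(dd$subject_id), ]
        m <- as.matrix(dd[, cols, drop = FALSE])
        rownames(m) <- as.character(dd$subject_id)
        m
      }
      g <- config$gwas
      endo <- runEndophenotypeGWAS(mkMat(et, "left", ecols),
                                   mkMat(et, "right", ecols),
                                   subjects[, c("id", "age", "sex")], panel,
                                   nPCs = g$nPCs, loco = g$loco,
                                   mafFilter = g$mafFilter)
      col3 <- c("mean_red", "mean_green", "mean_blue")
      colg <- runEndophenotypeGWAS(mkMat(ct, "left", col3),
                                   mkMat(ct, "right", col3),
                                   subjects[, c("id", "age", "sex")], panel,
                                   nPCs = g$nPCs, loco = g$loco,
                                   mafFilter = g$mafFilter)
      emit(.assocOut(endo$left), "assoc_endo_left.tsv", "gwas")
      emit(.assocOut(endo$right), "assoc_endo_right.tsv", "gwas")
      emit(.assocOut(colg$left), "assoc_color_left.tsv", "gwas")
      emit(.assocOut(colg$right), "assoc_color_right.tsv", "gwas")
    })
  }

  ## -- intersect + clump ---------------------------------------------------
  if (st[["intersect"]]) {
    tick("intersect", {
      g <- config$gwas
      for (set in c("endo", "color")) {
        L <- .assocIn(.need(file.path(outDir,
                                      sprintf("assoc_%s_left.tsv", set)),
                            "gwas"))
        R <- .assocIn(.need(file.path(outDir,
                                      sprintf("assoc_%s_right.tsv", set)),
                            "gwas"))
        sel <- intersectEyes(L, R, threshold = g$threshold)
        loci <- clumpLoci(sel, panel, r2Threshold = g$r2Threshold,
                          distThreshold = g$distThreshold)
        emit(sel, sprintf("selected_%s.tsv", set), "intersect")
        emit(loci, sprintf("loci_%s.tsv", set), "intersect")
      }
    })
  }

  ## -- ldsc ----------------------------------------------------------------
  if (st[["ldsc"]]) {
    tick("ldsc", {
      l <- computeLdScores(panel, windowBp = config$ldsc$windowBp)
      L <- .assocIn(.need(file.path(outDir, "assoc_endo_left.tsv"), "gwas"))
      N <- simCfg@nSubjects
      rows <- lapply(unique(L$trait), function(tr) {
        tt <- L[L$trait == tr & L$tested, ]
        fit <- ldscH2(tt$chisq, l[tt$snp], N = N, M = nrow(tt),
                      nBlocks = config$ldsc$nBlocks)
        data.frame(trait = tr, h2 = fit$h2, h2_se = fit$h2_se,
                   intercept = fit$intercept)
      })
      emit(do.call(rbind, rows), "ldsc_h2.tsv", "ldsc")
      Z <- as.matrix(et[, grep("^e[0-9]+$", names(et)), drop = FALSE])
      desc <- endophenotypeDescriptives(Z)
      emit(cbind(trait = rownames(desc$correlation),
                 as.data.frame(desc$correlation)),
           "endophenotype_correlation.tsv", "ldsc")
    })
  }

  ## -- report --------------------------------------------------------------
  yaml::write_yaml(.configForYaml(config), file.path(outDir, "config.yaml"))
  tsvs <- sort(list.files(outDir, pattern = "\\.tsv$"))
  tsvs <- setdiff(tsvs, "manifest.tsv")
  manifest <- data.frame(
    file = tsvs,
    md5 = unname(tools::md5sum(file.path(outDir, tsvs))))
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(logLines, file.path(outDir, "run_log.txt"))
  invisible(manifest)
}

.configForYaml <- function(config) {
  cfg <- unclass(config)
  cfg$sim$causalMap <- as.list(cfg$sim$causalMap)
  cfg$stages <- as.list(cfg$stages)
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Keys omitted from the file keep their [pipelineConfig()] defaults.
#'
#' @param path YAML file.
#' @return a `RunConfig` list.
#' @export
readPipelineConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- pipelineConfig(seed = if (!is.null(usr$seed)) usr$seed else 1L)
  for (sec in intersect(names(usr), setdiff(names(cfg), "seed"))) {
    if (sec == "stages") {
      v <- unlist(usr$stages)
      cfg$stages[names(v)] <- v
    } else if (is.list(usr[[sec]])) {
      for (k in names(usr[[sec]])) {
        cfg[[sec]][[k]] <- if (k == "causalMap")
          as.data.frame(usr[[sec]][[k]]) else usr[[sec]][[k]]
      }
    }
  }
  cfg
}
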