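---
title: "Self-supervised image phenotyping and mixed-model GWAS: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised image phenotyping and mixed-model GWAS: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Imaging GWAS usually tests phenotypes that an expert defined in advance.
An alternative is to let a self-supervised encoder discover quantitative
phenotypes ("endophenotypes") directly from images, then test each
embedding coordinate for genetic association. Retinal fundus photographs
are well suited to this: the two eyes of one person are natural biological
replicates (near-mirror images sharing genetics), which provides both the
supervision signal for contrastive training and an independent replication
arm for the GWAS.

`fundusGWAS` implements the full loop at desk scale: a procedural
genotype-to-image simulator with known causal structure, an image-quality
scorer, a contrastive phenotyper, retina-color phenotypes, an exact linear
mixed model (LMM) association engine, and post-processing (dual-eye
intersection, locus clumping, LD-score regression, catalog queries).
Because the simulator's ground truth is known, every stage is testable
end to end.

# The synthetic cohort

**Genotypes.** Each haplotype is a Gaussian copula: latent normals follow
an AR(1) process within LD blocks (`ldBlockSize` SNPs, adjacent-latent
correlation `withinBlockR`, default 0.8; blocks independent) and are
thresholded at the Hardy-Weinberg quantile of a per-SNP allele frequency
drawn uniformly from `mafRange`. Dosages are the sum of two haplotypes,
so genotype frequencies are exactly Hardy-Weinberg at the drawn
frequency. SNPs are split into `nChrom` chromosomes at a fixed
`posStride` (default 5 kb) with strictly increasing 1-based positions, so
distance-based locus merging is exercised with clean block-level ground
truth. Latent correlation 0.8 yields adjacent genotype r² of roughly
0.3-0.4 (thresholding attenuates the latent correlation, more so at
asymmetric allele frequencies), which is the regime LD clumping and LD
scores need.

**Traits.** Each latent trait (pigmentation, vessel density) is an
additive genetic score over the SNPs in `causalMap` plus environmental
noise. The noise is drawn, then residualized in-sample against the causal
predictors, and both components are rescaled so the realized variance
split equals the nominal one exactly (up to O(1/n) LD leakage between
causal SNPs). A plain draw would make each SNP's realized variance
explained fluctuate by ~0.014 at n = 1000 — as large as the quantity
itself matters for power — so calibrating the split makes the stated
study conditions (e.g. "five SNPs at 5% each") the conditions that
actually hold in every run. Age is uniform on 40-70 years, sex is
Bernoulli(0.5), and the retinopathy grade (0-4) is a fixed monotone
thresholding of the vessel trait.

**Images.** The renderer produces a circular fundus-like field of view:

* background color linear in the pigment trait (clamped at ±2.1 SD), with
  higher pigment darker and relatively redder; the linear map keeps the
  central-patch color a near-lossless readout of the trait, which is what
  the recovery analyses assume;
* a radial illumination falloff and a foveal dark spot (both
  deterministic, so they rescale but do not decorrelate the color
  readout);
* a recursive bifurcating vessel tree from the optic disc whose trunk
  count is monotone in the vessel trait, drawn from a subject-seeded
  stream so both eyes share topology; vessels avoid a foveal avascular
  zone (0.3 of the field radius), as real retinas do — this also keeps
  vessel pixels out of the color patch;
* bright/dark lesions proportional to the retinopathy grade, sparing the
  fovea; bad-quality corpus images are additionally defocused (blur sigma
  2.5-6 px), optionally with severe under-/over-illumination or occlusion
  on top, mirroring real bad-quality fundus corpora;
* the right eye is the horizontal mirror of the base rendering, and
  per-image nuisance is applied afterwards: rotation uniform in ±15°,
  illumination scale uniform in 0.95-1.05 (a standardized-camera
  protocol), and occasional mild blur (sigma 0.3-1 px with probability
  0.3).

What the simulator does **not** emulate: photorealistic texture, optic
disc and vessel anatomy beyond a branching sketch, camera vignetting
variation, pathology other than generic lesions, population structure or
relatedness (the GRM is homogeneous), or non-autosomal genetics. Passing
tests therefore demonstrate that the pipeline's statistics and plumbing
are correct under controlled conditions; they do not certify performance
on real cohorts with domain shift.

All randomness flows from one master seed through named substreams
(`substreamSeed`), so stages are individually reproducible and mutually
independent.

# Quality control

The scorer is a single-hidden-layer network (8 tanh units) over fixed
image features: the variance of the discrete Laplacian (sharpness),
intensity mean/SD, clipping fractions, mean gradient magnitude, and an
8×8 pooled grayscale map. It is trained with cross-entropy by full-batch
Adam, early stopping with patience 5 on a seeded 80/20 split. Scores are
in [0, 1]; 0.5 is the good/bad decision threshold and 0.95 the
top-quality cut used to pick phenotyper training images. AUROC uses the
rank statistic with ties counted one half (the Mann-Whitney convention),
and the remaining metrics come from the 2×2 table at the threshold.

# The contrastive phenotyper

**Encoder.** A lightweight convolutional feature encoder: 16×16
block-average pooling of each color channel plus 8×8 pooled gradient
magnitude (832 features, resolution-independent), standardized, followed
by a trained linear head to `d` dimensions and unit normalization. The
trainable surface is the head and the template bank; the pooled feature
maps are fixed. At desk scale this keeps training deterministic,
CPU-cheap, and transparent, while preserving the contrastive-learning
mechanics the framework is about. It will not capture subtle texture a
deep backbone could; the pair-separation diagnostics quantify what it
does capture.

**Loss.** Each training subject owns a template vector on the unit
sphere. With sample embedding z, its subject's template t (angle θ), and
scale s and margin m, the target logit is `s·cos(θ + m)` and every other
subject's template contributes `s·cos(θ_j)`; the loss is the mean
negative log of the margin-softmax probability. With m = 0 it reduces to
softmax cross-entropy over template logits (a frozen oracle test).
Defaults are s = 30 and m = 0.5 rad, the standard operating point of
additive-angular-margin losses: s is an inverse temperature (larger →
sharper softmax), m an angle (meaningful only in [0, π)). Templates are
learnable rows, unit-normalized through the gradient (the projection
`(I − tt')/‖v‖` is applied analytically), updated jointly with the head
by Adam.

**Training.** Right-eye images are flipped before encoding; rotation
augmentation (±15°, `nAug` precomputed variants per image, one sampled
per epoch) adds robustness. When retinopathy grades are supplied, an
auxiliary linear grade head is trained at weight 1/`auxWeightRatio`
(default 10:1 contrastive:classification, contrastive-dominant). Subjects
are split 80/20; since held-out subjects have no trained template, the
held-out loss uses each subject's left-eye embedding as their template
and their right-eye embedding as the sample — a template-free pair loss
that measures exactly the generalization we care about. The weights with
the lowest held-out loss are retained. The nominal Adam rate is 1e-4; at
desk scale (hundreds of optimizer steps rather than hundreds of
thousands) the worked examples use 0.01, which is the same optimizer
trajectory compressed into the available steps.

**Diagnostics.** Matched (left-right of one subject) and random
(cross-subject) cosine similarities are compared via the Jensen-Shannon
distance (base 2, square root of the divergence) and the Jaccard index
(intersection-over-union of area) on a fixed 80-bin histogram over
[−1, 1]; kernel density curves use Scott's bandwidth times 0.5. The mean
random-pair similarity is reported (deep encoders often show a "cone
effect" with random pairs centered above zero); no numeric target is
asserted for it on synthetic data.

# Retina color

The color phenotypes are the per-channel arithmetic means of the central
foveal patch. Right-eye images are mirrored first. For a 1536×2048 image
the half-open 0-based window rows [600, 1000), columns [800, 1200) — a
400×400 patch, slightly off the geometric center — is used verbatim; any
other size uses the same fractional window, floor-rounded, preserving the
offset. The window is deliberately not recentered.

# The association engine

The model is `y = Xβ + g + e` with `g ~ N(0, σ²_g K)`,
`e ~ N(0, σ²_e I)`, where `K = ZZ'/M` over MAF-filtered (default 0.01)
dosages standardized by `sqrt(2p(1−p))`. REML uses one eigendecomposition
of K and a bounded scalar search on `log(σ²_g/σ²_e)` in [−10, 10]
(tolerance 1e-8); a boundary optimum is reported as exactly zero genetic
variance, making the scan collapse to OLS. Per SNP, the effect is
generalized least squares under the fitted `V = σ²_g K + σ²_e I` with
covariates projected out in the V-metric, the Wald χ²(1 df) is
`(β/se)²`, and p-values are floored at 1e-300. This is the exact
statistic that large-cohort iterative LMM solvers approximate; at desk
scale the exact computation is affordable.

Leave-one-chromosome-out (LOCO) is on by default: the K used for a SNP
excludes its chromosome, avoiding proximal contamination. Covariates are
age, sex and the top 10 ancestry PCs. Two desk-scale specifics, both
found by tracing power loss on simulated causal SNPs:

* PCs come from an **LD-pruned** SNP set (greedy r² < 0.2 within 1 Mb).
  With a few hundred SNPs, the top eigenvectors of an unpruned GRM are
  individual LD-block factors, and projecting them out removes causal
  signal itself (in one diagnostic, 36% of a causal SNP's variance).
* Under LOCO the PCs for each chromosome's scan are computed from the
  **other** chromosomes' pruned SNPs — the covariate analog of the LOCO
  GRM. At biobank panel sizes per-SNP leakage into genome-wide PCs is
  negligible and this distinction vanishes.

The genomic inflation factor is the median χ² implied by the p-values
divided by 0.4549364 (the χ²(1) median). At M = 2000 LD-correlated SNPs
a single median-based λ has sampling SD around 0.05-0.08, so calibration
summaries average λ over several independent null phenotypes rather than
asserting an interval on one draw.

Both eyes are scanned separately and never meta-analyzed; replication is
the dual-eye intersection below.

# Post-processing

* **Intersection**: per SNP, the minimum p over traits within each eye;
  selected iff both minima pass 5e-8; the smaller minimum is reported.
* **Clumping**: same-chromosome selected variants merge when r² > 0.2 or
  they lie within 250 kb; merging is single-link and transitively closed
  (union-find), the standard clumping reading; the lead SNP has the
  smallest reported p, ties to the smaller position.
* **LD scores**: `l_j = Σ_k r²_jk` within 1 Mb on the same chromosome,
  self term included.
* **LD-score regression**: χ² on l with `E[χ²] = 1 + N h² l / M`, unit
  weights, free intercept; h² = slope·M/N; SEs by 20-block jackknife.
  Genetic correlation regresses `z₁z₂` on l and normalizes by the two
  heritabilities; rg is clipped to ±1.25 with a warning. The full LDSC
  weighting/regularization machinery is out of scope.
* **Catalog queries**: closed intervals `[start − 250 kb, end + 250 kb]`
  per chromosome against a local TSV catalog; genome-build conversion is
  out of scope (a build-mismatch must be resolved upstream).

# Pipeline and reproducibility

`runPipeline()` executes simulate → quality → phenotyper → embed →
colors → GWAS (endophenotypes and colors, both eyes) → intersect/clump →
LD-score regression → report. Every analysis constant (0.5, 0.95, 5e-8,
r² 0.2, 250 kb, s, m, the 10:1 auxiliary ratio) is a named configuration
key; the desk-scale defaults (120 subjects, 200 SNPs, 64×64 images, 16
endophenotypes) finish in minutes and are deliberately smaller than the
constants' native setting. Stage toggles reuse existing artifacts, with
a clear error naming the stage to enable when one is missing. Numeric
TSV artifacts are rounded to 6 significant digits and listed with MD5
checksums in a manifest; two runs from the same seed are
checksum-identical.

# Numerical notes and limitations

* Cosines are clamped to ±(1 − 1e-7) before the margin transform; its
  derivative is clamped accordingly.
* `selectTopQuality` breaks score ties by input order, making selection
  permutation-stable.
* Monomorphic SNPs are reported untested (β = 0, p = 1) so the SNP
  universe stays aligned across eyes; monomorphic r² is defined as 0
  with a warning.
* REML assumes K is PSD within tolerance and errors otherwise.
* Problem sizes in tests: calibration at 500×2000; oracle equivalence at
  n = 20; phenotyper separation at 200 subjects, 128×128, ≤30 epochs;
  causal recovery at n = 1000 with five 5%-variance pigmentation SNPs.
  These sizes make every check exact or well-powered while keeping a
  full run on one CPU in minutes.
* The encoder's fixed feature maps favor color and coarse structure;
  embeddings are expected to correlate strongly with retina color (the
  real framework observed the same coupling and ran color GWAS for that
  reason).
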