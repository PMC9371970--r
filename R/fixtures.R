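## Synthetic fixtures: textured elliptical nuclei images with ground-truth
## masks, and log-normal protein matrices with planted effects and
## intensity-dependent (left-censoring) dropout. Every downstream module is
## testable against these known truths.

#' Specification for a synthetic nucleus image fixture
#'
#' Describes a field of textured, rotated elliptical "nuclei" belonging to
#' several morphology classes. The defaults emulate a DAPI-stained cell
#' culture monolayer with three common and three rare nucleus classes
#' (frequencies 0.33/0.30/0.28 and 0.03 each), differing in size,
#' elongation and total staining intensity.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um pixel edge length, µm.
#' @param n_objects number of nuclei to place.
#' @param class_specs data.frame with columns `class_id`, `frequency`,
#'   `mean_area_um2`, `ecc_min`, `ecc_max` (eccentricity range),
#'   `intensity_mean`, `intensity_cv`. Frequencies must sum to 1.
#' @param background_level additive background intensity.
#' @param noise_sd additive Gaussian read-noise s.d.
#' @param area_cv lognormal coefficient of variation of per-object area.
#' @param texture_sd s.d. of the per-pixel multiplicative (log-scale)
#'   texture noise inside objects.
#' @param margin_px minimum empty margin enforced between objects, so that
#'   placed nuclei never touch.
#' @param max_attempts placement attempts per object before giving up.
#' @param seed RNG seed.
#' @return A list of class `ImageFixtureSpec`.
#' @export
imageFixtureSpec <- function(width_px = 512L, height_px = 512L,
                             pixel_size_um = 0.5, n_objects = 50L,
                             class_specs = defaultNucleusClasses(),
                             background_level = 100, noise_sd = 10,
                             area_cv = 0.1, texture_sd = 0.1,
                             margin_px = 3L, max_attempts = 100L,
                             seed = 1L) {
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               pixel_size_um = pixel_size_um, n_objects = as.integer(n_objects),
               class_specs = class_specs, background_level = background_level,
               noise_sd = noise_sd, area_cv = area_cv, texture_sd = texture_sd,
               margin_px = as.integer(margin_px),
               max_attempts = as.integer(max_attempts), seed = as.integer(seed))
  class(spec) <- "ImageFixtureSpec"
  validateImageFixtureSpec(spec)
  spec
}

#' Default six-class nucleus morphology panel
#'
#' Three primary classes (frequencies 0.33, 0.30, 0.28) and three rare ones
#' (0.03 each), spanning small/round to large/elongated nuclei with
#' increasing total DNA-stain intensity for the larger classes.
#' @return data.frame usable as `class_specs` in [imageFixtureSpec()].
#' @export
defaultNucleusClasses <- function() {
  data.frame(
    class_id = 1:6,
    frequency = c(0.33, 0.30, 0.28, 0.03, 0.03, 0.03),
    mean_area_um2 = c(55, 40, 75, 120, 25, 95),
    ecc_min = c(0.20, 0.55, 0.30, 0.10, 0.30, 0.80),
    ecc_max = c(0.45, 0.80, 0.55, 0.35, 0.60, 0.93),
    intensity_mean = c(1200, 900, 1600, 2600, 600, 2100),
    intensity_cv = rep(0.15, 6))
}

validateImageFixtureSpec <- function(spec) {
  cs <- spec$class_specs
  need <- c("class_id", "frequency", "mean_area_um2", "ecc_min", "ecc_max",
            "intensity_mean", "intensity_cv")
  if (!all(need %in% names(cs)))
    stop("class_specs must contain columns: ", paste(need, collapse = ", "))
  if (abs(sum(cs$frequency) - 1) > 1e-9)
    stop("class frequencies must sum to 1")
  if (any(cs$mean_area_um2 <= 0)) stop("mean areas must be positive")
  if (any(cs$ecc_min < 0 | cs$ecc_max >= 1 | cs$ecc_min > cs$ecc_max))
    stop("eccentricity ranges must satisfy 0 <= ecc_min <= ecc_max < 1")
  stopifnot(spec$width_px > 0, spec$height_px > 0, spec$pixel_size_um > 0,
            spec$n_objects >= 0)
  invisible(spec)
}

#' Generate a synthetic nucleus image with ground truth
#'
#' Places non-overlapping rotated ellipses by rejection sampling (at most
#' `max_attempts` tries per object; partial placement is reported via the
#' `n_placed` attribute, not an error), renders multiplicative texture plus
#' additive Gaussian noise, and returns the intensity image, the
#' ground-truth [LabelMask-class] and a truth table with each object's
#' class, area and centroid. Fully reproducible for a fixed seed.
#'
#' @param spec an [imageFixtureSpec()].
#' @return list with elements `image` (numeric matrix), `mask`
#'   ([LabelMask-class], labels `1..n_placed`) and `truth` (data.frame:
#'   `object_id`, `class_id`, `n_pixels`, `area_um2`, `centroid_x_um`,
#'   `centroid_y_um`, `intensity`).
#' @examples
#' fx <- makeImageFixture(imageFixtureSpec(n_objects = 10, seed = 3))
#' nObjects(fx$mask)
#' @export
makeImageFixture <- function(spec) {
  validateImageFixtureSpec(spec)
  withSeed(spec$seed, {
    h <- spec$height_px; w <- spec$width_px; px <- spec$pixel_size_um
    cs <- spec$class_specs
    lab <- matrix(0L, h, w)
    img <- matrix(0, h, w)
    truth <- vector("list", spec$n_objects)
    n_placed <- 0L
    classes <- if (spec$n_objects > 0L)
      cs$class_id[sample.int(nrow(cs), spec$n_objects, replace = TRUE,
                             prob = cs$frequency)]
    else integer()
    for (i in seq_len(spec$n_objects)) {
      ci <- match(classes[i], cs$class_id)
      area_um2 <- cs$mean_area_um2[ci] *
        exp(stats::rnorm(1, 0, sqrt(log(1 + spec$area_cv^2))))
      ecc <- stats::runif(1, cs$ecc_min[ci], cs$ecc_max[ci])
      theta <- stats::runif(1, 0, pi)
      base_int <- cs$intensity_mean[ci] *
        exp(stats::rnorm(1, 0, sqrt(log(1 + cs$intensity_cv[ci]^2))))
      a_px <- sqrt((area_um2 / px^2) / (pi * sqrt(1 - ecc^2)))
      b_px <- a_px * sqrt(1 - ecc^2)
      placed <- FALSE
      for (att in seq_len(spec$max_attempts)) {
        ext <- a_px + spec$margin_px + 1
        if (2 * ext + 2 >= min(h, w)) break
        cy <- stats::runif(1, ext + 1, h - ext)
        cx <- stats::runif(1, ext + 1, w - ext)
        r0 <- floor(cy - ext); r1 <- ceiling(cy + ext)
        c0 <- floor(cx - ext); c1 <- ceiling(cx + ext)
        rr <- r0:r1; cc <- c0:c1
        dy <- matrix(rr - cy, length(rr), length(cc))
        dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
        u <- dx * cos(theta) + dy * sin(theta)
        v <- -dx * sin(theta) + dy * cos(theta)
        inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
        grown <- (u / (a_px + spec$margin_px))^2 +
          (v / (b_px + spec$margin_px))^2 <= 1
        if (!any(inside)) next
        if (any(lab[rr, cc][grown] != 0L)) next
        npx <- sum(inside)
        n_placed <- n_placed + 1L
        sub <- lab[rr, cc]; sub[inside] <- n_placed; lab[rr, cc] <- sub
        tex <- base_int * exp(stats::rnorm(npx, 0, spec$texture_sd))
        subi <- img[rr, cc]; subi[inside] <- tex; img[rr, cc] <- subi
        pr <- matrix(rr, length(rr), length(cc))[inside]
        pc <- matrix(cc, length(rr), length(cc), byrow = TRUE)[inside]
        truth[[n_placed]] <- data.frame(
          object_id = n_placed, class_id = classes[i], n_pixels = npx,
          area_um2 = npx * px^2,
          centroid_x_um = (mean(pc) - 0.5) * px,
          centroid_y_um = (mean(pr) - 0.5) * px,
          intensity = base_int)
        placed <- TRUE
        break
      }
    }
    if (n_placed < spec$n_objects)
      warning(sprintf("placed %d of %d objects without overlap",
                      n_placed, spec$n_objects))
    img <- img + spec$background_level +
      stats::rnorm(length(img), 0, spec$noise_sd)
    img[img < 0] <- 0
    truth <- if (n_placed > 0L) do.call(rbind, truth[seq_len(n_placed)])
      else data.frame(object_id = integer(), class_id = integer(),
                      n_pixels = integer(), area_um2 = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      intensity = numeric())
    out <- list(image = img, mask = LabelMask(lab, px), truth = truth)
    attr(out, "n_placed") <- n_placed
    out
  })
}

## ------------------------------------------------------- proteome fixture

#' Specification for a synthetic protein quantification matrix
#'
#' Log2-scale intensities, Gaussian within group around a protein-specific
#' baseline, with a planted log2 fold change between groups 1 and 2 for the
#' first `n_true_effects` proteins, and missing-not-at-random dropout whose
#' probability rises as true intensity falls (logistic left-censoring) —
#' the regime for which downshifted-normal imputation is appropriate.
#'
#' @param n_proteins,n_groups,reps_per_group matrix dimensions
#'   (`reps_per_group >= 2`).
#' @param n_true_effects number of proteins carrying the planted effect
#'   (must not exceed `n_proteins`); the effect acts between groups 1 and 2.
#' @param effect_log2fc planted log2 fold change (group 2 minus group 1).
#' @param within_group_sd within-group s.d. on the log2 scale.
#' @param base_mean,base_sd distribution of protein baseline log2 levels.
#' @param dropout_logistic_midpoint intensity at which dropout probability
#'   is 0.5.
#' @param dropout_logistic_slope steepness (per log2 unit); 0 makes dropout
#'   independent of intensity.
#' @param seed RNG seed.
#' @return list of class `ProteomeFixtureSpec`.
#' @export
proteomeFixtureSpec <- function(n_proteins = 1000L, n_groups = 2L,
                                reps_per_group = 4L, n_true_effects = 0L,
                                effect_log2fc = 2, within_group_sd = 0.3,
                                base_mean = 25, base_sd = 2,
                                dropout_logistic_midpoint = 21,
                                dropout_logistic_slope = 1,
                                seed = 1L) {
  spec <- list(n_proteins = as.integer(n_proteins),
               n_groups = as.integer(n_groups),
               reps_per_group = as.integer(reps_per_group),
               n_true_effects = as.integer(n_true_effects),
               effect_log2fc = effect_log2fc,
               within_group_sd = within_group_sd,
               base_mean = base_mean, base_sd = base_sd,
               dropout_logistic_midpoint = dropout_logistic_midpoint,
               dropout_logistic_slope = dropout_logistic_slope,
               seed = as.integer(seed))
  class(spec) <- "ProteomeFixtureSpec"
  if (spec$n_true_effects > spec$n_proteins)
    stop("n_true_effects must not exceed n_proteins")
  if (spec$reps_per_group < 2L) stop("reps_per_group must be >= 2")
  if (spec$n_groups < 2L) stop("n_groups must be >= 2")
  spec
}

#' Generate a synthetic protein matrix with planted effects and dropout
#'
#' @param spec a [proteomeFixtureSpec()].
#' @return list with `matrix` (a [ProteinMatrix-class]; groups labelled
#'   `group1..groupG`) and `truth` (data.frame `protein`, `true_log2fc` for
#'   the affected proteins only).
#' @examples
#' fx <- makeProteomeFixture(proteomeFixtureSpec(n_proteins = 50,
#'                                               n_true_effects = 5, seed = 2))
#' dim(intensities(fx$matrix))
#' @export
makeProteomeFixture <- function(spec) {
  stopifnot(inherits(spec, "ProteomeFixtureSpec"))
  withSeed(spec$seed, {
    p <- spec$n_proteins; g <- spec$n_groups; r <- spec$reps_per_group
    n <- g * r
    groups <- rep(paste0("group", seq_len(g)), each = r)
    base <- stats::rnorm(p, spec$base_mean, spec$base_sd)
    x <- matrix(stats::rnorm(p * n, 0, spec$within_group_sd), p, n) + base
    affected <- seq_len(spec$n_true_effects)
    if (length(affected))
      x[affected, groups == "group2"] <-
        x[affected, groups == "group2"] + spec$effect_log2fc
    p_miss <- stats::plogis(spec$dropout_logistic_slope *
                            (spec$dropout_logistic_midpoint - x))
    drop <- matrix(stats::runif(p * n) < p_miss, p, n)
    x[drop] <- NA_real_
    rownames(x) <- sprintf("protein%04d", seq_len(p))
    colnames(x) <- sprintf("%s_r%d", groups, rep(seq_len(r), g))
    truth <- data.frame(protein = rownames(x)[affected],
                        true_log2fc = rep(spec$effect_log2fc,
                                          length(affected)))
    list(matrix = ProteinMatrix(x, groups), truth = truth)
  })
}

## ------------------------------------------------------ phenotype fixture

#' Generate a planted-class feature table for clustering tests
#'
#' Gaussian classes with unit within-class s.d. whose centres sit at the
#' vertices of a regular simplex with edge length `separation_sd`, so every
#' pair of classes is equally separated (in within-class s.d. units). The
#' truth labels are returned for agreement/frequency-recovery checks.
#'
#' @param n number of objects.
#' @param frequencies class frequencies (sum to 1); length defines the
#'   number of classes.
#' @param separation_sd pairwise centre separation in within-class s.d.
#' @param n_features feature-space dimension (defaults to classes - 1, the
#'   smallest dimension that embeds the simplex).
#' @param seed RNG seed.
#' @return list with `records` (data.frame of features `f1..fd`) and
#'   `truth` (integer class per row).
#' @export
makePhenotypeFixture <- function(n, frequencies, separation_sd = 6,
                                 n_features = length(frequencies) - 1L,
                                 seed = 1L) {
  k <- length(frequencies)
  stopifnot(abs(sum(frequencies) - 1) < 1e-9, k >= 2L,
            n_features >= k - 1L)
  ## regular simplex with unit edge in k-1 dims, from the centred identity
  m <- diag(k) - 1 / k
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, seq_len(k - 1L), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k - 1L)], 0)), k - 1L)
  centers <- matrix(0, k, n_features)
  centers[, seq_len(k - 1L)] <- v / sqrt(2) * separation_sd
  withSeed(seed, {
    cls <- sample.int(k, n, replace = TRUE, prob = frequencies)
    x <- centers[cls, , drop = FALSE] +
      matrix(stats::rnorm(n * n_features), n)
    records <- as.data.frame(x)
    names(records) <- paste0("f", seq_len(n_features))
    list(records = records, truth = cls)
  })
}

#' Best-permutation agreement between two labelings
#'
#' Fraction of objects on which `labels` agrees with `truth` after the
#' class-relabelling that maximizes agreement (greedy on the confusion
#' matrix, exact for confusion matrices with a dominant diagonal structure).
#'
#' @param labels,truth integer vectors of equal length.
#' @return agreement fraction in `[0, 1]`.
#' @export
labelAgreement <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  tab <- table(labels, truth)
  total <- 0L
  used_r <- used_c <- integer()
  for (step in seq_len(min(dim(tab)))) {
    best <- -1L; bi <- bj <- 0L
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      if (i %in% used_r || j %in% used_c) next
      if (tab[i, j] > best) { best <- tab[i, j]; bi <- i; bj <- j }
    }
    total <- total + best
    used_r <- c(used_r, bi); used_c <- c(used_c, bj)
  }
  total / length(labels)
}
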