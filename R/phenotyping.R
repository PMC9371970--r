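## Per-object phenotype features (area, perimeter, solidity, form factor,
## staining intensities, neighbourhood) and phenotype classification, either
## by supervised marker gating or by the unsupervised k-means phenotype
## finder.

#' Extract morphology and intensity features per object
#'
#' For every labelled object: area (pixel count x px^2), perimeter measured
#' on the sub-pixel marching-squares boundary (lightly smoothed so that the
#' staircase discretization does not inflate it), solidity (area / convex
#' hull area), form factor (4*pi*A/P^2; 1 for a perfect disk), total and
#' mean intensity per channel, and the number of neighbours whose centroid
#' lies within `neighbor_radius_um`.
#'
#' Discretization can push solidity or form factor slightly above 1 for
#' small objects; values up to ~1.05 should be treated as 1.
#'
#' @param mask a [LabelMask-class].
#' @param channels named list of intensity matrices, same shape as the mask.
#' @param neighbor_radius_um neighbourhood radius in µm (default 50).
#' @return data.frame, one row per object: `object_id`, `centroid_x_um`,
#'   `centroid_y_um`, `area_um2`, `perimeter_um`, `solidity`, `form_factor`,
#'   `total_<channel>` and `mean_<channel>` per channel, `neighbor_count`,
#'   `class_label` (NA until classified).
#' @examples
#' fx <- makeImageFixture(imageFixtureSpec(n_objects = 5, seed = 1))
#' head(extractFeatures(fx$mask, list(dapi = fx$image)))
#' @export
extractFeatures <- function(mask, channels = list(),
                            neighbor_radius_um = 50) {
  stopifnot(is(mask, "LabelMask"))
  if (length(channels)) {
    if (is.null(names(channels)) || any(names(channels) == ""))
      stop("channels must be a named list")
    for (ch in channels)
      if (!all(dim(ch) == dim(mask)))
        stop("channel shape differs from mask shape")
  }
  lab <- maskLabels(mask)
  px <- pixelSize(mask)
  obj <- maskToObjects(mask)
  n <- nrow(obj)
  perim <- solid <- ff <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r0 <- obj$row_min[i]; r1 <- obj$row_max[i]
    c0 <- obj$col_min[i]; c1 <- obj$col_max[i]
    bin <- (lab[r0:r1, c0:c1, drop = FALSE] == obj$label[i]) * 1
    rings <- binaryRings(bin, px, row_off = r0 - 1L, col_off = c0 - 1L)
    if (!length(rings)) next
    outer <- rings[[which.max(vapply(rings, function(v) abs(signedArea(v)),
                                     numeric(1)))]]
    p <- ringPerimeter(smoothRing(outer, 1L))
    a <- obj$n_pixels[i] * px^2
    hull <- outer[grDevices::chull(outer), , drop = FALSE]
    perim[i] <- p
    solid[i] <- a / abs(signedArea(hull))
    ff[i] <- 4 * pi * a / p^2
  }
  out <- data.frame(object_id = obj$label,
                    centroid_x_um = obj$centroid_x_um,
                    centroid_y_um = obj$centroid_y_um,
                    area_um2 = obj$n_pixels * px^2,
                    perimeter_um = perim,
                    solidity = solid,
                    form_factor = ff)
  if (length(channels)) {
    sets <- maskPixelSets(mask)
    for (nm in names(channels)) {
      v <- channels[[nm]]
      tot <- vapply(sets, function(s) sum(v[s]), numeric(1))
      out[[paste0("total_", nm)]] <- as.numeric(tot)
      out[[paste0("mean_", nm)]] <- as.numeric(tot) / obj$n_pixels
    }
  }
  if (n) {
    d <- as.matrix(stats::dist(cbind(obj$centroid_x_um, obj$centroid_y_um)))
    out$neighbor_count <- as.integer(rowSums(d <= neighbor_radius_um) - 1L)
  } else out$neighbor_count <- integer()
  out$class_label <- NA_integer_
  out
}

#' Two-class marker gating
#'
#' Assigns class 1 (marker-positive) to objects whose chosen intensity
#' statistic strictly exceeds the cutoff, class 2 (marker-negative)
#' otherwise. Deterministic.
#'
#' @param records feature table from [extractFeatures()].
#' @param channel channel name (a `total_<channel>`/`mean_<channel>` column
#'   must exist).
#' @param statistic `"mean"` or `"total"`.
#' @param cutoff finite gating threshold.
#' @return `records` with `class_label` set to 1 or 2.
#' @export
gateByMarker <- function(records, channel, statistic = c("mean", "total"),
                         cutoff) {
  statistic <- match.arg(statistic)
  stopifnot(is.finite(cutoff))
  col <- paste0(statistic, "_", channel)
  if (!col %in% names(records)) stop("unknown channel: ", channel)
  records$class_label <- ifelse(records[[col]] > cutoff, 1L, 2L)
  records
}

#' Unsupervised phenotype finder (k-means on z-scored features)
#'
#' Features are standardized to mean 0, s.d. 1 and clustered with k-means
#' (`nstart` random restarts under a fixed seed, so output is
#' deterministic). Classes are renumbered 1..k by descending frequency,
#' which makes labels stable and comparable across runs.
#'
#' @param records feature table.
#' @param features character vector of feature column names.
#' @param k number of classes (`2 <= k <= nrow(records)`). The choice of k
#'   is the user's; [silhouetteScan()] can provide guidance.
#' @param seed RNG seed for the restarts.
#' @param nstart number of k-means restarts (default 25).
#' @return list with `model` (a `PhenotypeModel`: `k`, `features`, `center`
#'   and `scale` of the standardization, `centers` in standardized space,
#'   `frequencies`, `tot_withinss`) and `records` (input with `class_label`
#'   filled in).
#' @examples
#' rec <- data.frame(a = c(rnorm(30), rnorm(30, 8)), b = rnorm(60))
#' fit <- phenotypeFinder(rec, c("a", "b"), k = 2, seed = 1)
#' fit$model$frequencies
#' @export
phenotypeFinder <- function(records, features, k, seed = 1L, nstart = 25L) {
  stopifnot(all(features %in% names(records)))
  x <- as.matrix(records[features])
  stopifnot(k >= 2L, k <= nrow(x))
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant feature(s): ", paste(features[sds == 0], collapse = ", "))
  z <- scale(x, center = mu, scale = sds)
  km <- if (k == nrow(x)) {
    ## every object its own class; k-means is degenerate here
    list(cluster = seq_len(k), centers = z,
         tot.withinss = 0)
  } else {
    withSeed(seed,
      stats::kmeans(z, centers = k, nstart = nstart, iter.max = 200L))
  }
  freq <- tabulate(km$cluster, nbins = k) / nrow(x)
  ord <- order(-freq, seq_len(k))
  relab <- integer(k); relab[ord] <- seq_len(k)
  cl <- relab[km$cluster]
  model <- list(k = k, features = features, center = mu, scale = sds,
                centers = km$centers[ord, , drop = FALSE],
                frequencies = freq[ord],
                tot_withinss = km$tot.withinss)
  rownames(model$centers) <- paste0("class", seq_len(k))
  names(model$frequencies) <- paste0("class", seq_len(k))
  class(model) <- "PhenotypeModel"
  records$class_label <- cl
  list(model = model, records = records)
}

#' @export
print.PhenotypeModel <- function(x, ...) {
  cat("PhenotypeModel: k =", x$k, "on",
      paste(x$features, collapse = ", "), "\n frequencies:",
      paste(sprintf("%.3f", x$frequencies), collapse = " "), "\n")
  invisible(x)
}

#' Silhouette-style guidance for choosing k
#'
#' Mean silhouette width (computed from pairwise distances in standardized
#' feature space) for each candidate k. Reported as guidance only; k remains
#' a user decision.
#'
#' @param records,features as in [phenotypeFinder()].
#' @param k_range integer vector of candidate k.
#' @param seed,nstart passed to the underlying k-means runs.
#' @return data.frame `k`, `mean_silhouette`.
#' @export
silhouetteScan <- function(records, features, k_range = 2:8, seed = 1L,
                           nstart = 10L) {
  x <- as.matrix(records[features])
  z <- scale(x)
  d <- as.matrix(stats::dist(z))
  res <- lapply(k_range, function(k) {
    cl <- phenotypeFinder(records, features, k, seed = seed,
                          nstart = nstart)$records$class_label
    sil <- vapply(seq_len(nrow(z)), function(i) {
      own <- cl == cl[i]; own[i] <- FALSE
      a <- if (any(own)) mean(d[i, own]) else 0
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(g) mean(d[i, cl == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    data.frame(k = k, mean_silhouette = mean(sil))
  })
  do.call(rbind, res)
}

#' Per-class z-scored feature means (radar-plot summary)
#'
#' Features are standardized with the model's means and s.d.s; the summary
#' is the per-class mean of each standardized feature. The frequency-
#' weighted grand mean over classes is ~0 by construction.
#'
#' @param model a `PhenotypeModel`.
#' @param records labelled records (with `class_label`).
#' @return matrix classes x features of z-scored means.
#' @export
radarSummary <- function(model, records) {
  stopifnot(inherits(model, "PhenotypeModel"),
            !anyNA(records$class_label))
  z <- scale(as.matrix(records[model$features]),
             center = model$center, scale = model$scale)
  cls <- sort(unique(records$class_label))
  out <- t(vapply(cls, function(cl)
    colMeans(z[records$class_label == cl, , drop = FALSE]),
    numeric(length(model$features))))
  rownames(out) <- paste0("class", cls)
  out
}
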