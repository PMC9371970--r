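## Classical baseline segmenter (threshold + distance-transform watershed
## object splitting) and the mask/object data plumbing. Deep-learning
## segmenters are supported through the same contract: any procedure that
## turns an intensity image into a LabelMask (e.g. masks imported from
## external tools via readLabelMaskTIFF) can stand in for baselineSegment.

#' Baseline nucleus segmentation: blur, adaptive threshold, watershed split
#'
#' A classical adaptive-threshold-plus-object-splitting segmenter. The image
#' is Gaussian-blurred, candidate regions are detected with a
#' background-robust global threshold (median + `k_mad` MADs — robust to
#' the background dominating the histogram), each connected candidate is
#' then re-thresholded with a local Otsu over its own pixels (so dim and
#' bright objects both get accurate boundaries instead of a single global
#' compromise), holes are filled, touching objects are split by a
#' distance-transform watershed, and objects smaller than `min_area_um2`
#' are removed. Label ids are assigned in raster-scan order of object
#' centroids (top-to-bottom, then left-to-right), so output is
#' deterministic for fixed parameters.
#'
#' @param image 2D numeric matrix of intensities (finite values).
#' @param pixel_size_um pixel edge length, µm.
#' @param blur_sigma_um Gaussian blur s.d. in µm (0 disables blurring).
#' @param threshold_method `"adaptive"` (default, as described above) or
#'   `"otsu"` (single global Otsu; can swallow dim objects when bright ones
#'   dominate the foreground mode).
#' @param k_mad MAD multiplier for the background detection threshold.
#' @param min_area_um2 objects below this area are discarded (speckle
#'   suppression; default 10 µm²).
#' @param split_footprint_um neighbourhood size for the watershed local-maxima
#'   seeds; controls how aggressively touching objects are split.
#' @return A [LabelMask-class]. An all-background result is legal and yields
#'   an empty mask.
#' @examples
#' img <- matrix(0, 60, 60); img[20:30, 20:30] <- 1; img[40:50, 40:50] <- 1
#' m <- baselineSegment(img, pixel_size_um = 1)
#' nObjects(m)
#' @export
baselineSegment <- function(image, pixel_size_um,
                            blur_sigma_um = 1,
                            threshold_method = c("adaptive", "otsu"),
                            min_area_um2 = 10,
                            split_footprint_um = 2,
                            k_mad = 5) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  threshold_method <- match.arg(threshold_method)
  px <- pixel_size_um
  im <- image
  if (blur_sigma_um > 0) {
    sigma_px <- blur_sigma_um / px
    im <- as.matrix(EBImage::gblur(EBImage::Image(im),
                                   sigma = max(sigma_px, 0.3)))
  }
  rng <- range(im)
  if (diff(rng) <= .Machine$double.eps)
    return(LabelMask(matrix(0L, nrow(image), ncol(image)), px))
  ext <- max(1L, round(split_footprint_um / px))
  segmentBinary <- function(bin) {
    bin <- EBImage::fillHull(EBImage::Image(bin))
    ws <- EBImage::watershed(EBImage::distmap(bin), tolerance = 1, ext = ext)
    matrix(as.integer(EBImage::imageData(ws)), nrow(image), ncol(image))
  }
  if (threshold_method == "otsu") {
    bin <- im > EBImage::otsu(EBImage::Image(im), range = rng)
    if (!any(bin))
      return(LabelMask(matrix(0L, nrow(image), ncol(image)), px))
    lab <- segmentBinary(bin)
  } else {
    low <- stats::median(im) + k_mad * stats::mad(im)
    bin <- im > low
    if (!any(bin))
      return(LabelMask(matrix(0L, nrow(image), ncol(image)), px))
    ## split candidate regions first, then refine each region with its own
    ## Otsu cut: the low threshold includes the blur halo, and a local cut
    ## per region gives dim and bright objects accurate boundaries
    localCut <- function(mask_px, keep_into) {
      for (s in mask_px) {
        v <- im[s]
        vr <- range(v)
        if (diff(vr) <= .Machine$double.eps) next
        th_local <- EBImage::otsu(EBImage::Image(matrix(v)), range = vr)
        keep_into[s] <- v > th_local
      }
      keep_into
    }
    lab0 <- segmentBinary(bin)
    refined <- localCut(split(which(lab0 > 0L), lab0[lab0 > 0L]),
                        bin & FALSE)
    ## recovery pass: a dim object sharing a region with a much brighter
    ## one is cut away with the halo; removed chunks that are solid blobs
    ## (distance-map depth >= 2 px) rather than thin halo are
    ## re-thresholded on their own
    removed <- bin & !refined
    if (any(removed)) {
      rl <- EBImage::bwlabel(EBImage::Image(removed))
      dmr <- as.matrix(EBImage::distmap(EBImage::Image(removed)))
      rlm <- matrix(as.integer(EBImage::imageData(rl)),
                    nrow(image), ncol(image))
      chunks <- split(which(rlm > 0L), rlm[rlm > 0L])
      solid <- vapply(chunks, function(s) max(dmr[s]) >= 2, logical(1))
      if (any(solid)) refined <- localCut(chunks[solid], refined)
    }
    if (!any(refined))
      return(LabelMask(matrix(0L, nrow(image), ncol(image)), px))
    lab <- segmentBinary(refined)
  }
  ## area filter
  min_px <- min_area_um2 / px^2
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes > 0L & sizes < min_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabelRasterOrder(LabelMask(lab, px))
}

#' Relabel a mask in raster-scan order of object centroids
#' @noRd
relabelRasterOrder <- function(mask) {
  lab <- maskLabels(mask)
  ids <- objectIds(mask)
  if (!length(ids)) return(mask)
  idx <- which(lab > 0L)
  f <- factor(lab[idx], levels = ids)
  cy <- tapply((idx - 1L) %% nrow(lab) + 1L, f, mean)
  cx <- tapply((idx - 1L) %/% nrow(lab) + 1L, f, mean)
  ord <- order(cy, cx)
  newlab <- integer(max(ids))
  newlab[ids[ord]] <- seq_along(ids)
  out <- lab
  out[idx] <- newlab[lab[idx]]
  LabelMask(out, pixelSize(mask))
}

#' Enumerate the objects of a mask
#'
#' One row per positive label with the pixel count, centroid in µm
#' (pixel-centre convention: origin at image top-left, x rightward, y
#' downward) and bounding box in pixel indices.
#'
#' @param mask a [LabelMask-class].
#' @return data.frame: `label`, `n_pixels`, `centroid_x_um`, `centroid_y_um`,
#'   `row_min`, `row_max`, `col_min`, `col_max`. Empty mask gives zero rows.
#' @export
maskToObjects <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  lab <- maskLabels(mask)
  px <- pixelSize(mask)
  ids <- objectIds(mask)
  if (!length(ids))
    return(data.frame(label = integer(), n_pixels = integer(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      row_min = integer(), row_max = integer(),
                      col_min = integer(), col_max = integer()))
  idx <- which(lab > 0L)
  f <- factor(lab[idx], levels = ids)
  r <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  data.frame(
    label = ids,
    n_pixels = as.integer(table(f)),
    centroid_x_um = as.numeric(tapply(cc, f, mean) - 0.5) * px,
    centroid_y_um = as.numeric(tapply(r, f, mean) - 0.5) * px,
    row_min = as.integer(tapply(r, f, min)),
    row_max = as.integer(tapply(r, f, max)),
    col_min = as.integer(tapply(cc, f, min)),
    col_max = as.integer(tapply(cc, f, max)),
    row.names = NULL)
}

#' Pixel index sets per object
#'
#' @param mask a [LabelMask-class].
#' @return named list mapping each label to its vector of linear pixel
#'   indices (column-major, as in base R matrices).
#' @export
maskPixelSets <- function(mask) {
  lab <- maskLabels(mask)
  ids <- objectIds(mask)
  if (!length(ids)) return(setNames(list(), character()))
  idx <- which(lab > 0L)
  split(idx, factor(lab[idx], levels = ids))
}

## ---------------------------------------------------------------- mask I/O

#' Read / write a 16-bit label TIFF
#'
#' Masks are exchanged as single-channel 16-bit TIFFs whose integer pixel
#' values are the object labels ("instance masks with increasing gray
#' intensities by objects").
#'
#' @param path file path.
#' @param pixel_size_um pixel size to attach on reading (µm).
#' @return `readLabelMaskTIFF`: a [LabelMask-class].
#' @export
readLabelMaskTIFF <- function(path, pixel_size_um) {
  v <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  LabelMask(matrix(as.integer(round(v)), nrow(v), ncol(v)), pixel_size_um)
}

#' @rdname readLabelMaskTIFF
#' @param mask a [LabelMask-class] with labels below 2^16.
#' @export
writeLabelMaskTIFF <- function(mask, path) {
  lab <- maskLabels(mask)
  if (max(lab) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname readLabelMaskTIFF
#' @param image numeric intensity matrix; values are scaled to the 16-bit
#'   range by `max_value`.
#' @param max_value full-scale intensity (defaults to the image maximum).
#' @export
writeImageTIFF <- function(image, path, max_value = max(image)) {
  if (max_value <= 0) max_value <- 1
  tiff::writeTIFF(pmin(pmax(image / max_value, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname readLabelMaskTIFF
#' @export
readImageTIFF <- function(path, max_value = 65535) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  v * max_value
}
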