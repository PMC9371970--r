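## Laser-microdissection planning: polygonization of mask objects, outward
## cutting offsets, cut-path ordering, fiducial-based stage registration and
## the throughput/recovery arithmetic of automated collection.

#' Polygonize mask objects into cut contours
#'
#' One outer contour per object (interior holes are discarded: the laser
#' cuts outer boundaries only), vertices in µm under the pixel-centre
#' convention, counter-clockwise orientation enforced (positive shoelace
#' area in the image frame). Objects whose boundary degenerates to fewer
#' than 3 distinct vertices are skipped with a warning.
#'
#' @param mask a [LabelMask-class].
#' @param class_labels optional vector/named vector assigning a class to
#'   each object id.
#' @return list of contours: `list(objectId, vertices, classLabel)` with
#'   `vertices` an n x 2 µm matrix (columns x, y).
#' @export
maskToContours <- function(mask, class_labels = NULL) {
  stopifnot(is(mask, "LabelMask"))
  lab <- maskLabels(mask)
  px <- pixelSize(mask)
  obj <- maskToObjects(mask)
  out <- vector("list", nrow(obj))
  kept <- logical(nrow(obj))
  for (i in seq_len(nrow(obj))) {
    r0 <- obj$row_min[i]; c0 <- obj$col_min[i]
    bin <- (lab[r0:obj$row_max[i], c0:obj$col_max[i], drop = FALSE] ==
              obj$label[i]) * 1
    rings <- binaryRings(bin, px, row_off = r0 - 1L, col_off = c0 - 1L)
    if (!length(rings)) next
    outer <- rings[[which.max(vapply(rings, function(v) abs(signedArea(v)),
                                     numeric(1)))]]
    outer <- outer[!duplicated(round(outer, 9)), , drop = FALSE]
    if (nrow(outer) < 3L) {
      warning("object ", obj$label[i], " has a degenerate boundary; skipped")
      next
    }
    if (signedArea(outer) < 0)
      outer <- outer[rev(seq_len(nrow(outer))), , drop = FALSE]
    cl <- if (is.null(class_labels)) NA_integer_
      else if (!is.null(names(class_labels)))
        class_labels[[as.character(obj$label[i])]]
      else class_labels[[obj$label[i]]]
    out[[i]] <- list(objectId = obj$label[i], vertices = outer,
                     classLabel = cl)
    kept[i] <- TRUE
  }
  out[kept]
}

#' Outward cutting offset of a contour
#'
#' Buffers the polygon outward by `offset_um` (Minkowski sum with a disk,
#' round joins) so the laser path clears the cell membrane. The result
#' strictly contains the input; offset 0 returns the contour unchanged.
#'
#' @param contour a contour `list(objectId, vertices, classLabel)`.
#' @param offset_um outward offset in µm (>= 0).
#' @return the offset contour (same `objectId`/`classLabel`).
#' @export
offsetContour <- function(contour, offset_um) {
  if (offset_um < 0) stop("offset_um must be >= 0")
  if (offset_um == 0) return(contour)
  v <- contour$vertices
  res <- polyclip::polyoffset(list(list(x = v[, 1L], y = v[, 2L])),
                              delta = offset_um, jointype = "round",
                              arctol = offset_um * 0.005)
  areas <- vapply(res, function(p)
    abs(signedArea(cbind(p$x, p$y))), numeric(1))
  p <- res[[which.max(areas)]]
  out <- cbind(p$x, p$y)
  if (signedArea(out) < 0) out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  contour$vertices <- out
  contour
}

#' Contour centroid in µm
#' @param contour a contour list.
#' @return length-2 numeric (x, y).
#' @export
contourCentroid <- function(contour) ringCentroid(contour$vertices)

#' Order contours to minimize laser travel
#'
#' Minimizes the summed centroid-to-centroid transit distance of the open
#' path that starts at `start` and visits every contour once. Exact
#' (Held-Karp dynamic programming) for up to `exact_max` contours;
#' nearest-neighbour construction followed by 2-opt refinement beyond that.
#' Deterministic: ties are resolved toward the lower contour index.
#'
#' @param contours non-empty list of contours.
#' @param start length-2 stage start point (µm).
#' @param exact_max largest instance solved exactly (default 10).
#' @return list with `order` (indices into `contours`), `travel_um`.
#' @export
orderCuts <- function(contours, start = c(0, 0), exact_max = 10L) {
  n <- length(contours)
  if (!n) stop("no contours to order")
  cen <- t(vapply(contours, contourCentroid, numeric(2)))
  d0 <- sqrt((cen[, 1L] - start[1L])^2 + (cen[, 2L] - start[2L])^2)
  if (n == 1L) return(list(order = 1L, travel_um = d0))
  d <- as.matrix(stats::dist(cen))
  ord <- if (n <= exact_max) heldKarpPath(d0, d) else twoOptPath(d0, d)
  trav <- d0[ord[1L]] +
    sum(d[cbind(ord[-n], ord[-1L])])
  list(order = ord, travel_um = trav)
}

## Held-Karp DP over subsets for the open path; exact minimum travel.
heldKarpPath <- function(d0, d) {
  n <- length(d0)
  full <- bitwShiftL(1L, n) - 1L
  cost <- matrix(Inf, full, n)
  parent <- matrix(NA_integer_, full, n)
  for (j in seq_len(n)) cost[bitwShiftL(1L, j - 1L), j] <- d0[j]
  for (m in seq_len(full)) {
    for (j in seq_len(n)) {
      if (!bitwAnd(m, bitwShiftL(1L, j - 1L))) next
      cj <- cost[m, j]
      if (!is.finite(cj)) next
      for (k in seq_len(n)) {
        if (bitwAnd(m, bitwShiftL(1L, k - 1L))) next
        m2 <- bitwOr(m, bitwShiftL(1L, k - 1L))
        nc <- cj + d[j, k]
        if (nc < cost[m2, k] - 1e-12) {
          cost[m2, k] <- nc
          parent[m2, k] <- j
        }
      }
    }
  }
  j <- which.min(cost[full, ])
  ord <- integer(n); m <- full
  for (i in n:1) {
    ord[i] <- j
    pj <- parent[m, j]
    m <- bitwAnd(m, bitwNot(bitwShiftL(1L, j - 1L)))
    j <- pj
  }
  ord
}

## Nearest neighbour + 2-opt, deterministic scan order.
twoOptPath <- function(d0, d) {
  n <- length(d0)
  ord <- integer(n)
  visited <- logical(n)
  cur <- which.min(d0)
  ord[1L] <- cur; visited[cur] <- TRUE
  for (i in 2:n) {
    cand <- which(!visited)
    nxt <- cand[which.min(d[cur, cand])]
    ord[i] <- nxt; visited[nxt] <- TRUE; cur <- nxt
  }
  travel <- function(o) d0[o[1L]] + sum(d[cbind(o[-n], o[-1L])])
  best <- travel(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        cand <- ord
        cand[i:j] <- rev(cand[i:j])
        tc <- travel(cand)
        if (tc < best - 1e-12) {
          ord <- cand; best <- tc; improved <- TRUE
        }
      }
    }
  }
  ord
}

#' Fit the scan-to-stage affine transform from fiducial pairs
#'
#' Least-squares six-parameter affine fit mapping scan-microscope fiducial
#' coordinates onto LMD stage coordinates. Requires at least 3 non-collinear
#' pairs. The RMS per-point residual distance is retained so degraded
#' fiducials are visible.
#'
#' @param fiducials_scan,fiducials_stage n x 2 matrices of matched
#'   landmarks (µm), n >= 3.
#' @return an [AffineTransform-class].
#' @examples
#' s <- cbind(c(0, 100, 0), c(0, 0, 100))
#' registerCoordinates(s, s)
#' @export
registerCoordinates <- function(fiducials_scan, fiducials_stage) {
  s <- as.matrix(fiducials_scan); g <- as.matrix(fiducials_stage)
  stopifnot(ncol(s) == 2L, ncol(g) == 2L, nrow(s) == nrow(g))
  if (nrow(s) < 3L) stop("at least 3 fiducial pairs are required")
  cs <- scale(s, scale = FALSE)
  sv <- svd(cs)$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1e-12))
    stop("fiducials are collinear; affine fit is degenerate")
  D <- cbind(s, 1)
  coef <- qr.solve(D, g)            # 3 x 2
  A <- t(coef[1:2, , drop = FALSE])
  b <- as.numeric(coef[3L, ])
  fit <- D %*% coef
  rms <- sqrt(mean(rowSums((fit - g)^2)))
  new("AffineTransform", A = A, b = b, rmsResidualUm = rms)
}

#' Apply / invert an affine transform
#'
#' @param transform an [AffineTransform-class].
#' @param points n x 2 matrix of points (µm).
#' @return `applyTransform`: transformed n x 2 matrix.
#' @export
applyTransform <- function(transform, points) {
  p <- as.matrix(points)
  t(transform@A %*% t(p) + transform@b)
}

#' @rdname applyTransform
#' @return `invertTransform`: the inverse [AffineTransform-class].
#' @export
invertTransform <- function(transform) {
  Ai <- solve(transform@A)
  new("AffineTransform", A = Ai, b = as.numeric(-Ai %*% transform@b),
      rmsResidualUm = transform@rmsResidualUm)
}

#' Theoretical LMD cutting accuracy for an objective
#'
#' `10 / magnification` micrometres; 10/150 ~= 0.07 µm (70 nm) for a x150
#' objective.
#'
#' @param objective_magnification positive magnification factor.
#' @return accuracy in µm.
#' @export
theoreticalAccuracyUm <- function(objective_magnification) {
  stopifnot(objective_magnification > 0)
  10 / objective_magnification
}

#' Estimate the number of cells in a collected area
#'
#' `total area x section thickness / average cell volume`, the standard
#' recovery estimate for thin sections (default volume 2,000 µm³, the
#' average mammalian cell).
#'
#' @param total_area_um2 collected area, µm².
#' @param thickness_um section thickness, µm.
#' @param cell_volume_um3 average cell volume, µm³.
#' @return estimated cell count (real-valued).
#' @export
estimateCellCount <- function(total_area_um2, thickness_um,
                              cell_volume_um3 = 2000) {
  stopifnot(total_area_um2 >= 0, thickness_um > 0, cell_volume_um3 > 0)
  total_area_um2 * thickness_um / cell_volume_um3
}

#' Route contours to 384-well plate wells
#'
#' Builds a [CutPlan-class]: applies the cutting offset, keeps the supplied
#' contour order (use [orderCuts()] first), and assigns wells either by
#' class (`per_class_well`, a named map class -> well id so each
#' sample/class lands in one well) or by chunking consecutive contours into
#' wells of `objects_per_well`. Per-well object counts and summed areas are
#' reported so samples can be normalized by collected object count or by
#' area; estimated cell recovery uses [estimateCellCount()].
#'
#' @param contours ordered list of contours (with `classLabel` set when
#'   routing by class).
#' @param per_class_well named character vector, e.g.
#'   `c("1" = "A1", "2" = "A2")`.
#' @param objects_per_well alternative routing: chunk size; wells are
#'   assigned `A1, A2, ...` in plate row-major order.
#' @param offset_um outward cutting offset applied to every contour
#'   (default 1 µm).
#' @param start stage start point for the travel bookkeeping.
#' @param thickness_um,cell_volume_um3 recovery-estimate parameters.
#' @return a [CutPlan-class]; empty input yields an empty plan.
#' @export
assignWells <- function(contours, per_class_well = NULL,
                        objects_per_well = NULL, offset_um = 1,
                        start = c(0, 0), thickness_um = 2.5,
                        cell_volume_um3 = 2000) {
  if (!length(contours))
    return(new("CutPlan", contours = list(), wells = character(),
               offsetUm = offset_um, totalTravelUm = 0,
               startPoint = as.numeric(start),
               wellSummary = data.frame(well = character(),
                                        n_objects = integer(),
                                        total_area_um2 = numeric(),
                                        estimated_cells = numeric())))
  if (is.null(per_class_well) == is.null(objects_per_well))
    stop("specify exactly one of per_class_well or objects_per_well")
  off <- lapply(contours, offsetContour, offset_um = offset_um)
  if (!is.null(per_class_well)) {
    cls <- vapply(off, function(cc) as.character(cc$classLabel), character(1))
    unknown <- setdiff(unique(cls), names(per_class_well))
    if (length(unknown))
      stop("no well assigned for class(es): ", paste(unknown, collapse = ", "))
    wells <- unname(per_class_well[cls])
  } else {
    stopifnot(objects_per_well >= 1)
    idx <- ceiling(seq_along(off) / objects_per_well)
    if (max(idx) > length(.WELL_IDS)) stop("plan exceeds 384 wells")
    wells <- .WELL_IDS[idx]
  }
  cen <- t(vapply(off, contourCentroid, numeric(2)))
  steps <- rbind(as.numeric(start), cen)
  travel <- sum(sqrt(rowSums(diff(steps)^2)))
  areas <- vapply(off, function(cc) abs(signedArea(cc$vertices)), numeric(1))
  agg <- stats::aggregate(
    data.frame(n_objects = 1L, total_area_um2 = areas),
    by = list(well = wells), FUN = sum)
  agg <- agg[order(match(agg$well, .WELL_IDS)), , drop = FALSE]
  agg$estimated_cells <- estimateCellCount(agg$total_area_um2, thickness_um,
                                           cell_volume_um3)
  rownames(agg) <- NULL
  new("CutPlan", contours = off, wells = wells, offsetUm = offset_um,
      totalTravelUm = travel, startPoint = as.numeric(start),
      wellSummary = agg)
}
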