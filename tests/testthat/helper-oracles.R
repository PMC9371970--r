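## Independent oracles, deliberately naive: exhaustive enumeration and
## direct summation, sharing no code with the implementation paths they
## check.

## Maximum number of one-to-one (pred, gt) matches among eligible pairs,
## by exhaustive recursion over all assignments.
oracleMaxMatching <- function(pairs) {
  if (!nrow(pairs)) return(0L)
  preds <- unique(pairs$pred_label)
  recur <- function(i, used_gt) {
    if (i > length(preds)) return(0L)
    best <- recur(i + 1L, used_gt)  # leave pred i unmatched
    cand <- pairs$gt_label[pairs$pred_label == preds[i]]
    for (g in setdiff(cand, used_gt))
      best <- max(best, 1L + recur(i + 1L, c(used_gt, g)))
    best
  }
  recur(1L, integer())
}

## Eligible pairs (IoU > t) recomputed from scratch off the raw matrices.
oracleEligiblePairs <- function(pred, gt, t) {
  p <- maskLabels(pred); g <- maskLabels(gt)
  out <- data.frame(pred_label = integer(), gt_label = integer())
  for (pl in setdiff(unique(as.vector(p)), 0L)) {
    for (gl in setdiff(unique(as.vector(g)), 0L)) {
      a <- which(p == pl); b <- which(g == gl)
      inter <- length(intersect(a, b))
      if (inter / (length(a) + length(b) - inter) > t)
        out <- rbind(out, data.frame(pred_label = pl, gt_label = gl))
    }
  }
  out
}

## Random small label-mask pair on a shared grid: a few rectangles each,
## overlapping by construction.
randomMaskPair <- function(seed, side = 24L, max_obj = 6L) {
  set.seed(seed)
  mk <- function() {
    m <- matrix(0L, side, side)
    n <- sample.int(max_obj, 1L)
    for (l in seq_len(n)) {
      r <- sort(sample.int(side, 2L)); cc <- sort(sample.int(side, 2L))
      m[r[1L]:r[2L], cc[1L]:cc[2L]] <- l
    }
    m
  }
  list(pred = LabelMask(mk(), 1), gt = LabelMask(mk(), 1))
}

## All permutations of a small vector.
permuteIndices <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in permuteIndices(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

## Open-path travel for a given visiting order.
pathTravel <- function(cen, ord, start) {
  pts <- rbind(start, cen[ord, , drop = FALSE])
  sum(sqrt(rowSums(diff(pts)^2)))
}

## One-sided hypergeometric tail by direct summation of point masses.
oracleHyperTail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

## Shoelace area, written independently of the package internals.
oracleArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## Square contour (axis-aligned) as a package-style contour object.
squareContour <- function(side = 1, origin = c(0, 0), id = 1L) {
  v <- rbind(origin,
             origin + c(side, 0),
             origin + c(side, side),
             origin + c(0, side))
  list(objectId = id, vertices = v, classLabel = NA_integer_)
}

## Random star-shaped simple polygon around a centre. Angles are spread
## over the full circle (positive increments normalized to 2*pi) so the
## centre is interior and the polygon is guaranteed simple.
randomStarPolygon <- function(seed, id = 1L) {
  set.seed(seed)
  nv <- sample(5:12, 1L)
  gaps <- stats::runif(nv, 0.2, 1)
  ang <- 2 * pi * cumsum(gaps) / sum(gaps)
  rad <- stats::runif(nv, 2, 6)
  ctr <- stats::runif(2, -20, 20)
  v <- cbind(ctr[1] + rad * cos(ang), ctr[2] + rad * sin(ang))
  list(objectId = id, vertices = v, classLabel = NA_integer_)
}

## Containment with a small boundary tolerance: inside, or within tol of
## the boundary.
containsWithTol <- function(pts, ring, tol = 1e-6) {
  inside <- LMDomics:::pointInRing(pts, ring)
  if (all(inside)) return(TRUE)
  d <- LMDomics:::distToRing(pts[!inside, , drop = FALSE], ring)
  all(d < tol)
}
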