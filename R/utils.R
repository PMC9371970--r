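## Internal helpers shared across modules.

#' Evaluate code under a fixed RNG state, restoring the caller's state
#'
#' All stochastic operations in the package route their `seed` argument
#' through this helper so that a fixed seed gives byte-identical output
#' without disturbing the global RNG stream.
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Shoelace signed area of a polygon ring (open representation, first != last)
#' @noRd
signedArea <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) / 2
}

#' Polygon perimeter of a closed ring given in open representation
#' @noRd
ringPerimeter <- function(v) {
  d <- v - rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  sum(sqrt(rowSums(d^2)))
}

#' Area centroid of a simple polygon (shoelace centroid)
#' @noRd
ringCentroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Circular moving-average smoothing of a polygon ring
#'
#' Window is `2*w + 1` vertices. Used to de-stair the marching-squares
#' boundary before measuring perimeter; `w = 0` is the identity.
#' @noRd
smoothRing <- function(v, w = 1L) {
  n <- nrow(v)
  if (w < 1L || n < 2L * w + 2L) return(v)
  ext <- rbind(v[(n - w + 1L):n, , drop = FALSE], v, v[1L:w, , drop = FALSE])
  sm <- stats::filter(ext, rep(1 / (2 * w + 1), 2 * w + 1), sides = 2)
  matrix(sm[(w + 1L):(w + n), ], ncol = 2L)
}

#' Marching-squares boundary rings of a binary matrix
#'
#' Returns sub-pixel contour rings in physical micrometres using the
#' pixel-centre convention: pixel (row r, col c), 1-based, has its centre at
#' ((c - 0.5) * px, (r - 0.5) * px) with x rightward and y downward.
#' @noRd
binaryRings <- function(bin, pixel_size_um, row_off = 0L, col_off = 0L) {
  nr <- nrow(bin); nc <- ncol(bin)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2L:(nr + 1L), 2L:(nc + 1L)] <- bin
  xs <- (seq_len(nc + 2L) - 1.5 + col_off) * pixel_size_um
  ys <- (seq_len(nr + 2L) - 1.5 + row_off) * pixel_size_um
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(pad), levels = 0.5)
  lapply(cl, function(ring) cbind(ring$x, ring$y))
}

#' Distance from points to a polygon boundary (segment distance)
#' @noRd
distToRing <- function(pts, ring) {
  a <- ring
  b <- rbind(ring[-1L, , drop = FALSE], ring[1L, , drop = FALSE])
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), .Machine$double.eps)
  apply(pts, 1L, function(p) {
    t <- pmin(pmax(((p[1L] - a[, 1L]) * ab[, 1L] +
                    (p[2L] - a[, 2L]) * ab[, 2L]) / len2, 0), 1)
    min(sqrt((a[, 1L] + t * ab[, 1L] - p[1L])^2 +
             (a[, 2L] + t * ab[, 2L] - p[2L])^2))
  })
}

#' Even-odd point-in-polygon test
#' @noRd
pointInRing <- function(pts, ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  apply(pts, 1L, function(p) {
    crosses <- ((y > p[2L]) != (yn > p[2L])) &
      (p[1L] < (xn - x) * (p[2L] - y) / (yn - y) + x)
    sum(crosses) %% 2L == 1L
  })
}

#' Round half away from zero is NOT used; the XML dialect rounds half up.
#' floor(x + 0.5): 0.5 -> 1, -0.5 -> 0, 2.5 -> 3.
#' @noRd
roundHalfUp <- function(x) floor(x + 0.5)
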