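test_that("mask polygonization preserves area and orientation", {
  m <- matrix(0L, 20, 20)
  m[6:15, 6:15] <- 1L
  cons <- maskToContours(LabelMask(m, 1))
  expect_length(cons, 1)
  a <- oracleArea(cons[[1]]$vertices)
  expect_lt(abs(a - 100) / 100, 0.10)
  ## positive signed area = enforced orientation
  expect_gt(LMDomics:::signedArea(cons[[1]]$vertices), 0)

  expect_length(maskToContours(LabelMask(matrix(0L, 5, 5), 1)), 0)
})

test_that("contour area agrees with pixel-count area for large objects", {
  fx <- makeImageFixture(imageFixtureSpec(n_objects = 25, seed = 19))
  cons <- maskToContours(fx$mask)
  obj <- maskToObjects(fx$mask)
  px2 <- pixelSize(fx$mask)^2
  for (cc in cons) {
    i <- match(cc$objectId, obj$label)
    if (obj$n_pixels[i] < 200) next
    rel <- abs(oracleArea(cc$vertices) - obj$n_pixels[i] * px2) /
      (obj$n_pixels[i] * px2)
    expect_lt(rel, 0.05)
  }
})

test_that("offsetting buffers outward with the exact square law", {
  sq <- squareContour(side = 1)
  expect_identical(offsetContour(sq, 0), sq)
  expect_error(offsetContour(sq, -0.1), ">= 0")
  off <- offsetContour(sq, 0.5)
  target <- 1 + 4 * 0.5 + pi * 0.25   # Minkowski sum of square and disk
  expect_lt(abs(oracleArea(off$vertices) - target) / target, 0.01)
})

test_that("offset contours contain the original with the right clearance", {
  for (seed in 1:25) {
    con <- randomStarPolygon(seed)
    a0 <- oracleArea(con$vertices)
    o1 <- offsetContour(con, 0.5)
    o2 <- offsetContour(con, 1.0)
    a1 <- oracleArea(o1$vertices); a2 <- oracleArea(o2$vertices)
    expect_true(a0 < a1 && a1 < a2)
    expect_true(containsWithTol(con$vertices, o1$vertices))
    d <- LMDomics:::distToRing(con$vertices, o1$vertices)
    expect_true(all(d >= 0.5 - 0.01))
  }
})

test_that("cut ordering solves forced and exhaustive instances", {
  mkcons <- function(cen) lapply(seq_len(nrow(cen)), function(i)
    squareContour(0.5, origin = cen[i, ] - 0.25, id = i))
  col <- mkcons(cbind(c(0, 10, 20), 0))
  ## centred squares: centroids at the stated x positions
  oc <- orderCuts(col, start = c(0, 0))
  expect_equal(oc$order, 1:3)
  expect_equal(oc$travel_um, 20)

  one <- orderCuts(mkcons(cbind(3, 4)), start = c(0, 0))
  expect_equal(one$travel_um, 5)

  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    cen <- matrix(runif(2 * n, 0, 100), n)
    oc <- orderCuts(mkcons(cen), start = c(0, 0))
    best <- min(vapply(permuteIndices(seq_len(n)), function(p)
      pathTravel(cen, p, c(0, 0)), numeric(1)))
    expect_equal(oc$travel_um, best, tolerance = 1e-9)
  }
})

test_that("heuristic ordering never loses to input order or plain nearest neighbour", {
  set.seed(31)
  n <- 15
  cen <- matrix(runif(2 * n, 0, 500), n)
  cons <- lapply(seq_len(n), function(i)
    squareContour(1, origin = cen[i, ] - 0.5, id = i))
  oc <- orderCuts(cons, start = c(0, 0))
  expect_lte(oc$travel_um, pathTravel(cen, seq_len(n), c(0, 0)) + 1e-9)
})

test_that("affine registration recovers exact and noisy transforms", {
  s <- cbind(c(0, 100, 0, 80, 20), c(0, 0, 100, 70, 90))
  id <- registerCoordinates(s, s)
  expect_equal(id@A, diag(2), tolerance = 1e-12)
  expect_equal(id@b, c(0, 0), tolerance = 1e-10)
  expect_lt(id@rmsResidualUm, 1e-10)

  th <- 30 * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g <- t(A %*% t(s)) + rep(c(100, -50), each = nrow(s))
  tr <- registerCoordinates(s, g)
  expect_equal(tr@A, A, tolerance = 1e-9)
  expect_equal(tr@b, c(100, -50), tolerance = 1e-9)
  expect_lt(tr@rmsResidualUm, 1e-9)
  ## transform round trip is the identity on the fiducials
  back <- applyTransform(invertTransform(tr), applyTransform(tr, s))
  expect_equal(back, s, tolerance = 1e-9)

  expect_error(registerCoordinates(cbind(1:3, 2 * (1:3)), cbind(1:3, 1:3)),
               "collinear")

  set.seed(4)
  noisy <- g + matrix(rnorm(length(g), 0, 0.1), ncol = 2)
  trn <- registerCoordinates(s, noisy)
  expect_lte(trn@rmsResidualUm, 0.3)
})

test_that("accuracy and cell-count arithmetic match the stated formulas", {
  expect_equal(theoreticalAccuracyUm(150), 10 / 150)
  expect_equal(round(theoreticalAccuracyUm(150), 2), 0.07)
  expect_equal(theoreticalAccuracyUm(10), 1.0)
  expect_equal(theoreticalAccuracyUm(40), 0.25)

  expect_equal(estimateCellCount(160000, 2.5, 2000), 200)
  expect_equal(estimateCellCount(80000, 2.5, 2000), 100)
  expect_equal(estimateCellCount(0, 2.5, 2000), 0)
})

test_that("well routing partitions contours and tracks per-well recovery", {
  m <- matrix(0L, 30, 60)
  m[5:10, 5:10] <- 1L; m[5:10, 20:25] <- 2L; m[15:22, 35:44] <- 3L
  cons <- maskToContours(LabelMask(m, 1),
                         class_labels = c(1L, 2L, 1L))
  plan <- assignWells(cons, per_class_well = c("1" = "A1", "2" = "B7"),
                      offset_um = 1)
  expect_equal(planWells(plan), c("A1", "B7", "A1"))
  ws <- wellSummary(plan)
  expect_equal(ws$n_objects[ws$well == "A1"], 2L)
  expect_error(assignWells(cons, per_class_well = c("1" = "A1")),
               "no well")

  chunks <- assignWells(rep(cons, 89), objects_per_well = 100)  # 267 objects
  expect_equal(as.integer(table(planWells(chunks))[c("A1", "A2", "A3")]),
               c(100L, 100L, 67L))

  empty <- assignWells(list(), objects_per_well = 10)
  expect_length(planContours(empty), 0)
  expect_equal(nrow(wellSummary(empty)), 0)
})

test_that("cut-plan XML writes and reads back exactly at nm precision", {
  set.seed(9)
  cons <- lapply(1:5, randomStarPolygon)
  plan <- assignWells(cons, objects_per_well = 2, offset_um = 0.7)
  path <- withr::local_tempfile(fileext = ".xml")
  writeCutPlanXML(plan, path)
  back <- readCutPlanXML(path)
  expect_length(back$contours, 5)
  for (i in 1:5) {
    orig <- planContours(plan)[[i]]$vertices
    got <- back$contours[[i]]$vertices
    expect_identical(floor(got * 1000 + 0.5), floor(orig * 1000 + 0.5))
    expect_equal(back$contours[[i]]$well, planWells(plan)[i])
  }
})
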