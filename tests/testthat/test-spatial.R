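## A one-square-cell geometry file in the package's contour dialect.
writeSquareXML <- function(path, origin = c(10, 20), side = 4) {
  plan <- assignWells(list(squareContour(side, origin)),
                      objects_per_well = 1, offset_um = 0)
  writeCutPlanXML(plan, path)
}

test_that("geometry XML parses to centroids and aggregates across classes", {
  dir <- withr::local_tempdir()
  writeSquareXML(file.path(dir, "c1.xml"), origin = c(10, 20), side = 4)
  cells <- readGeometryXML(file.path(dir, "c1.xml"), classes = "A")
  expect_equal(nrow(cells), 1)
  expect_equal(cells$centroid_x_um, 12)
  expect_equal(cells$centroid_y_um, 22)

  ## two files, ten cells each -> twenty rows, both classes, unique ids
  mk10 <- function(path) {
    cons <- lapply(1:10, function(i) squareContour(2, c(5 * i, 0), id = i))
    writeCutPlanXML(assignWells(cons, objects_per_well = 10, offset_um = 0),
                    path)
  }
  mk10(file.path(dir, "a.xml")); mk10(file.path(dir, "b.xml"))
  both <- readGeometryXML(file.path(dir, c("a.xml", "b.xml")),
                          classes = c("1", "2"))
  expect_equal(nrow(both), 20)
  expect_equal(as.integer(table(both$class_label)), c(10L, 10L))
  expect_false(any(duplicated(both$cell_id)))
})

test_that("the generic polygon XML dialect is accepted", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<Cells>",
               "<Cell id='1' class='x'>",
               "<Point x='0' y='0'/><Point x='2' y='0'/><Point x='2' y='2'/><Point x='0' y='2'/>",
               "</Cell>", "</Cells>"), path)
  cells <- readGeometryXML(path, classes = "x")
  expect_equal(cells$centroid_x_um, 1)
  expect_equal(cells$centroid_y_um, 1)
})

test_that("plan geometry survives the write-read round trip exactly", {
  set.seed(41)
  cons <- lapply(1:6, randomStarPolygon)
  plan <- assignWells(cons, objects_per_well = 3, offset_um = 1.2)
  path <- withr::local_tempfile(fileext = ".xml")
  writeCutPlanXML(plan, path)
  cells <- readGeometryXML(path, classes = "c1")
  expect_equal(nrow(cells), 6)
  for (i in 1:6)
    expect_identical(floor(cells$vertices[[i]] * 1000 + 0.5),
                     floor(planContours(plan)[[i]]$vertices * 1000 + 0.5))
})

test_that("pathway scores are medians per term, z-scored across classes", {
  cm <- matrix(rep(c(1, 2, 4), each = 4), 4, 3,
               dimnames = list(paste0("P", 1:4), c("c1", "c2", "c3")))
  ## single-protein term: score is that protein's level, z-scored
  sc <- classPathwayScores(cm, list(solo = "P2"))
  expect_equal(as.numeric(sc), as.numeric(scale(c(1, 2, 4))))

  ## identical levels across classes: all zeros
  flat <- matrix(5, 3, 4, dimnames = list(paste0("P", 1:3), paste0("c", 1:4)))
  expect_true(all(classPathwayScores(flat, list(t = paste0("P", 1:3))) == 0))

  ## planted-high class carries the maximal z-score
  set.seed(2)
  cm2 <- matrix(rnorm(40, 25, 0.3), 10, 4,
                dimnames = list(paste0("P", 1:10), paste0("c", 1:4)))
  cm2[1:4, "c3"] <- cm2[1:4, "c3"] + 5
  sc2 <- classPathwayScores(cm2, list(up = paste0("P", 1:4)))
  expect_equal(colnames(sc2)[which.max(sc2)], "c3")

  ## per-term z-scores have mean 0 and sd 1 across classes
  expect_equal(mean(sc2), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(sc2)), 1, tolerance = 1e-12)

  ## invariant to proteins outside all terms and to protein order
  cm3 <- rbind(cm2, matrix(rnorm(8, 25), 2, 4,
                           dimnames = list(c("X1", "X2"), colnames(cm2))))
  expect_equal(classPathwayScores(cm3, list(up = paste0("P", 1:4))), sc2)
  expect_equal(classPathwayScores(cm2[sample(1:10), ],
                                  list(up = paste0("P", 1:4))), sc2)

  ## unquantified term -> missing scores
  expect_true(all(is.na(classPathwayScores(cm2, list(gone = "ZZ")))))
})

test_that("the tissue heat map table carries scores to the right cells", {
  dir <- withr::local_tempdir()
  ## two spatially separated classes
  left <- lapply(1:5, function(i) squareContour(2, c(0, 10 * i), id = i))
  right <- lapply(1:5, function(i) squareContour(2, c(500, 10 * i), id = i))
  writeCutPlanXML(assignWells(left, objects_per_well = 5, offset_um = 0),
                  file.path(dir, "l.xml"))
  writeCutPlanXML(assignWells(right, objects_per_well = 5, offset_um = 0),
                  file.path(dir, "r.xml"))
  cells <- readGeometryXML(file.path(dir, c("l.xml", "r.xml")),
                           classes = c("L", "R"))
  scores <- matrix(c(-1, 1), 1, 2, dimnames = list("term1", c("L", "R")))
  ov <- buildSpatialOverlay(cells, scores)
  res <- renderTissueHeatmap(ov, "term1")
  expect_s3_class(res$plot, "ggplot")
  expect_true(all(res$table$score[res$table$x < 100] == -1))
  expect_true(all(res$table$score[res$table$x > 100] == 1))

  ## all-zero scores give an all-zero table
  z0 <- matrix(c(0, 0), 1, 2, dimnames = list("term1", c("L", "R")))
  expect_true(all(renderTissueHeatmap(buildSpatialOverlay(cells, z0),
                                      "term1")$table$score == 0))

  ## a class without a score is reported and drawn as missing
  partial <- matrix(1, 1, 1, dimnames = list("term1", "L"))
  ovp <- buildSpatialOverlay(cells, partial)
  expect_message(resp <- renderTissueHeatmap(ovp, "term1"), "no score")
  expect_true(all(is.na(resp$table$score[resp$table$class_label == "R"])))

  expect_error(renderTissueHeatmap(ov, "nope"), "unknown term")
})
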