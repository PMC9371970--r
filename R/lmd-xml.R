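## LMD contour XML exchange. The dialect is documented and bit-exact:
##   <ImageData>
##     <Calibration_1><X>...</X><Y>...</Y></Calibration_1>  (three points,
##     integer nanometres)
##     <ShapeCount>n</ShapeCount>
##     <Shape_1>
##       <PointCount>m</PointCount>
##       <CapID>A1</CapID>            (384-well collection well)
##       <X_1>...</X_1><Y_1>...</Y_1> ... vertex coordinates, integer
##       nanometres (um x 1000, rounded half-up)
##     </Shape_1> ...
##   </ImageData>
## Vendor schemas are proprietary; this dialect is the package's own, and
## the reader accepts it exactly, so write -> read is the identity at nm
## precision.

#' Write a cut plan to contour XML
#'
#' @param plan a [CutPlan-class].
#' @param path output file.
#' @param calibration 3 x 2 matrix of stage calibration points in µm
#'   (defaults to three corners of the plan's bounding box).
#' @return `path`, invisibly.
#' @export
writeCutPlanXML <- function(plan, path, calibration = NULL) {
  stopifnot(is(plan, "CutPlan"))
  contours <- planContours(plan)
  wells <- planWells(plan)
  if (is.null(calibration)) {
    if (length(contours)) {
      allv <- do.call(rbind, lapply(contours, `[[`, "vertices"))
      calibration <- rbind(c(min(allv[, 1]), min(allv[, 2])),
                           c(max(allv[, 1]), min(allv[, 2])),
                           c(min(allv[, 1]), max(allv[, 2])))
    } else calibration <- rbind(c(0, 0), c(1000, 0), c(0, 1000))
  }
  calibration <- as.matrix(calibration)
  stopifnot(nrow(calibration) == 3L, ncol(calibration) == 2L)
  nm <- function(um) format(roundHalfUp(um * 1000), scientific = FALSE,
                            trim = TRUE)
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<ImageData>")
  for (i in 1:3)
    lines <- c(lines, sprintf("  <Calibration_%d><X>%s</X><Y>%s</Y></Calibration_%d>",
                              i, nm(calibration[i, 1L]), nm(calibration[i, 2L]), i))
  lines <- c(lines, sprintf("  <ShapeCount>%d</ShapeCount>", length(contours)))
  for (i in seq_along(contours)) {
    v <- contours[[i]]$vertices
    body <- paste0(sprintf("    <X_%d>%s</X_%d><Y_%d>%s</Y_%d>",
                           seq_len(nrow(v)), nm(v[, 1L]), seq_len(nrow(v)),
                           seq_len(nrow(v)), nm(v[, 2L]), seq_len(nrow(v))),
                   collapse = "\n")
    lines <- c(lines,
               sprintf("  <Shape_%d>", i),
               sprintf("    <PointCount>%d</PointCount>", nrow(v)),
               sprintf("    <CapID>%s</CapID>", wells[i]),
               body,
               sprintf("  </Shape_%d>", i))
  }
  lines <- c(lines, "</ImageData>")
  writeLines(lines, path)
  invisible(path)
}

#' Read contour XML back into a geometry table
#'
#' Parses the package's contour-XML dialect (see [writeCutPlanXML()]).
#' Coordinates are integer nanometres in the file and returned in µm.
#'
#' @param path XML file.
#' @return list with `calibration` (3 x 2 µm matrix) and `contours` (list of
#'   `list(objectId, vertices, classLabel, well)`); `objectId` is the shape
#'   index within the file.
#' @export
readCutPlanXML <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "ImageData") stop("not a contour XML file")
  getnum <- function(node, name)
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, name)))
  calibration <- t(vapply(1:3, function(i) {
    node <- xml2::xml_find_first(doc, sprintf("./Calibration_%d", i))
    if (inherits(node, "xml_missing")) stop("missing Calibration_", i)
    c(getnum(node, "./X"), getnum(node, "./Y")) / 1000
  }, numeric(2)))
  n <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./ShapeCount")))
  if (is.na(n)) stop("missing ShapeCount")
  contours <- lapply(seq_len(n), function(i) {
    node <- xml2::xml_find_first(doc, sprintf("./Shape_%d", i))
    if (inherits(node, "xml_missing")) stop("missing Shape_", i)
    m <- as.integer(xml2::xml_text(xml2::xml_find_first(node, "./PointCount")))
    well <- xml2::xml_text(xml2::xml_find_first(node, "./CapID"))
    xs <- vapply(seq_len(m), function(j) getnum(node, sprintf("./X_%d", j)),
                 numeric(1))
    ys <- vapply(seq_len(m), function(j) getnum(node, sprintf("./Y_%d", j)),
                 numeric(1))
    list(objectId = i, vertices = matrix(c(xs, ys), ncol = 2L) / 1000,
         classLabel = NA_integer_, well = well)
  })
  list(calibration = calibration, contours = contours)
}
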