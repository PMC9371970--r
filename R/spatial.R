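## Spatial re-integration: parse per-class cell-geometry XML exports,
## attach per-class pathway scores (median protein level per annotation,
## z-scored across classes) and render the tissue heat map — proteomics
## painted back onto the image at the excised cells' centroids.

#' Read per-class cell geometry XML files into one table
#'
#' Accepts the package's contour-XML dialect (see [writeCutPlanXML()]) or a
#' minimal generic polygon XML (`<Cells><Cell id=.. class=..><Point x=..
#' y=../>...</Cell></Cells>`, coordinates in µm). One row per cell with its
#' class, centroid and polygon; cells from all files are aggregated into a
#' single data frame, with ids compounded as `<class>_<id>` so duplicate
#' ids across class files stay distinct.
#'
#' @param files character vector of XML paths.
#' @param classes class label per file (defaults to `1..length(files)`).
#' @return data.frame: `cell_id`, `class_label`, `centroid_x_um`,
#'   `centroid_y_um`, `n_vertices`, plus a `vertices` list-column of n x 2
#'   µm matrices.
#' @export
readGeometryXML <- function(files, classes = seq_along(files)) {
  stopifnot(length(files) == length(classes))
  rows <- list()
  for (i in seq_along(files)) {
    doc <- xml2::read_xml(files[i])
    polys <- if (xml2::xml_name(doc) == "ImageData") {
      lapply(readCutPlanXML(files[i])$contours, `[[`, "vertices")
    } else if (xml2::xml_name(doc) == "Cells") {
      lapply(xml2::xml_find_all(doc, "./Cell"), function(cell) {
        pts <- xml2::xml_find_all(cell, "./Point")
        cbind(as.numeric(xml2::xml_attr(pts, "x")),
              as.numeric(xml2::xml_attr(pts, "y")))
      })
    } else stop("unrecognized geometry XML root: ", xml2::xml_name(doc))
    if (!length(polys)) next
    cen <- t(vapply(polys, ringCentroid, numeric(2)))
    df <- data.frame(
      cell_id = sprintf("%s_%d", classes[i], seq_along(polys)),
      class_label = classes[i],
      centroid_x_um = cen[, 1L], centroid_y_um = cen[, 2L],
      n_vertices = vapply(polys, nrow, integer(1)))
    df$vertices <- polys
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows))
    return(data.frame(cell_id = character(), class_label = character(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      n_vertices = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-class pathway scores: median per annotation, z-scored across classes
#'
#' For each annotation term, the median level over its member proteins is
#' computed per class, then standardized across classes (`normalize =
#' "classes"`, the default) or against the moments of the whole
#' term-by-class score matrix (`"global"`). Terms with no quantified member
#' yield missing scores.
#'
#' @param class_matrix numeric matrix, proteins x classes (e.g. group means
#'   of an imputed [ProteinMatrix-class]).
#' @param terms named list: term -> member proteins.
#' @param normalize z-scoring reference: across classes per term, or global.
#' @return matrix terms x classes of scores (NA where a term has no
#'   quantified members).
#' @export
classPathwayScores <- function(class_matrix, terms,
                               normalize = c("classes", "global")) {
  normalize <- match.arg(normalize)
  cm <- as.matrix(class_matrix)
  med <- t(vapply(names(terms), function(tm) {
    members <- intersect(terms[[tm]], rownames(cm))
    if (!length(members)) return(rep(NA_real_, ncol(cm)))
    apply(cm[members, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(cm))))
  colnames(med) <- colnames(cm)
  if (normalize == "classes") {
    z <- t(apply(med, 1L, function(r) {
      if (anyNA(r)) return(r)
      s <- stats::sd(r)
      if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
    colnames(z) <- colnames(cm)
    z
  } else {
    ok <- !is.na(med)
    mu <- mean(med[ok]); s <- stats::sd(med[ok])
    if (is.na(s) || s == 0) (med - mu) * 0 else (med - mu) / s
  }
}

#' Build a spatial overlay of cells and pathway scores
#'
#' Joins a cell geometry table with a per-class score matrix: every cell of
#' a class carries that class's score (proteomes are measured per class,
#' not per cell). Classes without a score get NA.
#'
#' @param cells geometry table from [readGeometryXML()].
#' @param scores matrix terms x classes from [classPathwayScores()].
#' @return data.frame `cell_id`, `class_label`, `x`, `y`, one `score.<term>`
#'   column per term; of class `SpatialOverlay`.
#' @export
buildSpatialOverlay <- function(cells, scores) {
  out <- data.frame(cell_id = cells$cell_id,
                    class_label = cells$class_label,
                    x = cells$centroid_x_um, y = cells$centroid_y_um)
  for (tm in rownames(scores)) {
    col <- scores[tm, match(as.character(out$class_label),
                            colnames(scores))]
    out[[paste0("score.", tm)]] <- as.numeric(col)
  }
  class(out) <- c("SpatialOverlay", "data.frame")
  out
}

#' Render the tissue heat map for one annotation term
#'
#' Scatter of cell centroids coloured by the term's per-class z-score on a
#' symmetric diverging scale centred at 0; cells of classes without a score
#' are drawn in a neutral "no data" colour and reported. The y axis is
#' reversed to match image coordinates (origin top-left). Deterministic.
#'
#' @param overlay a `SpatialOverlay` from [buildSpatialOverlay()].
#' @param term annotation term to map (must have a score column).
#' @param point_size passed to the scatter layer.
#' @param file optional output path; the figure is written with
#'   [ggplot2::ggsave()].
#' @return list with `plot` (ggplot object) and `table` (data.frame
#'   `cell_id`, `x`, `y`, `class_label`, `score`), invisibly printable.
#' @export
renderTissueHeatmap <- function(overlay, term, point_size = 1.5,
                                file = NULL) {
  col <- paste0("score.", term)
  if (!col %in% names(overlay)) stop("unknown term: ", term)
  tab <- data.frame(cell_id = overlay$cell_id, x = overlay$x,
                    y = overlay$y, class_label = overlay$class_label,
                    score = overlay[[col]])
  missing_classes <- unique(tab$class_label[is.na(tab$score)])
  if (length(missing_classes))
    message("no score for class(es): ",
            paste(missing_classes, collapse = ", "),
            "; drawn in the 'no data' colour")
  lim <- max(abs(tab$score), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$score)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "#F7F7F7",
                                    high = "#B2182B", midpoint = 0,
                                    limits = c(-lim, lim),
                                    na.value = "grey70", name = "z") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = term, x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 5)
  list(plot = p, table = tab)
}
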