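#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## ---------------------------------------------------------------- LabelMask

#' LabelMask: an integer-labelled instance segmentation mask
#'
#' The unit of segmentation and evaluation. `0` is background; positive
#' integers identify objects. Labels need not be contiguous. The physical
#' pixel size (micrometres) travels with the mask so that all downstream
#' geometry is expressed in micrometres.
#'
#' Coordinate convention: pixel (row `r`, col `c`), 1-based, has its centre
#' at `((c - 0.5) * px, (r - 0.5) * px)` µm, with the origin at the image
#' top-left, x rightward and y downward.
#'
#' @slot labels integer matrix of object labels (0 = background).
#' @slot pixelSize positive numeric, pixel edge length in µm.
#'
#' @examples
#' m <- LabelMask(matrix(c(0L, 1L, 1L, 0L), 2, 2), pixelSize = 0.5)
#' nObjects(m)
#' @export
setClass("LabelMask",
  representation(labels = "matrix", pixelSize = "numeric"))

setValidity("LabelMask", function(object) {
  msg <- character()
  if (!is.numeric(object@labels))
    msg <- c(msg, "labels must be a numeric/integer matrix")
  else {
    if (anyNA(object@labels)) msg <- c(msg, "labels must not contain NA")
    else if (any(object@labels < 0)) msg <- c(msg, "labels must be >= 0")
    else if (any(object@labels != round(object@labels)))
      msg <- c(msg, "labels must be whole numbers")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMask
#'
#' @param labels integer matrix, 0 = background.
#' @param pixelSize pixel edge length in µm.
#' @return A [LabelMask-class] object.
#' @export
LabelMask <- function(labels, pixelSize) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, pixelSize = as.numeric(pixelSize))
}

#' @rdname LabelMask-class
#' @param object,x a `LabelMask`.
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname LabelMask-class
#' @export
setMethod("maskLabels", "LabelMask", function(x) x@labels)

#' @rdname LabelMask-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname LabelMask-class
#' @export
setMethod("pixelSize", "LabelMask", function(x) x@pixelSize)

#' @rdname LabelMask-class
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname LabelMask-class
#' @export
setMethod("nObjects", "LabelMask", function(x)
  length(setdiff(unique(as.vector(x@labels)), 0L)))

#' @rdname LabelMask-class
#' @export
setGeneric("objectIds", function(x) standardGeneric("objectIds"))

#' @rdname LabelMask-class
#' @export
setMethod("objectIds", "LabelMask", function(x)
  sort(setdiff(unique(as.vector(x@labels)), 0L)))

setMethod("show", "LabelMask", function(object) {
  cat("LabelMask:", nrow(object@labels), "x", ncol(object@labels),
      "px @", object@pixelSize, "um/px;",
      nObjects(object), "objects\n")
})

#' @rdname LabelMask-class
#' @export
setMethod("dim", "LabelMask", function(x) dim(x@labels))

## ------------------------------------------------------------ ProteinMatrix

#' ProteinMatrix: proteins x samples quantification with group labels
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] wrapper holding log2
#' protein intensities (assay `"log2intensity"`, `NA` = missing), a `group`
#' factor in `colData`, and the usual decoy/contaminant flags (`reverse`,
#' `contaminant`, `siteOnly`) in `rowData`, mirroring MaxQuant/DIA-NN-style
#' wide output tables.
#'
#' @examples
#' pm <- ProteinMatrix(matrix(rnorm(12, 25), 3,
#'                            dimnames = list(paste0("P", 1:3), paste0("s", 1:4))),
#'                     groups = rep(c("a", "b"), each = 2))
#' sampleGroups(pm)
#' @export
setClass("ProteinMatrix", contains = "SummarizedExperiment")

setValidity("ProteinMatrix", function(object) {
  msg <- character()
  if (!"log2intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2intensity' is required")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (anyNA(SummarizedExperiment::colData(object)$group))
    msg <- c(msg, "every sample needs a group label")
  if ("log2intensity" %in% SummarizedExperiment::assayNames(object)) {
    v <- SummarizedExperiment::assay(object, "log2intensity")
    if (any(is.infinite(v)))
      msg <- c(msg, "intensities must be finite where present (use NA for missing)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinMatrix
#'
#' @param values numeric matrix of log2 intensities, proteins x samples;
#'   `NA` marks missing values. Row and column names are used as protein and
#'   sample identifiers (defaults are generated when absent).
#' @param groups character/factor of length `ncol(values)`: group label per
#'   sample.
#' @param reverse,contaminant,siteOnly logical per-protein flags (decoy hits,
#'   contaminants, identified-by-site-only); recycled if length 1.
#' @return A [ProteinMatrix-class].
#' @export
ProteinMatrix <- function(values, groups, reverse = FALSE,
                          contaminant = FALSE, siteOnly = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("protein%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample%02d", seq_len(ncol(values)))
  stopifnot(length(groups) == ncol(values))
  rd <- S4Vectors::DataFrame(
    reverse = rep_len(as.logical(reverse), nrow(values)),
    contaminant = rep_len(as.logical(contaminant), nrow(values)),
    siteOnly = rep_len(as.logical(siteOnly), nrow(values)),
    row.names = rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2intensity = values),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(values)),
    rowData = rd)
  new("ProteinMatrix", se)
}

#' @rdname ProteinMatrix-class
#' @param x a `ProteinMatrix`.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname ProteinMatrix-class
#' @export
setMethod("intensities", "ProteinMatrix", function(x)
  SummarizedExperiment::assay(x, "log2intensity"))

#' @rdname ProteinMatrix-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ProteinMatrix-class
#' @export
setMethod("sampleGroups", "ProteinMatrix", function(x)
  as.character(SummarizedExperiment::colData(x)$group))

## --------------------------------------------------------- AffineTransform

#' AffineTransform: least-squares scan-to-stage coordinate mapping
#'
#' Six-parameter affine map `y = A x + b` between two microscope coordinate
#' systems (µm to µm), fitted to fiducial landmark pairs. The fit residual
#' is kept so bad fiducials are detectable.
#'
#' @slot A 2x2 numeric linear part (non-singular).
#' @slot b length-2 numeric translation (µm).
#' @slot rmsResidualUm root-mean-square per-point residual distance (µm).
#' @export
setClass("AffineTransform",
  representation(A = "matrix", b = "numeric", rmsResidualUm = "numeric"))

setValidity("AffineTransform", function(object) {
  msg <- character()
  if (!all(dim(object@A) == c(2L, 2L))) msg <- c(msg, "A must be 2x2")
  else if (abs(det(object@A)) < 1e-12) msg <- c(msg, "linear part is singular")
  if (length(object@b) != 2L) msg <- c(msg, "b must have length 2")
  if (object@rmsResidualUm < 0) msg <- c(msg, "rmsResidualUm must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (um -> um)\n  A:\n")
  print(round(object@A, 6))
  cat("  b:", round(object@b, 6), "\n  rms residual:",
      signif(object@rmsResidualUm, 4), "um\n")
})

## ----------------------------------------------------------------- CutPlan

#' CutPlan: an executable laser-microdissection collection plan
#'
#' Ordered, offset cut contours routed to 384-well plate wells, with travel
#' and per-well throughput/recovery bookkeeping.
#'
#' @slot contours list of contours (each `list(objectId, vertices, classLabel)`,
#'   vertices an n x 2 µm matrix, counter-clockwise) with the cutting offset
#'   already applied.
#' @slot wells character well id per contour, `A1`..`P24`.
#' @slot offsetUm the outward cutting offset that was applied (µm).
#' @slot totalTravelUm summed centroid-to-centroid transit distance under the
#'   stored order, from the stage start point (µm).
#' @slot startPoint length-2 numeric stage start (µm).
#' @slot wellSummary data.frame: well, n_objects, total_area_um2,
#'   estimated_cells (area x section thickness / cell volume).
#' @export
setClass("CutPlan",
  representation(contours = "list", wells = "character", offsetUm = "numeric",
                 totalTravelUm = "numeric", startPoint = "numeric",
                 wellSummary = "data.frame"))

.WELL_IDS <- paste0(rep(LETTERS[1:16], each = 24L), rep(1:24, 16L))

setValidity("CutPlan", function(object) {
  msg <- character()
  if (length(object@wells) != length(object@contours))
    msg <- c(msg, "one well id per contour required")
  bad <- setdiff(unique(object@wells), .WELL_IDS)
  if (length(bad))
    msg <- c(msg, paste("invalid 384-well ids:", paste(bad, collapse = ", ")))
  if (object@offsetUm < 0) msg <- c(msg, "offsetUm must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CutPlan", function(object) {
  cat("CutPlan:", length(object@contours), "contours ->",
      length(unique(object@wells)), "wells; offset",
      object@offsetUm, "um; travel",
      round(object@totalTravelUm, 1), "um\n")
})

#' @rdname CutPlan-class
#' @param x a `CutPlan`.
#' @export
setGeneric("planContours", function(x) standardGeneric("planContours"))

#' @rdname CutPlan-class
#' @export
setMethod("planContours", "CutPlan", function(x) x@contours)

#' @rdname CutPlan-class
#' @export
setGeneric("planWells", function(x) standardGeneric("planWells"))

#' @rdname CutPlan-class
#' @export
setMethod("planWells", "CutPlan", function(x) x@wells)

#' @rdname CutPlan-class
#' @export
setGeneric("wellSummary", function(x) standardGeneric("wellSummary"))

#' @rdname CutPlan-class
#' @export
setMethod("wellSummary", "CutPlan", function(x) x@wellSummary)

#' @rdname CutPlan-class
#' @export
setGeneric("totalTravelUm", function(x) standardGeneric("totalTravelUm"))

#' @rdname CutPlan-class
#' @export
setMethod("totalTravelUm", "CutPlan", function(x) x@totalTravelUm)
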