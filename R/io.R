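## Plain-text exchange formats: wide quantification tables with sample
## annotations, and GMT / two-column TSV term membership.

#' Read a wide protein quantification table plus sample annotation
#'
#' The matrix file is TSV or CSV (sniffed from the extension), first column
#' protein ids, remaining columns samples, in the style of MaxQuant /
#' DIA-NN wide output. The annotation file has columns `sample` and
#' `group`. Optional logical columns `reverse`, `contaminant`, `siteOnly`
#' in the matrix file are carried into the flags.
#'
#' @param matrix_path path to the quantification table.
#' @param annotation_path path to the sample annotation table.
#' @return a [ProteinMatrix-class] (zeros are kept; see [filterMatrix()]).
#' @export
readProteinMatrix <- function(matrix_path, annotation_path) {
  sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  asep <- if (grepl("\\.csv$", annotation_path, ignore.case = TRUE)) ","
    else "\t"
  ann <- utils::read.table(annotation_path, header = TRUE, sep = asep,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(ann)))
  flags <- intersect(c("reverse", "contaminant", "siteOnly"), names(tab))
  samples <- setdiff(names(tab)[-1L], flags)
  miss <- setdiff(samples, ann$sample)
  if (length(miss)) stop("samples without annotation: ",
                         paste(miss, collapse = ", "))
  v <- as.matrix(tab[samples])
  rownames(v) <- tab[[1L]]
  ProteinMatrix(v, groups = ann$group[match(samples, ann$sample)],
                reverse = if ("reverse" %in% flags) tab$reverse else FALSE,
                contaminant = if ("contaminant" %in% flags) tab$contaminant
                  else FALSE,
                siteOnly = if ("siteOnly" %in% flags) tab$siteOnly else FALSE)
}

#' Read term membership (GMT or two-column TSV)
#'
#' GMT: one term per line, `term<TAB>description<TAB>member...`. Two-column
#' TSV: header `term`, `protein`, one membership pair per row.
#'
#' @param path file path; format sniffed from the `.gmt` extension.
#' @return named list: term -> character vector of members.
#' @export
readGMT <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                    vapply(parts, `[[`, character(1), 1L))
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("term", "protein") %in% names(tab)))
    lapply(split(tab$protein, tab$term), unique)
  }
}
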