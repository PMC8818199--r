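#' MethProfileSet: per-sample normalized methylation profiles
#'
#' A \linkS4class{SummarizedExperiment} carrying ACTB-normalized qMSP
#' methylation ratios. Rows are the nine methylation markers (with their
#' multiplex in `rowData`), columns are samples. Two assays are kept in
#' step: `ratio`, the comparative-Ct methylation ratio (2^-dCt x 100,
#' `NA` where the measurement failed reference-gene QC), and `valid`, the
#' logical QC state. `colData` holds the per-multiplex ACTB Ct values
#' (`actb_A`, `actb_B`, `actb_C`) plus any clinical covariates attached at
#' construction.
#'
#' Validity enforces the QC contract: a ratio is present if and only if its
#' marker is valid, all markers of one multiplex share a validity state, and
#' ratios are non-negative.
#'
#' @aliases MethProfileSet
#' @export
setClass("MethProfileSet", contains = "SummarizedExperiment")

setValidity("MethProfileSet", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("ratio", "valid") %in% a)) {
    return("assays 'ratio' and 'valid' are required")
  }
  ratio <- SummarizedExperiment::assay(object, "ratio")
  valid <- SummarizedExperiment::assay(object, "valid")
  if (!is.logical(valid)) return("'valid' assay must be logical")
  if (!identical(sort(rownames(object)), sort(qmspMarkers()))) {
    return("rows must be the nine qMSP markers")
  }
  if (!"multiplex" %in% colnames(SummarizedExperiment::rowData(object))) {
    return("rowData must record the multiplex of each marker")
  }
  if (any(is.na(ratio) & valid) || any(!is.na(ratio) & !valid)) {
    return("ratio must be present iff the marker is valid")
  }
  if (any(ratio < 0, na.rm = TRUE)) return("ratios must be non-negative")
  mux <- SummarizedExperiment::rowData(object)$multiplex
  for (m in unique(mux)) {
    v <- valid[mux == m, , drop = FALSE]
    if (ncol(v) > 0 && any(apply(v, 2, function(z) length(unique(z)) > 1))) {
      return(sprintf("markers of multiplex %s disagree on validity", m))
    }
  }
  TRUE
})

#' Construct a MethProfileSet
#'
#' Usually produced by [buildProfiles()]; exposed for programmatic
#' construction (e.g. in tests).
#'
#' @param ratio numeric matrix, markers x samples; `NA` where invalid.
#' @param valid logical matrix of the same dimension.
#' @param actb numeric matrix (3 x samples, rows A/B/C) of ACTB Ct values,
#'   `NA` for undetected or absent multiplexes.
#' @param colData optional `DataFrame`/data.frame of sample covariates.
#' @return A [MethProfileSet-class] object.
#' @export
MethProfileSet <- function(ratio, valid, actb = NULL, colData = NULL) {
  markers <- qmspMarkers()
  ratio <- ratio[markers, , drop = FALSE]
  valid <- valid[markers, , drop = FALSE]
  rd <- S4Vectors::DataFrame(
    marker = markers,
    multiplex = vapply(markers, .multiplexOf, character(1)),
    row.names = markers
  )
  cd <- if (is.null(colData)) {
    S4Vectors::DataFrame(row.names = colnames(ratio))
  } else {
    S4Vectors::DataFrame(colData, row.names = colnames(ratio))
  }
  if (!is.null(actb)) {
    for (m in c("A", "B", "C")) {
      cd[[paste0("actb_", m)]] <- as.numeric(actb[m, ])
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = ratio, valid = valid),
    rowData = rd, colData = cd
  )
  methods::new("MethProfileSet", se)
}

#' @describeIn MethProfileSet-class matrix of methylation ratios
#'   (markers x samples, `NA` where invalid).
#' @param x,object a `MethProfileSet`.
#' @export
setGeneric("ratios", function(x) standardGeneric("ratios"))

#' @rdname MethProfileSet-class
#' @export
setMethod("ratios", "MethProfileSet", function(x) {
  SummarizedExperiment::assay(x, "ratio")
})

#' @describeIn MethProfileSet-class logical QC matrix (markers x samples).
#' @export
setGeneric("markerValid", function(x) standardGeneric("markerValid"))

#' @rdname MethProfileSet-class
#' @export
setMethod("markerValid", "MethProfileSet", function(x) {
  SummarizedExperiment::assay(x, "valid")
})

#' @describeIn MethProfileSet-class per-multiplex ACTB Ct values
#'   (3 x samples matrix with rows A, B, C).
#' @export
setGeneric("actbCt", function(x) standardGeneric("actbCt"))

#' @rdname MethProfileSet-class
#' @export
setMethod("actbCt", "MethProfileSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  out <- rbind(A = cd$actb_A, B = cd$actb_B, C = cd$actb_C)
  colnames(out) <- colnames(x)
  out
})

#' @rdname MethProfileSet-class
#' @export
setMethod("show", "MethProfileSet", function(object) {
  callNextMethod()
  flagged <- S4Vectors::metadata(object)$n_flagged
  if (!is.null(flagged)) {
    cat(sprintf(
      "QC: %d of %d samples with >=1 invalid multiplex (%.1f%%)\n",
      flagged, ncol(object), 100 * flagged / max(1L, ncol(object))
    ))
  }
})
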