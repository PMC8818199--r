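#' Read a long-format qMSP Ct table
#'
#' Reads raw quantification cycles exported per well, one row per
#' (sample, multiplex, target). Undetected wells are encoded as an empty
#' field or `NA`. Rows are validated against the fixed multiplex map:
#' unknown targets, target/multiplex mismatches and duplicate wells are hard
#' errors naming the offending row.
#'
#' @param path path to a delimited text file with header columns
#'   `sample_id`, `multiplex_id`, `target`, `ct`.
#' @param delimiter field delimiter, default comma.
#' @return A data.frame of Ct records with columns `sample_id`,
#'   `multiplex_id`, `target`, `ct` (`NA` = undetected).
#' @seealso [buildProfiles()] to normalize records into a
#'   [MethProfileSet-class].
#' @export
readCtTable <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(
    path, header = TRUE, sep = delimiter, comment.char = "#",
    stringsAsFactors = FALSE, na.strings = c("", "NA"),
    colClasses = "character", quote = "\""
  )
  validateCtRecords(raw)
}

#' Validate a data.frame of Ct records
#'
#' @param df data.frame with columns `sample_id`, `multiplex_id`, `target`,
#'   `ct` (character or numeric; `NA` = undetected).
#' @return The validated data.frame with `ct` numeric.
#' @export
validateCtRecords <- function(df) {
  need <- c("sample_id", "multiplex_id", "target", "ct")
  if (!all(need %in% colnames(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$ct <- suppressWarnings(as.numeric(df$ct))
  map <- qmspMultiplexMap()
  bad <- which(!df$multiplex_id %in% names(map))
  if (length(bad)) {
    stop("row ", bad[1], ": unknown multiplex '", df$multiplex_id[bad[1]], "'")
  }
  known <- c(qmspMarkers(), "ACTB")
  bad <- which(!df$target %in% known)
  if (length(bad)) {
    stop("row ", bad[1], ": unknown target '", df$target[bad[1]], "'")
  }
  allowed <- mapply(function(tg, mx) tg == "ACTB" || tg %in% map[[mx]],
                    df$target, df$multiplex_id)
  bad <- which(!allowed)
  if (length(bad)) {
    stop("row ", bad[1], ": target/multiplex mismatch ('", df$target[bad[1]],
         "' is not on multiplex ", df$multiplex_id[bad[1]], ")")
  }
  key <- paste(df$sample_id, df$multiplex_id, df$target, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad)) {
    stop("row ", bad[1], ": duplicate record for (", df$sample_id[bad[1]],
         ", ", df$multiplex_id[bad[1]], ", ", df$target[bad[1]], ")")
  }
  bad <- which(!is.na(df$ct) & (!is.finite(df$ct) | df$ct <= 0))
  if (length(bad)) {
    stop("row ", bad[1], ": Ct must be finite and positive when present")
  }
  rownames(df) <- NULL
  df
}

#' Read clinical metadata
#'
#' Reads the per-sample clinical table and enforces the case/control
#' contract: cases carry grade, stage and disease status and no control
#' subtype; controls the reverse.
#'
#' @param path path to a delimited file with columns `sample_id`, `group`,
#'   `gender`, `age`, `grade_1973`, `grade_2004`, `stage`, `status`,
#'   `control_subtype` and optionally `tumour_count`, `tumour_size_cm`,
#'   `concomitant_cis`. Empty fields mean "absent".
#' @param delimiter field delimiter, default comma.
#' @return A validated data.frame, one row per sample.
#' @export
readClinicalTable <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(
    path, header = TRUE, sep = delimiter, comment.char = "#",
    stringsAsFactors = FALSE, na.strings = c("", "NA", "absent")
  )
  validateClinical(df)
}

#' Validate clinical metadata
#'
#' @param df clinical data.frame (see [readClinicalTable()]).
#' @return The validated data.frame.
#' @export
validateClinical <- function(df) {
  need <- c("sample_id", "group", "gender")
  if (!all(need %in% colnames(df))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if (!all(df$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'")
  }
  if (!all(df$gender %in% c("male", "female"))) {
    stop("gender must be 'male' or 'female'")
  }
  lev <- list(
    grade_1973 = c("G1", "G2", "G3"),
    grade_2004 = c("LG", "HG"),
    stage = c("Ta", "T1", "Tis", "T2plus"),
    status = c("primary", "recurrent"),
    control_subtype = c("haematuria", "other_benign", "healthy")
  )
  for (nm in names(lev)) {
    if (!nm %in% colnames(df)) df[[nm]] <- NA_character_
    bad <- !is.na(df[[nm]]) & !df[[nm]] %in% lev[[nm]]
    if (any(bad)) {
      stop("invalid ", nm, " value: ", df[[nm]][which(bad)[1]])
    }
  }
  cases <- df$group == "case"
  if (any(cases & (is.na(df$grade_2004) | is.na(df$stage) | is.na(df$status)))) {
    stop("cases must carry grade, stage and disease status")
  }
  if (any(cases & !is.na(df$control_subtype))) {
    stop("cases must not carry a control_subtype")
  }
  if (any(!cases & is.na(df$control_subtype))) {
    stop("controls must carry a control_subtype")
  }
  if (any(!cases & (!is.na(df$grade_2004) | !is.na(df$stage) |
                    !is.na(df$status) | !is.na(df$grade_1973)))) {
    stop("controls must not carry tumour grade/stage/status")
  }
  rownames(df) <- NULL
  df
}

#' Reference-gene QC rule
#'
#' A multiplex is valid when its ACTB quantification cycle is detected and
#' does not exceed 32 cycles (a Ct strictly above 32 indicates insufficient
#' or degraded input DNA; exactly 32 passes).
#'
#' @param actb_ct numeric vector of ACTB Ct values, `NA` = undetected.
#' @param limit QC boundary, default 32.
#' @return Logical vector: `TRUE` where the multiplex is valid.
#' @examples
#' actbQcPass(c(26, 32, 32.5, NA))  # TRUE TRUE FALSE FALSE
#' @export
actbQcPass <- function(actb_ct, limit = 32) {
  !is.na(actb_ct) & actb_ct <= limit
}

#' Comparative-Ct methylation ratio
#'
#' Normalizes a target Ct against the ACTB reference using the comparative
#' Ct method: ratio = 2^-(Ct_target - Ct_ACTB) x 100. An undetected target
#' in a valid multiplex is scored as ratio 0 (no detectable methylated
#' template).
#'
#' @param ct_target numeric vector of target Ct values (`NA` = undetected).
#' @param ct_actb numeric vector of reference ACTB Ct values (recycled);
#'   assumed to have passed QC.
#' @return Non-negative numeric vector of methylation ratios.
#' @examples
#' ctRatio(30, 25)  # 3.125
#' ctRatio(24, 25)  # 200
#' @export
ctRatio <- function(ct_target, ct_actb) {
  out <- 2^(-(ct_target - ct_actb)) * 100
  out[is.na(ct_target)] <- 0
  out
}

#' Log2-transformed methylation ratio
#'
#' Display/summary transform log2(ratio + epsilon). Rank-based tests and
#' ROC analysis operate on the raw ratio, so epsilon cannot affect any
#' AUC, p-value or threshold-based call.
#'
#' @param ratio non-negative numeric vector.
#' @param epsilon positive offset guarding ratio 0; default 1e-4.
#' @return Numeric vector of log2 ratios.
#' @export
log2Ratio <- function(ratio, epsilon = 1e-4) {
  stopifnot(epsilon > 0)
  log2(ratio + epsilon)
}

#' Build per-sample methylation profiles from Ct records
#'
#' Groups Ct records by sample, applies the ACTB QC rule per multiplex
#' ([actbQcPass()]) and normalizes every target with [ctRatio()]. All
#' markers of an invalid (or incomplete) multiplex are flagged invalid with
#' their ratios set missing. The number and percentage of samples with at
#' least one invalid multiplex are recorded in the object metadata and
#' reported via a message.
#'
#' @param ct data.frame of Ct records (see [readCtTable()]).
#' @param clinical optional clinical data.frame ([readClinicalTable()]);
#'   matched by `sample_id` and attached to `colData`.
#' @param qcLimit ACTB Ct QC boundary, default 32.
#' @return A [MethProfileSet-class] with assays `ratio` and `valid`.
#' @export
buildProfiles <- function(ct, clinical = NULL, qcLimit = 32) {
  ct <- validateCtRecords(ct)
  map <- qmspMultiplexMap()
  markers <- qmspMarkers()
  samples <- unique(ct$sample_id)
  n <- length(samples)
  if (n == 0L) stop("no samples in Ct table")

  ratio <- matrix(NA_real_, nrow = length(markers), ncol = n,
                  dimnames = list(markers, samples))
  valid <- matrix(FALSE, nrow = length(markers), ncol = n,
                  dimnames = list(markers, samples))
  actb <- matrix(NA_real_, nrow = 3, ncol = n,
                 dimnames = list(c("A", "B", "C"), samples))

  for (s in samples) {
    rows <- ct[ct$sample_id == s, ]
    for (mx in intersect(names(map), unique(rows$multiplex_id))) {
      sub <- rows[rows$multiplex_id == mx, ]
      aref <- sub$ct[sub$target == "ACTB"]
      if (length(aref) == 0L) {
        warning("sample ", s, ", multiplex ", mx,
                ": missing ACTB record; multiplex marked invalid")
        next
      }
      actb[mx, s] <- aref
      if (!actbQcPass(aref, qcLimit)) next
      expected <- map[[mx]]
      present <- sub$target[sub$target != "ACTB"]
      if (!all(expected %in% present)) {
        warning("sample ", s, ", multiplex ", mx,
                ": incomplete target set; multiplex marked invalid")
        next
      }
      for (tg in expected) {
        ratio[tg, s] <- ctRatio(sub$ct[sub$target == tg], aref)
        valid[tg, s] <- TRUE
      }
    }
  }

  mux <- vapply(markers, .multiplexOf, character(1))
  flagged <- apply(valid, 2, function(v) any(!v))
  nFlagged <- sum(flagged)
  message(sprintf(
    "%d of %d samples (%.1f%%) have >=1 invalid multiplex",
    nFlagged, n, 100 * nFlagged / n
  ))

  cd <- NULL
  if (!is.null(clinical)) {
    clinical <- validateClinical(clinical)
    idx <- match(samples, clinical$sample_id)
    if (anyNA(idx)) {
      warning(sum(is.na(idx)), " sample(s) missing from clinical table")
    }
    cd <- clinical[idx, setdiff(colnames(clinical), "sample_id"), drop = FALSE]
  }
  mps <- MethProfileSet(ratio, valid, actb = actb, colData = cd)
  S4Vectors::metadata(mps)$n_flagged <- nFlagged
  S4Vectors::metadata(mps)$pct_invalid <- 100 * nFlagged / n
  S4Vectors::metadata(mps)$qc_limit <- qcLimit
  mps
}

#' Write normalized profiles to CSV
#'
#' One row per sample: `sample_id`, one ratio column per marker, and one
#' validity column per multiplex (`valid_A`, `valid_B`, `valid_C`).
#'
#' @param x a [MethProfileSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(x, path) {
  r <- t(ratios(x))
  v <- markerValid(x)
  mux <- SummarizedExperiment::rowData(x)$multiplex
  out <- data.frame(sample_id = colnames(x), r, check.names = FALSE)
  for (m in c("A", "B", "C")) {
    out[[paste0("valid_", m)]] <- as.logical(v[match(m, mux), ])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
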