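#' RocCurve: an empirical ROC curve
#'
#' Stores the empirical receiver operating characteristic of a continuous
#' score against binary case/control labels. Positivity is called as
#' `score >= threshold` (higher ratio = more case-like). Candidate
#' thresholds are the midpoints between consecutive distinct scores plus
#' `+Inf`/`-Inf` sentinels; ties are grouped (one vertex per distinct
#' score), so the curve always starts at (0, 0) and ends at (1, 1) and the
#' trapezoidal area equals the tie-adjusted Mann-Whitney U / (n1 * n2).
#'
#' @slot thresholds candidate thresholds, decreasing from `Inf` to `-Inf`.
#' @slot fpr,tpr operating points at each threshold (non-decreasing).
#' @slot nCases,nControls group sizes.
#' @aliases RocCurve
#' @export
setClass("RocCurve", representation(
  thresholds = "numeric", fpr = "numeric", tpr = "numeric",
  nCases = "integer", nControls = "integer"
))

setValidity("RocCurve", function(object) {
  k <- length(object@thresholds)
  if (length(object@fpr) != k || length(object@tpr) != k) {
    return("thresholds, fpr and tpr must have equal length")
  }
  if (any(diff(object@fpr) < 0) || any(diff(object@tpr) < 0)) {
    return("fpr and tpr must be non-decreasing")
  }
  if (any(object@fpr < 0 | object@fpr > 1 | object@tpr < 0 | object@tpr > 1)) {
    return("fpr and tpr must lie in [0, 1]")
  }
  TRUE
})

# drop NAs pairwise, coerce labels, insist on both classes
.rocInput <- function(scores, labels) {
  case <- .asCase(labels)
  keep <- !is.na(scores) & !is.na(case)
  scores <- scores[keep]
  case <- case[keep]
  if (!any(case) || all(case)) {
    stop("both cases and controls are required")
  }
  list(scores = scores, case = case)
}

#' Empirical ROC curve
#'
#' @param scores numeric vector of methylation ratios (or any score where
#'   higher values are more case-like). `NA` scores are dropped.
#' @param labels case/control labels (logical `TRUE` = case, or
#'   `"case"`/`"control"`).
#' @return A [RocCurve-class] object.
#' @examples
#' roc <- empiricalRoc(c(2, 3, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
#' aucRoc(roc)  # 0.875
#' @export
empiricalRoc <- function(scores, labels) {
  inp <- .rocInput(scores, labels)
  s <- inp$scores
  case <- inp$case
  d <- sort(unique(s), decreasing = TRUE)
  thr <- c(Inf, if (length(d) > 1) (d[-1] + d[-length(d)]) / 2, -Inf)
  n1 <- sum(case)
  n0 <- sum(!case)
  tpr <- vapply(thr, function(t) sum(case & s >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!case & s >= t) / n0, numeric(1))
  methods::new("RocCurve", thresholds = thr, fpr = fpr, tpr = tpr,
               nCases = as.integer(n1), nControls = as.integer(n0))
}

#' Trapezoidal area under a ROC curve
#'
#' Equals the tie-adjusted Mann-Whitney statistic U / (n1 * n2), i.e. the
#' probability that a random case outscores a random control (ties counted
#' half).
#'
#' @param roc a [RocCurve-class].
#' @return AUC in \[0, 1\].
#' @export
aucRoc <- function(roc) {
  sum(diff(roc@fpr) * (roc@tpr[-1] + roc@tpr[-length(roc@tpr)]) / 2)
}

#' @rdname RocCurve-class
#' @param object a `RocCurve`.
#' @export
setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d cases vs %d controls, %d thresholds, AUC %.3f\n",
              object@nCases, object@nControls, length(object@thresholds),
              aucRoc(object)))
})

#' @describeIn RocCurve-class curve as a data.frame
#'   (threshold, fpr, tpr), suitable for plotting or CSV export.
#' @param x a `RocCurve`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "RocCurve", function(x, ...) {
  data.frame(threshold = x@thresholds, fpr = x@fpr, tpr = x@tpr)
})

#' Discrimination band of an AUC
#'
#' Conventional labels: 0.5-0.6 very poor, 0.6-0.7 poor, 0.7-0.8 fair,
#' 0.8-0.9 good, 0.9-1.0 excellent. Intervals are closed on the left
#' (an AUC of exactly 0.9 is "excellent"); values below 0.5 are reported
#' as "very poor".
#'
#' @param auc numeric vector of AUC values.
#' @return Character vector of band labels.
#' @examples
#' aucBand(c(0.89, 0.90))  # "good" "excellent"
#' @export
aucBand <- function(auc) {
  bands <- c("very poor", "poor", "fair", "good", "excellent")
  idx <- findInterval(auc, c(0.6, 0.7, 0.8, 0.9)) + 1L
  bands[idx]
}

# DeLong placement-based variance of the empirical AUC
.delong <- function(scores, case) {
  x <- scores[case]   # cases
  y <- scores[!case]  # controls
  m <- length(x)
  n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  auc <- mean(v10)
  var <- stats::var(v10) / m + stats::var(v01) / n
  list(auc = auc, var = var)
}

#' DeLong confidence interval for an AUC
#'
#' Wald interval on the empirical AUC using the DeLong placement-based
#' variance, truncated to \[0, 1\]. With perfect (or perfectly reversed)
#' separation the variance is zero; a degenerate point interval is
#' returned with a warning.
#'
#' @param scores,labels as in [empiricalRoc()]; each class needs >= 2
#'   observations.
#' @param alpha two-sided error level, default 0.05.
#' @return List with `auc`, `lower`, `upper`.
#' @export
aucCi <- function(scores, labels, alpha = 0.05) {
  inp <- .rocInput(scores, labels)
  if (sum(inp$case) < 2 || sum(!inp$case) < 2) {
    stop("need >= 2 observations per class for a CI")
  }
  dl <- .delong(inp$scores, inp$case)
  if (dl$auc %in% c(0, 1) || dl$var == 0) {
    warning("degenerate AUC; returning a point interval")
    return(list(auc = dl$auc, lower = dl$auc, upper = dl$auc))
  }
  z <- stats::qnorm(1 - alpha / 2)
  list(auc = dl$auc,
       lower = max(0, dl$auc - z * sqrt(dl$var)),
       upper = min(1, dl$auc + z * sqrt(dl$var)))
}

#' Mann-Whitney U test for one marker with Bonferroni adjustment
#'
#' Two-sided rank-sum comparison of case vs control methylation ratios.
#' When both groups have at most `exactLimit` observations the p-value is
#' computed by exact enumeration over all group assignments of the
#' (mid-)ranks, which remains exact under ties; otherwise the normal
#' approximation with tie and continuity correction is used
#' (`stats::wilcox.test`). The adjusted p-value multiplies by the number
#' of markers tested and caps at 1.
#'
#' @param caseRatios,controlRatios numeric vectors (NA dropped).
#' @param nMarkers Bonferroni factor, default 9 (the full assay).
#' @param exactLimit exact enumeration when both groups are at most this
#'   size, default 8.
#' @return List with `p_raw`, `p_adjusted` and the rank-sum statistic `u`.
#' @export
mannWhitneyMarker <- function(caseRatios, controlRatios, nMarkers = 9,
                              exactLimit = 8) {
  x <- caseRatios[!is.na(caseRatios)]
  y <- controlRatios[!is.na(controlRatios)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("each group needs >= 1 valid observation")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exactLimit && n2 <= exactLimit) {
    mu <- n1 * n2 / 2
    sets <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  list(p_raw = p, p_adjusted = min(1, nMarkers * p), u = u)
}

#' Kruskal-Wallis comparison across control subtypes
#'
#' Tie-corrected H statistic referred to a chi-squared distribution with
#' k - 1 degrees of freedom (via `stats::kruskal.test`), used to check
#' that marker levels do not differ between control subgroups before
#' pooling them.
#'
#' @param values numeric vector of methylation ratios (NA dropped).
#' @param subtype grouping vector (e.g. control subtype), same length.
#' @return List with `statistic`, `df`, `p`.
#' @export
kruskalWallisControls <- function(values, subtype) {
  keep <- !is.na(values) & !is.na(subtype)
  values <- values[keep]
  subtype <- factor(as.character(subtype[keep]))
  if (nlevels(subtype) < 2) stop("need >= 2 non-empty subgroups")
  kt <- stats::kruskal.test(values, subtype)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Evaluate all markers of a profile set
#'
#' For each marker, compares valid case vs control ratios with
#' [mannWhitneyMarker()] (Bonferroni across the markers evaluated) and
#' summarizes discrimination with [aucCi()] and [aucBand()].
#'
#' @param x a [MethProfileSet-class].
#' @param labels case/control labels per sample (defaults to the `group`
#'   column of `colData(x)`).
#' @param markers markers to evaluate, default all nine.
#' @param alpha CI error level.
#' @return data.frame with one row per marker: `marker`, `n_cases_valid`,
#'   `n_controls_valid`, `auc`, `auc_lower`, `auc_upper`, `band`, `p_raw`,
#'   `p_adjusted`.
#' @export
evaluateMarkers <- function(x, labels = NULL, markers = qmspMarkers(),
                            alpha = 0.05) {
  if (is.null(labels)) labels <- SummarizedExperiment::colData(x)$group
  case <- .asCase(labels)
  r <- ratios(x)
  out <- lapply(markers, function(mk) {
    v <- r[mk, ]
    ok <- !is.na(v)
    mw <- mannWhitneyMarker(v[ok & case], v[ok & !case],
                            nMarkers = length(markers))
    ci <- aucCi(v[ok], case[ok], alpha = alpha)
    data.frame(
      marker = mk,
      n_cases_valid = sum(ok & case), n_controls_valid = sum(ok & !case),
      auc = ci$auc, auc_lower = ci$lower, auc_upper = ci$upper,
      band = aucBand(ci$auc), p_raw = mw$p_raw, p_adjusted = mw$p_adjusted,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
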