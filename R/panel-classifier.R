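#' PanelModel: a believe-the-positive marker panel
#'
#' Per-marker Youden thresholds on the methylation-ratio scale combined by
#' the fixed "believe-the-positive" OR rule: the panel is positive if at
#' least one member marker is positive (`ratio >= threshold`). The rule is
#' immutable; only the markers and thresholds vary.
#'
#' @slot markers panel marker names (default GHSR, MAL).
#' @slot thresholds named numeric, finite ratio-scale cutpoints.
#' @slot rule the combination rule, always `"believe-the-positive"`.
#' @slot stratum cohort or stratum the thresholds were derived on.
#' @aliases PanelModel
#' @export
setClass("PanelModel", representation(
  markers = "character", thresholds = "numeric",
  rule = "character", stratum = "character"
))

setValidity("PanelModel", function(object) {
  if (!identical(object@rule, "believe-the-positive")) {
    return("rule is fixed to 'believe-the-positive'")
  }
  if (!identical(names(object@thresholds), object@markers)) {
    return("thresholds must be named by the panel markers")
  }
  if (any(!is.finite(object@thresholds))) return("thresholds must be finite")
  TRUE
})

#' @rdname PanelModel-class
#' @param object a `PanelModel`.
#' @export
setMethod("show", "PanelModel", function(object) {
  cat(sprintf("PanelModel (%s, stratum: %s)\n", object@rule, object@stratum))
  for (m in object@markers) {
    cat(sprintf("  %s >= %.6g\n", m, object@thresholds[m]))
  }
})

#' Youden-index optimal threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over candidate cuts (the
#' midpoints of consecutive distinct scores, plus sentinel cuts below and
#' above the data for the all-positive/all-negative calls). A sample is
#' called positive when `score >= threshold`. Ties in J are broken in
#' favour of the highest specificity, then the larger threshold,
#' consistent with sparing unnecessary confirmatory procedures.
#'
#' @param scores,labels as in [empiricalRoc()].
#' @return List with `threshold`, `j`, `sensitivity`, `specificity`.
#' @examples
#' youdenThreshold(c(5, 6, 7, 1, 2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE,
#'                                        FALSE))$threshold  # 3.5
#' @export
youdenThreshold <- function(scores, labels) {
  inp <- .rocInput(scores, labels)
  s <- inp$scores
  case <- inp$case
  d <- sort(unique(s))
  cuts <- c(d[1] - 1,
            if (length(d) > 1) (d[-1] + d[-length(d)]) / 2,
            d[length(d)] + 1)
  sens <- vapply(cuts, function(t) mean(s[case] >= t), numeric(1))
  spec <- vapply(cuts, function(t) mean(s[!case] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[spec[best] >= max(spec[best]) - 1e-12]
  best <- best[which.max(cuts[best])]
  list(threshold = cuts[best], j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Fit a believe-the-positive panel
#'
#' Derives each member marker's Youden threshold from its valid
#' observations against the case/control labels.
#'
#' @param x a [MethProfileSet-class].
#' @param labels case/control labels (defaults to `colData(x)$group`).
#' @param markers panel markers, default `c("GHSR", "MAL")`.
#' @param stratum label recorded as the derivation stratum.
#' @return A [PanelModel-class].
#' @export
fitPanelModel <- function(x, labels = NULL, markers = c("GHSR", "MAL"),
                          stratum = "all") {
  if (is.null(labels)) labels <- SummarizedExperiment::colData(x)$group
  case <- .asCase(labels)
  r <- ratios(x)
  thr <- vapply(markers, function(mk) {
    v <- r[mk, ]
    ok <- !is.na(v)
    youdenThreshold(v[ok], case[ok])$threshold
  }, numeric(1))
  methods::new("PanelModel", markers = markers, thresholds = thr,
               rule = "believe-the-positive", stratum = stratum)
}

#' Classify samples with a marker panel
#'
#' Per-marker call: valid and `ratio >= threshold`. The panel is positive
#' if at least one valid member marker is positive (believe-the-positive).
#' If no valid marker is positive but at least one member is invalid, the
#' panel call is indeterminate (a negative cannot be asserted); such
#' samples are excluded from performance denominators.
#'
#' @param x a [MethProfileSet-class].
#' @param model a [PanelModel-class].
#' @return Factor of calls per sample with levels `negative`, `positive`,
#'   `indeterminate`.
#' @export
classifyPanel <- function(x, model) {
  r <- ratios(x)[model@markers, , drop = FALSE]
  pos <- !is.na(r) & r >= model@thresholds[model@markers]
  anyPos <- apply(pos, 2, any)
  anyInvalid <- apply(r, 2, anyNA)
  out <- ifelse(anyPos, "positive",
                ifelse(anyInvalid, "indeterminate", "negative"))
  factor(out, levels = c("negative", "positive", "indeterminate"))
}

#' Continuous panel score
#'
#' Max-margin score: the maximum over valid member markers of
#' `log2Ratio(ratio) - log2Ratio(threshold)`. The score is >= 0 exactly
#' when the believe-the-positive rule calls the sample positive, so its
#' ROC curve passes through the panel's operating point. `NA` when no
#' member marker is valid.
#'
#' @param x a [MethProfileSet-class].
#' @param model a [PanelModel-class].
#' @param epsilon log-transform offset (see [log2Ratio()]).
#' @return Numeric score per sample.
#' @export
panelScore <- function(x, model, epsilon = 1e-4) {
  r <- ratios(x)[model@markers, , drop = FALSE]
  marg <- log2Ratio(r, epsilon) -
    log2Ratio(model@thresholds[model@markers], epsilon)
  apply(marg, 2, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Lower bound `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0), upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#'
#' @param x number of successes (vectorized).
#' @param n number of trials.
#' @param alpha two-sided error level, default 0.05.
#' @return data.frame with `estimate`, `lower`, `upper`.
#' @examples
#' clopperPearsonCi(23, 23)$lower  # (0.025)^(1/23) ~ 0.852
#' @export
clopperPearsonCi <- function(x, n, alpha = 0.05) {
  stopifnot(all(x >= 0), all(x <= n), all(n >= 1))
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  data.frame(estimate = x / n, lower = lower, upper = upper)
}

#' Diagnostic performance of panel calls
#'
#' Sensitivity and specificity from determinate calls with exact
#' Clopper-Pearson intervals; indeterminate samples are excluded from the
#' denominators and counted.
#'
#' @param calls factor of panel calls ([classifyPanel()]).
#' @param labels case/control labels.
#' @param alpha CI error level.
#' @return List with `sensitivity`, `specificity` (each a one-row
#'   data.frame `estimate`/`lower`/`upper`), the counts `tp`, `fn`, `tn`,
#'   `fp`, and `n_indeterminate`.
#' @export
panelPerformance <- function(calls, labels, alpha = 0.05) {
  case <- .asCase(labels)
  det <- calls != "indeterminate" & !is.na(calls)
  tp <- sum(det & case & calls == "positive")
  fn <- sum(det & case & calls == "negative")
  tn <- sum(det & !case & calls == "negative")
  fp <- sum(det & !case & calls == "positive")
  if (tp + fn == 0 || tn + fp == 0) {
    stop("need >= 1 determinate case and control")
  }
  list(
    sensitivity = clopperPearsonCi(tp, tp + fn, alpha),
    specificity = clopperPearsonCi(tn, tn + fp, alpha),
    tp = tp, fn = fn, tn = tn, fp = fp,
    n_indeterminate = sum(calls == "indeterminate", na.rm = TRUE)
  )
}

#' Serialize a panel model to JSON
#'
#' Records markers, thresholds on both the ratio and log2 scales, the
#' combination rule and the derivation stratum.
#'
#' @param model a [PanelModel-class].
#' @param path output path; when `NULL` the JSON string is returned.
#' @param epsilon offset for the log2-scale thresholds.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
panelModelToJson <- function(model, path = NULL, epsilon = 1e-4) {
  obj <- list(
    markers = model@markers,
    thresholds_ratio = as.list(model@thresholds),
    thresholds_log2 = as.list(log2Ratio(model@thresholds, epsilon)),
    rule = model@rule,
    stratum = model@stratum
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
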