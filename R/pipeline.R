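# end-to-end orchestration: simulate/read -> QC -> markers -> panel ->
# LOOCV -> subgroups -> gender strata -> design summary

.performanceRecord <- function(perf) {
  list(
    sensitivity = perf$sensitivity$estimate,
    sensitivity_ci = c(perf$sensitivity$lower, perf$sensitivity$upper),
    specificity = perf$specificity$estimate,
    specificity_ci = c(perf$specificity$lower, perf$specificity$upper),
    tp = perf$tp, fn = perf$fn, tn = perf$tn, fp = perf$fp,
    n_indeterminate = perf$n_indeterminate
  )
}

#' Run the full panel-evaluation analysis
#'
#' Orchestrates every stage: input (files, in-memory tables, or a
#' simulated cohort), reference-gene QC and normalization, per-marker
#' statistics and ROC analysis, control-subtype homogeneity checks, panel
#' threshold derivation and resubstitution ("preclinical") performance,
#' leave-one-out cross-validation, case subgroup sensitivities,
#' gender-stratified post hoc evaluation, and the sample-size design
#' summary. Every random step is governed by the simulation config seed,
#' so a rerun with the same inputs is byte-identical.
#'
#' @param ctTable path to a Ct table CSV, or a Ct data.frame; ignored when
#'   `simConfig` is given.
#' @param clinical path to a clinical CSV, or a data.frame.
#' @param simConfig optional [CohortConfig-class]: simulate the cohort
#'   instead of reading files.
#' @param markers panel markers, default `c("GHSR", "MAL")`.
#' @param alpha CI error level.
#' @param epsilon log2-transform offset (display and panel score only).
#' @param loocv,subgroups,stratifyGender stage switches.
#' @param design arguments passed to [designSummary()].
#' @return A report list (class `qmspReport`) with elements `schema`,
#'   `inputs`, `qc`, `markers`, `control_subtypes`, `panel`, `loocv`,
#'   `subgroups`, `males`, `females`, `design`.
#' @seealso [writeReport()]
#' @export
runFullAnalysis <- function(ctTable = NULL, clinical = NULL,
                            simConfig = NULL, markers = c("GHSR", "MAL"),
                            alpha = 0.05, epsilon = 1e-4,
                            loocv = TRUE, subgroups = TRUE,
                            stratifyGender = TRUE, design = list()) {
  if (is.null(simConfig) && is.null(ctTable)) {
    stop("either input tables or a simulation config is required")
  }
  seed <- NA_integer_
  if (!is.null(simConfig)) {
    sim <- simulateCohort(simConfig)
    ct <- sim$ct
    clin <- sim$clinical
    seed <- simConfig@seed
  } else {
    ct <- if (is.character(ctTable)) readCtTable(ctTable) else ctTable
    clin <- if (is.character(clinical)) readClinicalTable(clinical)
            else clinical
    if (is.null(clin)) stop("clinical metadata is required")
  }
  clin <- validateClinical(clin)

  mps <- suppressMessages(buildProfiles(ct, clinical = clin))
  cd <- SummarizedExperiment::colData(mps)
  case <- .asCase(cd$group)
  if (!any(case)) stop("marker_eval requires at least one case")
  if (all(case)) stop("marker_eval requires at least one control")

  markerTab <- evaluateMarkers(mps, alpha = alpha)

  ctrl <- !case
  subtypeP <- data.frame(
    marker = qmspMarkers(),
    p = vapply(qmspMarkers(), function(mk) {
      v <- ratios(mps)[mk, ctrl]
      kruskalWallisControls(v, cd$control_subtype[ctrl])$p
    }, numeric(1)),
    stringsAsFactors = FALSE
  )

  model <- fitPanelModel(mps, markers = markers, stratum = "all")
  calls <- classifyPanel(mps, model)
  perf <- panelPerformance(calls, cd$group, alpha)
  sc <- panelScore(mps, model, epsilon)
  panelCi <- aucCi(sc, case, alpha = alpha)

  report <- list(
    schema = "qmspPanel-report/1.0",
    inputs = list(
      n_samples = ncol(mps), n_cases = sum(case), n_controls = sum(!case),
      markers = markers, alpha = alpha, epsilon = epsilon, seed = seed
    ),
    qc = list(
      n_flagged = S4Vectors::metadata(mps)$n_flagged,
      pct_invalid = S4Vectors::metadata(mps)$pct_invalid
    ),
    markers = markerTab,
    control_subtypes = subtypeP,
    panel = c(
      list(
        model = list(markers = model@markers,
                     thresholds = as.list(model@thresholds),
                     rule = model@rule, stratum = model@stratum),
        auc = panelCi$auc, auc_ci = c(panelCi$lower, panelCi$upper)
      ),
      .performanceRecord(perf)
    ),
    loocv = NULL, subgroups = NULL, males = NULL, females = NULL,
    design = do.call(designSummary, design)
  )

  if (loocv) {
    lo <- loocvPanel(mps, markers = markers, alpha = alpha,
                     epsilon = epsilon)
    report$loocv <- c(
      list(auc = lo$auc, auc_ci = lo$auc_ci, n_folds = lo$n_folds),
      .performanceRecord(lo$performance)
    )
  }
  if (subgroups) {
    report$subgroups <- subgroupSensitivity(calls, as.data.frame(cd),
                                            alpha = alpha)
  }
  if (stratifyGender) {
    gs <- genderStratifiedEval(mps, markers = markers, alpha = alpha,
                               epsilon = epsilon)
    for (g in c("male", "female")) {
      el <- gs[[g]]
      report[[paste0(g, "s")]] <- list(
        thresholds = as.list(el$model@thresholds),
        auc = el$auc, auc_ci = el$auc_ci,
        preclinical = .performanceRecord(el$performance),
        loocv = c(list(auc = el$loocv$auc, auc_ci = el$loocv$auc_ci,
                       n_folds = el$loocv$n_folds),
                  .performanceRecord(el$loocv$performance))
      )
    }
  }
  class(report) <- c("qmspReport", "list")
  report
}

#' @export
print.qmspReport <- function(x, ...) {
  cat("qmspPanel analysis report (", x$schema, ")\n", sep = "")
  cat(sprintf("  %d samples (%d cases / %d controls); QC flagged %d (%.1f%%)\n",
              x$inputs$n_samples, x$inputs$n_cases, x$inputs$n_controls,
              x$qc$n_flagged, x$qc$pct_invalid))
  cat(sprintf("  panel %s: AUC %.2f (95%% CI %.2f-%.2f)\n",
              paste(x$inputs$markers, collapse = "/"),
              x$panel$auc, x$panel$auc_ci[1], x$panel$auc_ci[2]))
  cat(sprintf("    sensitivity %.2f (%.2f-%.2f), specificity %.2f (%.2f-%.2f)\n",
              x$panel$sensitivity, x$panel$sensitivity_ci[1],
              x$panel$sensitivity_ci[2], x$panel$specificity,
              x$panel$specificity_ci[1], x$panel$specificity_ci[2]))
  if (!is.null(x$loocv)) {
    cat(sprintf("  LOOCV: AUC %.2f, sensitivity %.2f, specificity %.2f (%d folds)\n",
                x$loocv$auc, x$loocv$sensitivity, x$loocv$specificity,
                x$loocv$n_folds))
  }
  cat(sprintf("  design: n = %d per group (+dropout -> enrol %d)\n",
              x$design$n_cases, x$design$enrol_cases))
  invisible(x)
}

# flatten the per-stratum performance blocks into one table
.performanceTable <- function(report) {
  rows <- list()
  add <- function(population, phase, rec, auc = NA, auc_ci = c(NA, NA)) {
    rows[[length(rows) + 1L]] <<- data.frame(
      population = population, phase = phase,
      auc = auc, auc_lower = auc_ci[1], auc_upper = auc_ci[2],
      sensitivity = rec$sensitivity,
      sensitivity_lower = rec$sensitivity_ci[1],
      sensitivity_upper = rec$sensitivity_ci[2],
      specificity = rec$specificity,
      specificity_lower = rec$specificity_ci[1],
      specificity_upper = rec$specificity_ci[2],
      tp = rec$tp, fn = rec$fn, tn = rec$tn, fp = rec$fp,
      n_indeterminate = rec$n_indeterminate,
      stringsAsFactors = FALSE
    )
  }
  add("all", "preclinical", report$panel, report$panel$auc,
      report$panel$auc_ci)
  if (!is.null(report$loocv)) {
    add("all", "loocv", report$loocv, report$loocv$auc, report$loocv$auc_ci)
  }
  for (g in c("males", "females")) {
    if (is.null(report[[g]])) next
    add(g, "preclinical", report[[g]]$preclinical, report[[g]]$auc,
        report[[g]]$auc_ci)
    add(g, "loocv", report[[g]]$loocv, report[[g]]$loocv$auc,
        report[[g]]$loocv$auc_ci)
  }
  do.call(rbind, rows)
}

#' Write an analysis report to disk
#'
#' `json` writes one file mirroring the report structure at full numeric
#' precision; `csv` writes a bundle (`markers.csv`, `performance.csv`,
#' `subgroups.csv`, `design.csv`) carrying the same numbers.
#'
#' @param report a report from [runFullAnalysis()].
#' @param dir output directory (created if needed).
#' @param format `"json"`, `"csv"`, or both.
#' @return Character vector of the files written, invisibly.
#' @export
writeReport <- function(report, dir, format = c("json", "csv")) {
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", dataframe = "rows")
    written <- c(written, p)
  }
  if ("csv" %in% format) {
    tabs <- list(
      markers = report$markers,
      performance = .performanceTable(report),
      subgroups = report$subgroups,
      design = as.data.frame(report$design)
    )
    for (nm in names(tabs)) {
      if (is.null(tabs[[nm]])) next
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(tabs[[nm]], p, row.names = FALSE)
      written <- c(written, p)
    }
  }
  invisible(written)
}
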