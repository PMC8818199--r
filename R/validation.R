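#' Leave-one-out cross-validation of the marker panel
#'
#' For each sample with at least one valid panel marker, per-marker Youden
#' thresholds are re-derived on all other samples, the held-out sample is
#' classified with the believe-the-positive rule, and its continuous panel
#' score under the fold model is recorded. Out-of-fold determinate calls
#' are aggregated into sensitivity/specificity with exact binomial
#' intervals, and the out-of-fold scores into an AUC with DeLong interval.
#' Because the thresholds are re-estimated in every fold, LOOCV can differ
#' from resubstitution performance.
#'
#' @param x a [MethProfileSet-class].
#' @param labels case/control labels (defaults to `colData(x)$group`).
#' @param markers panel markers, default `c("GHSR", "MAL")`.
#' @param alpha CI error level.
#' @param epsilon log-transform offset for the panel score.
#' @return List with `calls` (factor, `NA` where no marker was valid),
#'   `scores`, `performance` (see [panelPerformance()]), `auc`, `auc_ci`
#'   and `n_folds` (number of determinate out-of-fold calls).
#' @export
loocvPanel <- function(x, labels = NULL, markers = c("GHSR", "MAL"),
                       alpha = 0.05, epsilon = 1e-4) {
  if (is.null(labels)) labels <- SummarizedExperiment::colData(x)$group
  case <- .asCase(labels)
  if (sum(case) < 2 || sum(!case) < 2) {
    stop("LOOCV needs >= 2 cases and >= 2 controls")
  }
  r <- ratios(x)[markers, , drop = FALSE]
  n <- ncol(r)
  calls <- rep(NA_character_, n)
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (all(is.na(r[, i]))) next
    thr <- vapply(markers, function(mk) {
      v <- r[mk, -i]
      ok <- !is.na(v)
      tr <- case[-i][ok]
      if (all(tr) || !any(tr)) {
        stop("fold ", i, ": training data for ", mk, " is single-class")
      }
      youdenThreshold(v[ok], tr)$threshold
    }, numeric(1))
    pos <- !is.na(r[, i]) & r[, i] >= thr
    calls[i] <- if (any(pos)) "positive"
      else if (anyNA(r[, i])) "indeterminate" else "negative"
    marg <- log2Ratio(r[, i], epsilon) - log2Ratio(thr, epsilon)
    scores[i] <- max(marg, na.rm = TRUE)
  }
  calls <- factor(calls, levels = c("negative", "positive", "indeterminate"))
  perf <- panelPerformance(calls[!is.na(calls)], case[!is.na(calls)], alpha)
  ci <- aucCi(scores, case, alpha = alpha)
  list(calls = calls, scores = scores, performance = perf,
       auc = ci$auc, auc_ci = c(ci$lower, ci$upper),
       n_folds = sum(calls %in% c("negative", "positive")))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (1 df), as used for case/control
#' comparisons of categorical baseline data and subgroup sensitivities.
#'
#' @param tab 2x2 matrix of counts.
#' @return List with `statistic`, `df`, `p`.
#' @examples
#' chiSquare2x2(matrix(c(79, 63, 29, 37), 2))$p  # ~0.116
#' @export
chiSquare2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in 2x2 table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

# exact-CI sensitivity rows for one partition of the determinate cases
.strataRows <- function(pos, strat, partition, alpha) {
  lv <- levels(strat)
  kept <- lv[vapply(lv, function(l) any(strat == l, na.rm = TRUE), logical(1))]
  if (length(kept) < length(lv)) {
    warning("partition ", partition, ": empty stratum dropped")
  }
  rows <- lapply(kept, function(l) {
    sel <- !is.na(strat) & strat == l
    ci <- clopperPearsonCi(sum(pos[sel]), sum(sel), alpha)
    data.frame(partition = partition, stratum = l, n = sum(sel),
               n_positive = sum(pos[sel]), sensitivity = ci$estimate,
               lower = ci$lower, upper = ci$upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_value <- if (length(kept) == 2) {
    tab <- rbind(
      c(sum(pos[strat == kept[1]], na.rm = TRUE),
        sum(!pos[strat == kept[1]], na.rm = TRUE)),
      c(sum(pos[strat == kept[2]], na.rm = TRUE),
        sum(!pos[strat == kept[2]], na.rm = TRUE))
    )
    if (any(colSums(tab) == 0)) 1  # all cases share one outcome: no contrast
    else chiSquare2x2(tab)$p
  } else NA_real_
  out
}

#' Subgroup sensitivity of the panel among cases
#'
#' Sensitivity (with exact binomial CI) of pooled-cohort panel calls
#' within case subgroups, for the dichotomized partitions WHO 1973 grade
#' (G3 vs G1-G2), WHO 2004 grade (HG vs LG), stage (>= T2 vs Ta/T1/Tis),
#' disease status (primary vs recurrent) and gender. Each partition's
#' contrast is tested with [chiSquare2x2()]; p-values are reported
#' unadjusted. Indeterminate calls are excluded.
#'
#' @param calls panel calls for all samples ([classifyPanel()]).
#' @param clinical clinical data.frame aligned with `calls` (must contain
#'   `group`, `gender`, `grade_1973`, `grade_2004`, `stage`, `status`).
#' @param alpha CI error level.
#' @return data.frame with columns `partition`, `stratum`, `n`,
#'   `n_positive`, `sensitivity`, `lower`, `upper`, `p_value` (repeated
#'   within a partition; `NA` for the overall row).
#' @export
subgroupSensitivity <- function(calls, clinical, alpha = 0.05) {
  sel <- clinical$group == "case" & calls %in% c("positive", "negative")
  cl <- clinical[sel, , drop = FALSE]
  pos <- calls[sel] == "positive"
  ciAll <- clopperPearsonCi(sum(pos), length(pos), alpha)
  out <- data.frame(partition = "all", stratum = "all", n = length(pos),
                    n_positive = sum(pos), sensitivity = ciAll$estimate,
                    lower = ciAll$lower, upper = ciAll$upper,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  parts <- list(
    grade_1973 = factor(ifelse(cl$grade_1973 == "G3", "G3", "G1-G2"),
                        levels = c("G1-G2", "G3")),
    grade_2004 = factor(cl$grade_2004, levels = c("LG", "HG")),
    stage = factor(ifelse(cl$stage == "T2plus", ">=T2", "Ta/T1/Tis"),
                   levels = c("Ta/T1/Tis", ">=T2")),
    status = factor(cl$status, levels = c("primary", "recurrent")),
    gender = factor(cl$gender, levels = c("male", "female"))
  )
  for (nm in names(parts)) {
    out <- rbind(out, .strataRows(pos, parts[[nm]], nm, alpha))
  }
  rownames(out) <- NULL
  out
}

#' Gender-stratified panel evaluation
#'
#' Post hoc analysis splitting the cohort by gender: within each stratum,
#' panel thresholds are re-derived with Youden's index, resubstitution
#' performance and panel-score AUC are computed, and the stratum is
#' cross-validated by LOOCV.
#'
#' @param x a [MethProfileSet-class] whose `colData` carries `group` and
#'   `gender`.
#' @param markers panel markers.
#' @param alpha CI error level.
#' @param epsilon log-transform offset.
#' @return Named list (`male`, `female`); each element has `model`,
#'   `calls`, `performance`, `auc`, `auc_ci` and `loocv`. A stratum
#'   lacking either class raises an error.
#' @export
genderStratifiedEval <- function(x, markers = c("GHSR", "MAL"),
                                 alpha = 0.05, epsilon = 1e-4) {
  cd <- SummarizedExperiment::colData(x)
  if (is.null(cd$group) || is.null(cd$gender)) {
    stop("colData must carry 'group' and 'gender'")
  }
  out <- list()
  for (g in c("male", "female")) {
    xi <- x[, cd$gender == g]
    lab <- SummarizedExperiment::colData(xi)$group
    case <- .asCase(lab)
    if (!any(case) || all(case)) {
      stop("gender stratum '", g, "' lacks cases or controls")
    }
    model <- fitPanelModel(xi, lab, markers = markers, stratum = g)
    calls <- classifyPanel(xi, model)
    perf <- panelPerformance(calls, lab, alpha)
    sc <- panelScore(xi, model, epsilon)
    ci <- aucCi(sc, case, alpha = alpha)
    out[[g]] <- list(
      model = model, calls = calls, performance = perf,
      auc = ci$auc, auc_ci = c(ci$lower, ci$upper),
      loocv = loocvPanel(xi, lab, markers = markers, alpha = alpha,
                         epsilon = epsilon)
    )
  }
  out
}
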