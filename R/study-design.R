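#' Hanley-McNeil standard error of an empirical AUC
#'
#' Closed-form approximation to the sampling SE of an AUC `A` observed on
#' `n1` cases and `n2` controls:
#' `SE^2 = [A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)] / (n1 n2)` with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc anticipated AUC in (0, 1).
#' @param nCases,nControls group sizes (>= 2).
#' @return Standard error (numeric scalar).
#' @examples
#' hanleyMcNeilSe(0.89, 87, 87)  # ~0.0254
#' @export
hanleyMcNeilSe <- function(auc, nCases, nControls) {
  stopifnot(auc > 0, auc < 1, nCases >= 2, nControls >= 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (nCases - 1) * (q1 - auc^2) +
          (nControls - 1) * (q2 - auc^2)) / (nCases * nControls))
}

#' Minimum group size for a target AUC confidence-interval width
#'
#' Smallest integer number of cases `n` such that the two-sided
#' `(1 - alpha)` confidence interval for the anticipated AUC, using the
#' Hanley-McNeil standard error with `ceiling(allocation * n)` controls,
#' has width at most `ciWidthMax`. Found by integer search from 2.
#'
#' @param auc anticipated AUC in (0.5, 1).
#' @param ciWidthMax maximum CI width (> 0).
#' @param alpha two-sided error level, default 0.05.
#' @param allocation controls per case, default 1 (matched groups).
#' @param nMax search cap; exceeding it raises an error.
#' @return List with `n_cases`, `n_controls`, and the achieved `ci_width`.
#' @examples
#' minNForCiWidth(0.89, 0.1)$n_cases  # 87
#' @export
minNForCiWidth <- function(auc, ciWidthMax, alpha = 0.05, allocation = 1,
                           nMax = 1e6) {
  stopifnot(auc > 0.5, auc < 1, ciWidthMax > 0, allocation > 0)
  z <- stats::qnorm(1 - alpha / 2)
  for (n in 2:nMax) {
    n2 <- as.integer(ceiling(allocation * n))
    w <- 2 * z * hanleyMcNeilSe(auc, n, n2)
    if (w <= ciWidthMax) {
      return(list(n_cases = n, n_controls = n2, ci_width = w))
    }
  }
  stop("no group size up to ", nMax, " achieves CI width ", ciWidthMax)
}

#' Inflate a sample size for anticipated dropout
#'
#' @param n required evaluable participants per group.
#' @param dropoutRate anticipated dropout fraction in \[0, 1).
#' @return Enrolment target `ceiling(n / (1 - dropoutRate))`.
#' @examples
#' inflateForDropout(87, 0.2)  # 109
#' @export
inflateForDropout <- function(n, dropoutRate) {
  stopifnot(dropoutRate >= 0, dropoutRate < 1)
  as.integer(ceiling(n / (1 - dropoutRate)))
}

#' Full study-size design summary
#'
#' Combines [minNForCiWidth()] and [inflateForDropout()] into one design
#' record.
#'
#' @param auc anticipated AUC.
#' @param ciWidthMax maximum CI width.
#' @param alpha two-sided error level.
#' @param allocation controls per case.
#' @param dropoutRate anticipated dropout fraction.
#' @return List with `auc`, `ci_width_max`, `alpha`, `n_cases`,
#'   `n_controls`, `ci_width`, `dropout_rate`, `enrol_cases`,
#'   `enrol_controls`.
#' @export
designSummary <- function(auc = 0.89, ciWidthMax = 0.1, alpha = 0.05,
                          allocation = 1, dropoutRate = 0.2) {
  mn <- minNForCiWidth(auc, ciWidthMax, alpha, allocation)
  list(
    auc = auc, ci_width_max = ciWidthMax, alpha = alpha,
    n_cases = mn$n_cases, n_controls = mn$n_controls,
    ci_width = mn$ci_width, dropout_rate = dropoutRate,
    enrol_cases = inflateForDropout(mn$n_cases, dropoutRate),
    enrol_controls = inflateForDropout(mn$n_controls, dropoutRate)
  )
}
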