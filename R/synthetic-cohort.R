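#' CohortConfig: generative parameters for a synthetic qMSP cohort
#'
#' Holds every parameter of the synthetic case-control cohort generator:
#' group sizes, categorical composition (gender, grades, stage, disease
#' status, control subtype), per-marker baseline and effect sizes on the
#' log2-ratio scale, covariate-dependent effect multipliers, the shared
#' tumour-burden dispersion, the ACTB reference-gene Ct distribution and
#' its sporadic failure rate, and the RNG seed.
#'
#' @slot nCases,nControls group sizes.
#' @slot composition named list of named frequency vectors
#'   (`gender_cases`, `gender_controls`, `grade_1973`, `grade_2004`,
#'   `stage`, `status`, `control_subtype`); each sums to 1.
#' @slot mu0 named numeric (9): mean control log2-ratio per marker.
#' @slot sigma within-group SD of the log2-ratio (shared across markers).
#' @slot delta named numeric (9): case shift per marker, in SD units.
#' @slot gradeMultiplier,stageMultiplier,recurrenceMultiplier,femaleDilution
#'   multiplicative factors applied to delta for high-grade, muscle-invasive
#'   (>= T2), recurrent and female cases respectively.
#' @slot burdenSd SD of the per-case lognormal tumour-burden factor shared
#'   across markers (induces inter-marker correlation).
#' @slot actbMean,actbSd reference-gene Ct distribution.
#' @slot actbFailureRate probability that a multiplex's ACTB Ct is drawn
#'   above the QC limit.
#' @slot ctDetectionLimit target wells with back-computed Ct above this are
#'   emitted as undetected.
#' @slot seed integer RNG seed.
#' @aliases CohortConfig
#' @seealso [cohortConfig()], [defaultCohortConfig()], [simulateCohort()]
#' @export
setClass("CohortConfig", representation(
  nCases = "integer", nControls = "integer", composition = "list",
  mu0 = "numeric", sigma = "numeric", delta = "numeric",
  gradeMultiplier = "numeric", stageMultiplier = "numeric",
  recurrenceMultiplier = "numeric", femaleDilution = "numeric",
  burdenSd = "numeric", actbMean = "numeric", actbSd = "numeric",
  actbFailureRate = "numeric", ctDetectionLimit = "numeric", seed = "integer"
))

setValidity("CohortConfig", function(object) {
  if (object@nCases < 1 || object@nControls < 1) return("group sizes must be >= 1")
  need <- c("gender_cases", "gender_controls", "grade_1973", "grade_2004",
            "stage", "status", "control_subtype")
  miss <- setdiff(need, names(object@composition))
  if (length(miss)) return(paste("missing composition:", paste(miss, collapse = ", ")))
  for (nm in need) {
    p <- object@composition[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      return(sprintf("composition '%s' must be non-negative and sum to 1", nm))
    }
  }
  mk <- qmspMarkers()
  if (!all(mk %in% names(object@mu0))) return("mu0 must name all nine markers")
  if (!all(mk %in% names(object@delta))) return("delta must name all nine markers")
  if (object@sigma <= 0) return("sigma must be positive")
  if (object@actbFailureRate < 0 || object@actbFailureRate > 1) {
    return("actbFailureRate must be in [0, 1]")
  }
  if (object@burdenSd < 0) return("burdenSd must be non-negative")
  TRUE
})

#' Create a cohort configuration
#'
#' All arguments default to the values of [defaultCohortConfig()]; see that
#' help page for the default study composition.
#'
#' @param nCases,nControls group sizes.
#' @param composition named list of frequency vectors (see
#'   [CohortConfig-class]); missing elements fall back to the defaults.
#' @param mu0 per-marker mean control log2-ratio (scalar recycled).
#' @param sigma within-group SD of the log2-ratio.
#' @param delta per-marker case shift in SD units (scalar recycled).
#' @param gradeMultiplier,stageMultiplier,recurrenceMultiplier,femaleDilution
#'   effect multipliers (1 = no modification).
#' @param burdenSd SD of the shared lognormal tumour-burden factor.
#' @param actbMean,actbSd ACTB Ct distribution.
#' @param actbFailureRate per-multiplex probability of an ACTB QC failure.
#' @param ctDetectionLimit assay detection limit in cycles.
#' @param seed integer RNG seed.
#' @return A [CohortConfig-class] object.
#' @export
cohortConfig <- function(nCases = 108, nControls = 100,
                         composition = list(),
                         mu0 = -5, sigma = 2, delta = NULL,
                         gradeMultiplier = 1.4, stageMultiplier = 1.3,
                         recurrenceMultiplier = 0.6, femaleDilution = 0.5,
                         burdenSd = 0.5, actbMean = 26, actbSd = 1.5,
                         actbFailureRate = 0.03, ctDetectionLimit = 45,
                         seed = 1L) {
  mk <- qmspMarkers()
  base <- list(
    gender_cases = c(male = 0.73, female = 0.27),
    gender_controls = c(male = 0.63, female = 0.37),
    grade_1973 = c(G1 = 0.16, G2 = 0.36, G3 = 0.48),
    grade_2004 = c(LG = 0.42, HG = 0.58),
    stage = c(Ta = 0.55, T1 = 0.15, Tis = 0.09, T2plus = 0.21),
    status = c(primary = 0.70, recurrent = 0.30),
    control_subtype = c(haematuria = 0.34, other_benign = 0.43, healthy = 0.23)
  )
  base[names(composition)] <- composition
  if (is.null(delta)) {
    delta <- c(FAM19A4 = 1.5, PHACTR3 = 1.4, PRDM14 = 1.5,
               GHSR = 1.9, SST = 1.6, ZIC1 = 1.8,
               MAL = 1.7, `miR-129` = 1.5, `miR-935` = 1.4)
  }
  if (length(mu0) == 1L) mu0 <- stats::setNames(rep(mu0, 9), mk)
  if (length(delta) == 1L) delta <- stats::setNames(rep(delta, 9), mk)
  methods::new("CohortConfig",
    nCases = as.integer(nCases), nControls = as.integer(nControls),
    composition = base, mu0 = mu0[mk], sigma = sigma, delta = delta[mk],
    gradeMultiplier = gradeMultiplier, stageMultiplier = stageMultiplier,
    recurrenceMultiplier = recurrenceMultiplier,
    femaleDilution = femaleDilution, burdenSd = burdenSd,
    actbMean = actbMean, actbSd = actbSd,
    actbFailureRate = actbFailureRate,
    ctDetectionLimit = ctDetectionLimit, seed = as.integer(seed)
  )
}

#' Default configuration: the 108/100 study composition
#'
#' Composition frequencies reproduce the study population: 108 bladder
#' cancer cases (73% male; WHO 1973 grades 16/36/48%; low/high grade
#' 42/58%; stages Ta/T1/Tis/>=T2 55/15/9/21%; 70% primary) and 100
#' controls (63% male; haematuria/other benign/healthy 34/43/23%). With
#' quota-based covariate sampling the generated cohort matches these
#' counts exactly.
#'
#' @param seed integer RNG seed.
#' @return A [CohortConfig-class].
#' @export
defaultCohortConfig <- function(seed = 1L) cohortConfig(seed = seed)

#' @rdname CohortConfig-class
#' @param object a `CohortConfig`.
#' @export
setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d cases / %d controls, seed %d\n",
              object@nCases, object@nControls, object@seed))
  cat(sprintf("  delta (SD units): %s\n",
              paste(sprintf("%s=%.2f", names(object@delta), object@delta),
                    collapse = " ")))
  cat(sprintf(
    "  multipliers: grade %.2f, stage %.2f, recurrence %.2f, female %.2f; burdenSd %.2f\n",
    object@gradeMultiplier, object@stageMultiplier,
    object@recurrenceMultiplier, object@femaleDilution, object@burdenSd))
  cat(sprintf("  ACTB ~ N(%.1f, %.1f), failure rate %.3f\n",
              object@actbMean, object@actbSd, object@actbFailureRate))
})

#' Read a cohort configuration from YAML or JSON
#'
#' Scalar fields map one-to-one to [cohortConfig()] arguments; `composition`
#' is a mapping of frequency vectors.
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return A [CohortConfig-class].
#' @export
readCohortConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$composition <- lapply(lst$composition, unlist)
  if (!is.null(lst$mu0)) lst$mu0 <- unlist(lst$mu0)
  if (!is.null(lst$delta)) lst$delta <- unlist(lst$delta)
  do.call(cohortConfig, lst)
}

# quota covariate assignment: counts by largest remainder, order randomized
.quotaAssign <- function(n, p, ord = sample.int(n)) {
  counts <- .quotaCounts(n, p)
  rep(names(p), counts)[order(ord)]
}

#' Simulate a qMSP case-control cohort
#'
#' Generates a raw Ct table and clinical metadata with the statistical
#' structure the downstream analysis assumes. Covariates are assigned by
#' exact quota (largest-remainder apportionment of the configured
#' frequencies), so the default cohort reproduces the study counts exactly;
#' the two grading systems share one latent severity order so high WHO 1973
#' grades nest inside high-grade WHO 2004 disease. Each case draws a
#' lognormal tumour burden shared across markers; marker log2-ratios are
#' Gaussian around `mu0` (controls) or `mu0 + delta * sigma * burden * g`
#' (cases), where `g` multiplies the applicable grade/stage/recurrence/
#' female factors. Ratios are back-transformed to target Ct values against
#' a drawn ACTB Ct (so normalization exactly inverts generation within the
#' assay's dynamic range: targets past the detection limit are emitted
#' undetected, and back-computed cycles below 1 saturate at 1), and each
#' (sample, multiplex) independently suffers an ACTB QC failure with the
#' configured probability. Output is deterministic given the config seed.
#'
#' @param config a [CohortConfig-class].
#' @return List with elements `ct` (long-format Ct data.frame), `clinical`
#'   (metadata data.frame) and `truth` (per-sample true log2-ratios, for
#'   calibration checks).
#' @export
simulateCohort <- function(config) {
  methods::validObject(config)
  .withSeed(config@seed, {
    comp <- config@composition
    n1 <- config@nCases
    n0 <- config@nControls
    ids <- c(sprintf("case_%03d", seq_len(n1)),
             sprintf("ctrl_%03d", seq_len(n0)))
    group <- rep(c("case", "control"), c(n1, n0))

    sev <- sample.int(n1)  # shared severity order couples the two gradings
    clinical <- data.frame(
      sample_id = ids, group = group,
      gender = c(.quotaAssign(n1, comp$gender_cases),
                 .quotaAssign(n0, comp$gender_controls)),
      age = round(stats::rnorm(n1 + n0, mean = c(rep(69, n1), rep(66, n0)),
                               sd = 9)),
      grade_1973 = c(.quotaAssign(n1, comp$grade_1973, ord = sev), rep(NA, n0)),
      grade_2004 = c(.quotaAssign(n1, comp$grade_2004, ord = sev), rep(NA, n0)),
      stage = c(.quotaAssign(n1, comp$stage), rep(NA, n0)),
      status = c(.quotaAssign(n1, comp$status), rep(NA, n0)),
      control_subtype = c(rep(NA, n1), .quotaAssign(n0, comp$control_subtype)),
      stringsAsFactors = FALSE
    )

    burden <- stats::rlnorm(n1, 0, config@burdenSd)
    g <- rep(1, n1)
    g <- g * ifelse(clinical$grade_2004[seq_len(n1)] == "HG",
                    config@gradeMultiplier, 1)
    g <- g * ifelse(clinical$stage[seq_len(n1)] == "T2plus",
                    config@stageMultiplier, 1)
    g <- g * ifelse(clinical$status[seq_len(n1)] == "recurrent",
                    config@recurrenceMultiplier, 1)
    g <- g * ifelse(clinical$gender[seq_len(n1)] == "female",
                    config@femaleDilution, 1)

    mk <- qmspMarkers()
    nAll <- n1 + n0
    shift <- outer(config@delta[mk] * config@sigma, c(burden * g, rep(0, n0)))
    truth <- config@mu0[mk] + shift +
      matrix(stats::rnorm(9 * nAll, 0, config@sigma), 9, nAll)
    dimnames(truth) <- list(mk, ids)

    map <- qmspMultiplexMap()
    actb <- matrix(stats::rnorm(3 * nAll, config@actbMean, config@actbSd),
                   3, nAll, dimnames = list(names(map), ids))
    fail <- matrix(stats::runif(3 * nAll) < config@actbFailureRate, 3, nAll)
    actb[fail] <- stats::runif(sum(fail), 32.5, 36)

    rows <- vector("list", nAll * 3)
    k <- 0L
    for (i in seq_len(nAll)) {
      for (mx in names(map)) {
        tg <- map[[mx]]
        tct <- actb[mx, i] - (truth[tg, i] - log2(100))
        tct[tct > config@ctDetectionLimit] <- NA
        tct[tct < 1] <- 1  # assay saturation: no signal before cycle 1
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample_id = ids[i], multiplex_id = mx,
          target = c(tg, "ACTB"), ct = c(tct, actb[mx, i]),
          stringsAsFactors = FALSE
        )
      }
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    list(ct = ct, clinical = clinical, truth = truth)
  })
}

#' Inject sporadic reference-gene QC failures
#'
#' For each (sample, multiplex) independently, with the given probability,
#' replaces the ACTB Ct by a draw above the QC limit; all other values are
#' untouched.
#'
#' @param ct long-format Ct data.frame.
#' @param rate failure probability in \[0, 1\].
#' @param seed integer RNG seed.
#' @return The modified Ct data.frame.
#' @export
injectQcFailures <- function(ct, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(ct)
  .withSeed(seed, {
    key <- unique(ct[, c("sample_id", "multiplex_id")])
    hit <- stats::runif(nrow(key)) < rate
    for (j in which(hit)) {
      sel <- ct$sample_id == key$sample_id[j] &
        ct$multiplex_id == key$multiplex_id[j] & ct$target == "ACTB"
      ct$ct[sel] <- stats::runif(sum(sel), 32.5, 36)
    }
    ct
  })
}

#' Write a simulated cohort to CSV
#'
#' Emits `ct_table.csv` and `clinical.csv` in the dialects consumed by
#' [readCtTable()] and [readClinicalTable()], with the generating seed
#' recorded in a header comment.
#'
#' @param cohort list as returned by [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param seed seed to record in the header comment.
#' @return The two file paths, invisibly.
#' @export
writeCohort <- function(cohort, dir, seed = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("ct_table.csv", "clinical.csv"))
  for (i in 1:2) {
    df <- if (i == 1) cohort$ct else cohort$clinical
    con <- file(paths[i], "w")
    writeLines(sprintf("# generated by qmspPanel simulateCohort; seed: %s",
                       seed), con)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    close(con)
  }
  invisible(paths)
}
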