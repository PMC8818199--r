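test_that("LOOCV runs one fold per sample and nails perfect separation", {
  cfg <- cohortConfig(nCases = 20, nControls = 20, delta = 6, burdenSd = 0,
                      gradeMultiplier = 1, stageMultiplier = 1,
                      recurrenceMultiplier = 1, femaleDilution = 1,
                      actbFailureRate = 0, ctDetectionLimit = Inf, seed = 9)
  sim <- simulateCohort(cfg)
  mps <- suppressMessages(buildProfiles(sim$ct, clinical = sim$clinical))
  expect_warning(lo <- loocvPanel(mps), "degenerate")  # AUC exactly 1
  expect_equal(lo$n_folds, 40)
  expect_equal(lo$performance$sensitivity$estimate, 1)
  expect_equal(lo$performance$specificity$estimate, 1)
  expect_equal(lo$auc, 1)
})

test_that("the out-of-fold call is invariant to the left-out label", {
  set.seed(14)
  n <- 30
  mps <- makeMps(n, values = list(
    GHSR = c(rlnorm(15, 1.5), rlnorm(15)),
    MAL = c(rlnorm(15, 1), rlnorm(15))
  ))
  lab <- rep(c("case", "control"), each = 15)
  lo <- loocvPanel(mps, lab)
  for (i in c(1, 8, 16, 30)) {
    flipped <- lab
    flipped[i] <- ifelse(lab[i] == "case", "control", "case")
    lo2 <- loocvPanel(mps, flipped)
    expect_identical(lo2$calls[i], lo$calls[i])
    expect_identical(lo2$scores[i], lo$scores[i])
  }
})

test_that("LOOCV on permuted labels is at chance level", {
  set.seed(55)
  n <- 200
  mps <- makeMps(n, values = list(GHSR = rlnorm(n, 1, 1.5),
                                  MAL = rlnorm(n, 0.5, 1.5)))
  aucs <- replicate(6, {
    lab <- sample(rep(c("case", "control"), each = 100))
    loocvPanel(mps, lab)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("resubstitution is optimistic relative to LOOCV on average", {
  set.seed(71)
  gap <- replicate(60, {
    n <- 30
    mps <- makeMps(2 * n, values = list(
      GHSR = c(rlnorm(n, 0.8), rlnorm(n)),
      MAL = c(rlnorm(n, 0.6), rlnorm(n))
    ))
    lab <- rep(c("case", "control"), each = n)
    model <- fitPanelModel(mps, lab)
    perf <- panelPerformance(classifyPanel(mps, model), lab)
    lo <- loocvPanel(mps, lab)
    (perf$sensitivity$estimate + perf$specificity$estimate) -
      (lo$performance$sensitivity$estimate +
         lo$performance$specificity$estimate)
  })
  expect_gt(mean(gap), 0)
})

test_that("the 2x2 chi-square is Pearson without continuity correction", {
  # the baseline gender table: p rounds to 0.12, not the corrected 0.155
  tab <- matrix(c(79, 63, 29, 37), 2)
  res <- chiSquare2x2(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(round(res$p, 2), 0.12)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.15)  # corrected: no

  expect_equal(chiSquare2x2(matrix(c(10, 10, 5, 5), 2))$statistic, 0)
  expect_equal(chiSquare2x2(matrix(c(10, 10, 5, 5), 2))$p, 1)
  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2)), "zero marginal")

  # direct-formula oracle on random tables
  set.seed(2)
  for (i in 1:20) {
    tab <- matrix(sample(5:40, 4, replace = TRUE), 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chiSquare2x2(tab)$statistic, sum((tab - e)^2 / e),
                 tolerance = 1e-10)
  }
})

test_that("subgroup sensitivities partition the determinate cases", {
  cfg <- cohortConfig(seed = 33)
  sim <- simulateCohort(cfg)
  mps <- suppressMessages(buildProfiles(sim$ct, clinical = sim$clinical))
  model <- fitPanelModel(mps)
  calls <- classifyPanel(mps, model)
  tab <- subgroupSensitivity(calls, sim$clinical)
  nDet <- tab$n[tab$partition == "all"]
  for (p in c("grade_1973", "grade_2004", "stage", "status", "gender")) {
    expect_equal(sum(tab$n[tab$partition == p]), nDet)
  }
  expect_true(all(tab$lower <= tab$sensitivity & tab$sensitivity <= tab$upper))
})

test_that("all-positive cases give unit sensitivity and p = 1 everywhere", {
  cl <- simulateCohort(cohortConfig(nCases = 30, nControls = 10,
                                    seed = 4))$clinical
  calls <- factor(rep("positive", 40),
                  levels = c("negative", "positive", "indeterminate"))
  tab <- subgroupSensitivity(calls, cl)
  expect_true(all(tab$sensitivity == 1))
  expect_true(all(tab$p_value[tab$partition != "all"] == 1, na.rm = TRUE))
})

test_that("a muscle-invasive effect raises sensitivity in >=T2 tumours", {
  cfg <- cohortConfig(nCases = 300, nControls = 300, delta = 1.2,
                      burdenSd = 0, gradeMultiplier = 1, stageMultiplier = 2.5,
                      recurrenceMultiplier = 1, femaleDilution = 1,
                      actbFailureRate = 0, ctDetectionLimit = Inf, seed = 41)
  sim <- simulateCohort(cfg)
  mps <- suppressMessages(buildProfiles(sim$ct, clinical = sim$clinical))
  calls <- classifyPanel(mps, fitPanelModel(mps))
  tab <- subgroupSensitivity(calls, sim$clinical)
  st <- tab[tab$partition == "stage", ]
  expect_gt(st$sensitivity[st$stratum == ">=T2"],
            st$sensitivity[st$stratum == "Ta/T1/Tis"])
})

test_that("gender strata are evaluated with their own thresholds", {
  cfg <- cohortConfig(nCases = 300, nControls = 300, delta = 1.6,
                      burdenSd = 0, gradeMultiplier = 1, stageMultiplier = 1,
                      recurrenceMultiplier = 1, femaleDilution = 0.4,
                      actbFailureRate = 0, ctDetectionLimit = Inf, seed = 61)
  sim <- simulateCohort(cfg)
  mps <- suppressMessages(buildProfiles(sim$ct, clinical = sim$clinical))
  gs <- genderStratifiedEval(mps)
  expect_gt(gs$male$auc, gs$female$auc)
  pooled <- fitPanelModel(mps)
  expect_false(identical(gs$male$model@thresholds, pooled@thresholds))
  expect_false(identical(gs$female$model@thresholds, pooled@thresholds))
  expect_equal(gs$male$model@stratum, "male")
  expect_s3_class(gs$female$loocv$calls, "factor")
})

test_that("without dilution the gender strata are indistinguishable", {
  cfg <- cohortConfig(nCases = 300, nControls = 300, delta = 1.6,
                      burdenSd = 0, gradeMultiplier = 1, stageMultiplier = 1,
                      recurrenceMultiplier = 1, femaleDilution = 1,
                      actbFailureRate = 0, ctDetectionLimit = Inf, seed = 62)
  sim <- simulateCohort(cfg)
  mps <- suppressMessages(buildProfiles(sim$ct, clinical = sim$clinical))
  gs <- genderStratifiedEval(mps)
  expect_lt(abs(gs$male$auc - gs$female$auc), 0.08)
})
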