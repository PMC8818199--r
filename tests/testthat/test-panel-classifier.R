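test_that("Youden thresholds maximize J with the documented tie-break", {
  yt <- youdenThreshold(c(5, 6, 7, 1, 2, 6),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(yt$threshold, 3.5)
  expect_equal(yt$j, 2 / 3, tolerance = 1e-12)

  # disjoint supports: the midpoint of the gap, J = 1
  yt <- youdenThreshold(c(10, 12, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(yt$threshold, 6)
  expect_equal(yt$j, 1)

  # J ties resolve towards specificity, then the larger cut: with equal J
  # at 1.5 (sens 1, spec 1/2) and 2.5 (sens 1/2, spec 1) pick 2.5
  yt <- youdenThreshold(c(1, 3, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(yt$threshold, 2.5)
  expect_error(youdenThreshold(1:4, rep(FALSE, 4)), "both cases and controls")
})

test_that("the attained J equals the exhaustive-search maximum", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    s <- sample(1:8, n, replace = TRUE)  # heavy ties
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(lab) || !any(lab)) next
    yt <- youdenThreshold(s, lab)
    expect_equal(yt$j, bruteMaxJ(s, lab), tolerance = 1e-12)
    # flipped orientation: best J on negated scores matches its own oracle
    yt2 <- youdenThreshold(-s, !lab)
    expect_equal(yt2$j, bruteMaxJ(-s, !lab), tolerance = 1e-12)
  }
})

test_that("believe-the-positive classification follows the truth table", {
  model <- methods::new("PanelModel", markers = c("GHSR", "MAL"),
                        thresholds = c(GHSR = 5, MAL = 5),
                        rule = "believe-the-positive", stratum = "all")
  mps <- makeMps(
    5,
    values = list(GHSR = c(10, 1, 1, 10, 1), MAL = c(1, 10, 1, 1, 1)),
    invalid = list(MAL = 4, GHSR = 5)
  )
  calls <- classifyPanel(mps, model)
  expect_equal(as.character(calls),
               c("positive",       # GHSR positive, MAL negative
                 "positive",       # MAL positive
                 "negative",       # both valid, both negative
                 "positive",       # MAL invalid but GHSR already positive
                 "indeterminate")) # GHSR invalid, MAL negative
})

test_that("the panel score is a max-margin score consistent with the call", {
  model <- methods::new("PanelModel", markers = c("GHSR", "MAL"),
                        thresholds = c(GHSR = 4, MAL = 8),
                        rule = "believe-the-positive", stratum = "all")
  mps <- makeMps(4, values = list(GHSR = c(4, 1, 500, 2),
                                  MAL = c(8, 1, 0.01, 2)))
  sc <- panelScore(mps, model)
  expect_equal(unname(sc[1]), 0)            # both exactly at threshold
  expect_lt(sc[2], 0)
  expect_gt(sc[3], 5)                       # far above, other marker ignored
  calls <- classifyPanel(mps, model)
  expect_equal(unname(sc >= 0), unname(calls == "positive"))
  # the OR decision is invariant to the log-transform offset
  for (eps in c(1e-6, 1e-4, 1e-1)) {
    expect_equal(unname(panelScore(mps, model, epsilon = eps) >= 0),
                 unname(calls == "positive"))
  }
})

test_that("Clopper-Pearson intervals match their closed forms and binom.test", {
  ci <- clopperPearsonCi(23, 23)
  expect_equal(ci$estimate, 1)
  expect_equal(ci$lower, 0.025^(1 / 23), tolerance = 1e-10)
  expect_equal(ci$upper, 1)
  ci0 <- clopperPearsonCi(0, 30)
  expect_equal(ci0$upper, 1 - 0.025^(1 / 30), tolerance = 1e-10)
  expect_equal(ci0$lower, 0)
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:120, 1)
    x <- sample(0:n, 1)
    ci <- clopperPearsonCi(x, n)
    ref <- stats::binom.test(x, n)$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("panel performance reports counts and exact intervals", {
  calls <- factor(rep(c("positive", "negative", "positive", "negative",
                        "indeterminate"),
                      c(86, 22, 7, 93, 4)),
                  levels = c("negative", "positive", "indeterminate"))
  labels <- rep(c("case", "control", "case"), c(108, 100, 4))
  perf <- panelPerformance(calls, labels)
  expect_equal(perf$tp, 86)
  expect_equal(perf$fn, 22)
  expect_equal(perf$sensitivity$estimate, 86 / 108)
  expect_equal(sprintf("%.2f", perf$sensitivity$estimate), "0.80")
  expect_equal(perf$specificity$estimate, 93 / 100)
  expect_equal(perf$n_indeterminate, 4)
  expect_true(perf$sensitivity$lower <= perf$sensitivity$estimate &&
                perf$sensitivity$estimate <= perf$sensitivity$upper)
  expect_error(panelPerformance(calls[1:86], labels[1:86]), "determinate")
})

test_that("the panel dominates its members in sensitivity, not specificity", {
  set.seed(77)
  for (i in 1:20) {
    n <- 60
    ghsr <- c(rlnorm(30, 2, 1), rlnorm(30, 0, 1))
    mal <- c(rlnorm(30, 1.5, 1), rlnorm(30, 0, 1))
    lab <- rep(c(TRUE, FALSE), each = 30)
    mps <- makeMps(n, values = list(GHSR = ghsr, MAL = mal))
    model <- fitPanelModel(mps, lab)
    calls <- classifyPanel(mps, model)
    panelSens <- mean(calls[lab] == "positive")
    panelSpec <- mean(calls[!lab] == "negative")
    for (mk in c("GHSR", "MAL")) {
      mkPos <- ratios(mps)[mk, ] >= model@thresholds[mk]
      expect_gte(panelSens, mean(mkPos[lab]))
      expect_lte(panelSpec, mean(!mkPos[!lab]))
    }
  }
})

test_that("panel models serialize with both threshold scales", {
  model <- methods::new("PanelModel", markers = c("GHSR", "MAL"),
                        thresholds = c(GHSR = 2.5, MAL = 0.8),
                        rule = "believe-the-positive", stratum = "male")
  js <- jsonlite::fromJSON(panelModelToJson(model))
  expect_equal(js$markers, c("GHSR", "MAL"))
  expect_equal(js$thresholds_ratio$GHSR, 2.5)
  expect_equal(js$thresholds_log2$MAL, log2(0.8 + 1e-4))
  expect_equal(js$stratum, "male")
  # the rule is immutable
  expect_error(methods::new("PanelModel", markers = "GHSR",
                            thresholds = c(GHSR = 1), rule = "majority",
                            stratum = "all"), "believe-the-positive")
})
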