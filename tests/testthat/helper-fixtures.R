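# programmatic fixtures: long-format Ct rows and ready-made profile sets

# rows for one (sample, multiplex): three targets plus ACTB
ctRows <- function(sample, mx, actb, targets = NULL) {
  mk <- qmspMultiplexMap()[[mx]]
  if (is.null(targets)) targets <- stats::setNames(rep(28, 3), mk)
  data.frame(
    sample_id = sample, multiplex_id = mx,
    target = c(names(targets), "ACTB"),
    ct = c(unname(targets), actb),
    stringsAsFactors = FALSE
  )
}

# complete three-multiplex Ct rows for one sample
fullSampleCt <- function(sample, actb = c(A = 26, B = 26, C = 26),
                         targetCt = 28) {
  do.call(rbind, lapply(names(qmspMultiplexMap()), function(mx) {
    mk <- qmspMultiplexMap()[[mx]]
    ctRows(sample, mx, actb[[mx]], stats::setNames(rep(targetCt, 3), mk))
  }))
}

# MethProfileSet with chosen per-marker ratios; invalidity propagates to
# the whole multiplex, mirroring the QC contract
makeMps <- function(n, values = list(), invalid = list(), colData = NULL) {
  mk <- qmspMarkers()
  ratio <- matrix(1, 9, n, dimnames = list(mk, sprintf("s%03d", seq_len(n))))
  for (m in names(values)) ratio[m, ] <- values[[m]]
  valid <- matrix(TRUE, 9, n, dimnames = dimnames(ratio))
  for (m in names(invalid)) valid[m, invalid[[m]]] <- FALSE
  mux <- vapply(mk, function(m) {
    names(which(vapply(qmspMultiplexMap(), function(z) m %in% z, logical(1))))
  }, character(1))
  for (g in unique(mux)) {
    rows <- mk[mux == g]
    bad <- apply(!valid[rows, , drop = FALSE], 2, any)
    valid[rows, bad] <- FALSE
  }
  ratio[!valid] <- NA
  MethProfileSet(ratio, valid, colData = colData)
}

# brute-force pairwise AUC: P(case > control) + 0.5 P(tie)
pairwiseAuc <- function(scores, case) {
  x <- scores[case]
  y <- scores[!case]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive Youden maximum over every achievable classification
bruteMaxJ <- function(scores, case) {
  cuts <- c(sort(unique(scores)), Inf)
  max(vapply(cuts, function(t) {
    mean(scores[case] >= t) + mean(scores[!case] < t) - 1
  }, numeric(1)))
}
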