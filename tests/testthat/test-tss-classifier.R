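test_that("column tests agree with the reference implementations", {
  withr::local_seed(41)
  x <- matrix(rnorm(30 * 25, 0.3, 0.1), 30, 25)
  x[sample(length(x), 60)] <- NA
  x[, 25] <- round(x[, 25], 1)           # force ties
  x[, 24] <- 0.3                         # constant column
  g <- rep(c(TRUE, FALSE), c(14, 16))
  pa <- methscreen:::colAnovaP(x, g)
  pw <- methscreen:::colWilcoxP(x, g)
  for (j in c(1:5, 24, 25)) {
    ok <- !is.na(x[, j])
    if (j == 24) {
      expect_equal(pa[j], 1)
      expect_equal(pw[j], 1)
      next
    }
    ref <- oneway.test(x[ok, j] ~ g[ok], var.equal = TRUE)$p.value
    expect_equal(pa[j], ref, tolerance = 1e-12)
    refW <- suppressWarnings(
      wilcox.test(x[ok & g, j], x[ok & !g, j], exact = FALSE,
                  correct = TRUE))$p.value
    expect_equal(pw[j], refW, tolerance = 1e-12)
  }
})

test_that("feature selection keeps separated promoters, drops flat ones", {
  x <- cbind(disjoint = c(rep(0.2, 8), rep(0.6, 8)),
             flat = rep(0.4, 16),
             noise = c(0.31, 0.29, 0.33, 0.30, 0.28, 0.32, 0.31, 0.30,
                       0.30, 0.32, 0.29, 0.31, 0.33, 0.28, 0.30, 0.31))
  rownames(x) <- sprintf("E%02d", 1:16)
  labels <- rep(c(1L, 0L), each = 8)
  fs <- selectFeatures(x, labels)
  expect_true("disjoint" %in% fs$features)
  expect_false("flat" %in% fs$features)
  expect_true(all(pmin(fs$p_anova, fs$p_wilcox)[fs$features] < 0.05))
  expect_error(selectFeatures(x, rep(1L, 16)), "both outcome")
})

test_that("null promoters are selected at roughly the nominal rate", {
  rates <- vapply(1:20, function(r) {
    d <- shiftedMatrix(20, 20, 500, 0, 0, seed = 600 + r)
    length(selectFeatures(d$x, d$labels)$features) / 500
  }, numeric(1))
  expect_gte(mean(rates), 0.01)
  expect_lte(mean(rates), 0.12)
})

test_that("the ensemble scorer is deterministic and well-bounded", {
  d <- shiftedMatrix(25, 25, 60, 10, 0.15, seed = 43)
  sc1 <- fitScorer(d$x, d$labels, nRepeats = 12, seed = 5)
  sc2 <- fitScorer(d$x, d$labels, nRepeats = 12, seed = 5)
  p1 <- tssScore(sc1, d$x)
  expect_identical(p1, tssScore(sc2, d$x))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_length(sc1@models, 12)
  expect_error(fitScorer(d$x, d$labels, nRepeats = 10),
               "more than 10")
  # brute-force average over ensemble members
  xf <- d$x[, sc1@features, drop = FALSE]
  med <- apply(xf, 2, median, na.rm = TRUE)
  for (j in seq_len(ncol(xf))) xf[is.na(xf[, j]), j] <- med[j]
  manual <- rowMeans(vapply(sc1@models, function(m)
    as.numeric(predict(m, xgboost::xgb.DMatrix(xf, nthread = 1))),
    numeric(nrow(xf))))
  expect_equal(unname(p1), unname(manual))
})

test_that("scoring imputes unknown features instead of rejecting them", {
  d <- shiftedMatrix(20, 20, 40, 8, 0.2, seed = 44)
  sc <- fitScorer(d$x, d$labels, nRepeats = 12, seed = 2)
  # drop half the model's features from the query matrix
  drop <- sc@features[seq_len(ceiling(length(sc@features) / 2))]
  xq <- d$x[, setdiff(colnames(d$x), drop), drop = FALSE]
  p <- tssScore(sc, xq)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(p, nrow(d$x))
  # a degenerate ensemble without subsampling has identical members,
  # so the average equals a single member's output
  scFull <- fitScorer(d$x, d$labels, nRepeats = 12, seed = 2,
                      params = list(subsample = 1))
  pAll <- tssScore(scFull, d$x)
  xf <- d$x[, scFull@features, drop = FALSE]
  one <- as.numeric(predict(scFull@models[[1]],
                            xgboost::xgb.DMatrix(xf, nthread = 1)))
  expect_equal(unname(pAll), one)
})

test_that("cross-validation gives every embryo all repeats out of fold", {
  d <- shiftedMatrix(20, 20, 60, 10, 0.15, seed = 45)
  cv <- crossValidatedScores(d$x, d$labels, nRepeats = 12, folds = 5,
                             seed = 3)
  expect_false(anyNA(cv$perRepeat))
  expect_equal(dim(cv$perRepeat), c(40L, 12L))
  expect_equal(unname(cv$scores), unname(rowMeans(cv$perRepeat)))
  cv2 <- crossValidatedScores(d$x, d$labels, nRepeats = 12, folds = 5,
                              seed = 3)
  expect_identical(cv$scores, cv2$scores)
  expect_gt(cv$auc, 0.8)  # strongly separated planted signal
})

test_that("whole-set feature selection leaks and inflates null AUC", {
  aucs <- vapply(1:6, function(r) {
    d <- shiftedMatrix(18, 18, 300, 0, 0, seed = 700 + r)
    proper <- crossValidatedScores(d$x, d$labels, nRepeats = 12,
                                   seed = r)$auc
    leakedFeatures <- selectFeatures(d$x, d$labels)$features
    leaked <- crossValidatedScores(d$x, d$labels, nRepeats = 12,
                                   seed = r,
                                   features = leakedFeatures)$auc
    c(proper, leaked)
  }, numeric(2))
  expect_gt(mean(aucs[2, ]) - mean(aucs[1, ]), 0.1)
  expect_gt(mean(aucs[2, ]), 0.65)  # leakage looks like signal
  expect_lt(abs(mean(aucs[1, ]) - 0.5), 0.15)
})

test_that("noise probabilities follow |label - prediction|", {
  expect_equal(noiseProbability(1L, 0.9), 0.1)
  expect_equal(noiseProbability(0L, 0.9), 0.9)
  expect_equal(noiseProbability(c("Birth", "Failed"), c(0.7, 0.7)),
               c(0.3, 0.7))
  expect_error(noiseProbability(1L, 1.2), "scores")
})

test_that("noise cleaning removes one failed embryo per iteration", {
  d <- shiftedMatrix(22, 22, 60, 12, 0.2, seed = 46)
  # plant two flipped labels: truly high-signal embryos recorded failed
  labels <- d$labels
  labels[c(1, 2)] <- 0L
  res <- cleanNoise(d$x, labels, maxRemovals = 3, nRepeats = 12,
                    seed = 9)
  expect_equal(nrow(res$history), 3)
  expect_equal(res$history$iteration, 1:3)
  expect_length(res$keepIds, nrow(d$x) - 3)
  # only failed-labelled embryos are ever removed
  failedIds <- rownames(d$x)[labels == 0L]
  expect_true(all(res$history$embryo_id %in% failedIds))
  expect_equal(nrow(res$aucCurve), 4)   # learning curve incl. start
  expect_true(all(res$history$noise_probability >= 0 &
                    res$history$noise_probability <= 1))
  # identity case: nothing removed, empty history
  res0 <- cleanNoise(d$x, labels, maxRemovals = 0, nRepeats = 12,
                     seed = 9)
  expect_equal(nrow(res0$history), 0)
  expect_identical(res0$keepIds, rownames(d$x))
  expect_error(cleanNoise(d$x, rep(c(1L, 0L), c(41, 3)),
                          maxRemovals = 5), "smaller than the failed")
})

test_that("AUC estimator handles ties and matches an oracle", {
  expect_equal(rankAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(rankAuc(c(0.5, 0.5, 0.5, 0.5), c(1, 1, 0, 0)), 0.5)
  withr::local_seed(47)
  scores <- round(runif(60), 1)  # plenty of ties
  labels <- rbinom(60, 1, 0.5)
  # pairwise oracle with half-credit for ties
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b))
  expect_equal(rankAuc(scores, labels), mean(cmp))
  expect_equal(rankAuc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(
                 labels, scores, quiet = TRUE,
                 levels = c(0, 1), direction = "<"))))
})
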