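test_that("promoters must be covered in 10% of both groups", {
  # 20 embryos: 11 birth, 9 failed; promoter 1 covered in 1/11 birth
  # (9%) but most failed; promoter 2 covered everywhere; promoter 3
  # covered in exactly 10% of neither group
  outcomes <- c(rep("Birth", 11), rep("Failed", 9))
  meth <- matrix(0.3, 3, 20)
  meth[1, 2:11] <- NA           # birth coverage 1/11 < 10%
  meth[1, 12:16] <- NA          # failed coverage 4/9 ~ 44%
  meth[3, c(1:9, 12:19)] <- NA  # birth 2/11, failed 1/9 ~ 11%
  cov <- matrix(100L, 3, 20); cov[is.na(meth)] <- 0L
  ms <- toyMset(meth, outcomes, coverage = cov, minCoverage = 1)
  kept <- filterCoveredPromoters(ms, minFraction = 0.10)
  expect_false("prom01" %in% kept)
  expect_true("prom02" %in% kept)
  expect_true("prom03" %in% kept)
  # hand count on a random masking pattern
  withr::with_seed(31, {
    meth2 <- matrix(runif(10 * 20, 0.1, 0.9), 10, 20)
    meth2[sample(length(meth2), 120)] <- NA
  })
  cov2 <- matrix(100L, 10, 20); cov2[is.na(meth2)] <- 0L
  ms2 <- toyMset(meth2, outcomes, coverage = cov2, minCoverage = 1)
  kept2 <- filterCoveredPromoters(ms2, minFraction = 0.10)
  byHand <- rownames(methLevels(ms2))[
    rowSums(!is.na(meth2[, 1:11])) / 11 >= 0.10 &
      rowSums(!is.na(meth2[, 12:20])) / 9 >= 0.10]
  expect_identical(kept2, byHand)
  expect_error(filterCoveredPromoters(ms, labels = setNames(
    rep("Birth", 20), colnames(methLevels(ms)))), "both clinical")
})

test_that("AM/RM calls follow the dual-threshold rule", {
  # one birth baseline promoter with mean 0.25 and controlled sd
  buildCase <- function(value, sds) {
    # 5 birth embryos engineered to a target mean/sd, 1 failed embryo
    # c(-1,-1,0,1,1) has mean 0 and sample sd exactly 1
    bvals <- 0.25 + sds * c(-1, -1, 0, 1, 1)
    meth <- matrix(c(bvals, value), 1, 6)
    toyMset(meth, c(rep("Birth", 5), "Failed"))
  }
  ms <- buildCase(0.40, 0.04)
  bl <- promoterBaselines(ms)
  expect_equal(bl$mean_birth, 0.25)
  expect_equal(bl$sd_birth, 0.04)
  calls <- callEpimutations(ms, bl)
  f <- calls[calls$embryo_id == "E06", ]
  expect_equal(f$am, 0.15)
  expect_equal(f$rm, 3.75)
  expect_true(f$is_epimutation)

  f <- with(callEpimutations(buildCase(0.40, 0.06),
                             promoterBaselines(buildCase(0.40, 0.06))),
            data.frame(am, rm, is_epimutation)[6, ])
  expect_equal(f$am, 0.15)
  expect_equal(f$rm, 2.5)
  expect_false(f$is_epimutation)  # RM fails

  ms3 <- buildCase(0.34, 0.01)
  f <- callEpimutations(ms3, promoterBaselines(ms3))[6, ]
  expect_equal(f$am, 0.09)
  expect_equal(f$rm, 9)
  expect_false(f$is_epimutation)  # AM fails
})

test_that("a zero-variance baseline reduces the call to AM alone", {
  meth <- matrix(c(0.25, 0.25, 0.25, 0.25, 0.40, 0.30), 1, 6)
  ms <- toyMset(meth, c(rep("Birth", 4), "Failed", "Failed"))
  bl <- promoterBaselines(ms)
  expect_equal(bl$sd_birth, 0)
  calls <- callEpimutations(ms, bl)
  expect_equal(calls$rm[calls$embryo_id == "E05"], Inf)
  expect_true(calls$is_epimutation[calls$embryo_id == "E05"])
  expect_false(calls$is_epimutation[calls$embryo_id == "E06"])  # AM 0.05
  expect_equal(calls$rm[calls$embryo_id == "E01"], 0)  # AM exactly 0
})

test_that("the epimutation flag is monotone in AM and RM", {
  withr::local_seed(33)
  for (i in 1:20) {
    am <- runif(2, 0, 0.3); rm_ <- runif(2, 0, 6)
    flag <- function(a, r) a > 0.1 && r > 3
    if (am[1] <= am[2])
      expect_lte(flag(am[1], rm_[1]), flag(am[2], rm_[1]))
    if (rm_[1] <= rm_[2])
      expect_lte(flag(am[1], rm_[1]), flag(am[1], rm_[2]))
  }
})

test_that("embryo frequencies are epimutation counts over coverage", {
  calls <- data.frame(
    embryo_id = rep(c("A", "B"), c(100, 50)),
    promoter_id = c(sprintf("p%03d", 1:100), sprintf("p%03d", 1:50)),
    am = 0, rm = 0,
    is_epimutation = c(rep(c(TRUE, FALSE), c(2, 98)),
                       rep(FALSE, 50)))
  freq <- embryoEpimutationFrequency(calls)
  expect_equal(freq[["A"]], 0.02)
  expect_equal(freq[["B"]], 0)
  # recount oracle on a shuffled toy call set
  withr::with_seed(34, {
    toy <- data.frame(embryo_id = sample(c("A", "B", "C"), 60, TRUE),
                      promoter_id = sprintf("p%02d", sample(60)),
                      am = 0, rm = 0,
                      is_epimutation = runif(60) < 0.3)
  })
  freq <- embryoEpimutationFrequency(toy)
  for (id in c("A", "B", "C")) {
    sub <- toy[toy$embryo_id == id, ]
    expect_equal(freq[[id]], sum(sub$is_epimutation) / nrow(sub))
  }
  expect_error(embryoEpimutationFrequency(calls[0, ]), "no covered")
})

test_that("group frequencies count epimutated over covered embryos", {
  calls <- data.frame(
    embryo_id = sprintf("E%02d", 1:20),
    promoter_id = "prom01", am = 0, rm = 0,
    is_epimutation = c(rep(FALSE, 10), rep(c(TRUE, FALSE), c(3, 7))))
  labels <- setNames(rep(c("Birth", "Failed"), each = 10),
                     sprintf("E%02d", 1:20))
  freq <- promoterGroupFrequency(calls, labels)
  expect_equal(freq$failed_freq, 0.3)
  expect_equal(freq$birth_freq, 0)
  # symmetric relabeling swaps the two frequencies
  swapped <- setNames(ifelse(labels == "Birth", "Failed", "Birth"),
                      names(labels))
  freq2 <- promoterGroupFrequency(calls, swapped)
  expect_equal(freq2$birth_freq, freq$failed_freq)
  expect_equal(freq2$failed_freq, freq$birth_freq)
})

test_that("differential testing matches enumeration and is symmetric", {
  freq <- data.frame(promoter_id = "p1",
                     birth_epimutated = 0L, birth_covered = 10L,
                     failed_epimutated = 5L, failed_covered = 10L,
                     birth_freq = 0, failed_freq = 0.5)
  res <- differentialEpimutation(freq)
  expect_equal(res$diff, 0.5)
  expect_equal(res$p.value, fisherOracle(5, 5, 0, 10, "two.sided"))
  expect_true(res$higher_in_failed)
  # identical counts: difference 0, p = 1
  same <- data.frame(promoter_id = "p2",
                     birth_epimutated = 3L, birth_covered = 12L,
                     failed_epimutated = 3L, failed_covered = 12L,
                     birth_freq = 0.25, failed_freq = 0.25)
  res <- differentialEpimutation(same)
  expect_equal(res$diff, 0)
  expect_equal(res$p.value, 1)
  expect_false(res$higher_in_failed)
  # swapping groups negates the difference and preserves the p-value
  sw <- data.frame(promoter_id = "p1",
                   birth_epimutated = 5L, birth_covered = 10L,
                   failed_epimutated = 0L, failed_covered = 10L,
                   birth_freq = 0.5, failed_freq = 0)
  res1 <- differentialEpimutation(freq)
  res2 <- differentialEpimutation(sw)
  expect_equal(res2$diff, -res1$diff)
  expect_equal(res2$p.value, res1$p.value)
  # BH adjustment is available but off by default
  two <- rbind(freq, same)
  adj <- differentialEpimutation(two, adjust = TRUE)
  expect_equal(adj$p.adj, p.adjust(adj$p.value, "BH"))
})

test_that("planted cohorts show higher failed-group frequencies", {
  co <- generateCohort(signalConfig(77, n_patients = 110,
                                    n_promoters = 200))
  labels <- setNames(co$truth$true_outcome, co$truth$embryo_id)
  kept <- filterCoveredPromoters(co$mset, labels)
  bl <- promoterBaselines(co$mset, labels, kept)
  freq <- embryoEpimutationFrequency(callEpimutations(co$mset, bl))
  failed <- freq[names(labels)[labels == "Failed"]]
  birth <- freq[names(labels)[labels == "Birth"]]
  expect_gte(length(freq), 150)
  wt <- wilcox.test(failed, birth, alternative = "greater")
  expect_lt(wt$p.value, 0.05)
})

test_that("null cohorts keep the differential false-positive rate low", {
  fprs <- vapply(1:20, function(r) {
    co <- generateCohort(nullConfig(500 + r, n_patients = 40,
                                    n_promoters = 100))
    labels <- setNames(co$truth$recorded_outcome, co$truth$embryo_id)
    if (length(unique(labels)) < 2) return(NA_real_)
    kept <- filterCoveredPromoters(co$mset, labels)
    bl <- promoterBaselines(co$mset, labels, kept)
    calls <- callEpimutations(co$mset, bl)
    res <- differentialEpimutation(promoterGroupFrequency(calls, labels))
    mean(res$p.value < 0.05)
  }, numeric(1))
  expect_lte(mean(fprs, na.rm = TRUE), 0.08)
})
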