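test_that("nucleus classification matches the documented signal patterns", {
  expect_equal(as.character(classifyNuclei("chr9", 1, 2)), "TARGET_DELETED")
  expect_equal(as.character(classifyNuclei("chr9", 1, 1)), "MONOSOMY")
  expect_equal(as.character(classifyNuclei("chr19", 1, 1)), "UNINFORMATIVE")
  expect_equal(as.character(classifyNuclei("chr9", 2, 4)), "TARGET_DELETED")
  expect_equal(as.character(classifyNuclei("chr9", 3, 3)),
               "POLYSOMY_IMBALANCED")
  expect_equal(as.character(classifyNuclei("chr1", 2, 2)), "NORMAL")
  # truncation / artifact patterns are uninformative
  for (p in list(c(2, 1), c(1, 0), c(0, 4), c(0, 0), c(5, 0)))
    expect_equal(as.character(classifyNuclei("chr9", p[1], p[2])),
                 "UNINFORMATIVE", info = paste(p, collapse = ","))
  expect_error(classifyNuclei("chr9", -1, 2), "non-negative")
  expect_error(classifyNuclei("chr9", 1.5, 2), "non-negative")
})

test_that("classification is total on [0,10]^2 and agrees with brute force", {
  grid <- expand.grid(r = 0:10, g = 0:10)
  for (id in c("chr1", "chr9", "chr10", "chr19")) {
    rule <- chromPair(id)@monosomyRule
    got <- as.character(classifyNuclei(id, grid$r, grid$g))
    want <- mapply(bruteClassify, grid$r, grid$g,
                   MoreArgs = list(monosomyRule = rule))
    expect_false(anyNA(got))
    expect_equal(got, unname(want), info = id)
  }
})

test_that("sample summaries compute percentages over analyzable nuclei", {
  # 90 analyzable of 100: 60 deleted (1R/2G), 30 normal, 10 uninformative
  s <- summarizeSample("chr1", rep(c(1, 2, 0), c(60, 30, 10)),
                       rep(c(2, 2, 3), c(60, 30, 10)))
  expect_equal(nAnalyzable(s), 90L)
  expect_equal(pctDeleted(s), 100 * 60 / 90, tolerance = 1e-12)

  s2 <- summarizeSample("chr9", rep(2, 50), rep(2, 50))
  expect_equal(pctDeleted(s2), 0)
  expect_equal(pctImbalanced(s2), 0)

  # monosomy counts as deleted on chr9 but not on chr19
  s3 <- summarizeSample("chr9", rep(c(1, 2), c(50, 50)),
                        rep(c(1, 2), c(50, 50)))
  expect_equal(pctDeleted(s3), 50)
  expect_equal(pctMonosomy(s3), 50)
  s4 <- summarizeSample("chr19", rep(c(1, 2), c(50, 50)),
                        rep(c(1, 2), c(50, 50)))
  expect_equal(pctDeleted(s4), 0)
  expect_equal(nAnalyzable(s4), 50L)

  # zero analyzable nuclei: flagged, no percentages
  s5 <- summarizeSample("chr1", c(0, 2), c(0, 1))
  expect_equal(nAnalyzable(s5), 0L)
  expect_true(is.na(pctDeleted(s5)))
})

mkSummary <- function(chrom, del = 0, imb = 0, mono = 0, n = 100) {
  # build a summary with given percentages via explicit signal patterns
  stopifnot((del + imb + mono) <= 100)
  norm <- n - (del + imb + mono)
  r <- rep(c(1, 3, 1, 2), c(del, imb, mono, norm))
  g <- rep(c(2, 3, 1, 2), c(del, imb, mono, norm))
  summarizeSample(chrom, r, g)
}

test_that("arm status follows the cutoff decision order", {
  co <- defaultCutoffs()
  # clear deletion on chr1: 60 > 55, imbalance 5 <= 20
  expect_equal(armStatus(callArmStatus(mkSummary("chr1", del = 60, imb = 5), co)),
               "DELETED")
  # mixed-sum rule on chr10: 10 + 20 >= 25
  expect_equal(armStatus(callArmStatus(mkSummary("chr10", del = 10, imb = 20), co)),
               "IMBALANCED")
  # imbalance override beats deletion on chr1
  expect_equal(armStatus(callArmStatus(mkSummary("chr1", del = 60, imb = 25), co)),
               "IMBALANCED")
  # boundary: deletion rule is strict (55 is not > 55) but then the
  # mixed-sum rule (>= 55) fires
  expect_equal(armStatus(callArmStatus(mkSummary("chr1", del = 55), co)),
               "IMBALANCED")
  expect_equal(armStatus(callArmStatus(mkSummary("chr1", del = 54), co)),
               "NORMAL")
  # chr9 monosomy: 35% 1R/1G >= 30 flags the control arm; deleted 45 +
  # mono 35 = 80 > 30 makes the target arm deleted
  cl <- callArmStatus(mkSummary("chr9", del = 45, mono = 35), co)
  expect_equal(armStatus(cl), "DELETED")
  expect_true(controlArmDeleted(cl))
  # no control-arm flag outside the monosomy-rule chromosomes
  cl1 <- callArmStatus(mkSummary("chr1", del = 60), co)
  expect_false(controlArmDeleted(cl1))
  # no analyzable nuclei -> no call
  s0 <- summarizeSample("chr1", 0, 0)
  expect_error(callArmStatus(s0, co), "no analyzable")
})

test_that("raising the deleted percentage never downgrades a call", {
  co <- defaultCutoffs()
  rank <- c(NORMAL = 0, IMBALANCED = 1, DELETED = 1)
  for (imb in c(0, 10, 20)) {
    prev <- -1
    for (del in seq(0, 80, by = 5)) {
      st <- armStatus(callArmStatus(mkSummary("chr1", del = del, imb = imb), co))
      expect_gte(rank[[st]], prev)
      prev <- rank[[st]]
    }
  }
})

test_that("cutoff calibration is mean + 3 sample SD with a floor", {
  ctl <- data.frame(pctDeleted = c(10, 12, 8, 11, 9),
                    pctImbalanced = c(2, 2, 2, 2, 2))
  co <- calibrateCutoffs(list(chr9 = ctl))
  expect_equal(deletionCutoff(co, "chr9"), 10 + 3 * sd(c(10, 12, 8, 11, 9)),
               tolerance = 1e-12)
  expect_equal(deletionCutoff(co, "chr9"), 14.74342, tolerance = 1e-5)
  expect_equal(monosomyCutoff(co, "chr9"), deletionCutoff(co, "chr9"))
  expect_equal(cutoffSource(co), "calibrated")
  # degenerate all-zero controls clamp to the floor
  z <- data.frame(pctDeleted = c(0, 0, 0), pctImbalanced = c(0, 0, 0))
  expect_equal(deletionCutoff(calibrateCutoffs(list(chr1 = z), floor = 5),
                              "chr1"), 5)
  # fewer than 2 samples: SD undefined
  expect_error(calibrateCutoffs(list(chr9 = ctl[1, ])), ">= 2")
  # monotone in inputs and in their spread
  base <- deletionCutoff(calibrateCutoffs(list(chr9 = ctl)), "chr9")
  up <- ctl; up$pctDeleted <- up$pctDeleted + 2
  expect_gt(deletionCutoff(calibrateCutoffs(list(chr9 = up)), "chr9"), base)
  spread <- ctl; spread$pctDeleted <- 10 + 2 * (spread$pctDeleted - 10)
  expect_gt(deletionCutoff(calibrateCutoffs(list(chr9 = spread)), "chr9"), base)
})

test_that("QC flags low cell counts and uninformative excess at the stated boundaries", {
  pol <- qcPolicy(minAnalyzableCells = 50)
  s45 <- summarizeSample("chr1", rep(2, 45), rep(2, 45))
  expect_false(qcSample(s45, pol)$pass)
  expect_match(qcSample(s45, pol)$reason, "insufficient")
  s50 <- summarizeSample("chr1", rep(2, 50), rep(2, 50))
  expect_true(qcSample(s50, pol)$pass)
  s0 <- summarizeSample("chr1", 0, 0)
  expect_false(qcSample(s0, pol)$pass)
  # uninformative fraction rule, and QC failure does not suppress the call
  sU <- summarizeSample("chr1", rep(c(2, 0), c(60, 80)),
                        rep(c(2, 0), c(60, 80)))
  expect_false(qcSample(sU, pol)$pass)
  expect_match(qcSample(sU, pol)$reason, "uninformative")
  cl <- callArmStatus(sU, defaultCutoffs(), "chr1", pol)
  expect_equal(armStatus(cl), "NORMAL")
  expect_false(qcPass(cl))
})

test_that("callCohort calls every case/chromosome pair in a counts table", {
  counts <- rbind(
    data.frame(case_id = "a", chromosome = "chr1",
               simulateNuclei(clonesForState("deleted", 0.9),
                              detectionModel(), 200, seed = 7)),
    data.frame(case_id = "a", chromosome = "chr9",
               simulateNuclei(clonesForState("normal"),
                              detectionModel(), 200, seed = 8)))
  calls <- callCohort(counts)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$status[calls$chromosome == "chr1"], "DELETED")
  expect_equal(calls$status[calls$chromosome == "chr9"], "NORMAL")
  expect_true(all(calls$qc_pass))
})
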