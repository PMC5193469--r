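test_that("noise-free detection reproduces true karyotypes exactly", {
  perfect <- detectionModel(pDetect = 1, lambdaBackground = 0, pSplit = 0)
  nuc <- simulateNuclei(clonesForState("normal"), perfect, 50, seed = 1)
  expect_true(all(nuc$n_red == 2 & nuc$n_green == 2))
  nuc2 <- simulateNuclei(clones(1, 2, 1), perfect, 50, seed = 1)
  expect_true(all(nuc2$n_red == 1 & nuc2$n_green == 2))
})

test_that("simulation is reproducible under a seed", {
  m <- detectionModel()
  a <- simulateNuclei(clonesForState("deleted"), m, 100, seed = 11)
  b <- simulateNuclei(clonesForState("deleted"), m, 100, seed = 11)
  expect_identical(a, b)
  c1 <- simulateCohort(sizes = c(OII = 5, GBM = 5), seed = 3)
  c2 <- simulateCohort(sizes = c(OII = 5, GBM = 5), seed = 3)
  expect_identical(c1, c2)
})

test_that("dropout probabilities match binomial arithmetic", {
  # diploid, pDetect 0.9, no background/split:
  # P(observe (1,2)) = [2*0.9*0.1] * [0.81] = 0.1458
  m <- detectionModel(pDetect = 0.9, lambdaBackground = 0, pSplit = 0)
  n <- 10000
  nuc <- simulateNuclei(clonesForState("normal"), m, n, seed = 21)
  phat <- mean(nuc$n_red == 1 & nuc$n_green == 2)
  p <- 2 * 0.9 * 0.1 * 0.81
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  # mean observed count per channel = pDetect*(1+pSplit)*copies + lambda
  m2 <- detectionModel(pDetect = 0.9, lambdaBackground = 0.2, pSplit = 0.05)
  nuc2 <- simulateNuclei(clonesForState("normal"), m2, n, seed = 22)
  mu <- 0.9 * 1.05 * 2 + 0.2
  se <- sd(nuc2$n_red) / sqrt(n)
  expect_lt(abs(mean(nuc2$n_red) - mu), 4 * se)
})

test_that("invalid detection parameters and clone tables are rejected", {
  expect_error(detectionModel(pDetect = 0), "pDetect")
  expect_error(detectionModel(lambdaBackground = -1), "lambdaBackground")
  expect_error(clones(1, 2, c(0.5, 0.4)), "sum to 1")
  expect_error(clones(-1, 2, 1), "non-negative")
})

test_that("noise-free controls calibrate to the floor; noisy controls near routine cutoffs", {
  perfect <- detectionModel(pDetect = 1, lambdaBackground = 0, pSplit = 0)
  ctl <- simulateNormalControls("chr9", perfect, nSamples = 5,
                                nNuclei = 200, pDetectSD = 0, seed = 5)
  expect_true(all(vapply(ctl, pctDeleted, numeric(1)) == 0))
  co <- calibrateCutoffs(list(chr9 = ctl), floor = 5)
  expect_equal(deletionCutoff(co, "chr9"), 5)

  # at the default probe-specific noise the mean+3SD deletion cutoffs land
  # near the routine 30% (chr9) and 25% (chr10); consistency, not exactness
  reps <- vapply(1:20, function(i) {
    ctl9 <- simulateNormalControls("chr9", seed = 100 + i)
    ctl10 <- simulateNormalControls("chr10", seed = 300 + i)
    co <- calibrateCutoffs(list(chr9 = ctl9, chr10 = ctl10))
    c(deletionCutoff(co, "chr9"), deletionCutoff(co, "chr10"))
  }, numeric(2))
  expect_gt(mean(reps[1, ]), 24); expect_lt(mean(reps[1, ]), 36)
  expect_gt(mean(reps[2, ]), 19); expect_lt(mean(reps[2, ]), 31)
  expect_gt(mean(reps[1, ]), mean(reps[2, ]))  # 9p noisier than 10q
})

test_that("cohort generator reproduces the group profiles in expectation", {
  # every OII is truly 1p/19q codeleted
  oii <- simulateCohort(sizes = c(OII = 50), seed = 9)
  expect_true(all(oii$state_chr1 == "deleted" & oii$state_chr19 == "deleted"))
  # 9p loss (deletion or whole-chromosome loss) in ~70% of OIII
  oiii <- simulateCohort(sizes = c(OIII = 2000), seed = 10)
  frac <- mean(oiii$state_chr9 %in% c("deleted", "monosomy"))
  expect_lt(abs(frac - 0.70), 3 * sqrt(0.7 * 0.3 / 2000))
  # GBM always 9p-deleted
  gbm <- simulateCohort(sizes = c(GBM = 30), seed = 11)
  expect_true(all(gbm$state_chr9 == "deleted"))
  # zero hazard -> everyone censored
  pr <- defaultGroupProfiles()
  pr$OII$hazard <- 0; pr$OII$censorRate <- 0
  z <- simulateCohort(pr, sizes = c(OII = 20), seed = 12)
  expect_true(all(!z$event))
  expect_error(simulateCohort(list(), sizes = c(OII = 1)), "empty|named")
})

test_that("paired-call generator honours its confusion model", {
  labs <- c("DELETED", "IMBALANCED", "NORMAL")
  idm <- diag(3); dimnames(idm) <- list(labs, labs)
  truth <- sample(labs, 40, replace = TRUE)
  p <- simulatePairedCalls(truth, idm, seed = 31)
  expect_equal(p$manual, p$automated)
  expect_equal(kappaValue(cohensKappa(p)), 1)
  # uniform-random automated: kappa ~ 0 in expectation
  unif <- matrix(1 / 3, 3, 3, dimnames = list(labs, labs))
  ks <- vapply(1:200, function(i)
    kappaValue(cohensKappa(simulatePairedCalls(
      rep(labs, length.out = 60), unif, seed = 500 + i))), numeric(1))
  expect_lt(abs(mean(ks)), 3 * sd(ks) / sqrt(length(ks)))
})

test_that("the caller recovers simulated true arm states end to end", {
  cases <- simulateCohort(sizes = c(OII = 4, OIII = 4, AII = 2, AIII = 2,
                                    GBM = 3), seed = 41)
  counts <- simulateCaseCounts(cases, nNuclei = 500, cloneFraction = 0.85,
                               seed = 42)
  calls <- callCohort(counts)
  truth <- unlist(lapply(seq_len(nrow(cases)), function(i)
    vapply(c("chr1", "chr9", "chr10", "chr19"), function(ch)
      cases[[paste0("state_", ch)]][i], character(1))))
  key <- paste(rep(cases$case_id, each = 4),
               rep(c("chr1", "chr9", "chr10", "chr19"), nrow(cases)))
  calls <- calls[match(key, paste(calls$case_id, calls$chromosome)), ]
  want <- c(normal = "NORMAL", deleted = "DELETED",
            imbalanced = "IMBALANCED", monosomy = "DELETED")[truth]
  expect_gte(mean(calls$status == unname(want)), 0.95)
  # whole-chromosome losses flag the control arm
  mono <- truth == "monosomy"
  if (any(mono)) expect_true(all(calls$control_arm_deleted[mono]))
})
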