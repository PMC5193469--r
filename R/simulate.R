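#' DetectionModel constructor
#'
#' @param pDetect per-spot detection probability in (0, 1]. Missed spots
#'   stand in for nuclear truncation in 5-micron sections and local
#'   hybridisation failure.
#' @param lambdaBackground mean spurious background spots per channel per
#'   nucleus (Poisson).
#' @param pSplit probability a detected spot is counted as two.
#' @return a [DetectionModel-class].
#' @examples
#' detectionModel(pDetect = 0.9)
#' @export
detectionModel <- function(pDetect = 0.9, lambdaBackground = 0.01,
                           pSplit = 0.005) {
  new("DetectionModel", pDetect = pDetect,
      lambdaBackground = lambdaBackground, pSplit = pSplit)
}

## Per-chromosome detection models for diploid control tissue. pDetect is
## probe-specific: the 10q assay is the cleanest per-spot but shows more
## background, the 9p assay drops more spots. Chosen once so that mean+3SD
## calibration on diploid controls lands near the routine 9p/10q cutoffs;
## see the methods vignette.
CONTROL_PDETECT <- c(chr1 = 0.90, chr9 = 0.91, chr10 = 0.93, chr19 = 0.90)

#' Per-chromosome default detection model for control tissue
#'
#' @param chrom chromosome id or [ChromPair-class].
#' @return a [DetectionModel-class] with the probe-specific default
#'   detection probability.
#' @export
controlDetectionModel <- function(chrom) {
  id <- resolveChrom(chrom)@id
  detectionModel(pDetect = CONTROL_PDETECT[[id]])
}

#' Clone mixtures for canonical arm states
#'
#' A tumour is modelled as a mixture of cell clones, each with fixed true
#' copy numbers of the target and control arm. `clones()` builds a mixture
#' table; `clonesForState()` returns the canonical mixture for one true
#' arm state: a deleted tumour is `fraction` cells of karyotype (1 target,
#' 2 control) plus diploid admixture, monosomy is (1, 1), imbalance is
#' (3, 3) polysomy, and normal is pure diploid.
#'
#' @param copiesTarget,copiesControl,fraction equal-length vectors of true
#'   copy numbers and mixture fractions (fractions must sum to 1).
#' @param state one of `"normal"`, `"deleted"`, `"imbalanced"`,
#'   `"monosomy"`.
#' @return data frame with columns `copiesTarget`, `copiesControl`,
#'   `fraction`.
#' @examples
#' clonesForState("deleted", fraction = 0.8)
#' @export
clones <- function(copiesTarget, copiesControl, fraction) {
  if (any(copiesTarget < 0) || any(copiesControl < 0) ||
      any(copiesTarget != floor(copiesTarget)) ||
      any(copiesControl != floor(copiesControl)))
    abort("clones: copy numbers must be non-negative integers")
  if (abs(sum(fraction) - 1) > 1e-8 || any(fraction < 0))
    abort("clones: fractions must be non-negative and sum to 1")
  data.frame(copiesTarget = as.integer(copiesTarget),
             copiesControl = as.integer(copiesControl), fraction = fraction)
}

#' @rdname clones
#' @export
clonesForState <- function(state = c("normal", "deleted", "imbalanced",
                                     "monosomy"),
                           fraction = 0.85) {
  state <- match.arg(state)
  switch(state,
    normal = clones(2, 2, 1),
    deleted = clones(c(1, 2), c(2, 2), c(fraction, 1 - fraction)),
    monosomy = clones(c(1, 2), c(1, 2), c(fraction, 1 - fraction)),
    imbalanced = clones(c(3, 2), c(3, 2), c(fraction, 1 - fraction)))
}

## one channel through the detection process, vectorized over nuclei
observeChannel <- function(copies, model) {
  k <- stats::rbinom(length(copies), copies, model@pDetect)
  k <- k + stats::rbinom(length(k), k, model@pSplit)
  k + stats::rpois(length(k), model@lambdaBackground)
}

#' Simulate per-nucleus spot counts from a clonal mixture
#'
#' Each nucleus draws a clone according to the mixture fractions; each true
#' copy of each arm is then observed independently with probability
#' `pDetect`, counted twice with probability `pSplit`, and the channel
#' gains Poisson background spots. The expected observed count per channel
#' is `pDetect * (1 + pSplit) * copies + lambdaBackground`.
#'
#' @param cloneTable data frame from [clones()] / [clonesForState()].
#' @param model a [DetectionModel-class].
#' @param n number of nuclei.
#' @param seed optional integer seed for reproducibility.
#' @return data frame with columns `nucleus_id`, `n_red`, `n_green`.
#' @examples
#' simulateNuclei(clonesForState("deleted"), detectionModel(), 10, seed = 1)
#' @export
simulateNuclei <- function(cloneTable, model = detectionModel(), n,
                           seed = NULL) {
  stopifnot(is(model, "DetectionModel"))
  if (n < 1) abort("simulateNuclei: n must be >= 1")
  if (abs(sum(cloneTable$fraction) - 1) > 1e-8)
    abort("simulateNuclei: clone fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(cloneTable), n, replace = TRUE,
                    prob = cloneTable$fraction)
  data.frame(
    nucleus_id = seq_len(n),
    n_red = observeChannel(cloneTable$copiesTarget[idx], model),
    n_green = observeChannel(cloneTable$copiesControl[idx], model))
}

#' Simulate non-neoplastic control samples for cutoff calibration
#'
#' Generates pure diploid samples observed through the detection model and
#' summarizes each with [summarizeSample()]. Real control slides differ in
#' hybridisation efficiency, so the per-sample detection probability is
#' jittered around the model's `pDetect` (truncated normal, SD
#' `pDetectSD`); without this slide-to-slide component the between-sample
#' SD that drives the mean + 3 SD calibration would be implausibly small.
#'
#' @param chrom chromosome id or [ChromPair-class].
#' @param model a [DetectionModel-class]; defaults to the chromosome's
#'   control model.
#' @param nSamples number of control samples (>= 2; default 5).
#' @param nNuclei nuclei per sample (default 400).
#' @param pDetectSD slide-to-slide SD of the detection probability
#'   (default 0.015).
#' @param seed optional integer seed.
#' @return list of [SampleSummary-class], one per control sample.
#' @examples
#' ctl <- simulateNormalControls("chr9", nSamples = 5, seed = 1)
#' calibrateCutoffs(list(chr9 = ctl))
#' @export
simulateNormalControls <- function(chrom, model = controlDetectionModel(chrom),
                                   nSamples = 5, nNuclei = 400,
                                   pDetectSD = 0.015, seed = NULL) {
  chrom <- resolveChrom(chrom)
  if (nSamples < 2) abort("simulateNormalControls: need >= 2 samples")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nSamples), function(i) {
    p <- min(1, max(0.5, stats::rnorm(1, model@pDetect, pDetectSD)))
    m <- detectionModel(p, model@lambdaBackground, model@pSplit)
    nuc <- simulateNuclei(clonesForState("normal"), m, nNuclei)
    summarizeSample(chrom, nuc$n_red, nuc$n_green)
  })
}

#' Default diagnostic-group profiles
#'
#' Generative profiles for the five WHO-2016 groups of an
#' oligodendroglial-histology cohort (OII, OIII, AII, AIII, GBM). Each
#' profile gives, per chromosome, the probability distribution over true
#' arm states, marker probabilities (IDH, ATRX retention, INA,
#' microvascular proliferation type, calcifications), a mitotic-count
#' distribution and a per-month exponential death hazard with independent
#' exponential censoring. The state and marker probabilities are the
#' empirical per-group frequencies of a 33-case oligodendroglial cohort
#' (e.g. 9p loss in 70% of OIII and 100% of GBM); hazards are the
#' reciprocal of the group mean survivals (OII 108, OIII 86, AII 156,
#' AIII 81, GBM 19 months).
#'
#' @return named list of group profiles.
#' @export
defaultGroupProfiles <- function() {
  st <- function(normal = 0, deleted = 0, imbalanced = 0, monosomy = 0) {
    p <- c(normal = normal, deleted = deleted, imbalanced = imbalanced,
           monosomy = monosomy)
    if (abs(sum(p) - 1) > 1e-8) abort("state probabilities must sum to 1")
    p
  }
  list(
    OII = list(
      states = list(chr1 = st(deleted = 1), chr19 = st(deleted = 1),
                    chr9 = st(normal = 11 / 13, imbalanced = 2 / 13),
                    chr10 = st(normal = 11 / 13, imbalanced = 2 / 13)),
      pIDH = 1, pATRXRetained = 1, pINA = 11 / 13, mvp = "endocrinoid",
      pNecrosis = 0, pCalcifications = 5 / 13, mitosesMean = 1.7,
      ki67Mean = 10, hazard = 1 / 108, censorRate = 0.27 / 108),
    OIII = list(
      states = list(chr1 = st(deleted = 1), chr19 = st(deleted = 1),
                    chr9 = st(normal = 0.2, deleted = 0.5, imbalanced = 0.1,
                              monosomy = 0.2),
                    chr10 = st(normal = 0.9, imbalanced = 0.1)),
      pIDH = 1, pATRXRetained = 1, pINA = 0.8, mvp = "glomeruloid",
      pNecrosis = 0, pCalcifications = 0.5, mitosesMean = 7,
      ki67Mean = 21, hazard = 1 / 86, censorRate = 0.27 / 86),
    AII = list(
      states = list(chr1 = st(deleted = 1 / 3, imbalanced = 2 / 3),
                    chr19 = st(imbalanced = 1),
                    chr9 = st(normal = 2 / 3, imbalanced = 1 / 3),
                    chr10 = st(normal = 2 / 3, imbalanced = 1 / 3)),
      pIDH = 1, pATRXRetained = 2 / 3, pINA = 0, mvp = "endocrinoid",
      pNecrosis = 0, pCalcifications = 0, mitosesMean = 0,
      ki67Mean = 8, hazard = 1 / 156, censorRate = 0.27 / 156),
    AIII = list(
      states = list(chr1 = st(normal = 1 / 3, deleted = 1 / 3,
                              imbalanced = 1 / 3),
                    chr19 = st(normal = 2 / 3, imbalanced = 1 / 3),
                    chr9 = st(normal = 2 / 3, imbalanced = 1 / 3),
                    chr10 = st(normal = 1)),
      pIDH = 1, pATRXRetained = 1 / 3, pINA = 0, mvp = "endocrinoid",
      pNecrosis = 0, pCalcifications = 2 / 3, mitosesMean = 3.7,
      ki67Mean = 8, hazard = 1 / 81, censorRate = 0.27 / 81),
    GBM = list(
      states = list(chr1 = st(normal = 0.5, deleted = 0.25,
                              imbalanced = 0.25),
                    chr19 = st(normal = 0.75, imbalanced = 0.25),
                    chr9 = st(deleted = 1),
                    chr10 = st(normal = 0.5, deleted = 0.5)),
      pIDH = 0.25, pATRXRetained = 0.75, pINA = 0.25, mvp = "glomeruloid",
      pNecrosis = 0.75, pCalcifications = 0, mitosesMean = 4.3,
      ki67Mean = 23, hazard = 1 / 19, censorRate = 0.27 / 19)
  )
}

#' Simulate a cohort of cases with true states, features and survival
#'
#' Draws, per case: a true arm state per chromosome from the group
#' profile, marker statuses (Bernoulli), a Poisson mitotic count, survival
#' time from an exponential death hazard with independent exponential
#' censoring (Weibull death times available via `shape`), and (optionally
#' via [simulateCaseCounts()]) per-nucleus spot counts.
#'
#' @param profiles named list of group profiles
#'   (default [defaultGroupProfiles()]).
#' @param sizes named integer vector of group sizes, names matching
#'   `profiles`.
#' @param seed integer seed.
#' @param shape Weibull shape for death times (1 = exponential, the
#'   default).
#' @return data frame, one row per case: `case_id`, `group`, true state per
#'   chromosome (`state_chr1`, ...), marker columns, `time_months`,
#'   `event`.
#' @examples
#' simulateCohort(sizes = c(OII = 3, GBM = 2), seed = 1)
#' @export
simulateCohort <- function(profiles = defaultGroupProfiles(), sizes,
                           seed = NULL, shape = 1) {
  if (!length(profiles)) abort("simulateCohort: empty profile list")
  if (is.null(names(sizes)) || !all(names(sizes) %in% names(profiles)))
    abort("simulateCohort: 'sizes' must be named by profile groups")
  if (any(sizes < 1)) abort("simulateCohort: sizes must be positive")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(sizes), function(g) {
    pr <- profiles[[g]]
    n <- sizes[[g]]
    states <- lapply(pr$states, function(p)
      sample(names(p), n, replace = TRUE, prob = p))
    death <- if (pr$hazard == 0) rep(Inf, n)
             else if (shape == 1) stats::rexp(n, pr$hazard)
             else stats::rweibull(n, shape, 1 / pr$hazard)
    cens <- if (pr$censorRate > 0) stats::rexp(n, pr$censorRate)
            else rep(200, n)   # administrative censoring horizon, months
    data.frame(
      case_id = sprintf("%s-%03d", g, seq_len(n)), group = g,
      state_chr1 = states$chr1, state_chr19 = states$chr19,
      state_chr9 = states$chr9, state_chr10 = states$chr10,
      idh_mutant = stats::runif(n) < pr$pIDH,
      atrx = ifelse(stats::runif(n) < pr$pATRXRetained, "retained", "lost"),
      ina_positive = stats::runif(n) < pr$pINA,
      mvp = pr$mvp,
      necrosis = stats::runif(n) < pr$pNecrosis,
      calcifications = stats::runif(n) < pr$pCalcifications,
      mitoses = stats::rpois(n, pr$mitosesMean),
      ki67 = pmax(1, round(stats::rnorm(n, pr$ki67Mean, 3))),
      time_months = pmax(0.5, pmin(death, cens)),
      event = death <= cens,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-nucleus counts for simulated (or fixture) cases
#'
#' Expands a case table carrying true arm states (`state_chr1`, ...,
#' `state_chr10`) into a long per-nucleus spot-count table in the format
#' consumed by [callCohort()], using the canonical clone mixture for each
#' true state and the chromosome's control detection model.
#'
#' @param cases data frame with `case_id` and `state_chr*` columns.
#' @param nNuclei nuclei per case and chromosome (default 600).
#' @param cloneFraction aberrant-clone fraction for non-normal states
#'   (default 0.85).
#' @param seed integer seed; per-case/chromosome streams are derived from
#'   it, so any subset of cases reproduces identically.
#' @return data frame `case_id`, `chromosome`, `nucleus_id`, `n_red`,
#'   `n_green`.
#' @export
simulateCaseCounts <- function(cases, nNuclei = 600, cloneFraction = 0.85,
                               seed = 1) {
  out <- vector("list", nrow(cases) * 4L)
  k <- 0L
  for (i in seq_len(nrow(cases))) {
    for (chrom in CHROM_IDS) {
      k <- k + 1L
      state <- cases[[paste0("state_", chrom)]][i]
      nuc <- simulateNuclei(clonesForState(state, cloneFraction),
                            controlDetectionModel(chrom), nNuclei,
                            seed = childSeed(seed, k))
      out[[k]] <- data.frame(case_id = cases$case_id[i], chromosome = chrom,
                             nuc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate paired manual/automated calls under a confusion model
#'
#' The manual vector is taken as truth; the automated call for each case is
#' drawn from the confusion row of its manual status. Used to validate the
#' concordance statistics against known agreement structure.
#'
#' @param truth character vector of statuses (the manual calls).
#' @param confusion square matrix of transition probabilities, rows =
#'   manual status, columns = automated status, rows summing to 1;
#'   dimnames give the status labels.
#' @param seed optional integer seed.
#' @return data frame `case_id`, `manual`, `automated`, `interpretable`.
#' @examples
#' cm <- diag(3); dimnames(cm) <- rep(list(c("DELETED", "IMBALANCED",
#'                                           "NORMAL")), 2)
#' simulatePairedCalls(c("DELETED", "NORMAL"), cm, seed = 1)
#' @export
simulatePairedCalls <- function(truth, confusion, seed = NULL) {
  if (is.null(dimnames(confusion)) ||
      !all(truth %in% rownames(confusion)))
    abort("simulatePairedCalls: confusion needs dimnames covering 'truth'")
  if (any(abs(rowSums(confusion) - 1) > 1e-8) || any(confusion < 0))
    abort("simulatePairedCalls: confusion rows must be probabilities summing to 1")
  if (!is.null(seed)) set.seed(seed)
  automated <- vapply(truth, function(s)
    sample(colnames(confusion), 1, prob = confusion[s, ]), character(1))
  data.frame(case_id = sprintf("case-%03d", seq_along(truth)),
             manual = truth, automated = unname(automated),
             interpretable = TRUE, stringsAsFactors = FALSE)
}
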