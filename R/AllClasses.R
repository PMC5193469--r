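#' @import methods
NULL

## Status alphabets used throughout the package.
NUCLEUS_CATEGORIES <- c("NORMAL", "TARGET_DELETED", "POLYSOMY_IMBALANCED",
                        "MONOSOMY", "UNINFORMATIVE")
ARM_STATUSES <- c("DELETED", "IMBALANCED", "NORMAL")
CHROM_IDS <- c("chr1", "chr9", "chr10", "chr19")

#' ChromPair: a dual-colour FISH probe pair for one chromosome
#'
#' One red (target-arm) / green (control-arm) probe pair hybridised to
#' opposite arms of the same chromosome. The target arm is the arm whose
#' copy-number status is being called; the opposite arm acts as an internal
#' reference. For chromosomes 9 and 10 the 1R/1G signal pattern is read as
#' loss of the whole chromosome (monosomy), because loss of the control arm
#' (9q, 10p) is a recognised event in diffuse gliomas; for chromosomes 1 and
#' 19 the same pattern is treated as uninterpretable.
#'
#' @slot id chromosome identifier, one of `"chr1"`, `"chr9"`, `"chr10"`,
#'   `"chr19"`.
#' @slot targetLocus cytoband of the red-labelled target-arm probe.
#' @slot controlLocus cytoband of the green-labelled control-arm probe.
#' @slot monosomyRule logical; is the 1R/1G whole-chromosome-loss rule
#'   enabled (`TRUE` only for chr9 and chr10)?
#'
#' @seealso [chromPair()], [classifyNuclei()]
#' @export
setClass("ChromPair",
  representation(id = "character", targetLocus = "character",
                 controlLocus = "character", monosomyRule = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@id) != 1L || !object@id %in% CHROM_IDS)
      msg <- c(msg, sprintf("'id' must be one of %s",
                            paste(CHROM_IDS, collapse = ", ")))
    else if (object@monosomyRule != (object@id %in% c("chr9", "chr10")))
      msg <- c(msg, "monosomy rule is enabled exactly for chr9 and chr10")
    if (length(msg)) msg else TRUE
  })

#' CutoffSet: per-chromosome calling cutoffs
#'
#' Percent-of-analyzable-nuclei cutoffs driving the tumour-level call. A
#' sample is deleted when its deleted-nucleus percentage exceeds the
#' deletion cutoff `D`, and imbalanced when its imbalanced percentage
#' exceeds the imbalance cutoff `I` or when the deleted + imbalanced sum
#' reaches `D`. Where the monosomy rule applies, a 1R/1G rate at or above
#' `D` additionally flags the control arm as deleted.
#'
#' @slot cutoffs `data.frame` with columns `chrom`, `deletion`, `imbalance`,
#'   `monosomy` (percent values in (0, 100)).
#' @slot source `"defaults"` for the published routine cutoffs or
#'   `"calibrated"` for cutoffs derived from non-neoplastic controls.
#' @slot provenance free-text description of how the cutoffs were obtained.
#'
#' @seealso [defaultCutoffs()], [calibrateCutoffs()], [callArmStatus()]
#' @export
setClass("CutoffSet",
  representation(cutoffs = "data.frame", source = "character",
                 provenance = "character"),
  validity = function(object) {
    df <- object@cutoffs
    msg <- character()
    need <- c("chrom", "deletion", "imbalance", "monosomy")
    if (!all(need %in% names(df)))
      return(sprintf("cutoff table needs columns %s",
                     paste(need, collapse = ", ")))
    if (!all(df$chrom %in% CHROM_IDS))
      msg <- c(msg, "unknown chromosome in cutoff table")
    if (anyDuplicated(df$chrom))
      msg <- c(msg, "duplicated chromosome in cutoff table")
    num <- unlist(df[c("deletion", "imbalance")])
    if (any(!is.finite(num)) || any(num <= 0) || any(num >= 100))
      msg <- c(msg, "cutoffs must lie strictly between 0 and 100 percent")
    if (!object@source %in% c("defaults", "calibrated"))
      msg <- c(msg, "'source' must be 'defaults' or 'calibrated'")
    if (length(msg)) msg else TRUE
  })

#' QCPolicy: minimal evidence required for a reliable call
#'
#' @slot minAnalyzableCells minimum number of analyzable (informative)
#'   nuclei; below it the automated call is marked unreliable (default 50).
#' @slot maxUninformativeFraction maximal tolerated percentage of
#'   uninformative nuclei (default 50).
#'
#' @seealso [qcPolicy()], [qcSample()]
#' @export
setClass("QCPolicy",
  representation(minAnalyzableCells = "numeric",
                 maxUninformativeFraction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@minAnalyzableCells < 1)
      msg <- c(msg, "minAnalyzableCells must be >= 1")
    if (object@maxUninformativeFraction < 0 ||
        object@maxUninformativeFraction > 100)
      msg <- c(msg, "maxUninformativeFraction must be in [0, 100]")
    if (length(msg)) msg else TRUE
  })

#' SampleSummary: per-sample nucleus category tallies
#'
#' Counts of nuclei per category for one sample and one probe pair, with
#' percentages computed over analyzable nuclei only (uninformative signal
#' patterns are excluded from every denominator). `pctDeleted` pools the
#' clean target-arm deletions with the 1R/1G monosomy pattern, which counts
#' as deleted exactly where the monosomy rule is enabled (elsewhere the
#' monosomy tally is structurally zero).
#'
#' @slot chrom chromosome id.
#' @slot counts named integer vector over the five nucleus categories.
#' @slot nTotal total number of nuclei scored.
#' @slot nAnalyzable nuclei in an informative category.
#' @slot pctNormal,pctTargetDeleted,pctMonosomy,pctImbalanced,pctDeleted
#'   percentages of analyzable nuclei (`NA` when `nAnalyzable == 0`).
#'
#' @seealso [summarizeSample()], [callArmStatus()]
#' @export
setClass("SampleSummary",
  representation(chrom = "character", counts = "integer", nTotal = "integer",
                 nAnalyzable = "integer", pctNormal = "numeric",
                 pctTargetDeleted = "numeric", pctMonosomy = "numeric",
                 pctImbalanced = "numeric", pctDeleted = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(sort(names(object@counts)), sort(NUCLEUS_CATEGORIES)))
      msg <- c(msg, "counts must be named by the five nucleus categories")
    else if (sum(object@counts) != object@nTotal)
      msg <- c(msg, "counts must sum to nTotal")
    if (object@nAnalyzable > 0) {
      tot <- object@pctNormal + object@pctTargetDeleted +
        object@pctMonosomy + object@pctImbalanced
      if (!isTRUE(all.equal(tot, 100, tolerance = 1e-8)))
        msg <- c(msg, "category percentages must sum to 100")
      if (object@pctDeleted < object@pctMonosomy - 1e-12)
        msg <- c(msg, "pctDeleted must be >= pctMonosomy")
    }
    if (length(msg)) msg else TRUE
  })

#' ArmCall: the tumour-level status call for one chromosome arm
#'
#' @slot chrom chromosome id.
#' @slot status `"DELETED"`, `"IMBALANCED"` or `"NORMAL"`.
#' @slot controlArmDeleted logical; `TRUE` when the 1R/1G rate reaches the
#'   deletion cutoff on a monosomy-rule chromosome, i.e. the green control
#'   arm (9q or 10p) is itself lost.
#' @slot summary the [SampleSummary-class] the call was made from.
#' @slot qcPass,qcReason quality-control verdict; a failing call is still
#'   reported but marked unreliable (mirroring fallback to manual counting).
#'
#' @seealso [callArmStatus()], [callSample()]
#' @export
setClass("ArmCall",
  representation(chrom = "character", status = "character",
                 controlArmDeleted = "logical", summary = "SampleSummary",
                 qcPass = "logical", qcReason = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@status %in% ARM_STATUSES)
      msg <- c(msg, "unknown arm status")
    if (object@controlArmDeleted &&
        !object@chrom %in% c("chr9", "chr10"))
      msg <- c(msg, "control-arm deletion can only be flagged for chr9/chr10")
    if (length(msg)) msg else TRUE
  })

#' DetectionModel: the lossy FISH spot-detection process
#'
#' Describes how true chromosome copies become counted spots: each true
#' copy is seen independently with probability `pDetect` (missed spots model
#' nuclear truncation in 5-micron sections and hybridisation failure), a
#' detected spot is counted twice with probability `pSplit` (split signal),
#' and each channel gains a Poisson number of spurious background spots
#' with mean `lambdaBackground`.
#'
#' @slot pDetect per-spot detection probability in (0, 1].
#' @slot lambdaBackground mean spurious spots per channel per nucleus.
#' @slot pSplit probability that a detected spot is counted twice.
#'
#' @seealso [detectionModel()], [simulateNuclei()]
#' @export
setClass("DetectionModel",
  representation(pDetect = "numeric", lambdaBackground = "numeric",
                 pSplit = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@pDetect <= 0 || object@pDetect > 1)
      msg <- c(msg, "pDetect must be in (0, 1]")
    if (object@lambdaBackground < 0)
      msg <- c(msg, "lambdaBackground must be >= 0")
    if (object@pSplit < 0 || object@pSplit > 1)
      msg <- c(msg, "pSplit must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' ConcordanceResult: chance-corrected agreement between two raters
#'
#' Cohen's kappa for paired nominal status calls,
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)}, with the expected agreement
#' \eqn{p_e} from the product of the two raters' marginal frequencies.
#' Agreement bands: kappa in (0.6, 0.8] is read as good agreement, above
#' 0.8 as high concordance.
#'
#' @slot nUsed,nAgree,nExcluded case tallies (excluded = weak-signal cases
#'   removed before comparison).
#' @slot percentAgreement observed agreement in percent (full precision).
#' @slot po,pe observed and chance-expected agreement proportions.
#' @slot kappa Cohen's kappa; `NA` when `pe == 1` (degenerate marginals).
#' @slot interpretation `"high"`, `"good"`, `"moderate-or-less"` or
#'   `"undefined"`.
#'
#' @seealso [cohensKappa()], [percentAgreement()]
#' @export
setClass("ConcordanceResult",
  representation(nUsed = "integer", nAgree = "integer", nExcluded = "integer",
                 percentAgreement = "numeric", po = "numeric", pe = "numeric",
                 kappa = "numeric", interpretation = "character"),
  validity = function(object) {
    msg <- character()
    if (object@po < 0 || object@po > 1) msg <- c(msg, "po must be in [0, 1]")
    if (!is.na(object@kappa) && object@kappa > object@po + 1e-12)
      msg <- c(msg, "kappa cannot exceed observed agreement")
    if (length(msg)) msg else TRUE
  })

#' GradingThresholds: numeric knobs of the WHO-2016 grading rules
#'
#' WHO grading criteria for mitotic activity are qualitative; these
#' thresholds make them operational and are deliberately configuration, not
#' ground truth. Defaults: an oligodendroglioma is anaplastic (grade III)
#' from 6 mitoses per 10 HPF, an astrocytoma from 2.
#'
#' @slot ogMitosesGrade3 mitoses/10 HPF for oligodendroglioma grade III.
#' @slot asMitosesGrade3 mitoses/10 HPF for astrocytoma grade III.
#'
#' @seealso [gradingThresholds()], [assignGrade()]
#' @export
setClass("GradingThresholds",
  representation(ogMitosesGrade3 = "numeric", asMitosesGrade3 = "numeric"),
  validity = function(object) {
    if (object@ogMitosesGrade3 <= 0 || object@asMitosesGrade3 <= 0)
      "mitotic thresholds must be positive" else TRUE
  })
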