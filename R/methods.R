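## Accessor and show methods for the S4 classes.

cutoffLookup <- function(x, chrom, col) {
  chrom <- if (is(chrom, "ChromPair")) chrom@id else match.arg(chrom, CHROM_IDS)
  row <- x@cutoffs[x@cutoffs$chrom == chrom, ]
  if (!nrow(row)) abort("no cutoffs for %s in this CutoffSet", chrom)
  row[[col]]
}

#' @rdname accessors
#' @export
setMethod("deletionCutoff", "CutoffSet",
          function(x, chrom) cutoffLookup(x, chrom, "deletion"))
#' @rdname accessors
#' @export
setMethod("imbalanceCutoff", "CutoffSet",
          function(x, chrom) cutoffLookup(x, chrom, "imbalance"))
#' @rdname accessors
#' @export
setMethod("monosomyCutoff", "CutoffSet",
          function(x, chrom) cutoffLookup(x, chrom, "monosomy"))
#' @rdname accessors
#' @export
setMethod("cutoffSource", "CutoffSet", function(x) x@source)

#' @rdname accessors
#' @export
setMethod("armStatus", "ArmCall", function(x) x@status)
#' @rdname accessors
#' @export
setMethod("controlArmDeleted", "ArmCall", function(x) x@controlArmDeleted)
#' @rdname accessors
#' @export
setMethod("qcPass", "ArmCall", function(x) x@qcPass)
#' @rdname accessors
#' @export
setMethod("qcReason", "ArmCall", function(x) x@qcReason)
#' @rdname accessors
#' @export
setMethod("sampleSummary", "ArmCall", function(x) x@summary)

#' @rdname accessors
#' @export
setMethod("nAnalyzable", "SampleSummary", function(x) x@nAnalyzable)
#' @rdname accessors
#' @export
setMethod("pctDeleted", "SampleSummary", function(x) x@pctDeleted)
#' @rdname accessors
#' @export
setMethod("pctImbalanced", "SampleSummary", function(x) x@pctImbalanced)
#' @rdname accessors
#' @export
setMethod("pctMonosomy", "SampleSummary", function(x) x@pctMonosomy)

#' @rdname accessors
#' @export
setMethod("kappaValue", "ConcordanceResult", function(x) x@kappa)

setMethod("show", "CutoffSet", function(object) {
  cat(sprintf("CutoffSet (%s): %s\n", object@source, object@provenance))
  print(object@cutoffs, row.names = FALSE)
})

setMethod("show", "SampleSummary", function(object) {
  cat(sprintf("SampleSummary %s: %d nuclei, %d analyzable\n",
              object@chrom, object@nTotal, object@nAnalyzable))
  if (object@nAnalyzable > 0)
    cat(sprintf(
      "  normal %.1f%% | deleted %.1f%% (1R/1G %.1f%%) | imbalanced %.1f%%\n",
      object@pctNormal, object@pctDeleted, object@pctMonosomy,
      object@pctImbalanced))
  else cat("  no analyzable nuclei\n")
})

setMethod("show", "ArmCall", function(object) {
  cat(sprintf("ArmCall %s: %s%s [QC %s%s]\n", object@chrom, object@status,
              if (object@controlArmDeleted) " + control arm deleted" else "",
              if (object@qcPass) "pass" else "FAIL",
              if (object@qcPass) "" else paste0(": ", object@qcReason)))
})

setMethod("show", "QCPolicy", function(object) {
  cat(sprintf(
    "QCPolicy: >= %d analyzable cells, <= %.0f%% uninformative\n",
    as.integer(object@minAnalyzableCells), object@maxUninformativeFraction))
})

setMethod("show", "DetectionModel", function(object) {
  cat(sprintf(
    "DetectionModel: pDetect %.3f, background %.3f/channel, pSplit %.3f\n",
    object@pDetect, object@lambdaBackground, object@pSplit))
})

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf(
    "Concordance: %d/%d agree (%.0f%%), kappa %s (%s), %d excluded\n",
    object@nAgree, object@nUsed, roundHalfUp(object@percentAgreement),
    ifelse(is.na(object@kappa), "undefined",
           sprintf("%.2f", object@kappa)),
    object@interpretation, object@nExcluded))
})

setMethod("show", "GradingThresholds", function(object) {
  cat(sprintf(
    "GradingThresholds: OG grade III >= %g mitoses/10 HPF, AS grade III >= %g\n",
    object@ogMitosesGrade3, object@asMitosesGrade3))
})
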