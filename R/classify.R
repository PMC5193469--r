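#' Classify nuclei from red/green FISH spot counts
#'
#' Maps each nucleus's (red, green) spot-count pair to one of five
#' categories given the probe pair. Red marks the target arm, green the
#' control arm. The mapping is total and deterministic:
#'
#' * `(2, 2)` — `NORMAL` (two copies of each arm);
#' * `(1, 1)` — `MONOSOMY` where the whole-chromosome-loss rule is enabled
#'   (chr9, chr10), otherwise `UNINFORMATIVE`;
#' * red/green ratio `<= 0.5` with at least one red and two green spots —
#'   `TARGET_DELETED` (relative loss of the target arm);
#' * ratio `> 0.5` with a maximum count of at least 3 —
#'   `POLYSOMY_IMBALANCED` (increased copy number without clean loss);
#' * anything else (no green signal, complete red dropout `(0, k)`,
#'   `(2, 1)`, `(1, 0)`, ...) — `UNINFORMATIVE`, treated as a
#'   section-truncation artifact and excluded from all percentage
#'   denominators.
#'
#' @param chrom a [ChromPair-class] or chromosome id string.
#' @param nRed,nGreen integer vectors of red (target) and green (control)
#'   spot counts, recycled to common length.
#'
#' @return factor with levels `NORMAL`, `TARGET_DELETED`,
#'   `POLYSOMY_IMBALANCED`, `MONOSOMY`, `UNINFORMATIVE`.
#'
#' @examples
#' classifyNuclei("chr9", c(1, 1, 2, 3), c(2, 1, 4, 3))
#' classifyNuclei("chr19", 1, 1)  # 1R/1G uninformative outside chr9/chr10
#' @export
classifyNuclei <- function(chrom, nRed, nGreen) {
  chrom <- resolveChrom(chrom)
  n <- max(length(nRed), length(nGreen))
  nRed <- checkCounts(rep_len(nRed, n), "nRed")
  nGreen <- checkCounts(rep_len(nGreen, n), "nGreen")

  out <- rep("UNINFORMATIVE", n)
  normal <- nRed == 2L & nGreen == 2L
  mono11 <- nRed == 1L & nGreen == 1L
  rest <- !normal & !mono11
  ratio <- ifelse(nGreen > 0L, nRed / nGreen, NA_real_)
  del <- rest & nRed >= 1L & nGreen >= 2L & !is.na(ratio) & ratio <= 0.5
  imb <- rest & !del & nGreen >= 1L & !is.na(ratio) & ratio > 0.5 &
    pmax(nRed, nGreen) >= 3L
  out[normal] <- "NORMAL"
  out[mono11] <- if (chrom@monosomyRule) "MONOSOMY" else "UNINFORMATIVE"
  out[del] <- "TARGET_DELETED"
  out[imb] <- "POLYSOMY_IMBALANCED"
  factor(out, levels = NUCLEUS_CATEGORIES)
}

#' Summarize nucleus categories for one sample
#'
#' Tallies the nucleus categories for one sample/probe-pair and computes
#' percentages over analyzable (informative) nuclei. The pooled
#' deleted percentage adds the 1R/1G monosomy rate to the clean target-arm
#' deletion rate; outside chr9/chr10 the monosomy tally is structurally
#' zero, so the pooling is a no-op there.
#'
#' @inheritParams classifyNuclei
#' @return a [SampleSummary-class]. With zero analyzable nuclei the
#'   percentage slots are `NA` and the summary is only usable for QC.
#' @examples
#' s <- summarizeSample("chr9", c(1, 1, 2, 1), c(2, 2, 2, 1))
#' pctDeleted(s)
#' @export
summarizeSample <- function(chrom, nRed, nGreen) {
  chrom <- resolveChrom(chrom)
  cats <- classifyNuclei(chrom, nRed, nGreen)
  counts <- table(cats)
  counts <- stats::setNames(as.integer(counts), names(counts))
  nTotal <- length(cats)
  nAna <- nTotal - counts[["UNINFORMATIVE"]]
  pct <- function(k) if (nAna > 0) 100 * counts[[k]] / nAna else NA_real_
  new("SampleSummary", chrom = chrom@id, counts = counts,
      nTotal = as.integer(nTotal), nAnalyzable = as.integer(nAna),
      pctNormal = pct("NORMAL"), pctTargetDeleted = pct("TARGET_DELETED"),
      pctMonosomy = pct("MONOSOMY"),
      pctImbalanced = pct("POLYSOMY_IMBALANCED"),
      pctDeleted = if (nAna > 0)
        pct("TARGET_DELETED") + pct("MONOSOMY") else NA_real_)
}

#' Quality control for an automated sample
#'
#' A sample fails QC when too few analyzable nuclei were scored (automated
#' detection of fewer than `minAnalyzableCells` cells) or when too large a
#' fraction of nuclei is uninformative (weak or artifact-ridden signal).
#' Failing QC does not suppress the call; the call is reported but flagged
#' unreliable, the situation in which a secondary manual count is
#' warranted.
#'
#' @param summary a [SampleSummary-class].
#' @param policy a [QCPolicy-class]; see [qcPolicy()].
#' @return list with elements `pass` (logical) and `reason` (string, `"ok"`
#'   on a pass; otherwise names the rule that fired).
#' @examples
#' s <- summarizeSample("chr1", rep(2, 45), rep(2, 45))
#' qcSample(s, qcPolicy(minAnalyzableCells = 50))
#' @export
qcSample <- function(summary, policy = qcPolicy()) {
  stopifnot(is(summary, "SampleSummary"), is(policy, "QCPolicy"))
  reasons <- character()
  if (summary@nAnalyzable < policy@minAnalyzableCells)
    reasons <- c(reasons, sprintf(
      "insufficient analyzable cells (%d < %d)",
      summary@nAnalyzable, as.integer(policy@minAnalyzableCells)))
  uninfPct <- if (summary@nTotal > 0)
    100 * summary@counts[["UNINFORMATIVE"]] / summary@nTotal else 100
  if (uninfPct > policy@maxUninformativeFraction)
    reasons <- c(reasons, sprintf(
      "uninformative fraction too high (%.1f%% > %.0f%%)",
      uninfPct, policy@maxUninformativeFraction))
  list(pass = length(reasons) == 0L,
       reason = if (length(reasons)) paste(reasons, collapse = "; ") else "ok")
}

#' QCPolicy constructor
#'
#' @param minAnalyzableCells minimum analyzable nuclei (default 50).
#' @param maxUninformativeFraction maximal uninformative percentage
#'   (default 50).
#' @return a [QCPolicy-class].
#' @export
qcPolicy <- function(minAnalyzableCells = 50, maxUninformativeFraction = 50) {
  new("QCPolicy", minAnalyzableCells = minAnalyzableCells,
      maxUninformativeFraction = maxUninformativeFraction)
}

#' Published routine cutoffs
#'
#' The deletion/imbalance cutoffs used in routine practice: 55% deleted
#' nuclei for a 1p or 19q deletion call with a 20% imbalance cutoff, and
#' the mean + 3 SD cutoffs calibrated on non-neoplastic brain for 9p
#' (deletion 30%, imbalance 40%) and 10q (deletion 25%, imbalance 55%).
#' The monosomy (1R/1G) cutoff equals the deletion cutoff on the
#' monosomy-rule chromosomes.
#'
#' @return a [CutoffSet-class] with `source = "defaults"`.
#' @examples
#' deletionCutoff(defaultCutoffs(), "chr9")
#' @export
defaultCutoffs <- function() {
  df <- data.frame(
    chrom = CHROM_IDS,
    deletion = c(55, 30, 25, 55),
    imbalance = c(20, 40, 55, 20),
    monosomy = c(NA, 30, 25, NA))
  new("CutoffSet", cutoffs = df, source = "defaults",
      provenance = "routine cutoffs (1p/19q) and mean + 3 SD on 5 non-neoplastic brain controls (9p/10q)")
}

#' Calibrate cutoffs on non-neoplastic control samples
#'
#' Computes, per chromosome, the deletion cutoff as mean + 3 SD of the
#' deleted-nucleus percentages across control samples and the imbalance
#' cutoff as mean + 3 SD of the imbalanced percentages, using the sample
#' (n - 1) standard deviation. Both are clamped below by `floor` to avoid
#' degenerate near-zero cutoffs when controls are noiseless. On
#' monosomy-rule chromosomes the monosomy cutoff equals the deletion
#' cutoff.
#'
#' @param normalSummaries named list (`chr1`, `chr9`, ...); each element a
#'   list of [SampleSummary-class] for the control samples of that
#'   chromosome, or a data frame with columns `pctDeleted` and
#'   `pctImbalanced`.
#' @param floor minimal cutoff in percent (default 5).
#' @return a [CutoffSet-class] with `source = "calibrated"`.
#' @examples
#' ctl <- data.frame(pctDeleted = c(10, 12, 8, 11, 9),
#'                   pctImbalanced = c(4, 6, 5, 5, 5))
#' calibrateCutoffs(list(chr9 = ctl))
#' @export
calibrateCutoffs <- function(normalSummaries, floor = 5) {
  if (!length(normalSummaries) || is.null(names(normalSummaries)))
    abort("calibrateCutoffs: supply a named list of per-chromosome controls")
  rows <- lapply(names(normalSummaries), function(id) {
    id <- match.arg(id, CHROM_IDS)
    x <- normalSummaries[[id]]
    if (is.data.frame(x)) {
      pd <- x$pctDeleted; pi <- x$pctImbalanced
    } else {
      pd <- vapply(x, pctDeleted, numeric(1))
      pi <- vapply(x, pctImbalanced, numeric(1))
    }
    if (length(pd) < 2)
      abort("calibrateCutoffs: need >= 2 control samples for %s (SD undefined)", id)
    D <- max(mean(pd) + 3 * stats::sd(pd), floor)
    I <- max(mean(pi) + 3 * stats::sd(pi), floor)
    mono <- if (chromPair(id)@monosomyRule) D else NA_real_
    data.frame(chrom = id, deletion = D, imbalance = I, monosomy = mono)
  })
  df <- do.call(rbind, rows)
  new("CutoffSet", cutoffs = df, source = "calibrated",
      provenance = sprintf(
        "mean + 3 SD (sample SD) over control samples, floor %.1f%%", floor))
}

#' Call tumour-level chromosome-arm status
#'
#' Applies the percentage cutoffs to a sample summary, in this order:
#' the sample is IMBALANCED when its imbalanced percentage exceeds the
#' imbalance cutoff (independently of its deletion status); otherwise
#' DELETED when the deleted percentage exceeds the deletion cutoff;
#' otherwise IMBALANCED when deleted + imbalanced together reach the
#' deletion cutoff; otherwise NORMAL. On monosomy-rule chromosomes the
#' control arm (9q/10p) is independently flagged deleted when the 1R/1G
#' rate is at or above the deletion cutoff.
#'
#' @param summary a [SampleSummary-class] with `nAnalyzable > 0`.
#' @param cutoffs a [CutoffSet-class].
#' @param chrom a [ChromPair-class] or id; defaults to the summary's.
#' @param policy a [QCPolicy-class] for the reliability flag.
#' @return an [ArmCall-class].
#' @examples
#' s <- summarizeSample("chr1", rep(c(1, 2), c(60, 40)), 2)
#' armStatus(callArmStatus(s, defaultCutoffs()))
#' @export
callArmStatus <- function(summary, cutoffs = defaultCutoffs(),
                          chrom = summary@chrom, policy = qcPolicy()) {
  stopifnot(is(summary, "SampleSummary"), is(cutoffs, "CutoffSet"))
  chrom <- resolveChrom(chrom)
  if (summary@nAnalyzable == 0L)
    abort("callArmStatus: no analyzable nuclei; no call possible")
  D <- deletionCutoff(cutoffs, chrom@id)
  I <- imbalanceCutoff(cutoffs, chrom@id)
  status <-
    if (summary@pctImbalanced > I) "IMBALANCED"
    else if (summary@pctDeleted > D) "DELETED"
    else if (summary@pctDeleted + summary@pctImbalanced >= D) "IMBALANCED"
    else "NORMAL"
  ctrlDel <- chrom@monosomyRule &&
    summary@pctMonosomy >= monosomyCutoff(cutoffs, chrom@id)
  qc <- qcSample(summary, policy)
  new("ArmCall", chrom = chrom@id, status = status,
      controlArmDeleted = isTRUE(ctrlDel), summary = summary,
      qcPass = qc$pass, qcReason = qc$reason)
}

#' Call one sample straight from nucleus counts
#'
#' Convenience wrapper: classify, summarize, QC and call in one step.
#'
#' @inheritParams classifyNuclei
#' @inheritParams callArmStatus
#' @return an [ArmCall-class].
#' @export
callSample <- function(chrom, nRed, nGreen, cutoffs = defaultCutoffs(),
                       policy = qcPolicy()) {
  chrom <- resolveChrom(chrom)
  callArmStatus(summarizeSample(chrom, nRed, nGreen), cutoffs, chrom, policy)
}

#' Call every case/chromosome in a nucleus-count table
#'
#' @param counts data frame with columns `case_id`, `chromosome`,
#'   `nucleus_id`, `n_red`, `n_green` (the format read by
#'   [readNucleusCounts()]).
#' @inheritParams callArmStatus
#' @return data frame with one row per case/chromosome: status,
#'   control-arm flag, nucleus tallies, percentages and QC fields.
#' @export
callCohort <- function(counts, cutoffs = defaultCutoffs(),
                       policy = qcPolicy()) {
  need <- c("case_id", "chromosome", "n_red", "n_green")
  if (!all(need %in% names(counts)))
    abort("callCohort: counts table needs columns %s",
          paste(need, collapse = ", "))
  keys <- unique(counts[c("case_id", "chromosome")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- counts[counts$case_id == keys$case_id[i] &
                  counts$chromosome == keys$chromosome[i], ]
    cl <- callSample(keys$chromosome[i], sub$n_red, sub$n_green,
                     cutoffs, policy)
    s <- cl@summary
    data.frame(case_id = keys$case_id[i], chromosome = keys$chromosome[i],
               status = cl@status, control_arm_deleted = cl@controlArmDeleted,
               n_total = s@nTotal, n_analyzable = s@nAnalyzable,
               pct_deleted = s@pctDeleted, pct_imbalanced = s@pctImbalanced,
               pct_monosomy = s@pctMonosomy, qc_pass = cl@qcPass,
               qc_reason = cl@qcReason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
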