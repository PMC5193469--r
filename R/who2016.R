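#' GradingThresholds constructor
#'
#' @param ogMitosesGrade3 mitoses/10 HPF from which an oligodendroglioma is
#'   graded III (default 6).
#' @param asMitosesGrade3 mitoses/10 HPF from which an astrocytoma is
#'   graded III (default 2).
#' @return a [GradingThresholds-class].
#' @export
gradingThresholds <- function(ogMitosesGrade3 = 6, asMitosesGrade3 = 2) {
  new("GradingThresholds", ogMitosesGrade3 = ogMitosesGrade3,
      asMitosesGrade3 = asMitosesGrade3)
}

## effective IDH status: IDH1-R132H IHC, with an optional IDH2 sequencing
## override for IHC-negative cases
idhStatus <- function(idh1Positive, idh2Mutant = NA) {
  if (is.na(idh1Positive)) return("unknown")
  if (idh1Positive || isTRUE(idh2Mutant)) "mutant" else "wildtype"
}

#' Assign glioma lineage from molecular status
#'
#' WHO-2016 lineage rule: a diffuse glioma is an oligodendroglioma if and
#' only if it is IDH-mutant *and* 1p and 19q are both whole-arm deleted;
#' every other configuration (including 1p deletion without 19q loss, and
#' codeletion without IDH mutation) is an astrocytic neoplasm. An IDH2
#' sequencing result, when available, overrides a negative IDH1-R132H
#' immunostain.
#'
#' @param features one-row data frame (or list) with `idh1_positive`
#'   (logical), optional `idh2_mutant` (logical), `status_1p`,
#'   `status_19q` (`"DELETED"`, `"IMBALANCED"`, `"NORMAL"`).
#' @return `"oligodendroglioma"` or `"astrocytoma"`.
#' @examples
#' assignLineage(list(idh1_positive = TRUE, status_1p = "DELETED",
#'                    status_19q = "DELETED"))
#' @export
assignLineage <- function(features) {
  idh <- idhStatus(features$idh1_positive,
                   if (!is.null(features$idh2_mutant))
                     features$idh2_mutant else NA)
  if (idh == "unknown")
    abort("assignLineage: IDH status unknown; case unclassifiable")
  codeleted <- features$status_1p == "DELETED" &&
    features$status_19q == "DELETED"
  if (idh == "mutant" && codeleted) "oligodendroglioma" else "astrocytoma"
}

#' Assign WHO grade within a lineage
#'
#' Oligodendrogliomas are grade III (anaplastic) on glomeruloid
#' microvascular proliferation or a mitotic count at/above the
#' oligodendroglioma threshold, otherwise grade II. Astrocytomas are grade
#' IV (glioblastoma) on glomeruloid MVP or necrosis, grade III on a
#' mitotic count at/above the astrocytoma threshold, otherwise grade II.
#' The benign "endocrinoid" (chicken-wire) vasculature typical of
#' oligodendroglioma is not MVP and never raises the grade.
#'
#' @param features one-row data frame (or list) with `mvp` (`"none"`,
#'   `"endocrinoid"`, `"glomeruloid"`), `necrosis` (logical), `mitoses`
#'   (count per 10 HPF).
#' @param lineage `"oligodendroglioma"` or `"astrocytoma"`.
#' @param thresholds a [GradingThresholds-class].
#' @return `"II"`, `"III"` or `"IV"`.
#' @export
assignGrade <- function(features, lineage, thresholds = gradingThresholds()) {
  glomeruloid <- identical(features$mvp, "glomeruloid")
  if (lineage == "oligodendroglioma") {
    if (glomeruloid || features$mitoses >= thresholds@ogMitosesGrade3)
      "III" else "II"
  } else {
    if (glomeruloid || isTRUE(features$necrosis)) "IV"
    else if (features$mitoses >= thresholds@asMitosesGrade3) "III"
    else "II"
  }
}

#' Integrated WHO-2016 diagnosis
#'
#' Combines the lineage and grading rules into the integrated label (OII,
#' OIII, AII, AIII, GBM) for each case, recording every fired rule in a
#' rationale string. ATRX and INA status are carried through for reporting
#' but are never decisive (characteristic, not required).
#'
#' @param features data frame of case features, one row per case, with the
#'   columns used by [assignLineage()] and [assignGrade()] (as produced by
#'   [cohortFixture()]).
#' @param thresholds a [GradingThresholds-class].
#' @return data frame `case_id`, `lineage`, `grade`, `label`, `rationale`.
#' @examples
#' diag <- integratedDiagnosis(cohortFixture())
#' table(diag$label)
#' @export
integratedDiagnosis <- function(features, thresholds = gradingThresholds()) {
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- as.list(features[i, ])
    fired <- character()
    idh <- idhStatus(f$idh1_positive,
                     if (!is.null(f$idh2_mutant)) f$idh2_mutant else NA)
    if (idh == "mutant" && !isTRUE(f$idh1_positive))
      fired <- c(fired, "IDH2 sequencing overrides negative IDH1-R132H IHC")
    lineage <- assignLineage(f)
    fired <- c(fired, if (lineage == "oligodendroglioma")
      "IDH-mutant with 1p/19q codeletion: oligodendroglioma"
      else sprintf("not IDH-mutant-codeleted (IDH %s, 1p %s, 19q %s): astrocytoma",
                   idh, f$status_1p, f$status_19q))
    grade <- assignGrade(f, lineage, thresholds)
    fired <- c(fired, switch(grade,
      II = "no high-grade feature: grade II",
      III = if (identical(f$mvp, "glomeruloid"))
        "glomeruloid MVP: grade III"
      else sprintf("mitoses %s >= threshold: grade III", f$mitoses),
      IV = if (identical(f$mvp, "glomeruloid"))
        "glomeruloid MVP in astrocytoma: GBM"
      else "necrosis in astrocytoma: GBM"))
    label <- if (lineage == "oligodendroglioma")
      c(II = "OII", III = "OIII")[[grade]]
    else c(II = "AII", III = "AIII", IV = "GBM")[[grade]]
    data.frame(case_id = f$case_id, lineage = lineage, grade = grade,
               label = label, rationale = paste(fired, collapse = " | "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
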