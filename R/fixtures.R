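## Frozen reference cohort -----------------------------------------------
##
## A 33-case oligodendroglial-histology series with every per-group
## marginal (molecular status, IHC, MVP, calcifications, mitoses, Ki-67)
## fixed, used to exercise the WHO-2016 engine, the frequency reports and
## the deleted-arm summaries. Joint assignments beyond the published
## marginal counts and textual joint constraints (e.g. which OIII cases
## carry the whole-chromosome-9 loss) are arbitrary but frozen; the
## construction order is documented in the methods vignette. The single
## 1p-deleted AII case carries the 19q-imbalanced status required by the
## AII column margins, and the single IDH1-IHC-negative OII carries an
## IDH2 sequencing override.

statusFromState <- function(state) {
  c(normal = "NORMAL", deleted = "DELETED", imbalanced = "IMBALANCED",
    monosomy = "DELETED")[state]
}

buildCohortFixture <- function() {
  rep5 <- function(oii, oiii, aii, aiii, gbm)
    c(rep(oii, length.out = 13)[1:13], rep(oiii, length.out = 10)[1:10],
      rep(aii, length.out = 3)[1:3], rep(aiii, length.out = 3)[1:3],
      rep(gbm, length.out = 4)[1:4])
  df <- data.frame(
    case_id = c(sprintf("OII-%03d", 1:13), sprintf("OIII-%03d", 1:10),
                sprintf("AII-%03d", 1:3), sprintf("AIII-%03d", 1:3),
                sprintf("GBM-%03d", 1:4)),
    group = rep(c("OII", "OIII", "AII", "AIII", "GBM"),
                c(13, 10, 3, 3, 4)),
    mvp = rep5("endocrinoid", "glomeruloid", "endocrinoid", "endocrinoid",
               "glomeruloid"),
    necrosis = rep5(FALSE, FALSE, FALSE, FALSE, TRUE),
    mitoses = c(3, 3, 3, 2, 2, 2, 2, 2, 1, 1, 1, 0, 0,       # OII
                4, 5, 6, 6, 6, 6, 7, 8, 10, 12,              # OIII
                0, 0, 0,                                     # AII
                2, 3, 6,                                     # AIII
                2, 5, 5, 5),                                 # GBM
    ki67 = c(rep(10, 13), rep(21, 10), rep(8, 3), rep(8, 3),
             18, 20, 20, 34),
    calcifications = c(rep(c(TRUE, FALSE), c(5, 8)),         # OII 5/13
                       rep(c(TRUE, FALSE), c(5, 5)),         # OIII 5/10
                       rep(FALSE, 3),                        # AII 0/3
                       TRUE, TRUE, FALSE,                    # AIII 2/3
                       rep(FALSE, 4)),                       # GBM 0/4
    idh1_positive = c(rep(TRUE, 12), FALSE,                  # OII 12/13
                      rep(TRUE, 10), rep(TRUE, 3), rep(TRUE, 3),
                      TRUE, FALSE, FALSE, FALSE),            # GBM 1/4
    idh2_mutant = c(rep(NA, 12), TRUE, rep(NA, 20)),
    atrx = c(rep("retained", 13), rep("retained", 10),
             "retained", "retained", "lost",                 # AII 2/3
             "lost", "lost", "retained",                     # AIII 1/3
             "retained", "retained", "retained", "lost"),    # GBM 3/4
    ina_positive = c(rep(c(TRUE, FALSE), c(11, 2)),          # OII 11/13
                     rep(c(TRUE, FALSE), c(8, 2)),           # OIII 8/10
                     rep(FALSE, 3), rep(FALSE, 3),
                     TRUE, FALSE, FALSE, FALSE),             # GBM 1/4
    state_chr1 = c(rep("deleted", 13), rep("deleted", 10),
                   "deleted", "imbalanced", "imbalanced",
                   "deleted", "normal", "imbalanced",
                   "deleted", "normal", "normal", "imbalanced"),
    state_chr19 = c(rep("deleted", 13), rep("deleted", 10),
                    rep("imbalanced", 3),
                    "normal", "normal", "imbalanced",
                    "normal", "normal", "normal", "imbalanced"),
    state_chr9 = c("imbalanced", "imbalanced", rep("normal", 11),
                   rep("deleted", 5), "monosomy", "monosomy",
                   "imbalanced", "normal", "normal",
                   "normal", "imbalanced", "normal",
                   "normal", "imbalanced", "normal",
                   rep("deleted", 4)),
    state_chr10 = c("normal", "normal", "imbalanced", "imbalanced",
                    rep("normal", 9),
                    rep("normal", 7), "imbalanced", "normal", "normal",
                    "normal", "normal", "imbalanced",
                    rep("normal", 3),
                    "deleted", "deleted", "normal", "normal"),
    stringsAsFactors = FALSE)
  df$status_1p <- unname(statusFromState(df$state_chr1))
  df$status_19q <- unname(statusFromState(df$state_chr19))
  df$status_9p <- unname(statusFromState(df$state_chr9))
  df$status_10q <- unname(statusFromState(df$state_chr10))
  df$ctrl_9q_deleted <- df$state_chr9 == "monosomy"
  df$ctrl_10p_deleted <- df$state_chr10 == "monosomy"
  df
}

buildConcordanceFixture <- function(chrom) {
  fx <- buildCohortFixture()
  auto <- if (chrom == "chr9") fx$status_9p else fx$status_10q
  manual <- auto
  if (chrom == "chr9") {
    ## 8 manual/automated disagreements, 2 of them (OII-005, OIII-009)
    ## with weak signal for both assays of chromosome 9
    disagree <- c("OII-003" = "IMBALANCED", "OII-004" = "IMBALANCED",
                  "OII-005" = "DELETED", "OIII-008" = "DELETED",
                  "OIII-009" = "DELETED", "AII-001" = "IMBALANCED",
                  "AIII-001" = "IMBALANCED", "GBM-003" = "IMBALANCED")
    weak <- c("OII-005", "OIII-009")
  } else {
    ## 10 disagreements; 5 weak-signal cases (4 disagreeing + 1 agreeing)
    disagree <- c("OII-001" = "IMBALANCED", "OII-002" = "DELETED",
                  "OII-006" = "IMBALANCED", "OIII-001" = "IMBALANCED",
                  "OIII-002" = "DELETED", "OIII-003" = "IMBALANCED",
                  "AII-001" = "IMBALANCED", "AIII-002" = "IMBALANCED",
                  "GBM-003" = "DELETED", "GBM-004" = "DELETED")
    weak <- c("OII-002", "OII-007", "OIII-002", "GBM-003", "GBM-004")
  }
  manual[match(names(disagree), fx$case_id)] <- unname(disagree)
  data.frame(case_id = fx$case_id, chromosome = chrom, manual = manual,
             automated = auto, interpretable = !fx$case_id %in% weak,
             stringsAsFactors = FALSE)
}

## djb2 string hash, folded to a portable 31-bit integer; guards the frozen
## fixtures against accidental edits
fixtureChecksum <- function(df) {
  txt <- paste(vapply(df, function(col) paste(as.character(col),
                                              collapse = "\036"),
                      character(1)), collapse = "\035")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  h
}

FIXTURE_CHECKSUMS <- c(cohort = 1857806056, chr9 = 1270711355,
                       chr10 = 862832515)

#' The packaged 33-case reference cohort
#'
#' A frozen 33-case series with oligodendroglial histology (13 OII, 10
#' OIII, 3 AII, 3 AIII, 4 GBM after WHO-2016 reclassification) carrying
#' histological features, IHC statuses, true per-chromosome arm states and
#' the derived tumour-level status calls. All per-group marginal counts
#' are fixed; joint assignments beyond the recorded constraints are
#' arbitrary but frozen, and the table is checksum-verified on load.
#'
#' @param verify check the frozen checksum (default `TRUE`).
#' @return data frame with one row per case.
#' @examples
#' table(cohortFixture()$group)
#' @export
cohortFixture <- function(verify = TRUE) {
  df <- buildCohortFixture()
  if (verify && fixtureChecksum(df) != FIXTURE_CHECKSUMS[["cohort"]])
    abort("cohortFixture: checksum mismatch; fixture has been modified")
  df
}

#' Packaged paired manual/automated call fixtures
#'
#' Frozen paired call vectors for the chromosome 9 and chromosome 10
#' assays of the reference cohort: 33 cases each, with weak-signal cases
#' flagged uninterpretable (2 for chr9, 5 for chr10). The agreement
#' structure is fixed: chr9 agrees in 25/33 cases overall and 25/31 after
#' exclusions; chr10 in 23/33 and 22/28.
#'
#' @param chrom `"chr9"` or `"chr10"`.
#' @param verify check the frozen checksum (default `TRUE`).
#' @return data frame `case_id`, `chromosome`, `manual`, `automated`,
#'   `interpretable`.
#' @examples
#' cohensKappa(concordanceFixture("chr9"))
#' @export
concordanceFixture <- function(chrom = c("chr9", "chr10"), verify = TRUE) {
  chrom <- match.arg(chrom)
  df <- buildConcordanceFixture(chrom)
  if (verify && fixtureChecksum(df) != FIXTURE_CHECKSUMS[[chrom]])
    abort("concordanceFixture: checksum mismatch; fixture has been modified")
  df
}

#' Load a packaged fixture by name
#'
#' @param name `"cohort"`, `"concordance-chr9"` or `"concordance-chr10"`.
#' @return the fixture data frame (checksum-verified).
#' @export
loadFixture <- function(name = c("cohort", "concordance-chr9",
                                 "concordance-chr10")) {
  name <- match.arg(name)
  switch(name,
         cohort = cohortFixture(),
         `concordance-chr9` = concordanceFixture("chr9"),
         `concordance-chr10` = concordanceFixture("chr10"))
}
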