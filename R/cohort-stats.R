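#' Chi-square group-comparison test
#'
#' Pearson chi-square on a contingency table, with Yates continuity
#' correction applied to 2x2 tables (the convention matching the printed
#' group-comparison p-values). `method = "fisher"` gives Fisher's exact
#' test for sparse tables.
#'
#' @param tab matrix (or table) of non-negative integer counts, at least
#'   2x2, with no all-zero row or column margin.
#' @param correct apply the Yates correction for 2x2 tables (default
#'   `TRUE`).
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return list with `statistic` (`NA` for Fisher) and `p.value`.
#' @examples
#' chiSquareTest(matrix(c(0, 7, 13, 3), 2))  # p prints as 0.002
#' @export
chiSquareTest <- function(tab, correct = TRUE, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    abort("chiSquareTest: table must be at least 2x2")
  if (any(tab < 0) || any(tab != floor(tab)))
    abort("chiSquareTest: counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("chiSquareTest: zero row or column margin")
  if (method == "fisher") {
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, p.value = ft$p.value))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p.value = ct$p.value)
}

#' Count deleted and altered arms per case
#'
#' From a per-case call table, counts how many of the four target arms
#' (1p, 19q, 9p, 10q) are deleted, and how many are altered (deleted or
#' imbalanced). A whole-chromosome-9 (or -10) loss contributes exactly one
#' deleted arm through its target-arm call; the control-arm (9q/10p)
#' deletion flags are reported separately and never added to the counts.
#'
#' @param calls data frame with columns `case_id`, and per chromosome
#'   either `status_chr*`-style wide columns (`status_1p`, `status_19q`,
#'   `status_9p`, `status_10q`) or long format as produced by
#'   [callCohort()] (`chromosome`, `status`).
#' @param groups optional named vector or data frame (`case_id`, `group`)
#'   assigning cases to diagnostic groups for group means.
#' @return list with `perCase` (data frame: `case_id`, `nDeleted`,
#'   `nAltered`, control-arm flags if available) and `groupMeans` (data
#'   frame of per-group and overall means, `NULL` without `groups`).
#' @examples
#' fx <- cohortFixture()
#' deletionCountSummary(fx, fx[c("case_id", "group")])$groupMeans
#' @export
deletionCountSummary <- function(calls, groups = NULL) {
  wide <- c("status_1p", "status_19q", "status_9p", "status_10q")
  if (all(wide %in% names(calls))) {
    st <- as.matrix(calls[wide])
    perCase <- data.frame(case_id = calls$case_id,
                          nDeleted = rowSums(st == "DELETED"),
                          nAltered = rowSums(st != "NORMAL"),
                          stringsAsFactors = FALSE)
    for (cc in c("ctrl_9q_deleted", "ctrl_10p_deleted"))
      if (cc %in% names(calls)) perCase[[cc]] <- calls[[cc]]
  } else if (all(c("chromosome", "status") %in% names(calls))) {
    if (!all(table(calls$case_id) == 4))
      abort("deletionCountSummary: every case needs calls for all four chromosomes")
    agg <- function(f) stats::aggregate(
      calls$status, by = list(case_id = calls$case_id), FUN = f)
    nd <- agg(function(s) sum(s == "DELETED"))
    na <- agg(function(s) sum(s != "NORMAL"))
    perCase <- data.frame(case_id = nd$case_id, nDeleted = nd$x,
                          nAltered = na$x, stringsAsFactors = FALSE)
  } else abort("deletionCountSummary: unrecognized call-table format")

  groupMeans <- NULL
  if (!is.null(groups)) {
    if (is.data.frame(groups))
      groups <- stats::setNames(groups$group, groups$case_id)
    g <- groups[perCase$case_id]
    means <- function(v) c(tapply(v, g, mean), Total = mean(v))
    groupMeans <- data.frame(group = names(means(perCase$nDeleted)),
                             meanDeleted = as.numeric(means(perCase$nDeleted)),
                             meanAltered = as.numeric(means(perCase$nAltered)),
                             stringsAsFactors = FALSE)
  }
  list(perCase = perCase, groupMeans = groupMeans)
}

## survival records: data.frame with time_months > 0, event logical
checkSurvival <- function(records) {
  if (!all(c("time_months", "event") %in% names(records)))
    abort("survival records need columns time_months and event")
  if (any(records$time_months <= 0))
    abort("survival times must be positive")
  records
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with right censoring; a thin wrapper over
#' [survival::survfit()] keeping the package's record format.
#'
#' @param records data frame with `time_months` (> 0) and `event`
#'   (logical or 0/1).
#' @param group optional grouping vector for stratified curves.
#' @return a `survfit` object.
#' @export
kmEstimate <- function(records, group = NULL) {
  checkSurvival(records)
  df <- data.frame(time = records$time_months,
                   event = as.integer(records$event),
                   g = if (is.null(group)) 1 else group)
  survival::survfit(survival::Surv(time, event) ~ g, data = df)
}

#' Median survival from a Kaplan-Meier curve
#'
#' @param fit a `survfit` object (from [kmEstimate()]).
#' @return median survival time(s); `NA` (undefined, not infinite) when
#'   the curve never falls to 0.5.
#' @export
medianSurvival <- function(fit) {
  tab <- summary(fit)$table
  if (is.matrix(tab)) unname(tab[, "median"]) else unname(tab[["median"]])
}

#' Log-rank test
#'
#' @param records data frame with `time_months` and `event`.
#' @param group grouping vector with at least two groups.
#' @return list with `statistic` (chi-square), `df` and `p.value`.
#' @export
logrankTest <- function(records, group) {
  checkSurvival(records)
  if (length(unique(group)) < 2)
    abort("logrankTest: need at least two groups")
  df <- data.frame(time = records$time_months,
                   event = as.integer(records$event), g = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  dfree <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = dfree,
       p.value = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE))
}

#' Univariate screen of candidate covariates
#'
#' Log-rank test of each dichotomous covariate against survival; the
#' covariates significant at `alpha` are the candidates for the
#' multivariate Cox model, mirroring the two-stage workflow of first
#' screening in univariate analysis.
#'
#' @param records data frame with `time_months`, `event` and the covariate
#'   columns.
#' @param covariates character vector of covariate column names.
#' @param alpha significance threshold (default 0.05).
#' @return data frame `covariate`, `p.value`, `selected`.
#' @export
screenCovariates <- function(records, covariates, alpha = 0.05) {
  checkSurvival(records)
  p <- vapply(covariates, function(cv) {
    g <- records[[cv]]
    if (length(unique(g)) < 2) return(NA_real_)
    logrankTest(records, g)$p.value
  }, numeric(1))
  data.frame(covariate = covariates, p.value = p,
             selected = !is.na(p) & p < alpha, stringsAsFactors = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Breslow tie handling) of the supplied
#' covariates, with hazard ratios and 95% confidence intervals. Warns when
#' the events-per-covariate ratio falls below 10. Monotone-likelihood
#' degeneracies (a perfectly separating covariate, flagged by an infinite
#' or extreme coefficient path) are reported per covariate in the `flagged`
#' column instead of being silently returned as estimates.
#'
#' @param records data frame with `time_months`, `event` and covariate
#'   columns.
#' @param covariates character vector of covariate column names.
#' @return data frame `covariate`, `hr`, `lower95`, `upper95`, `p.value`,
#'   `flagged`.
#' @export
coxFit <- function(records, covariates) {
  checkSurvival(records)
  nev <- sum(records$event)
  if (nev < 10 * length(covariates))
    warning(sprintf("coxFit: only %d events for %d covariates (< 10 per covariate)",
                    nev, length(covariates)), call. = FALSE)
  df <- records
  df$.time <- records$time_months
  df$.event <- as.integer(records$event)
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(covariates, collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = df, ties = "breslow"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  flagged <- warned | !is.finite(co[, "se(coef)"]) |
    abs(co[, "coef"]) > 15 | co[, "se(coef)"] > 1e3
  data.frame(covariate = rownames(co), hr = unname(ci[, "exp(coef)"]),
             lower95 = unname(ci[, "lower .95"]),
             upper95 = unname(ci[, "upper .95"]),
             p.value = unname(co[, "Pr(>|z|)"]),
             flagged = unname(flagged), stringsAsFactors = FALSE)
}

#' Dichotomize prognostic covariates
#'
#' Applies the standard dichotomization cutoffs used for survival
#' analysis: age at diagnosis 50 years, mitoses 5 per 10 HPF, Ki-67
#' labelling index 12%, INA 10%, ATRX 10% (the IHC markers are usually
#' already recorded as binary status; numeric columns are cut at the
#' threshold, `x >= cutoff`).
#'
#' @param records data frame of survival records/features.
#' @param cutoffs named list of cutoffs (defaults above); names must match
#'   numeric columns of `records`.
#' @return `records` with added logical columns `<name>_high`.
#' @export
dichotomize <- function(records,
                        cutoffs = list(age = 50, mitoses = 5, ki67 = 12,
                                       ina_pct = 10, atrx_pct = 10)) {
  for (nm in names(cutoffs)) {
    if (!nm %in% names(records)) next
    records[[paste0(nm, "_high")]] <- records[[nm]] >= cutoffs[[nm]]
  }
  records
}

#' Group frequency report
#'
#' Builds a per-group summary table of a case-feature table in the style
#' of a clinical series description: for categorical/logical variables,
#' counts with integer percentages (rounded half-up) per diagnostic group
#' and overall; for numeric variables, mean (rounded half-up to one
#' decimal) and median.
#'
#' @param cases data frame with a `group` column plus feature columns.
#' @param variables columns to summarize (default: all except `case_id`
#'   and `group`).
#' @return data frame with columns `variable`, `level`, one column per
#'   group and `Total`; count rows formatted `"n (pct)"`, numeric rows
#'   formatted as numbers.
#' @examples
#' groupFrequencyTable(cohortFixture(), variables = "status_9p")
#' @export
groupFrequencyTable <- function(cases, variables = NULL) {
  if (!"group" %in% names(cases))
    abort("groupFrequencyTable: 'group' column required")
  if (is.null(variables))
    variables <- setdiff(names(cases), c("case_id", "group"))
  groups <- unique(cases$group)
  gsplit <- c(stats::setNames(lapply(groups, function(g)
    cases[cases$group == g, , drop = FALSE]), groups),
    list(Total = cases))
  rows <- list()
  for (v in variables) {
    x <- cases[[v]]
    if (is.numeric(x) && !is.logical(x)) {
      cells <- vapply(gsplit, function(d)
        sprintf("%g / %g", roundHalfUp(mean(d[[v]]), 1),
                roundHalfUp(stats::median(d[[v]]), 1)), character(1))
      rows[[length(rows) + 1L]] <- c(variable = v, level = "mean / median",
                                     cells)
    } else {
      levs <- if (is.logical(x)) TRUE else sort(unique(x))
      for (lv in levs) {
        cells <- vapply(gsplit, function(d) {
          n <- sum(d[[v]] == lv)
          if (nrow(d) == 0) "0 (0)" else
            sprintf("%d (%d)", n, as.integer(roundHalfUp(100 * n / nrow(d))))
        }, character(1))
        rows[[length(rows) + 1L]] <- c(variable = v, level = as.character(lv),
                                       cells)
      }
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
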