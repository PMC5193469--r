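#' Drop weak-signal cases from a paired-calls table
#'
#' Removes cases whose `interpretable` flag is `FALSE` (weak fluorescent
#' signal in one or both assays) before computing agreement, and records
#' how many were excluded.
#'
#' @param paired data frame with columns `manual`, `automated` and
#'   optionally `interpretable` (missing flag = all interpretable).
#' @return the filtered data frame, with the number of removed cases in
#'   attribute `"nExcluded"`.
#' @examples
#' p <- concordanceFixture("chr9")
#' nrow(applyExclusions(p))
#' @export
applyExclusions <- function(paired) {
  flags <- if (is.null(paired$interpretable)) rep(TRUE, nrow(paired))
           else paired$interpretable
  out <- paired[flags, , drop = FALSE]
  attr(out, "nExcluded") <- sum(!flags)
  out
}

#' Percent agreement between manual and automated calls
#'
#' @param paired data frame with columns `manual` and `automated`.
#' @return agreement in percent, full precision (round with
#'   [roundHalfUp()] for reporting).
#' @examples
#' percentAgreement(data.frame(manual = c("a", "a", "b"),
#'                             automated = c("a", "b", "b")))
#' @export
percentAgreement <- function(paired) {
  if (!nrow(paired)) abort("percentAgreement: no cases")
  100 * sum(paired$manual == paired$automated) / nrow(paired)
}

#' Cohen's kappa for paired nominal calls
#'
#' Unweighted chance-corrected agreement
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}, where \eqn{p_o} is the observed
#' agreement proportion and \eqn{p_e} the agreement expected from the two
#' raters' marginal frequencies. When the marginals are degenerate
#' (\eqn{p_e = 1}, both raters constant) kappa is undefined and returned
#' as `NA` with interpretation `"undefined"` rather than an error.
#'
#' @param paired data frame with columns `manual` and `automated`
#'   (statuses are treated as nominal labels).
#' @return a [ConcordanceResult-class].
#' @examples
#' cohensKappa(concordanceFixture("chr9"))
#' @export
cohensKappa <- function(paired) {
  if (nrow(paired) < 2) abort("cohensKappa: need >= 2 cases")
  n <- nrow(paired)
  agree <- sum(paired$manual == paired$automated)
  po <- agree / n
  levs <- sort(unique(c(paired$manual, paired$automated)))
  pm <- table(factor(paired$manual, levs)) / n
  pa <- table(factor(paired$automated, levs)) / n
  pe <- sum(as.numeric(pm) * as.numeric(pa))
  kap <- if (abs(1 - pe) < 1e-12) NA_real_ else (po - pe) / (1 - pe)
  interp <- if (is.na(kap)) "undefined"
            else if (kap > 0.8) "high"
            else if (kap > 0.6) "good"
            else "moderate-or-less"
  nExcl <- attr(paired, "nExcluded")
  new("ConcordanceResult", nUsed = as.integer(n), nAgree = as.integer(agree),
      nExcluded = as.integer(if (is.null(nExcl)) 0L else nExcl),
      percentAgreement = 100 * po, po = po, pe = pe, kappa = kap,
      interpretation = interp)
}
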