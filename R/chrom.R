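## Probe-pair registry. The red fluorophore always marks the target arm
## (1p36.32, 9p21.3, 10q23.31, 19q13.33) and the green fluorophore the
## opposite arm of the same chromosome, which serves as internal control.
CHROM_PANEL <- data.frame(
  id           = c("chr1", "chr9", "chr10", "chr19"),
  targetArm    = c("1p", "9p", "10q", "19q"),
  controlArm   = c("1q", "9q", "10p", "19p"),
  targetLocus  = c("1p36.32", "9p21.3", "10q23.31", "19q13.33"),
  controlLocus = c("1q25.2", "9q34.12", "10p12.31", "19p13.2"),
  monosomyRule = c(FALSE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

#' Probe pairs of the four-chromosome glioma FISH panel
#'
#' `chromPair()` returns the [ChromPair-class] object for one chromosome;
#' `chromPanel()` returns the full panel as a data frame (target/control
#' arms and loci, monosomy-rule flag).
#'
#' @param id chromosome id: `"chr1"`, `"chr9"`, `"chr10"` or `"chr19"`.
#'
#' @return `chromPair()`: a [ChromPair-class]; `chromPanel()`: a
#'   `data.frame` with one row per probe pair.
#'
#' @examples
#' chromPair("chr9")
#' chromPanel()
#' @export
chromPair <- function(id) {
  id <- match.arg(id, CHROM_IDS)
  row <- CHROM_PANEL[CHROM_PANEL$id == id, ]
  new("ChromPair", id = row$id, targetLocus = row$targetLocus,
      controlLocus = row$controlLocus, monosomyRule = row$monosomyRule)
}

#' @rdname chromPair
#' @export
chromPanel <- function() CHROM_PANEL

## Accepts either a ChromPair or a chromosome id string.
resolveChrom <- function(chrom) {
  if (is(chrom, "ChromPair")) chrom else chromPair(chrom)
}

setMethod("show", "ChromPair", function(object) {
  cat(sprintf("ChromPair %s: target %s (red) / control %s (green)%s\n",
              object@id, object@targetLocus, object@controlLocus,
              if (object@monosomyRule) " [1R/1G = whole-chromosome loss]"
              else ""))
})
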