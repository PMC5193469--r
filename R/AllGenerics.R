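#' Accessor generics
#'
#' Small accessor generics for the package's S4 objects: cutoff lookup,
#' status and QC extraction, and percentage access on sample summaries.
#'
#' @param x,object an object of the relevant class.
#' @param chrom chromosome id (`"chr1"`, `"chr9"`, `"chr10"`, `"chr19"`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("deletionCutoff", function(x, chrom) standardGeneric("deletionCutoff"))
#' @rdname accessors
#' @export
setGeneric("imbalanceCutoff", function(x, chrom) standardGeneric("imbalanceCutoff"))
#' @rdname accessors
#' @export
setGeneric("monosomyCutoff", function(x, chrom) standardGeneric("monosomyCutoff"))
#' @rdname accessors
#' @export
setGeneric("cutoffSource", function(x) standardGeneric("cutoffSource"))
#' @rdname accessors
#' @export
setGeneric("armStatus", function(x) standardGeneric("armStatus"))
#' @rdname accessors
#' @export
setGeneric("controlArmDeleted", function(x) standardGeneric("controlArmDeleted"))
#' @rdname accessors
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))
#' @rdname accessors
#' @export
setGeneric("qcReason", function(x) standardGeneric("qcReason"))
#' @rdname accessors
#' @export
setGeneric("sampleSummary", function(x) standardGeneric("sampleSummary"))
#' @rdname accessors
#' @export
setGeneric("nAnalyzable", function(x) standardGeneric("nAnalyzable"))
#' @rdname accessors
#' @export
setGeneric("pctDeleted", function(x) standardGeneric("pctDeleted"))
#' @rdname accessors
#' @export
setGeneric("pctImbalanced", function(x) standardGeneric("pctImbalanced"))
#' @rdname accessors
#' @export
setGeneric("pctMonosomy", function(x) standardGeneric("pctMonosomy"))
#' @rdname accessors
#' @export
setGeneric("kappaValue", function(x) standardGeneric("kappaValue"))
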