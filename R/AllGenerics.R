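#' @importFrom BiocGenerics counts
NULL

#' Accessors for trajDEG classes
#'
#' @param object a trajDEG S4 object.
#' @name accessors
NULL

#' @describeIn accessors sample annotation (`group`, `day`, `librarySize`)
#'   of a [TimecourseExperiment] as a data.frame.
#' @export
setGeneric("sampleDesign", function(object) standardGeneric("sampleDesign"))

#' @describeIn accessors original (pre-filtering) per-sample library sizes.
#' @export
setGeneric("librarySizes", function(object) standardGeneric("librarySizes"))

#' @describeIn accessors planted simulation truth (archetype, amplitude,
#'   true per-day log fold-changes, baseline mean, dispersion) or `NULL`
#'   for imported data.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @describeIn accessors the per-gene result table of a [DEResult].
#' @export
setGeneric("deTable", function(object) standardGeneric("deTable"))

#' @describeIn accessors ordered days of a [TrajectorySet] or [DEResult].
#' @export
setGeneric("assayDays", function(object) standardGeneric("assayDays"))

#' @describeIn accessors per-gene log fold-change matrix of a
#'   [TrajectorySet].
#' @export
setGeneric("trajLogFC", function(object) standardGeneric("trajLogFC"))

#' @describeIn accessors per-gene p-value matrix of a [TrajectorySet].
#' @export
setGeneric("trajPValue", function(object) standardGeneric("trajPValue"))

#' @describeIn accessors per-gene FDR matrix of a [TrajectorySet].
#' @export
setGeneric("trajFDR", function(object) standardGeneric("trajFDR"))

#' @describeIn accessors selected genes of a [PanelSelection]
#'   (up then down).
#' @export
setGeneric("selectedGenes", function(object) standardGeneric("selectedGenes"))
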