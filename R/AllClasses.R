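#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#'   colData<- rowData<-
NULL

#' Container for a longitudinal two-group count experiment
#'
#' `TimecourseExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with a fixed contract on its
#' column annotation: every sample carries a `group` label (`"ISO"` for
#' exposed, `"naive"` for control), an integer `day` (time post exposure) and
#' its original `librarySize` (total counts at import time). Library sizes
#' are frozen when the object is built so that counts-per-million keep a
#' stable denominator through gene filtering.
#'
#' Simulated objects additionally carry the planted ground truth in
#' `rowData`: the trajectory `archetype`, the signed log2 `amplitude`, the
#' per-day true log fold-changes, the baseline mean and the NB dispersion
#' (see [simulateExperiment()]).
#'
#' @slot .. inherited from `SummarizedExperiment`; the single assay is named
#'   `"counts"`.
#' @seealso [timecourseExperiment()] (constructor), [sampleDesign()],
#'   [librarySizes()], [groundTruth()]
#' @export
setClass("TimecourseExperiment", contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(cnt)) || any(cnt < 0))
            msg <- c(msg, "counts must be finite and non-negative")
        if (any(abs(cnt - round(cnt)) > 1e-8))
            msg <- c(msg, "counts must be integral")
    }
    cd <- colData(object)
    for (col in c("group", "day", "librarySize"))
        if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", col))
    if ("group" %in% colnames(cd) && !all(cd$group %in% c("ISO", "naive")))
        msg <- c(msg, "group labels must be 'ISO' or 'naive'")
    if ("librarySize" %in% colnames(cd)) {
        if (any(cd$librarySize <= 0)) msg <- c(msg, "library sizes must be positive")
        if ("counts" %in% SummarizedExperiment::assayNames(object)) {
            cs <- colSums(SummarizedExperiment::assay(object, "counts"))
            # filtering may only remove counts, never add
            if (any(cs > cd$librarySize + 1e-6))
                msg <- c(msg, "librarySize smaller than the column sum of counts")
        }
    }
    if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
    if (length(msg)) msg else TRUE
})

#' Configuration of the longitudinal count simulator
#'
#' Holds every tunable of [simulateExperiment()]. Defaults reproduce the
#' emulated study design: four post-exposure days (1, 30, 240, 360), six
#' naive samples per day, five exposed samples at day 1 and six elsewhere,
#' NB dispersion 0.05, planted amplitudes uniform on 0.3-1.2 log2 units and
#' the two trajectory archetype shapes (short-term: full effect at day 1,
#' half at day 30, none later; late-onset: none early, half at day 240, full
#' at day 360).
#'
#' @slot nGenes number of simulated genes.
#' @slot days ordered integer vector of post-exposure days.
#' @slot nNaive,nIso integer vectors, samples per group at each day.
#' @slot baselineLog2Mean length-2 numeric: mean and sd of per-gene log2
#'   baseline relative expression.
#' @slot dispersion named list: `type` (`"constant"` or `"trend"`), `phi`
#'   (constant value), and for the trend model `a`, `b` of
#'   `phi = a / mu + b`.
#' @slot librarySizeLog length-2 numeric: meanlog and sdlog of the log-normal
#'   per-sample sequencing depth (total counts).
#' @slot archetypeFractions named numeric over
#'   `null, short_term_up, short_term_down, late_onset_up, late_onset_down`,
#'   summing to 1.
#' @slot archetypeCounts optional named integer vector of exact per-archetype
#'   gene counts; when set it overrides the fractions.
#' @slot amplitudeRange length-2 numeric, bounds of the uniform signed log2
#'   amplitude.
#' @slot patternShortTerm,patternLateOnset per-day multipliers of the two
#'   archetype shapes (same length as `days`).
#' @slot seed integer RNG seed (`NA` leaves the RNG state alone).
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig", representation(
    nGenes = "integer", days = "integer",
    nNaive = "integer", nIso = "integer",
    baselineLog2Mean = "numeric", dispersion = "list",
    librarySizeLog = "numeric",
    archetypeFractions = "numeric", archetypeCounts = "integer",
    amplitudeRange = "numeric",
    patternShortTerm = "numeric", patternLateOnset = "numeric",
    seed = "integer"))

.ARCHETYPES <- c("null", "short_term_up", "short_term_down",
                 "late_onset_up", "late_onset_down")

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1) msg <- c(msg, "nGenes must be positive")
    nd <- length(object@days)
    if (nd < 1 || is.unsorted(object@days, strictly = TRUE))
        msg <- c(msg, "days must be strictly increasing integers")
    if (length(object@nNaive) != nd || length(object@nIso) != nd)
        msg <- c(msg, "nNaive and nIso must have one entry per day")
    if (any(c(object@nNaive, object@nIso) < 2))
        msg <- c(msg, "at least 2 samples per group per day are required")
    f <- object@archetypeFractions
    if (!setequal(names(f), .ARCHETYPES))
        msg <- c(msg, "archetypeFractions must name all five archetypes")
    else if (abs(sum(f) - 1) > 1e-12 || any(f < 0))
        msg <- c(msg, "archetypeFractions must be non-negative and sum to 1 (tol 1e-12)")
    if (length(object@archetypeCounts) &&
        (!setequal(names(object@archetypeCounts), .ARCHETYPES) ||
         sum(object@archetypeCounts) != object@nGenes ||
         any(object@archetypeCounts < 0)))
        msg <- c(msg, "archetypeCounts must name all archetypes and sum to nGenes")
    if (length(object@amplitudeRange) != 2 ||
        object@amplitudeRange[1] >= object@amplitudeRange[2] ||
        object@amplitudeRange[1] <= 0)
        msg <- c(msg, "amplitudeRange must be 0 < low < high")
    if (length(object@patternShortTerm) != nd || length(object@patternLateOnset) != nd)
        msg <- c(msg, "pattern multipliers must have one entry per day")
    d <- object@dispersion
    if (!identical(d$type, "constant") && !identical(d$type, "trend"))
        msg <- c(msg, "dispersion$type must be 'constant' or 'trend'")
    if (identical(d$type, "constant") && (is.null(d$phi) || d$phi < 0))
        msg <- c(msg, "constant dispersion needs phi >= 0")
    if (length(msg)) msg else TRUE
})

#' Per-gene log fold-change trajectories across timepoints
#'
#' Aligned genes-by-days matrices of estimated log2 fold-changes, unadjusted
#' p-values and within-day BH FDR, built from per-timepoint differential
#' expression tables by [buildTrajectories()]. A gene filtered out at some
#' day is `NA`-masked at that day and retained elsewhere.
#'
#' @slot days ordered numeric vector of timepoints.
#' @slot logFC,pvalue,fdr genes-by-days numeric matrices (rownames = gene
#'   ids, `NA` = masked).
#' @export
setClass("TrajectorySet", representation(
    days = "numeric", logFC = "matrix", pvalue = "matrix", fdr = "matrix"))

setValidity("TrajectorySet", function(object) {
    msg <- character()
    dm <- dim(object@logFC)
    if (!identical(dim(object@pvalue), dm) || !identical(dim(object@fdr), dm))
        msg <- c(msg, "logFC, pvalue and fdr must share dimensions")
    if (ncol(object@logFC) != length(object@days))
        msg <- c(msg, "one column per day is required")
    if (is.unsorted(object@days, strictly = TRUE))
        msg <- c(msg, "days must be strictly increasing")
    if (anyDuplicated(rownames(object@logFC))) msg <- c(msg, "duplicate gene ids")
    if (length(msg)) msg else TRUE
})

#' Result of a trajectory selection rule
#'
#' Up- and down-regulated gene lists produced by [selectShortTerm()] or
#' [selectLateOnset()], with the thresholds used and a per-gene reason code
#' (`"primary"` for a primary-day hit, `"consistent"` for the two-day
#' sign-consistency arm, `"joint"` for the late-onset joint rule).
#'
#' @slot rule `"short_term"` or `"late_onset"`.
#' @slot up,down character vectors of selected gene ids (disjoint).
#' @slot reason named character, reason code per selected gene.
#' @slot excluded character, genes that met a rule but had no usable
#'   direction (zero log fold-change at every qualifying day).
#' @slot criteria named list of the thresholds that were applied.
#' @export
setClass("PanelSelection", representation(
    rule = "character", up = "character", down = "character",
    reason = "character", excluded = "character", criteria = "list"))

setValidity("PanelSelection", function(object) {
    msg <- character()
    if (length(intersect(object@up, object@down)))
        msg <- c(msg, "up and down lists must be disjoint")
    sel <- c(object@up, object@down)
    if (anyDuplicated(sel)) msg <- c(msg, "duplicate genes in selection")
    if (!all(sel %in% names(object@reason)))
        msg <- c(msg, "every selected gene needs a reason code")
    if (length(msg)) msg else TRUE
})

#' Per-timepoint differential expression result
#'
#' One two-group NB contrast (`ISO` minus `naive`) at a single day. The
#' table has one row per gene with the log2 fold-change, average log2 CPM,
#' unadjusted p-value and the within-table BH FDR.
#'
#' @slot table data.frame with columns `gene`, `logFC`, `aveLog2CPM`,
#'   `pvalue`, `fdr`.
#' @slot day numeric timepoint of the contrast.
#' @slot engine `"qlf"` (quasi-likelihood F-test) or `"lrt"` (likelihood
#'   ratio test).
#' @export
setClass("DEResult", representation(
    table = "data.frame", day = "numeric", engine = "character"))

setValidity("DEResult", function(object) {
    msg <- character()
    need <- c("gene", "logFC", "aveLog2CPM", "pvalue", "fdr")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(object@table$gene)) msg <- c(msg, "duplicate gene ids")
        p <- object@table$pvalue
        if (any(p < 0 | p > 1, na.rm = TRUE)) msg <- c(msg, "p-values outside [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' Principal-component QC of normalized expression
#'
#' Sample scores on the first two principal components of gene-centered
#' log-expression, variance explained per component, per-group 95%
#' confidence ellipses (from the 2D score covariance and the chi-square(2)
#' quantile) and the samples falling outside their group's ellipse.
#'
#' @slot scores samples-by-2 matrix of PC scores.
#' @slot varExplained proportion of variance per component (all components).
#' @slot ellipses named list per group: `center`, `cov`, `radii`, `angle`
#'   (radians), `n`; `NULL` when the group has fewer than 3 samples.
#' @slot outliers character, samples outside their group ellipse.
#' @slot level confidence level of the ellipses.
#' @export
setClass("PcaResult", representation(
    scores = "matrix", varExplained = "numeric", ellipses = "list",
    outliers = "character", level = "numeric"))
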