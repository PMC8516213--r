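# Per-timepoint two-group NB differential expression. The model fitting is
# delegated to edgeR (NB GLM with quasi-likelihood F-test or likelihood
# ratio test); this module fixes the contrasts, offsets and multiplicity
# handling of the longitudinal pipeline around it.

.subsetDay <- function(tce, day) {
    des <- sampleDesign(tce)
    sel <- des$day == day
    if (!any(sel)) stop("no samples at day ", day)
    if (length(unique(des$group[sel])) < 2)
        stop("both groups are required at day ", day)
    tce[, sel]
}

.dayDGEList <- function(tce, normFactors) {
    des <- sampleDesign(tce)
    nf <- normFactors$normFactor[match(des$sample_id, normFactors$sample)]
    if (any(is.na(nf))) stop("normalization factors missing for some samples")
    nf <- nf / exp(mean(log(nf)))   # re-anchor geometric mean within the subset
    group <- factor(des$group, levels = c("naive", "ISO"))
    y <- edgeR::DGEList(counts = counts(tce), group = group,
                        lib.size = unname(librarySizes(tce)),
                        norm.factors = nf)
    list(y = y, design = stats::model.matrix(~group))
}

#' Estimate NB dispersions for one timepoint
#'
#' Per-gene dispersion of the NB model (variance `mu + phi * mu^2`),
#' estimated by [edgeR::estimateDisp()]: a raw per-gene estimate (maximized
#' adjusted profile likelihood), an abundance trend, and the empirical-Bayes
#' shrunk value that pulls each gene toward the trend with `priorDf` prior
#' degrees of freedom. Genes with no counts take the trend value and are
#' flagged.
#'
#' @param tce filtered [TimecourseExperiment].
#' @param day timepoint whose samples are used.
#' @param priorDf prior degrees of freedom of the shrinkage (default 10).
#' @param normFactors output of [tmmFactors()]; computed from `tce` when
#'   `NULL`.
#' @return data.frame with `gene`, `raw`, `trended`, `shrunk`, `allZero`.
#' @export
estimateDispersion <- function(tce, day, priorDf = 10, normFactors = NULL) {
    stopifnot(is(tce, "TimecourseExperiment"))
    if (is.null(normFactors)) normFactors <- tmmFactors(tce)
    sub <- .subsetDay(tce, day)
    d <- .dayDGEList(sub, normFactors)
    fitS <- edgeR::estimateDisp(d$y, d$design, prior.df = priorDf)
    fitR <- edgeR::estimateDisp(d$y, d$design, prior.df = 0)
    allZero <- rowSums(counts(sub)) == 0
    raw <- fitR$tagwise.dispersion
    shrunk <- fitS$tagwise.dispersion
    raw[allZero] <- fitS$trended.dispersion[allZero]
    shrunk[allZero] <- fitS$trended.dispersion[allZero]
    data.frame(gene = rownames(sub), raw = raw,
               trended = fitS$trended.dispersion, shrunk = shrunk,
               allZero = allZero, row.names = NULL)
}

#' Two-group differential expression at one timepoint
#'
#' Fits a per-gene NB generalized linear model with a group indicator
#' (ISO vs naive) and TMM-effective library size offsets on the samples of
#' one day, and tests the group coefficient. Engine `"qlf"` is the
#' quasi-likelihood F-test (moderated denominator degrees of freedom);
#' `"lrt"` is the likelihood-ratio chi-square(1) test. Log2 fold-changes
#' are stabilized with `priorCount` (average pseudo-count per library) so
#' they stay finite at zero counts. FDR is the BH adjustment within the
#' returned table.
#'
#' @param tce filtered [TimecourseExperiment].
#' @param day the timepoint to test.
#' @param engine `"qlf"` or `"lrt"`.
#' @param normFactors output of [tmmFactors()] on the full experiment;
#'   computed when `NULL`.
#' @param priorDf prior degrees of freedom for dispersion shrinkage.
#' @param priorCount fold-change stabilizing pseudo-count (default 0.5).
#' @return A [DEResult].
#' @examples
#' tce <- simulateExperiment(simulationConfig(
#'     nGenes = 300, days = c(1, 30), nIso = c(5, 6),
#'     patternShortTerm = c(1, 0.5), patternLateOnset = c(0, 0), seed = 7))
#' de <- testTimepoint(filterLowExpression(tce, verbose = FALSE), day = 1)
#' head(deTable(de))
#' @export
testTimepoint <- function(tce, day, engine = c("qlf", "lrt"),
                          normFactors = NULL, priorDf = 10, priorCount = 0.5) {
    stopifnot(is(tce, "TimecourseExperiment"))
    engine <- match.arg(engine)
    if (is.null(normFactors)) normFactors <- tmmFactors(tce)
    sub <- .subsetDay(tce, day)
    d <- .dayDGEList(sub, normFactors)
    y <- edgeR::estimateDisp(d$y, d$design, prior.df = priorDf)
    if (engine == "qlf") {
        fit <- edgeR::glmQLFit(y, d$design, prior.count = priorCount)
        res <- edgeR::glmQLFTest(fit, coef = 2)
    } else {
        fit <- edgeR::glmFit(y, d$design, prior.count = priorCount)
        res <- edgeR::glmLRT(fit, coef = 2)
    }
    tab <- res$table
    p <- tab$PValue
    bad <- !is.finite(p)
    if (any(bad)) {
        # rare non-convergence: exact conditional NB test as fallback
        et <- edgeR::exactTest(y)
        p[bad] <- et$table$PValue[bad]
        tab$logFC[bad] <- et$table$logFC[bad]
    }
    out <- data.frame(gene = rownames(sub), logFC = tab$logFC,
                      aveLog2CPM = tab$logCPM, pvalue = p,
                      fdr = bhAdjust(p), fallback = bad, row.names = NULL)
    new("DEResult", table = out, day = as.numeric(day), engine = engine)
}

#' @rdname accessors
#' @export
setMethod("deTable", "DEResult", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("assayDays", "DEResult", function(object) object@day)

setMethod("show", "DEResult", function(object) {
    tab <- object@table
    cat(sprintf("DEResult (ISO vs naive, day %g, engine %s): %d genes\n",
                object@day, object@engine, nrow(tab)))
    cat(sprintf("  p < 0.05: %d | FDR < 0.05: %d\n",
                sum(tab$pvalue < 0.05, na.rm = TRUE),
                sum(tab$fdr < 0.05, na.rm = TRUE)))
})

#' Volcano-plot table
#'
#' Per-gene coordinates of a volcano plot: log2 fold-change against
#' `-log10(p)` (clamped at 300 against underflow), with genes flagged
#' significant at `p < pCut` (strict, so a p-value exactly at the cut is
#' not flagged).
#'
#' @param de a [DEResult] or a list of them (concatenated, e.g. to pool all
#'   timepoints in one plot).
#' @param pCut significance cut on the unadjusted p-value.
#' @return data.frame with `gene`, `day`, `logFC`, `negLog10P`,
#'   `significant`.
#' @export
volcanoTable <- function(de, pCut = 0.05) {
    if (is(de, "DEResult")) de <- list(de)
    out <- do.call(rbind, lapply(de, function(d) {
        tab <- deTable(d)
        data.frame(gene = tab$gene, day = rep(d@day, nrow(tab)), logFC = tab$logFC,
                   negLog10P = pmin(-log10(tab$pvalue), 300),
                   significant = tab$pvalue < pCut, row.names = NULL)
    }))
    out
}
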