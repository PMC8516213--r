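#' Counts per million
#'
#' `CPM = counts / librarySize * 1e6`. For a [TimecourseExperiment] the
#' denominator is the object's stored original library size, so values are
#' unchanged by gene filtering. With `log = TRUE`, log2 CPM is computed with
#' the pseudo-count handling of [edgeR::cpm()] (`prior.count` added to
#' counts against proportionally adjusted library sizes).
#'
#' @param x [TimecourseExperiment] or numeric count matrix.
#' @param log return log2 values.
#' @param priorCount pseudo-count for the log transform (default 1).
#' @param libSizes optional explicit library sizes (matrix input only;
#'   defaults to column sums).
#' @return genes x samples numeric matrix.
#' @export
computeCPM <- function(x, log = FALSE, priorCount = 1, libSizes = NULL) {
    if (is(x, "TimecourseExperiment")) {
        libSizes <- librarySizes(x)
        x <- counts(x)
    } else {
        x <- as.matrix(x)
        if (is.null(libSizes)) libSizes <- colSums(x)
    }
    if (any(libSizes <= 0)) stop("zero or negative library size")
    edgeR::cpm(x, lib.size = libSizes, log = log, prior.count = priorCount)
}

#' Remove genes with uniformly low expression
#'
#' Drops genes whose CPM is below `cpmThreshold` in every sample (the
#' default 0.5 reproduces the standard low-expression exclusion for this
#' design); a gene reaching the threshold in at least one sample is kept.
#' Library sizes are not recomputed, so the operation is idempotent.
#'
#' @param tce a [TimecourseExperiment].
#' @param cpmThreshold CPM threshold (>= 0).
#' @param verbose report the number of genes removed.
#' @return Filtered [TimecourseExperiment]; the number of removed genes is
#'   recorded in `metadata(x)$nFiltered`.
#' @export
filterLowExpression <- function(tce, cpmThreshold = 0.5, verbose = TRUE) {
    stopifnot(is(tce, "TimecourseExperiment"))
    if (cpmThreshold < 0) stop("cpmThreshold must be >= 0")
    keep <- rowSums(computeCPM(tce) >= cpmThreshold) > 0
    out <- tce[keep, ]
    metadata(out)$nFiltered <- sum(!keep)
    if (verbose)
        message(sum(!keep), " of ", length(keep), " genes below ", cpmThreshold,
                " CPM in all samples removed; ", sum(keep), " retained")
    out
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors via
#' [edgeR::calcNormFactors()]: per-gene log2 CPM ratios (M) against a
#' reference sample are doubly trimmed by M and by average abundance, and
#' the factor is two to the precision-weighted mean of the surviving M
#' values, rescaled so the factors have geometric mean 1. The reference
#' defaults to the sample whose upper-quartile CPM is closest to the mean
#' upper-quartile.
#'
#' @param x [TimecourseExperiment] or count matrix (ideally already
#'   filtered).
#' @param trimM fraction of M values trimmed from each tail (default 0.30).
#' @param trimA fraction trimmed by average abundance (default 0.05).
#' @param reference optional reference sample id.
#' @return data.frame with `sample`, `libSize`, `normFactor`,
#'   `effLibSize` (= libSize * normFactor).
#' @export
tmmFactors <- function(x, trimM = 0.30, trimA = 0.05, reference = NULL) {
    if (is(x, "TimecourseExperiment")) {
        libSizes <- librarySizes(x)
        m <- counts(x)
    } else {
        m <- as.matrix(x)
        libSizes <- colSums(m)
    }
    if (ncol(m) < 2) stop("TMM needs at least 2 samples")
    refColumn <- NULL
    if (!is.null(reference)) {
        refColumn <- match(reference, colnames(m))
        if (is.na(refColumn)) stop("reference sample not found: ", reference)
    }
    f <- edgeR::calcNormFactors(m, lib.size = unname(libSizes), method = "TMM",
                                refColumn = refColumn,
                                logratioTrim = trimM, sumTrim = trimA)
    if (any(!is.finite(f)) || any(f <= 0))
        stop("TMM failed: a sample shares no positively expressed genes with the reference")
    data.frame(sample = colnames(m), libSize = unname(libSizes),
               normFactor = f, effLibSize = unname(libSizes) * f,
               row.names = NULL)
}

#' PCA quality assessment with group confidence ellipses
#'
#' Projects samples on the first two principal components of gene-centered
#' log-expression. For each group with at least three samples, a confidence
#' ellipse is derived from the 2D score covariance and the chi-square(2)
#' quantile at `level`. Outlier flagging is leave-one-out: each sample's
#' squared Mahalanobis distance is computed against the center and
#' covariance of the other samples of its group, and compared with the
#' Hotelling T-squared (F-based) quantile appropriate for a covariance
#' estimated from few samples. (Using the group's own covariance a single
#' outlier in a small group could never be flagged, since that distance is
#' bounded by `(n - 1)^2 / n`; and the chi-square quantile is far too
#' liberal when the covariance comes from 4-5 points.) Flagging needs at
#' least 4 samples per group.
#'
#' @param logExpr genes x samples matrix of normalized log-expression.
#' @param design data.frame with `sample_id` and a grouping column.
#' @param groupBy name of the grouping column (default `"group"`).
#' @param level confidence level of the ellipses.
#' @return A [PcaResult].
#' @export
pcaQC <- function(logExpr, design, groupBy = "group", level = 0.95) {
    logExpr <- as.matrix(logExpr)
    if (ncol(logExpr) < 3) stop("PCA QC needs at least 3 samples")
    if (any(!is.finite(logExpr))) stop("non-finite expression values")
    design <- as.data.frame(design)
    if (!all(c("sample_id", groupBy) %in% colnames(design)))
        stop("design needs columns 'sample_id' and '", groupBy, "'")
    idx <- match(colnames(logExpr), design$sample_id)
    if (any(is.na(idx))) stop("samples missing from design")
    grp <- as.character(design[[groupBy]][idx])

    pc <- stats::prcomp(t(logExpr), center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    scores <- pc$x[, 1:2, drop = FALSE]
    colnames(scores) <- c("PC1", "PC2")

    q <- stats::qchisq(level, df = 2)
    ellipses <- list()
    outliers <- character()
    for (g in unique(grp)) {
        s <- scores[grp == g, , drop = FALSE]
        if (nrow(s) < 3) {
            ellipses[[g]] <- NULL
            next
        }
        ctr <- colMeans(s)
        cv <- stats::cov(s)
        ev <- eigen(cv, symmetric = TRUE)
        ellipses[[g]] <- list(center = ctr, cov = cv,
                              radii = sqrt(pmax(ev$values, 0) * q),
                              angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
                              n = nrow(s))
        if (nrow(s) >= 4) {
            m <- nrow(s) - 1
            # held-out point vs mean/cov of m others: scaled F with 2, m-2 df
            qLoo <- (m + 1) / m * 2 * (m - 1) / (m - 2) *
                stats::qf(level, 2, m - 2)
            for (i in seq_len(nrow(s))) {
                rest <- s[-i, , drop = FALSE]
                cvr <- stats::cov(rest)
                if (min(eigen(cvr, symmetric = TRUE, only.values = TRUE)$values)
                    <= 1e-12) next
                if (stats::mahalanobis(s[i, , drop = FALSE],
                                       colMeans(rest), cvr) > qLoo)
                    outliers <- c(outliers, rownames(s)[i])
            }
        }
    }
    new("PcaResult", scores = scores, varExplained = ve,
        ellipses = ellipses, outliers = outliers, level = level)
}

setMethod("show", "PcaResult", function(object) {
    cat(sprintf("PcaResult: %d samples, PC1 %.1f%%, PC2 %.1f%% variance\n",
                nrow(object@scores), 100 * object@varExplained[1],
                100 * object@varExplained[2]))
    if (length(object@outliers))
        cat("  outside their ", 100 * object@level, "% group ellipse: ",
            paste(object@outliers, collapse = ", "), "\n", sep = "")
    else cat("  no samples outside their group ellipse\n")
})
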