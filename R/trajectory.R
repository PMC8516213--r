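# Per-gene logFC trajectories across days, the short-term / late-onset
# selection rules, and the nonparametric trend-test battery on pooled
# trajectories.

#' Align per-day DE tables into trajectories
#'
#' Collects per-timepoint [DEResult] tables into genes-by-days matrices of
#' log2 fold-change, p-value and FDR, days sorted ascending. The gene
#' universe is the union across tables; a gene absent from some day's table
#' (e.g. filtered there) is `NA`-masked at that day.
#'
#' @param tables list of [DEResult] objects, one per day (any order).
#' @return A [TrajectorySet].
#' @export
buildTrajectories <- function(tables) {
    if (is(tables, "DEResult")) tables <- list(tables)
    if (length(tables) < 2) stop("need tables for >= 2 days")
    days <- vapply(tables, assayDays, numeric(1))
    if (anyDuplicated(days)) stop("duplicate day tables: ",
                                  paste(days[duplicated(days)], collapse = ", "))
    o <- order(days)
    tables <- tables[o]; days <- days[o]
    genes <- unique(unlist(lapply(tables, function(t) deTable(t)$gene)))
    mk <- function(col) {
        m <- matrix(NA_real_, length(genes), length(days),
                    dimnames = list(genes, paste0("day", days)))
        for (i in seq_along(tables)) {
            tab <- deTable(tables[[i]])
            m[match(tab$gene, genes), i] <- tab[[col]]
        }
        m
    }
    new("TrajectorySet", days = days, logFC = mk("logFC"),
        pvalue = mk("pvalue"), fdr = mk("fdr"))
}

#' @rdname accessors
#' @export
setMethod("assayDays", "TrajectorySet", function(object) object@days)
#' @rdname accessors
#' @export
setMethod("trajLogFC", "TrajectorySet", function(object) object@logFC)
#' @rdname accessors
#' @export
setMethod("trajPValue", "TrajectorySet", function(object) object@pvalue)
#' @rdname accessors
#' @export
setMethod("trajFDR", "TrajectorySet", function(object) object@fdr)

setMethod("show", "TrajectorySet", function(object) {
    cat("TrajectorySet:", nrow(object@logFC), "genes x",
        length(object@days), "days (", paste(object@days, collapse = ", "), ")\n")
    masked <- sum(is.na(object@logFC))
    if (masked) cat("  masked entries:", masked, "\n")
})

.dayCol <- function(ts, day) {
    i <- match(day, ts@days)
    if (is.na(i)) stop("day ", day, " not present in trajectories")
    i
}

.resolveDirection <- function(lfcPrimary, lfcSecondary) {
    s <- sign(lfcPrimary)
    zero <- !is.na(s) & s == 0
    s[zero] <- sign(lfcSecondary)[zero]
    s
}

#' Select short-term (dissipating) genes
#'
#' A gene is selected when, within the optional panel restriction, it is
#' significant at the primary day (`p < pPrimary`, unadjusted) or changes in
#' the same direction at both early days with `p < pConsistent` at each
#' (the sign-consistency arm). The up/down split uses the log fold-change
#' sign at the primary day; a selected gene with zero primary-day logFC
#' falls back to the consistency day's sign and is excluded (and recorded)
#' if both are zero.
#'
#' @param ts a [TrajectorySet] containing both early days.
#' @param panel optional character vector of gene ids the rule is restricted
#'   to (e.g. a GO-derived panel); `NULL` means all measured genes.
#' @param pPrimary primary-day threshold (default 0.05).
#' @param pConsistent two-day consistency threshold (default 0.1).
#' @param primaryDay,consistentDay the two early days (defaults 1 and 30).
#' @return A [PanelSelection] with reason codes `"primary"` /
#'   `"consistent"`.
#' @export
selectShortTerm <- function(ts, panel = NULL, pPrimary = 0.05,
                            pConsistent = 0.1, primaryDay = 1,
                            consistentDay = 30) {
    stopifnot(is(ts, "TrajectorySet"))
    if (any(c(pPrimary, pConsistent) <= 0) || any(c(pPrimary, pConsistent) > 1))
        stop("thresholds must lie in (0, 1]")
    i1 <- .dayCol(ts, primaryDay); i2 <- .dayCol(ts, consistentDay)
    genes <- rownames(ts@logFC)
    keep <- if (is.null(panel)) rep(TRUE, length(genes)) else genes %in% panel
    if (!any(keep)) stop("panel shares no genes with the trajectories")

    p1 <- ts@pvalue[, i1]; p2 <- ts@pvalue[, i2]
    l1 <- ts@logFC[, i1]; l2 <- ts@logFC[, i2]
    primary <- !is.na(p1) & p1 < pPrimary
    consistent <- !is.na(p1) & !is.na(p2) & p1 < pConsistent & p2 < pConsistent &
        sign(l1) == sign(l2) & sign(l1) != 0
    hit <- keep & (primary | consistent)

    dir <- .resolveDirection(l1, l2)
    excluded <- genes[hit & (is.na(dir) | dir == 0)]
    if (length(excluded))
        warning(length(excluded), " selected gene(s) without a usable direction excluded")
    up <- genes[hit & !is.na(dir) & dir > 0]
    down <- genes[hit & !is.na(dir) & dir < 0]
    reason <- ifelse(primary, "primary", "consistent")[match(c(up, down), genes)]
    new("PanelSelection", rule = "short_term", up = up, down = down,
        reason = stats::setNames(reason, c(up, down)), excluded = excluded,
        criteria = list(pPrimary = pPrimary, pConsistent = pConsistent,
                        primaryDay = primaryDay, consistentDay = consistentDay,
                        panelSize = if (is.null(panel)) NA_integer_ else sum(keep)))
}

#' Select late-onset genes
#'
#' A gene is selected when it reaches `FDR < fdrLate` at the late day,
#' `p < pLate` (unadjusted) at the preceding day, and its log fold-changes
#' at the two days share a (non-zero) sign. The up/down split uses that
#' common sign.
#'
#' @param ts a [TrajectorySet] containing both late days.
#' @param fdrLate FDR threshold at the late day (default 0.05).
#' @param pLate unadjusted threshold at the preceding day (default 0.1).
#' @param lateDay,precedingDay the two late days (defaults 360 and 240).
#' @return A [PanelSelection] with reason code `"joint"`.
#' @export
selectLateOnset <- function(ts, fdrLate = 0.05, pLate = 0.1,
                            lateDay = 360, precedingDay = 240) {
    stopifnot(is(ts, "TrajectorySet"))
    if (any(c(fdrLate, pLate) <= 0) || any(c(fdrLate, pLate) > 1))
        stop("thresholds must lie in (0, 1]")
    iL <- .dayCol(ts, lateDay); iP <- .dayCol(ts, precedingDay)
    genes <- rownames(ts@logFC)
    fdrL <- ts@fdr[, iL]; pP <- ts@pvalue[, iP]
    lL <- ts@logFC[, iL]; lP <- ts@logFC[, iP]
    hit <- !is.na(fdrL) & !is.na(pP) & fdrL < fdrLate & pP < pLate &
        sign(lL) == sign(lP) & sign(lL) != 0
    up <- genes[hit & lL > 0]
    down <- genes[hit & lL < 0]
    new("PanelSelection", rule = "late_onset", up = up, down = down,
        reason = stats::setNames(rep("joint", length(c(up, down))), c(up, down)),
        excluded = character(),
        criteria = list(fdrLate = fdrLate, pLate = pLate,
                        lateDay = lateDay, precedingDay = precedingDay))
}

#' @rdname accessors
#' @export
setMethod("selectedGenes", "PanelSelection",
          function(object) c(object@up, object@down))

setMethod("show", "PanelSelection", function(object) {
    cat(sprintf("PanelSelection (%s): %d genes (%d up, %d down)\n",
                object@rule, length(object@up) + length(object@down),
                length(object@up), length(object@down)))
    if (length(object@excluded))
        cat("  excluded (no direction):", length(object@excluded), "\n")
})

#' Summarize the trajectory of a gene panel
#'
#' Per-day mean and median log fold-change over a gene list, with the
#' gene-level spread. Masked entries are omitted day by day.
#'
#' @param ts a [TrajectorySet].
#' @param genes non-empty character vector of gene ids.
#' @return data.frame with `day`, `n`, `mean`, `median`, `sd`, `se`.
#' @export
summarizeTrajectory <- function(ts, genes) {
    stopifnot(is(ts, "TrajectorySet"))
    if (!length(genes)) stop("empty gene list")
    m <- ts@logFC[rownames(ts@logFC) %in% genes, , drop = FALSE]
    if (!nrow(m)) stop("none of the genes are present in the trajectories")
    n <- colSums(!is.na(m))
    data.frame(day = ts@days, n = n,
               mean = colMeans(m, na.rm = TRUE),
               median = apply(m, 2, stats::median, na.rm = TRUE),
               sd = apply(m, 2, stats::sd, na.rm = TRUE),
               se = apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1)),
               row.names = NULL)
}

#' Panel mean expression difference with sample-level errors
#'
#' Per-gene log fold-change estimates at one day share samples and
#' normalization factors, so their errors are correlated across genes and
#' the naive `sd/sqrt(nGenes)` understates the uncertainty of a panel mean.
#' This summary instead treats samples as the unit of replication: for each
#' sample it averages TMM-normalized log2 CPM over the panel genes, and per
#' day reports the ISO minus naive difference of those panel means with its
#' two-sample pooled standard error.
#'
#' @param tce the (filtered) [TimecourseExperiment] the DE tables came
#'   from.
#' @param genes panel gene ids.
#' @param normFactors output of [tmmFactors()]; computed when `NULL`.
#' @param priorCount pseudo-count of the log2 CPM transform.
#' @return data.frame with `day`, `diff`, `se`, `nIso`, `nNaive`.
#' @export
panelMeanDifference <- function(tce, genes, normFactors = NULL, priorCount = 1) {
    stopifnot(is(tce, "TimecourseExperiment"))
    genes <- intersect(genes, rownames(tce))
    if (!length(genes)) stop("no panel genes present in the experiment")
    if (is.null(normFactors)) normFactors <- tmmFactors(tce)
    des <- sampleDesign(tce)
    eff <- normFactors$effLibSize[match(des$sample_id, normFactors$sample)]
    lcpm <- edgeR::cpm(counts(tce), lib.size = eff, log = TRUE,
                       prior.count = priorCount)
    pm <- colMeans(lcpm[genes, , drop = FALSE])
    out <- lapply(sort(unique(des$day)), function(d) {
        iso <- pm[des$day == d & des$group == "ISO"]
        nai <- pm[des$day == d & des$group == "naive"]
        n1 <- length(iso); n2 <- length(nai)
        sp2 <- ((n1 - 1) * stats::var(iso) + (n2 - 1) * stats::var(nai)) /
            (n1 + n2 - 2)
        data.frame(day = d, diff = mean(iso) - mean(nai),
                   se = sqrt(sp2 * (1 / n1 + 1 / n2)), nIso = n1, nNaive = n2)
    })
    do.call(rbind, out)
}

#' Battery presets matching the study's trend tables
#'
#' `"short_term"`: Mann-Whitney on days 240 vs 360 (two-sided),
#' Kruskal-Wallis on days 1/30/240, and the Jonckheere-Terpstra trend over
#' all days with the decreasing alternative for the up panel and increasing
#' for the down panel (a dissipating effect shrinks toward zero).
#' `"late_onset"`: Kruskal-Wallis on days 30/240/360 and
#' Jonckheere-Terpstra over all days with increasing (up) / decreasing
#' (down) alternatives.
#'
#' @param rule `"short_term"` or `"late_onset"`.
#' @return List of comparison specifications consumed by [trendBattery()].
#' @export
batteryPreset <- function(rule = c("short_term", "late_onset")) {
    rule <- match.arg(rule)
    if (rule == "short_term") list(
        list(test = "mann_whitney", days = c(240, 360),
             altUp = "two.sided", altDown = "two.sided",
             hypothesis = "Equal logFC distribution on days 240 and 360"),
        list(test = "kruskal_wallis", days = c(1, 30, 240),
             altUp = "two.sided", altDown = "two.sided",
             hypothesis = "Equal logFC distribution on days 1, 30 and 240"),
        list(test = "jonckheere", days = NULL,
             altUp = "decreasing", altDown = "increasing",
             hypothesis = "No trend of logFC over time"))
    else list(
        list(test = "kruskal_wallis", days = c(30, 240, 360),
             altUp = "two.sided", altDown = "two.sided",
             hypothesis = "Equal logFC distribution on days 30, 240 and 360"),
        list(test = "jonckheere", days = NULL,
             altUp = "increasing", altDown = "decreasing",
             hypothesis = "No trend of logFC over time"))
}

#' Trend-test battery on pooled panel trajectories
#'
#' For each of the up and down panels, pools the per-gene log fold-changes
#' by day and runs the configured comparisons (Mann-Whitney between two
#' days, Kruskal-Wallis across a day triple, Jonckheere-Terpstra over all
#' days with a panel-direction-specific one-sided alternative). Genes
#' masked at any day of a comparison are dropped from that comparison
#' (complete case).
#'
#' @param ts a [TrajectorySet].
#' @param panel a [PanelSelection].
#' @param comparisons a preset from [batteryPreset()] (default chosen by
#'   the panel's rule) or a custom list in the same format.
#' @return data.frame with `panel`, `hypothesis`, `test`, `alternative`,
#'   `statistic`, `p`; p-values below 2.2e-16 are additionally formatted in
#'   the `pText` column as `"< 2.2e-16"`.
#' @export
trendBattery <- function(ts, panel, comparisons = NULL) {
    stopifnot(is(ts, "TrajectorySet"), is(panel, "PanelSelection"))
    if (is.null(comparisons)) comparisons <- batteryPreset(panel@rule)
    sides <- list(up = panel@up, down = panel@down)
    rows <- list()
    for (side in names(sides)) {
        genes <- sides[[side]]
        if (!length(genes)) next
        m <- ts@logFC[rownames(ts@logFC) %in% genes, , drop = FALSE]
        for (cmp in comparisons) {
            days <- if (is.null(cmp$days)) ts@days else cmp$days
            cols <- vapply(days, function(d) .dayCol(ts, d), integer(1))
            sub <- m[stats::complete.cases(m[, cols, drop = FALSE]), cols,
                     drop = FALSE]
            if (!nrow(sub)) stop("no complete-case genes for a battery comparison")
            groups <- lapply(seq_along(cols), function(i) sub[, i])
            alt <- if (side == "up") cmp$altUp else cmp$altDown
            ht <- switch(cmp$test,
                mann_whitney = mannWhitneyU(groups[[1]], groups[[2]],
                                            alternative = alt, method = "normal"),
                kruskal_wallis = kruskalWallisTest(groups),
                jonckheere = jonckheereTerpstra(groups, alternative = alt,
                                                method = "normal"),
                stop("unknown test: ", cmp$test))
            rows[[length(rows) + 1L]] <- data.frame(
                panel = side, hypothesis = paste0(cmp$hypothesis,
                                                  " in the '", side, "' panel"),
                test = cmp$test, alternative = alt,
                statistic = unname(ht$statistic), p = ht$p.value,
                n = nrow(sub), row.names = NULL)
        }
    }
    out <- do.call(rbind, rows)
    out$pText <- ifelse(out$p < 2.2e-16, "< 2.2e-16",
                        formatC(out$p, digits = 3, format = "g"))
    out
}
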