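# Report-layer helpers: heatmap matrices, figure wrappers and the
# end-to-end pipeline driver. Figures are thin wrappers; every plotted
# quantity is also available as a plain table so results can be asserted
# numerically.

#' Z-scored expression matrix for a heatmap
#'
#' Selects the top `nTop` genes of one direction by ascending FDR (ties
#' broken by ascending p, then gene id) from a per-day DE table, and
#' standardizes each gene's expression row to mean 0, SD 1 across the
#' supplied samples. Constant rows are rendered as zeros and flagged.
#'
#' @param logExpr genes x samples matrix of normalized log-expression
#'   (typically all samples, so the dissipation pattern is visible across
#'   days).
#' @param de a [DEResult] choosing and ordering the genes.
#' @param nTop number of genes per direction (default 50; fewer are
#'   returned with a warning when not enough genes qualify).
#' @param direction `"up"` or `"down"` (sign of the log fold-change).
#' @return List with `matrix` (z-scored rows), `genes`, `direction` and
#'   `constant` (flagged zero-variance genes).
#' @export
heatmapMatrix <- function(logExpr, de, nTop = 50, direction = c("up", "down")) {
    direction <- match.arg(direction)
    stopifnot(is(de, "DEResult"))
    logExpr <- as.matrix(logExpr)
    tab <- deTable(de)
    tab <- tab[tab$gene %in% rownames(logExpr), , drop = FALSE]
    tab <- tab[if (direction == "up") tab$logFC > 0 else tab$logFC < 0, , drop = FALSE]
    tab <- tab[order(tab$fdr, tab$pvalue, tab$gene), , drop = FALSE]
    if (nrow(tab) < nTop)
        warning("only ", nrow(tab), " ", direction, "-regulated genes available")
    genes <- utils::head(tab$gene, nTop)
    m <- logExpr[genes, , drop = FALSE]
    mu <- rowMeans(m)
    s <- apply(m, 1, stats::sd)
    constant <- s == 0
    z <- (m - mu) / ifelse(constant, 1, s)
    z[constant, ] <- 0
    list(matrix = z, genes = genes, direction = direction,
         constant = genes[constant])
}

#' @name plots
#' @title Figure wrappers
#' @description ggplot2 wrappers over the pipeline's result tables: volcano
#'   plot of a DE table, mean-trajectory plot of a panel summary, PCA score
#'   plot with group confidence ellipses, and an enrichment bar chart.
#' @param de,summary,pca,enrichment result objects of the corresponding
#'   pipeline stages.
#' @param pCut significance cut of the volcano plot.
#' @param nTop number of sets shown in the enrichment bars.
#' @return A ggplot object.
NULL

#' @rdname plots
#' @export
plotVolcano <- function(de, pCut = 0.05) {
    v <- volcanoTable(de, pCut)
    ggplot2::ggplot(v, ggplot2::aes(x = .data$logFC, y = .data$negLog10P,
                                    colour = .data$significant)) +
        ggplot2::geom_point(size = 0.6, alpha = 0.7) +
        ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "red3"),
                                     guide = "none") +
        ggplot2::facet_wrap(~day, labeller = ggplot2::label_both) +
        ggplot2::labs(x = "log2 fold-change (ISO vs naive)", y = "-log10 p") +
        ggplot2::theme_bw()
}

#' @rdname plots
#' @export
plotTrajectory <- function(summary) {
    ggplot2::ggplot(summary, ggplot2::aes(x = .data$day, y = .data$mean)) +
        ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
        ggplot2::geom_line(colour = "blue3") +
        ggplot2::geom_point(shape = 17, colour = "blue3", size = 2) +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - 2 * .data$se,
                                            ymax = .data$mean + 2 * .data$se),
                               width = 5, colour = "blue3") +
        ggplot2::labs(x = "day post exposure", y = "mean log2 fold-change") +
        ggplot2::theme_bw()
}

#' @rdname plots
#' @export
plotPcaQC <- function(pca) {
    sc <- data.frame(sample = rownames(pca@scores), pca@scores)
    ell <- do.call(rbind, lapply(names(pca@ellipses), function(g) {
        e <- pca@ellipses[[g]]
        th <- seq(0, 2 * pi, length.out = 120)
        pts <- cbind(e$radii[1] * cos(th), e$radii[2] * sin(th))
        rot <- matrix(c(cos(e$angle), sin(e$angle),
                        -sin(e$angle), cos(e$angle)), 2)
        pts <- sweep(pts %*% t(rot), 2, e$center, "+")
        data.frame(group = g, PC1 = pts[, 1], PC2 = pts[, 2])
    }))
    p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
        ggplot2::geom_point() +
        ggplot2::labs(
            x = sprintf("PC1 (%.1f%%)", 100 * pca@varExplained[1]),
            y = sprintf("PC2 (%.1f%%)", 100 * pca@varExplained[2])) +
        ggplot2::theme_bw()
    if (!is.null(ell))
        p <- p + ggplot2::geom_path(
            data = ell, ggplot2::aes(colour = .data$group))
    p
}

#' @rdname plots
#' @export
plotEnrichment <- function(enrichment, nTop = 10) {
    e <- utils::head(enrichment, nTop)
    e$label <- ifelse(is.na(e$description), e$set, e$description)
    ggplot2::ggplot(e, ggplot2::aes(x = .data$negLog10P,
                                    y = stats::reorder(.data$label, .data$negLog10P))) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = "-log10 p", y = NULL) +
        ggplot2::theme_bw()
}

.writeTSV <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full longitudinal pipeline
#'
#' Executes, in order: simulation (or import), low-expression filtering,
#' TMM normalization, per-day PCA QC, per-day differential expression,
#' trajectory construction, the short-term and late-onset selection rules,
#' panel summaries, the trend-test battery, optional overrepresentation
#' against a GMT collection, and heatmap matrices. Every stage's table is
#' written as TSV under `outDir` and a JSON manifest records parameters,
#' seed and output paths.
#'
#' @param input a [SimulationConfig], a [TimecourseExperiment], or a named
#'   list `list(counts = <tsv path>, design = <csv path>)`.
#' @param outDir output directory.
#' @param gmt optional path to a GMT file (or a named list of sets); when
#'   absent the enrichment stage is skipped and noted in the manifest.
#' @param panel optional gene id vector restricting the short-term rule.
#' @param cpmThreshold low-expression filter threshold.
#' @param engine DE engine, `"qlf"` or `"lrt"`.
#' @param nTop genes per direction in heatmap matrices.
#' @param figures also write PDF figures.
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
runAll <- function(input, outDir, gmt = NULL, panel = NULL,
                   cpmThreshold = 0.5, engine = "qlf", nTop = 50,
                   figures = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    tce <- stage("input", {
        if (is(input, "SimulationConfig")) simulateExperiment(input)
        else if (is(input, "TimecourseExperiment")) input
        else timecourseExperiment(readCounts(input$counts), readDesign(input$design))
    })
    seed <- if (is(input, "SimulationConfig")) input@seed else NA_integer_
    paths$experiment <- writeExperiment(tce, file.path(outDir, "data"))

    filtered <- stage("filter", filterLowExpression(tce, cpmThreshold, verbose = FALSE))
    nf <- stage("tmm", tmmFactors(filtered))
    paths$normFactors <- .writeTSV(nf, file.path(outDir, "norm_factors.tsv"))

    lcpm <- computeCPM(filtered, log = TRUE)
    des <- sampleDesign(filtered)
    days <- sort(unique(des$day))
    pca <- stage("pca", lapply(days, function(d) {
        sel <- des$day == d
        pcaQC(lcpm[, sel, drop = FALSE], des[sel, , drop = FALSE])
    }))
    names(pca) <- paste0("day", days)
    paths$pcaScores <- .writeTSV(
        do.call(rbind, lapply(names(pca), function(nm)
            data.frame(day = sub("day", "", nm),
                       sample = rownames(pca[[nm]]@scores), pca[[nm]]@scores))),
        file.path(outDir, "pca_scores.tsv"))

    de <- stage("de", lapply(days, function(d)
        testTimepoint(filtered, d, engine = engine, normFactors = nf)))
    names(de) <- paste0("day", days)
    for (nm in names(de))
        paths[[paste0("de_", nm)]] <- .writeTSV(deTable(de[[nm]]),
            file.path(outDir, paste0("de_", nm, ".tsv")))

    ts <- stage("trajectories", buildTrajectories(de))
    paths$volcano <- .writeTSV(volcanoTable(de), file.path(outDir, "volcano.tsv"))

    results <- list(experiment = tce, filtered = filtered, normFactors = nf,
                    pca = pca, de = de, trajectories = ts)
    selections <- list()
    if (all(c(1, 30) %in% days))
        selections$short_term <- stage("select_short_term",
                                       selectShortTerm(ts, panel = panel))
    if (all(c(240, 360) %in% days))
        selections$late_onset <- stage("select_late_onset", selectLateOnset(ts))

    gmtSets <- NULL
    if (!is.null(gmt))
        gmtSets <- stage("gmt", if (is.character(gmt)) readGMT(gmt) else gmt)

    for (rule in names(selections)) {
        sel <- selections[[rule]]
        selTab <- data.frame(gene = selectedGenes(sel),
                             direction = rep(c("up", "down"),
                                             c(length(sel@up), length(sel@down))),
                             reason = unname(sel@reason[selectedGenes(sel)]))
        paths[[paste0("selection_", rule)]] <-
            .writeTSV(selTab, file.path(outDir, paste0("selection_", rule, ".tsv")))
        for (side in c("up", "down")) {
            genes <- slot(sel, side)
            if (!length(genes)) next
            smry <- summarizeTrajectory(ts, genes)
            paths[[paste0("summary_", rule, "_", side)]] <- .writeTSV(
                smry, file.path(outDir, paste0("summary_", rule, "_", side, ".tsv")))
            if (figures)
                .savePDF(plotTrajectory(smry),
                         file.path(outDir, paste0("trajectory_", rule, "_", side, ".pdf")))
        }
        battery <- stage("battery", trendBattery(ts, sel))
        paths[[paste0("battery_", rule)]] <-
            .writeTSV(battery, file.path(outDir, paste0("battery_", rule, ".tsv")))
        results[[paste0("battery_", rule)]] <- battery
        if (!is.null(gmtSets)) {
            enr <- stage("enrichment", overrepresentation(
                selectedGenes(sel), rownames(filtered), gmtSets))
            paths[[paste0("enrichment_", rule)]] <-
                .writeTSV(enr, file.path(outDir, paste0("enrichment_", rule, ".tsv")))
            results[[paste0("enrichment_", rule)]] <- enr
        }
        hday <- if (rule == "short_term") 1 else 360
        if (hday %in% days) {
            for (side in c("up", "down")) {
                hm <- stage("heatmap", suppressWarnings(heatmapMatrix(
                    lcpm, de[[paste0("day", hday)]], nTop = nTop, direction = side)))
                paths[[paste0("heatmap_", rule, "_", side)]] <- .writeTSV(
                    data.frame(gene = rownames(hm$matrix), hm$matrix,
                               check.names = FALSE),
                    file.path(outDir, paste0("heatmap_", rule, "_", side, ".tsv")))
            }
        }
    }
    results$selections <- selections

    if (figures) {
        .savePDF(plotVolcano(de), file.path(outDir, "volcano.pdf"))
        for (nm in names(pca))
            .savePDF(plotPcaQC(pca[[nm]]), file.path(outDir, paste0("pca_", nm, ".pdf")))
    }

    manifest <- list(
        package = "trajDEG",
        version = as.character(utils::packageVersion("trajDEG")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed,
        parameters = list(cpmThreshold = cpmThreshold, engine = engine,
                          nTop = nTop, days = days,
                          enrichment = !is.null(gmtSets)),
        enrichmentSkipped = is.null(gmtSets),
        outputs = lapply(paths, as.character))
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    results$manifest <- manifest
    invisible(results)
}

.savePDF <- function(p, path, width = 6, height = 4.5) {
    grDevices::pdf(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    print(p)
    invisible(path)
}
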