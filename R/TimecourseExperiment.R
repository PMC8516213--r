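#' Build a TimecourseExperiment from counts and a design table
#'
#' Binds a validated gene-by-sample count matrix to its sample design. The
#' design must describe exactly the samples present in the matrix; library
#' sizes are computed as column sums at this point and kept fixed through
#' later filtering so CPM values retain their original denominator.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param design data.frame with columns `sample_id`, `group`
#'   (`"ISO"`/`"naive"`) and `day`; one row per sample.
#' @param requireReplicates require at least 2 samples in every
#'   (group, day) cell (default `TRUE`).
#' @return A [TimecourseExperiment].
#' @examples
#' cnt <- matrix(rpois(40, 50), 10, 4,
#'               dimnames = list(paste0("G", 1:10), paste0("S", 1:4)))
#' des <- data.frame(sample_id = paste0("S", 1:4),
#'                   group = rep(c("naive", "ISO"), each = 2), day = 1)
#' tce <- timecourseExperiment(cnt, des, requireReplicates = FALSE)
#' librarySizes(tce)
#' @export
timecourseExperiment <- function(counts, design, requireReplicates = TRUE) {
    counts <- .checkCountMatrix(counts)
    design <- .checkDesign(design)
    if (!setequal(colnames(counts), design$sample_id))
        stop("design and count matrix must describe the same samples; ",
             "missing from design: ",
             paste(setdiff(colnames(counts), design$sample_id), collapse = ", "),
             "; missing from counts: ",
             paste(setdiff(design$sample_id, colnames(counts)), collapse = ", "))
    design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
    if (requireReplicates) {
        tab <- table(design$group, design$day)
        if (any(tab > 0 & tab < 2))
            stop("every (group, day) cell must contain at least 2 samples")
    }
    cd <- DataFrame(group = design$group, day = design$day,
                    librarySize = colSums(counts),
                    row.names = design$sample_id)
    new("TimecourseExperiment",
        SummarizedExperiment(assays = list(counts = counts), colData = cd))
}

.checkCountMatrix <- function(counts) {
    counts <- as.matrix(counts)
    if (nrow(counts) == 0L) stop("no genes in the count matrix")
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts need gene rownames and sample colnames")
    if (anyDuplicated(rownames(counts)))
        stop("duplicate gene ids: ",
             paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
    if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
    bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("invalid count at gene '%s', sample '%s'",
                     rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
    storage.mode(counts) <- "double"
    if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
    counts
}

.checkDesign <- function(design) {
    design <- as.data.frame(design)
    need <- c("sample_id", "group", "day")
    if (!all(need %in% colnames(design)))
        stop("design needs columns: ", paste(need, collapse = ", "))
    design$sample_id <- as.character(design$sample_id)
    design$group <- as.character(design$group)
    design$day <- as.numeric(design$day)
    if (anyDuplicated(design$sample_id)) stop("duplicate sample ids in design")
    if (!all(design$group %in% c("ISO", "naive")))
        stop("group must be 'ISO' or 'naive'")
    if (any(is.na(design$day))) stop("non-numeric day in design")
    design
}

#' @rdname accessors
#' @export
setMethod("sampleDesign", "TimecourseExperiment", function(object) {
    cd <- colData(object)
    data.frame(sample_id = rownames(cd), group = cd$group, day = cd$day,
               librarySize = cd$librarySize, row.names = NULL)
})

#' @rdname accessors
#' @export
setMethod("librarySizes", "TimecourseExperiment", function(object) {
    stats::setNames(colData(object)$librarySize, colnames(object))
})

#' @rdname accessors
#' @export
setMethod("groundTruth", "TimecourseExperiment", function(object) {
    rd <- rowData(object)
    if (!"archetype" %in% colnames(rd)) return(NULL)
    as.data.frame(rd)
})

#' @rdname accessors
#' @param ... ignored.
#' @export
setMethod("counts", "TimecourseExperiment", function(object, ...) {
    SummarizedExperiment::assay(object, "counts")
})

setMethod("show", "TimecourseExperiment", function(object) {
    cd <- colData(object)
    cat("TimecourseExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  days:", paste(sort(unique(cd$day)), collapse = ", "), "\n")
    tab <- table(cd$group, cd$day)
    for (g in rownames(tab))
        cat(sprintf("  %-6s n per day: %s\n", g, paste(tab[g, ], collapse = ", ")))
    if (!is.null(groundTruth(object))) {
        at <- table(rowData(object)$archetype)
        cat("  planted archetypes:",
            paste(sprintf("%s=%d", names(at), at), collapse = ", "), "\n")
    }
})

#' Read a count matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds sample ids. Entries must be non-negative integers;
#' offending cells are reported by gene and sample.
#'
#' @param path path to the TSV file.
#' @return Integer matrix (genes x samples).
#' @seealso [readDesign()], [timecourseExperiment()]
#' @export
readCounts <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("no genes in ", path)
    if (ncol(df) < 2L) stop("no samples in ", path)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
        num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
        bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
        if (!nrow(bad)) bad <- which(is.na(num), arr.ind = TRUE)
        stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                     ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    rownames(m) <- ids
    .checkCountMatrix(m)
}

#' Read a sample design table from CSV
#'
#' @param path CSV with columns `sample_id`, `group`, `day`.
#' @return Validated data.frame.
#' @export
readDesign <- function(path) {
    .checkDesign(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an experiment to plain-text files
#'
#' Writes `counts.tsv` (first column `gene`, one column per sample),
#' `design.csv` (`sample_id`, `group`, `day`) and, for simulated objects,
#' `truth.tsv` with the planted ground truth.
#'
#' @param tce a [TimecourseExperiment].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeExperiment <- function(tce, dir) {
    stopifnot(is(tce, "TimecourseExperiment"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cpath <- file.path(dir, "counts.tsv")
    cnt <- data.frame(gene = rownames(tce), counts(tce), check.names = FALSE)
    utils::write.table(cnt, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
    dpath <- file.path(dir, "design.csv")
    utils::write.csv(sampleDesign(tce)[, c("sample_id", "group", "day")],
                     dpath, row.names = FALSE, quote = FALSE)
    paths <- c(counts = cpath, design = dpath)
    gt <- groundTruth(tce)
    if (!is.null(gt)) {
        tpath <- file.path(dir, "truth.tsv")
        utils::write.table(data.frame(gene = rownames(tce), gt, check.names = FALSE),
                           tpath, sep = "\t", quote = FALSE, row.names = FALSE)
        paths["truth"] <- tpath
    }
    invisible(paths)
}
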