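# Gene-set handling and hypergeometric overrepresentation: a reproducible,
# database-free replacement for web-service enrichment reports.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are dropped; malformed lines are
#' reported with their line number.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors, with per-set descriptions in
#'   `attr(x, "description")`.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no sets in ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3)
    if (length(bad))
        stop("malformed GMT line ", bad[1], ": need name, description and >= 1 member")
    names <- vapply(fields, `[[`, character(1), 1)
    if (anyDuplicated(names))
        stop("duplicate set names: ",
             paste(unique(names[duplicated(names)]), collapse = ", "))
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- names
    attr(sets, "description") <- stats::setNames(
        vapply(fields, `[[`, character(1), 2), names)
    sets
}

#' Restrict gene sets to the measured universe
#'
#' Intersects every set with the measured gene ids, drops sets emptied by
#' the restriction (with a warning), and reports the before/after sizes and
#' the union coverage (how many of all set members were measured at all).
#'
#' @param sets named list of gene id vectors (e.g. from [readGMT()]).
#' @param universe character vector of measured gene ids.
#' @return The restricted list; `attr(x, "report")` holds a data.frame of
#'   per-set sizes and `attr(x, "unionCoverage")` the measured/total union
#'   counts.
#' @export
restrictToMeasured <- function(sets, universe) {
    if (!length(universe)) stop("empty universe")
    if (!length(sets)) stop("empty gene-set collection")
    before <- lengths(sets)
    restricted <- lapply(sets, intersect, y = universe)
    after <- lengths(restricted)
    dropped <- names(sets)[after == 0]
    if (length(dropped))
        warning("sets with no measured members dropped: ",
                paste(dropped, collapse = ", "))
    un <- unique(unlist(sets, use.names = FALSE))
    out <- restricted[after > 0]
    desc <- attr(sets, "description")
    if (!is.null(desc)) attr(out, "description") <- desc[names(out)]
    attr(out, "report") <- data.frame(set = names(sets), before = unname(before),
                                      after = unname(after), row.names = NULL)
    attr(out, "unionCoverage") <- c(measured = sum(un %in% universe),
                                    total = length(un))
    out
}

#' Hypergeometric overrepresentation analysis
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected when drawing `length(query)` genes at random from the measured
#' universe (upper-tail hypergeometric, [hypergeomTest()]). Sets overlapping
#' the query in fewer than `minOverlap` genes are not tested; BH adjustment
#' is applied across the tested sets only.
#'
#' @param query character vector of gene ids, a subset of `universe`.
#' @param universe character vector of measured gene ids.
#' @param sets named list of gene sets (restricted to the universe first;
#'   see [restrictToMeasured()]).
#' @param minOverlap minimum overlap for a set to be tested (default 3).
#' @return data.frame sorted by p with columns `set`, `description`,
#'   `overlap`, `setSize`, `querySize`, `universeSize`, `p`, `fdr`,
#'   `negLog10P`, `negLog10FDR`, `genes` (comma-separated overlap).
#' @export
overrepresentation <- function(query, universe, sets, minOverlap = 3) {
    query <- unique(query)
    universe <- unique(universe)
    off <- setdiff(query, universe)
    if (length(off))
        stop("query genes outside the universe: ",
             paste(utils::head(off, 10), collapse = ", "),
             if (length(off) > 10) sprintf(" (and %d more)", length(off) - 10) else "")
    sets <- restrictToMeasured(sets, universe)
    desc <- attr(sets, "description")
    N <- length(universe); n <- length(query)
    rows <- lapply(names(sets), function(nm) {
        members <- sets[[nm]]
        ov <- intersect(query, members)
        if (length(ov) < minOverlap) return(NULL)
        p <- hypergeomTest(length(ov), length(members), n, N)
        data.frame(set = nm,
                   description = if (is.null(desc)) NA_character_ else unname(desc[nm]),
                   overlap = length(ov), setSize = length(members),
                   querySize = n, universeSize = N, p = p,
                   genes = paste(sort(ov), collapse = ","), row.names = NULL)
    })
    rows <- Filter(Negate(is.null), rows)
    if (!length(rows)) {
        warning("no set reaches the minimum overlap of ", minOverlap)
        return(data.frame(set = character(), description = character(),
                          overlap = integer(), setSize = integer(),
                          querySize = integer(), universeSize = integer(),
                          p = numeric(), fdr = numeric(), negLog10P = numeric(),
                          negLog10FDR = numeric(), genes = character()))
    }
    out <- do.call(rbind, rows)
    out$fdr <- bhAdjust(out$p)
    out$negLog10P <- -log10(out$p)
    out$negLog10FDR <- -log10(out$fdr)
    out <- out[order(out$p, out$set), c("set", "description", "overlap", "setSize",
                                        "querySize", "universeSize", "p", "fdr",
                                        "negLog10P", "negLog10FDR", "genes")]
    rownames(out) <- NULL
    out
}
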