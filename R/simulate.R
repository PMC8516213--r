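#' Create a simulator configuration
#'
#' Defaults emulate the study design this package targets: days 1, 30, 240
#' and 360 post exposure, six naive samples per day, five exposed (ISO)
#' samples at day 1 and six at the other days, constant NB dispersion 0.05,
#' and planted log2 amplitudes drawn uniformly from 0.3-1.2. Archetype
#' shapes are expressed as per-day multipliers of the amplitude: a
#' short-term gene carries its full effect at day 1, half at day 30 and
#' nothing afterwards; a late-onset gene is flat early, at half amplitude on
#' day 240 and at full amplitude on day 360.
#'
#' @param nGenes number of genes (default 5000, a desk-scale transcriptome).
#' @param days ordered integer days.
#' @param nNaive,nIso samples per group per day (recycled to
#'   `length(days)`).
#' @param baselineLog2Mean mean and sd of per-gene log2 baseline expression.
#' @param dispersion list; `list(type = "constant", phi = 0.05)` or
#'   `list(type = "trend", a, b)` for `phi = a / mu + b`.
#' @param librarySizeLog meanlog and sdlog of log-normal sequencing depth.
#' @param archetypeFractions named fractions over the five archetypes,
#'   summing to 1.
#' @param archetypeCounts optional named exact gene counts per archetype
#'   (overrides fractions).
#' @param amplitudeRange bounds of the uniform log2 amplitude.
#' @param patternShortTerm,patternLateOnset per-day shape multipliers.
#' @param seed RNG seed (`NA` to leave the RNG state untouched).
#' @return A [SimulationConfig].
#' @examples
#' cfg <- simulationConfig(nGenes = 100, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nGenes = 5000L,
                             days = c(1L, 30L, 240L, 360L),
                             nNaive = 6L,
                             nIso = c(5L, 6L, 6L, 6L),
                             baselineLog2Mean = c(5, 2.5),
                             dispersion = list(type = "constant", phi = 0.05),
                             librarySizeLog = c(log(5e6), 0.2),
                             archetypeFractions = c(null = 0.40,
                                                    short_term_up = 0.15,
                                                    short_term_down = 0.15,
                                                    late_onset_up = 0.15,
                                                    late_onset_down = 0.15),
                             archetypeCounts = NULL,
                             amplitudeRange = c(0.3, 1.2),
                             patternShortTerm = c(1, 0.5, 0, 0),
                             patternLateOnset = c(0, 0, 0.5, 1),
                             seed = NA_integer_) {
    days <- as.integer(days)
    new("SimulationConfig",
        nGenes = as.integer(nGenes), days = days,
        nNaive = as.integer(rep_len(nNaive, length(days))),
        nIso = as.integer(rep_len(nIso, length(days))),
        baselineLog2Mean = as.numeric(baselineLog2Mean),
        dispersion = dispersion,
        librarySizeLog = as.numeric(librarySizeLog),
        archetypeFractions = archetypeFractions,
        archetypeCounts = if (is.null(archetypeCounts)) integer()
                          else vapply(archetypeCounts, as.integer, integer(1)),
        amplitudeRange = as.numeric(amplitudeRange),
        patternShortTerm = as.numeric(patternShortTerm),
        patternLateOnset = as.numeric(patternLateOnset),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nGenes, "genes, days",
        paste(object@days, collapse = "/"), "\n")
    cat("  n naive:", paste(object@nNaive, collapse = ", "),
        "| n ISO:", paste(object@nIso, collapse = ", "), "\n")
    f <- object@archetypeFractions
    cat("  archetypes:", paste(sprintf("%s=%.2f", names(f), f), collapse = ", "), "\n")
    cat("  amplitude: U(", object@amplitudeRange[1], ",",
        object@amplitudeRange[2], ") log2 units\n")
})

#' Planted log2 fold-change of an archetype at one day
#'
#' The true effect is the signed amplitude times the archetype's per-day
#' shape multiplier; `*_down` archetypes negate the multiplier and `null`
#' genes are identically zero.
#'
#' @param archetype one of `null`, `short_term_up`, `short_term_down`,
#'   `late_onset_up`, `late_onset_down`.
#' @param amplitude log2 amplitude.
#' @param dayIndex index into `config@days`.
#' @param config a [SimulationConfig].
#' @return Numeric log2 fold-change.
#' @examples
#' cfg <- simulationConfig(nGenes = 10)
#' archetypeLogFC("short_term_down", 1, 2, cfg)  # -0.5
#' @export
archetypeLogFC <- function(archetype, amplitude, dayIndex, config) {
    stopifnot(is(config, "SimulationConfig"))
    if (dayIndex < 1 || dayIndex > length(config@days))
        stop("dayIndex out of range")
    mult <- switch(archetype,
        null = 0,
        short_term_up = config@patternShortTerm[dayIndex],
        short_term_down = -config@patternShortTerm[dayIndex],
        late_onset_up = config@patternLateOnset[dayIndex],
        late_onset_down = -config@patternLateOnset[dayIndex],
        stop("unknown archetype: ", archetype))
    amplitude * mult
}

.drawArchetypes <- function(config) {
    if (length(config@archetypeCounts)) {
        a <- rep(names(config@archetypeCounts), config@archetypeCounts)
        if (length(a) > 1) a <- sample(a)
        a
    } else {
        sample(.ARCHETYPES, config@nGenes, replace = TRUE,
               prob = config@archetypeFractions[.ARCHETYPES])
    }
}

#' Simulate a longitudinal two-group NB count experiment
#'
#' Draws per-gene baseline expression and a trajectory archetype, then
#' negative-binomial counts (variance `mu + phi * mu^2`) for every sample:
#' each sample's expected counts are its log-normal library size times the
#' gene's relative expression, and exposed (ISO) samples are additionally
#' scaled by `2^trueLogFC` of the gene's archetype at that day. The planted
#' truth (archetype, amplitude, per-day true log fold-change, baseline mean,
#' dispersion) is stored in `rowData`, so downstream selection rules can be
#' scored against it.
#'
#' Given a seed, the output is fully reproducible.
#'
#' @param config a [SimulationConfig].
#' @return A [TimecourseExperiment] with ground truth in `rowData` and the
#'   configuration in `metadata(x)$config`.
#' @examples
#' tce <- simulateExperiment(simulationConfig(nGenes = 200, seed = 1))
#' tce
#' head(groundTruth(tce))
#' @export
simulateExperiment <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    if (!is.na(config@seed)) set.seed(config@seed)

    ng <- config@nGenes
    days <- config@days
    genes <- sprintf("G%06d", seq_len(ng))

    archetype <- .drawArchetypes(config)
    amplitude <- stats::runif(ng, config@amplitudeRange[1], config@amplitudeRange[2])
    amplitude[archetype == "null"] <- 0
    trueLFC <- matrix(0, ng, length(days),
                      dimnames = list(NULL, paste0("trueLogFC_day", days)))
    for (i in seq_along(days))
        trueLFC[, i] <- vapply(seq_len(ng), function(g)
            archetypeLogFC(archetype[g], amplitude[g], i, config), numeric(1))

    b <- stats::rnorm(ng, config@baselineLog2Mean[1], config@baselineLog2Mean[2])
    relExpr <- 2^b / sum(2^b)
    meanDepth <- exp(config@librarySizeLog[1] + config@librarySizeLog[2]^2 / 2)
    baselineMean <- relExpr * meanDepth

    phi <- switch(config@dispersion$type,
        constant = rep(config@dispersion$phi, ng),
        trend = config@dispersion$a / baselineMean + config@dispersion$b)
    phi <- pmax(phi, 0)

    design <- do.call(rbind, lapply(seq_along(days), function(i) {
        rbind(
            data.frame(group = "naive", day = days[i], rep = seq_len(config@nNaive[i])),
            data.frame(group = "ISO", day = days[i], rep = seq_len(config@nIso[i])))
    }))
    design$sample_id <- sprintf("%s_d%d_%d", design$group, design$day, design$rep)
    depth <- stats::rlnorm(nrow(design), config@librarySizeLog[1], config@librarySizeLog[2])

    cnt <- matrix(0, ng, nrow(design), dimnames = list(genes, design$sample_id))
    for (j in seq_len(nrow(design))) {
        mu <- relExpr * depth[j]
        if (design$group[j] == "ISO")
            mu <- mu * 2^trueLFC[, match(design$day[j], days)]
        pois <- phi == 0
        x <- numeric(ng)
        if (any(pois)) x[pois] <- stats::rpois(sum(pois), mu[pois])
        if (any(!pois)) x[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                                   size = 1 / phi[!pois])
        cnt[, j] <- x
    }

    tce <- timecourseExperiment(cnt, design[, c("sample_id", "group", "day")])
    rowData(tce) <- DataFrame(archetype = archetype, amplitude = amplitude,
                              trueLFC, baselineMean = baselineMean,
                              dispersion = phi, row.names = genes)
    metadata(tce)$config <- config
    tce
}

#' Gene sets of the planted archetypes
#'
#' Convenience for exercising the gene-set machinery on simulated data:
#' returns the planted archetype classes of a simulated experiment as a
#' named list of gene id vectors (the format [readGMT()] produces), plus
#' combined `short_term` and `late_onset` sets.
#'
#' @param tce a simulated [TimecourseExperiment].
#' @return Named list of character vectors.
#' @export
archetypeGeneSets <- function(tce) {
    gt <- groundTruth(tce)
    if (is.null(gt)) stop("no ground truth: not a simulated experiment")
    a <- split(rownames(tce), gt$archetype)
    a$short_term <- c(a$short_term_up, a$short_term_down)
    a$late_onset <- c(a$late_onset_up, a$late_onset_down)
    Filter(length, a)
}
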