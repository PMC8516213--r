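# Shared simulation fixtures, built once per test run and cached.

.simCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .simCache)) assign(key, force(expr), envir = .simCache)
  get(key, envir = .simCache)
}

# the default planted study-design simulation plus its full DE pipeline
defaultPipeline <- function() {
  cached("defaultPipeline", {
    tce <- simulateExperiment(simulationConfig(seed = 1L))
    filt <- filterLowExpression(tce, verbose = FALSE)
    nf <- tmmFactors(filt)
    de <- lapply(c(1, 30, 240, 360), function(d)
      testTimepoint(filt, d, normFactors = nf))
    list(tce = tce, filt = filt, nf = nf, de = de,
         ts = buildTrajectories(de), truth = groundTruth(tce))
  })
}

# a small two-day simulation for cheap unit tests
smallPipeline <- function() {
  cached("smallPipeline", {
    cfg <- simulationConfig(nGenes = 400L, days = c(1L, 30L),
                            nIso = c(5L, 6L),
                            patternShortTerm = c(1, 0.5),
                            patternLateOnset = c(0, 0),
                            seed = 11L)
    tce <- simulateExperiment(cfg)
    filt <- filterLowExpression(tce, verbose = FALSE)
    list(tce = tce, filt = filt, nf = tmmFactors(filt))
  })
}

# planted trajectory panel embedded in a null background; returns the JT
# p-value on the per-gene estimated logFC of the planted genes, pooled by day
panelTrendP <- function(nPanel, archetype, alternative, seed,
                        nBackground = 2000L) {
  counts <- c(null = nBackground, short_term_up = 0L, short_term_down = 0L,
              late_onset_up = 0L, late_onset_down = 0L)
  counts[archetype] <- as.integer(nPanel)
  cfg <- simulationConfig(nGenes = nBackground + as.integer(nPanel),
                          archetypeCounts = counts, seed = as.integer(seed))
  tce <- simulateExperiment(cfg)
  filt <- filterLowExpression(tce, verbose = FALSE)
  nf <- tmmFactors(filt)
  de <- lapply(c(1, 30, 240, 360), function(d)
    testTimepoint(filt, d, normFactors = nf))
  ts <- buildTrajectories(de)
  planted <- rownames(filt)[groundTruth(filt)$archetype == archetype]
  lfc <- trajLogFC(ts)[planted, , drop = FALSE]
  lfc <- lfc[stats::complete.cases(lfc), , drop = FALSE]
  ht <- jonckheereTerpstra(lapply(seq_len(ncol(lfc)), function(i) lfc[, i]),
                           alternative = alternative, method = "normal")
  list(p = ht$p.value, n = nrow(lfc))
}

# hand-built DEResult for rule-level tests
makeDE <- function(day, gene, logFC, pvalue, fdr = bhAdjust(pvalue)) {
  new("DEResult",
      table = data.frame(gene = gene, logFC = logFC,
                         aveLog2CPM = rep(5, length(gene)),
                         pvalue = pvalue, fdr = fdr),
      day = day, engine = "qlf")
}
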