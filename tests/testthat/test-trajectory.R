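twoDayTables <- function() {
  list(
    makeDE(30, c("g1", "g2", "g3"), c(0.1, -0.2, 0.3), c(0.5, 0.04, 0.2)),
    makeDE(1, c("g1", "g2"), c(0.5, -0.6), c(0.01, 0.02)))
}

test_that("trajectories align, mask and ignore supply order", {
  ts <- buildTrajectories(twoDayTables())
  expect_equal(assayDays(ts), c(1, 30))
  expect_equal(unname(trajLogFC(ts)["g1", ]), c(0.5, 0.1))
  expect_equal(unname(trajLogFC(ts)["g3", ]), c(NA_real_, 0.3))  # masked day 1

  rev <- buildTrajectories(rev(twoDayTables()))
  expect_identical(trajLogFC(rev), trajLogFC(ts))

  expect_error(buildTrajectories(list(twoDayTables()[[1]], twoDayTables()[[1]])),
               "duplicate day")
  expect_error(buildTrajectories(twoDayTables()[1]), ">= 2 days")
})

test_that("the short-term rule selects by primary-day or sign-consistency", {
  # Ptgds-like: day 1 logFC 1.88, p 6.86e-06; day 30 logFC 0.52
  d1 <- makeDE(1,
    gene   = c("Ptgds", "weakBoth", "inconsistent", "flat", "zeroStart"),
    logFC  = c(1.88, 0.3, 0.3, 0.1, 0),
    pvalue = c(6.86e-06, 0.08, 0.08, 0.2, 0.03))
  d30 <- makeDE(30,
    gene   = c("Ptgds", "weakBoth", "inconsistent", "flat", "zeroStart"),
    logFC  = c(0.52, 0.4, -0.3, 0.1, -0.7),
    pvalue = c(0.3, 0.07, 0.07, 0.2, 0.01))
  ts <- buildTrajectories(list(d1, d30))
  sel <- selectShortTerm(ts)

  expect_true("Ptgds" %in% sel@up)
  expect_equal(unname(sel@reason["Ptgds"]), "primary")
  expect_true("weakBoth" %in% sel@up)               # consistency arm
  expect_equal(unname(sel@reason["weakBoth"]), "consistent")
  expect_false("inconsistent" %in% selectedGenes(sel))  # sign flip
  expect_false("flat" %in% selectedGenes(sel))          # fails both arms
  # primary-day hit with zero logFC there: direction from day 30
  expect_true("zeroStart" %in% sel@down)

  # identical rerun gives identical memberships; up/down disjoint by validity
  expect_identical(selectShortTerm(ts), sel)
})

test_that("panel restriction confines the short-term rule", {
  ts <- buildTrajectories(list(
    makeDE(1, c("a", "b"), c(1, 1), c(0.001, 0.001)),
    makeDE(30, c("a", "b"), c(1, 1), c(0.5, 0.5))))
  sel <- selectShortTerm(ts, panel = "a")
  expect_identical(selectedGenes(sel), "a")
  expect_error(selectShortTerm(ts, panel = "zzz"), "panel shares no genes")
  expect_error(selectShortTerm(ts, pPrimary = 0), "thresholds")
})

test_that("the late-onset rule requires joint significance and a shared sign", {
  # Col4a2-like (up) and Atp5e-like (down) table rows; one FDR-significant
  # gene with flipped signs must be rejected
  d240 <- makeDE(240,
    gene   = c("Col4a2", "Atp5e", "flipper"),
    logFC  = c(0.30, -0.39, 0.5),
    pvalue = c(2.16e-02, 1.70e-03, 0.05))
  d360 <- makeDE(360,
    gene   = c("Col4a2", "Atp5e", "flipper"),
    logFC  = c(0.63, -0.50, -0.5),
    pvalue = c(2.34e-07, 5.50e-06, 1e-6),
    fdr    = c(2.78e-04, 7.98e-04, 1e-4))
  ts <- buildTrajectories(list(d240, d360))
  sel <- selectLateOnset(ts)
  expect_identical(sel@up, "Col4a2")
  expect_identical(sel@down, "Atp5e")
  expect_false("flipper" %in% selectedGenes(sel))
})

test_that("trajectory summaries follow their definition", {
  ts <- buildTrajectories(twoDayTables())
  one <- summarizeTrajectory(ts, "g1")
  expect_equal(one$mean, unname(trajLogFC(ts)["g1", ]))
  expect_equal(one$median, one$mean)

  sym <- buildTrajectories(list(
    makeDE(1, c("a", "b"), c(0.7, -0.7), c(0.5, 0.5)),
    makeDE(30, c("a", "b"), c(0.2, -0.2), c(0.5, 0.5))))
  expect_equal(summarizeTrajectory(sym, c("a", "b"))$mean, c(0, 0))
  expect_error(summarizeTrajectory(ts, character()), "empty gene list")
})

test_that("a degenerate panel yields no trend evidence", {
  genes <- paste0("g", 1:6)
  tabs <- lapply(c(1, 30, 240, 360), function(d)
    makeDE(d, genes, rep(0.4, 6), rep(0.5, 6)))
  ts <- buildTrajectories(tabs)
  sel <- new("PanelSelection", rule = "short_term", up = genes,
             down = character(),
             reason = setNames(rep("primary", 6), genes),
             excluded = character(), criteria = list())
  bat <- trendBattery(ts, sel)
  kw <- bat[bat$test == "kruskal_wallis", ]
  jt <- bat[bat$test == "jonckheere", ]
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p, 1)
  expect_equal(jt$p, 1)
})

test_that("the battery has the preset shape and honors alternative reversal", {
  pl <- defaultPipeline()
  st <- selectShortTerm(pl$ts)
  bat <- trendBattery(pl$ts, st)
  expect_equal(nrow(bat), 6)      # 3 tests x up/down panels
  expect_setequal(unique(bat$test),
                  c("mann_whitney", "kruskal_wallis", "jonckheere"))
  expect_equal(bat$alternative[bat$test == "jonckheere" & bat$panel == "up"],
               "decreasing")

  # sign-flipped panel under the reversed alternative gives the same JT p
  lfc <- trajLogFC(pl$ts)[st@up, ]
  lfc <- lfc[stats::complete.cases(lfc), ]
  groups <- lapply(seq_len(ncol(lfc)), function(i) lfc[, i])
  flipped <- lapply(groups, function(x) -x)
  pDec <- jonckheereTerpstra(groups, "decreasing", method = "normal")$p.value
  pInc <- jonckheereTerpstra(flipped, "increasing", method = "normal")$p.value
  expect_equal(pDec, pInc)

  badPreset <- list(list(test = "mann_whitney", days = c(240, 999),
                         altUp = "two.sided", altDown = "two.sided",
                         hypothesis = "missing day"))
  expect_error(trendBattery(pl$ts, st, badPreset), "not present")
})

test_that("selection recovers planted genes with low null contamination", {
  pl <- defaultPipeline()
  truth <- groundTruth(pl$filt)
  st <- selectShortTerm(pl$ts)
  planted <- rownames(pl$filt)[grepl("^short_term", truth$archetype)]
  recovered <- mean(planted %in% selectedGenes(st))
  nullIn <- mean(selectedGenes(st) %in%
                 rownames(pl$filt)[truth$archetype == "null"])
  expect_gte(recovered, 0.70)
  expect_lte(nullIn, 0.10)
})
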