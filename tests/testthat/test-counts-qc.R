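make_tce <- function(counts, days = 1) {
  n <- ncol(counts)
  des <- data.frame(sample_id = colnames(counts),
                    group = rep(c("naive", "ISO"), length.out = n),
                    day = rep(days, length.out = n))
  timecourseExperiment(counts, des, requireReplicates = FALSE)
}

test_that("count import validates structure and reports offending cells", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "g1\t1\t2", "g2\t3\t4"), tsv)
  m <- readCounts(tsv)
  expect_equal(unname(colSums(m)), c(4, 6))

  writeLines(c("gene\tS1\tS2", "g1\t1\t2", "g1\t3\t4"), tsv)
  expect_error(readCounts(tsv), "duplicate gene ids: g1")

  writeLines("gene\tS1\tS2", tsv)
  expect_error(readCounts(tsv), "no genes")

  writeLines(c("gene\tS1\tS2", "g1\t-1\t2"), tsv)
  expect_error(readCounts(tsv), "gene 'g1', sample 'S1'")

  writeLines(c("gene\tS1\tS2", "g1\tx\t2"), tsv)
  expect_error(readCounts(tsv), "gene 'g1', sample 'S1'")
})

test_that("CPM matches its definition and is scale invariant", {
  cnt <- matrix(c(5, 100, 395, 0, 50, 100), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  cpm <- computeCPM(cnt)
  expect_equal(cpm["g1", "A"], 5 / 500 * 1e6)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))

  zero <- rbind(cnt, g4 = c(0, 0))
  expect_equal(unname(computeCPM(zero)["g4", ]), c(0, 0))

  doubled <- cnt
  doubled[, "B"] <- cnt[, "B"] * 2
  expect_equal(computeCPM(doubled)[, "B"], computeCPM(cnt)[, "B"])

  expect_error(computeCPM(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2")))), "library size")
})

test_that("the low-expression filter keeps any gene reaching the threshold", {
  # filler gene brings every library to 2.5e6, so a count of 1 is CPM 0.4
  # and a count of 2 is CPM 0.8
  cnt <- rbind(gBelow = c(1, 1, 1),      # CPM 0.4 everywhere: removed
               gOnce  = c(2, 1, 1),      # CPM 0.8 in one sample: kept
               gZero  = c(0, 0, 0))      # removed
  cnt <- rbind(cnt, filler = 2.5e6 - colSums(cnt))
  colnames(cnt) <- paste0("S", 1:3)
  tce <- make_tce(cnt)

  filt <- filterLowExpression(tce, 0.5, verbose = FALSE)
  expect_false("gBelow" %in% rownames(filt))
  expect_true("gOnce" %in% rownames(filt))
  expect_equal(S4Vectors::metadata(filt)$nFiltered, 2)   # gBelow and gZero

  # idempotent: library sizes are retained, so a second pass removes nothing
  again <- filterLowExpression(filt, 0.5, verbose = FALSE)
  expect_identical(counts(again), counts(filt))
  expect_identical(librarySizes(again), librarySizes(filt))

  none <- filterLowExpression(tce, 0, verbose = FALSE)
  expect_equal(nrow(none), nrow(tce))
  expect_error(filterLowExpression(tce, -1), "cpmThreshold")
})

test_that("TMM factors are unit for proportional samples and scale invariant", {
  set.seed(2)
  a <- rpois(500, 200)
  cnt <- cbind(A = a, B = a, C = 3 * a)
  rownames(cnt) <- paste0("g", seq_len(500))
  nf <- tmmFactors(cnt)
  expect_equal(nf$normFactor, rep(1, 3), tolerance = 1e-6)
  expect_equal(exp(mean(log(nf$normFactor))), 1, tolerance = 1e-8)

  # multiplying every count of one sample by a constant leaves factors alone
  # (up to the depth-dependent precision weights of the weighted estimator)
  cnt2 <- cnt; cnt2[, "B"] <- cnt2[, "B"] * 7
  expect_equal(tmmFactors(cnt2)$normFactor, nf$normFactor, tolerance = 5e-3)
})

test_that("a sample with extra expression in a gene subset gets a smaller factor", {
  set.seed(3)
  a <- rpois(1000, 300) + 1
  b <- a
  boost <- sample(1000, 100)
  b[boost] <- b[boost] * 2
  cnt <- cbind(A = a, B = b)
  rownames(cnt) <- paste0("g", seq_len(1000))
  nf <- tmmFactors(cnt)
  # B's library is inflated by the boosted 10%; the trimmed mean of M over
  # the unchanged majority is negative, so B is scaled down relative to A
  expect_lt(nf$normFactor[nf$sample == "B"], nf$normFactor[nf$sample == "A"])
  # oracle: sign of the plain trimmed mean of M over doubly-trimmed genes
  cpm <- sweep(cnt, 2, colSums(cnt), "/")
  M <- log2(cpm[, "B"] / cpm[, "A"])
  A <- 0.5 * log2(cpm[, "B"] * cpm[, "A"])
  keep <- M >= quantile(M, 0.3) & M <= quantile(M, 0.7) &
    A >= quantile(A, 0.05) & A <= quantile(A, 0.95)
  expect_lt(mean(M[keep]), 0)
})

test_that("PCA QC flags constructed outliers and orders components", {
  set.seed(4)
  expr <- matrix(rnorm(50 * 12), 50, 12,
                 dimnames = list(paste0("g", 1:50), paste0("S", 1:12)))
  expr[1:10, 7:12] <- expr[1:10, 7:12] + 3      # group structure
  des <- data.frame(sample_id = paste0("S", 1:12),
                    group = rep(c("naive", "ISO"), each = 6))
  pca <- pcaQC(expr, des)
  expect_true(all(diff(pca@varExplained) <= 1e-12))

  # duplicated samples score identically
  expr2 <- expr; expr2[, 2] <- expr2[, 1]
  pca2 <- pcaQC(expr2, des)
  expect_equal(pca2@scores[1, ], pca2@scores[2, ])

  # push one sample far out in gene space (~10 within-group score SDs)
  expr3 <- expr
  expr3[, 1] <- expr3[, 1] + 10
  pca3 <- pcaQC(expr3, des)
  expect_true("S1" %in% pca3@outliers)

  expect_error(pcaQC(expr[, 1:2], des[1:2, ]), "at least 3 samples")
})

test_that("PCA scores are invariant to sample order up to sign", {
  set.seed(8)
  expr <- matrix(rnorm(30 * 8), 30, 8,
                 dimnames = list(paste0("g", 1:30), paste0("S", 1:8)))
  des <- data.frame(sample_id = paste0("S", 1:8),
                    group = rep(c("naive", "ISO"), each = 4))
  perm <- sample(8)
  s1 <- pcaQC(expr, des)@scores
  s2 <- pcaQC(expr[, perm], des)@scores[colnames(expr), ]
  for (k in 1:2)
    expect_true(isTRUE(all.equal(s1[, k], s2[, k], tolerance = 1e-8)) ||
                isTRUE(all.equal(s1[, k], -s2[, k], tolerance = 1e-8)))
})
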