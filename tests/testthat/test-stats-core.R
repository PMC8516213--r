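test_that("Mann-Whitney U matches its definition and symmetry cases", {
  ht <- mannWhitneyU(c(1, 2), c(1, 2))
  expect_equal(unname(ht$statistic), 2)        # nx*ny/2 under exchangeability
  expect_equal(ht$p.value, 1)

  ht <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 0.1)                # 2 of the 20 labelings as extreme

  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p equals full enumeration (ties included)", {
  set.seed(21)
  for (r in 1:12) {
    nx <- sample(2:4, 1); ny <- sample(2:5, 1)
    vals <- sample(1:4, nx + ny, replace = TRUE)   # heavy ties
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    for (alt in c("two.sided", "greater", "less")) {
      ours <- mannWhitneyU(x, y, alternative = alt, method = "exact")
      expect_equal(unname(ours$statistic), oracle_mw_u(x, y))
      expect_equal(ours$p.value, oracle_mw_exact_p(x, y, alt))
    }
  }
})

test_that("Mann-Whitney agrees with wilcox.test in both regimes", {
  set.seed(22)
  x <- rnorm(8); y <- rnorm(8) + 0.5              # tie-free
  ours <- mannWhitneyU(x, y, method = "exact", exactLimit = 16)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$p.value, ref$p.value)

  xs <- round(rnorm(30), 1); ys <- round(rnorm(30) + 0.3, 1)   # with ties
  ours <- mannWhitneyU(xs, ys, method = "normal")
  ref <- wilcox.test(xs, ys, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)

  # exact and normal approximation agree closely at moderate size
  expect_equal(mannWhitneyU(x, y, method = "exact", exactLimit = 16)$p.value,
               mannWhitneyU(x, y, method = "normal")$p.value, tolerance = 0.02)
})

test_that("Kruskal-Wallis handles ties, degeneracy and the hand-ranked case", {
  allTied <- kruskalWallisTest(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(unname(allTied$statistic), 0)
  expect_equal(allTied$p.value, 1)

  # hand computation without ties: H = 12/(6*7) * sum n_i rbar_i^2 - 3*7
  ht <- kruskalWallisTest(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(ht$statistic),
               12 / (6 * 7) * (2 * 1.5^2 + 2 * 3.5^2 + 2 * 5.5^2) - 3 * 7)

  set.seed(23)
  g <- lapply(1:4, function(i) round(rnorm(7, i / 4), 1))
  ref <- kruskal.test(g)
  ours <- kruskalWallisTest(g)
  expect_equal(unname(ours$statistic), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)

  expect_error(kruskalWallisTest(list(1:3)), ">= 2 groups")
  expect_error(kruskalWallisTest(list(1:3, numeric(0))), "empty group")
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z", {
  set.seed(24)
  x <- round(rnorm(9), 1); y <- round(rnorm(11) + 0.4, 1)
  pKW <- kruskalWallisTest(list(x, y))$p.value
  pMW <- mannWhitneyU(x, y, method = "normal", correct = FALSE)$p.value
  expect_equal(pKW, pMW, tolerance = 1e-6)
})

test_that("Jonckheere-Terpstra statistic and reversal identities hold", {
  ht <- jonckheereTerpstra(list(c(1, 2), c(3, 4), c(5, 6)), "increasing")
  expect_equal(unname(ht$statistic), 12)

  rev <- jonckheereTerpstra(list(c(5, 6), c(3, 4), c(1, 2)), "increasing")
  expect_equal(unname(rev$statistic), 0)
  revDec <- jonckheereTerpstra(list(c(5, 6), c(3, 4), c(1, 2)), "decreasing")
  expect_equal(revDec$p.value, ht$p.value)

  # J + J(reversed order) = total cross pairs for tie-free data
  set.seed(25)
  for (r in 1:8) {
    g <- lapply(1:3, function(i) rnorm(sample(2:5, 1)))
    J1 <- unname(jonckheereTerpstra(g)$statistic)
    J2 <- unname(jonckheereTerpstra(rev(g))$statistic)
    ns <- lengths(g)
    expect_equal(J1 + J2, ns[1] * ns[2] + ns[1] * ns[3] + ns[2] * ns[3])
  }

  expect_error(jonckheereTerpstra(list(1:2, 3:4)), ">= 3 ordered groups")
})

test_that("small-sample JT equals the brute-force pair count and enumeration", {
  set.seed(26)
  for (r in 1:8) {
    ns <- sample(2:3, 3, replace = TRUE)
    vals <- sample(1:5, sum(ns), replace = TRUE)   # ties likely
    g <- split(vals, rep(seq_along(ns), ns))
    ours <- jonckheereTerpstra(g, "increasing", method = "exact")
    expect_equal(unname(ours$statistic), oracle_jt_statistic(g))
    expect_equal(ours$p.value, oracle_jt_exact_p(g))
  }
})

test_that("JT exact and normal p agree for tie-free moderate samples", {
  set.seed(27)
  for (r in 1:4) {
    g <- list(rnorm(3), rnorm(3), rnorm(4))
    pe <- jonckheereTerpstra(g, method = "exact", exactLimit = 10)$p.value
    pn <- jonckheereTerpstra(g, method = "normal")$p.value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("rank tests hold their nominal level on a simulated null", {
  set.seed(5)
  R <- 2000
  n <- 40
  rej <- matrix(FALSE, R, 3)
  # the continuity correction deliberately makes the approximations
  # conservative, so the nominal-level check targets the plain asymptotics
  for (r in seq_len(R)) {
    g <- list(rnorm(n), rnorm(n), rnorm(n))
    rej[r, 1] <- mannWhitneyU(g[[1]], g[[2]], method = "normal",
                              correct = FALSE)$p.value < 0.05
    rej[r, 2] <- kruskalWallisTest(g)$p.value < 0.05
    rej[r, 3] <- jonckheereTerpstra(g, method = "normal",
                                    correct = FALSE)$p.value < 0.05
  }
  # band: Monte-Carlo error plus the finite-sample bias of the chi-square /
  # normal approximations (true levels at this n are ~0.045-0.049, measured
  # at 20000 replicates; they approach 0.05 only asymptotically)
  band <- 2 * sqrt(0.05 * 0.95 / R) + 0.005
  expect_true(all(abs(colMeans(rej) - 0.05) <= band))
})

test_that("BH adjustment is the step-up transform and matches p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(c(1.0, 0.5)), c(1, 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(28)
  for (r in 1:10) {
    p <- runif(sample(1:50, 1))
    p[sample(length(p), size = min(2, length(p) - 1))] <- NA
    expect_equal(bhAdjust(p), p.adjust(p, "BH"))
  }

  # monotone: order preserved, never below the input
  p <- runif(100)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("hypergeometric overrepresentation matches exact enumeration", {
  expect_equal(hypergeomTest(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeomTest(0, 5, 4, 10), 1)
  expect_equal(hypergeomTest(3, 3, 3, 3), 1)
  expect_error(hypergeomTest(5, 4, 10, 10), "inconsistent")

  # oracle: sum the hypergeometric pmf over the upper tail
  for (k in 0:3) {
    tail <- sum(dhyper(k:3, 3, 9, 5))
    expect_equal(hypergeomTest(k, 3, 5, 12), tail)
  }
})
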