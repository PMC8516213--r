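# Rank statistics for the trajectory trend battery. Midranks are used
# throughout; exact p-values are full enumerations over group labelings and
# are therefore valid under ties as well.

.midranks <- function(x) rank(x, ties.method = "average")

.tieSizes <- function(x) {
    t <- table(x)
    as.numeric(t[t > 1])
}

.htest <- function(statistic, p, method, alternative, dataName, extra = list()) {
    out <- c(list(statistic = statistic, p.value = min(max(p, 0), 1),
                  method = method, alternative = alternative,
                  data.name = dataName), extra)
    class(out) <- "htest"
    out
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test. U counts the pairs (x, y) with x above y, ties
#' counting one half. The normal approximation uses the tie-corrected null
#' variance and (by default) a continuity correction; for small pooled
#' samples (`<= exactLimit`) the exact p-value is computed by full
#' enumeration of the label assignments, with the two-sided p defined as the
#' null probability of a U at least as far from its mean as observed.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param method `"auto"` (exact when `length(x) + length(y) <=
#'   exactLimit`), `"exact"` or `"normal"`.
#' @param correct continuity correction for the normal approximation.
#' @param exactLimit pooled-size bound for automatic exact enumeration.
#' @return An object of class `"htest"` with the U statistic (for `x`),
#'   the p-value and the method used.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))            # exact p = 0.1
#' @export
mannWhitneyU <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         method = c("auto", "exact", "normal"),
                         correct = TRUE, exactLimit = 10) {
    alternative <- match.arg(alternative)
    method <- match.arg(method)
    x <- as.numeric(x); y <- as.numeric(y)
    if (!length(x) || !length(y)) stop("both samples must be non-empty")
    nx <- length(x); ny <- length(y); n <- nx + ny
    if (method == "auto") method <- if (n <= exactLimit) "exact" else "normal"

    pooled <- c(x, y)
    r <- .midranks(pooled)
    U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * ny / 2

    if (method == "exact") {
        Uall <- .enumU(pooled, nx)
        eps <- 1e-9
        p <- switch(alternative,
            greater = mean(Uall >= U - eps),
            less = mean(Uall <= U + eps),
            two.sided = mean(abs(Uall - mu) >= abs(U - mu) - eps))
        meth <- "Mann-Whitney U test (exact)"
    } else {
        ties <- .tieSizes(pooled)
        v <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        if (v <= 0) {
            p <- 1
        } else {
            cc <- if (correct) 0.5 else 0
            z <- switch(alternative,
                greater = (U - mu - cc) / sqrt(v),
                less = (U - mu + cc) / sqrt(v),
                two.sided = (U - mu - sign(U - mu) * cc) / sqrt(v))
            p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
        }
        meth <- "Mann-Whitney U test (normal approximation)"
    }
    .htest(c(U = U), p, meth, alternative,
           paste(deparse1(substitute(x)), "and", deparse1(substitute(y))),
           extra = list(n = c(nx = nx, ny = ny)))
}

# all U values over C(n, nx) assignments of the pooled values to sample x
.enumU <- function(pooled, nx) {
    r <- .midranks(pooled)
    sets <- utils::combn(length(pooled), nx)
    colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
}

#' Kruskal-Wallis rank test
#'
#' H statistic over k groups with the tie correction
#' `1 - sum(t^3 - t) / (n^3 - n)`; p-value from the chi-square
#' approximation with k - 1 degrees of freedom. Fully tied input is the
#' degenerate no-evidence case and returns H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return An object of class `"htest"`.
#' @export
kruskalWallisTest <- function(groups) {
    if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
    if (any(!lengths(groups))) stop("empty group")
    groups <- lapply(groups, as.numeric)
    k <- length(groups)
    pooled <- unlist(groups, use.names = FALSE)
    n <- length(pooled)
    r <- .midranks(pooled)
    idx <- rep(seq_len(k), lengths(groups))
    rsum <- tapply(r, idx, sum)
    H <- 12 / (n * (n + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (n + 1)
    corr <- 1 - sum(vapply(.tieSizes(pooled), function(t) t^3 - t, numeric(1))) /
        (n^3 - n)
    if (corr <= 0) {
        H <- 0
        p <- 1
    } else {
        H <- H / corr
        p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
    }
    .htest(c(H = H), p, "Kruskal-Wallis rank test", "two.sided",
           deparse1(substitute(groups)),
           extra = list(parameter = c(df = k - 1), n = lengths(groups)))
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone shift across k >= 3 ordered groups (here: days).
#' The statistic sums, over all ordered group pairs i < j, the number of
#' value pairs with the group-i value below the group-j value, ties counting
#' one half; it is always reported for the supplied group order. Under the
#' `"decreasing"` alternative the test is run on the reversed order. The
#' p-value is the upper tail of the statistic: exact by enumeration over all
#' distinct group labelings when the pooled size is within `exactLimit`,
#' otherwise by normal approximation with the tie-corrected null mean and
#' variance.
#'
#' @param groups list of numeric vectors in increasing factor order.
#' @param alternative `"increasing"` or `"decreasing"` trend.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param correct continuity correction for the normal approximation.
#' @param exactLimit pooled-size bound for automatic exact enumeration.
#' @return An object of class `"htest"` with the J statistic and one-sided
#'   p-value.
#' @examples
#' jonckheereTerpstra(list(c(1, 2), c(3, 4), c(5, 6)))  # J = 12
#' @export
jonckheereTerpstra <- function(groups,
                               alternative = c("increasing", "decreasing"),
                               method = c("auto", "exact", "normal"),
                               correct = TRUE, exactLimit = 10) {
    alternative <- match.arg(alternative)
    method <- match.arg(method)
    if (!is.list(groups) || length(groups) < 3)
        stop("need >= 3 ordered groups (use mannWhitneyU for 2)")
    if (any(!lengths(groups))) stop("empty group")
    groups <- lapply(groups, as.numeric)
    ns <- lengths(groups)
    N <- sum(ns)
    if (method == "auto") method <- if (N <= exactLimit) "exact" else "normal"

    J <- .jtStatistic(groups)
    totalPairs <- sum(utils::combn(length(ns), 2, function(ij) ns[ij[1]] * ns[ij[2]]))
    # reversal identity: J(increasing) + J(reversed) = total cross pairs
    Jeff <- if (alternative == "increasing") J else totalPairs - J

    if (method == "exact") {
        Jall <- .enumJT(unlist(groups, use.names = FALSE), ns)
        p <- mean(Jall >= Jeff - 1e-9)
        meth <- "Jonckheere-Terpstra trend test (exact)"
    } else {
        pooled <- unlist(groups, use.names = FALSE)
        EJ <- (N^2 - sum(ns^2)) / 4
        t <- as.numeric(table(pooled))
        A <- N * (N - 1) * (2 * N + 5) -
            sum(ns * (ns - 1) * (2 * ns + 5)) -
            sum(t * (t - 1) * (2 * t + 5))
        B <- sum(ns * (ns - 1) * (ns - 2)) * sum(t * (t - 1) * (t - 2))
        C <- sum(ns * (ns - 1)) * sum(t * (t - 1))
        v <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) + C / (8 * N * (N - 1))
        if (v <= 0) {
            p <- 1
        } else {
            cc <- if (correct) 0.5 else 0
            p <- stats::pnorm((Jeff - EJ - cc) / sqrt(v), lower.tail = FALSE)
        }
        meth <- "Jonckheere-Terpstra trend test (normal approximation)"
    }
    .htest(c(J = J), p, meth, paste0(alternative, " trend"),
           deparse1(substitute(groups)), extra = list(n = ns))
}

.jtStatistic <- function(groups) {
    k <- length(groups)
    J <- 0
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        d <- outer(groups[[i]], groups[[j]], "-")
        J <- J + sum(d < 0) + 0.5 * sum(d == 0)
    }
    J
}

# J statistic over every distinct assignment of the pooled values to groups
# of the given sizes (each assignment equally likely under the null)
.enumJT <- function(pooled, ns) {
    res <- numeric(0)
    recurse <- function(remaining, sizes, acc) {
        if (!length(sizes)) {
            res[length(res) + 1L] <<- .jtStatistic(acc)
            return(invisible())
        }
        picks <- utils::combn(length(remaining), sizes[1], simplify = FALSE)
        for (p in picks)
            recurse(remaining[-p], sizes[-1], c(acc, list(remaining[p])))
    }
    recurse(pooled, ns, list())
    res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: with the p-values sorted ascending, the
#' i-th adjusted value is `min over j >= i of p_(j) * m / j`, capped at 1
#' and returned in the original order. `NA` values are ignored (and
#' returned as `NA`) with `m` reduced accordingly.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
    p <- as.numeric(p)
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    pv <- p[ok]
    m <- length(pv)
    if (m) {
        o <- order(pv)
        q <- pv[o] * m / seq_len(m)
        q <- rev(cummin(rev(q)))      # enforce min over j >= i
        out[ok][o] <- pmin(q, 1)
    }
    out
}

#' Hypergeometric overrepresentation p-value
#'
#' Upper-tail probability `P(X >= k)` that a random query of size `n` drawn
#' without replacement from a universe of `N` genes, of which `K` belong to
#' the set, overlaps the set in at least `k` genes.
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return p-value.
#' @examples
#' hypergeomTest(4, 5, 4, 10)  # 5/210
#' @export
hypergeomTest <- function(k, K, n, N) {
    if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
        stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
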