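# Independent brute-force oracles for the rank tests, written as plain
# nested loops so they share no code path with the package implementations.

# pair count J: explicit double loop over all ordered group pairs
oracle_jt_statistic <- function(groups) {
  J <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      for (a in groups[[i]]) {
        for (b in groups[[j]]) {
          if (a < b) J <- J + 1
          else if (a == b) J <- J + 0.5
        }
      }
    }
  }
  J
}

# exact one-sided upper-tail p for J by enumerating every distinct way of
# assigning the pooled values to groups of the observed sizes
oracle_jt_exact_p <- function(groups) {
  ns <- lengths(groups)
  pooled <- unlist(groups)
  Jobs <- oracle_jt_statistic(groups)
  count <- 0L
  total <- 0L
  assign_next <- function(values, sizes, built) {
    if (length(sizes) == 0) {
      total <<- total + 1L
      if (oracle_jt_statistic(built) >= Jobs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    for (pick in utils::combn(seq_along(values), sizes[1], simplify = FALSE)) {
      assign_next(values[-pick], sizes[-1], c(built, list(values[pick])))
    }
  }
  assign_next(pooled, ns, list())
  count / total
}

# exact Mann-Whitney p by enumerating the label assignments and counting
# pairwise wins directly (no ranks)
oracle_mw_u <- function(x, y) {
  U <- 0
  for (a in x) for (b in y) {
    if (a > b) U <- U + 1 else if (a == b) U <- U + 0.5
  }
  U
}

oracle_mw_exact_p <- function(x, y, alternative = "two.sided") {
  nx <- length(x)
  pooled <- c(x, y)
  Uobs <- oracle_mw_u(x, y)
  mu <- nx * length(y) / 2
  sets <- utils::combn(length(pooled), nx, simplify = FALSE)
  Uall <- vapply(sets, function(s) oracle_mw_u(pooled[s], pooled[-s]), numeric(1))
  eps <- 1e-9
  switch(alternative,
    greater = mean(Uall >= Uobs - eps),
    less = mean(Uall <= Uobs + eps),
    two.sided = mean(abs(Uall - mu) >= abs(Uobs - mu) - eps))
}
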