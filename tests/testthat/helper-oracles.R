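# Independent brute-force oracles. These deliberately avoid stats::cor,
# stats::kruskal.test and every package code path they are used to check:
# ranks by pairwise counting, moments by explicit sums.

bf_rank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sx <- sqrt(sum((x - mx)^2))
  sy <- sqrt(sum((y - my)^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sxy / (sx * sy)
}

bf_spearman <- function(x, y) bf_pearson(bf_rank(x), bf_rank(y))

# Kruskal-Wallis statistic with tie correction, straight from the formula.
bf_kw_stat <- function(y, g) {
  g <- as.factor(g)
  N <- length(y)
  r <- bf_rank(y)
  h <- 0
  for (lv in levels(g)) {
    ni <- sum(g == lv)
    h <- h + ni * (mean(r[g == lv]) - (N + 1) / 2)^2
  }
  h <- 12 / (N * (N + 1)) * h
  ties <- table(y)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# All permutations of 1..n (n small), for exhaustive rank-arrangement oracles.
bf_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- bf_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
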