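# Shared statistical primitives. The rank-sum and Levene tests are written
# in-package because the exact-enumeration tie handling (rank-sum) is part of
# the contract and no installed package provides Levene's test; both are
# cross-checked against independent oracles in the test suite.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package internals never clobber user RNG
#' streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop2 <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "evoniche_error")))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum distribution (tie-aware, via all
#' \eqn{\binom{n_x+n_y}{n_x}} group assignments) when both groups have at most
#' 10 observations; otherwise the normal approximation with tie correction
#' (no continuity correction, which keeps the nominal type-I error at
#' moderate group sizes).
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `statistic` (Mann-Whitney U for `x`) and `p.value`.
#' @examples
#' rank_sum_test(c(5, 6, 7), c(1, 2, 3))$p.value # exact 0.1
#' @export
rank_sum_test <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L || ny == 0L) {
    stop2("rank_sum_test: both groups must be non-empty", "evoniche_empty_group")
  }
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  if (nx <= 10L && ny <= 10L) {
    sums <- colSums(matrix(r[utils::combn(nx + ny, nx)], nrow = nx))
    eps <- 1e-9
    p <- 2 * min(mean(sums <= W + eps), mean(sums >= W - eps))
  } else {
    n <- nx + ny
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      return(list(statistic = U, p.value = 1))
    }
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = U, p.value = min(1, p))
}

#' Levene's test for equality of variances
#'
#' Classical (mean-centered) Levene test: one-way ANOVA on the absolute
#' deviations of each observation from its group center. The median-centered
#' Brown-Forsythe variant is available via `center = "median"`.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.
#' @param center `"mean"` (classical, default) or `"median"`.
#' @return list with `statistic` (W), `df` (numerator, denominator) and
#'   `p.value` from the F reference distribution.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(groups)
  if (nlevels(g) < 2L) {
    stop2("levene_test: need at least two groups", "evoniche_empty_group")
  }
  k <- nlevels(g)
  N <- length(values)
  ctr_fun <- if (center == "mean") mean else stats::median
  ctr <- tapply(values, g, ctr_fun)
  z <- abs(values - ctr[as.integer(g)])
  zi <- tapply(z, g, mean)
  ni <- tabulate(g)
  num <- sum(ni * (zi - mean(z))^2) / (k - 1)
  den <- sum((z - zi[as.integer(g)])^2) / (N - k)
  if (!is.finite(den) || den <= 0) {
    W <- 0
    p <- 1
  } else {
    W <- num / den
    p <- stats::pf(W, k - 1, N - k, lower.tail = FALSE)
  }
  list(statistic = W, df = c(k - 1, N - k), p.value = p)
}

#' Spearman rank correlation with average ranks
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation of mid-ranks (NA if either side is constant).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop2("spearman_rho: length mismatch", "evoniche_dim_error")
  }
  suppressWarnings(stats::cor(rank(x), rank(y)))
}

# natural chromosome ordering: numeric labels first in numeric order, then
# X, Y, M/MT, then anything else alphabetically; tolerates a "chr" prefix
chrom_order_key <- function(chrom) {
  stripped <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  num <- suppressWarnings(as.integer(stripped))
  special <- match(toupper(stripped), c("X", "Y", "M", "MT"))
  key <- ifelse(!is.na(num), num,
         ifelse(!is.na(special), 1000L + special, NA_integer_))
  if (anyNA(key)) {
    extra <- sort(unique(stripped[is.na(key)]))
    key[is.na(key)] <- 2000L + match(stripped[is.na(key)], extra)
  }
  key
}
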