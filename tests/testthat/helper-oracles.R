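# Independent oracles built from first principles, kept free of the code
# paths they check.

# natural cubic spline: second-derivative system solved by the Thomas
# (tridiagonal) algorithm, then piecewise-cubic evaluation
natural_spline_eval <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n, !is.unsorted(x))
  h <- diff(x)
  m <- n - 2L
  sub <- numeric(m); diagc <- numeric(m); sup <- numeric(m); rhs <- numeric(m)
  for (i in 2:(n - 1)) {
    j <- i - 1L
    sub[j] <- h[i - 1]
    diagc[j] <- 2 * (h[i - 1] + h[i])
    sup[j] <- h[i]
    rhs[j] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  if (m > 1) {
    for (i in 2:m) {
      w <- sub[i] / diagc[i - 1]
      diagc[i] <- diagc[i] - w * sup[i - 1]
      rhs[i] <- rhs[i] - w * rhs[i - 1]
    }
  }
  M <- numeric(m)
  M[m] <- rhs[m] / diagc[m]
  if (m > 1) for (i in (m - 1):1) M[i] <- (rhs[i] - sup[i] * M[i + 1]) / diagc[i]
  M <- c(0, M, 0)
  vapply(xout, function(x0) {
    i <- min(max(findInterval(x0, x, rightmost.closed = TRUE), 1L), n - 1L)
    hi <- h[i]
    A <- (x[i + 1] - x0) / hi
    B <- (x0 - x[i]) / hi
    A * y[i] + B * y[i + 1] +
      ((A^3 - A) * M[i] + (B^3 - B) * M[i + 1]) * hi^2 / 6
  }, numeric(1))
}

# simple-linear-regression slope and two-sided slope t-test from the
# normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - 2L
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[2, 2])
  tstat <- beta[2] / se
  list(slope = unname(beta[2]),
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}

# pairwise studentized-range statistics for a balanced one-way layout
range_stats <- function(values, groups) {
  n <- table(groups)
  stopifnot(length(unique(n)) == 1L)
  n1 <- n[[1]]
  k <- nlevels(groups)
  means <- tapply(values, groups, mean)
  mse <- sum((values - means[as.integer(groups)])^2) /
    (length(values) - k)
  pairs <- utils::combn(levels(groups), 2)
  q <- abs(means[pairs[1, ]] - means[pairs[2, ]]) / sqrt(mse / n1)
  setNames(as.numeric(q), paste(pairs[2, ], pairs[1, ], sep = "-"))
}

# permutation distribution of the maximum range statistic: the oracle for
# Tukey pairwise p-values (p_ab = P(max-range* >= q_ab))
perm_tukey_oracle <- function(values, groups, B = 1e5, seed = 42) {
  set.seed(seed)
  obs <- range_stats(values, groups)
  hits <- numeric(length(obs))
  N <- length(values)
  for (b in seq_len(B)) {
    qmax <- max(range_stats(values[sample.int(N)], groups))
    hits <- hits + (qmax >= obs)
  }
  list(p = hits / B, se = sqrt(pmax(hits / B * (1 - hits / B), 1e-12) / B))
}

# exhaustive per-pixel rasterization oracle: looks up each pixel's county
# and rate independently of the vectorized implementation
pixel_oracle <- function(rates, county_raster, mask, crop, year) {
  ids <- attr(county_raster, "county_ids")
  g <- county_raster$geom
  sub <- rates[rates$crop == crop & rates$year == year, ]
  out <- matrix(NA_real_, g$nrow, g$ncol)
  for (i in seq_len(g$nrow)) {
    for (j in seq_len(g$ncol)) {
      ci <- county_raster$values[i, j]
      if (is.na(ci)) next
      if (is.na(mask$values[i, j]) || mask$values[i, j] <= 0) next
      row <- sub[sub$county == ids[ci], ]
      if (nrow(row) == 1L && !is.na(row$p2o5_rate) &&
          is.finite(row$p2o5_rate)) {
        out[i, j] <- row$p2o5_rate
      }
    }
  }
  out
}
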