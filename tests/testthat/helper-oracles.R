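# Independent brute-force oracles, deliberately written in the most naive
# style possible; they never call the package functions they check.

# O(N^2) discrete Fourier transform, non-negative half-spectrum magnitudes.
oracle_dft_magnitudes <- function(x) {
  n <- length(x)
  nh <- n %/% 2 + 1
  out <- numeric(nh)
  for (k in 0:(nh - 1)) {
    re <- 0; im <- 0
    for (j in 0:(n - 1)) {
      re <- re + x[j + 1] * cos(-2 * pi * k * j / n)
      im <- im + x[j + 1] * sin(-2 * pi * k * j / n)
    }
    out[k + 1] <- sqrt(re^2 + im^2)
  }
  out
}

# Mean of magnitudes at bins inside [center +/- hw] and outside
# [center +/- ehw], by explicit bin enumeration.
oracle_band_mean <- function(freqs, mags, center, hw, ehw = 0) {
  vals <- c()
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    inside <- f >= center - hw && f <= center + hw
    excluded <- ehw > 0 && f >= center - ehw && f <= center + ehw
    if (inside && !excluded) vals <- c(vals, mags[i])
  }
  if (length(vals) == 0) stop("no bins")
  sum(vals) / length(vals)
}

# Median by sorting, in dB.
oracle_noise_floor_db <- function(mags) {
  s <- sort(mags)
  n <- length(s)
  m <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  20 * log10(m)
}

# OLS via the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# All permutations of 1..n, built by a different recursion than the
# package's (insertion rather than prefix-block).
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

oracle_kendall <- function(x, y, alternative = "two.sided") {
  n <- length(x)
  score <- function(a, b) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
    s
  }
  s_obs <- score(x, y)
  ties <- function(v) {
    tt <- 0
    for (u in unique(v)) {
      m <- sum(v == u)
      tt <- tt + m * (m - 1) / 2
    }
    tt
  }
  n0 <- n * (n - 1) / 2
  tau <- s_obs / sqrt((n0 - ties(x)) * (n0 - ties(y)))
  hits <- 0; total <- 0
  for (p in oracle_perms(n)) {
    s <- score(x, y[p])
    total <- total + 1
    ok <- switch(alternative,
                 two.sided = abs(s) >= abs(s_obs) - 1e-12,
                 greater = s >= s_obs - 1e-12,
                 less = s <= s_obs + 1e-12)
    if (ok) hits <- hits + 1
  }
  list(tau = tau, p = hits / total)
}

# Fisher exact by filtering an exhaustive cell grid (free cells are the
# (r-1) x (c-1) top-left block; the rest follow from the margins).
oracle_fisher <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  r <- nrow(tab); cc <- ncol(tab)
  lp <- function(tb) sum(lfactorial(rs)) + sum(lfactorial(cs)) -
    lfactorial(N) - sum(lfactorial(tb))
  free <- expand.grid(rep(list(0:N), (r - 1) * (cc - 1)))
  p_obs <- lp(tab)
  total <- 0
  for (i in seq_len(nrow(free))) {
    tb <- matrix(0, r, cc)
    tb[1:(r - 1), 1:(cc - 1)] <- as.numeric(free[i, ])
    tb[1:(r - 1), cc] <- rs[1:(r - 1)] - rowSums(tb[1:(r - 1), 1:(cc - 1),
                                                    drop = FALSE])
    tb[r, ] <- cs - colSums(tb[1:(r - 1), , drop = FALSE])
    if (any(tb < 0)) next
    if (lp(tb) <= p_obs + 1e-7) total <- total + exp(lp(tb))
  }
  total
}

# Wilcoxon-Pratt by explicit 2^m sign enumeration (bit twiddling).
oracle_wilcoxon_pratt <- function(d, alternative = "two.sided") {
  n <- length(d)
  rk <- rank(abs(d))
  nz_ranks <- rk[d != 0]
  m <- length(nz_ranks)
  v_obs <- sum(rk[d > 0])
  if (m == 0) return(list(V = v_obs, p = 1))
  vs <- numeric(2^m)
  for (code in 0:(2^m - 1)) {
    v <- 0
    for (b in 1:m) if (bitwAnd(code, bitwShiftL(1L, b - 1L)) != 0)
      v <- v + nz_ranks[b]
    vs[code + 1] <- v
  }
  mu <- sum(nz_ranks) / 2
  p <- switch(alternative,
              two.sided = mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9),
              greater = mean(vs >= v_obs - 1e-9),
              less = mean(vs <= v_obs + 1e-9))
  list(V = v_obs, p = p)
}

# Jonckheere-Terpstra null by permuting the pooled vector through all n!
# orderings (positions 1..n1 are group 1, etc.).
oracle_jt <- function(groups, alternative = "increasing") {
  sizes <- lengths(groups)
  pooled <- unlist(groups)
  n <- length(pooled)
  stat <- function(v) {
    gs <- split(v, rep(seq_along(sizes), sizes))
    s <- 0
    for (a in 1:(length(gs) - 1)) for (b in (a + 1):length(gs))
      for (xa in gs[[a]]) for (xb in gs[[b]])
        s <- s + (xa < xb) + 0.5 * (xa == xb)
    s
  }
  obs <- stat(pooled)
  vals <- sapply(oracle_perms(n), function(p) stat(pooled[p]))
  p <- switch(alternative,
              increasing = mean(vals >= obs - 1e-9),
              decreasing = mean(vals <= obs + 1e-9),
              two.sided = min(1, 2 * min(mean(vals >= obs - 1e-9),
                                         mean(vals <= obs + 1e-9))))
  list(statistic = obs, p = p)
}

# Coarse grid-search least squares for the Gompertz curve.
oracle_gompertz_grid <- function(p, y, grid) {
  best <- NULL; best_ss <- Inf
  for (cc in grid$c) for (A in grid$A) for (k in grid$k) for (p0 in grid$p0) {
    yhat <- cc + A * exp(-exp(-k * (p - p0)))
    ss <- sum((y - yhat)^2)
    if (ss < best_ss) { best_ss <- ss; best <- c(c = cc, A = A, k = k, p0 = p0) }
  }
  list(par = best, ss = best_ss)
}

make_spectrum <- function(frequencies, magnitudes) {
  structure(list(frequencies = frequencies, magnitudes = magnitudes),
            class = "magnitude_spectrum")
}
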