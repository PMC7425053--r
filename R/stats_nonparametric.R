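# Nonparametric tests with exact small-sample null distributions:
# tie-corrected Kendall tau-b, r x c Fisher exact, Wilcoxon signed-rank
# with the Pratt zero treatment, and the Jonckheere-Terpstra trend test.
# Each test enumerates its exact null below a configurable size cutoff and
# falls back to a tie-corrected normal approximation (or seeded Monte
# Carlo) above it.

.bbb_cache <- new.env(parent = emptyenv())

test_result <- function(method, statistic, p_value, n, exact,
                        tie_correction_applied = FALSE,
                        alternative = "two.sided", mc_se = NULL,
                        extra = list()) {
  p_value <- min(max(p_value, .Machine$double.xmin), 1)
  structure(c(list(method = method, statistic = statistic,
                   p_value = p_value, n = n, exact = exact,
                   tie_correction_applied = tie_correction_applied,
                   alternative = alternative, mc_se = mc_se),
              extra),
            class = "bbb_test")
}

#' @export
print.bbb_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (%s, %s%s)\n",
              x$method, x$statistic, x$p_value, x$alternative,
              if (x$exact) "exact" else "approximate",
              if (isTRUE(x$tie_correction_applied)) ", tie-corrected" else ""))
  invisible(x)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

kendall_S <- function(x, y) {
  d <- outer(x, x, "-"); e <- outer(y, y, "-")
  sum(sign(d[upper.tri(d)]) * sign(e[upper.tri(e)]))
}

tie_sizes <- function(v) as.integer(table(v)[table(v) > 1])

#' Kendall rank correlation (tau-b) with exact permutation p-value
#'
#' The tie-corrected tau-b statistic, with a p-value by exhaustive
#' enumeration of all `n!` permutations of `y` when `n <= exact_max_n`, and
#' a tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric vectors, `n >= 3`; neither may be entirely tied.
#' @param alternative `"two.sided"`, `"greater"` (positive association), or
#'   `"less"`.
#' @param exact_max_n Largest `n` for full enumeration (default 8).
#' @return A `bbb_test` with `statistic` = tau-b.
#' @export
kendall_tau <- function(x, y, alternative = c("two.sided", "greater", "less"),
                        exact_max_n = 8L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 3L) stop("need n >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("all-tied input: tau undefined")

  tx <- tie_sizes(x); ty <- tie_sizes(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  S <- kendall_S(x, y)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  ties <- n1 > 0 || n2 > 0
  eps <- 1e-12

  if (n <= exact_max_n) {
    perms <- all_permutations(n)
    stats_perm <- apply(perms, 1, function(pr) kendall_S(x, y[pr]))
    p <- switch(alternative,
                two.sided = mean(abs(stats_perm) >= abs(S) - eps),
                greater = mean(stats_perm >= S - eps),
                less = mean(stats_perm <= S + eps))
    return(test_result("kendall_tau", tau, p, n, exact = TRUE,
                       tie_correction_applied = ties,
                       alternative = alternative,
                       extra = list(S = S)))
  }

  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(varS)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  test_result("kendall_tau", tau, p, n, exact = FALSE,
              tie_correction_applied = ties, alternative = alternative,
              extra = list(S = S, z = z))
}

table_log_prob <- function(tab, lr, lc, lN) {
  lr + lc - lN - sum(lfactorial(tab))
}

# Enumerate all non-negative integer tables with the given margins,
# calling fn(table) for each; aborts via condition when more than `cap`
# tables are generated.
enumerate_tables <- function(row_sums, col_sums, fn, cap = Inf) {
  r <- length(row_sums); cc <- length(col_sums)
  count <- 0L
  tab <- matrix(0L, r, cc)
  rec_row <- function(i, rem_cols) {
    if (i == r) {
      if (any(rem_cols < 0)) return()
      tab[r, ] <<- rem_cols
      count <<- count + 1L
      if (count > cap) stop(structure(class = c("bbb_table_cap", "error",
                                                "condition"),
                                      list(message = "cap", call = NULL)))
      fn(tab)
      return()
    }
    rec_cell <- function(j, left, cols) {
      if (j == cc) {
        tab[i, cc] <<- left
        if (left <= cols[cc]) {
          cols2 <- cols; cols2[cc] <- cols2[cc] - left
          rec_row(i + 1L, cols2)
        }
        return()
      }
      for (v in 0:min(left, cols[j])) {
        tab[i, j] <<- v
        cols2 <- cols; cols2[j] <- cols2[j] - v
        rec_cell(j + 1L, left - v, cols2)
      }
    }
    rec_cell(1L, row_sums[i], rem_cols)
  }
  rec_row(1L, col_sums)
  count
}

#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided p-value by the point-probability rule: the sum of the
#' probabilities, under the fixed-margin multivariate hypergeometric null,
#' of all tables as or less probable than the observed one.  Tables are
#' enumerated exhaustively up to `max_tables`; beyond that a seeded Monte
#' Carlo estimate over random fixed-margin tables (via [stats::r2dtable()])
#' is returned with its standard error.
#'
#' @param tab Non-negative integer matrix; no all-zero row or column.
#' @param max_tables Enumeration cap (default 1e5 tables).
#' @param B Monte Carlo draws when beyond the cap (default 1e4).
#' @param seed Seed for the Monte Carlo path.
#' @return A `bbb_test` with `statistic` = observed table probability.
#' @export
fisher_exact <- function(tab, max_tables = 1e5, B = 1e4, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: empty row or column margin")
  N <- sum(tab)
  lr <- sum(lfactorial(rs)); lc <- sum(lfactorial(cs)); lN <- lfactorial(N)
  lp_obs <- table_log_prob(tab, lr, lc, lN)
  eps <- 1e-7

  acc <- new.env()
  acc$p <- 0
  res <- tryCatch({
    nt <- enumerate_tables(rs, cs, function(tb) {
      lp <- table_log_prob(tb, lr, lc, lN)
      if (lp <= lp_obs + eps) acc$p <- acc$p + exp(lp)
    }, cap = max_tables)
    list(p = acc$p, n_tables = nt)
  }, bbb_table_cap = function(e) NULL)

  if (!is.null(res)) {
    return(test_result("fisher_exact", exp(lp_obs), res$p, N, exact = TRUE,
                       extra = list(n_tables = res$n_tables)))
  }
  set.seed(seed)
  draws <- stats::r2dtable(B, rs, cs)
  hits <- vapply(draws, function(tb)
    table_log_prob(tb, lr, lc, lN) <= lp_obs + eps, logical(1))
  p <- mean(hits)
  test_result("fisher_exact", exp(lp_obs), max(p, 1 / B), N, exact = FALSE,
              mc_se = sqrt(p * (1 - p) / B),
              extra = list(B = B))
}

#' Wilcoxon signed-rank test with the Pratt zero treatment
#'
#' Zero differences are included when ranking the absolute differences and
#' their signs discarded afterwards (Pratt); the statistic is the sum of
#' the ranks of the positive differences.  For `n <= exact_max_n` the
#' exact null is built by enumerating all `2^m` sign assignments of the
#' non-zero differences (zeros stay fixed); above the cutoff a normal
#' approximation with zero and tie corrections is used.
#'
#' @param d Paired differences (`n >= 1`).
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @param exact_max_n Largest `n` for sign-flip enumeration (default 12).
#' @return A `bbb_test` with `statistic` = positive-rank sum `V`.
#' @export
wilcoxon_pratt <- function(d, alternative = c("two.sided", "greater", "less"),
                           exact_max_n = 12L) {
  alternative <- match.arg(alternative)
  d <- as.numeric(d)
  n <- length(d)
  if (n < 1L) stop("need at least one difference")
  rk <- rank(abs(d))            # zeros included in the ranking
  nz <- d != 0
  m <- sum(nz)
  V <- sum(rk[d > 0])
  eps <- 1e-9
  ties <- anyDuplicated(abs(d[nz])) > 0

  if (m == 0L)
    return(test_result("wilcoxon_pratt", V, 1, n, exact = TRUE,
                       alternative = alternative))

  if (n <= exact_max_n) {
    r_nz <- rk[nz]
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    Vs <- as.numeric(signs %*% r_nz)
    mu <- sum(r_nz) / 2
    p <- switch(alternative,
                two.sided = mean(abs(Vs - mu) >= abs(V - mu) - eps),
                greater = mean(Vs >= V - eps),
                less = mean(Vs <= V + eps))
    return(test_result("wilcoxon_pratt", V, p, n, exact = TRUE,
                       tie_correction_applied = ties,
                       alternative = alternative,
                       extra = list(n_nonzero = m)))
  }

  z0 <- n - m
  mu <- (n * (n + 1) - z0 * (z0 + 1)) / 4
  t_all <- as.integer(table(rk[nz]))
  sig2 <- (n * (n + 1) * (2 * n + 1) - z0 * (z0 + 1) * (2 * z0 + 1)) / 24 -
    sum(t_all^3 - t_all) / 48
  z <- (V - mu) / sqrt(sig2)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  test_result("wilcoxon_pratt", V, p, n, exact = FALSE,
              tie_correction_applied = ties, alternative = alternative,
              extra = list(n_nonzero = m, z = z))
}

jt_statistic <- function(groups) {
  k <- length(groups)
  s <- 0
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    xa <- groups[[a]]; xb <- groups[[b]]
    cmp <- outer(xa, xb, "<") + 0.5 * outer(xa, xb, "==")
    s <- s + sum(cmp)
  }
  s
}

# Exact null distribution of the JT statistic by enumeration of all
# assignments of the pooled values to groups of the given sizes.  When the
# pooled data are tie-free the distribution depends only on the group
# sizes and is cached.
jt_exact_distribution <- function(pooled, sizes) {
  no_ties <- !anyDuplicated(pooled)
  key <- if (no_ties) paste0("jt:", paste(sort(sizes), collapse = ","))
  if (no_ties && !is.null(.bbb_cache[[key]])) return(.bbb_cache[[key]])
  vals <- if (no_ties) seq_along(pooled) else pooled
  N <- length(vals)
  cmp <- outer(vals, vals, "<") + 0.5 * outer(vals, vals, "==")
  k <- length(sizes)
  stats_all <- numeric(0)
  rec <- function(remaining, gi, chosen) {
    if (gi > k) {
      s <- 0
      for (a in seq_len(k - 1)) for (b in (a + 1):k)
        s <- s + sum(cmp[chosen[[a]], chosen[[b]]])
      stats_all[length(stats_all) + 1L] <<- s
      return()
    }
    if (gi == k) { rec(integer(0), k + 1L, c(chosen, list(remaining))); return() }
    for (s in utils::combn(remaining, sizes[gi], simplify = FALSE))
      rec(setdiff(remaining, s), gi + 1L, c(chosen, list(s)))
  }
  rec(seq_len(N), 1L, list())
  if (no_ties) .bbb_cache[[key]] <- stats_all
  stats_all
}

#' Jonckheere-Terpstra test for an ordered trend
#'
#' The statistic is the sum over ordered group pairs of the Mann-Whitney
#' counts (ties counted 1/2).  For pooled `n <= exact_max_n` the p-value
#' comes from exhaustive enumeration of all group assignments; otherwise
#' either a tie-corrected normal approximation or a seeded Monte Carlo
#' permutation estimate is used.
#'
#' @param groups List of numeric samples in the hypothesized increasing
#'   order (>= 2 non-empty groups).
#' @param alternative `"two.sided"`, `"increasing"`, or `"decreasing"`.
#' @param exact_max_n Largest pooled `n` for enumeration (default 12).
#' @param method `"auto"` (exact below the cutoff, normal above),
#'   `"exact"`, `"normal"`, or `"mc"`.
#' @param B Monte Carlo permutation draws (default 1e4).
#' @param seed Seed for the Monte Carlo path.
#' @return A `bbb_test` with `statistic` = JT.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("two.sided", "increasing",
                                                "decreasing"),
                                exact_max_n = 12L,
                                method = c("auto", "exact", "normal", "mc"),
                                B = 1e4, seed = 1L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 ordered groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  jt <- jt_statistic(groups)
  eps <- 1e-9
  ties <- anyDuplicated(pooled) > 0

  if (method == "auto") method <- if (N <= exact_max_n) "exact" else "normal"

  tail_p <- function(dist, obs) {
    mu <- mean(dist)
    switch(alternative,
           two.sided = min(1, 2 * min(mean(dist >= obs - eps),
                                      mean(dist <= obs + eps))),
           increasing = mean(dist >= obs - eps),
           decreasing = mean(dist <= obs + eps))
  }

  if (method == "exact") {
    if (N > exact_max_n)
      stop(sprintf("exact enumeration limited to n <= %d (n = %d)",
                   exact_max_n, N))
    dist <- jt_exact_distribution(pooled, sizes)
    return(test_result("jonckheere_terpstra", jt, tail_p(dist, jt), N,
                       exact = TRUE, tie_correction_applied = ties,
                       alternative = alternative))
  }
  if (method == "mc") {
    set.seed(seed)
    dist <- vapply(seq_len(B), function(b) {
      perm <- sample(pooled)
      jt_statistic(split(perm, rep(seq_along(sizes), sizes)))
    }, numeric(1))
    p <- tail_p(dist, jt)
    return(test_result("jonckheere_terpstra", jt, max(p, 1 / B), N,
                       exact = FALSE, tie_correction_applied = ties,
                       alternative = alternative,
                       mc_se = sqrt(p * (1 - p) / B),
                       extra = list(B = B)))
  }

  # tie-corrected normal approximation (Hollander & Wolfe)
  t_j <- as.integer(table(pooled))
  mu <- (N^2 - sum(sizes^2)) / 4
  A <- N * (N - 1) * (2 * N + 5) -
    sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
    sum(t_j * (t_j - 1) * (2 * t_j + 5))
  Bn <- sum(sizes * (sizes - 1) * (sizes - 2)) *
    sum(t_j * (t_j - 1) * (t_j - 2))
  Cn <- sum(sizes * (sizes - 1)) * sum(t_j * (t_j - 1))
  varJ <- A / 72 + Bn / (36 * N * (N - 1) * (N - 2)) +
    Cn / (8 * N * (N - 1))
  z <- (jt - mu) / sqrt(varJ)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              increasing = stats::pnorm(z, lower.tail = FALSE),
              decreasing = stats::pnorm(z))
  test_result("jonckheere_terpstra", jt, p, N, exact = FALSE,
              tie_correction_applied = ties, alternative = alternative,
              extra = list(z = z))
}
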