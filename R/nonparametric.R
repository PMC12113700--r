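# Nonparametric statistical battery, implemented from first principles with
# exact small-sample null distributions.
#
# Exact paths use dynamic-programming enumeration of the null distribution
# (rank-sum counts for Mann-Whitney, the signed-rank generating function for
# Wilcoxon, within-block permutations for Friedman, permutations of one rank
# vector for Spearman).  Thresholds are chosen so the study design (two
# groups of 12 rats, per-rat aggregation) hits the exact path whenever the
# data are tie-free.

new_test_result <- function(test, statistic, p, n, method, ties = FALSE,
                            extra = list()) {
  structure(c(list(test = test, statistic = statistic,
                   p = min(max(p, 0), 1), n = n, method = method,
                   ties = ties), extra),
            class = "ephys_test")
}

#' @export
print.ephys_test <- function(x, ...) {
  cat(sprintf("<%s> %s = %.4g, p = %.4g (%s%s), n = %s\n", x$test,
              names(x$statistic)[1], x$statistic[1], x$p, x$method,
              if (isTRUE(x$ties)) ", ties" else "",
              paste(x$n, collapse = "/")))
  invisible(x)
}

# Counts of rank-sum arrangements: distribution of U for sample sizes m, n.
# Returns counts over u = 0..m*n (classic recursion, O(m*n^2)).
mw_u_counts <- function(m, n) {
  maxu <- m * n
  # f[[k]][u+1]: number of ways to choose k of the ranks seen so far with
  # Mann-Whitney count u; iterate over the N = m+n ranks.
  f <- vector("list", m + 1)
  f[[1]] <- c(1, rep(0, maxu))
  for (k in seq_len(m)) f[[k + 1]] <- rep(0, maxu + 1)
  for (i in seq_len(m + n)) {
    for (k in rev(seq_len(min(i, m)))) {
      # taking rank i as an x: it beats (i - k) of the y's already placed...
      # standard recurrence: shift by number of y's among the first i-1 ranks
      # handled implicitly via u-shift of (i - k)
      shift <- i - k
      g <- f[[k + 1]]
      h <- f[[k]]
      if (shift <= maxu) {
        g[(shift + 1):(maxu + 1)] <- g[(shift + 1):(maxu + 1)] +
          h[seq_len(maxu + 1 - shift)]
      }
      f[[k + 1]] <- g
    }
  }
  f[[m + 1]]
}

#' Mann-Whitney U test (two-sided)
#'
#' Reports the U statistic of the first sample
#' (`U = sum of x-over-y wins + half-ties`).  The p-value is exact (full
#' null enumeration via rank-sum counts) when `n1 + n2 <= exact_max` and the
#' pooled data are tie-free; otherwise a normal approximation with tie
#' correction and 0.5 continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest pooled size for the exact path (default 25, so
#'   12-vs-12 designs are exact when tie-free).
#' @return an `ephys_test` with fields `statistic` (U), `p`, `n`, `method`,
#'   `ties`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 25) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); nn <- n1 + n2
  r <- rank(c(x, y))
  ties <- anyDuplicated(c(x, y)) > 0
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!ties && nn <= exact_max) {
    cnt <- mw_u_counts(n1, n2)
    tot <- sum(cnt)
    lo <- sum(cnt[seq_len(u + 1)]) / tot          # P(U <= u)
    hi <- sum(cnt[(u + 1):(n1 * n2 + 1)]) / tot   # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tt <- table(c(x, y))
    tie_term <- sum(tt^3 - tt) / (nn * (nn - 1))
    s2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(s2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approx"
  }
  new_test_result("mann-whitney", c(U = u), p, c(n1 = n1, n2 = n2),
                  method, ties)
}

# Signed-rank null counts: distribution of W+ over 0..sum(ranks), as the
# coefficients of prod_k (1 + t^{r_k}).
signrank_counts <- function(ranks) {
  maxw <- sum(ranks)
  cnt <- c(1, rep(0, maxw))
  for (rk in ranks) {
    shifted <- c(rep(0, rk), cnt[seq_len(maxw + 1 - rk)])
    cnt <- cnt + shifted
  }
  cnt
}

#' Wilcoxon signed-rank test (two-sided, paired)
#'
#' Zero differences are dropped (Wilcoxon's original proposal).  The p-value
#' is exact (enumeration of all sign patterns via the signed-rank generating
#' function) when `n <= exact_max` non-zero differences remain and the
#' absolute differences are tie-free; otherwise a normal approximation with
#' tie correction and 0.5 continuity correction.
#'
#' @param x,y paired numeric samples of equal length.
#' @param exact_max largest n for the exact path (default 20).
#' @return an `ephys_test`; `statistic` is `W` (the positive-rank sum).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 20) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("paired samples must have equal length",
                                   call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(new_test_result("wilcoxon-signed-rank", c(W = 0), 1,
                           c(n = 0), "degenerate", FALSE))
  }
  if (n < 2) stop("need at least 2 non-zero differences", call. = FALSE)
  r <- rank(abs(d))
  ties <- anyDuplicated(abs(d)) > 0
  w <- sum(r[d > 0])
  if (!ties && n <= exact_max) {
    cnt <- signrank_counts(seq_len(n))
    tot <- 2^n
    maxw <- n * (n + 1) / 2
    lo <- sum(cnt[seq_len(floor(w) + 1)]) / tot
    hi <- sum(cnt[(floor(w) + 1):(maxw + 1)]) / tot
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tt <- table(abs(d))
    s2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(s2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approx"
  }
  new_test_result("wilcoxon-signed-rank", c(W = w), p, c(n = n),
                  method, ties)
}

#' Friedman rank test for repeated measures
#'
#' Blocks are rows (rats), treatments are columns (weeks).  The statistic is
#' the classic `chi^2_F = 12 / (n k (k+1)) * sum_j R_j^2 - 3 n (k+1)` with
#' average ranks for ties; the p-value comes from the chi-squared
#' approximation with `k - 1` df, or from full within-block permutation
#' enumeration (`method = "exact"`, feasible for `k!^n` up to ~1e6).
#'
#' @param m numeric matrix, `n_blocks x k_treatments`, complete.
#' @param method `"chisq"` (default), `"exact"`, or `"auto"` (exact when
#'   `n * k <= 16`).
#' @return an `ephys_test`; `statistic` is `chisq_F` with `df` alongside.
#' @export
friedman_test <- function(m, method = c("chisq", "exact", "auto")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (anyNA(m)) stop("incomplete block matrix; exclude incomplete blocks",
                     call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 blocks and >= 2 treatments",
                           call. = FALSE)
  rk <- t(apply(m, 1, rank))
  stat_from_ranks <- function(rk) {
    rj <- colSums(rk)
    12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  }
  chi <- stat_from_ranks(rk)
  ties <- any(apply(m, 1, anyDuplicated) > 0)
  if (method == "auto") method <- if (n * k <= 16) "exact" else "chisq"
  if (method == "exact") {
    perms <- all_permutations(k)
    np <- nrow(perms)
    if (np^n > 1e6) stop("exact Friedman infeasible for this size",
                         call. = FALSE)
    # expand all k!^n combinations of within-block orderings, tracking the
    # column rank-sum vector of each combination
    acc <- matrix(0, 1, k)
    for (b in seq_len(n)) {
      rkb <- rk[b, ]
      blk <- matrix(rkb[perms], np, k)
      na <- nrow(acc)
      acc <- acc[rep(seq_len(na), times = np), , drop = FALSE] +
        blk[rep(seq_len(np), each = na), , drop = FALSE]
    }
    stats_all <- 12 / (n * k * (k + 1)) * rowSums(acc^2) - 3 * n * (k + 1)
    p <- mean(stats_all >= chi - 1e-9)
    return(new_test_result("friedman", c(chisq_F = chi), p,
                           c(n_blocks = n, k = k), "exact-permutation",
                           ties, extra = list(df = k - 1)))
  }
  p <- stats::pchisq(chi, df = k - 1, lower.tail = FALSE)
  new_test_result("friedman", c(chisq_F = chi), p,
                  c(n_blocks = n, k = k), "chisq-approx", ties,
                  extra = list(df = k - 1))
}

# All permutations of 1..k as a (k!) x k integer matrix.
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  ns <- nrow(sub)
  out <- matrix(0L, ns * k, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out[(i - 1) * ns + seq_len(ns), ] <-
      cbind(rep(i, ns), matrix(rest[sub], ns, k - 1))
  }
  out
}

#' Holm step-down multiple-testing adjustment
#'
#' Sort ascending, multiply the i-th smallest by `m - i + 1`, enforce the
#' running maximum, cap at 1, return in input order.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out[is.na(p)] <- NA_real_
  out
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of average ranks.  The p-value is a
#' two-sided t approximation (`t = rho * sqrt((n-2)/(1-rho^2))`), or an
#' exact permutation enumeration over all `n!` orderings when
#' `n <= exact_max`.
#'
#' @param x,y equal-length numeric samples, `n >= 3`.
#' @param exact_max largest n for the exact permutation path (default 8).
#' @return an `ephys_cor`: list with `rho`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, exact_max = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("samples must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: zero variance in ranks", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- as.vector(matrix(ryc[perms], nrow(perms), n) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approx"
  }
  structure(list(rho = rho, p = p, n = n, method = method),
            class = "ephys_cor")
}

#' @export
print.ephys_cor <- function(x, ...) {
  cat(sprintf("<spearman> rho = %.4f, p = %.4g (%s), n = %d\n",
              x$rho, x$p, x$method, x$n))
  invisible(x)
}

#' Lilliefors normality test (Monte-Carlo p-value)
#'
#' Kolmogorov-Smirnov distance to a normal with estimated mean and SD; the
#' null distribution of the distance is resampled (`n_mc` standard-normal
#' samples of the same size), which is reproducible at any n given `seed`.
#'
#' @param x numeric sample, `n >= 4`.
#' @param n_mc Monte-Carlo replicates (default 1e4).
#' @param seed RNG seed for the resampling (default 1).
#' @return an `ephys_test`; `statistic` is the KS distance `D`.
#' @export
lilliefors_test <- function(x, n_mc = 1e4, seed = 1) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate input: zero variance",
                              call. = FALSE)
  ks_d <- function(v) {
    z <- sort((v - mean(v)) / stats::sd(v))
    ph <- stats::pnorm(z)
    i <- seq_along(z)
    max(max(i / length(z) - ph), max(ph - (i - 1) / length(z)))
  }
  d <- ks_d(x)
  dstar <- with_seed(seed, vapply(seq_len(n_mc),
                                  function(i) ks_d(stats::rnorm(n)),
                                  numeric(1)))
  p <- (1 + sum(dstar >= d)) / (n_mc + 1)
  new_test_result("lilliefors", c(D = d), p, c(n = n), "monte-carlo",
                  FALSE, extra = list(n_mc = n_mc))
}

#' Levene test of homoscedasticity (classic, mean-centered)
#'
#' One-way ANOVA F on absolute deviations from the group means.
#'
#' @param groups list of numeric samples, each `n >= 2`.
#' @return an `ephys_test`; `statistic` is `F` with dfs alongside.
#' @export
levene_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("each group needs n >= 2", call. = FALSE)
  z <- lapply(groups, function(g) abs(g - mean(g)))
  k <- length(z)
  nn <- sum(sizes)
  zbar <- mean(unlist(z))
  zmeans <- vapply(z, mean, numeric(1))
  ssb <- sum(sizes * (zmeans - zbar)^2)
  ssw <- sum(vapply(z, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw <= 0) stop("degenerate input: zero within-group deviation",
                     call. = FALSE)
  f <- (ssb / (k - 1)) / (ssw / (nn - k))
  p <- stats::pf(f, k - 1, nn - k, lower.tail = FALSE)
  new_test_result("levene", c(F = f), p, sizes, "f-dist", FALSE,
                  extra = list(df1 = k - 1, df2 = nn - k))
}

#' Total duration and episode count of a behavior
#'
#' Sum of `offset - onset` over all episodes of the behavior, plus the
#' episode count.  An absent behavior gives 0 s, 0 episodes.
#'
#' @param episodes data.frame with columns `behavior`, `onset_s`,
#'   `offset_s`.
#' @param behavior behavior label.
#' @return list with `total_s` and `n_episodes`.
#' @export
behavior_duration <- function(episodes, behavior) {
  sel <- episodes$behavior == behavior
  list(total_s = sum(episodes$offset_s[sel] - episodes$onset_s[sel]),
       n_episodes = sum(sel))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
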