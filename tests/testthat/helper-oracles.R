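# Independent brute-force oracles for the exact nonparametric tests.  These
# enumerate the null directly (label assignments, sign patterns, within-block
# permutations, rank permutations) and never share code with the package's
# dynamic-programming implementations.

mw_oracle <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  nn <- length(pool)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(nn, n1), 2, u_of)
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(lo, hi)))
}

wsr_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  list(W = w_obs, p = min(1, 2 * min(lo, hi)))
}

perms_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (sub in perms_of(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(sub, k, after = pos - 1L)
    }
  }
  out
}

friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  stat_of <- function(mm) {
    rk <- t(apply(mm, 1, rank))
    rj <- colSums(rk)
    12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  }
  obs <- stat_of(m)
  pp <- perms_of(k)
  grid <- expand.grid(rep(list(seq_along(pp)), n))
  stats_all <- apply(grid, 1, function(choice) {
    mm <- m
    for (b in seq_len(n)) mm[b, ] <- m[b, pp[[choice[b]]]]
    stat_of(mm)
  })
  mean(stats_all >= obs - 1e-9)
}

spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  pp <- perms_of(length(y))
  rhos <- vapply(pp, function(idx) stats::cor(rx, ry[idx]), numeric(1))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}
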