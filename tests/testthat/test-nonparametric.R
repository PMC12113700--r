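# Exact-null nonparametric tests against hand-computed values, reference
# implementations and (small-n) brute-force oracles; larger-scale oracle
# sweeps live in the acceptance suite.

test_that("Mann-Whitney U matches hand enumeration and handles ties", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  expect_identical(r$method, "exact")

  tie <- mann_whitney_u(c(5, 7, 9), c(5, 7, 9))
  expect_identical(tie$method, "normal-approx")
  expect_true(tie$ties)
  expect_equal(tie$p, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney exact path equals oracle and wilcox.test", {
  set.seed(101)
  for (i in 1:25) {
    x <- sample(100, sample(2:6, 1))
    y <- sample(100 + seq(0.5, 99.5), sample(2:6, 1))
    r <- mann_whitney_u(x, y)
    o <- mw_oracle(x, y)
    expect_equal(unname(r$statistic), o$U)
    expect_equal(r$p, o$p, tolerance = 1e-12)
    expect_equal(r$p, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact and normal-approx p agree within 0.01 at n=12", {
  set.seed(202)
  for (i in 1:30) {
    x <- rnorm(12); y <- rnorm(12)
    pe <- mann_whitney_u(x, y)$p
    pa <- mann_whitney_u(x, y, exact_max = 0)$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("two-sided tests are symmetric in group order", {
  set.seed(7)
  x <- rnorm(10); y <- rnorm(8)
  expect_equal(mann_whitney_u(x, y)$p, mann_whitney_u(y, x)$p)
  a <- rnorm(9); b <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(a, b)$p, wilcoxon_signed_rank(b, a)$p)
})

test_that("Wilcoxon signed-rank matches enumeration and drops zeros", {
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(r$p, 2 / 2^5, tolerance = 1e-12) # all-positive pattern
  expect_identical(r$method, "exact")

  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    r <- wilcoxon_signed_rank(x, y)
    o <- wsr_oracle(x, y)
    expect_equal(unname(r$statistic), o$W)
    expect_equal(r$p, o$p, tolerance = 1e-12)
  }

  expect_warning(rz <- wilcoxon_signed_rank(1:4, 1:4), "all differences")
  expect_equal(rz$p, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("Friedman statistic and p behave as derived", {
  m <- matrix(rep(c(1, 2, 3), each = 4), 4, 3) # identical rankings
  r <- friedman_test(m)
  expect_equal(unname(r$statistic), 8) # n (k - 1)
  expect_equal(r$p, friedman.test(m)$p.value, tolerance = 1e-12)

  same <- matrix(5, 3, 3)
  r0 <- friedman_test(same)
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p, 1)

  set.seed(55)
  for (i in 1:10) {
    mm <- matrix(rnorm(9), 3, 3)
    expect_equal(friedman_test(mm, method = "exact")$p,
                 friedman_oracle(mm), tolerance = 1e-12)
  }
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "incomplete")
})

test_that("Holm step-down matches the hand rule and p.adjust", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  set.seed(66)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, "holm"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("Spearman rho and p match oracles and endpoints", {
  x <- as.numeric(1:10)
  expect_equal(spearman_cor(x, 2 * x + 3, exact_max = 0)$rho, 1)
  expect_equal(spearman_cor(x, rev(x), exact_max = 0)$rho, -1)

  set.seed(77)
  for (i in 1:12) {
    a <- rnorm(6); b <- rnorm(6)
    r <- spearman_cor(a, b) # n <= 8: exact permutation path
    o <- spearman_oracle(a, b)
    expect_equal(r$rho, o$rho, tolerance = 1e-12)
    expect_equal(r$p, o$p, tolerance = 1e-12)
  }
  # ties: rank-then-Pearson oracle at n = 10
  a <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7)
  b <- rnorm(10)
  expect_equal(spearman_cor(a, b)$rho, cor(rank(a), rank(b)),
               tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("Lilliefors test has near-nominal size and real power", {
  set.seed(88)
  rej <- mean(vapply(1:300, function(i) {
    lilliefors_test(rnorm(50), n_mc = 400, seed = i)$p <= 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  pow <- mean(vapply(1:20, function(i) {
    set.seed(1000 + i)
    lilliefors_test(runif(500), n_mc = 500, seed = i)$p < 0.01
  }, logical(1)))
  expect_gte(pow, 0.95)
  expect_error(lilliefors_test(rep(2, 10)), "degenerate")
})

test_that("Levene test has near-nominal size and real power", {
  set.seed(99)
  rej <- mean(replicate(400, levene_test(list(rnorm(20), rnorm(20)))$p <=
                          0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  pow <- mean(replicate(40, levene_test(list(rnorm(50),
                                             rnorm(50) * 10))$p < 0.01))
  expect_gte(pow, 0.95)
  expect_error(levene_test(list(rep(1, 5), rep(2, 5))), "degenerate")
  expect_error(levene_test(list(rnorm(5))), ">= 2 groups")
})

test_that("behavior_duration sums intervals and counts episodes", {
  ep <- data.frame(behavior = c("resting", "grooming", "resting"),
                   onset_s = c(0, 12, 20), offset_s = c(10, 15, 25))
  d <- behavior_duration(ep, "resting")
  expect_equal(d$total_s, 15)
  expect_equal(d$n_episodes, 2)
  expect_equal(behavior_duration(ep[0, ], "resting")$total_s, 0)
  ep2 <- ep; ep2$onset_s <- ep2$onset_s + 100; ep2$offset_s <- ep2$offset_s + 100
  expect_equal(behavior_duration(ep2, "resting")$total_s, 15)
})
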