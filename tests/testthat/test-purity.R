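test_that("neighbourhood purity matches hand enumeration", {
  # perfectly separated clusters: every neighbourhood is same-class
  p <- neighborhood_purity(c(0, 1, 2, 3, 10, 11, 12, 13),
                           rep(c("A", "B"), each = 4), k = 3)
  expect_equal(p, rep(1, 8))

  # interleaved labels: instance 1 (value 0, label A) has neighbours at
  # 1, 2, 3 carrying B, A, B -- one of three matches
  p <- neighborhood_purity(c(0, 1, 2, 3), c("A", "B", "A", "B"), k = 3)
  expect_equal(p[1], 1 / 3)

  # single class: purity 1 everywhere whatever the values
  p <- neighborhood_purity(rnorm(10), rep("A", 10), k = 3)
  expect_equal(p, rep(1, 10))

  expect_error(neighborhood_purity(1:3, c("A", "A", "B"), k = 3),
               "insufficient instances")
})

test_that("discernment uses a strict threshold: purity equal to mu is blur", {
  mask <- discern(c(1, 2 / 3, 1 / 3, 0), mu = 0.66)
  expect_identical(mask, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(discern(c(0.2, 0.9), mu = 0), c(FALSE, FALSE))
  # boundary: exactly mu is blur-discerned
  expect_true(discern(0.5, mu = 0.5))
})

test_that("remi counts blur overlap with the candidate in the denominator", {
  b <- function(idx, n = 6) seq_len(n) %in% idx
  expect_equal(remi(b(c(1, 2)), b(c(1, 2))), 1)
  expect_equal(remi(b(c(1, 2)), b(c(3, 4))), 0)
  expect_equal(remi(b(1:4), b(1:2)), 0.5)
  expect_equal(remi(b(integer(0)), b(1:2)), 0)  # no blur instances -> no penalty
  expect_error(remi(b(1, n = 4), b(1, n = 5)), "length")
})

test_that("t-statistic uses sample variances and degrades gracefully", {
  expect_equal(abs(t_statistic(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))),
               3 / sqrt(2 / 3))
  # equal class means -> 0 regardless of variance
  expect_equal(t_statistic(c(1, 3, 2, 0, 4, 2), rep(c("a", "b"), each = 3)), 0)
  # relabeling negates t, |t| unchanged
  y <- rep(c("a", "b"), each = 3)
  x <- c(5, 6, 7, 1, 2, 9)
  expect_equal(t_statistic(x, y),
               -t_statistic(x, ifelse(y == "a", "b", "a")))
  # zero variance, unequal means -> signed infinity
  expect_identical(t_statistic(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3)),
                   -Inf)
  # zero variance, equal means -> 0
  expect_identical(t_statistic(rep(1, 6), rep(c("a", "b"), each = 3)), 0)
})

test_that("vectorised t-statistics agree with the scalar definition", {
  set.seed(1)
  x <- matrix(rnorm(60), 10, 6)
  y <- rep(c("a", "b"), each = 5)
  tv <- resi:::t_statistics(x, y)
  ts <- vapply(1:6, function(j) t_statistic(x[, j], y), numeric(1))
  expect_equal(tv, ts, ignore_attr = TRUE)
})

test_that("j_remi is |t| minus the mean redundancy, and needs a selected set", {
  expect_equal(j_remi(2, 0.5), 1.5)
  expect_equal(j_remi(3.2, c(0, 0, 0)), 3.2)
  expect_equal(j_remi(3.2, c(1, 1)), 2.2)
  expect_error(j_remi(1, numeric(0)), "empty")
})

test_that("purity is invariant under affine transforms and relabeling", {
  set.seed(11)
  for (trial in 1:20) {
    n <- sample(8:25, 1)
    x <- rnorm(n)
    y <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
    k <- sample(c(1, 3, 5), 1)
    p <- neighborhood_purity(x, y, k)
    # affine transforms (and negation) preserve neighbour distances
    expect_equal(neighborhood_purity(2.5 * x + 1, y, k), p)
    expect_equal(neighborhood_purity(-x, y, k), p)
    # swapping class names preserves purity
    expect_equal(neighborhood_purity(x, ifelse(y == "a", "b", "a"), k), p)
    # purities are multiples of 1/k
    expect_true(all(abs(p * k - round(p * k)) < 1e-12))
  }
})

test_that("production purity and remi match the brute-force oracles", {
  set.seed(99)
  for (trial in 1:40) {
    n <- sample(6:30, 1)
    m <- sample(2:10, 1)
    k <- sample(c(1, 3, 5), 1)
    if (n <= k) n <- k + 2
    mu <- runif(1, 0.05, 0.95)
    x <- matrix(sample(c(rnorm(n * m), round(rnorm(n * m)))[seq_len(n * m)]),
                n, m)  # mix of continuous and tied values
    y <- c("a", "b", sample(c("a", "b"), n - 2, replace = TRUE))
    blur <- matrix(NA, n, m)
    for (j in seq_len(m)) {
      p_prod <- neighborhood_purity(x[, j], y, k)
      expect_identical(p_prod, oracle_purity(x[, j], y, k))
      blur[, j] <- discern(p_prod, mu)
    }
    for (j in seq_len(min(m, 4))) {
      for (l in seq_len(min(m, 4))) {
        expect_identical(remi(blur[, j], blur[, l]),
                         oracle_remi(blur[, j], blur[, l]))
      }
    }
  }
})

test_that("remi is monotone in the overlap and reflexive on blurred features", {
  set.seed(5)
  for (trial in 1:20) {
    n <- 20
    blur_p <- runif(n) < 0.5
    if (!any(blur_p)) blur_p[1] <- TRUE
    expect_equal(remi(blur_p, blur_p), 1)
    blur_q <- runif(n) < 0.3
    base <- remi(blur_p, blur_q)
    grow <- which(blur_p & !blur_q)
    if (length(grow)) {
      blur_q2 <- blur_q
      blur_q2[grow[1]] <- TRUE
      expect_gte(remi(blur_p, blur_q2), base)
    }
  }
})
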