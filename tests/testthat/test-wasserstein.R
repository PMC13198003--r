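test_that("distributions normalize soft and binary domains to unit mass", {
  sp <- spot_set(paste0("s", 1:5), 1:5, rep(0, 5))
  d <- to_distribution(1:4, sp)
  expect_equal(d$weights, c(0.25, 0.25, 0.25, 0.25, 0))
  dom <- structure(list(id = 1L, lifetime = 1, death = Inf,
                        coreness = c(1, 1, 1, 1, 0.5),
                        normalized = c(1, 1, 1, 1, 0), support = 1:5),
                   class = "multiscale_domain")
  expect_equal(to_distribution(dom, sp)$weights,
               c(0.25, 0.25, 0.25, 0.25, 0))
  expect_equal(sum(to_distribution(c(2L, 5L), sp)$weights), 1)
  empty <- dom; empty$normalized <- numeric(5)
  expect_error(to_distribution(empty, sp), "all-zero")
})

test_that("point-mass transport equals Euclidean distance", {
  sp <- spot_set(c("a", "b"), c(0, 3), c(0, 4))
  expect_equal(wasserstein2(to_distribution(1L, sp),
                            to_distribution(2L, sp)), 5)
  expect_equal(wasserstein2(to_distribution(1L, sp),
                            to_distribution(1L, sp)), 0)
})

test_that("two-point uniform vs point mass gives sqrt(1/2)", {
  sp <- spot_set(c("a", "b"), c(0, 1), c(0, 0))
  w <- wasserstein2(to_distribution(c(1L, 2L), sp), to_distribution(1L, sp))
  expect_equal(w, sqrt(0.5), tolerance = 1e-12)
})

test_that("solver agrees with a brute-force LP on random instances", {
  set.seed(70)
  for (rep in 1:25) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    a <- runif(m); a <- a / sum(a)
    b <- runif(n); b <- b / sum(b)
    C <- matrix(runif(m * n), m, n)
    expect_equal(phdms:::transport_simplex_cpp(a, b, C)$cost,
                 lp_transport_cost(a, b, C), tolerance = 1e-10)
  }
})

test_that("uniform equal-size transport matches the optimal assignment", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 10
    xa <- matrix(runif(2 * n), n); xb <- matrix(runif(2 * n), n)
    C <- outer(xa[, 1], xb[, 1], "-")^2 + outer(xa[, 2], xb[, 2], "-")^2
    mine <- phdms:::transport_simplex_cpp(rep(1 / n, n), rep(1 / n, n),
                                          C)$cost
    lsap <- sum(C[cbind(seq_len(n), as.integer(clue::solve_LSAP(C)))]) / n
    expect_equal(mine, lsap, tolerance = 1e-10)
  }
})

test_that("wasserstein2 behaves as a metric and is translation invariant", {
  set.seed(72)
  n <- 40
  sp <- spot_set(paste0("s", 1:n), runif(n, 0, 10), runif(n, 0, 10))
  mk <- function() {
    supp <- sample(n, sample(3:12, 1))
    to_distribution(supp, sp)
  }
  for (rep in 1:20) {
    d1 <- mk(); d2 <- mk(); d3 <- mk()
    w12 <- wasserstein2(d1, d2)
    w21 <- wasserstein2(d2, d1)
    w13 <- wasserstein2(d1, d3)
    w23 <- wasserstein2(d2, d3)
    expect_equal(w12, w21, tolerance = 1e-8)
    expect_gte(w13 + w23 - w12, -1e-8)
  }
  # shifting the frame shifts nothing
  sp2 <- spot_set(sp$spot_id, sp$x + 100, sp$y - 50)
  s1 <- sample(n, 5); s2 <- sample(n, 7)
  expect_equal(
    wasserstein2(to_distribution(s1, sp), to_distribution(s2, sp)),
    wasserstein2(to_distribution(s1, sp2), to_distribution(s2, sp2)),
    tolerance = 1e-8)
})

test_that("mismatched coordinate frames are rejected", {
  spA <- spot_set(c("a", "b"), c(0, 1), c(0, 0))
  spB <- spot_set(c("a", "b"), c(0, 2), c(0, 0))
  expect_error(wasserstein2(to_distribution(1L, spA),
                            to_distribution(1L, spB)), "coordinate frame")
})

test_that("oversized supports are subsampled reproducibly", {
  set.seed(73)
  n <- 400
  sp <- spot_set(paste0("s", 1:n), runif(n, 0, 50), runif(n, 0, 50))
  d1 <- to_distribution(1:300, sp)
  d2 <- to_distribution(101:400, sp)
  exact <- wasserstein2(d1, d2)
  set.seed(9); sub1 <- wasserstein2(d1, d2, max_support = 150)
  set.seed(9); sub2 <- wasserstein2(d1, d2, max_support = 150)
  expect_equal(sub1, sub2)
  expect_lt(abs(sub1 - exact), 10)  # rough agreement on a 50-unit frame
})
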