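test_that("state enumeration produces each composition exactly once", {
  s0 <- enumerate_states(0)
  expect_equal(nrow(s0), 1L)
  expect_true(all(s0 == 0))
  expect_equal(nrow(enumerate_states(15, c("fiber", "single_wrap", "extended"))),
               choose(17, 2))
  s2 <- enumerate_states(2, c("fiber", "single_wrap"))
  expect_equal(nrow(s2), 3L)
  expect_setequal(apply(s2, 1, paste, collapse = ","), c("2,0", "1,1", "0,2"))
  s <- enumerate_states(5, c("fiber", "single_wrap", "extended"))
  expect_true(all(rowSums(s) == 5))
  expect_equal(anyDuplicated(s), 0L)
})

test_that("pairwise-binomial degeneracy matches examples and modes", {
  lab4 <- c("fiber", "single_wrap", "extended", "unwrapped")
  for (n in c(1, 4, 9)) for (mode in c("degenerate", "non_degenerate_first"))
    expect_equal(degeneracy(setNames(c(n, 0, 0, 0), lab4), mode), 1)
  expect_equal(degeneracy(setNames(c(1, 1, 0, 0), lab4)), 2)
  expect_equal(degeneracy(setNames(c(2, 2, 0, 0), lab4)), 6)
  expect_equal(degeneracy(setNames(c(2, 2, 0, 0), lab4), "fully_non_degenerate"), 1)
  expect_equal(degeneracy(setNames(c(2, 2, 0, 0), lab4), "non_degenerate_first"), 1)
  # with only the (single_wrap, extended) pair occupied the first-transition
  # mode keeps the degeneracy
  expect_equal(degeneracy(setNames(c(0, 2, 2, 0), lab4), "non_degenerate_first"), 6)
  # pairwise product over-counts orderings once three conformations mix
  expect_equal(degeneracy(setNames(c(1, 1, 1, 0), lab4)), 8)
  expect_equal(degeneracy(setNames(c(1, 1, 1, 0), lab4), "multinomial"), 6)
})

test_that("two-conformation degeneracy equals a brute-force ordering count", {
  # enumerate every arrangement of n A/B particles along the array and count
  # those with the requested composition
  for (n in 2:8) {
    arr <- as.matrix(expand.grid(rep(list(0:1), n)))
    for (n1 in 0:n) {
      orderings <- sum(rowSums(arr) == n1)
      expect_equal(degeneracy(setNames(c(n - n1, n1, 0, 0),
                                       c("fiber", "single_wrap", "extended",
                                         "unwrapped"))),
                   orderings)
    }
  }
})

test_that("mean extension equals the literal brute-force state sum", {
  set.seed(101)
  f <- c(0.5, 1.7, 3.4, 5, 8)
  for (rep in 1:20) {
    m <- fiber_197(n_fiber = sample(0:6, 1),
                   n_unfolded = sample(0:3, 1),
                   k = runif(1, 0.1, 1),
                   z0 = runif(1, 0, 3),
                   z_ext = runif(1, 0, 8),
                   dG1 = runif(1, 2, 30),
                   dG2 = runif(1, 0.5, 10))
    if (m$n_fiber == 0) {
      expect_equal(mean_extension(f, m),
                   wlc_extension(f, m$handle_contour * m$mech$rise_per_bp) +
                     m$n_unfolded * (conformation_extension(f, "extended", m)),
                   tolerance = 1e-12)
    } else {
      expect_equal(mean_extension(f, m), brute_mean_extension(f, m),
                   tolerance = 1e-9)
    }
  }
})

test_that("single-state and bare-DNA limits are exact", {
  f <- c(0.5, 2, 6)
  m0 <- fiber_197(n_fiber = 0)
  expect_equal(mean_extension(f, m0),
               wlc_extension(f, 2000 * 0.34), tolerance = 1e-12)
  # an astronomically costly first transition pins everything in the fiber
  m <- fiber_197(n_fiber = 10, n_unfolded = 2, dG1 = 1e6)
  expected <- 10 * fiber_extension(f, m$k, m$z0) +
    wlc_extension(f, 2000 * 0.34) +
    2 * conformation_extension(f, "extended", m)
  expect_equal(mean_extension(f, m), expected, tolerance = 1e-10)
})

test_that("occupancies are normalised and hand off monotonically with force", {
  f <- seq(0.5, 12, by = 0.1)
  set.seed(7)
  for (rep in 1:5) {
    m <- fiber_197(n_fiber = sample(3:15, 1), dG1 = runif(1, 5, 30),
                   dG2 = runif(1, 0.5, 8))
    P <- occupancies(f, m)
    expect_equal(rowSums(P), rep(1, length(f)), tolerance = 1e-12)
    expect_true(all(diff(P[, "fiber"]) <= 1e-9))
    # the pairwise-binomial degeneracy over-counts mixed three-conformation
    # states, which can dent the extended occupancy by O(1e-3); the exact
    # ordering count is monotone
    expect_true(all(diff(P[, "extended"]) >= -0.01))
    m$degeneracy_mode <- "multinomial"
    Pm <- occupancies(f, m)
    expect_true(all(diff(Pm[, "extended"]) >= -1e-5))
  }
  # at low force the fiber conformation dominates; at 7 pN the extended one
  m <- fiber_197(n_fiber = 12, dG1 = 19, dG2 = 4.4, k = 0.22)
  expect_gt(occupancies(0.5, m)[, "fiber"], 0.99)
  P7 <- occupancies(7, fiber_197())
  expect_equal(colnames(P7)[which.max(P7)], "extended")
})

test_that("raising dG2 shifts weight from extended back to single wrap", {
  f <- c(3, 4.5, 6)
  m <- fiber_197()
  m2 <- fiber_197(dG2 = m$dG2 + 2)
  P <- occupancies(f, m); P2 <- occupancies(f, m2)
  expect_true(all(P2[, "extended"] < P[, "extended"]))
  # the displaced weight lands on the earlier pathway states; in the
  # hand-off region it goes to the single wrap
  expect_true(all(P2[, "single_wrap"] + P2[, "fiber"] >
                    P[, "single_wrap"] + P[, "fiber"]))
  expect_true(all(P2[f >= 4, "single_wrap"] > P[f >= 4, "single_wrap"]))
})

test_that("fractional composition interpolates the integer state sums", {
  f <- seq(0.5, 7, by = 0.5)
  m <- fiber_197(n_fiber = 12)
  expect_equal(mean_extension_fractional(f, m), mean_extension(f, m))
  m12 <- fiber_197(n_fiber = 12); m13 <- fiber_197(n_fiber = 13)
  mhalf <- fiber_197(n_fiber = 12.5)
  expect_equal(mean_extension_fractional(f, mhalf),
               0.5 * (mean_extension(f, m12) + mean_extension(f, m13)),
               tolerance = 1e-12)
  # below the plateau each added nucleosome only lengthens the tether
  z <- sapply(seq(10, 14, by = 0.5), function(n)
    mean_extension_fractional(2, fiber_197(n_fiber = n)))
  expect_true(all(diff(z) > 0))
})

test_that("mean extension increases strictly with force", {
  f <- seq(0.5, 30, by = 0.25)
  set.seed(13)
  for (rep in 1:5) {
    m <- fiber_197(n_fiber = sample(1:10, 1), dG1 = runif(1, 3, 30),
                   dG2 = runif(1, 0.5, 8), k = runif(1, 0.1, 2))
    expect_true(all(diff(mean_extension(f, m)) > 0))
  }
})
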