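# deterministic staircase fixture: n steps of given size on a flat baseline
make_staircase <- function(n_steps, step_nm = 25, plateau = 60, sigma = 0,
                           seed = 1) {
  z <- rep(seq(0, by = step_nm, length.out = n_steps + 1), each = plateau)
  set.seed(seed)
  fiber_trace(force = seq(9, 25, length.out = length(z)),
              extension = 1000 + z + rnorm(length(z), 0, sigma))
}

test_that("t-test step finder detects staircases and ignores flat noise", {
  set.seed(5)
  flat <- fiber_trace(force = rep(5, 800), extension = rnorm(800, 0, 3))
  expect_equal(nrow(find_steps(flat)), 0L)
  # 17 steps of 25 nm at sigma = 3 nm are all resolved
  tr <- make_staircase(17, 25, sigma = 3, seed = 2)
  st <- find_steps(tr)
  expect_equal(nrow(st), 17L)
  expect_equal(mean(st$step_nm), 25, tolerance = 0.1)
  expect_true(all(diff(st$index) >= 10))
  expect_true(all(st$t_stat > 0))
  expect_error(find_steps(flat[1:15, ]), "too short")
})

test_that("detected step sizes conserve the total extension gain", {
  tr <- make_staircase(8, 25, sigma = 0)
  st <- find_steps(tr)
  expect_equal(nrow(st), 8L)
  expect_equal(sum(st$step_nm), 8 * 25, tolerance = 1e-9)
  # step positions exact on noiseless input
  expect_equal(st$index, seq(61, by = 60, length.out = 8))
})

test_that("step finder false-positive rate on pure noise is under 1% of samples", {
  set.seed(99)
  n_false <- sum(replicate(30, {
    tr <- fiber_trace(force = rep(5, 1000), extension = rnorm(1000, 0, 4))
    nrow(find_steps(tr))
  }))
  expect_lt(n_false / (30 * 1000), 0.01)
})

test_that("offset alignment recovers an injected attachment offset", {
  mech <- mechanics_params()
  f <- seq(10, 25, length.out = 400)
  set.seed(3)
  bare <- fiber_trace(force = f,
                      extension = wlc_extension(f, 3000 * 0.34, mech) +
                        rnorm(400, 0, 3) + 150)
  aligned <- align_offset(bare, 3000, mech)
  expect_equal(attr(aligned, "offset"), 150, tolerance = 1)
  # idempotent: a second pass finds essentially no offset
  again <- align_offset(aligned, 3000, mech)
  expect_lt(abs(attr(again, "offset")), 0.5)
})

test_that("offset alignment uses only the post-last-rupture segment", {
  m <- fiber_197()
  proto <- stair_protocol(seed = 11, f_max = 25)
  proto$forces <- force_ramp(9, 27, 60, 60)
  tr <- generate_rupture_staircase(m, proto)
  tr$extension_nm <- tr$extension_nm + 80
  total_bp <- m$handle_contour + (m$n_fiber + m$n_unfolded) * m$nrl
  aligned <- align_offset(tr, total_bp)
  expect_equal(attr(aligned, "offset"), 80, tolerance = 2)
  short <- fiber_trace(force = rep(5, 12), extension = rnorm(12))
  expect_error(align_offset(short, 3000), "too short|cannot align")
})

test_that("linear drift is recovered from a pull/reference pair", {
  m <- fiber_197()
  p0 <- eq_protocol(seed = 31, noise_sigma = 2)
  ref <- generate_equilibrium_segment(m, p0)
  pd <- eq_protocol(seed = 32, noise_sigma = 2)
  pd$drift_rate <- 0.5
  drifted <- generate_equilibrium_segment(m, pd)
  fixed <- correct_drift(drifted, ref)
  expect_equal(attr(fixed, "drift_rate"), 0.5, tolerance = 0.05)
  clean <- generate_equilibrium_segment(m, eq_protocol(seed = 33, noise_sigma = 2))
  expect_lt(abs(attr(correct_drift(clean, ref), "drift_rate")), 0.05)
  no_time <- fiber_trace(force = 1:10, extension = 1:10)
  expect_error(correct_drift(no_time, ref), "time")
})

test_that("state assignment recovers the generating rupture sequence", {
  m <- fiber_197(n_fiber = 10)
  p <- stair_protocol(seed = 8, noise_sigma = 0, f_min = 9)
  tr <- generate_rupture_staircase(m, p)
  truth <- sapply(tr$force_pN, function(fi)
    sum(attr(tr, "rupture_forces") <= fi))
  asg <- assign_states(tr, m)
  # noiseless: exact recovery away from the filter edges at each jump
  expect_gt(mean(asg$n_unwrapped == truth), 0.999)
  p4 <- stair_protocol(seed = 8, noise_sigma = 4, f_min = 9)
  tr4 <- generate_rupture_staircase(m, p4)
  truth4 <- sapply(tr4$force_pN, function(fi)
    sum(attr(tr4, "rupture_forces") <= fi))
  expect_gt(mean(assign_states(tr4, m)$n_unwrapped == truth4), 0.95)
})

test_that("assignment is invariant under a common offset of data and ladder", {
  m <- fiber_197(n_fiber = 6)
  tr <- generate_rupture_staircase(m, stair_protocol(seed = 12, f_min = 9))
  base <- assign_states(tr, m)$n_unwrapped
  ladder <- chromfiber:::.state_ladder(tr$force_pN, m)
  for (const in c(-120, 75)) {
    shifted <- abs((ladder + const) - (tr$extension_nm + const))
    lab <- max.col(-shifted, ties.method = "first") - 1L
    expect_equal(lab, base)
  }
})

test_that("ladder spacing and median filter behave as specified", {
  m <- fiber_197()
  ladder <- chromfiber:::.state_ladder(15, m)
  # adjacent rungs at 15 pN are one 89-bp WLC release minus z_ext apart
  spacing <- diff(as.numeric(ladder))
  expect_lt(max(abs(spacing - (wlc_extension(15, 89 * 0.34) - 4.6))), 1e-9)
  expect_equal(spacing[1], 24.9, tolerance = 0.05)
  # median filter shifts noiseless step edges by at most window/2 samples
  x <- rep(c(0, 25), each = 40)
  xf <- chromfiber:::.rolling_median(x, 10)
  expect_lte(abs(which(xf > 12.5)[1] - which(x > 12.5)[1]), 5)
})

test_that("z_ext calibration recovers the ladder offset", {
  m <- fiber_197(n_fiber = 8)
  trs <- lapply(1:3, function(s)
    generate_rupture_staircase(m, stair_protocol(seed = 600 + s, f_min = 9)))
  ze <- calibrate_z_ext(trs, m, candidates = seq(0, 10, by = 0.1))
  expect_equal(as.numeric(ze), 4.6, tolerance = 0.3)
})
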