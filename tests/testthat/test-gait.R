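ref_gait <- gait_params(1, 1.5, 2, 2.4, tau = 1, T = 0.5, L = 20)

test_that("the cubic amplitude interpolates its nodes and matches a Vandermonde solve", {
  g <- gait_params(1, 2, 2, 1, tau = 1, T = 1, L = 3)
  s_nodes <- c(0, 1, 2, 3)
  # node reproduction (t chosen at the phase peak of each station)
  a <- swimchain:::gait_amplitude_coefficients(g)
  amp <- function(s) a[1] + s * (a[2] + s * (a[3] + s * a[4]))
  expect_equal(amp(s_nodes) * g$L, c(1, 2, 2, 1), tolerance = 1e-12)
  # independent Vandermonde solve at s = L/6
  V <- outer(s_nodes, 0:3, "^")
  cf <- solve(V, c(1, 2, 2, 1))
  s6 <- 0.5
  expect_equal(amp(s6) * g$L, sum(cf * s6^(0:3)), tolerance = 1e-12)
  # zero gait: zero curvature everywhere
  g0 <- gait_params(0, 0, 0, 0, tau = 1, T = 1, L = 3)
  expect_equal(curvature_profile(g0, seq(0, 3, 0.1), 0.37), rep(0, 31))
  expect_error(curvature_profile(g, 3.5, 0), "arclength")
})

test_that("unit-speed curves have unit tangent speed and exact arclength", {
  # constant curvature reconstructs a circular arc
  R <- 5
  g <- gait_params(3 / R, 3 / R, 3 / R, 3 / R, tau = 1, T = 1, L = 3)
  # freeze the phase at its peak: kappa(s) = (K/L) at 2*pi*t/T = pi/2, tau=0
  g$tau <- 0
  cur <- unit_speed_curve(g, t = 0.25, n_points = 801)
  expect_equal(cur$theta, cur$s / R, tolerance = 1e-6)
  expect_equal(cur$x[801], R * sin(3 / R), tolerance = 1e-5)
  expect_equal(cur$y[801], R * (1 - cos(3 / R)), tolerance = 1e-5)
  # arclength and unit speed for a generic gait
  cur2 <- unit_speed_curve(ref_gait, 0.13, n_points = 1001)
  seg <- sqrt(diff(cur2$x)^2 + diff(cur2$y)^2)
  expect_equal(sum(seg), ref_gait$L, tolerance = 1e-4)
  expect_equal(max(seg) / (ref_gait$L / 1000), 1, tolerance = 1e-3)
  # zero curvature: a straight segment of length L
  g0 <- gait_params(0, 0, 0, 0, tau = 1, T = 1, L = 3)
  cur0 <- unit_speed_curve(g0, 0.4, n_points = 33)
  expect_equal(cur0$x, cur0$s)
  expect_equal(cur0$y, rep(0, 33))
  expect_error(unit_speed_curve(g0, 0, n_points = 8), ">= 16")
})

test_that("the objective vanishes for degenerate kinematics and respects symmetries", {
  g0 <- gait_params(0, 0, 0, 0, tau = 1, T = 1, L = 3)
  expect_equal(objective_J(g0, 61, 32), 0)
  # standing wave (tau = 0): v and theta in quadrature everywhere
  gs <- gait_params(1, 1, 1, 1, tau = 0, T = 1, L = 3)
  expect_lt(abs(objective_J(gs, 61, 32)), 1e-10)
  # time-translation invariance
  J1 <- objective_J(ref_gait, 61, 32)
  J2 <- objective_J(ref_gait, 61, 32, t0 = 0.177)
  expect_equal(J1, J2, tolerance = 1e-10)
  # wave-direction reversal flips the sign
  flip <- ref_gait; flip$tau <- -ref_gait$tau
  expect_equal(objective_J(flip, 61, 32), -J1, tolerance = 1e-8)
  # quadrature refinement: doubling resolution changes J by < 1%
  Jc <- objective_J(ref_gait, 61, 32)
  Jf <- objective_J(ref_gait, 121, 64)
  expect_lt(abs(Jf - Jc) / abs(Jf), 0.01)
})

test_that("the optimizer ascends, improves on the reference, and certifies against a grid", {
  opt <- optimize_gait(ref_gait, n_s = 61, n_t = 32)
  expect_gt(opt$J, opt$J_initial)
  # the returned optimum dominates every evaluated iterate
  expect_gte(opt$J, max(opt$trace$J) - 1e-6 * abs(opt$J))
  # coarse 5-points-per-axis grid certificate
  lower <- c(0, 0, 0, 0, 0.8); upper <- c(2.5, 2.5, 2.5, 2.5, 2)
  grids <- lapply(1:5, function(i) seq(lower[i], upper[i], length.out = 5))
  best <- -Inf
  for (K1 in grids[[1]]) for (K2 in grids[[2]]) for (K3 in grids[[3]])
    for (K4 in grids[[4]]) for (tau in grids[[5]]) {
      J <- objective_J(gait_params(K1, K2, K3, K4, tau, T = 0.5, L = 20),
                       n_s = 31, n_t = 16)
      if (J > best) best <- J
    }
  J_opt_coarse <- objective_J(opt$gait, n_s = 31, n_t = 16)
  expect_gte(J_opt_coarse, 0.99 * best)
  # a stationary interior point of a quadratic surrogate is returned as-is:
  # starting the optimizer at its own optimum does not move it
  opt2 <- optimize_gait(opt$gait, n_s = 61, n_t = 32)
  expect_equal(opt2$J, opt$J, tolerance = 1e-6)
})
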