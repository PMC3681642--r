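test_that("a straight resting chain is an equilibrium of every model", {
  case <- small_case(N = 6)
  st <- build_chain(case$params)
  none <- activation_spec("none")
  d1 <- rhs_nonlinear(st, 0, case$params, case$drag, none)
  d2 <- rhs_leading_order(st, 0, case$params, case$drag, none)
  d3 <- constrained_oracle_rhs(st, 0, case$params, case$drag, none)
  for (d in list(d1, d2, d3))
    expect_lt(max(abs(unlist(d))), 1e-6)
})

test_that("axial drag decay matches the closed-form exponential", {
  # straight chain translating axially: u decouples and decays as
  # exp(-CT ell t / m) per link under linear drag
  case <- small_case(N = 4)
  st <- build_chain(case$params)
  st$vx <- rep(2, 4)
  traj <- integrate_chain("leading_order", case$params, case$drag,
                          activation_spec("none"), 0.05, state0 = st,
                          dt_out = 1e-3, rtol = 1e-8, atol = 1e-10)
  ck <- com_kinematics(traj)
  lam <- case$drag$CT * case$params$ell / case$params$m
  expect_equal(ck$vx_com, 2 * exp(-lam * ck$t), tolerance = 1e-5)
  # a zero right-hand side leaves the state constant
  traj0 <- integrate_chain("leading_order", case$params, case$drag,
                           activation_spec("none"), 0.02, dt_out = 1e-3)
  expect_equal(max(abs(traj0$state[nrow(traj0$state), ] -
                         traj0$state[1, ])), 0, tolerance = 1e-9)
})

test_that("axial dynamics decouple one-way from transverse/rotational dynamics", {
  case <- small_case(N = 6)
  st <- build_chain(case$params, stats::runif(6, -0.05, 0.05))
  st$vy <- stats::rnorm(6, sd = 0.1); st$omega <- stats::rnorm(6, sd = 0.1)
  d0 <- rhs_leading_order(st, 0.01, case$params, case$drag, case$act)
  st$vx <- st$vx + 0.5   # perturb axial velocity only
  d1 <- rhs_leading_order(st, 0.01, case$params, case$drag, case$act)
  expect_equal(d1$dvy, d0$dvy)
  expect_equal(d1$domega, d0$domega)
  expect_false(isTRUE(all.equal(d1$dvx, d0$dvx)))
})

test_that("steady-velocity estimator obeys quadrature and isotropy nulls", {
  case <- small_case(N = 4)
  p <- case$params
  # synthetic trajectory with v and theta in exact quadrature
  tt <- seq(0, 1, by = 1 / 256)
  st0 <- build_chain(p)
  rows <- t(vapply(tt, function(t) {
    st0$theta <- rep(0.1 * cos(2 * pi * t), 4)
    st0$vy <- rep(0.3 * sin(2 * pi * t), 4)
    state_to_vec_t(st0)
  }, numeric(24)))
  traj <- list(time = tt, state = rows, N = 4, params = p)
  class(traj) <- "swim_trajectory"
  est <- steady_velocity_estimate(traj, case$drag, 0, 1)
  expect_lt(abs(est$U), 1e-10)
  # isotropic drag nulls the estimate for any kinematics
  iso <- drag_spec("lighthill", CN = 0.3, CT = 0.3)
  st0$theta <- rep(0.1, 4); st0$vy <- rep(0.3, 4)
  rows2 <- t(vapply(tt, function(t) state_to_vec_t(st0), numeric(24)))
  traj2 <- traj; traj2$state <- rows2
  est2 <- steady_velocity_estimate(traj2, iso, 0, 1)
  expect_identical(est2$U, 0)
  expect_identical(est2$anisotropy, 1)
  expect_error(steady_velocity_estimate(traj, case$drag, 0.9, 1), "window")
})

test_that("steady-state detection finds a constructed plateau", {
  p <- small_case(N = 4)$params
  tt <- seq(0, 10, by = 0.01)
  u <- 1 - exp(-tt / 1.5)      # transient then plateau
  st0 <- build_chain(p)
  rows <- t(vapply(seq_along(tt), function(i) {
    st0$vx <- rep(u[i], 4); state_to_vec_t(st0)
  }, numeric(24)))
  traj <- list(time = tt, state = rows, N = 4, params = p)
  class(traj) <- "swim_trajectory"
  det <- detect_steady_state(traj, period = 1, tol = 0.01)
  expect_true(det$steady)
  expect_lte(det$start, 8)
  expect_gte(det$start, 4)
  # constant series: steady from the first period boundary
  rows_c <- t(vapply(seq_along(tt), function(i) {
    st0$vx <- rep(1, 4); state_to_vec_t(st0)
  }, numeric(24)))
  traj_c <- traj; traj_c$state <- rows_c
  expect_equal(detect_steady_state(traj_c, period = 1)$start, 1)
  # a diverging series is reported as not steady, without an error
  rows_d <- t(vapply(seq_along(tt), function(i) {
    st0$vx <- rep(2^tt[i], 4); state_to_vec_t(st0)
  }, numeric(24)))
  traj_d <- traj; traj_d$state <- rows_d
  expect_false(detect_steady_state(traj_d, period = 1, tol = 1e-4)$steady)
})

test_that("penalty trajectories converge to the constrained oracle as k grows", {
  params0 <- physical_params(L = 1, N = 3, r = 0.05, E = 0.7e6)
  drag <- drag_spec("lighthill", params0, wavelength = 1)
  act <- activation_spec("traveling_wave", B = 0.08, f = 20, wavelength = 1)
  orc <- integrate_chain("oracle", params0, drag, act, 0.1, dt_out = 1e-3,
                         state0 = build_chain(params0))
  errs <- vapply(c(3e2, 3e3, 3e4), function(k) {
    p <- params0; p$k_spring <- k
    pm <- integrate_chain("nonlinear", p, drag, act, 0.1, dt_out = 1e-3,
                          method = "bdf", rtol = 1e-7, atol = 1e-9)
    max(abs(com_kinematics(pm)$vy_com - com_kinematics(orc)$vy_com))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("momentum decays monotonically without forcing", {
  case <- small_case(N = 5)
  st <- build_chain(case$params, stats::runif(5, -0.2, 0.2))
  st$vx <- rep(1.5, 5); st$vy <- rep(-0.8, 5)  # coasting start
  traj <- integrate_chain("nonlinear", case$params, case$drag,
                          activation_spec("none"), 0.2, state0 = st,
                          dt_out = 5e-3, method = "bdf",
                          rtol = 1e-6, atol = 1e-8)
  ck <- com_kinematics(traj)
  pmag <- sqrt(ck$vx_com^2 + ck$vy_com^2)
  expect_true(all(diff(pmag) < 1e-10))
})
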