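p_rod <- physical_params(L = 20, N = 40, r = 1, E = 0.7e6)
drag_demo <- drag_spec("linearized", CN = 10, CT = 5)

test_that("rest is a fixed point of every passive scenario", {
  spec <- external_flow_spec(Vf = 0, lambda_f = 10, f_f = 2)
  r1 <- simulate_rigid_in_flow(spec, p_rod, drag_demo, t_end = 2)
  expect_lt(max(abs(r1$u), abs(r1$v), abs(r1$theta)), 1e-12)
  f0 <- rigid_forcing_spec(F0 = 0, T0 = 0, phi = 0, omega_f = 2 * pi)
  r2 <- simulate_forced_rigid_link(f0, p_rod, drag_demo, t_end = 2)
  expect_lt(max(abs(r2$u), abs(r2$v)), 1e-12)
  # no torque: no angle, hence no thrust
  f1 <- rigid_forcing_spec(F0 = 1000, T0 = 0, phi = 0, omega_f = 2 * pi)
  r3 <- simulate_forced_rigid_link(f1, p_rod, drag_demo, t_end = 6)
  expect_lt(max(abs(r3$theta)), 1e-12)
  expect_lt(abs(r3$U_sim), 1e-8)
})

test_that("analytic forced-link steady state matches the simulation across phases", {
  w <- 2 * pi * 2
  phis <- seq(0, 2 * pi, length.out = 17)[1:16]
  U <- vapply(phis, function(phi) {
    spec <- rigid_forcing_spec(F0 = 1500, T0 = 5e4, phi = phi, omega_f = w)
    ana <- rigid_link_steady_analytic(spec, p_rod, drag_demo)
    num <- simulate_forced_rigid_link(spec, p_rod, drag_demo, t_end = 18)
    c(ana$U, num$U_sim, ana$theta_amp)
  }, numeric(3))
  expect_lt(max(abs(U[3, ])), 0.2)               # leading-order validity
  expect_lt(max(abs(U[1, ] - U[2, ])) / max(abs(U[1, ])), 0.02)
  # the analytic null phase gives zero velocity
  spec0 <- rigid_forcing_spec(F0 = 1500, T0 = 5e4, phi = 0, omega_f = w)
  ana0 <- rigid_link_steady_analytic(spec0, p_rod, drag_demo)
  spec_null <- rigid_forcing_spec(F0 = 1500, T0 = 5e4, phi = ana0$phi_null,
                                  omega_f = w)
  expect_lt(abs(rigid_link_steady_analytic(spec_null, p_rod,
                                           drag_demo)$U), 1e-12)
})

test_that("flow-field averages match quadrature and symmetry expectations", {
  spec <- external_flow_spec(Vf = 3, lambda_f = 7, f_f = 2)
  vf <- external_flow_field(spec)
  # periodicity and zero spatial mean over one wavelength
  expect_equal(vf(1.3, 0.4 + 1 / 2), vf(1.3, 0.4), tolerance = 1e-12)
  xs <- seq(0, 7, length.out = 2001)
  expect_lt(abs(pracma::trapz(xs, vf(xs, 0.21)) / 7), 1e-6)
  # a link spanning exactly one wavelength averages to zero
  lam_avg <- link_averaged_flow(spec, list(xc = 2.2, theta = 0, ell = 7), 0.1)
  expect_lt(abs(lam_avg$vbar), 1e-12)
  # uniform-flow limit reproduces the pointwise value
  spec_u <- external_flow_spec(Vf = 3, lambda_f = 1e9, f_f = 2)
  expect_equal(link_averaged_flow(spec_u, list(xc = 1, theta = 0.2,
                                               ell = 0.5), 0.1)$vbar,
               external_flow_field(spec_u)(1, 0.1), tolerance = 1e-6)
  # generic inclined pose against numerical quadrature along the link
  pose <- list(xc = 1.7, theta = 0.5, ell = 2.3)
  ss <- seq(-pose$ell / 2, pose$ell / 2, length.out = 4001)
  direct <- pracma::trapz(ss, vf(pose$xc + ss * cos(pose$theta), 0.37)) /
    pose$ell
  expect_equal(link_averaged_flow(spec, pose, 0.37)$vbar, direct,
               tolerance = 1e-6)
})

test_that("flow moment matches quadrature and is odd in the flow", {
  spec <- external_flow_spec(Vf = 3, lambda_f = 7, f_f = 2)
  vf <- external_flow_field(spec)
  drag <- drag_demo
  pose <- list(xc = 0.9, theta = 0, ell = 2.5)
  ss <- seq(-pose$ell / 2, pose$ell / 2, length.out = 8001)
  quad <- drag$CN * pracma::trapz(ss, vf(pose$xc + ss, 0.13) * ss)
  expect_equal(flow_moment(spec, pose, 0, 0.13, drag), quad,
               tolerance = 1e-6)
  # uniform flow over a non-rotating link: no gradient, no arm, no moment
  spec_u <- external_flow_spec(Vf = 3, lambda_f = 1e9, f_f = 2)
  expect_lt(abs(flow_moment(spec_u, pose, 0, 0.13, drag)), 1e-6)
  # odd under a flow sign flip (omega = 0)
  spec_m <- external_flow_spec(Vf = -3, lambda_f = 7, f_f = 2)
  expect_equal(flow_moment(spec_m, pose, 0, 0.13, drag),
               -flow_moment(spec, pose, 0, 0.13, drag), tolerance = 1e-10)
})

test_that("rigid link drifts in a traveling flow; reversing the wave reverses the drift", {
  spec <- external_flow_spec(Vf = 10, lambda_f = 200, f_f = 2)
  cr <- drag_demo$CN * 20^3 / 24   # tapered-rod damping; breaks degeneracy
  r <- simulate_rigid_in_flow(spec, p_rod, drag_demo, t_end = 20, c_r = cr)
  expect_gt(abs(r$U_sim), 1e-4)
  expect_lt(abs(r$U_est - r$U_sim) / abs(r$U_sim), 0.01)
  spec_rev <- external_flow_spec(Vf = 10, lambda_f = 200, f_f = 2,
                                 direction = -1)
  r2 <- simulate_rigid_in_flow(spec_rev, p_rod, drag_demo, t_end = 20,
                               c_r = cr)
  expect_equal(r2$U_sim, -r$U_sim, tolerance = 1e-6)
})

test_that("a flexible body swims passively in a short-wavelength flow", {
  spec <- external_flow_spec(Vf = 10, lambda_f = 10, f_f = 2)
  params <- physical_params(L = 20, N = 20, r = 1, E = 0.7e6)
  params$k_spring <- 2e6
  res <- simulate_flexible_in_flow(spec, params, drag_demo, t_end = 12)
  expect_gt(abs(res$U_sim), 1e-7)
  expect_lt(abs(res$U_est - res$U_sim) / abs(res$U_sim), 0.02)
  # no flow, no muscle: the body stays at rest
  spec0 <- external_flow_spec(Vf = 0, lambda_f = 10, f_f = 2)
  res0 <- simulate_flexible_in_flow(spec0, params, drag_demo, t_end = 2)
  ck <- com_kinematics(res0$traj)
  expect_lt(max(abs(ck$vx_com), abs(ck$vy_com)), 1e-10)
})
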