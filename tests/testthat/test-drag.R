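p_lowre <- physical_params(L = 1, N = 40, r = 0.05, E = 0.7e6)

test_that("Taylor drag opposes motion, is odd in velocity, and follows its power law", {
  spec <- drag_spec("taylor", p_lowre, wavespeed = 20)
  expect_equal(unlist(taylor_drag(0, 0, p_lowre, spec)), c(fN = 0, fT = 0))
  a <- taylor_drag(2.3, 0, p_lowre, spec)
  b <- taylor_drag(-2.3, 0, p_lowre, spec)
  expect_equal(a$fN, -b$fN)
  expect_lte(a$fN * 2.3, 0)
  # quadratic power law, against a scalar transcription of the force law
  f1 <- taylor_drag(1.7, 0.9, p_lowre, spec)
  expect_equal(f1$fN, -0.5 * p_lowre$rho * 2 * p_lowre$r * spec$Cf *
                 abs(1.7) * 1.7)
  expect_equal(f1$fT, -0.5 * p_lowre$rho * 2 * p_lowre$r * spec$Ct_taylor *
                 abs(0.9) * 0.9)
  f2 <- taylor_drag(3.4, 0, p_lowre, spec)
  expect_equal(f2$fN / f1$fN * (abs(1.7) * 1.7), abs(3.4) * 3.4)
  expect_error(taylor_drag(NaN, 0, p_lowre, spec), "non-finite")
})

test_that("slender-body coefficients are anisotropic, scale-invariant, and monotone in r", {
  co <- lighthill_coefficients(p_lowre, wavelength = 1)
  expect_gt(co$CN / co$CT, 1)
  expect_gt(co$CT, 0)
  # joint rescaling of all lengths at fixed aspect ratio leaves them unchanged
  p_big <- physical_params(L = 10, N = 40, r = 0.5, E = 0.7e6)
  co_big <- lighthill_coefficients(p_big, wavelength = 10)
  expect_equal(co_big$CN, co$CN, tolerance = 1e-12)
  expect_equal(co_big$CT, co$CT, tolerance = 1e-12)
  # thicker body at fixed length: weaker logarithms, larger coefficients
  p_thick <- physical_params(L = 1, N = 40, r = 0.08, E = 0.7e6)
  co_thick <- lighthill_coefficients(p_thick, wavelength = 1)
  expect_gt(co_thick$CN, co$CN)
  expect_gt(co_thick$CT, co$CT)
  expect_error(lighthill_coefficients(p_lowre, wavelength = -1), "positive")
})

test_that("linear drag is linear and isotropic drag is antiparallel to velocity", {
  spec <- drag_spec("lighthill", p_lowre, wavelength = 1)
  f <- lighthill_drag(1.2, -0.7, spec)
  f2 <- lighthill_drag(2.4, -1.4, spec)
  expect_equal(unlist(f2), 2 * unlist(f))
  expect_equal(unlist(lighthill_drag(0, 0, spec)), c(fN = 0, fT = 0))
  # isotropic coefficients: force antiparallel to velocity in any frame
  iso <- drag_spec("lighthill", CN = 0.3, CT = 0.3)
  for (th in c(0.3, 1.1, 2.7)) {
    vx <- 1.3; vy <- -0.4
    vT <- vx * cos(th) + vy * sin(th)
    vN <- -vx * sin(th) + vy * cos(th)
    ff <- lighthill_drag(vN, vT, iso)
    Fx <- ff$fT * cos(th) - ff$fN * sin(th)
    Fy <- ff$fT * sin(th) + ff$fN * cos(th)
    expect_equal(c(Fx, Fy), -0.3 * c(vx, vy), tolerance = 1e-12)
  }
})

test_that("linearized drag matches the full resolved drag to second order in theta", {
  spec <- drag_spec("lighthill", p_lowre, wavelength = 1)
  ell <- p_lowre$ell
  u <- 0.3; v <- 2.1
  err <- vapply(c(0.2, 0.1, 0.05), function(th) {
    ld <- linearized_drag(v, u, th, 0, spec, p_lowre)
    vT <- u * cos(th) + v * sin(th)
    vN <- -u * sin(th) + v * cos(th)
    ff <- lighthill_drag(vN, vT, spec)
    Fx_full <- (ff$fT * cos(th) - ff$fN * sin(th)) * ell
    abs(ld$Fx - Fx_full)
  }, numeric(1))
  slope <- coef(stats::lm(log(err) ~ log(c(0.2, 0.1, 0.05))))[2]
  expect_gte(slope, 1.8)
  # aligned motion: pure tangential resistance, no transverse force
  ld0 <- linearized_drag(0, 1.5, 0, 0, spec, p_lowre)
  expect_equal(ld0$Fx, -spec$CT * ell * 1.5)
  expect_equal(ld0$Fy, 0)
  expect_equal(unlist(linearized_drag(0, 0, 0, 0, spec, p_lowre)),
               c(Fx = 0, Fy = 0, Mz = 0))
  # isotropic drag kills the thrust-generating cross term
  iso <- drag_spec("lighthill", CN = 0.3, CT = 0.3)
  ldi <- linearized_drag(2, 0, 0.4, 0, iso, p_lowre)
  expect_equal(ldi$Fx, 0)
})

test_that("all drag variants dissipate energy on a moving link", {
  taylor <- drag_spec("taylor", p_lowre, wavespeed = 20)
  linear <- drag_spec("lighthill", p_lowre, wavelength = 1)
  set.seed(42)
  for (i in 1:20) {
    vN <- stats::rnorm(1, sd = 5); vT <- stats::rnorm(1, sd = 5)
    ft <- taylor_drag(vN, vT, p_lowre, taylor)
    expect_lte(ft$fN * vN + ft$fT * vT, 0)
    fl <- lighthill_drag(vN, vT, linear)
    expect_lte(fl$fN * vN + fl$fT * vT, 0)
    # linearized variant: power of force and moment on the link
    u <- stats::rnorm(1); v <- stats::rnorm(1)
    th <- stats::rnorm(1, sd = 0.1); om <- stats::rnorm(1)
    ld <- linearized_drag(v, u, th, om, linear, p_lowre)
    expect_lte(ld$Fx * u + ld$Fy * v + ld$Mz * om, 1e-10)
  }
})
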