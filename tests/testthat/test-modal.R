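lowre_drag <- function(params) drag_spec("lighthill", params, wavelength = params$L)

test_that("two-link system matches hand-assembled matrices", {
  p <- physical_params(L = 1, N = 2, r = 0.05, E = 0.7e6)
  p$k_spring <- 1e4
  drag <- lowre_drag(p)
  sys <- assemble_mck(p, drag)
  ell <- p$ell; k <- p$k_spring; EI <- p$E * p$Ic
  cj <- 2 * sqrt(k * p$m / 2)
  cr <- drag$CN * ell^3 / 12
  K_hand <- rbind(
    c(k, -k, k * ell / 2, k * ell / 2),
    c(-k, k, -k * ell / 2, -k * ell / 2),
    c(k * ell / 2, -k * ell / 2, k * ell^2 / 4 + EI / ell,
      k * ell^2 / 4 - EI / ell),
    c(k * ell / 2, -k * ell / 2, k * ell^2 / 4 - EI / ell,
      k * ell^2 / 4 + EI / ell))
  expect_equal(sys$K, K_hand)
  C_hand <- rbind(
    c(drag$CN * ell + cj, -cj, cj * ell / 2, cj * ell / 2),
    c(-cj, drag$CN * ell + cj, -cj * ell / 2, -cj * ell / 2),
    c(cj * ell / 2, -cj * ell / 2,
      cr + p$delta / ell + cj * ell^2 / 4,
      cj * ell^2 / 4 - p$delta / ell),
    c(cj * ell / 2, -cj * ell / 2, cj * ell^2 / 4 - p$delta / ell,
      cr + p$delta / ell + cj * ell^2 / 4))
  expect_equal(sys$C, C_hand)
  expect_equal(diag(sys$M), c(p$m, p$m, p$Irot, p$Irot))
})

test_that("stiffness scales with E and k_spring; damping with the drag coefficients", {
  p <- physical_params(L = 1, N = 6, r = 0.05, E = 0.7e6)
  p$k_spring <- 1e4
  drag <- lowre_drag(p)
  sys <- assemble_mck(p, drag)
  p2 <- p; p2$E <- 2 * p$E
  dK_E <- assemble_mck(p2, drag)$K - sys$K   # elastic part, linear in E
  p3 <- p; p3$E <- 3 * p$E
  expect_equal(assemble_mck(p3, drag)$K - sys$K, 2 * dK_E)
  pk2 <- p; pk2$k_spring <- 2e4
  pk3 <- p; pk3$k_spring <- 3e4
  dK_k <- assemble_mck(pk2, drag)$K - sys$K  # penalty part, linear in k
  expect_equal(assemble_mck(pk3, drag)$K - sys$K, 2 * dK_k)
  drag2 <- drag_spec("lighthill", CN = 2 * drag$CN, CT = 2 * drag$CT)
  pz <- p; pz$zeta_joint <- 0; pz$delta <- 0
  Ca <- assemble_mck(pz, drag)$C
  Cb <- assemble_mck(pz, drag2)$C
  expect_equal(Cb, 2 * Ca)
})

test_that("undamped limit reproduces the generalized eigenproblem and the free-free beam", {
  p <- physical_params(L = 1, N = 20, r = 0.05, E = 0.7e6)
  p$k_spring <- 2e6
  drag <- lowre_drag(p)
  sys <- assemble_mck(p, drag)
  # zero damping: purely imaginary eigenvalues at the (K, M) frequencies
  sysu <- sys
  sysu$C <- 0 * sys$C
  sysu$A <- rbind(cbind(matrix(0, 40, 40), diag(40)),
                  cbind(-solve(sys$M, sys$K), matrix(0, 40, 40)))
  ev <- eigen(sysu$A, only.values = TRUE)$values
  expect_lt(max(abs(Re(ev))), 1e-4 * max(abs(ev)))
  wu <- sort(Im(ev[Im(ev) > 1]))
  gen <- sort(Re(eigen(solve(sys$M, sys$K), only.values = TRUE)$values))
  gen <- sqrt(gen[gen > 1])
  expect_equal(wu, gen, tolerance = 1e-6)
  # lowest frequencies approach the continuum free-free beam values
  beam <- (c(4.7300407, 7.8532046) / p$L)^2 *
    sqrt(p$E * p$Ic / (p$rho * pi * p$r^2)) / (2 * pi)
  expect_equal(gen[1:2] / (2 * pi), beam, tolerance = 0.02)
})

test_that("eigenmodes are conjugate-closed, dissipative, and frequency-ordered", {
  p <- physical_params(L = 1, N = 12, r = 0.05, E = 0.7e6)
  p$k_spring <- 1e5
  sys <- assemble_mck(p, lowre_drag(p))
  modes <- eigenmodes(sys)
  lam <- modes$all_values
  expect_lt(max(Re(lam)), 1e-8 * max(abs(lam)))
  # closed under conjugation
  for (z in lam[Im(lam) > 1])
    expect_true(min(abs(lam - Conj(z))) < 1e-6 * max(1, abs(z)))
  fr <- modes$frequency_hz[modes$classification == "underdamped"]
  expect_true(all(diff(fr) >= 0))
  expect_equal(2 * modes$n_underdamped + modes$n_overdamped, 4 * p$N)
})

test_that("every natural frequency grows with Young's modulus", {
  f_of_E <- function(E) {
    p <- physical_params(L = 1, N = 8, r = 0.05, E = E)
    p$k_spring <- 1e5
    m <- eigenmodes(assemble_mck(p, lowre_drag(p)))
    utils::head(m$frequency_hz[m$classification == "underdamped"], 3)
  }
  fs <- vapply(c(0.7e5, 0.7e6, 0.7e7), f_of_E, numeric(3))
  expect_true(all(fs[, 2] > fs[, 1]))
  expect_true(all(fs[, 3] > fs[, 2]))
})

test_that("mode weights recover pure eigenvectors and reconstruct random states", {
  p <- physical_params(L = 1, N = 6, r = 0.05, E = 0.7e6)
  p$k_spring <- 1e4
  sys <- assemble_mck(p, lowre_drag(p))
  modes <- eigenmodes(sys)
  z <- modes$vectors[, 3]
  w <- mode_weights(z, sys, modes)
  mags <- w$magnitude
  expect_equal(which.max(mags), 3)
  expect_lt(sum(mags[-3]) / mags[3], 1e-8)
  set.seed(7)
  zr <- stats::rnorm(4 * p$N)
  wr <- mode_weights(zr, sys, modes)
  expect_lt(wr$reconstruction_error, 1e-8)
})

test_that("slow forcing concentrates the response in the lowest modes", {
  case <- zebrafish_case()
  p <- case$params
  p$k_spring <- 1.3e5
  sys <- assemble_mck(p, case$drag)
  modes <- eigenmodes(sys)
  w <- swimchain:::forced_response_weights(sys, modes, case$act, 20)
  expect_lt(w$residual, 1e-8)
  en <- w$energy
  expect_gt(sum(en[1:5]) / sum(en), 0.9)
})

test_that("beam modes are orthonormal and projections recover a pure mode", {
  s <- seq(0, 1, length.out = 4001)
  phi <- beam_modes(s, 6)
  G <- crossprod(phi * sqrt(c(0.5, rep(1, 3999), 0.5)) /
                   sqrt(4000))       # trapezoid-weighted Gram
  expect_lt(max(abs(G - diag(6))), 1e-5)
  # a midline shaped as beam mode 1 projects onto mode 1 only
  y <- 0.3 * phi[, 1]
  a <- beam_project(s, y, 4)
  expect_equal(a[1], 0.3, tolerance = 1e-4)
  expect_lt(max(abs(a[-1])), 1e-4)
  expect_error(beam_project(s[1:3], y[1:3], 4), "resolution")
})
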