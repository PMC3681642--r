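#' Five-parameter gait-curvature family
#'
#' A traveling wave of midline curvature whose amplitude along the arclength
#' `s` is the unique cubic through four control values:
#' \deqn{\kappa(s, t) = \frac{K(s)}{L}\,\sin\!\big(2\pi(t/T - \tau s/L)\big),}
#' with `K(s)` interpolating `(0, K1)`, `(L/3, K2)`, `(2L/3, K3)`, `(L, K4)`.
#' The `K` values are nondimensional curvature amplitudes (curvature times
#' body length); `tau` is the number of waves on the body (its sign sets the
#' wave direction) and `T` the period.
#'
#' @param K1,K2,K3,K4 curvature amplitudes (kappa * L, dimensionless) at
#'   arclength stations 0, L/3, 2L/3, L
#' @param tau phase/wave parameter (dimensionless)
#' @param T period (s)
#' @param L body length (cm)
#' @return an object of class `gait_params`
#' @export
gait_params <- function(K1, K2, K3, K4, tau, T = 1, L = 1) {
  stopifnot(T > 0, L > 0)
  g <- list(K1 = K1, K2 = K2, K3 = K3, K4 = K4, tau = tau, T = T, L = L)
  class(g) <- "gait_params"
  g
}

# cubic amplitude coefficients a0..a3 of K(s)/L in 1/cm: amp(s) = sum a_k s^k
gait_amplitude_coefficients <- function(gait) {
  L <- gait$L
  s <- c(0, L / 3, 2 * L / 3, L)
  V <- outer(s, 0:3, "^")
  as.vector(solve(V, c(gait$K1, gait$K2, gait$K3, gait$K4) / L))
}

#' Curvature of a gait at arclength and time
#'
#' @param gait a [gait_params()] object
#' @param s arclength (cm), within `[0, L]`
#' @param t time (s)
#' @return curvature (1/cm), vectorized over `s`
#' @export
curvature_profile <- function(gait, s, t) {
  if (any(s < -1e-12 | s > gait$L + 1e-12))
    stop("arclength outside [0, L]", call. = FALSE)
  a <- gait_amplitude_coefficients(gait)
  amp <- a[1] + s * (a[2] + s * (a[3] + s * a[4]))
  amp * sin(2 * pi * (t / gait$T - gait$tau * s / gait$L))
}

#' Unit-speed midline reconstruction
#'
#' Integrates the curvature to the tangent angle and the tangent angle to
#' coordinates, producing a curve parametrized by arclength with unit tangent
#' speed: `theta(s) = int kappa ds`, `(x, y)(s) = int (cos theta, sin theta) ds`.
#'
#' @param gait a [gait_params()] object
#' @param t time (s)
#' @param n_points number of arclength samples (>= 16)
#' @return data.frame with `s`, `x`, `y`, `theta`
#' @export
unit_speed_curve <- function(gait, t, n_points = 201) {
  if (n_points < 16) stop("n_points must be >= 16", call. = FALSE)
  s <- seq(0, gait$L, length.out = n_points)
  kap <- curvature_profile(gait, s, t)
  theta <- as.vector(pracma::cumtrapz(s, kap))
  x <- as.vector(pracma::cumtrapz(s, cos(theta)))
  y <- as.vector(pracma::cumtrapz(s, sin(theta)))
  data.frame(s = s, x = x, y = y, theta = theta)
}

#' Fast-swimming gait objective
#'
#' The body- and period-averaged product of the body-frame lateral midline
#' velocity and the local tangent angle of the prescribed kinematics,
#' sign-adjusted so that larger `J` means faster forward swimming for a
#' head-to-tail wave: `J = -<v theta>`.  Only the prescribed kinematics are
#' needed; no swimming simulation is involved.  For each time the midline is
#' reconstructed as a unit-speed curve, the rigid components (COM position,
#' mean tangent angle) are removed, and `v` is the time derivative of the
#' lateral position at fixed arclength (spectral differentiation over the
#' periodic cycle).
#'
#' @param gait a [gait_params()] object
#' @param n_s arclength quadrature points
#' @param n_t time samples per period
#' @param t0 phase origin (s); the period average makes `J` independent of it
#' @return scalar objective (cm/s rad)
#' @export
objective_J <- function(gait, n_s = 201, n_t = 128, t0 = 0) {
  s <- seq(0, gait$L, length.out = n_s)
  tt <- t0 + seq(0, gait$T, length.out = n_t + 1)[seq_len(n_t)]  # periodic
  Y <- matrix(0, n_t, n_s)
  TH <- matrix(0, n_t, n_s)
  for (i in seq_len(n_t)) {
    cur <- unit_speed_curve(gait, tt[i], n_points = n_s)
    th <- cur$theta - pracma::trapz(s, cur$theta) / gait$L
    # rebuild lateral position in the frame with zero mean tangent angle
    yb <- as.vector(pracma::cumtrapz(s, sin(th)))
    yb <- yb - pracma::trapz(s, yb) / gait$L
    Y[i, ] <- yb
    TH[i, ] <- th
  }
  # time derivative at fixed s over the periodic cycle (spectral)
  n <- n_t
  kvec <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) # fft wavenumbers
  if (n %% 2 == 0) kvec[n %/% 2 + 1] <- 0          # drop Nyquist derivative
  om <- 2i * pi * kvec / gait$T
  V <- Re(stats::mvfft(stats::mvfft(Y) * om, inverse = TRUE) / n)
  prod_bt <- rowMeans(V * TH)  # body average at each time (equal arc weights)
  -mean(prod_bt)
}

#' Optimize a gait for fast swimming
#'
#' Bound-constrained local maximization of [objective_J()] over the five
#' gait parameters, optionally from multiple deterministic starts.  The
#' default bounds keep the midline tangent angles within roughly half a
#' radian — the regime where the kinematic objective is a valid proxy for
#' the swimming speed of the dynamic models.  The iterate trace is
#' recorded; the best feasible point found is always returned (with a
#' convergence flag).
#'
#' @param initial a [gait_params()] starting gait (the reference gait)
#' @param lower,upper named bounds for `K1..K4` and `tau` (length-5 vectors,
#'   order K1, K2, K3, K4, tau)
#' @param n_s,n_t quadrature resolution passed to [objective_J()]
#' @param extra_starts optional list of additional length-5 start vectors
#'   (for example the best point of a coarse grid search)
#' @return list with `gait` (optimized [gait_params()]), `J`, `J_initial`,
#'   `trace` (data.frame of accepted evaluations), `converged`
#' @export
optimize_gait <- function(initial, lower = c(0, 0, 0, 0, 0.8),
                          upper = c(2.5, 2.5, 2.5, 2.5, 2),
                          n_s = 121, n_t = 64, extra_starts = list()) {
  to_gait <- function(p) gait_params(p[1], p[2], p[3], p[4], p[5],
                                     T = initial$T, L = initial$L)
  trace_env <- new.env()
  trace_env$rows <- list()
  fn <- function(p) {
    J <- objective_J(to_gait(p), n_s = n_s, n_t = n_t)
    trace_env$rows[[length(trace_env$rows) + 1]] <- c(p, J = J)
    -J
  }
  p0 <- c(initial$K1, initial$K2, initial$K3, initial$K4, initial$tau)
  starts <- c(list(p0), extra_starts)
  best <- NULL
  converged <- FALSE
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    res <- stats::optim(st, fn, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 200, factr = 1e9))
    if (is.null(best) || res$value < best$value) {
      best <- res
      converged <- res$convergence == 0
    }
  }
  tr <- as.data.frame(do.call(rbind, trace_env$rows))
  names(tr) <- c("K1", "K2", "K3", "K4", "tau", "J")
  J0 <- objective_J(initial, n_s = n_s, n_t = n_t)
  list(gait = to_gait(best$par), J = -best$value, J_initial = J0,
       trace = tr, converged = converged)
}
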