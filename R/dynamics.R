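# Equations of motion, time integration, steady-state machinery.

# Flatten model/drag/activation settings into the parameter list consumed by
# the compiled RHS kernel.
build_cpp_parms <- function(model, params, drag, act, flow = NULL) {
  stopifnot(inherits(params, "phys_params"), inherits(drag, "drag_spec"),
            inherits(act, "activation_spec"))
  if (is.na(params$k_spring))
    stop("k_spring is uncalibrated; run calibrate_k_spring() first",
         call. = FALSE)
  dragv <- match(drag$variant, c("taylor", "lighthill", "linearized")) - 1L
  actv <- match(act$kind, c("none", "traveling_wave", "gait_family",
                            "table")) - 1L
  g <- c(0, 0, 0, 0)
  gtau <- 0; gT <- 1; gL <- params$L
  if (act$kind == "gait_family") {
    g <- gait_amplitude_coefficients(act$gait)
    gtau <- act$gait$tau; gT <- act$gait$T; gL <- act$gait$L
  }
  lam <- if (is.null(act$wavelength)) params$L else act$wavelength
  Tp <- switch(act$kind, table = act$period, gait_family = act$gait$T,
               if (act$f > 0) 1 / act$f else 0)
  rp <- if (is.null(act$ramp_periods)) 0 else act$ramp_periods
  zj <- if (is.null(params$zeta_joint)) 1 else params$zeta_joint
  list(N = params$N, model = as.integer(model), dragv = dragv, act = actv,
       ell = params$ell, m = params$m, I = params$Irot, k = params$k_spring,
       cj = 2 * zj * sqrt(params$k_spring * params$m / 2),
       EI = params$E * params$Ic, delta = params$delta,
       rho = params$rho, r = params$r, Cf = drag$Cf,
       Ct = if (is.null(drag$Ct_taylor)) 0 else drag$Ct_taylor,
       CN = if (is.null(drag$CN)) 0 else drag$CN,
       CT = if (is.null(drag$CT)) 0 else drag$CT,
       B = act$B, lam = lam, f = act$f,
       g0 = g[1], g1 = g[2], g2 = g[3], g3 = g[4],
       gtau = gtau, gT = gT, gL = gL,
       ramp_t = rp * Tp,
       flow_on = !is.null(flow), Vf = if (is.null(flow)) 0 else flow$Vf,
       lamf = if (is.null(flow)) 1 else flow$lambda_f,
       ff = if (is.null(flow)) 0 else flow$f_f,
       flowdir = if (is.null(flow)) 1 else flow$direction,
       has_tab = identical(act$kind, "table"),
       tab = if (identical(act$kind, "table")) act$kappa0_tab else matrix(0),
       tab_period = if (identical(act$kind, "table")) act$period else 1)
}

rhs_named <- function(dy, N) {
  list(dxc = dy[seq_len(N)], dyc = dy[N + seq_len(N)],
       dtheta = dy[2 * N + seq_len(N)], dvx = dy[3 * N + seq_len(N)],
       dvy = dy[4 * N + seq_len(N)], domega = dy[5 * N + seq_len(N)])
}

#' Nonlinear penalty-method equations of motion
#'
#' Per-link Newton-Euler balance: translational equations with resistive drag
#' and penalty joint-spring forces, rotational equation with the joint-force
#' moments and the viscoelastic muscle moment.  End links have free boundary
#' conditions (their missing joint terms are zero).
#'
#' @param state a `chain_state`
#' @param t time (s)
#' @param params a [physical_params()] object with calibrated `k_spring`
#' @param drag a [drag_spec()]
#' @param act an [activation_spec()]
#' @return named list of state derivatives (`dxc`, `dyc`, `dtheta`, `dvx`,
#'   `dvy`, `domega`)
#' @export
rhs_nonlinear <- function(state, t, params, drag, act) {
  p <- build_cpp_parms(0L, params, drag, act)
  rhs_named(chain_rhs_cpp(t, state_to_vec(state), p), params$N)
}

#' Leading-order equations of motion
#'
#' Small-inclination equations: the transverse and rotational equations are
#' linear, coupled to each other and to the muscle forcing, and independent
#' of the axial velocity; the axial equation is driven one-way by the
#' `(CN - CT) v theta` source term.
#'
#' @inheritParams rhs_nonlinear
#' @param flow optional [external_flow_spec()]
#' @return named list of state derivatives
#' @export
rhs_leading_order <- function(state, t, params, drag, act, flow = NULL) {
  p <- build_cpp_parms(1L, params, drag, act, flow)
  rhs_named(chain_rhs_cpp(t, state_to_vec(state), p), params$N)
}

# ---- constraint-elimination oracle -----------------------------------------

# Generalized coordinates q = (X, Y, theta_1..theta_N) where (X, Y) is the
# head endpoint; exact kinematic joints (no penalty springs).  The projected
# Newton-Euler system A(q) qdd = b(q, qd) is assembled with the constant
# influence matrix a[i, j] = ell (j < i), ell/2 (j = i), 0 otherwise.
oracle_geometry <- function(params) {
  N <- params$N
  A <- matrix(0, N, N)
  A[lower.tri(A)] <- params$ell
  diag(A) <- params$ell / 2
  list(A = A, G = crossprod(A), n = colSums(A))
}

oracle_drag <- function(vxl, vyl, th, om, params, drag) {
  ell <- params$ell
  ct <- cos(th); st <- sin(th)
  vT <- vxl * ct + vyl * st
  vN <- -vxl * st + vyl * ct
  if (drag$variant == "taylor") {
    gx <- c(-0.9061798459386640, -0.5384693101056831, 0,
            0.5384693101056831, 0.9061798459386640) * ell / 2
    gw <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
            0.4786286704993665, 0.2369268850561891) * ell / 2
    cN <- params$rho * params$r * drag$Cf       # (1/2) rho (2r) Cf
    cT <- params$rho * params$r * drag$Ct_taylor
    FT <- -cT * abs(vT) * vT * ell
    FN <- numeric(length(th)); MZ <- numeric(length(th))
    for (q in seq_along(gx)) {
      vloc <- vN + om * gx[q]
      fn <- -cN * abs(vloc) * vloc
      FN <- FN + gw[q] * fn
      MZ <- MZ + gw[q] * fn * gx[q]
    }
  } else {
    FT <- -drag$CT * vT * ell
    FN <- -drag$CN * vN * ell
    MZ <- -drag$CN * ell^3 / 12 * om
  }
  list(Fx = FT * ct - FN * st, Fy = FT * st + FN * ct, Mz = MZ)
}

oracle_rhs_vec <- function(t, z, params, drag, act, geom) {
  N <- params$N
  ell <- params$ell
  q <- z[seq_len(N + 2)]
  qd <- z[N + 2 + seq_len(N + 2)]
  th <- q[2 + seq_len(N)]
  thd <- qd[2 + seq_len(N)]
  ct <- cos(th); st <- sin(th)
  # link COM velocities
  vxl <- qd[1] - as.vector(geom$A %*% (st * thd))
  vyl <- qd[2] + as.vector(geom$A %*% (ct * thd))
  dr <- oracle_drag(vxl, vyl, th, thd, params, drag)
  # muscle torque pairs
  kap <- diff(th) / ell
  kdot <- diff(thd) / ell
  k0 <- preferred_curvature(act, params, t)
  M <- params$E * params$Ic * (k0 - kap) - params$delta * kdot
  Me <- c(M, 0)   # joint at right end of link i (0 for link N)
  Mw <- c(0, M)   # joint at left end of link i (0 for link 1)
  tau <- -Me + Mw + dr$Mz
  # generalized forces
  SxF <- as.vector(crossprod(geom$A, dr$Fx))
  SyF <- as.vector(crossprod(geom$A, dr$Fy))
  Qth <- -st * SxF + ct * SyF + tau
  # velocity-product terms
  w2 <- thd^2
  hX <- -params$m * sum(geom$n * ct * w2)
  hY <- -params$m * sum(geom$n * st * w2)
  dth_mat <- outer(th, th, "-")
  hth <- params$m * as.vector((geom$G * sin(dth_mat)) %*% w2)
  # mass matrix
  Mthth <- params$m * geom$G * cos(dth_mat)
  diag(Mthth) <- diag(Mthth) + params$Irot
  mX <- -params$m * geom$n * st
  mY <- params$m * geom$n * ct
  Afull <- rbind(cbind(params$m * N, 0, t(mX)),
                 cbind(0, params$m * N, t(mY)),
                 cbind(mX, mY, Mthth))
  b <- c(sum(dr$Fx) - hX, sum(dr$Fy) - hY, Qth - hth)
  qdd <- solve(Afull, b)
  c(qd, qdd)
}

oracle_pack <- function(state, params) {
  h <- params$ell / 2
  ct <- cos(state$theta); st <- sin(state$theta)
  X <- state$xc[1] - h * ct[1]
  Y <- state$yc[1] - h * st[1]
  Xd <- state$vx[1] + h * st[1] * state$omega[1]
  Yd <- state$vy[1] - h * ct[1] * state$omega[1]
  c(X, Y, state$theta, Xd, Yd, state$omega)
}

oracle_unpack <- function(z, params, t, geom) {
  N <- params$N
  q <- z[seq_len(N + 2)]
  qd <- z[N + 2 + seq_len(N + 2)]
  th <- q[2 + seq_len(N)]
  thd <- qd[2 + seq_len(N)]
  ct <- cos(th); st <- sin(th)
  xc <- q[1] + as.vector(geom$A %*% ct)
  yc <- q[2] + as.vector(geom$A %*% st)
  vx <- qd[1] - as.vector(geom$A %*% (st * thd))
  vy <- qd[2] + as.vector(geom$A %*% (ct * thd))
  stt <- list(xc = xc, yc = yc, theta = th, vx = vx, vy = vy, omega = thd,
              t = t)
  class(stt) <- "chain_state"
  stt
}

#' Constraint-elimination oracle equations of motion
#'
#' Exact kinematic-joint dynamics in generalized coordinates (link angles
#' plus one reference point), with the joint forces eliminated by projecting
#' the Newton-Euler equations onto the constraint manifold.  This is the
#' ground-truth model that the penalty method approximates as
#' `k_spring -> Inf`.
#'
#' @inheritParams rhs_nonlinear
#' @return named list of state derivatives (same layout as [rhs_nonlinear()])
#' @export
constrained_oracle_rhs <- function(state, t, params, drag, act) {
  geom <- oracle_geometry(params)
  z <- oracle_pack(state, params)
  dz <- oracle_rhs_vec(t, z, params, drag, act, geom)
  N <- params$N
  qdd <- dz[N + 2 + seq_len(N + 2)]
  th <- state$theta; thd <- state$omega
  ct <- cos(th); st <- sin(th)
  thdd <- qdd[2 + seq_len(N)]
  dvx <- qdd[1] - as.vector(geom$A %*% (ct * thd^2 + st * thdd))
  dvy <- qdd[2] + as.vector(geom$A %*% (-st * thd^2 + ct * thdd))
  list(dxc = state$vx, dyc = state$vy, dtheta = thd,
       dvx = dvx, dvy = dvy, domega = thdd)
}

# ---- integration -----------------------------------------------------------

#' Integrate the chain-link equations of motion
#'
#' Adaptive explicit Runge-Kutta (Dormand-Prince) integration with the step
#' size bounded by `max_step` (default 1 ms), with a BDF fallback for
#' stiffness-dominated configurations.  Output is reported on a uniform grid.
#'
#' @param model `"nonlinear"` (penalty method), `"leading_order"`, or
#'   `"oracle"` (constraint elimination)
#' @param params a [physical_params()] object; `k_spring` must be calibrated
#'   for the penalty models (the oracle does not use it)
#' @param drag a [drag_spec()]
#' @param act an [activation_spec()]
#' @param t_end end time (s); integration starts at 0
#' @param state0 initial `chain_state` (default: straight rest)
#' @param flow optional [external_flow_spec()] (leading-order model only)
#' @param dt_out output grid spacing (s)
#' @param max_step maximum integrator step (s), default 1 ms
#' @param rtol,atol integrator tolerances
#' @param method `"ode45"` or `"bdf"`
#' @return a `swim_trajectory`: list with `time`, `state` (matrix, one row
#'   per time, columns x/y/theta/vx/vy/omega blocks), `N`, `params`, `drag`,
#'   `act`, `model`, and `diagnostics` (max joint gap over the stored states)
#' @export
integrate_chain <- function(model = c("nonlinear", "leading_order", "oracle"),
                            params, drag, act, t_end,
                            state0 = NULL, flow = NULL,
                            dt_out = NULL, max_step = 1e-3,
                            rtol = 1e-6, atol = 1e-9,
                            method = c("ode45", "bdf")) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (is.null(state0)) state0 <- build_chain(params)
  if (is.null(dt_out)) {
    dt_out <- if (act$f > 0) 1 / (200 * act$f) else t_end / 400
  }
  times <- seq(0, t_end, by = dt_out)
  N <- params$N
  if (model == "oracle") {
    geom <- oracle_geometry(params)
    z0 <- oracle_pack(state0, params)
    fn <- function(t, z, p) list(oracle_rhs_vec(t, z, params, drag, act, geom))
    sol <- deSolve::ode(z0, times, fn, parms = NULL, method = method,
                        hmax = max_step, rtol = rtol, atol = atol)
    if (nrow(sol) < length(times))
      stop(sprintf("integration failed at t = %g s", sol[nrow(sol), 1]),
           call. = FALSE)
    st <- t(apply(sol[, -1, drop = FALSE], 1, function(z) {
      s <- oracle_unpack(z, params, 0, geom)
      state_to_vec(s)
    }))
  } else {
    p <- build_cpp_parms(if (model == "nonlinear") 0L else 1L,
                         params, drag, act, flow)
    fn <- function(t, y, pp) list(chain_rhs_cpp(t, y, pp))
    y0 <- state_to_vec(state0)
    sol <- if (method == "bdf") {
      # A-stable low-order BDF with the analytic Jacobian: the bending-stiff
      # cases have lightly damped high-frequency modes that higher BDF orders
      # cannot step over
      jac <- function(t, y, pp) chain_jac_cpp(t, y, pp)
      deSolve::lsode(y0, times, fn, parms = p, maxord = 2, hmax = max_step,
                     jacfunc = jac, jactype = "fullusr",
                     rtol = rtol, atol = atol, maxsteps = 500000)
    } else {
      deSolve::ode(y0, times, fn, parms = p, method = "ode45",
                   hmax = max_step, rtol = rtol, atol = atol,
                   maxsteps = 500000)
    }
    if (nrow(sol) < length(times))
      stop(sprintf("integration failed at t = %g s", sol[nrow(sol), 1]),
           call. = FALSE)
    st <- unname(sol[, -1, drop = FALSE])
  }
  traj <- list(time = times, state = st, N = N, params = params, drag = drag,
               act = act, model = model, flow = flow,
               meta = list(axes = "x axial, y transverse; backward wave => swims toward -x"))
  class(traj) <- "swim_trajectory"
  traj$diagnostics <- list(max_joint_gap = max_gap_over(traj))
  traj
}

max_gap_over <- function(traj, stride = NULL) {
  nt <- length(traj$time)
  if (is.null(stride)) stride <- max(1L, nt %/% 50L)
  idx <- unique(c(seq(1L, nt, by = stride), nt))
  lin <- identical(traj$model, "leading_order")
  max(vapply(idx,
             function(i) joint_gaps(state_at(traj, i), traj$params, lin),
             numeric(1)))
}

#' @export
print.swim_trajectory <- function(x, ...) {
  cat(sprintf("swim_trajectory: %s model, N = %d, t in [0, %g] s (%d points)\n",
              x$model, x$N, max(x$time), length(x$time)))
  cat(sprintf("  max joint gap: %.3g cm\n", x$diagnostics$max_joint_gap))
  invisible(x)
}

# ---- steady state ----------------------------------------------------------

#' Detect the steady swimming window
#'
#' Finds the earliest period boundary after which consecutive
#' period-averaged COM axial velocities agree to a relative tolerance.
#'
#' @param traj a `swim_trajectory`
#' @param period forcing period (s)
#' @param tol relative tolerance between successive period averages
#' @return list with `steady` (logical), `start` (s; `NA` if never steady)
#' @export
detect_steady_state <- function(traj, period, tol = 0.01) {
  ck <- com_kinematics(traj)
  t_end <- max(ck$t)
  np <- floor(t_end / period)
  if (np < 3) stop("trajectory must span at least 3 periods", call. = FALSE)
  avg <- vapply(seq_len(np), function(j) {
    sel <- ck$t >= (j - 1) * period & ck$t <= j * period
    mean(ck$vx_com[sel])
  }, numeric(1))
  scale <- max(abs(avg), 1e-300)
  ok <- abs(diff(avg)) < tol * pmax(abs(avg[-1]), 1e-3 * scale)
  # earliest j with all subsequent pairs converged
  good <- rev(cumprod(rev(ok))) > 0
  if (!any(good)) return(list(steady = FALSE, start = NA_real_))
  j <- which(good)[1]
  list(steady = TRUE, start = j * period)
}

#' Closed-form steady-velocity estimate
#'
#' Averaging the leading-order axial momentum equation over the links and
#' one forcing period gives the steady swimming velocity
#' \deqn{U = \frac{C_N - C_T}{C_T}\,\langle v\,\theta\rangle,}
#' where the angle brackets denote the body- and cycle-average of the product
#' of transverse velocity and inclination.  Drag anisotropy (`CN != CT`) is
#' necessary for swimming.  The direct COM average over the same window is
#' returned for comparison.
#'
#' @param traj a `swim_trajectory`
#' @param drag a linear [drag_spec()] (provides CN, CT)
#' @param start start of the steady window (s)
#' @param period averaging window: exactly one forcing period (s)
#' @return object of class `steady_velocity_estimate` with `U` (closed form,
#'   cm/s), `U_direct` (COM average), `vtheta_mean`, `anisotropy`
#' @export
steady_velocity_estimate <- function(traj, drag, start, period) {
  sel <- traj$time >= start - 1e-12 & traj$time <= start + period + 1e-12
  if (max(traj$time) < start + period - 1e-9)
    stop("window extends past the trajectory", call. = FALSE)
  if (sum(sel) < 8)
    stop("window shorter than one forcing period", call. = FALSE)
  N <- traj$N
  tt <- traj$time[sel]
  th <- traj$state[sel, 2 * N + seq_len(N), drop = FALSE]
  vy <- traj$state[sel, 4 * N + seq_len(N), drop = FALSE]
  vx <- traj$state[sel, 3 * N + seq_len(N), drop = FALSE]
  vth <- rowMeans(vy * th)
  vtheta_mean <- pracma::trapz(tt, vth) / (max(tt) - min(tt))
  U <- (drag$CN - drag$CT) / drag$CT * vtheta_mean
  U_direct <- pracma::trapz(tt, rowMeans(vx)) / (max(tt) - min(tt))
  out <- list(U = U, U_direct = U_direct, vtheta_mean = vtheta_mean,
              anisotropy = drag$CN / drag$CT, window = c(start, start + period))
  class(out) <- "steady_velocity_estimate"
  out
}

#' @export
print.steady_velocity_estimate <- function(x, ...) {
  cat(sprintf("steady velocity: closed form U = %.5g cm/s, direct COM average = %.5g cm/s\n",
              x$U, x$U_direct))
  cat(sprintf("  <v theta> = %.5g, anisotropy CN/CT = %.4g\n",
              x$vtheta_mean, x$anisotropy))
  invisible(x)
}

#' Calibrate the penalty spring stiffness
#'
#' The joints must not open: `k_spring` is chosen as the smallest stiffness
#' in a doubling sweep for which the maximum joint gap during a short probe
#' run stays below `gap_tol` (default `1e-3 * ell`).
#'
#' @param params a [physical_params()] object (k_spring may be `NA`)
#' @param drag,act as for [integrate_chain()]
#' @param model penalty model to probe
#' @param n_periods probe duration in forcing periods
#' @param gap_tol gap tolerance (cm)
#' @param margin safety factor: the sweep accepts a stiffness only when the
#'   probe gap is below `margin * gap_tol`, since longer production runs
#'   explore slightly larger gaps than the short probe
#' @param k0 starting stiffness (dyn/cm); default scales with the link
#'   inertia at the forcing frequency
#' @param max_doublings sweep length cap
#' @param flow optional [external_flow_spec()] forcing the probe run
#' @param method,rtol,atol passed to [integrate_chain()]
#' @return `params` with `k_spring` set; attribute `"calibration"` holds the
#'   sweep log
#' @export
calibrate_k_spring <- function(params, drag, act,
                               model = c("nonlinear", "leading_order"),
                               n_periods = 3, gap_tol = 1e-3 * params$ell,
                               margin = 0.7,
                               k0 = NULL, max_doublings = 24, flow = NULL,
                               method = "ode45", rtol = 1e-6, atol = 1e-9) {
  model <- match.arg(model)
  f <- if (act$f > 0) act$f else if (!is.null(flow)) flow$f_f else 1
  if (is.null(k0)) k0 <- params$m * (2 * pi * f)^2 * params$N
  t_end <- n_periods / f
  k <- k0
  log <- list()
  for (i in seq_len(max_doublings)) {
    params$k_spring <- k
    traj <- integrate_chain(model, params, drag, act, t_end, flow = flow,
                            dt_out = 1 / (50 * f), method = method,
                            rtol = rtol, atol = atol)
    gap <- max_gap_over(traj, stride = 1L)
    log[[length(log) + 1]] <- c(k = k, gap = gap)
    if (gap < margin * gap_tol) {
      attr(params, "calibration") <- do.call(rbind, log)
      return(params)
    }
    k <- 2 * k
  }
  stop("k_spring calibration did not converge", call. = FALSE)
}
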