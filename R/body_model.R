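#' Physical parameters of a chain-link swimmer
#'
#' Bundles the geometry, material, fluid, and penalty constants shared by all
#' dynamics in the package.  Internally everything is CGS (cm, g, s, dyn);
#' `E` may be given in Pa (SI) with `E_units = "Pa"` and is converted on
#' construction (1 Pa = 10 dyn/cm^2).
#'
#' The body is a uniform circular cylinder of length `L` and radius `r`,
#' discretized into `N` rigid links of length `ell = L/N`.  Links are taken
#' neutrally buoyant, so the link mass is `m = rho * pi * r^2 * ell` and the
#' rotational inertia is the slender-rod value `Irot = m * ell^2 / 12`.
#'
#' @param L body length (cm)
#' @param N number of links (integer, >= 2)
#' @param r cross-section radius (cm)
#' @param E Young's modulus of the body material
#' @param E_units `"Pa"` (default) or `"cgs"` (dyn/cm^2)
#' @param delta viscoelastic damping coefficient of the muscle moment
#'   (dyn cm^2 s; moment per unit curvature rate).  Kelvin-Voigt
#'   curvature-rate damping gives bending mode n a damping ratio
#'   `zeta_n = (delta/2) beta_n^2 / sqrt(E Ic m')` (`m'` = mass per unit
#'   length), growing with mode number; the default puts `zeta = 0.7` at the
#'   shortest bending wavelength the chain resolves (`beta = pi/ell`), so
#'   grid-scale ringing is quenched while the low deformation modes stay
#'   essentially undamped (`zeta_1` of order 1e-3).
#' @param k_spring penalty spring stiffness at the joints (dyn/cm).  `NA`
#'   means "not yet calibrated"; see [calibrate_k_spring()].
#' @param zeta_joint damping ratio of the penalty joints (a damper in
#'   parallel with each joint spring, acting on the gap rate only).  The
#'   default critically damps the constraint-violation modes; it does not
#'   act on physical motions, for which the gap stays closed.
#' @param mu fluid dynamic viscosity (g cm^-1 s^-1); default water, 0.01
#' @param rho fluid density (g cm^-3); default water, 1
#' @param Cf Taylor drag fit constant, within \[0.9, 1.1\]
#' @return an object of class `phys_params`
#' @export
physical_params <- function(L, N, r, E, E_units = c("Pa", "cgs"),
                            delta = NULL, k_spring = NA_real_,
                            zeta_joint = 1, mu = 0.01, rho = 1, Cf = 1.0) {
  E_units <- match.arg(E_units)
  stopifnot(is.numeric(L), L > 0, is.numeric(r), r > 0,
            is.numeric(E), E > 0, mu > 0, rho > 0)
  N <- as.integer(N)
  if (N < 2L) stop("N must be >= 2 links", call. = FALSE)
  if (Cf < 0.9 || Cf > 1.1)
    stop("Cf must lie in [0.9, 1.1]", call. = FALSE)
  if (E_units == "Pa") E <- E * 10  # Pa -> dyn/cm^2
  ell <- L / N
  Ic <- pi * r^4 / 4
  m <- rho * pi * r^2 * ell
  Irot <- m * ell^2 / 12
  if (is.null(delta))
    delta <- 2 * 0.7 * sqrt(E * Ic * rho * pi * r^2) * (ell / pi)^2
  p <- list(L = L, N = N, ell = ell, r = r, E = E, Ic = Ic,
            delta = delta, k_spring = k_spring, zeta_joint = zeta_joint,
            m = m, Irot = Irot, mu = mu, rho = rho, Cf = Cf)
  class(p) <- "phys_params"
  p
}

#' @export
print.phys_params <- function(x, ...) {
  cat("Chain-link swimmer parameters (CGS units)\n")
  cat(sprintf("  L = %g cm, N = %d links (ell = %g cm), r = %g cm\n",
              x$L, x$N, x$ell, x$r))
  cat(sprintf("  E = %g dyn/cm^2, Ic = %g cm^4, delta = %g\n",
              x$E, x$Ic, x$delta))
  cat(sprintf("  link mass m = %g g, Irot = %g g cm^2\n", x$m, x$Irot))
  cat(sprintf("  fluid: mu = %g, rho = %g; Cf = %g; k_spring = %s dyn/cm\n",
              x$mu, x$rho, x$Cf,
              if (is.na(x$k_spring)) "uncalibrated" else format(x$k_spring)))
  invisible(x)
}

#' Build a chain state
#'
#' Constructs a contiguous chain of `N` links from a midline description.
#' Axes: x is the axial / swimming direction, y transverse, link inclination
#' `theta` is measured counterclockwise from +x.  The chain starts with its
#' head (link 1 left endpoint) at the origin.
#'
#' @param params a [physical_params()] object
#' @param pose `"straight-rest"` or a numeric vector of `N` link angles (rad)
#' @return an object of class `chain_state` with per-link fields `xc`, `yc`,
#'   `theta`, `vx`, `vy` (lab-frame velocities, cm/s), `omega` (rad/s) and
#'   scalar time `t`
#' @export
build_chain <- function(params, pose = "straight-rest") {
  N <- params$N
  ell <- params$ell
  if (identical(pose, "straight-rest")) {
    theta <- numeric(N)
  } else {
    theta <- as.numeric(pose)
    if (length(theta) != N)
      stop("pose must be 'straight-rest' or an angle profile of length N",
           call. = FALSE)
    if (!all(is.finite(theta)))
      stop("pose contains non-finite entries", call. = FALSE)
  }
  # accumulate joint positions, COM midway along each link
  cx <- cos(theta); sx <- sin(theta)
  jx <- c(0, cumsum(ell * cx))   # N+1 joint/end points
  jy <- c(0, cumsum(ell * sx))
  st <- list(xc = jx[seq_len(N)] + (ell / 2) * cx,
             yc = jy[seq_len(N)] + (ell / 2) * sx,
             theta = theta,
             vx = numeric(N), vy = numeric(N), omega = numeric(N),
             t = 0)
  class(st) <- "chain_state"
  st
}

#' Axial/transverse link-frame velocities of a chain state
#'
#' Rotates lab-frame link velocities into each link's own frame: `u` along
#' the link axis, `v` normal to it.
#'
#' @param state a `chain_state`
#' @return list with components `u` and `v` (cm/s)
#' @export
link_frame_velocities <- function(state) {
  ct <- cos(state$theta); st <- sin(state$theta)
  list(u = state$vx * ct + state$vy * st,
       v = -state$vx * st + state$vy * ct)
}

#' Discrete curvature at the joints
#'
#' Forward difference of link angles over one link length:
#' `kappa_i = (theta_{i+1} - theta_i) / ell` at interior joint i.
#'
#' @param state a `chain_state`
#' @param params a [physical_params()] object
#' @return numeric vector of length `N - 1` (1/cm)
#' @export
curvature_at_joints <- function(state, params) {
  diff(state$theta) / params$ell
}

#' Maximum joint endpoint separation
#'
#' Diagnostic for the penalty constraint: the largest distance between the
#' endpoints of adjacent links at their common joint.  Zero for a freshly
#' built chain; should stay below ~1e-3 * ell in a converged penalty-method
#' run.
#'
#' @inheritParams curvature_at_joints
#' @param linearized use the small-angle endpoint geometry consistent with
#'   the leading-order equations instead of the exact trigonometric one
#' @return nonnegative scalar (cm)
#' @export
joint_gaps <- function(state, params, linearized = FALSE) {
  N <- params$N
  h <- params$ell / 2
  if (linearized) {
    th <- state$theta
    gx <- diff(state$xc) - params$ell + (params$ell / 4) * (th[-N]^2 + th[-1]^2)
    gy <- diff(state$yc) - h * (th[-N] + th[-1])
    if (!all(is.finite(gx)) || !all(is.finite(gy)))
      stop("non-finite joint gap", call. = FALSE)
    return(max(sqrt(gx^2 + gy^2)))
  }
  ct <- cos(state$theta); st <- sin(state$theta)
  rx <- state$xc + h * ct; ry <- state$yc + h * st  # right endpoints
  lx <- state$xc - h * ct; ly <- state$yc - h * st  # left endpoints
  gx <- lx[-1] - rx[-N]
  gy <- ly[-1] - ry[-N]
  if (!all(is.finite(gx)) || !all(is.finite(gy)))
    stop("non-finite joint gap", call. = FALSE)
  max(sqrt(gx^2 + gy^2))
}

#' Center-of-mass kinematics of a trajectory
#'
#' Mass-weighted (equal link masses, hence plain) mean of the link velocities
#' at each stored time, in the lab frame.
#'
#' @param traj a `swim_trajectory` (see [integrate_chain()])
#' @return data.frame with columns `t`, `vx_com`, `vy_com` (cm/s)
#' @export
com_kinematics <- function(traj) {
  if (!inherits(traj, "swim_trajectory")) stop("not a swim_trajectory")
  if (length(traj$time) < 2) stop("trajectory needs >= 2 time points")
  N <- traj$N
  vx <- traj$state[, 3 * N + seq_len(N), drop = FALSE]
  vy <- traj$state[, 4 * N + seq_len(N), drop = FALSE]
  data.frame(t = traj$time,
             vx_com = rowMeans(vx),
             vy_com = rowMeans(vy))
}

# --- internal helpers shared across modules ---------------------------------

# pack/unpack the ODE state vector layout: x, y, theta, vx, vy, omega (each N)
state_to_vec <- function(state) {
  c(state$xc, state$yc, state$theta, state$vx, state$vy, state$omega)
}

vec_to_state <- function(y, N, t = 0) {
  st <- list(xc = y[seq_len(N)], yc = y[N + seq_len(N)],
             theta = y[2 * N + seq_len(N)],
             vx = y[3 * N + seq_len(N)], vy = y[4 * N + seq_len(N)],
             omega = y[5 * N + seq_len(N)], t = t)
  class(st) <- "chain_state"
  st
}

#' Extract the chain state at one stored time of a trajectory
#'
#' @param traj a `swim_trajectory`
#' @param i time index (default: last)
#' @return a `chain_state`
#' @export
state_at <- function(traj, i = length(traj$time)) {
  vec_to_state(traj$state[i, ], traj$N, traj$time[i])
}
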