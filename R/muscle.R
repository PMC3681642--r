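#' Muscle activation specification
#'
#' The activation program is a time-dependent preferred curvature `kappa0`
#' along the body; the muscle moment drives the realized curvature toward it.
#'
#' * `none`: no activation (`kappa0 = 0`).
#' * `traveling_wave`: preferred shape is the backward traveling wave
#'   `h(x, t) = B sin(2 pi (x / lambda - f t))`; the preferred curvature is
#'   its second spatial derivative evaluated at the joint stations.  The wave
#'   travels head-to-tail with wavespeed `f * lambda`, so the body swims in
#'   the `-x` direction.
#' * `gait_family`: the five-parameter gait-curvature family of
#'   [gait_params()].
#' * `table`: a tabulated periodic per-joint curvature program (matrix
#'   `kappa0_tab` of size `n_t x (N-1)` sampled uniformly over one period),
#'   used to replay captured kinematics.
#'
#' @param kind activation kind
#' @param B wave amplitude (cm); traveling wave only
#' @param f activation frequency (Hz)
#' @param wavelength wavelength of the traveling wave (cm); defaults to the
#'   body length when used with [integrate_chain()]
#' @param gait a [gait_params()] object (gait_family only)
#' @param kappa0_tab,period tabulated program and its period (table only)
#' @param ramp_periods soft-start: the program amplitude rises smoothly from
#'   zero over this many periods (default 1) so that switching the muscles
#'   on does not ring the high-frequency bending modes.  Set to 0 for an
#'   instantaneous start.  The steady cycle is unaffected.
#' @return an object of class `activation_spec`
#' @export
activation_spec <- function(kind = c("none", "traveling_wave", "gait_family",
                                     "table"),
                            B = 0, f = 0, wavelength = NULL, gait = NULL,
                            kappa0_tab = NULL, period = NULL,
                            ramp_periods = 1) {
  kind <- match.arg(kind)
  if (kind != "none" && kind != "table" && f <= 0)
    stop("f must be positive for an active program", call. = FALSE)
  if (B < 0) stop("B must be nonnegative", call. = FALSE)
  if (kind == "gait_family" && is.null(gait))
    stop("gait_family requires a gait_params object", call. = FALSE)
  if (kind == "table") {
    if (is.null(kappa0_tab) || is.null(period))
      stop("table activation requires kappa0_tab and period", call. = FALSE)
    kappa0_tab <- as.matrix(kappa0_tab)
  }
  a <- list(kind = kind, B = B, f = f, wavelength = wavelength, gait = gait,
            kappa0_tab = kappa0_tab, period = period,
            ramp_periods = ramp_periods)
  class(a) <- "activation_spec"
  a
}

# smooth cosine ramp from 0 to 1 over ramp_periods forcing periods
activation_ramp <- function(spec, t) {
  if (is.null(spec$ramp_periods) || spec$ramp_periods <= 0) return(1)
  Tp <- if (spec$kind == "table") spec$period
        else if (spec$kind == "gait_family") spec$gait$T
        else if (spec$f > 0) 1 / spec$f else return(1)
  tr <- spec$ramp_periods * Tp
  if (t >= tr) 1 else 0.5 - 0.5 * cos(pi * t / tr)
}

#' Preferred curvature at the joints
#'
#' Evaluates the activation program's preferred curvature `kappa0` at the
#' interior joint stations `x_j = j * ell`, `j = 1 .. N-1`, at time `t`.
#' For the traveling wave this is the second-derivative curvature of the
#' preferred shape `h(x, t)`; the program is periodic in `t` with period
#' `1/f`.
#'
#' @param spec an [activation_spec()]
#' @param params a [physical_params()] object
#' @param t time (s)
#' @return numeric vector of length `N - 1` (1/cm)
#' @export
preferred_curvature <- function(spec, params, t) {
  nj <- params$N - 1L
  xj <- seq_len(nj) * params$ell
  activation_ramp(spec, t) * switch(spec$kind,
    none = numeric(nj),
    traveling_wave = {
      lam <- if (is.null(spec$wavelength)) params$L else spec$wavelength
      -spec$B * (2 * pi / lam)^2 * sin(2 * pi * (xj / lam - spec$f * t))
    },
    gait_family = curvature_profile(spec$gait, xj, t),
    table = {
      tab <- spec$kappa0_tab
      nt <- nrow(tab)
      phase <- (t / spec$period) %% 1
      # periodic linear interpolation over the tabulated cycle
      pos <- phase * nt
      i0 <- floor(pos)
      w <- pos - i0
      i0 <- (as.integer(i0) %% nt) + 1L
      i1 <- (i0 %% nt) + 1L
      (1 - w) * tab[i0, ] + w * tab[i1, ]
    })
}

#' Viscoelastic muscle moment at the joints
#'
#' The joint moment model
#' \deqn{M_j = E I_c (\kappa_{0,j} - \kappa_j) - \delta \dot\kappa_j,}
#' zero when the body sits at its preferred shape at rest.  The elastic term
#' is the muscle activation (and, with `kappa0 = 0`, the passive bending
#' stiffness of the body); the `delta` term is tissue viscoelasticity.
#' `M_j` is applied as a torque pair: `-M_j` on link `j`, `+M_j` on link
#' `j + 1`.
#'
#' @param kappa realized joint curvature (length `N - 1`, 1/cm)
#' @param kappa_dot its time derivative, computed from the link angular
#'   velocities (1/(cm s))
#' @param kappa0 preferred curvature (length `N - 1`)
#' @param params a [physical_params()] object
#' @return per-joint moment (dyn cm)
#' @export
muscle_moment <- function(kappa, kappa_dot, kappa0, params) {
  if (length(kappa) != length(kappa0) || length(kappa) != length(kappa_dot))
    stop("kappa, kappa_dot and kappa0 must have equal length", call. = FALSE)
  params$E * params$Ic * (kappa0 - kappa) - params$delta * kappa_dot
}
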