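#' Resistive drag specification
#'
#' Selects which resistive hydrodynamic model applies and carries its
#' coefficients.  Regime selection is always explicit: Taylor's quadratic
#' model is appropriate at intermediate-to-high Reynolds number, Lighthill's
#' slender-body coefficients at low Reynolds number, and the `linearized`
#' variant is the small-inclination form of the Lighthill model used by the
#' leading-order equations.
#'
#' * `taylor`: nonlinear-in-speed cross-flow drag.  The normal force per unit
#'   length is `-(1/2) rho (2r) Cf |vN| vN` with `Cf` in \[0.9, 1.1\] (the
#'   cylinder drag-coefficient plateau), the tangential force is skin
#'   friction `-(1/2) rho (2r) Ct |vT| vT`.
#' * `lighthill` / `linearized`: linear anisotropic drag `fN = -CN vN`,
#'   `fT = -CT vT` with coefficients from [lighthill_coefficients()].
#'
#' @param variant one of `"taylor"`, `"lighthill"`, `"linearized"`
#' @param params a [physical_params()] object (used to derive defaults)
#' @param wavelength undulation wavelength (cm) entering the slender-body
#'   logarithms; defaults to the body length
#' @param CN,CT normal/tangential drag coefficients per unit length
#'   (dyn s/cm^2); computed from `params` and `wavelength` when `NULL`
#' @param Ct_taylor tangential (skin friction) coefficient of the Taylor
#'   variant; default `1.33 * pi / sqrt(Re_L)` with `Re_L` based on the
#'   actuation wavespeed when available, else 0.01
#' @param wavespeed reference speed for the default `Ct_taylor` (cm/s)
#' @return an object of class `drag_spec`
#' @export
drag_spec <- function(variant = c("lighthill", "taylor", "linearized"),
                      params = NULL, wavelength = NULL,
                      CN = NULL, CT = NULL, Ct_taylor = NULL,
                      wavespeed = NULL) {
  variant <- match.arg(variant)
  Lambda <- NA_real_
  if (variant %in% c("lighthill", "linearized")) {
    if (is.null(CN) || is.null(CT)) {
      if (is.null(params))
        stop("params needed to derive Lighthill coefficients", call. = FALSE)
      if (is.null(wavelength)) wavelength <- params$L
      co <- lighthill_coefficients(params, wavelength)
      CN <- co$CN; CT <- co$CT; Lambda <- co$Lambda
    }
    if (CT < 0 || CN < CT)
      stop("slender-body anisotropy requires CN >= CT >= 0", call. = FALSE)
  } else {
    if (is.null(Ct_taylor)) {
      Ct_taylor <- if (!is.null(wavespeed) && !is.null(params)) {
        ReL <- params$rho * wavespeed * params$L / params$mu
        1.33 * pi / sqrt(ReL)
      } else 0.01
    }
  }
  d <- list(variant = variant, CN = CN, CT = CT, Lambda = Lambda,
            Cf = if (is.null(params)) 1.0 else params$Cf,
            Ct_taylor = Ct_taylor,
            wavelength = if (is.null(wavelength)) NA_real_ else wavelength)
  class(d) <- "drag_spec"
  d
}

#' Lighthill slender-body drag coefficients
#'
#' Closed-form low-Reynolds-number resistive coefficients for a slender
#' cylinder undulating with wavelength `wavelength`:
#' \deqn{C_N = \frac{4\pi\mu}{\ln(2\Lambda/r) + 1/2}, \qquad
#'       C_T = \frac{2\pi\mu}{\ln(2\Lambda/r)},}
#' with \eqn{\Lambda = 0.09\,\lambda}.  Both coefficients are per unit length
#' per unit velocity (dyn s/cm^2) and satisfy `CN > CT > 0`.
#'
#' @param params a [physical_params()] object
#' @param wavelength undulation wavelength \eqn{\lambda} (cm)
#' @return list with `CN`, `CT`, `Lambda`
#' @export
lighthill_coefficients <- function(params, wavelength) {
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("wavelength must be positive", call. = FALSE)
  if (params$r >= params$L)
    warning("body is not slender (r >= L); coefficients unreliable")
  Lambda <- 0.09 * wavelength
  lg <- log(2 * Lambda / params$r)
  if (lg <= 0.5)
    stop("slenderness too weak: log(2*Lambda/r) must exceed 1/2", call. = FALSE)
  list(CN = 4 * pi * params$mu / (lg + 0.5),
       CT = 2 * pi * params$mu / lg,
       Lambda = Lambda)
}

#' Taylor resistive drag per unit length
#'
#' Quadratic cross-flow drag for a smooth oblique cylinder: forces oppose the
#' normal and tangential velocity components and are nonlinear in speed.
#'
#' @param vN,vT normal and tangential velocity components (cm/s)
#' @param params a [physical_params()] object
#' @param spec a `drag_spec` with `variant = "taylor"`
#' @return list with `fN`, `fT` (dyn/cm)
#' @export
taylor_drag <- function(vN, vT, params, spec) {
  if (spec$variant != "taylor") stop("spec$variant must be 'taylor'")
  if (!all(is.finite(vN)) || !all(is.finite(vT)))
    stop("non-finite velocity", call. = FALSE)
  d <- 2 * params$r
  list(fN = -0.5 * params$rho * d * spec$Cf * abs(vN) * vN,
       fT = -0.5 * params$rho * d * spec$Ct_taylor * abs(vT) * vT)
}

#' Lighthill linear drag per unit length
#'
#' `fN = -CN vN`, `fT = -CT vT`: linear anisotropic resistive drag for low
#' Reynolds number.
#'
#' @param vN,vT normal and tangential velocity components (cm/s)
#' @param spec a `drag_spec` with `variant = "lighthill"` (or `"linearized"`)
#' @return list with `fN`, `fT` (dyn/cm)
#' @export
lighthill_drag <- function(vN, vT, spec) {
  if (!spec$variant %in% c("lighthill", "linearized"))
    stop("spec$variant must be 'lighthill' or 'linearized'")
  if (!all(is.finite(vN)) || !all(is.finite(vT)))
    stop("non-finite velocity", call. = FALSE)
  list(fN = -spec$CN * vN, fT = -spec$CT * vT)
}

#' Leading-order link drag force and moment
#'
#' Small-inclination expansion of the Lighthill drag integrated over one
#' link of length `ell`.  Writing the lab-frame link velocity as axial `u`
#' and transverse `v` with inclination `theta` and angular velocity `omega`:
#' \deqn{F_x = \ell\,[-C_T u + (C_N - C_T)\, v\, \theta], \quad
#'       F_y = -C_N \ell v, \quad
#'       M_z = -C_N \frac{\ell^3}{12} \omega.}
#' The `(CN - CT) v theta` cross term is the source of axial thrust; it
#' vanishes for isotropic drag `CN = CT`.
#'
#' @param v transverse (lab y) velocity (cm/s)
#' @param u axial (lab x) velocity (cm/s)
#' @param theta link inclination (rad)
#' @param omega angular velocity (rad/s)
#' @param spec a `drag_spec` with linear coefficients
#' @param params a [physical_params()] object
#' @return list with `Fx`, `Fy` (dyn) and `Mz` (dyn cm)
#' @export
linearized_drag <- function(v, u, theta, omega, spec, params) {
  ell <- params$ell
  list(Fx = ell * (-spec$CT * u + (spec$CN - spec$CT) * v * theta),
       Fy = -spec$CN * ell * v,
       Mz = -spec$CN * ell^3 / 12 * omega)
}

#' Rotational drag damping coefficient of a link
#'
#' Distributed normal drag of the rotation-induced velocity field integrated
#' along a link: the moment is `-c_r * omega` with `c_r = CN * ell^3 / 12`.
#'
#' @param spec a linear `drag_spec`
#' @param ell link length (cm)
#' @return scalar `c_r` (dyn cm s)
#' @export
rotational_drag_coefficient <- function(spec, ell) {
  spec$CN * ell^3 / 12
}
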