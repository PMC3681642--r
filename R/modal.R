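# Linearized spring-inertia-damper system of the transverse/rotational
# dynamics, its eigenmodes, and beam-mode decomposition of kinematics.

#' Assemble the linearized mass/damping/stiffness system
#'
#' Differentiating the leading-order transverse and rotational equations once
#' more gives a second-order system `M w'' + C w' + K w = F(t)` in the
#' stacked velocity variables `w = (v_1..v_N, omega_1..omega_N)`:
#' diagonal inertia, drag (plus tissue viscoelasticity) damping, and
#' stiffness from the penalty springs and the elastic muscle term.  The
#' forcing vector comes from the preferred-curvature rate,
#' `F = (0, E I D' kappadot0)` with `D` the joint difference operator.
#'
#' @param params a [physical_params()] object with calibrated `k_spring`
#' @param drag a linear [drag_spec()]
#' @return object of class `modal_system` with `M`, `C`, `K`, the first-order
#'   matrix `A`, and `forcing_map(kappa0dot)`
#' @export
assemble_mck <- function(params, drag) {
  N <- params$N
  ell <- params$ell
  if (is.na(params$k_spring)) stop("k_spring is uncalibrated", call. = FALSE)
  k <- params$k_spring
  EI <- params$E * params$Ic
  cr <- drag$CN * ell^3 / 12
  D <- diff(diag(N))                           # (N-1) x N joint differences
  Amid <- (abs(D) / 2)                         # joint averaging operator
  Lap <- crossprod(D)                          # D' D
  zj <- if (is.null(params$zeta_joint)) 1 else params$zeta_joint
  cj <- 2 * zj * sqrt(k * params$m / 2)
  M <- diag(c(rep(params$m, N), rep(params$Irot, N)))
  DtA <- crossprod(D, Amid)
  C <- rbind(cbind(diag(drag$CN * ell, N) + cj * Lap, -cj * ell * DtA),
             cbind(-cj * ell * t(DtA),
                   diag(cr, N) + (params$delta / ell) * Lap +
                     cj * ell^2 * crossprod(Amid)))
  K <- rbind(cbind(k * Lap, -k * ell * DtA),
             cbind(-k * ell * t(DtA),
                   k * ell^2 * crossprod(Amid) + (EI / ell) * Lap))
  A <- rbind(cbind(matrix(0, 2 * N, 2 * N), diag(2 * N)),
             cbind(-solve(M, K), -solve(M, C)))
  fmap <- function(kappa0dot) c(numeric(N), EI * crossprod(D, kappa0dot))
  sys <- list(M = M, C = C, K = K, A = A, forcing_map = fmap,
              N = N, params = params, drag = drag)
  class(sys) <- "modal_system"
  sys
}

#' Eigenmodes of the linearized swimmer
#'
#' Eigendecomposition of the first-order system matrix.  Underdamped modes
#' are complex-conjugate pairs (counted once) with natural frequency
#' `|Im(lambda)| / (2 pi)`; overdamped modes are purely real.  Underdamped
#' modes are listed first, sorted by increasing natural frequency, then the
#' real modes sorted by `|Re(lambda)|`.
#'
#' @param system a [assemble_mck()] result
#' @param im_tol relative threshold on `|Im(lambda)|` for classifying a mode
#'   as underdamped
#' @return object of class `modal_eigen` with `values`, `vectors` (columns
#'   aligned with `values`), `frequency_hz` (NA for overdamped),
#'   `classification`, `n_underdamped`, `n_overdamped`
#' @export
eigenmodes <- function(system, im_tol = 1e-8) {
  eg <- tryCatch(eigen(system$A), error = function(e) {
    message("dense eigen failed; falling back to Schur-based analysis")
    sc <- pracma::schur(system$A)
    eigen(sc$T)
  })
  lam <- eg$values
  scale <- max(abs(lam))
  osc <- abs(Im(lam)) > im_tol * scale
  # keep one member of each conjugate pair
  und_idx <- which(osc & Im(lam) > 0)
  und_idx <- und_idx[order(abs(Im(lam[und_idx])), abs(Re(lam[und_idx])))]
  real_idx <- which(!osc)
  real_idx <- real_idx[order(abs(Re(lam[real_idx])))]
  idx <- c(und_idx, real_idx)
  out <- list(values = lam[idx],
              vectors = eg$vectors[, idx, drop = FALSE],
              all_values = lam,
              all_vectors = eg$vectors,
              frequency_hz = ifelse(seq_along(idx) <= length(und_idx),
                                    abs(Im(lam[idx])) / (2 * pi), NA_real_),
              classification = rep(c("underdamped", "overdamped"),
                                   c(length(und_idx), length(real_idx))),
              n_underdamped = length(und_idx),
              n_overdamped = length(real_idx),
              N = system$N)
  class(out) <- "modal_eigen"
  out
}

#' @export
print.modal_eigen <- function(x, ...) {
  cat(sprintf("modal_eigen: %d underdamped pairs, %d real modes\n",
              x$n_underdamped, x$n_overdamped))
  nf <- utils::head(x$frequency_hz[x$classification == "underdamped"], 5)
  cat("  first natural frequencies (Hz):",
      paste(sprintf("%.2f", nf), collapse = ", "), "\n")
  invisible(x)
}

#' Transverse mode shape of an eigenmode
#'
#' Extracts the transverse (`v`) displacement profile of the requested mode,
#' normalized to unit maximum amplitude.
#'
#' @param modes a [eigenmodes()] result
#' @param i mode index (into the sorted listing)
#' @return numeric vector of length N
#' @export
mode_shape <- function(modes, i) {
  v <- modes$vectors[seq_len(modes$N), i]
  # rotate the complex profile to a real shape at its phase of peak amplitude
  ph <- Arg(v[which.max(Mod(v))])
  s <- Re(v * exp(-1i * ph))
  s / max(abs(s))
}

#' Modal weights of a deformation state
#'
#' Least-squares coordinates of a state in the eigenvector basis of the
#' first-order system.  A state is `(w, w')` of length `4N`; a plain
#' deformation-velocity snapshot of length `2N` is lifted with zero
#' derivative.
#'
#' @param x numeric (or complex) vector of length `2N` or `4N`
#' @param system a [assemble_mck()] result
#' @param modes optional precomputed [eigenmodes()]
#' @return object of class `mode_weights`: complex coefficients aligned with
#'   `modes$all_values`, with `magnitude` aggregated per listed mode
#'   (conjugate pairs combined) and `reconstruction_error`
#' @export
mode_weights <- function(x, system, modes = NULL) {
  if (is.null(modes)) modes <- eigenmodes(system)
  n <- 2 * system$N
  z <- if (length(x) == n) c(x, numeric(n)) else x
  if (length(z) != 2 * n) stop("x must have length 2N or 4N", call. = FALSE)
  V <- modes$all_vectors
  w <- tryCatch(solve(V, as.complex(z)),
                error = function(e) stop("rank-deficient eigenbasis",
                                         call. = FALSE))
  recon <- V %*% w
  # magnitude per listed mode: match listed eigenvalues to raw indices
  mag <- vapply(seq_along(modes$values), function(i) {
    lam <- modes$values[i]
    hit <- which(abs(modes$all_values - lam) < 1e-12 * max(1, abs(lam)) |
                   abs(modes$all_values - Conj(lam)) <
                     1e-12 * max(1, abs(lam)))
    sum(Mod(w[hit]))
  }, numeric(1))
  out <- list(coefficients = w, magnitude = mag,
              reconstruction_error =
                sqrt(sum(Mod(recon - z)^2) / max(sum(Mod(z)^2), 1e-300)))
  class(out) <- "mode_weights"
  out
}

# ---- Euler-Bernoulli free-free beam modes ----------------------------------

beam_beta_l <- function(n) {
  known <- c(4.73004074486270, 7.85320462409584, 10.9956078380016,
             14.1371654912575, 17.2787596573995)
  ifelse(n <= 5, known[pmin(n, 5)], (2 * n + 1) * pi / 2)
}

#' Free-free Euler-Bernoulli beam modes
#'
#' The first `n_modes` bending eigenfunctions of a free-free beam evaluated
#' at arclength stations `s` in `[0, L]`, normalized so that
#' `(1/L) int phi_m phi_n ds = delta_mn`.  Rigid translation and rotation
#' are not included.
#'
#' @param s arclength stations (cm)
#' @param n_modes number of modes (<= 8; higher modes lose accuracy to
#'   hyperbolic cancellation)
#' @param L beam length (default `max(s)`)
#' @return matrix `length(s) x n_modes`
#' @export
beam_modes <- function(s, n_modes, L = max(s)) {
  if (n_modes > 8) stop("n_modes must be <= 8", call. = FALSE)
  phi <- matrix(0, length(s), n_modes)
  for (n in seq_len(n_modes)) {
    bl <- beam_beta_l(n)
    b <- bl / L
    sig <- (cosh(bl) - cos(bl)) / (sinh(bl) - sin(bl))
    phi[, n] <- cosh(b * s) + cos(b * s) - sig * (sinh(b * s) + sin(b * s))
  }
  phi
}

#' Project a lateral profile onto beam modes
#'
#' Removes the rigid components (mean and best-fit straight line) and
#' computes the amplitudes `(1/L) int phi_n y ds` by trapezoidal quadrature.
#'
#' @param s arclength stations (cm)
#' @param y lateral displacements at `s` (cm)
#' @param n_modes number of beam modes
#' @return numeric vector of amplitudes (cm)
#' @export
beam_project <- function(s, y, n_modes) {
  if (n_modes >= length(s))
    stop("n_modes exceeds the grid resolution", call. = FALSE)
  L <- max(s) - min(s)
  fit <- stats::lm.fit(cbind(1, s), y)
  yd <- fit$residuals
  phi <- beam_modes(s - min(s), n_modes, L = L)
  vapply(seq_len(n_modes),
         function(n) pracma::trapz(s, phi[, n] * yd) / L,
         numeric(1))
}

#' Beam-mode amplitude time series of a trajectory
#'
#' Resamples the midline to its N+1 uniform-arclength stations (the link
#' endpoints), moves to the COM frame aligned with the mean body
#' orientation, removes the rigid components, and projects the lateral
#' displacement onto the first free-free beam modes at each stored time.
#'
#' @param traj a `swim_trajectory`
#' @param n_modes number of beam modes
#' @return matrix `length(traj$time) x n_modes` of amplitudes (cm)
#' @export
beam_mode_projection <- function(traj, n_modes) {
  N <- traj$N
  ell <- traj$params$ell
  s <- seq(0, N) * ell
  amps <- matrix(0, length(traj$time), n_modes)
  for (i in seq_along(traj$time)) {
    st <- state_at(traj, i)
    ct <- cos(st$theta); sn <- sin(st$theta)
    ex <- c(st$xc[1] - ell / 2 * ct[1], st$xc + ell / 2 * ct)
    ey <- c(st$yc[1] - ell / 2 * sn[1], st$yc + ell / 2 * sn)
    alpha <- atan2(mean(sn), mean(ct))   # mean body orientation
    xr <- (ex - mean(ex)) * cos(alpha) + (ey - mean(ey)) * sin(alpha)
    yr <- -(ex - mean(ex)) * sin(alpha) + (ey - mean(ey)) * cos(alpha)
    amps[i, ] <- beam_project(s, yr, n_modes)
  }
  amps
}
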