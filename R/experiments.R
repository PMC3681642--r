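# Named, reproducible experiments and their serialization: the package's
# user surface for the standard study cases.

#' Canonical parameter sets
#'
#' `validation_case()`: a 20-cm neutrally buoyant rod actuated at 2 Hz
#' (wavespeed 40 cm/s) in water, the intermediate-Reynolds-number regime of
#' Taylor drag.  `zebrafish_case()`: the juvenile-zebrafish case, a 1-cm
#' body actuated at 20 Hz (wavespeed 20 cm/s) at low Reynolds number with
#' Lighthill drag; the traveling-wave amplitude defaults to `B = 0.125 L`,
#' the same amplitude-to-length ratio as the 2.5-cm validation wave.
#'
#' @param B traveling-wave amplitude (cm)
#' @param f actuation frequency (Hz)
#' @return list with `params`, `drag`, `act`, `wavespeed`
#' @export
validation_case <- function(B = 2.5, f = 2) {
  params <- physical_params(L = 20, N = 40, r = 1, E = 0.7e6)
  drag <- drag_spec("taylor", params, wavespeed = f * params$L)
  act <- activation_spec("traveling_wave", B = B, f = f, wavelength = params$L)
  list(params = params, drag = drag, act = act, wavespeed = f * params$L)
}

#' @rdname validation_case
#' @export
zebrafish_case <- function(B = 0.125, f = 20) {
  params <- physical_params(L = 1, N = 40, r = 0.05, E = 0.7e6)
  drag <- drag_spec("lighthill", params, wavelength = params$L)
  act <- activation_spec("traveling_wave", B = B, f = f, wavelength = params$L)
  list(params = params, drag = drag, act = act, wavespeed = f * params$L)
}

config_allowed_keys <- c("experiment", "physical", "drag", "activation",
                         "flow", "forcing", "integration", "sweep",
                         "output_dir")

#' Read and validate an experiment configuration
#'
#' YAML (or JSON) configuration with blocks for the physical parameters,
#' drag model, activation / flow / forcing, integration options, and sweep
#' definitions.  Unknown top-level keys are rejected.
#'
#' @param path configuration file
#' @return validated named list
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), config_allowed_keys)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg
}

#' Write a run summary as JSON
#'
#' @param x named list of results (the full resolved configuration included)
#' @param path output file
#' @export
write_run_summary <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' One row per stored time: `t`, per-link `x`, `y`, `theta`, and the COM
#' velocity columns.
#'
#' @param traj a `swim_trajectory`
#' @param path output file
#' @export
trajectory_to_csv <- function(traj, path) {
  N <- traj$N
  ck <- com_kinematics(traj)
  df <- data.frame(t = traj$time)
  for (blk in 1:3) {
    cols <- traj$state[, (blk - 1) * N + seq_len(N), drop = FALSE]
    colnames(cols) <- paste0(c("x", "y", "theta")[blk], seq_len(N))
    df <- cbind(df, cols)
  }
  df$vx_com <- ck$vx_com
  df$vy_com <- ck$vy_com
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# shallow merge of a config block over defaults
merge_cfg <- function(defaults, block) {
  if (is.null(block)) return(defaults)
  defaults[names(block)] <- block
  defaults
}

#' Penalty-method validation against the constraint-elimination oracle
#'
#' Runs the nonlinear penalty-method model and the exact constrained model
#' for two traveling-wave amplitudes on the validation case and reports the
#' normalized forward/lateral COM velocity series and their discrepancy.
#'
#' @param B_values traveling-wave amplitudes (cm)
#' @param n_periods simulated forcing periods
#' @param N optional reduced link count (default 40)
#' @param config optional config list overriding the physical block
#' @return list per amplitude with `U_pm`, `U_oracle` (normalized, steady),
#'   `discrepancy` (max normalized COM-velocity difference over the final
#'   period), and the series
#' @export
run_validation <- function(B_values = c(2.5, 3.5), n_periods = 5, N = 40,
                           config = NULL) {
  out <- list(wavespeed = 2 * 20)
  f <- 2
  for (B in B_values) {
    case <- validation_case(B = B, f = f)
    params <- case$params
    if (N != params$N) params <- physical_params(L = 20, N = N, r = 1,
                                                 E = 0.7e6)
    params <- calibrate_k_spring(params, case$drag, case$act)
    t_end <- n_periods / f
    pm <- integrate_chain("nonlinear", params, case$drag, case$act, t_end,
                          dt_out = 1 / (100 * f))
    orc <- integrate_chain("oracle", params, case$drag, case$act, t_end,
                           dt_out = 1 / (100 * f))
    ck_pm <- com_kinematics(pm)
    ck_or <- com_kinematics(orc)
    sel <- ck_pm$t >= t_end - 1 / f
    disc <- max(abs(ck_pm$vx_com[sel] - ck_or$vx_com[sel]),
                abs(ck_pm$vy_com[sel] - ck_or$vy_com[sel])) / out$wavespeed
    U_pm <- pracma::trapz(ck_pm$t[sel], ck_pm$vx_com[sel]) * f
    U_or <- pracma::trapz(ck_or$t[sel], ck_or$vx_com[sel]) * f
    out[[paste0("B_", B)]] <- list(
      B = B, k_spring = params$k_spring,
      U_pm = U_pm / out$wavespeed, U_oracle = U_or / out$wavespeed,
      discrepancy = disc,
      series = data.frame(t = ck_pm$t,
                          vx_pm = ck_pm$vx_com / out$wavespeed,
                          vy_pm = ck_pm$vy_com / out$wavespeed,
                          vx_oracle = ck_or$vx_com / out$wavespeed,
                          vy_oracle = ck_or$vy_com / out$wavespeed))
  }
  out
}

#' Juvenile-zebrafish comparison of the three model variants
#'
#' Integrates the leading-order penalty model, the nonlinear penalty model,
#' and (optionally) the constraint-elimination oracle with linear
#' slender-body drag from the straight rest state, detects the steady
#' window, and reports steady forward velocities normalized by the
#' wavespeed together with the closed-form cross-check.
#'
#' @param B_over_L traveling-wave amplitude ratio
#' @param n_periods simulated forcing periods
#' @param include_oracle also run the constrained model
#' @param params optional precalibrated [physical_params()]
#' @return list with normalized velocities, the steady-velocity estimate of
#'   the leading-order run, and diagnostics
#' @export
run_zebrafish <- function(B_over_L = 0.125, n_periods = 16,
                          include_oracle = FALSE, params = NULL) {
  case <- zebrafish_case(B = B_over_L * 1)
  f <- case$act$f
  if (is.null(params))
    params <- calibrate_k_spring(case$params, case$drag, case$act,
                                 method = "bdf", rtol = 1e-5, atol = 1e-7)
  t_end <- n_periods / f
  res <- list(wavespeed = case$wavespeed, B_over_L = B_over_L,
              k_spring = params$k_spring)
  lo <- integrate_chain("leading_order", params, case$drag, case$act, t_end,
                        method = "bdf", rtol = 1e-5, atol = 1e-7)
  nl <- integrate_chain("nonlinear", params, case$drag, case$act, t_end,
                        method = "bdf", rtol = 1e-5, atol = 1e-7)
  stw <- detect_steady_state(lo, 1 / f)
  if (!stw$steady) stop("leading-order run did not reach steady state")
  start <- min(stw$start, t_end - 1 / f)
  est <- steady_velocity_estimate(lo, case$drag, start, 1 / f)
  res$steady_start <- start
  res$U_leading <- abs(est$U_direct) / case$wavespeed
  res$eq_closed_form <- abs(est$U) / case$wavespeed
  res$closed_form_gap <- abs(est$U - est$U_direct) / case$wavespeed
  stn <- detect_steady_state(nl, 1 / f)
  startn <- if (stn$steady) min(stn$start, t_end - 1 / f) else t_end - 1 / f
  estn <- steady_velocity_estimate(nl, case$drag, startn, 1 / f)
  res$U_nonlinear <- abs(estn$U_direct) / case$wavespeed
  res$max_joint_gap <- max(lo$diagnostics$max_joint_gap,
                           nl$diagnostics$max_joint_gap)
  if (include_oracle) {
    orc <- integrate_chain("oracle", params, case$drag, case$act, t_end)
    eso <- steady_velocity_estimate(orc, case$drag, startn, 1 / f)
    res$U_oracle <- abs(eso$U_direct) / case$wavespeed
  }
  res$traj_leading <- lo
  res$traj_nonlinear <- nl
  res$params <- params
  res
}

#' Modal census of the zebrafish-case linearized system
#'
#' Assembles the spring-inertia-damper system at the zebrafish parameters
#' with the calibrated penalty stiffness, eigendecomposes it, and reports
#' the underdamped/overdamped census, the first natural frequencies, the
#' first mode shapes, and the forced-response mode weights at the actuation
#' frequency.
#'
#' @param params optional precalibrated [physical_params()]
#' @param f_forcing forcing frequency (Hz) for the response weights
#' @param n_shapes number of mode shapes to return
#' @return list with `modes` (a [eigenmodes()] result), census counts,
#'   `frequencies_hz`, `shapes`, `forced_weights`
#' @export
run_modes <- function(params = NULL, f_forcing = 20, n_shapes = 3) {
  case <- zebrafish_case()
  if (is.null(params))
    params <- calibrate_k_spring(case$params, case$drag, case$act,
                                 method = "bdf", rtol = 1e-5, atol = 1e-7)
  sys <- assemble_mck(params, case$drag)
  modes <- eigenmodes(sys)
  und <- modes$classification == "underdamped"
  shapes <- vapply(seq_len(n_shapes), function(i) mode_shape(modes, i),
                   numeric(params$N))
  # steady forced response at the actuation frequency
  W <- forced_response_weights(sys, modes, case$act, f_forcing)
  list(modes = modes, n_underdamped = modes$n_underdamped,
       n_overdamped = modes$n_overdamped,
       frequencies_hz = modes$frequency_hz[und],
       shapes = shapes, forced_weights = W, k_spring = params$k_spring)
}

# Complex steady response of the linear system to the traveling-wave
# activation at frequency f, decomposed over the underdamped transverse
# mode shapes (plus the two rigid recoil shapes).  A least-squares fit of
# the response shape is used instead of raw eigenbasis coordinates: the
# eigenbasis is not orthogonal, and within the penalty band large
# coefficients cancel pairwise, which would misrepresent where the motion
# actually lives.
forced_response_weights <- function(sys, modes, act, f) {
  params <- sys$params
  N <- params$N
  Om <- 2 * pi * f
  lam <- if (is.null(act$wavelength)) params$L else act$wavelength
  xj <- seq_len(N - 1) * params$ell
  q <- 2 * pi / lam
  # kappa0_j(t) = -B q^2 sin(q x_j - Om t) = Re(k0hat e^{i Om t})
  k0hat <- act$B * q^2 * exp(-1i * (q * xj + pi / 2))
  Fhat <- sys$forcing_map(1i * Om * k0hat)
  What <- solve(-Om^2 * sys$M + 1i * Om * sys$C + sys$K, Fhat)
  wv <- What[seq_len(N)]                      # transverse response shape
  und <- which(modes$classification == "underdamped")
  S <- vapply(und, function(i) modes$vectors[seq_len(N), i],
              complex(N))
  basis <- cbind(rep(1, N), seq_len(N) - (N + 1) / 2, S)
  cf <- qr.solve(basis, wv)
  energy <- Mod(cf[-(1:2)])^2 * colSums(Mod(S)^2)
  list(energy = energy, coefficients = cf, response = What,
       residual = sqrt(sum(Mod(basis %*% cf - wv)^2) /
                         max(sum(Mod(wv)^2), 1e-300)))
}

#' Frequency sweep of wave efficiency and deformation-mode content
#'
#' Nonlinear runs of the validation case over a grid of actuation
#' frequencies.  Wave efficiency is the steady forward speed normalized by
#' the wavespeed `f L`; the high-mode content is the steady-cycle energy
#' fraction of beam modes above mode 3.
#'
#' @param freqs frequency grid (Hz)
#' @param B traveling-wave amplitude (cm)
#' @param n_periods simulated periods per frequency
#' @param n_modes beam modes for the weight spectra
#' @return data.frame with `f`, `efficiency`, `high_mode_fraction`
#' @export
run_frequency_sweep <- function(freqs = c(2, 4, 8, 16, 32, 64), B = 2.5,
                                n_periods = 5, n_modes = 6) {
  rows <- lapply(freqs, function(f) {
    case <- validation_case(B = B, f = f)
    # calibrate per frequency: joint forces scale with f^2, and an
    # over-stiff penalty needlessly shrinks the stable step at low f
    params <- calibrate_k_spring(case$params, case$drag, case$act,
                                 n_periods = 2, method = "bdf",
                                 rtol = 1e-5, atol = 1e-7)
    traj <- integrate_chain("nonlinear", params, case$drag, case$act,
                            n_periods / f, dt_out = 1 / (100 * f),
                            method = "bdf", rtol = 1e-5, atol = 1e-7)
    sel <- traj$time >= (n_periods - 1) / f
    ck <- com_kinematics(traj)
    U <- pracma::trapz(ck$t[sel], ck$vx_com[sel]) * f
    amps <- beam_mode_projection(
      list_subset_traj(traj, sel), n_modes)
    en <- colMeans(amps^2)
    data.frame(f = f, efficiency = abs(U) / (f * params$L),
               high_mode_fraction = sum(en[-(1:3)]) / sum(en))
  })
  do.call(rbind, rows)
}

# restrict a trajectory to selected time indices
list_subset_traj <- function(traj, sel) {
  traj$time <- traj$time[sel]
  traj$state <- traj$state[sel, , drop = FALSE]
  traj
}

#' Stiffness sweep of swimming speed and the gait objective
#'
#' Nonlinear runs of the validation case over a log grid of Young's moduli
#' under (a) the traveling-wave preferred curvature, and optionally (b) the
#' realized kinematics captured at (a)'s optimum replayed as the preferred
#' curvature.  Under (a) an interior optimum in speed appears; under (b)
#' the speed plateaus at high stiffness.
#'
#' @param E_grid_Pa Young's moduli (Pa)
#' @param B traveling-wave amplitude (cm)
#' @param n_periods simulated periods per case
#' @param programs subset of `c("wave", "optimal")`
#' @return list with data.frames `wave` and `optimal` (columns `E_Pa`,
#'   `U_norm`, `J`), and `E_opt_Pa`
#' @export
run_stiffness_sweep <- function(E_grid_Pa = 10^seq(3.5, 6.5, length.out = 6),
                                B = 2.5, n_periods = 5,
                                programs = c("wave", "optimal")) {
  f <- 2
  base <- validation_case(B = B, f = f)
  run_one <- function(E_Pa, act, params0 = NULL) {
    params <- physical_params(L = 20, N = 40, r = 1, E = E_Pa)
    params$k_spring <- params0$k_spring
    traj <- integrate_chain("nonlinear", params, base$drag, act,
                            n_periods / f, dt_out = 1 / (100 * f),
                            method = "bdf", rtol = 1e-5, atol = 1e-7)
    est <- steady_velocity_estimate(traj, drag_spec("lighthill", params),
                                    (n_periods - 1) / f, 1 / f)
    ck <- com_kinematics(traj)
    sel <- ck$t >= (n_periods - 1) / f
    U <- pracma::trapz(ck$t[sel], ck$vx_com[sel]) * f
    list(U_norm = abs(U) / (f * 20), J = -est$vtheta_mean / (f * 20),
         traj = traj)
  }
  # calibrate once at the stiffest case (largest muscle moments)
  pstiff <- physical_params(L = 20, N = 40, r = 1, E = max(E_grid_Pa))
  pstiff <- calibrate_k_spring(pstiff, base$drag, base$act, n_periods = 2,
                               method = "bdf", rtol = 1e-5, atol = 1e-7)
  wave <- lapply(E_grid_Pa, function(E) run_one(E, base$act, pstiff))
  res <- list(wave = data.frame(E_Pa = E_grid_Pa,
                                U_norm = vapply(wave, `[[`, 1, "U_norm"),
                                J = vapply(wave, `[[`, 1, "J")))
  iopt <- which.max(res$wave$U_norm)
  res$E_opt_Pa <- E_grid_Pa[iopt]
  if ("optimal" %in% programs) {
    # capture the realized kinematics at the optimum as a kappa0 table
    topt <- wave[[iopt]]$traj
    sel <- which(topt$time >= (n_periods - 1) / f &
                   topt$time < n_periods / f)
    N <- topt$N
    tab <- t(vapply(sel, function(i) {
      diff(topt$state[i, 2 * N + seq_len(N)]) / topt$params$ell
    }, numeric(N - 1)))
    act_tab <- activation_spec("table", f = f, kappa0_tab = tab,
                               period = 1 / f)
    opt <- lapply(E_grid_Pa, function(E) run_one(E, act_tab, pstiff))
    res$optimal <- data.frame(E_Pa = E_grid_Pa,
                              U_norm = vapply(opt, `[[`, 1, "U_norm"),
                              J = vapply(opt, `[[`, 1, "J"))
  }
  res
}

#' Passive-swimming demonstrations
#'
#' (i) Phase sweep of the forced rigid link, analytic versus numerical;
#' (ii) a rigid link drifting in a traveling transverse flow; (iii) a
#' flexible body swimming passively in a short-wavelength flow.  The drag
#' coefficients default to `CN = 10`, `CT = 5` dyn s/cm^2 — the scale of the
#' quadratic cross-flow drag linearized about the 10 cm/s flow amplitude
#' (`rho * r * Cf * |v|`) — so damping and inertia compete and the
#' scenarios settle within a few forcing periods.
#'
#' @param scenarios subset of `c("forced", "rigid_flow", "flexible_flow")`
#' @param n_phi phase-grid size for the forced-link sweep
#' @param CN,CT drag coefficients (dyn s/cm^2)
#' @return list of per-scenario results
#' @export
run_passive_demos <- function(scenarios = c("forced", "rigid_flow",
                                            "flexible_flow"),
                              n_phi = 16, CN = 10, CT = 5) {
  params <- physical_params(L = 20, N = 40, r = 1, E = 0.7e6)
  drag <- drag_spec("linearized", CN = CN, CT = CT)
  out <- list()
  if ("forced" %in% scenarios) {
    w <- 2 * pi * 2
    phis <- seq(0, 2 * pi, length.out = n_phi + 1)[seq_len(n_phi)]
    rows <- lapply(phis, function(phi) {
      spec <- rigid_forcing_spec(F0 = 1500, T0 = 5e4, phi = phi, omega_f = w)
      ana <- rigid_link_steady_analytic(spec, params, drag)
      num <- simulate_forced_rigid_link(spec, params, drag, t_end = 18)
      data.frame(phi = phi, U_analytic = ana$U, U_numeric = num$U_sim,
                 theta_amp = ana$theta_amp)
    })
    out$forced <- do.call(rbind, rows)
  }
  if ("rigid_flow" %in% scenarios) {
    spec <- external_flow_spec(Vf = 10, lambda_f = 10 * params$L, f_f = 2)
    # half the uniform-rod rotational damping: breaks the uniform-rod drift
    # degeneracy (see simulate_rigid_in_flow) as a tapered body would
    out$rigid_flow <- simulate_rigid_in_flow(spec, params, drag, t_end = 20,
                                             c_r = CN * params$L^3 / 24)
  }
  if ("flexible_flow" %in% scenarios) {
    spec <- external_flow_spec(Vf = 10, lambda_f = params$L / 2, f_f = 2)
    pcal <- calibrate_k_spring(params, drag,
                               activation_spec("none"),
                               model = "leading_order", flow = spec,
                               n_periods = 3)
    out$flexible_flow <- simulate_flexible_in_flow(spec, pcal, drag,
                                                   t_end = 20)
  }
  out
}

#' Gait optimization and its nonlinear cross-check
#'
#' Optimizes the five-parameter gait family from the reference gait and
#' (optionally) replays both gaits as preferred curvature in the nonlinear
#' reduced-order swimmer to confirm that the higher-objective gait swims
#' faster.
#'
#' @param reference reference [gait_params()]
#' @param simulate also run the nonlinear cross-check
#' @param n_periods simulated periods for the cross-check
#' @param n_s,n_t objective quadrature resolution
#' @param extra_starts additional optimizer starts (see [optimize_gait()])
#' @return list with the optimization result and, when simulated,
#'   `U_reference`, `U_optimized` (normalized steady speeds)
#' @export
run_gait_optimization <- function(reference = gait_params(1, 1.5, 2, 2.4,
                                                          tau = 1,
                                                          T = 0.5, L = 20),
                                  simulate = TRUE, n_periods = 5,
                                  n_s = 121, n_t = 64,
                                  extra_starts = list()) {
  opt <- optimize_gait(reference, n_s = n_s, n_t = n_t,
                       extra_starts = extra_starts)
  res <- list(optimization = opt)
  if (simulate) {
    f <- 1 / reference$T
    base <- validation_case(B = 2.5, f = f)
    params <- calibrate_k_spring(base$params, base$drag, base$act)
    sim_u <- function(g) {
      act <- activation_spec("gait_family", f = f, gait = g)
      traj <- integrate_chain("nonlinear", params, base$drag, act,
                              n_periods / f, dt_out = 1 / (100 * f))
      ck <- com_kinematics(traj)
      sel <- ck$t >= (n_periods - 1) / f
      abs(pracma::trapz(ck$t[sel], ck$vx_com[sel]) * f) / (f * params$L)
    }
    res$U_reference <- sim_u(reference)
    res$U_optimized <- sim_u(opt$gait)
  }
  res
}
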