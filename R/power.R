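# Cycle-averaged kinetic-energy / power bookkeeping.

# Instantaneous power channels of a stored trajectory state.
# Mirrors the rotational / transverse / axial kinetic-energy equations:
# muscle activation power enters the rotational channel, is handed to the
# joint springs, and leaves through drag in the transverse and axial
# channels.
instantaneous_power <- function(traj, idx) {
  p <- traj$params
  drag <- traj$drag
  N <- traj$N
  ell <- p$ell
  h <- ell / 2
  EI <- p$E * p$Ic
  k <- p$k_spring
  st <- state_at(traj, idx)
  t <- traj$time[idx]
  th <- st$theta; om <- st$omega; vx <- st$vx; vy <- st$vy
  kap <- diff(th) / ell
  kdot <- diff(om) / ell
  k0 <- preferred_curvature(traj$act, p, t)
  rel <- diff(om)                      # joint relative angular rate
  M_act <- EI * k0
  M_pass <- -EI * kap - p$delta * kdot
  ct <- cos(th); sn <- sin(th)
  zj <- if (is.null(p$zeta_joint)) 1 else p$zeta_joint
  cj <- 2 * zj * sqrt(k * p$m / 2)
  if (traj$model == "nonlinear") {
    gx <- (st$xc[-1] - h * ct[-1]) - (st$xc[-N] + h * ct[-N])
    gy <- (st$yc[-1] - h * sn[-1]) - (st$yc[-N] + h * sn[-N])
    gxd <- diff(vx) + h * (sn[-N] * om[-N] + sn[-1] * om[-1])
    gyd <- diff(vy) - h * (ct[-N] * om[-N] + ct[-1] * om[-1])
  } else {
    gx <- diff(st$xc) - ell + (ell / 4) * (th[-N]^2 + th[-1]^2)
    gy <- diff(st$yc) - h * (th[-N] + th[-1])
    gxd <- diff(vx) + (ell / 2) * (th[-N] * om[-N] + th[-1] * om[-1])
    gyd <- diff(vy) - h * (om[-N] + om[-1])
  }
  Fjx <- k * gx + cj * gxd; Fjy <- k * gy + cj * gyd
  Fr_x <- c(Fjx, 0); Fl_x <- c(0, Fjx)   # joint force at right/left end
  Fr_y <- c(Fjy, 0); Fl_y <- c(0, Fjy)
  # drag forces and moments per link
  if (traj$model == "nonlinear" && drag$variant == "taylor") {
    dr <- oracle_drag(vx, vy, th, om, p, drag)
  } else if (traj$model == "nonlinear") {
    dr <- oracle_drag(vx, vy, th, om, p, drag)  # linear drag, exact frames
  } else {
    ld <- linearized_drag(vy, vx, th, om, drag, p)
    dr <- list(Fx = ld$Fx, Fy = ld$Fy, Mz = ld$Mz)
  }
  spring_mom <- if (traj$model == "nonlinear") {
    h * (ct * (Fr_y + Fl_y) - sn * (Fr_x + Fl_x))
  } else {
    h * (Fr_y + Fl_y)
  }
  list(P_muscle = sum(M_act * rel),
       P_elastic_rot = sum(M_pass * rel) + sum(spring_mom * om) +
         sum(dr$Mz * om),
       P_elastic_trans = sum((Fr_y - Fl_y) * vy),
       P_elastic_axial = sum((Fr_x - Fl_x) * vx),
       P_drag_trans = sum(dr$Fy * vy),
       P_drag_axial = sum(dr$Fx * vx))
}

#' Cycle-averaged power ledger
#'
#' Time-averages the instantaneous power channels over an integer number of
#' forcing periods of a steady swimming cycle.  At steady state the ledger
#' satisfies the balances
#' `P_muscle + P_elastic_rot ~ 0`, `P_elastic_trans + P_drag_trans ~ 0`,
#' `P_elastic_axial + P_drag_axial ~ 0`: muscle power becomes elastic power
#' in the joint springs, which drag then dissipates, mostly transversely.
#' `P_elastic_rot` is the whole non-muscle side of the rotational
#' kinetic-energy equation (passive bending, viscoelasticity, spring
#' moments, rotational drag).
#'
#' @param traj a `swim_trajectory`
#' @param start window start (s), e.g. from [detect_steady_state()]
#' @param period forcing period (s)
#' @param n_periods number of periods to average over (integer)
#' @return object of class `power_ledger`: cycle-averaged channel powers in
#'   erg/s, plus `energy_per_cycle_J` (channel energies over one cycle, J)
#' @export
power_ledger <- function(traj, start, period, n_periods = 1) {
  if (abs(n_periods - round(n_periods)) > 1e-9)
    stop("window must cover an integer number of periods", call. = FALSE)
  t1 <- start + n_periods * period
  if (max(traj$time) < t1 - 1e-9)
    stop("window extends past the trajectory", call. = FALSE)
  sel <- which(traj$time >= start - 1e-12 & traj$time <= t1 + 1e-12)
  tt <- traj$time[sel]
  ch <- c("P_muscle", "P_elastic_rot", "P_elastic_trans", "P_elastic_axial",
          "P_drag_trans", "P_drag_axial")
  series <- vapply(sel, function(i) unlist(instantaneous_power(traj, i)),
                   numeric(length(ch)))
  avg <- apply(series, 1, function(row) pracma::trapz(tt, row)) /
    (max(tt) - min(tt))
  names(avg) <- ch
  out <- as.list(avg)
  out$energy_per_cycle_J <- avg * period * 1e-7
  out$window <- c(start, t1)
  class(out) <- "power_ledger"
  out
}

#' @export
print.power_ledger <- function(x, ...) {
  cat("Cycle-averaged power ledger (erg/s):\n")
  for (nm in c("P_muscle", "P_elastic_rot", "P_elastic_trans",
               "P_elastic_axial", "P_drag_trans", "P_drag_axial"))
    cat(sprintf("  %-16s %+.5g\n", nm, x[[nm]]))
  invisible(x)
}

#' Transverse fraction of drag dissipation
#'
#' @param ledger a [power_ledger()] result
#' @return fraction of the total drag dissipation occurring in the
#'   transverse channel (`NA` with a message if there is no dissipation)
#' @export
dissipation_split <- function(ledger) {
  tot <- abs(ledger$P_drag_trans) + abs(ledger$P_drag_axial)
  if (tot == 0) {
    message("no dissipation in the window; split undefined")
    return(NA_real_)
  }
  abs(ledger$P_drag_trans) / tot
}
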