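# Impedance control with sEMG-scheduled desired force and stiffness, and
# Lyapunov instrumentation.
#
# The control law imposes the desired error dynamics
#   Md e'' + Bd e' + Kd e = -(F - Fd),        e = theta1 - theta1d
# by commanding
#   u = M Gamma1(e) + J^T F + f~ + C thetadot^2 + G,
#   Gamma1 = thetaddot1d - Md^-1 [Bd e' + Kd e + (F - Fd)].
# Against a linear-spring object (F - Fd = K_eff e~ around the contact
# equilibrium) the closed loop is the scalar LTI system
#   e~'' + Bd/Md e~' + (Kd + K_eff)/Md e~ = 0
# whose Lyapunov function V = e~'^2/2 + (Kd + K_eff)/Md e~^2/2 has
# derivative V' = -Bd/Md e~'^2 <= 0 whenever the gains are positive.

#' Impedance parameters
#'
#' @param Md desired inertia (kg m^2), > 0.
#' @param Bd desired damping (N m s/rad), > 0.
#' @param Kd desired stiffness (N m/rad), >= 0.
#' @param Fd desired grasp force (N).
#' @param theta1d,theta1d_dot,theta1d_ddot desired trajectory.
#' @return list of class `impedance_parameters`.
#' @export
impedance_parameters <- function(Md = 0.01, Bd = 0.5, Kd = 50, Fd = 0,
                                 theta1d = 0, theta1d_dot = 0,
                                 theta1d_ddot = 0) {
  if (Md <= 0 || Bd <= 0 || Kd < 0)
    stop("need Md > 0, Bd > 0, Kd >= 0", call. = FALSE)
  structure(list(Md = Md, Bd = Bd, Kd = Kd, Fd = Fd,
                 theta1d = theta1d, theta1d_dot = theta1d_dot,
                 theta1d_ddot = theta1d_ddot),
            class = "impedance_parameters")
}

#' Controller configuration
#'
#' @param Md desired inertia.
#' @param Bd desired damping; ignored when `auto_damping` is on.
#' @param auto_damping if `TRUE`, `Bd = sqrt(4 Md Kd)` (critical damping
#'   of the free error dynamics) is recomputed whenever gains are
#'   scheduled.
#' @param Bd_min damping floor used with auto-damping so `Bd` stays
#'   positive even at `Kd = 0`.
#' @param kd_gain scale from the fuzzy output (0-100 scale) to the
#'   controller stiffness `Kd`; the default 0.3 maps the fuzzy range
#'   onto `Kd` in 0-30 N m/rad, small enough that the scheduled
#'   stiffness shades the contact behaviour without overwhelming the
#'   desired-force term at equilibrium.
#' @param force_gain scale from the estimated human grasp force to `Fd`.
#' @param torque_limit actuator saturation (N m).
#' @param contact_threshold force level declaring contact (N).
#' @param approach_torque constant drive torque before contact (N m).
#' @return list of class `controller_config`.
#' @export
controller_config <- function(Md = 0.01, Bd = 0.5, auto_damping = TRUE,
                              Bd_min = 0.05, kd_gain = 0.3, force_gain = 1,
                              torque_limit = 2, contact_threshold = 0.05,
                              approach_torque = 0.01) {
  structure(list(Md = Md, Bd = Bd, auto_damping = auto_damping,
                 Bd_min = Bd_min, kd_gain = kd_gain,
                 force_gain = force_gain, torque_limit = torque_limit,
                 contact_threshold = contact_threshold,
                 approach_torque = approach_torque),
            class = "controller_config")
}

#' Schedule impedance gains from the sEMG estimates
#'
#' Maps the estimated grasp force and the fuzzy controller-stiffness
#' output to the impedance parameters: `Fd = force_gain * F_est`,
#' `Kd = kd_gain * Kd_tilde`, with damping either fixed or set for
#' critical damping `Bd = sqrt(4 Md Kd)`.
#'
#' @param F_est estimated human grasp force (N), >= 0.
#' @param Kd_tilde fuzzy controller-stiffness output (0-100 scale).
#' @param cfg a [controller_config()].
#' @param theta1d desired (frozen) drive angle.
#' @return an [impedance_parameters()] object.
#' @export
schedule_gains <- function(F_est, Kd_tilde, cfg = controller_config(),
                           theta1d = 0) {
  stopifnot(inherits(cfg, "controller_config"))
  if (F_est < 0) stop("F_est must be non-negative", call. = FALSE)
  Kd <- cfg$kd_gain * Kd_tilde
  Bd <- if (cfg$auto_damping) max(sqrt(4 * cfg$Md * Kd), cfg$Bd_min) else cfg$Bd
  impedance_parameters(Md = cfg$Md, Bd = Bd, Kd = Kd,
                       Fd = cfg$force_gain * F_est, theta1d = theta1d)
}

#' Impedance control command
#'
#' Assembles the joint torque
#' `u = M Gamma1 + J^T F n + f~ + C thetadot^2 + G` with
#' `Gamma1 = thetaddot1d - Md^-1 [Bd e' + Kd e + (F - Fd)]`. The
#' contact force enters the compensation as the joint torque `(J . n) F`
#' of the normal force. Saturation at the torque limit is flagged.
#'
#' @param state a [finger_state()].
#' @param dyn [dynamics_matrices()] at this state.
#' @param F measured contact force (N).
#' @param imp [impedance_parameters()].
#' @param friction friction torque `f~` to compensate (N m).
#' @param normal unit contact normal (for the Jacobian projection).
#' @param torque_limit saturation level (N m).
#' @return list of class `control_command`: `u` plus the individual
#'   `feedback`, `force_comp`, `friction_comp`, `dynamics_comp` terms
#'   and a `saturated` flag.
#' @export
impedance_command <- function(state, dyn, F, imp, friction = 0,
                              normal = c(0, 1), torque_limit = 2) {
  stopifnot(inherits(imp, "impedance_parameters"))
  e <- state$theta1 - imp$theta1d
  e_dot <- state$theta1_dot - imp$theta1d_dot
  gamma1 <- imp$theta1d_ddot -
    (imp$Bd * e_dot + imp$Kd * e + (F - imp$Fd)) / imp$Md
  jeff <- sum(dyn$J * normal)
  feedback <- dyn$M * gamma1
  force_comp <- jeff * F
  dynamics_comp <- dyn$C * state$theta1_dot^2 + dyn$G
  u <- feedback + force_comp + friction + dynamics_comp
  saturated <- abs(u) > torque_limit
  structure(list(u = clamp(u, -torque_limit, torque_limit),
                 feedback = feedback, force_comp = force_comp,
                 friction_comp = friction, dynamics_comp = dynamics_comp,
                 saturated = saturated),
            class = "control_command")
}

#' Lyapunov function of the contact error dynamics
#'
#' `V = e_dot^2 / 2 + (Kd + K_eff) / Md * e^2 / 2` and
#' `Vdot = -Bd / Md * e_dot^2`, evaluated with the scheduled stiffness
#' and the effective (joint-space) contact stiffness. `V >= 0` and
#' `Vdot <= 0` hold whenever `(Kd + K_eff)/Md > 0` and `Bd/Md > 0`.
#'
#' @param e position error (rad), measured from the contact equilibrium.
#' @param e_dot error rate (rad/s).
#' @param Kd scheduled controller stiffness.
#' @param K_eff effective contact stiffness seen at the joint.
#' @param Md,Bd desired inertia and damping.
#' @return list with `V` and `Vdot`.
#' @export
lyapunov <- function(e, e_dot, Kd, K_eff, Md, Bd) {
  if (Md <= 0) stop("Md must be positive", call. = FALSE)
  list(V = 0.5 * e_dot^2 + 0.5 * (Kd + K_eff) / Md * e^2,
       Vdot = -Bd / Md * e_dot^2)
}

#' Closed-loop contact error simulation (scalar impedance model)
#'
#' Integrates the error dynamics
#' `e'' = -Bd/Md e' - (Kd + K_eff)/Md e` -- the closed loop obtained
#' under perfect model compensation against a linear-spring contact --
#' with fixed-step RK4, and samples the Lyapunov pair at `sample_dt`.
#'
#' @param imp [impedance_parameters()].
#' @param K_eff effective contact stiffness at the joint (>= 0).
#' @param e0,edot0 initial error and error rate.
#' @param dt integration step (s).
#' @param t_end duration (s).
#' @param sample_dt sampling period of the returned trace (s); must be
#'   a multiple of `dt`.
#' @return data.frame with `time`, `e`, `e_dot`, `V`, `Vdot`.
#' @export
simulate_impedance_response <- function(imp, K_eff, e0 = 0.1, edot0 = 0,
                                        dt = 1e-4, t_end = 2,
                                        sample_dt = 1e-3) {
  stopifnot(inherits(imp, "impedance_parameters"), K_eff >= 0)
  b <- imp$Bd / imp$Md
  k <- (imp$Kd + K_eff) / imp$Md
  stride <- round(sample_dt / dt)
  if (abs(stride * dt - sample_dt) > 1e-12)
    stop("sample_dt must be a multiple of dt", call. = FALSE)
  nt <- round(t_end / dt)
  keep <- seq(0, nt, by = stride)
  x <- c(e0, edot0)
  deriv <- function(t, x) c(x[2], -b * x[2] - k * x[1])
  E <- matrix(0, length(keep), 2)
  E[1, ] <- x
  row <- 2
  for (i in seq_len(nt)) {
    x <- rk4_step(deriv, (i - 1) * dt, x, dt)
    if (row <= length(keep) && i == keep[row]) {
      E[row, ] <- x
      row <- row + 1
    }
  }
  ly <- lyapunov(E[, 1], E[, 2], imp$Kd, K_eff, imp$Md, imp$Bd)
  data.frame(time = keep * dt, e = E[, 1], e_dot = E[, 2],
             V = ly$V, Vdot = ly$Vdot)
}

#' Closed-form solution of the contact error dynamics
#'
#' Analytic solution of `e'' + Bd/Md e' + (Kd + K_eff)/Md e = 0` from
#' `(e0, edot0)`, via the (possibly complex) characteristic roots; used
#' as the oracle for the simulated response.
#'
#' @inheritParams simulate_impedance_response
#' @param times evaluation times (s).
#' @return numeric vector `e(times)`.
#' @export
closed_form_error <- function(imp, K_eff, e0 = 0.1, edot0 = 0, times) {
  b <- imp$Bd / imp$Md
  k <- (imp$Kd + K_eff) / imp$Md
  disc <- sqrt(as.complex(b^2 - 4 * k))
  s1 <- (-b + disc) / 2
  s2 <- (-b - disc) / 2
  if (abs(s1 - s2) < 1e-9 * max(1, abs(s1))) {
    # repeated root: e = (c1 + c2 t) exp(s t)
    c1 <- e0
    c2 <- edot0 - s1 * e0
    return(Re((c1 + c2 * times) * exp(s1 * times)))
  }
  c2 <- (edot0 - s1 * e0) / (s2 - s1)
  c1 <- e0 - c2
  Re(c1 * exp(s1 * times) + c2 * exp(s2 * times))
}
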