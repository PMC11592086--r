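# Kinematics and single-coordinate Lagrangian dynamics of the linkage
# finger. One actuated joint angle theta1 drives every link through a
# coupling map theta_n(theta1); positions are evaluated as planar
# rotations in complex arithmetic, with first and second sensitivities
# d/dtheta1 tracked analytically so the generalized mass M(theta1), the
# velocity coefficient C = dM/dtheta1 / 2, the gravity torque G and the
# contact Jacobian are all closed form.

#' Link parameters of the finger
#'
#' Default geometry is a plausible finger-scale five-link chain
#' (lengths 10-40 mm, ~60 g total) standing in for the closed-chain
#' linkage: every quantity needed by the dynamics is expressed through
#' the coupling map, so a measured four-bar closure can be substituted
#' without touching the dynamics code.
#'
#' @param lengths link lengths l_n (m).
#' @param masses link masses m_n (kg).
#' @param inertias link moments of inertia about the centroid (kg m^2);
#'   default slender-rod value `m l^2 / 12`.
#' @param centroid_offset distance from the geometric center to the
#'   centroid (m).
#' @param centroid_angle angular offset of the centroid (rad).
#' @param gravity gravitational acceleration (m/s^2).
#' @param viscous viscous friction coefficient at the drive (N m s/rad).
#' @param coulomb Coulomb friction level (N m).
#' @return list of class `finger_links`.
#' @export
finger_links <- function(lengths = c(0.012, 0.030, 0.022, 0.010, 0.018),
                         masses = c(0.010, 0.018, 0.012, 0.006, 0.014),
                         inertias = masses * lengths^2 / 12,
                         centroid_offset = rep(0.002, 5),
                         centroid_angle = rep(0.05, 5),
                         gravity = 9.81,
                         viscous = 0.02, coulomb = 0.002) {
  n <- length(lengths)
  stopifnot(n >= 1, length(masses) == n, length(inertias) == n,
            length(centroid_offset) == n, length(centroid_angle) == n)
  if (any(lengths <= 0) || any(masses <= 0) || any(inertias <= 0))
    stop("lengths, masses and inertias must be positive", call. = FALSE)
  structure(list(lengths = lengths, masses = masses, inertias = inertias,
                 centroid_offset = centroid_offset,
                 centroid_angle = centroid_angle,
                 gravity = gravity, viscous = viscous, coulomb = coulomb,
                 n = n),
            class = "finger_links")
}

#' Coupling map from the drive angle to all link angles
#'
#' `coupling_map()` wraps arbitrary differentiable functions
#' `theta(theta1)`, `dtheta(theta1)`, `d2theta(theta1)` (each returning
#' one value per link); `linear_coupling()` builds the default affine
#' map `theta_n = c_n theta1 + theta0_n`.
#'
#' @param theta,dtheta,d2theta functions of `theta1` returning the link
#'   angles and their first/second derivatives.
#' @param range admissible `theta1` operating range (rad).
#' @return list of class `coupling_map`.
#' @export
coupling_map <- function(theta, dtheta, d2theta, range = c(-0.3, 1.6)) {
  stopifnot(is.function(theta), is.function(dtheta), is.function(d2theta))
  structure(list(theta = theta, dtheta = dtheta, d2theta = d2theta,
                 range = range),
            class = "coupling_map")
}

#' @rdname coupling_map
#' @param coeffs per-link coupling coefficients `c_n`; the distal links
#'   of an underactuated finger typically rotate faster than the drive.
#' @param offsets per-link angle offsets at `theta1 = 0` (straight
#'   finger reference pose).
#' @export
linear_coupling <- function(coeffs = c(1, 0.7, 1.3, 0.5, 0.9),
                            offsets = rep(0, length(coeffs)),
                            range = c(-0.3, 1.6)) {
  force(coeffs); force(offsets)
  coupling_map(
    theta = function(theta1) coeffs * theta1 + offsets,
    dtheta = function(theta1) coeffs,
    d2theta = function(theta1) numeric(length(coeffs)),
    range = range)
}

#' Full joint configuration for a drive angle
#'
#' @param theta1 drive angle (rad); must lie in the map's range.
#' @param map a [coupling_map()].
#' @return list of class `finger_config` with `theta1`, `theta`,
#'   `dtheta`, `d2theta`.
#' @export
coupled_configuration <- function(theta1, map) {
  stopifnot(inherits(map, "coupling_map"))
  if (theta1 < map$range[1] || theta1 > map$range[2])
    stop(sprintf("theta1 = %.3f rad outside operating range [%.3f, %.3f]",
                 theta1, map$range[1], map$range[2]), call. = FALSE)
  structure(list(theta1 = theta1,
                 theta = map$theta(theta1),
                 dtheta = map$dtheta(theta1),
                 d2theta = map$d2theta(theta1)),
            class = "finger_config")
}

# Chain kinematics with analytic first and second theta1-sensitivities.
# Links are chained serially: link n starts where link n-1 ends. Complex
# numbers encode planar points; derivatives of exp(i theta_n) follow
# the chain rule through dtheta_n/dtheta1.
chain_kinematics <- function(config, links) {
  stopifnot(inherits(config, "finger_config"), inherits(links, "finger_links"))
  n <- links$n
  e <- exp(1i * config$theta)
  e_d <- 1i * config$dtheta * e
  e_dd <- (1i * config$d2theta - config$dtheta^2) * e
  base <- base_d <- base_dd <- complex(n + 1)
  for (k in seq_len(n)) {
    base[k + 1] <- base[k] + links$lengths[k] * e[k]
    base_d[k + 1] <- base_d[k] + links$lengths[k] * e_d[k]
    base_dd[k + 1] <- base_dd[k] + links$lengths[k] * e_dd[k]
  }
  center <- base[1:n] + 0.5 * links$lengths * e
  center_d <- base_d[1:n] + 0.5 * links$lengths * e_d
  center_dd <- base_dd[1:n] + 0.5 * links$lengths * e_dd
  et <- exp(1i * (config$theta + links$centroid_angle))
  et_d <- 1i * config$dtheta * et
  et_dd <- (1i * config$d2theta - config$dtheta^2) * et
  centroid <- center + links$centroid_offset * et
  centroid_d <- center_d + links$centroid_offset * et_d
  centroid_dd <- center_dd + links$centroid_offset * et_dd
  list(e = e, e_d = e_d,
       base = base, base_d = base_d, base_dd = base_dd,
       center = center, center_d = center_d,
       centroid = centroid, centroid_d = centroid_d,
       centroid_dd = centroid_dd)
}

#' Link centroid positions and sensitivities
#'
#' Places each centroid at
#' `(x_n, y_n) + l~_n exp(i (theta_n + theta~_n))` relative to the link
#' geometric center and differentiates through the coupling map.
#'
#' @param config a [coupled_configuration()].
#' @param links a [finger_links()].
#' @param theta1_dot optional drive velocity; when given, centroid
#'   velocities are included.
#' @return data.frame with `x`, `y`, `dx_dtheta1`, `dy_dtheta1` (and
#'   `vx`, `vy` when `theta1_dot` is supplied).
#' @export
centroid_positions <- function(config, links, theta1_dot = NULL) {
  kin <- chain_kinematics(config, links)
  out <- data.frame(x = Re(kin$centroid), y = Im(kin$centroid),
                    dx_dtheta1 = Re(kin$centroid_d),
                    dy_dtheta1 = Im(kin$centroid_d))
  if (!is.null(theta1_dot)) {
    out$vx <- out$dx_dtheta1 * theta1_dot
    out$vy <- out$dy_dtheta1 * theta1_dot
  }
  out
}

#' Contact pad geometry
#'
#' The contact point sits at the tip of the distal phalanx (link 3):
#' geometric center plus half a link length along the link, plus a pad
#' offset `lp` in the fixed direction `theta_p`.
#'
#' @param lp pad offset (m), >= 0.
#' @param theta_p pad direction (rad, world frame).
#' @return list of class `contact_geometry`.
#' @export
contact_geometry <- function(lp = 0.004, theta_p = 1.0) {
  if (lp < 0) stop("lp must be non-negative", call. = FALSE)
  structure(list(lp = lp, theta_p = theta_p), class = "contact_geometry")
}

#' Fingertip contact point
#'
#' @param config a [coupled_configuration()].
#' @param geom a [contact_geometry()].
#' @param links a [finger_links()].
#' @param theta1_dot optional drive velocity for point velocities.
#' @return list with `p` (x, y), `dp_dtheta1`, and `v` when
#'   `theta1_dot` is given.
#' @export
contact_point <- function(config, geom, links, theta1_dot = NULL) {
  stopifnot(inherits(geom, "contact_geometry"))
  kin <- chain_kinematics(config, links)
  zp <- kin$center[3] + 0.5 * links$lengths[3] * kin$e[3] +
    geom$lp * exp(1i * geom$theta_p)
  zp_d <- kin$center_d[3] + 0.5 * links$lengths[3] * kin$e_d[3]
  out <- list(p = c(Re(zp), Im(zp)), dp_dtheta1 = c(Re(zp_d), Im(zp_d)))
  if (!is.null(theta1_dot)) out$v <- out$dp_dtheta1 * theta1_dot
  out
}

#' Contact Jacobian
#'
#' The 2x1 Jacobian `J = d(xp, yp)/dtheta1` mapping drive velocity to
#' contact-point velocity through the coupling map.
#'
#' @inheritParams contact_point
#' @return numeric length-2 vector.
#' @export
contact_jacobian <- function(config, geom, links) {
  contact_point(config, geom, links)$dp_dtheta1
}

#' Generalized dynamics in the drive coordinate
#'
#' Reduces the five-link Lagrangian through the coupling map: kinetic
#' energy `T = M(theta1) thetadot1^2 / 2` with
#' `M = sum I_n (dtheta_n/dtheta1)^2 + m_n |d centroid_n / dtheta1|^2`,
#' `C = dM/dtheta1 / 2`, and gravity torque
#' `G = sum m_n g d y~_n/dtheta1`, so the equation of motion is
#' `M thetaddot1 + C thetadot1^2 + G = tau1 - J^T F - f`.
#'
#' @param state list with `theta1` (rad) and `theta1_dot` (rad/s), e.g.
#'   [finger_state()].
#' @param map a [coupling_map()].
#' @param links a [finger_links()].
#' @param geom a [contact_geometry()] for the Jacobian.
#' @return list of class `dynamics_matrices` with scalars `M`, `C`,
#'   `G` and the 2-vector `J`.
#' @export
dynamics_matrices <- function(state, map, links, geom = contact_geometry()) {
  config <- coupled_configuration(state$theta1, map)
  kin <- chain_kinematics(config, links)
  M <- sum(links$inertias * config$dtheta^2 +
             links$masses * Mod(kin$centroid_d)^2)
  if (M <= 0) stop("non-positive generalized mass; check link parameters",
                   call. = FALSE)
  dM <- sum(2 * links$inertias * config$dtheta * config$d2theta +
              2 * links$masses * Re(Conj(kin$centroid_d) * kin$centroid_dd))
  G <- sum(links$masses * links$gravity * Im(kin$centroid_d))
  zp_d <- kin$center_d[3] + 0.5 * links$lengths[3] * kin$e_d[3]
  structure(list(M = M, C = dM / 2, G = G, J = c(Re(zp_d), Im(zp_d))),
            class = "dynamics_matrices")
}

#' Finger state
#'
#' @param theta1 drive angle (rad).
#' @param theta1_dot drive velocity (rad/s).
#' @return list of class `finger_state`.
#' @export
finger_state <- function(theta1 = 0, theta1_dot = 0) {
  structure(list(theta1 = theta1, theta1_dot = theta1_dot),
            class = "finger_state")
}

# Joint friction torque: viscous plus smoothed Coulomb.
friction_torque <- function(theta1_dot, links) {
  links$viscous * theta1_dot + links$coulomb * tanh(theta1_dot / 0.01)
}

#' Virtual grasped object
#'
#' A frictionless linear-spring surface: contact force
#' `F = K max(0, penetration)` along the fixed contact normal.
#'
#' @param surface_position surface coordinate along the normal (m).
#' @param stiffness object stiffness K (N/m), > 0.
#' @param label object name for reports.
#' @param normal unit contact normal (default `c(0, 1)`).
#' @return list of class `object_model`.
#' @export
object_model <- function(surface_position, stiffness, label = "object",
                         normal = c(0, 1)) {
  if (stiffness <= 0) stop("object stiffness must be positive", call. = FALSE)
  normal <- normal / sqrt(sum(normal^2))
  structure(list(surface_position = surface_position, stiffness = stiffness,
                 label = label, normal = normal),
            class = "object_model")
}

#' Contact force at a fingertip position
#'
#' @param xp_yp fingertip position, length-2 vector (m).
#' @param object an [object_model()].
#' @return normal contact force (N), zero out of contact.
#' @export
contact_force <- function(xp_yp, object) {
  stopifnot(inherits(object, "object_model"))
  pen <- sum(object$normal * xp_yp) - object$surface_position
  object$stiffness * max(0, pen)
}

#' Total mechanical energy of the finger
#'
#' `E = M(theta1) theta1_dot^2 / 2 + sum m_n g y~_n`; conserved in a
#' frictionless free swing.
#'
#' @inheritParams dynamics_matrices
#' @return energy in joules.
#' @export
finger_energy <- function(state, map, links) {
  config <- coupled_configuration(state$theta1, map)
  kin <- chain_kinematics(config, links)
  dyn <- dynamics_matrices(state, map, links)
  0.5 * dyn$M * state$theta1_dot^2 +
    sum(links$masses * links$gravity * Im(kin$centroid))
}

#' Free swing of the unforced finger
#'
#' Integrates `M thetaddot + C thetadot^2 + G = 0` (no drive, contact
#' or friction) with fixed-step RK4; used to verify energy conservation
#' of the reduced Lagrangian.
#'
#' @param state initial [finger_state()].
#' @param map a [coupling_map()].
#' @param links a [finger_links()].
#' @param t_end duration (s).
#' @param dt step (s).
#' @return data.frame with `time`, `theta1`, `theta1_dot`, `energy`.
#' @export
simulate_free_swing <- function(state, map, links, t_end = 1, dt = 1e-4) {
  nt <- round(t_end / dt)
  out <- matrix(0, nt + 1, 3)
  x <- c(state$theta1, state$theta1_dot)
  deriv <- function(t, x) {
    dyn <- dynamics_matrices(finger_state(x[1], x[2]), map, links)
    c(x[2], (-dyn$C * x[2]^2 - dyn$G) / dyn$M)
  }
  out[1, ] <- c(x, finger_energy(finger_state(x[1], x[2]), map, links))
  for (i in seq_len(nt)) {
    x <- rk4_step(deriv, (i - 1) * dt, x, dt)
    out[i + 1, ] <- c(x, finger_energy(finger_state(x[1], x[2]), map, links))
  }
  data.frame(time = seq(0, by = dt, length.out = nt + 1),
             theta1 = out[, 1], theta1_dot = out[, 2], energy = out[, 3])
}
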