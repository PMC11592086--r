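# Muscle stiffness estimation from the force trace via the Hill
# force-velocity relation: stiffness is the windowed force change per
# unit muscle shortening, K(t) = dF / dX, with the shortening dX
# obtained by integrating the Hill velocity over the window.

#' Hill force-velocity parameters
#'
#' The hyperbolic Hill relation `(F + Fa)(v + vb) = (F0 + Fa) vb` links
#' muscle force to shortening velocity: at the maximum isometric force
#' `F0` the velocity is zero, and lighter loads shorten faster.
#'
#' @param F0 maximum isometric force (N).
#' @param Fa force offset of the hyperbola (N).
#' @param vb velocity offset (normalized muscle lengths per second).
#' @return list of class `hill_parameters`.
#' @export
hill_parameters <- function(F0 = 10, Fa = 4, vb = 0.1) {
  if (F0 <= 0 || Fa <= 0 || vb <= 0)
    stop("F0, Fa and vb must all be positive", call. = FALSE)
  structure(list(F0 = F0, Fa = Fa, vb = vb), class = "hill_parameters")
}

#' Stiffness estimation configuration
#'
#' @param window_T sliding-window length in seconds over which force
#'   change and muscle shortening are measured; default 0.1 s.
#' @param k_max maximum measured muscle stiffness (N per normalized
#'   length) used to normalize `Ka = K / k_max`; obtain it with
#'   [calibrate_kmax()].
#' @param dka_scale full-scale rate for the normalized stiffness change,
#'   in 1/s; `dKa = clamp((Ka(t) - Ka(t-T)) / T / dka_scale, 0, 1)`.
#' @param strict if `TRUE`, forces outside `[0, F0]` raise an error
#'   instead of a warning before clamping.
#' @return list of class `stiffness_config`.
#' @export
stiffness_config <- function(window_T = 0.1, k_max = 1, dka_scale = 5,
                             strict = FALSE) {
  if (window_T <= 0 || k_max <= 0 || dka_scale <= 0)
    stop("window_T, k_max and dka_scale must be positive", call. = FALSE)
  structure(list(window_T = window_T, k_max = k_max,
                 dka_scale = dka_scale, strict = strict),
            class = "stiffness_config")
}

check_force_range <- function(F, hill, strict = FALSE) {
  if (any(F < 0 | F > hill$F0)) {
    msg <- "force outside [0, F0]; clamping"
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  clamp_force(F, hill)
}

#' Hill shortening velocity
#'
#' `v(F) = vb (F0 + Fa) / (Fa + F) - vb`; strictly decreasing in `F`,
#' with `v(F0) = 0` exactly.
#'
#' @param F muscle force (N), clamped to `[0, F0]`.
#' @param hill [hill_parameters()].
#' @param strict raise instead of warn on out-of-range force.
#' @return shortening velocity in normalized lengths per second.
#' @examples
#' shortening_velocity(6, hill_parameters(F0 = 10, Fa = 4, vb = 0.1)) # 0.04
#' @export
shortening_velocity <- function(F, hill, strict = FALSE) {
  stopifnot(inherits(hill, "hill_parameters"))
  F <- check_force_range(F, hill, strict)
  hill$vb * (hill$F0 + hill$Fa) / (hill$Fa + F) - hill$vb
}

#' Muscle shortening over a force-trace window
#'
#' Trapezoidal quadrature of
#' `dX = vb * integral (F0 - F(t)) / (Fa + F(t)) dt` over the supplied
#' window; always non-negative, and zero only when `F` sits at `F0`
#' throughout.
#'
#' @param trace `force_trace` segment (columns `time`, `force`) covering
#'   exactly the window of interest.
#' @param hill [hill_parameters()].
#' @param strict raise instead of warn on out-of-range force.
#' @return shortening in normalized muscle lengths.
#' @export
contraction_displacement <- function(trace, hill, strict = FALSE) {
  stopifnot(is.data.frame(trace), all(c("time", "force") %in% names(trace)))
  if (nrow(trace) < 2) stop("window must contain at least two samples", call. = FALSE)
  F <- check_force_range(trace$force, hill, strict)
  integrand <- hill$vb * (hill$F0 - F) / (hill$Fa + F)
  dt <- diff(trace$time)
  sum((integrand[-1] + integrand[-length(integrand)]) / 2 * dt)
}

#' Windowed muscle stiffness
#'
#' `K(t) = dF / dX` with `dF = F(t) - F(t - T)` and `dX` the Hill
#' shortening over `[t - T, t]`. Negative force changes (relaxation) map
#' to `K = 0`, keeping the stiffness usable as a non-negative controller
#' gain.
#'
#' @param trace full `force_trace` (columns `time`, `force`).
#' @param t evaluation time (s); must be at least `window_T` after the
#'   trace start.
#' @param cfg [stiffness_config()].
#' @param hill [hill_parameters()].
#' @param eps_x smallest admissible shortening; an error is raised below
#'   it (only possible when `F` is pinned at `F0` across the window).
#' @return stiffness in N per normalized muscle length.
#' @export
estimate_stiffness <- function(trace, t, cfg, hill, eps_x = 1e-9) {
  stopifnot(inherits(cfg, "stiffness_config"))
  t0 <- t - cfg$window_T
  if (t0 < min(trace$time) - 1e-12)
    stop("window extends before the start of the trace", call. = FALSE)
  idx <- trace$time >= t0 - 1e-12 & trace$time <= t + 1e-12
  win <- trace[idx, , drop = FALSE]
  if (nrow(win) < 2) stop("window contains fewer than two samples", call. = FALSE)
  dX <- contraction_displacement(win, hill)
  if (dX < eps_x)
    stop("undefined stiffness: no measurable shortening over the window",
         call. = FALSE)
  dF <- win$force[nrow(win)] - win$force[1]
  if (dF <= 0) 0 else dF / dX
}

#' Normalize stiffness to the calibrated maximum
#'
#' `Ka = clamp(K / k_max, 0, 1)`. When `K_prev` (the stiffness one
#' window earlier) is supplied, the normalized change rate
#' `dKa = clamp((Ka - Ka_prev) / T / dka_scale, 0, 1)` is also returned.
#'
#' @param K stiffness value(s), N per normalized length.
#' @param cfg [stiffness_config()].
#' @param K_prev stiffness one window earlier (optional).
#' @return list with `Ka` (and `dKa` when `K_prev` given).
#' @export
normalize_stiffness <- function(K, cfg, K_prev = NULL) {
  stopifnot(inherits(cfg, "stiffness_config"))
  Ka <- clamp(K / cfg$k_max, 0, 1)
  out <- list(Ka = Ka)
  if (!is.null(K_prev)) {
    Ka_prev <- clamp(K_prev / cfg$k_max, 0, 1)
    out$dKa <- clamp((Ka - Ka_prev) / cfg$window_T / cfg$dka_scale, 0, 1)
  }
  out
}

#' Stiffness estimate along a whole force trace
#'
#' Vectorized sliding-window evaluation of [estimate_stiffness()] and
#' [normalize_stiffness()] on a uniformly sampled force trace. Samples
#' whose window (or previous window, for `dKa`) is not yet available
#' report 0.
#'
#' @inheritParams estimate_stiffness
#' @return data.frame of class `stiffness_estimate` with columns `time`,
#'   `K`, `Ka`, `dKa`.
#' @export
stiffness_trace <- function(trace, cfg, hill) {
  stopifnot(is.data.frame(trace), is_uniform_grid(trace$time))
  dt <- mean(diff(trace$time))
  w <- round(cfg$window_T / dt)
  if (w < 1) stop("window_T shorter than the trace sampling step", call. = FALSE)
  n <- nrow(trace)
  F <- clamp_force(trace$force, hill)
  integrand <- hill$vb * (hill$F0 - F) / (hill$Fa + F)
  cum <- c(0, cumsum((integrand[-1] + integrand[-n]) / 2 * dt))
  K <- numeric(n)
  i <- seq(w + 1, n)
  dX <- cum[i] - cum[i - w]
  dF <- F[i] - F[i - w]
  K[i] <- ifelse(dF <= 0 | dX < 1e-9, 0, dF / pmax(dX, 1e-12))
  Ka <- clamp(K / cfg$k_max, 0, 1)
  dKa <- numeric(n)
  j <- seq(2 * w + 1, n)
  if (length(j) > 0)
    dKa[j] <- clamp((Ka[j] - Ka[j - w]) / cfg$window_T / cfg$dka_scale, 0, 1)
  structure(data.frame(time = trace$time, K = K, Ka = Ka, dKa = dKa),
            class = c("stiffness_estimate", "data.frame"))
}

#' Calibrate the maximum muscle stiffness
#'
#' Runs the reduced muscle model through a brisk maximal contraction --
#' a ramp to full activation over `t_rise` seconds, emulating the
#' fastest voluntary effort of a calibration protocol -- and returns
#' the maximum windowed stiffness observed, the `k_max` used to
#' normalize `Ka`. (An instantaneous activation step would put all of
#' the force rise inside a single window and yield a maximum far above
#' anything a voluntary contraction produces, crushing every grasp-level
#' `Ka` toward zero.)
#'
#' @param model a calibrated `reduced_muscle_model`.
#' @param hill [hill_parameters()].
#' @param window_T stiffness window (s), default 0.1.
#' @param t_step time of the contraction onset (s).
#' @param t_rise ramp duration of the calibration effort (s); default
#'   0.4, a brisk voluntary effort.
#' @param r_max activation plateau of the calibration effort; default
#'   0.9. Staying below full activation keeps the force off the `F0`
#'   saturation, where the shortening vanishes and the windowed
#'   stiffness is undefined.
#' @param t_end calibration run duration (s).
#' @param dt simulation step (s).
#' @return maximum stiffness (N per normalized length).
#' @export
calibrate_kmax <- function(model, hill, window_T = 0.1, t_step = 0.2,
                           t_rise = 0.4, r_max = 0.9, t_end = 1.5,
                           dt = 1e-3) {
  tt <- seq(0, t_end, by = dt)
  act <- data.frame(time = tt,
                    r = r_max * clamp((tt - t_step) / t_rise, 0, 1))
  tr <- simulate_reduced(model, act, hill, dt)
  st <- stiffness_trace(tr, stiffness_config(window_T = window_T), hill)
  max(st$K)
}
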