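# Huxley cross-bridge muscle model: full bond-distribution PDE, spectral
# discretization, balanced-truncation reduction to a low-order model, and
# force simulation closed through the Hill force-velocity relation.
#
# The bond-distribution PDE is
#   dp/dt - v(t) dp/dx = r(t) f(x) [1 - p] - g(x) p
# with p(x, t) the fraction of attached cross-bridges at normalized bond
# displacement x, r(t) the neural activation, f the attachment rate and
# g the detachment rate. Force is the scaled first moment of p. The
# shortening velocity v is closed through the Hill relation
# v = vb (F0 + Fa) / (Fa + F) - vb at every step.

#' Huxley model parameters
#'
#' Rate functions follow the classical piecewise-linear forms:
#' `f(x) = f1 * x` on `0 <= x <= 1` (zero elsewhere) and
#' `g(x) = g1 * x` for `x >= 0`, `g(x) = g2` for `x < 0`.
#'
#' The defaults use a detachment-dominated rate balance (`f1/g1 = 0.1`),
#' which keeps the activation-frozen linearization used for model
#' reduction close to the bilinear dynamics across the whole activation
#' range (see the package vignette). They are engineering defaults, not
#' subject-identified values.
#'
#' @param gamma activation shape constant shared with [activation()].
#' @param f1 attachment rate slope (1/s) on the power-stroke region.
#' @param g1 detachment rate slope (1/s) for `x >= 0`.
#' @param g2 detachment rate (1/s) for `x < 0`.
#' @param x_min,x_max normalized bond-displacement domain; must satisfy
#'   `x_min < 0 < 1 <= x_max`.
#' @param force_scale N per unit first moment of p; if `NULL` it is
#'   calibrated so that the isometric force at full activation equals
#'   the Hill `F0`.
#' @return list of class `huxley_parameters`.
#' @export
huxley_parameters <- function(gamma = -3, f1 = 5, g1 = 50, g2 = 100,
                              x_min = -1, x_max = 2, force_scale = NULL) {
  if (any(c(f1, g1, g2) <= 0)) stop("rate constants must be positive", call. = FALSE)
  if (!(x_min < 0 && 1 <= x_max))
    stop("domain must satisfy x_min < 0 < 1 <= x_max", call. = FALSE)
  structure(list(gamma = gamma, f1 = f1, g1 = g1, g2 = g2,
                 x_min = x_min, x_max = x_max, force_scale = force_scale),
            class = "huxley_parameters")
}

attach_rate <- function(x, params) {
  ifelse(x >= 0 & x <= 1, params$f1 * x, 0)
}

detach_rate <- function(x, params) {
  ifelse(x >= 0, params$g1 * x, params$g2)
}

#' Spectral discretization of the bond-distribution PDE
#'
#' Chebyshev collocation of the Huxley PDE on `[x_min, x_max]`. Returns
#' the linear operators of the activation-frozen form
#' `dp/dt = (R0 + v D) p + r b`, where `R0 = -diag(r_nominal f + g)` is
#' the reaction operator frozen at the nominal activation, `D` is the
#' spectral differentiation operator and `b = f` is the attachment
#' input. At `r = r_nominal` the frozen form reproduces the nonlinear
#' right-hand side exactly.
#'
#' @param params [huxley_parameters()].
#' @param n_grid number of collocation points (>= 16).
#' @param r_nominal activation level at which the bilinear reaction term
#'   is frozen for the linear operators; default 0.7 (mid-range of
#'   typical grasp efforts).
#' @return list of class `huxley_operators` with `grid` (descending
#'   nodes), `D`, `R0`, `b`, quadrature `weights`, rate vectors `f`,
#'   `g`, and `r_nominal`.
#' @export
spectral_discretize <- function(params, n_grid = 64, r_nominal = 0.7) {
  stopifnot(inherits(params, "huxley_parameters"))
  if (n_grid < 16) stop("n_grid must be >= 16", call. = FALSE)
  if (params$x_min >= params$x_max)
    stop("degenerate domain: x_min >= x_max", call. = FALSE)
  cb <- cheb_collocation(n_grid, params$x_min, params$x_max)
  f <- attach_rate(cb$x, params)
  g <- detach_rate(cb$x, params)
  structure(list(grid = cb$x, D = cb$D,
                 R0 = -diag(r_nominal * f + g),
                 b = f,
                 weights = cc_quad_weights(n_grid, params$x_min, params$x_max),
                 f = f, g = g, r_nominal = r_nominal, params = params),
            class = "huxley_operators")
}

# First-moment force functional on the collocation grid (N per unit scale).
moment_functional <- function(ops) ops$weights * ops$grid

# Pointwise isometric steady state p = r f / (r f + g) (0 where both
# rates vanish).
isometric_steady_state <- function(ops, r) {
  tot <- r * ops$f + ops$g
  ifelse(tot > 0, r * ops$f / tot, 0)
}

# force_scale making the full-activation isometric force equal F0 under
# the grid quadrature used everywhere else.
calibrate_force_scale <- function(ops, F0) {
  m <- sum(moment_functional(ops) * isometric_steady_state(ops, 1))
  if (m <= 0) stop("degenerate force functional", call. = FALSE)
  F0 / m
}

resolve_force_scale <- function(ops, hill) {
  if (!is.null(ops$params$force_scale)) ops$params$force_scale
  else calibrate_force_scale(ops, hill$F0)
}

# Conservative explicit-RK4 stability bound for the method-of-lines
# system, and the largest admissible dt.
stable_dt <- function(ops, hill) {
  v_max <- hill$vb * hill$F0 / hill$Fa
  lam <- max(ops$f + ops$g) + v_max * max(abs(eigen(ops$D, only.values = TRUE)$values))
  2.5 / lam
}

#' Solve the full bond-distribution PDE
#'
#' Method-of-lines RK4 integration of the Huxley PDE with the exact
#' bilinear reaction term. Unless `velocity` is supplied, the filament
#' velocity is closed through the Hill relation from the current force
#' at every step. The state is clipped to `[0, 1]` after each step.
#'
#' @param params [huxley_parameters()].
#' @param act activation trace: data.frame with columns `time` and `r`.
#' @param hill [hill_parameters()].
#' @param n_grid collocation points (>= 16).
#' @param dt time step in seconds (<= 1e-3); an error names the largest
#'   stable step if `dt` violates the explicit stability bound.
#' @param p0 initial distribution on the grid (default zero).
#' @param velocity optional fixed velocity override (e.g. 0 for
#'   isometric studies); default `NULL` means Hill closure.
#' @return list with `distribution` (list: `grid`, `time`, `p` matrix of
#'   time x grid values) and `force` (a `force_trace` data.frame with
#'   `time`, `force`, `velocity`).
#' @export
solve_full_pde <- function(params, act, hill, n_grid = 64, dt = 1e-3,
                           p0 = NULL, velocity = NULL) {
  stopifnot(is.data.frame(act), all(c("time", "r") %in% names(act)))
  if (dt > 1e-3) stop("dt must be <= 1e-3 s", call. = FALSE)
  ops <- spectral_discretize(params, n_grid)
  dt_max <- stable_dt(ops, hill)
  if (dt > dt_max)
    stop(sprintf("time step %.3g s violates the stability bound; use dt <= %.3g s",
                 dt, dt_max), call. = FALSE)
  scale <- resolve_force_scale(ops, hill)
  cw <- moment_functional(ops)
  t_end <- max(act$time)
  nt <- floor(t_end / dt + 1e-9)
  time <- seq(0, by = dt, length.out = nt + 1)
  r_t <- interp_signal(act$time, act$r, time)
  r_half <- interp_signal(act$time, act$r, time + dt / 2)
  p <- if (is.null(p0)) numeric(n_grid) else as.numeric(p0)
  P <- matrix(0, nt + 1, n_grid)
  Fv <- Vv <- numeric(nt + 1)
  P[1, ] <- p
  Fv[1] <- scale * sum(cw * p)
  Vv[1] <- if (is.null(velocity)) shortening_velocity(clamp_force(Fv[1], hill), hill)
           else velocity
  for (i in seq_len(nt)) {
    v <- Vv[i]
    rhs <- function(r, p) {
      as.vector(v * (ops$D %*% p)) + r * ops$f * (1 - p) - ops$g * p
    }
    k1 <- rhs(r_t[i], p)
    k2 <- rhs(r_half[i], p + dt / 2 * k1)
    k3 <- rhs(r_half[i], p + dt / 2 * k2)
    k4 <- rhs(r_t[i + 1], p + dt * k3)
    p <- clamp(p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0, 1)
    P[i + 1, ] <- p
    Fv[i + 1] <- scale * sum(cw * p)
    Vv[i + 1] <- if (is.null(velocity))
      shortening_velocity(clamp_force(Fv[i + 1], hill), hill) else velocity
  }
  force <- structure(data.frame(time = time, force = Fv, velocity = Vv),
                     class = c("force_trace", "data.frame"))
  list(distribution = list(grid = ops$grid, time = time, p = P),
       force = force)
}

#' Balanced truncation of the discretized muscle model
#'
#' Balances the frozen-velocity linear system `(R0 + v_nominal D, b,
#' first-moment functional)` and truncates to `order` states. The
#' advection operator is projected onto the same balanced basis, giving
#' the velocity-coupled part `A1` of the reduced system
#' `da/dt = (A0 + v A1) a + B r`. States below the numerical Hankel
#' rank (`sigma < 1e-12 sigma_1`) are never retained, so requesting
#' `order = n_grid` reproduces the reachable-observable subsystem.
#'
#' @param ops [spectral_discretize()] output.
#' @param order number of retained states (default 3).
#' @param v_nominal frozen velocity for the balancing (default 0).
#' @return list of class `reduced_muscle_model` with `order`, `A0`,
#'   `A1`, `B`, `C`, Hankel singular values `hsv`, the projection
#'   `basis` (`T`, `Tinv`) and the originating operators.
#' @export
balanced_truncate <- function(ops, order = 3, v_nominal = 0) {
  stopifnot(inherits(ops, "huxley_operators"))
  n <- length(ops$grid)
  if (order < 1 || order > n) stop("order must lie in [1, n_grid]", call. = FALSE)
  A <- ops$R0 + v_nominal * ops$D
  lam <- eigen(A, only.values = TRUE)$values
  if (max(Re(lam)) >= -1e-12)
    stop("frozen-velocity system is not stable; cannot balance", call. = FALSE)
  B <- matrix(ops$b, ncol = 1)
  Cv <- matrix(moment_functional(ops), nrow = 1)
  Wc <- lyap_solve(A, B %*% t(B))
  Wo <- lyap_solve(t(A), t(Cv) %*% Cv)
  sqrt_fac <- function(W) {
    e <- eigen((W + t(W)) / 2, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(W))
  }
  Lc <- sqrt_fac(Wc)
  Lo <- sqrt_fac(Wo)
  sv <- svd(t(Lo) %*% Lc)
  hsv <- sv$d
  k <- min(order, sum(hsv > 1e-12 * hsv[1]))
  Si <- diag(1 / sqrt(hsv[seq_len(k)]), k)
  Tm <- Lc %*% sv$v[, seq_len(k), drop = FALSE] %*% Si
  Ti <- Si %*% t(sv$u[, seq_len(k), drop = FALSE]) %*% t(Lo)
  structure(list(order = k,
                 A0 = Ti %*% A %*% Tm,
                 A1 = Ti %*% ops$D %*% Tm,
                 B = as.vector(Ti %*% B),
                 C = as.vector(Cv %*% Tm),
                 hsv = hsv,
                 basis = list(T = Tm, Tinv = Ti),
                 v_nominal = v_nominal,
                 ops = ops),
            class = "reduced_muscle_model")
}

#' @export
print.reduced_muscle_model <- function(x, ...) {
  cat(sprintf("reduced Huxley muscle model: order %d (grid %d)\n",
              x$order, length(x$ops$grid)))
  cat("leading Hankel singular values:",
      format(utils::head(x$hsv, 5), digits = 3), "\n")
  if (!is.null(x$force_scale))
    cat(sprintf("force scale: %.4g N per unit moment\n", x$force_scale))
  invisible(x)
}

#' Build a force-calibrated reduced muscle model
#'
#' Convenience pipeline: spectral discretization, balanced truncation,
#' and calibration of the force scale so the full-activation isometric
#' force equals the Hill `F0`.
#'
#' @inheritParams spectral_discretize
#' @inheritParams balanced_truncate
#' @param hill [hill_parameters()] used for calibration.
#' @return a `reduced_muscle_model` with `force_scale` set.
#' @export
build_muscle_model <- function(params = huxley_parameters(),
                               hill = hill_parameters(),
                               n_grid = 64, order = 3,
                               r_nominal = 0.7, v_nominal = 0) {
  ops <- spectral_discretize(params, n_grid, r_nominal)
  model <- balanced_truncate(ops, order, v_nominal)
  model$force_scale <- resolve_force_scale(ops, hill)
  model
}

# DC gain (constant r -> steady force, unscaled moment units) of the
# frozen-velocity systems; used to check reduction fidelity.
dc_gain_full <- function(ops, v_nominal = 0) {
  A <- ops$R0 + v_nominal * ops$D
  -as.numeric(matrix(moment_functional(ops), nrow = 1) %*%
                solve(A, matrix(ops$b, ncol = 1)))
}

dc_gain_reduced <- function(model) {
  -as.numeric(matrix(model$C, nrow = 1) %*% solve(model$A0, model$B))
}

clamp_force <- function(F, hill) clamp(F, 0, hill$F0)

#' Simulate the reduced muscle model
#'
#' Integrates `da/dt = (A0 + v A1) a + B r` with RK4 at fixed step `dt`.
#' The force `F = force_scale * C a` is clamped to `[0, F0]` before
#' closing the shortening velocity through the Hill relation.
#'
#' @param model a `reduced_muscle_model` with `force_scale` set (see
#'   [build_muscle_model()]).
#' @param act activation trace: data.frame with columns `time`, `r`.
#' @param hill [hill_parameters()].
#' @param dt time step (s), <= 1e-3.
#' @param a0 initial reduced state (default zero).
#' @return a `force_trace` data.frame with `time`, `force`, `velocity`.
#' @export
simulate_reduced <- function(model, act, hill, dt = 1e-3, a0 = NULL) {
  stopifnot(inherits(model, "reduced_muscle_model"))
  if (is.null(model$force_scale))
    stop("model has no force_scale; use build_muscle_model()", call. = FALSE)
  if (dt > 1e-3) stop("dt must be <= 1e-3 s", call. = FALSE)
  k <- model$order
  a <- if (is.null(a0)) numeric(k) else as.numeric(a0)
  t_end <- max(act$time)
  nt <- floor(t_end / dt + 1e-9)
  time <- seq(0, by = dt, length.out = nt + 1)
  r_t <- interp_signal(act$time, act$r, time)
  r_half <- interp_signal(act$time, act$r, time + dt / 2)
  Cs <- model$force_scale * model$C
  Fv <- Vv <- numeric(nt + 1)
  Fv[1] <- clamp(sum(Cs * a), 0, hill$F0)
  Vv[1] <- shortening_velocity(clamp_force(Fv[1], hill), hill)
  bound <- 1e6 * max(1, sqrt(sum((model$B / diag(model$A0))^2)))
  for (i in seq_len(nt)) {
    Amat <- model$A0 + Vv[i] * model$A1
    da <- function(a, r) as.vector(Amat %*% a) + model$B * r
    k1 <- da(a, r_t[i])
    k2 <- da(a + dt / 2 * k1, r_half[i])
    k3 <- da(a + dt / 2 * k2, r_half[i])
    k4 <- da(a + dt * k3, r_t[i + 1])
    a <- a + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(a)) || sqrt(sum(a^2)) > bound)
      stop(sprintf("reduced muscle state diverged at t = %.4f s", i * dt),
           call. = FALSE)
    Fv[i + 1] <- clamp(sum(Cs * a), 0, hill$F0)
    Vv[i + 1] <- shortening_velocity(clamp_force(Fv[i + 1], hill), hill)
  }
  structure(data.frame(time = time, force = Fv, velocity = Vv),
            class = c("force_trace", "data.frame"))
}
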