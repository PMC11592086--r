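# Shared numerical helpers: seeded RNG scope, Chebyshev collocation,
# Clenshaw-Curtis quadrature, Lyapunov-equation solve, fixed-step RK4.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Chebyshev differentiation matrix and collocation nodes
#'
#' Returns the spectral differentiation matrix on the `n` Chebyshev-Gauss-
#' Lobatto nodes of `[a, b]`, in descending node order. Exact for
#' polynomials up to degree `n - 1`.
#'
#' @param n number of collocation points (>= 2).
#' @param a,b interval endpoints, `a < b`.
#' @return list with `x` (nodes, descending) and `D` (n x n matrix).
#' @keywords internal
cheb_collocation <- function(n, a = -1, b = 1) {
  stopifnot(n >= 2, a < b)
  N <- n - 1
  xi <- cos(pi * (0:N) / N)
  cc <- c(2, rep(1, N - 1), 2) * (-1)^(0:N)
  X <- matrix(rep(xi, n), ncol = n)
  dX <- X - t(X)
  D <- (cc %o% (1 / cc)) / (dX + diag(n))
  D <- D - diag(rowSums(D))
  list(x = a + (b - a) * (xi + 1) / 2, D = D * 2 / (b - a))
}

# Clenshaw-Curtis quadrature weights on the same descending Lobatto nodes.
cc_quad_weights <- function(n, a = -1, b = 1) {
  N <- n - 1
  w <- numeric(n)
  ks <- seq(2, N, by = 2)
  for (j in 0:N) {
    s <- sum(ifelse(ks == N, 1, 2) / (ks^2 - 1) * cos(ks * pi * j / N))
    cj <- if (j == 0 || j == N) 1 else 2
    w[j + 1] <- cj / N * (1 - s)
  }
  w * (b - a) / 2
}

# Solve A P + P A^T + Q = 0 for symmetric Q, A Hurwitz and diagonalizable,
# via the eigendecomposition of A (complex-safe).
lyap_solve <- function(A, Q) {
  e <- eigen(A)
  V <- e$vectors
  lam <- e$values
  Vi <- solve(V)
  Qt <- Vi %*% Q %*% t(Vi)
  P <- -Qt / outer(lam, lam, `+`)
  P <- V %*% P %*% t(V)
  P <- Re(P)
  (P + t(P)) / 2
}

# One classical RK4 step for dx/dt = f(t, x).
rk4_step <- function(f, t, x, dt) {
  k1 <- f(t, x)
  k2 <- f(t + dt / 2, x + dt / 2 * k1)
  k3 <- f(t + dt / 2, x + dt / 2 * k2)
  k4 <- f(t + dt, x + dt * k3)
  x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# Linear interpolation of a sampled signal onto new times, constant beyond
# the ends.
interp_signal <- function(time, value, t_out) {
  stats::approx(time, value, xout = t_out, rule = 2)$y
}

is_uniform_grid <- function(time, tol = 1e-9) {
  if (length(time) < 2) return(TRUE)
  d <- diff(time)
  all(d > 0) && (max(d) - min(d)) <= tol * max(d)
}
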