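test_that("spectral operators differentiate exactly and match the PDE rhs", {
  ops <- spectral_discretize(fix_muscle(), n_grid = 32)
  n <- length(ops$grid)
  expect_lt(max(abs(ops$D %*% rep(1, n))), 1e-10)       # derivative of 1
  expect_lt(max(abs(ops$D %*% ops$grid - 1)), 1e-8)     # derivative of x
  # frozen operator reproduces the bilinear rhs at the nominal activation
  set.seed(1)
  p <- runif(n)
  v <- 0.17
  r <- ops$r_nominal
  lhs <- as.vector((ops$R0 + v * ops$D) %*% p) + r * ops$b
  rhs <- as.vector(v * (ops$D %*% p)) + r * ops$f * (1 - p) - ops$g * p
  expect_lt(max(abs(lhs - rhs)), 1e-8)
  expect_error(spectral_discretize(fix_muscle(), n_grid = 8), ">= 16")
  expect_error(huxley_parameters(x_min = 2, x_max = 1), "x_min")
})

test_that("full PDE: zero activation stays zero; state stays in [0, 1]", {
  act <- data.frame(time = c(0, 0.3), r = c(0, 0))
  sol <- solve_full_pde(fix_muscle(), act, fix_hill(), n_grid = 32)
  expect_true(all(sol$distribution$p == 0))
  expect_true(all(sol$force$force == 0))

  act <- data.frame(time = seq(0, 0.5, 0.01),
                    r = pmin(seq(0, 0.5, 0.01) / 0.2, 1))
  sol <- solve_full_pde(fix_muscle(), act, fix_hill(), n_grid = 32)
  expect_true(all(sol$distribution$p >= -1e-9 & sol$distribution$p <= 1 + 1e-9))
})

test_that("isometric bond distribution converges to the pointwise fixed point", {
  r0 <- 0.6
  act <- data.frame(time = c(0, 3.5), r = c(r0, r0))
  sol <- solve_full_pde(fix_muscle(), act, fix_hill(), n_grid = 32,
                        velocity = 0)
  ops <- spectral_discretize(fix_muscle(), n_grid = 32)
  target <- isometric_steady_state(ops, r0)
  p_end <- sol$distribution$p[nrow(sol$distribution$p), ]
  expect_lt(max(abs(p_end - target)), 1e-4)
})

test_that("terminal isometric force is grid-converged and monotone in r", {
  term_force <- function(n, r0) {
    act <- data.frame(time = c(0, 2.5), r = c(r0, r0))
    sol <- solve_full_pde(fix_muscle(), act, fix_hill(), n_grid = n,
                          velocity = 0)
    tail(sol$force$force, 1)
  }
  f32 <- term_force(32, 0.7)
  f64 <- term_force(64, 0.7)
  expect_lt(abs(f64 - f32) / f64, 0.005)

  levels <- c(0, 0.25, 0.5, 0.75, 1)
  forces <- vapply(levels, function(r) term_force(32, r), numeric(1))
  expect_true(all(diff(forces) >= 0))
  expect_equal(forces[5], fix_hill()$F0, tolerance = 1e-3)  # calibration
})

test_that("explicit-step stability violations are reported with a usable dt", {
  stiff_params <- huxley_parameters(g2 = 5000)
  act <- data.frame(time = c(0, 0.1), r = c(0.5, 0.5))
  expect_error(solve_full_pde(stiff_params, act, fix_hill(), n_grid = 32,
                              dt = 1e-3),
               "use dt <=")
  expect_error(solve_full_pde(fix_muscle(), act, fix_hill(), dt = 0.01),
               "<= 1e-3")
})

test_that("balanced truncation preserves the reachable dynamics", {
  ops <- spectral_discretize(fix_muscle(), n_grid = 32)
  model <- balanced_truncate(ops, order = 3)
  expect_true(all(diff(model$hsv) <= 1e-12))             # non-increasing
  expect_equal(model$order, 3)

  # DC gain of the order-3 model within 2% of the full operator's
  expect_equal(dc_gain_reduced(model), dc_gain_full(ops), tolerance = 0.02)

  # "identity" reduction (order = n_grid, numerical rank retained):
  # step responses of full and reduced frozen systems agree
  full_step <- function(tt) {
    rate <- -diag(ops$R0)
    y <- vapply(tt, function(t) sum(ops$weights * ops$grid *
                                      ops$b / rate * (1 - exp(-rate * t))),
                numeric(1))
    y
  }
  big <- balanced_truncate(ops, order = 32)
  e <- eigen(big$A0)
  x0 <- solve(e$vectors, big$B)
  red_step <- function(tt) {
    vapply(tt, function(t) {
      a <- e$vectors %*% ((exp(e$values * t) - 1) / e$values * x0)
      Re(sum(big$C * a))
    }, numeric(1))
  }
  tt <- seq(0.05, 1, by = 0.05)
  expect_lt(max(abs(full_step(tt) - red_step(tt))), 1e-8)

  # an unstable frozen system is refused
  expect_error(balanced_truncate(ops, order = 3, v_nominal = 60),
               "not stable")
})

test_that("reduced model force tracks the full PDE", {
  model <- fix_model()
  hill <- fix_hill()
  # zero activation -> zero force
  act0 <- data.frame(time = c(0, 0.5), r = c(0, 0))
  expect_true(all(simulate_reduced(model, act0, hill)$force == 0))

  # step activation: monotone rise to a plateau below F0
  tt <- seq(0, 2, by = 1e-3)
  act <- data.frame(time = tt, r = 0.6 * as.numeric(tt >= 0.1))
  tr <- simulate_reduced(model, act, hill)
  expect_true(all(diff(tr$force) >= -1e-9))
  expect_lt(max(tr$force), hill$F0)

  # order-3 reduced force within 5% relative L2 of the full PDE
  ramp <- function(lvl, rise) {
    tt <- seq(0, 3, by = 1e-3)
    data.frame(time = tt, r = lvl * pmin(tt / rise, 1))
  }
  profs <- list(ramp(0.4, 0.5), ramp(0.7, 0.3), ramp(1.0, 0.2))
  for (act in profs) {
    full <- solve_full_pde(fix_muscle(), act, hill)$force$force
    red <- simulate_reduced(model, act, hill)$force
    rel <- sqrt(sum((red - full)^2) / sum(full^2))
    expect_lt(rel, 0.05)
  }
})
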