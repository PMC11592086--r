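test_that("contact detection finds the first threshold crossing", {
  expect_true(is.na(detect_contact(rep(0, 100), 0.05)))
  f <- c(rep(0, 100), rep(1, 100))
  tt <- seq(0, 0.199, by = 1e-3)
  expect_equal(detect_contact(f, 0.05, tt), 0.1)
  expect_true(is.na(detect_contact(f, 2, tt)))
  expect_error(detect_contact(f, 0), "positive")
})

test_that("summaries report final force, settling and peak stiffness", {
  # synthetic exponential force approach after contact at t = 0.3 s
  tau <- 0.05
  tt <- seq(0, 2, by = 1e-3)
  f <- ifelse(tt < 0.3, 0, 2 * (1 - exp(-(tt - 0.3) / tau)))
  log <- structure(
    data.frame(time = tt, theta1_deg = 10 * tt, force_N = f,
               torque_Nm = 0, current_A = 0, voltage_V = 0,
               F_est = 0, Ka = pmin(tt / 2, 0.1), dKa = 0, Kd_tilde = 0,
               V = 0, Vdot = 0, contact = as.integer(tt >= 0.3)),
    class = c("grasp_log", "data.frame"),
    contact_time = 0.3, kd_tilde_latched = 42, label = "exp")
  s <- summarize_grasp(log)
  # 2% band entry of 1 - exp(-t/tau) happens at tau * log(50)
  expect_equal(s$settling_ms, tau * log(50) * 1000, tolerance = 2e-3 * 1000)
  expect_equal(s$final_force_N, 2, tolerance = 1e-3)
  expect_equal(s$max_angle_deg, 20, tolerance = 1e-9)
  expect_equal(s$Ka_terminal, 0.1)
  expect_equal(s$Kd_tilde_terminal, 42)
  expect_equal(s$label, "exp")

  # constant force from contact onward settles immediately
  logc <- structure(
    data.frame(time = tt, theta1_deg = 0, force_N = c(rep(0, 300),
                                                      rep(1.5, 1701)),
               torque_Nm = 0, current_A = 0, voltage_V = 0, F_est = 0,
               Ka = 0, dKa = 0, Kd_tilde = 0, V = 0, Vdot = 0,
               contact = c(rep(0L, 300), rep(1L, 1701))),
    class = c("grasp_log", "data.frame"),
    contact_time = 0.3, kd_tilde_latched = 0, label = "const")
  expect_equal(summarize_grasp(logc)$settling_ms, 0)
})

test_that("a grasp run is deterministic and schema-consistent", {
  scn <- small_scenario()
  log1 <- run_grasp(scn)
  log2 <- run_grasp(scn)
  expect_identical(as.data.frame(log1), as.data.frame(log2))

  expect_named(log1, c("time", "theta1_deg", "force_N", "torque_Nm",
                       "current_A", "voltage_V", "F_est", "Ka", "dKa",
                       "Kd_tilde", "V", "Vdot", "contact"))
  expect_true(all(abs(diff(log1$time) - 1e-3) < 1e-9))
  expect_true(all(is.finite(as.matrix(log1))))
  expect_true(all(log1$Ka >= 0 & log1$Ka <= 1))
  expect_true(all(log1$dKa >= 0 & log1$dKa <= 1))
  expect_true(all(log1$Kd_tilde >= 0 & log1$Kd_tilde <= 100))
  expect_true(all(log1$contact %in% c(0L, 1L)))

  # contact happened, and the Lyapunov columns certify stability there
  expect_false(is.na(attr(log1, "contact_time")))
  during <- log1$contact == 1
  expect_true(any(during))
  expect_true(all(log1$V[during] >= 0))
  expect_true(all(log1$Vdot[during] <= 0))
  # V is non-increasing sample to sample once in contact
  expect_lt(max(diff(log1$V[during])), 1e-8)
})

test_that("steady contact balances the scheduled stiffness and force error", {
  log <- run_grasp(small_scenario())
  imp <- attr(log, "impedance")
  e_ss <- tail(log$theta1_deg, 1) * pi / 180 - imp$theta1d
  f_ss <- mean(tail(log$force_N, 50))
  expect_equal(imp$Kd * e_ss, -(f_ss - imp$Fd),
               tolerance = 0.01 * abs(f_ss - imp$Fd))
})

test_that("an out-of-reach object never makes contact", {
  scn <- small_scenario(surface_shift = 1)   # surface 1 m beyond reach
  log <- run_grasp(scn)
  expect_true(all(log$contact == 0L))
  expect_true(all(log$force_N == 0))
  expect_true(is.na(attr(log, "contact_time")))
  s <- summarize_grasp(log)
  expect_true(is.na(s$contact_ms))
  expect_true(is.na(s$settling_ms))
})

test_that("grasp logs round-trip through CSV", {
  log <- run_grasp(small_scenario(duration = 1.6))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_grasp_log(log, path)
  back <- read_grasp_log(path)
  expect_equal(back$force_N, log$force_N, tolerance = 1e-15)
  expect_equal(back$V, log$V, tolerance = 1e-15)
})

test_that("the four-object demo reproduces the soft-to-hard ordering", {
  demo <- fix_demo(seed = 1)
  s <- demo$summaries
  expect_equal(nrow(s), 4)
  # harder objects: stiffer estimate, at least as stiff a controller,
  # larger final force, quicker settling
  expect_true(all(diff(s$Ka_terminal) > 0))
  expect_true(all(diff(s$Kd_tilde_terminal) >= 0))
  expect_true(all(diff(s$final_force_N) > 0))
  expect_true(all(diff(s$settling_ms) < 0))
  # estimated grasp efforts span everyday levels
  fd <- vapply(demo$logs, function(l) attr(l, "impedance")$Fd, numeric(1))
  expect_true(all(fd > 0.5 & fd < 5))
  expect_true(all(diff(fd) > 0))
  # every log certifies stability during contact
  for (log in demo$logs) {
    during <- log$contact == 1
    expect_true(all(log$V[during] >= 0))
    expect_true(all(log$Vdot[during] <= 0))
  }
})
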