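links <- finger_links()
map <- linear_coupling()
geom <- contact_geometry()

# maps used by specific oracles
identity_map <- coupling_map(function(t1) rep(t1, 5),
                             function(t1) rep(1, 5),
                             function(t1) rep(0, 5), range = c(-7, 7))
frozen_map <- coupling_map(function(t1) rep(0.3, 5),
                           function(t1) rep(0, 5),
                           function(t1) rep(0, 5), range = c(-7, 7))

test_that("coupling maps expose consistent angles and sensitivities", {
  cfg <- coupled_configuration(0.4, identity_map)
  expect_equal(cfg$theta, rep(0.4, 5))
  expect_equal(cfg$dtheta, rep(1, 5))

  cc <- c(1, 0.7, 1.3, 0.5, 0.9)
  lin <- linear_coupling(coeffs = cc, offsets = rep(0.1, 5))
  cfg <- coupled_configuration(0.5, lin)
  expect_equal(cfg$theta, cc * 0.5 + 0.1)
  expect_equal(cfg$dtheta, cc)
  # straight reference pose at theta1 = 0 with the defaults
  expect_equal(coupled_configuration(0, map)$theta, rep(0, 5))
  expect_error(coupled_configuration(3, map), "operating range")

  # supplied derivatives agree with central differences
  h <- 1e-6
  fd <- (map$theta(0.5 + h) - map$theta(0.5 - h)) / (2 * h)
  expect_equal(map$dtheta(0.5), fd, tolerance = 1e-6)
})

test_that("centroid placement follows the planar-rotation law", {
  # zero offset: centroid coincides with the geometric center
  l0 <- finger_links(centroid_offset = rep(0, 5), centroid_angle = rep(0, 5))
  cfg <- coupled_configuration(0.3, map)
  cp <- centroid_positions(cfg, l0)
  kin <- semgrasp:::chain_kinematics(cfg, l0)
  expect_equal(cp$x, Re(kin$center), tolerance = 1e-12)
  expect_equal(cp$y, Im(kin$center), tolerance = 1e-12)

  # straight pose, zero angle offset: centroid displaced along x
  la <- finger_links(centroid_offset = rep(0.003, 5),
                     centroid_angle = rep(0, 5))
  cfg0 <- coupled_configuration(0, map)
  cp0 <- centroid_positions(cfg0, la)
  k0 <- semgrasp:::chain_kinematics(cfg0, finger_links(
    centroid_offset = rep(0, 5), centroid_angle = rep(0, 5)))
  expect_equal(cp0$x, Re(k0$center) + 0.003, tolerance = 1e-12)
  expect_equal(cp0$y, Im(k0$center), tolerance = 1e-12)

  # rotating a link by pi/2 turns an (a, 0) offset into (0, a)
  rot <- coupling_map(function(t1) rep(t1, 5), function(t1) rep(1, 5),
                      function(t1) rep(0, 5), range = c(-7, 7))
  cpr <- centroid_positions(coupled_configuration(pi / 2, rot), la)
  kr <- semgrasp:::chain_kinematics(coupled_configuration(pi / 2, rot),
                                    finger_links(
    centroid_offset = rep(0, 5), centroid_angle = rep(0, 5)))
  expect_equal(cpr$x - Re(kr$center), rep(0, 5), tolerance = 1e-12)
  expect_equal(cpr$y - Im(kr$center), rep(0.003, 5), tolerance = 1e-12)
})

test_that("contact point and Jacobian match finite-difference oracles", {
  cfg <- coupled_configuration(0.4, map)
  # pad offset acts linearly along its fixed direction
  p0 <- contact_point(cfg, contact_geometry(lp = 0), links)$p
  p1 <- contact_point(cfg, contact_geometry(lp = 0.004), links)$p
  p2 <- contact_point(cfg, contact_geometry(lp = 0.008), links)$p
  expect_equal(p1 - p0, 0.004 * c(cos(1.0), sin(1.0)), tolerance = 1e-12)
  expect_equal(p2 - p1, p1 - p0, tolerance = 1e-12)

  # velocity via chain rule agrees with central differences
  h <- 1e-6
  for (th in c(0.1, 0.5, 1.0)) {
    pp <- contact_point(coupled_configuration(th + h, map), geom, links)$p
    pm <- contact_point(coupled_configuration(th - h, map), geom, links)$p
    fd <- (pp - pm) / (2 * h)
    cp <- contact_point(coupled_configuration(th, map), geom, links,
                        theta1_dot = 2)
    expect_equal(cp$v, fd * 2, tolerance = 1e-6)
  }

  # Jacobian oracle at 10 random angles
  set.seed(3)
  for (th in runif(10, -0.2, 1.5)) {
    J <- contact_jacobian(coupled_configuration(th, map), geom, links)
    pp <- contact_point(coupled_configuration(th + h, map), geom, links)$p
    pm <- contact_point(coupled_configuration(th - h, map), geom, links)$p
    expect_equal(J, (pp - pm) / (2 * h), tolerance = 1e-6)
  }

  # frozen chain: zero sensitivities give a zero Jacobian
  Jf <- contact_jacobian(coupled_configuration(0.9, frozen_map), geom, links)
  expect_equal(Jf, c(0, 0), tolerance = 1e-15)

  # doubling all lengths (including the pad) doubles the Jacobian
  links2 <- finger_links(lengths = 2 * links$lengths)
  geom2 <- contact_geometry(lp = 2 * geom$lp)
  J1 <- contact_jacobian(cfg, geom, links)
  J2 <- contact_jacobian(cfg, geom2, links2)
  expect_equal(J2, 2 * J1, tolerance = 1e-12)
})

test_that("generalized dynamics agree with finite differences of M and U", {
  h <- 1e-5
  for (th in c(-0.1, 0.3, 0.8, 1.3)) {
    dyn <- dynamics_matrices(finger_state(th, 0.5), map, links)
    expect_gt(dyn$M, 0)
    Mp <- dynamics_matrices(finger_state(th + h, 0), map, links)$M
    Mm <- dynamics_matrices(finger_state(th - h, 0), map, links)$M
    expect_equal(dyn$C, (Mp - Mm) / (2 * h) / 2, tolerance = 1e-6)
    U <- function(t1) {
      kin <- semgrasp:::chain_kinematics(coupled_configuration(t1, map),
                                         links)
      sum(links$masses * links$gravity * Im(kin$centroid))
    }
    expect_equal(dyn$G, (U(th + h) - U(th - h)) / (2 * h), tolerance = 1e-6)
  }
  # no gravity, no gravity torque
  l0 <- finger_links(gravity = 0)
  expect_identical(dynamics_matrices(finger_state(0.5, 0), map, l0)$G, 0)
  # positive mass over the whole operating range
  Ms <- vapply(seq(-0.3, 1.6, length.out = 100), function(th)
    dynamics_matrices(finger_state(th, 0), map, links)$M, numeric(1))
  expect_true(all(Ms > 0))
})

test_that("free swing conserves energy", {
  # start near the hanging equilibrium so the finger oscillates
  wide <- linear_coupling(range = c(-7, 7))
  sw <- simulate_free_swing(finger_state(-1.2, 1), wide, links,
                            t_end = 1, dt = 1e-4)
  expect_gt(diff(range(sw$theta1)), 0.05)   # it actually swings
  drift <- max(abs(sw$energy - sw$energy[1]))
  expect_lt(drift / max(abs(sw$energy[1]), 1e-6), 1e-6)
})

test_that("object contact is a one-sided linear spring", {
  obj <- object_model(surface_position = 0.02, stiffness = 500)
  expect_identical(contact_force(c(0.05, 0.01), obj), 0)
  expect_equal(contact_force(c(0.05, 0.023), obj), 500 * 0.003,
               tolerance = 1e-12)
  pens <- seq(-0.01, 0.01, length.out = 41)
  fs <- vapply(pens, function(d) contact_force(c(0, 0.02 + d), obj),
               numeric(1))
  expect_true(all(diff(fs) >= 0))
  expect_error(object_model(0, -1), "positive")
})
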