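# 4th-order central differences for the ODE-residual and derivative checks
.d1 <- function(f, y, s = 1e-3) (8 * (f(y + s) - f(y - s)) - (f(y + 2 * s) - f(y - 2 * s))) / (12 * s)
.d2 <- function(f, y, s = 1e-3) (-f(y + 2 * s) + 16 * f(y + s) - 30 * f(y) + 16 * f(y - s) - f(y - 2 * s)) / (12 * s^2)

test_that("temperature satisfies its boundary values and the small-eta limit", {
  p <- defaultParams()
  xs <- runif(10)
  h <- wallHeight(xs, p)
  expect_equal(temperature(xs, 0, p), rep(0, 10))
  expect_equal(temperature(xs, h, p), rep(1, 10))
  # small-angle limit: theta -> y/h
  p0 <- flowParams(Br = 1, eta = 1e-12)
  h0 <- wallHeight(0.3, p0)
  expect_equal(temperature(0.3, h0 / 2, p0), 0.5, tolerance = 1e-6)
  expect_error(temperature(0, 2 * wallHeight(0, p), p), "outside")
})

test_that("solution constants match their closed-form definitions and close the boundary system", {
  expect_equal(solutionConstants(0, 0, flowParams(M = 2, lambda1 = 1, beta = 0))$a1, 8)
  expect_equal(solutionConstants(0, 0, flowParams(M = 1, lambda1 = 0, beta = pi / 3))$a1, 0.25)
  expect_equal(solutionConstants(0, 0, flowParams(c2 = 3, lambda1 = 1))$a2, 6)
  p <- defaultParams()
  sc <- solutionConstants(0.3, 1.2, p)
  expect_equal(sc$cI, (1 + p$lambda1) * (p$c1 * sin(p$alpha) - 1.2))
  # boundary closure: u(0) = 0 and u(h) = -1 from the reported constants
  s <- sqrt(sc$a1); k <- p$Br * sqrt(p$eta)
  u_of <- function(y) -1 + sc$cI / sc$a1 + sc$c3 * exp(s * y) + sc$c4 * exp(-s * y) +
    sc$a2 * sin(k * y) / (sin(k * sc$h) * (sc$a1 + k^2))
  expect_equal(u_of(0), 0, tolerance = 1e-12)
  expect_equal(u_of(sc$h), -1, tolerance = 1e-12)
})

test_that("boundary-solved c4 agrees with the printed closed-form expression", {
  set.seed(42)
  for (i in 1:25) {
    d <- randomDraw()
    p <- d$params
    sc <- solutionConstants(d$x, d$dpdx, p)
    s <- sqrt(sc$a1); k <- p$Br * sqrt(p$eta); h <- sc$h
    c4_printed <- sc$a2 / (2 * (sc$a1 + k^2) * sinh(h * s)) +
      sc$cI * (1 - exp(h * s)) / (2 * sc$a1 * sinh(h * s)) +
      exp(h * s) / (2 * sinh(h * s))
    expect_equal(sc$c4, c4_printed, tolerance = 1e-9)
    expect_equal(sc$c3, 1 - sc$cI / sc$a1 - sc$c4, tolerance = 1e-9)
  }
})

test_that("velocity and temperature hit the wave-frame boundary conditions on random draws", {
  set.seed(7)
  worst <- 0
  for (i in 1:200) {
    d <- randomDraw()
    h <- wallHeight(d$x, d$params)
    worst <- max(worst,
                 abs(velocity(d$x, 0, d$dpdx, d$params)),
                 abs(velocity(d$x, h, d$dpdx, d$params) + 1),
                 abs(temperature(d$x, 0, d$params)),
                 abs(temperature(d$x, h, d$params) - 1))
  }
  expect_lt(worst, 1e-10)
})

test_that("closed forms satisfy the reduced momentum and energy ODEs pointwise", {
  set.seed(11)
  for (i in 1:20) {
    d <- randomDraw()
    p <- d$params
    h <- wallHeight(d$x, p)
    yy <- seq(0.15 * h, 0.85 * h, length.out = 7)
    lam <- 1 + p$lambda1
    a1 <- p$M^2 * lam * cos(p$beta)^2
    a2 <- p$c2 * lam
    cI <- lam * (p$c1 * sin(p$alpha) - d$dpdx)
    k2 <- p$Br^2 * p$eta
    r_th <- .d2(function(y) temperature(d$x, y, p), yy) + k2 * temperature(d$x, yy, p)
    r_u <- .d2(function(y) velocity(d$x, y, d$dpdx, p), yy) -
      a1 * velocity(d$x, yy, d$dpdx, p) - (a1 - cI - a2 * temperature(d$x, yy, p))
    expect_lt(max(abs(r_th)), 1e-7)
    expect_lt(max(abs(r_u)), 1e-7)
  }
})

test_that("velocity matches the frozen finite-difference oracle value at the reference point", {
  # FD solve (n = 4001) of the reduced system at the default configuration,
  # x = 0, dp/dx = 1, y = 0.5, computed once and frozen:
  expect_equal(velocity(0, 0.5, 1, defaultParams()), -0.64766926472051611,
               tolerance = 1e-6)
})

test_that("shear stress is the analytic derivative over (1 + lambda1)", {
  set.seed(5)
  for (i in 1:10) {
    d <- randomDraw()
    p <- d$params
    h <- wallHeight(d$x, p)
    yy <- seq(0.2 * h, 0.8 * h, length.out = 5)
    du <- .d1(function(y) velocity(d$x, y, d$dpdx, p), yy)
    expect_equal(shearStress(d$x, yy, d$dpdx, p), du / (1 + p$lambda1),
                 tolerance = 1e-8)
  }
  # 1/(1+lambda1) prefactor: scaling lambda1 up at fixed a1 (via compensated M)
  p <- defaultParams()
  a1 <- p$M^2 * (1 + p$lambda1) * cos(p$beta)^2
  big <- 199
  M_big <- sqrt(a1 / ((1 + big) * cos(p$beta)^2))
  p_big <- modifyParams(p, lambda1 = big, M = M_big)
  s_ref <- shearStress(0, 0.6, 1, p)
  s_big <- shearStress(0, 0.6, 1, p_big)
  expect_lt(abs(s_big), abs(s_ref) / 10)
  # shear stress grows with Hartmann number at a fixed interior point
  sM <- vapply(c(1, 1.5, 2, 2.5), function(M)
    shearStress(0, 0.5, 1, modifyParams(p, M = M)), numeric(1))
  expect_true(all(diff(sM) > 0))
})

test_that("fields are invariant under beta -> -beta", {
  set.seed(3)
  for (i in 1:10) {
    d <- randomDraw()
    pm <- d$params; pm$beta <- -pm$beta
    y <- 0.5 * wallHeight(d$x, d$params)
    expect_identical(velocity(d$x, y, d$dpdx, d$params), velocity(d$x, y, d$dpdx, pm))
    expect_identical(shearStress(d$x, y, d$dpdx, d$params), shearStress(d$x, y, d$dpdx, pm))
    expect_identical(temperature(d$x, y, d$params), temperature(d$x, y, pm))
  }
})

test_that("limit paths: no-buoyancy and quadratic lubrication profiles are recovered", {
  # eta -> 0 with c2 = 0: u solves u'' - a1 u = a1 - cI; check against the
  # independent FD solve
  p <- flowParams(eps = 0.4, M = 1.5, beta = 0.3, alpha = 0.5, lambda1 = 0.8,
                  Br = 1, eta = 1e-14, c2 = 0, c1 = 1)
  v <- verifyClosedForm(p, dpdx = 0.7, x = 0.2, tol = 1e-6, n = 2001)
  expect_true(v$ok)
  # a1 -> 0 additionally: the quadratic lubrication profile (direct integration)
  p0 <- flowParams(eps = 0.4, M = 0, alpha = 0.5, lambda1 = 0.8, Br = 1,
                   eta = 1e-14, c2 = 0, c1 = 1)
  h <- wallHeight(0.2, p0)
  cI <- (1 + p0$lambda1) * (p0$c1 * sin(p0$alpha) - 0.7)
  y <- seq(0, h, length.out = 33)
  u_quad <- -cI * y^2 / 2 + ((-1 + cI * h^2 / 2) / h) * y
  expect_equal(velocity(0.2, y, 0.7, p0, degenerate = "limit"), u_quad,
               tolerance = 1e-10)
  # without the explicit flag the degenerate configuration errors
  expect_error(velocity(0.2, 0.1, 0.7, p0), "degenerate")
})

test_that("profile monotonicities at the documented favourable gradient", {
  # profile-study driver conditions: x = 0, y = h/2, dpdx = -1 (favourable,
  # dpdx < c1 sin(alpha): net forward forcing)
  p <- defaultParams()
  at <- function(pp) velocity(0, 0.5, -1, pp)
  uM <- vapply(c(0.5, 1, 1.5, 2, 2.5), function(v) at(modifyParams(p, M = v)), numeric(1))
  uA <- vapply(c(pi / 8, pi / 6, pi / 4, pi / 3), function(v) at(modifyParams(p, alpha = v)), numeric(1))
  uC <- vapply(c(0.5, 1, 1.5, 2), function(v) at(modifyParams(p, c1 = v)), numeric(1))
  uL <- vapply(c(0, 0.5, 1, 1.5), function(v) at(modifyParams(p, lambda1 = v)), numeric(1))
  expect_true(all(diff(uM) < 0))   # magnetic damping slows the flow
  expect_true(all(diff(uA) > 0))   # steeper channel, stronger gravity forcing
  expect_true(all(diff(uC) > 0))
  expect_true(all(diff(uL) > 0))   # smaller effective viscosity
  thB <- vapply(c(1, 1.5, 2, 2.5), function(v) temperature(0, 0.5, modifyParams(p, Br = v)), numeric(1))
  thE <- vapply(c(0.1, 0.3, 0.5), function(v) temperature(0, 0.5, modifyParams(p, eta = v)), numeric(1))
  expect_true(all(diff(thB) > 0))
  expect_true(all(diff(thE) > 0))
})

test_that("rectangular evaluation masks points outside the channel", {
  p <- defaultParams()
  tab <- evalFields(c(0.75, 0.75), c(0.1, 1.2), dpdx = 1, params = p)
  expect_false(anyNA(tab$u[1]))
  expect_true(is.na(tab$u[2]))     # y = 1.2 > h(0.75) = 0.5
  expect_true(is.na(tab$S_xy[2]))
})
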