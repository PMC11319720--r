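test_that("stream function vanishes on the centreline and equals F on the wall", {
  p <- defaultParams()
  for (F in c(-0.4, 0, 0.3)) {
    xs <- seq(0, 1, length.out = 50)
    expect_lt(max(abs(streamFunction(xs, 0, F, p))), 1e-12)
    expect_lt(max(abs(streamFunction(xs, wallHeight(xs, p), F, p) - F)), 1e-8)
  }
})

test_that("the stream function's y-derivative recovers the velocity", {
  set.seed(31)
  for (i in 1:8) {
    d <- randomDraw()
    p <- d$params
    h <- wallHeight(d$x, p)
    yy <- seq(0.2 * h, 0.8 * h, length.out = 5)
    s <- 1e-4
    dpsi <- (streamFunction(d$x, yy + s, d$F, p) -
             streamFunction(d$x, yy - s, d$F, p)) / (2 * s)
    dpdx <- solveDpdx(d$F, d$x, p)
    expect_equal(dpsi, velocity(d$x, yy, dpdx, p), tolerance = 1e-7)
  }
})

test_that("field grid boundary rows satisfy the wave-frame boundary conditions", {
  p <- defaultParams()
  g <- fieldGrid(p, F = -0.4, nx = 65, ny = 65, periods = 1)
  ny <- length(g$yfrac)
  expect_lt(max(abs(g$u[, 1])), 1e-10)
  expect_lt(max(abs(g$u[, ny] + 1)), 1e-10)
  expect_lt(max(abs(g$theta[, 1])), 1e-10)
  expect_lt(max(abs(g$theta[, ny] - 1)), 1e-10)
  expect_lt(max(abs(g$psi[, 1])), 1e-10)
  expect_lt(max(abs(g$psi[, ny] - g$F)), 1e-8)
})

test_that("a synthetic Gaussian stream function yields one bolus with the analytic contour area", {
  # psi = exp(-((x-0.5)^2 + (y-0.5)^2)/0.01) on the unit square; its level-0.5
  # contour is the circle r^2 = 0.01*ln 2, area pi*r^2
  n <- 129
  xs <- seq(0, 1, length.out = n)
  psi <- outer(xs, xs, function(x, y) exp(-((x - 0.5)^2 + (y - 0.5)^2) / 0.01))
  g <- structure(list(x = xs, yfrac = xs, h = rep(1, n), psi = psi,
                      F = 0, params = flowParams(eps = 0), nx_per_period = n),
                 class = "peristFieldGrid")
  b <- detectBoluses(g, n_levels = 1)   # single level at mid-range ~ 0.5
  expect_length(b$regions, 1)
  expect_equal(b$regions[[1]]$level, 0.5, tolerance = 1e-6)
  expect_equal(b$regions[[1]]$area, pi * 0.01 * log(2), tolerance = 0.02)
  expect_equal(unname(b$regions[[1]]$centroid), c(0.5, 0.5), tolerance = 1e-3)
  expect_equal(b$regions[[1]]$psi_extremum, 1, tolerance = 1e-3)
})

test_that("no boluses form in a straight channel (parallel flow)", {
  for (F in c(-0.4, 0, 0.4)) {
    g <- fieldGrid(flowParams(eps = 0, M = 1), F = F, nx = 65, ny = 65)
    expect_length(detectBoluses(g)$regions, 0)
  }
})

test_that("bolus detection is stable under grid refinement", {
  p <- defaultParams()
  a1 <- totalArea(detectBoluses(fieldGrid(p, F = 0, nx = 129, ny = 129)))
  a2 <- totalArea(detectBoluses(fieldGrid(p, F = 0, nx = 257, ny = 257)))
  expect_gt(a1, 0)
  expect_lt(abs(a2 - a1) / a1, 0.01)
})

test_that("degenerate grids are rejected and sweeps reduce to direct detection", {
  p <- defaultParams()
  expect_error(detectBoluses(fieldGrid(p, F = 0, nx = 33, ny = 33)), "resolution")
  sw <- bolusSweep("M", 2, 0, p)
  direct <- detectBoluses(fieldGrid(p, F = 0))
  expect_equal(sw$total_area, totalArea(direct))
  expect_equal(sw$n_boluses, length(direct$regions))
  # per-row errors are reported, not raised: Br = 9 violates the resonance guard
  sw2 <- bolusSweep("Br", c(2, 9), 0, p)
  expect_false(is.na(sw2$total_area[1]))
  expect_true(is.na(sw2$total_area[2]))
  expect_match(sw2$error[2], "resonance")
})

test_that("trapped boluses detach from both walls and have positive area", {
  p <- defaultParams()
  b <- detectBoluses(fieldGrid(p, F = 0))
  expect_gt(length(b$regions), 0)
  for (r in b$regions) {
    expect_gt(r$area, 0)
    first <- r$contour[1, ]; last <- r$contour[nrow(r$contour), ]
    expect_equal(unname(first), unname(last), tolerance = 1e-9)
    xs <- r$contour[, "x"]; ys <- r$contour[, "y"]
    expect_gt(min(ys), 0)
    expect_lt(max(ys - wallHeight(xs, p)), 0)
  }
})
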