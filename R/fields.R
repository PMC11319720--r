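# Closed-form solutions of the reduced (lubrication-limit) wave-frame system
#
#   theta'' + (Br^2 eta) theta = 0,            theta(0) = 0, theta(h) = 1
#   u'' - a1 u = a1 - cI - a2 theta,           u(0)    = 0, u(h)    = -1
#
# with a1 = M^2 (1+lambda1) cos^2(beta), a2 = c2 (1+lambda1),
#      cI = (1+lambda1) (c1 sin(alpha) - dp/dx),  k = Br sqrt(eta).
#
# The homogeneous velocity part is evaluated in a wall-anchored hyperbolic
# basis  phi1 = sinh(s y)/sinh(s h), phi2 = sinh(s (h-y))/sinh(s h)  written
# with decaying exponentials only, so nothing overflows at large Hartmann
# number.  The buoyancy particular solution is a2 * theta / (a1 + k^2), which
# is exact in both the oscillatory and the small-argument (eta -> 0) branch.

.A1_MIN <- 1e-8       # below this a1 the cI/a1 form is abandoned for the a1 -> 0 limit
.KH2_MIN <- 1e-10     # below this (k h)^2 the temperature uses its linear limit y/h

# temperature helpers, vectorized over y and h (k scalar)
.thetaVal <- function(y, h, k) {
  kh2 <- (k * h)^2
  ifelse(kh2 < .KH2_MIN, y / h, sin(k * y) / sin(k * h))
}
.thetaDer <- function(y, h, k) {
  kh2 <- (k * h)^2
  ifelse(kh2 < .KH2_MIN, 1 / h, k * cos(k * y) / sin(k * h))
}
.thetaInt <- function(y, h, k) {            # int_0^y theta
  kh2 <- (k * h)^2
  ifelse(kh2 < .KH2_MIN, y^2 / (2 * h), (1 - cos(k * y)) / (k * sin(k * h)))
}

.degenArg <- function(degenerate) {
  degenerate <- match.arg(degenerate, c("error", "limit"))
  degenerate
}

# Core evaluator: recycles x, y, dpdx to a common length and returns a list
# with u, dudy, psi at each point.  x, y, dpdx numeric vectors.
.fieldEval <- function(x, y, dpdx, params, degenerate = "error",
                       check_range = TRUE) {
  validateParams(params)
  degenerate <- .degenArg(degenerate)
  n <- max(length(x), length(y), length(dpdx))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  dpdx <- rep_len(as.numeric(dpdx), n)
  h <- wallHeight(x, params)
  if (check_range && any(y < -1e-12 | y > h + 1e-12))
    stop("y outside the channel: require 0 <= y <= h(x)")
  lam <- 1 + params$lambda1
  k <- params$Br * sqrt(params$eta)
  a1 <- params$M^2 * lam * cos(params$beta)^2
  a2 <- params$c2 * lam
  cI <- lam * (params$c1 * sin(params$alpha) - dpdx)
  th  <- .thetaVal(y, h, k)
  dth <- .thetaDer(y, h, k)
  Th  <- .thetaInt(y, h, k)

  if (a1 >= .A1_MIN) {
    s <- sqrt(a1)
    P <- a2 / (a1 + k^2)
    cA <- -1 + cI / a1
    B0 <- 1 - cI / a1
    Bh <- -cI / a1 - P
    Q  <- exp(-2 * s * h)                 # e^{-2 s h}
    E1 <- exp(-s * (h - y))
    E2 <- exp(-s * y)
    q1 <- exp(-2 * s * y)
    q2 <- exp(-2 * s * (h - y))
    d  <- 1 - Q
    phi1  <- E1 * (1 - q1) / d
    phi2  <- E2 * (1 - q2) / d
    dphi1 <- s * E1 * (1 + q1) / d
    dphi2 <- -s * E2 * (1 + q2) / d
    Phi1  <- (E1 * (1 + q1) - 2 * exp(-s * h)) / (s * d)
    Phi1h <- (1 - exp(-s * h)) / (s * (1 + exp(-s * h)))  # tanh(sh/2)/s
    Phi2  <- Phi1h - (E2 * (1 + q2) - 2 * exp(-s * h)) / (s * d)
    u    <- cA + B0 * phi2 + Bh * phi1 + P * th
    dudy <- B0 * dphi2 + Bh * dphi1 + P * dth
    psi  <- cA * y + B0 * Phi2 + Bh * Phi1 + P * Th
  } else {
    if (degenerate == "error")
      stop("degenerate configuration: a1 = M^2 (1+lambda1) cos^2(beta) = ",
           signif(a1, 4), " < ", .A1_MIN,
           "; pass degenerate = \"limit\" to use the a1 -> 0 solution")
    small_k <- (k * h)^2 < .KH2_MIN
    if (k^2 >= .KH2_MIN / max(h)^2) {
      up   <- -cI * y^2 / 2 + (a2 / k^2) * th
      dup  <- -cI * y + (a2 / k^2) * dth
      Iup  <- -cI * y^3 / 6 + (a2 / k^2) * Th
      uph  <- -cI * h^2 / 2 + a2 / k^2          # theta(h) = 1
    } else {
      up   <- -cI * y^2 / 2 - a2 * y^3 / (6 * h)
      dup  <- -cI * y - a2 * y^2 / (2 * h)
      Iup  <- -cI * y^3 / 6 - a2 * y^4 / (24 * h)
      uph  <- -cI * h^2 / 2 - a2 * h^2 / 6
    }
    B <- (-1 - uph) / h
    u    <- up + B * y
    dudy <- dup + B
    psi  <- Iup + B * y^2 / 2
  }
  list(x = x, y = y, h = h, u = u, dudy = dudy, psi = psi, theta = th)
}

#' Closed-form temperature field
#'
#' Dimensionless temperature
#' \eqn{\theta(y) = \sin(Br\,y\sqrt{\eta}) / \sin(Br\,h\sqrt{\eta})},
#' the exact solution of \eqn{\theta'' + \eta Br^2 \theta = 0} with
#' \eqn{\theta(0)=0,\ \theta(h)=1}.  When \eqn{(Br\,h\sqrt{\eta})^2 < 10^{-10}}
#' the small-argument limit \eqn{\theta = y/h} is returned instead (the
#' cosecant form is numerically unstable there).
#'
#' @param x dimensionless axial coordinate (vectorized, recycled with `y`).
#' @param y height above the channel centreline, `0 <= y <= h(x)`.
#' @param params a [flowParams()] object.
#' @return Numeric vector of temperatures.
#' @examples
#' p <- defaultParams()
#' temperature(0.25, wallHeight(0.25, p), p)  # wall value: exactly 1
#' @export
temperature <- function(x, y, params) {
  validateParams(params)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  h <- wallHeight(x, params)
  if (any(y < -1e-12 | y > h + 1e-12))
    stop("y outside the channel: require 0 <= y <= h(x)")
  k <- params$Br * sqrt(params$eta)
  if (any(abs(sin(k * h)) < 1e-12 & (k * h)^2 >= .KH2_MIN))
    stop("singular configuration: sin(Br*h*sqrt(eta)) vanishes at a requested x")
  .thetaVal(y, h, k)
}

#' Per-station solution constants of the closed-form velocity
#'
#' Returns the derived constants of the velocity closed form at station `x`
#' with imposed pressure gradient `dpdx`:
#' \eqn{a_1 = M^2(1+\lambda_1)\cos^2\beta}, \eqn{a_2 = c_2(1+\lambda_1)},
#' the momentum forcing constant
#' \eqn{c_I = (1+\lambda_1)(c_1\sin\alpha - dp/dx)}, and the
#' homogeneous-solution coefficients `c3`, `c4` obtained by solving the
#' two-point boundary system \eqn{u(0)=0,\ u(h)=-1} directly (in a
#' decaying-exponential form, so large Hartmann numbers do not overflow).
#'
#' @param x axial coordinate (scalar).
#' @param dpdx axial pressure gradient at this station (scalar).
#' @param params a [flowParams()] object.
#' @return An object of class `"peristConstants"`: list with fields
#'   `a1`, `a2`, `cI`, `c3`, `c4`, `h`, `dpdx`.
#' @export
solutionConstants <- function(x, dpdx, params) {
  validateParams(params)
  stopifnot(length(x) == 1L, length(dpdx) == 1L)
  lam <- 1 + params$lambda1
  k <- params$Br * sqrt(params$eta)
  a1 <- params$M^2 * lam * cos(params$beta)^2
  a2 <- params$c2 * lam
  cI <- lam * (params$c1 * sin(params$alpha) - dpdx)
  h <- wallHeight(x, params)
  if (a1 < .A1_MIN)
    stop("degenerate configuration: a1 = ", signif(a1, 4), " < ", .A1_MIN,
         "; the exponential-form constants c3, c4 are undefined as a1 -> 0")
  s <- sqrt(a1)
  P <- a2 / (a1 + k^2)
  B0 <- 1 - cI / a1              # u_hom(0) requirement
  Bh <- -cI / a1 - P             # u_hom(h) requirement
  E <- exp(-s * h)
  c4 <- (B0 - Bh * E) / (1 - E^2)
  c3 <- E * (Bh - B0 * E) / (1 - E^2)
  structure(list(a1 = a1, a2 = a2, cI = cI, c3 = c3, c4 = c4,
                 h = h, dpdx = dpdx),
            class = "peristConstants")
}

#' @export
print.peristConstants <- function(x, ...) {
  cat(sprintf("Solution constants at h = %g, dp/dx = %g:\n", x$h, x$dpdx))
  cat(sprintf("  a1 = %g  a2 = %g  cI = %g\n  c3 = %g  c4 = %g\n",
              x$a1, x$a2, x$cI, x$c3, x$c4))
  invisible(x)
}

#' Closed-form axial velocity (wave frame)
#'
#' Exact solution of the reduced momentum balance
#' \eqn{u'' - a_1 u = a_1 - c_I - a_2\theta} with no-slip wave-frame boundary
#' conditions \eqn{u(0) = 0}, \eqn{u(h) = -1}:
#' \deqn{u = -1 + c_I/a_1 + c_3 e^{\sqrt{a_1} y} + c_4 e^{-\sqrt{a_1} y}
#'       + \frac{a_2 \csc(Br\,h\sqrt{\eta}) \sin(Br\,y\sqrt{\eta})}{a_1 + Br^2\eta},}
#' evaluated in an overflow-safe hyperbolic form.  For degenerate
#' configurations (`a1` below `1e-8`, e.g. `M = 0`) the analytic
#' \eqn{a_1 \to 0} limit (the buoyant lubrication profile) is available via
#' `degenerate = "limit"`.
#'
#' @param x axial coordinate (vectorized; recycled with `y` and `dpdx`).
#' @param y height, `0 <= y <= h(x)`.
#' @param dpdx imposed axial pressure gradient.
#' @param params a [flowParams()] object.
#' @param degenerate `"error"` (default) or `"limit"`: behaviour when
#'   \eqn{a_1 < 10^{-8}}.
#' @return Numeric vector of wave-frame axial velocities.
#' @export
velocity <- function(x, y, dpdx, params, degenerate = "error") {
  .fieldEval(x, y, dpdx, params, degenerate)$u
}

#' Closed-form shear stress
#'
#' Jeffrey-fluid shear stress under the long-wavelength reduction,
#' \eqn{S_{xy} = \frac{1}{1+\lambda_1}\,\partial u/\partial y}, using the
#' analytic derivative of the velocity closed form (never numerical
#' differencing).
#'
#' @inheritParams velocity
#' @return Numeric vector of dimensionless shear stresses.
#' @export
shearStress <- function(x, y, dpdx, params, degenerate = "error") {
  .fieldEval(x, y, dpdx, params, degenerate)$dudy / (1 + params$lambda1)
}

#' Pointwise field evaluation over arbitrary points with wall masking
#'
#' Evaluates `u`, `theta`, `S_xy` (and the stream-function integrand
#' antiderivative `psi`, taken from `y = 0`) at arbitrary `(x, y)` points for
#' a fixed imposed pressure gradient.  Points above the wall (`y > h(x)`) or
#' below the centreline are returned as `NA` rather than an error, which is
#' the behaviour wanted for rectangular export grids.
#'
#' @inheritParams velocity
#' @return A `data.frame` with columns `x`, `y`, `h`, `u`, `theta`, `S_xy`,
#'   `psi`; masked rows carry `NA` fields.
#' @export
evalFields <- function(x, y, dpdx, params, degenerate = "error") {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  h <- wallHeight(x, params)
  ok <- y >= 0 & y <= h
  out <- data.frame(x = x, y = y, h = h, u = NA_real_, theta = NA_real_,
                    S_xy = NA_real_, psi = NA_real_)
  if (any(ok)) {
    ev <- .fieldEval(x[ok], y[ok], dpdx, params, degenerate)
    out$u[ok] <- ev$u
    out$theta[ok] <- ev$theta
    out$S_xy[ok] <- ev$dudy / (1 + params$lambda1)
    out$psi[ok] <- ev$psi
  }
  out
}
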