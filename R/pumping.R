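# Pressure-gradient / flow-rate coupling and per-wavelength pumping integrals.
#
# The wave-frame flow rate is F = int_0^h u dy, evaluated from the term-wise
# antiderivative of the velocity closed form.  F is affine in dp/dx (the model
# is linear in the forcing constant cI), so the inverse problem solve_dpdx is
# a two-evaluation linear solve, exact to rounding.

#' Wave-frame volumetric flow rate
#'
#' \eqn{F(x; dp/dx) = \int_0^{h(x)} u\,dy}, computed from the closed-form
#' antiderivative of the velocity profile (no quadrature).
#'
#' @inheritParams velocity
#' @return Numeric vector of flow rates (recycled over `x`, `dpdx`).
#' @export
flowRate <- function(x, dpdx, params, degenerate = "error") {
  n <- max(length(x), length(dpdx))
  x <- rep_len(as.numeric(x), n); dpdx <- rep_len(as.numeric(dpdx), n)
  h <- wallHeight(x, params)
  .fieldEval(x, h, dpdx, params, degenerate, check_range = FALSE)$psi
}

#' Pressure gradient for a prescribed flow rate
#'
#' Inverts the flux relation: returns the unique `dpdx` with
#' `flowRate(x, dpdx) = F`.  Because the reduced model is linear in the
#' forcing constant, the flow rate is an affine function of `dpdx`; two
#' evaluations determine the line and the solve is exact to rounding
#' (round-trip error below `1e-9`).
#'
#' @param F prescribed wave-frame flow rate (vectorized, recycled with `x`).
#' @param x axial coordinate.
#' @inheritParams velocity
#' @return Numeric vector of pressure gradients.
#' @export
solveDpdx <- function(F, x, params, degenerate = "error") {
  n <- max(length(F), length(x))
  F <- rep_len(as.numeric(F), n); x <- rep_len(as.numeric(x), n)
  F0 <- flowRate(x, 0, params, degenerate)
  F1 <- flowRate(x, 1, params, degenerate)
  slope <- F1 - F0
  if (any(abs(slope) < 1e-14))
    stop("degenerate flux/pressure-gradient coupling: |dF/d(dp/dx)| < 1e-14")
  (F - F0) / slope
}

# shared quadrature driver: integrates fun over [0, L] by composite
# Gauss-Legendre, doubling the panel count until successive estimates agree.
.glIntegrate <- function(fun, L, tol = 1e-9, nodes = 16, max_panels = 512) {
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  panels <- 4
  prev <- NA_real_
  repeat {
    edges <- seq(0, L, length.out = panels + 1)
    w <- diff(edges)
    total <- 0
    for (i in seq_len(panels)) {
      xs <- edges[i] + gl$x * w[i]
      total <- total + w[i] * sum(gl$w * fun(xs))
    }
    if (!is.na(prev) && abs(total - prev) < tol) return(total)
    prev <- total
    panels <- panels * 2
    if (panels > max_panels)
      stop("quadrature did not converge to ", tol, " within ", max_panels,
           " Gauss-Legendre panels (last change ", signif(abs(total - prev), 4), ")")
  }
}

.windowLength <- function(window) {
  window <- match.arg(window, c("paper", "one"))
  if (window == "paper") 2 * pi else 1
}

#' Pressure rise over the integration window
#'
#' \eqn{\Delta p_\lambda = \int_0^{2\pi} (dp/dx)\,dx} at prescribed flow rate
#' `F`, with `dpdx(x)` obtained from the flux condition at each station.  The
#' default window `[0, 2*pi]` follows the convention of the model's pumping
#' integrals; `window = "one"` integrates over a single geometric wavelength
#' `[0, 1]` instead (for `eps = 0` the two differ exactly by the factor
#' `2*pi`).  Composite Gauss--Legendre quadrature with panel doubling until
#' successive estimates differ by less than `tol`.
#'
#' @param F prescribed wave-frame flow rate (scalar).
#' @param params a [flowParams()] object.
#' @param window `"paper"` (default, `[0, 2*pi]`) or `"one"` (`[0, 1]`).
#' @param tol quadrature refinement tolerance.
#' @inheritParams velocity
#' @return Scalar pressure rise.
#' @export
pressureRise <- function(F, params, window = "paper", tol = 1e-9,
                         degenerate = "error") {
  stopifnot(length(F) == 1L)
  L <- .windowLength(window)
  .glIntegrate(function(xs) solveDpdx(F, xs, params, degenerate), L, tol)
}

#' Friction force over the integration window
#'
#' \eqn{F_\lambda = \int_0^{2\pi} -h^2\,(dp/dx)\,dx} at prescribed flow rate
#' `F`; same quadrature and window conventions as [pressureRise()].
#'
#' @inheritParams pressureRise
#' @return Scalar friction force.
#' @export
frictionForce <- function(F, params, window = "paper", tol = 1e-9,
                          degenerate = "error") {
  stopifnot(length(F) == 1L)
  L <- .windowLength(window)
  .glIntegrate(function(xs) {
    -wallHeight(xs, params)^2 * solveDpdx(F, xs, params, degenerate)
  }, L, tol)
}

#' Pumping curve over a grid of flow rates
#'
#' Evaluates the pressure rise and friction force at each flow rate in `F`,
#' producing the standard pumping characteristic of the configuration.
#'
#' @param F numeric vector of wave-frame flow rates.
#' @inheritParams pressureRise
#' @return A `data.frame` of class `"peristPumping"` with columns `F`,
#'   `delta_p`, `friction`; the parameter set, window and tolerance are
#'   attached as attributes and written into export headers.
#' @export
pumpingCurve <- function(F, params, window = "paper", tol = 1e-9,
                         degenerate = "error") {
  out <- data.frame(
    F = as.numeric(F),
    delta_p = vapply(F, pressureRise, numeric(1), params = params,
                     window = window, tol = tol, degenerate = degenerate),
    friction = vapply(F, frictionForce, numeric(1), params = params,
                      window = window, tol = tol, degenerate = degenerate))
  structure(out, params = params, window = window, tol = tol,
            class = c("peristPumping", "data.frame"))
}

#' Literal transcription of the printed pressure-gradient formula
#'
#' The model's printed pressure-gradient expression,
#' \deqn{\frac{dp}{dx} = c_1\sin\alpha +
#'   \frac{c_3\sqrt{a_1}e^{h\sqrt{a_1}} + c_4\sqrt{a_1}e^{-h\sqrt{a_1}}
#'         - a_1(F+h)}{h(1+\lambda_1)}
#'   + \frac{a_2 a_1}{h\,Br\sqrt{\eta}\,(a_1+Br^2\eta)(1+\lambda_1)},}
#' is implicit: its right side contains `c3`, `c4`, `cI`, which themselves
#' depend on `dp/dx`.  This function evaluates it by damped fixed-point
#' iteration, for use as a cross-check against the flux-condition solve
#' ([solveDpdx()], the product path).  See [pumpingDiscrepancy()].
#'
#' @param F prescribed flow rate (scalar).
#' @param x axial coordinate (scalar).
#' @param params a [flowParams()] object.
#' @param max_iter,tol iteration controls.
#' @param relax damping factor in (0, 1].
#' @return List with `dpdx` (the fixed point, or `NA` if not converged),
#'   `converged`, `iterations`.
#' @export
dpdxLiteral <- function(F, x, params, max_iter = 200, tol = 1e-10,
                        relax = 0.5) {
  validateParams(params)
  stopifnot(length(F) == 1L, length(x) == 1L)
  lam <- 1 + params$lambda1
  k <- params$Br * sqrt(params$eta)
  if (k <= 0) stop("the printed formula requires eta > 0 (it divides by Br*sqrt(eta))")
  h <- wallHeight(x, params)
  rhs <- function(dpdx) {
    sc <- solutionConstants(x, dpdx, params)
    s <- sqrt(sc$a1)
    params$c1 * sin(params$alpha) +
      (sc$c3 * s * exp(h * s) + sc$c4 * s * exp(-h * s) - sc$a1 * (F + h)) /
        (h * lam) +
      sc$a2 * sc$a1 / (h * k * (sc$a1 + k^2) * lam)
  }
  dpdx <- solveDpdx(F, x, params)      # start from the flux-condition value
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    nxt <- (1 - relax) * dpdx + relax * rhs(dpdx)
    if (!is.finite(nxt)) break
    if (abs(nxt - dpdx) < tol) { dpdx <- nxt; converged <- TRUE; break }
    dpdx <- nxt
  }
  list(dpdx = if (converged) dpdx else NA_real_, converged = converged,
       iterations = it)
}

#' Discrepancy report: printed formula vs flux-condition pressure gradient
#'
#' Compares the flux-condition pressure gradient (the product path) with the
#' printed implicit formula evaluated by fixed-point iteration, at a set of
#' stations.  The two routes are not forced to agree; the report documents
#' whatever difference exists.
#'
#' @param F prescribed flow rate (scalar).
#' @param params a [flowParams()] object.
#' @param x_stations axial stations to compare at.
#' @return A `data.frame` with columns `x`, `dpdx_flux`, `dpdx_literal`,
#'   `abs_diff`, `converged`.
#' @export
pumpingDiscrepancy <- function(F, params, x_stations = seq(0, 0.9, by = 0.1)) {
  rows <- lapply(x_stations, function(x) {
    flux_val <- solveDpdx(F, x, params)
    lit <- tryCatch(dpdxLiteral(F, x, params),
                    error = function(e) list(dpdx = NA_real_, converged = FALSE))
    data.frame(x = x, dpdx_flux = flux_val, dpdx_literal = lit$dpdx,
               abs_diff = abs(flux_val - lit$dpdx),
               converged = isTRUE(lit$converged))
  })
  do.call(rbind, rows)
}
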