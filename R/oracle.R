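# Independent finite-difference oracle for the reduced boundary-value system.
#
# At a fixed station x the reduced system is a pair of one-way-coupled linear
# two-point boundary-value problems on [0, h]:
#
#   theta'' + (Br^2 eta) theta = 0,      theta(0) = 0, theta(h) = 1
#   u''     - a1 u = a1 - cI - a2 theta, u(0)    = 0, u(h)    = -1
#
# discretized with second-order central differences on a uniform grid and
# solved directly (sparse tridiagonal LU).  The oracle shares no algebra with
# the closed forms: it never sees exponentials, cosecants or the printed
# constants, only the differential equations and boundary values.

.triSolve <- function(diag_main, off, rhs) {
  m <- length(diag_main)
  A <- Matrix::bandSparse(m, m, k = c(-1L, 0L, 1L),
                          diagonals = list(rep(off, m - 1L),
                                           diag_main,
                                           rep(off, m - 1L)))
  sol <- as.numeric(Matrix::solve(A, rhs))
  resid <- max(abs(A %*% sol - rhs))
  list(sol = sol, resid = resid, A = A)
}

#' Finite-difference solution of the reduced boundary-value system
#'
#' Solves the temperature equation first (it is independent of `u` after the
#' long-wavelength reduction), then the momentum equation with the discrete
#' temperature as source, both by direct sparse tridiagonal solves on a
#' uniform grid of `n` nodes spanning `[0, h(x)]`.  The scheme is
#' second-order accurate (and exact for solutions that are quadratic in `y`).
#'
#' @param x axial coordinate (scalar).
#' @param dpdx imposed axial pressure gradient (scalar).
#' @param params a [flowParams()] object.
#' @param n node count, `n >= 11` (odd preferred so the midpoint is a node).
#' @param cond_limit 1-norm condition-estimate threshold above which the
#'   discrete temperature system is declared near-resonant.
#' @return An object of class `"peristOracle"`: list with `y_nodes`, `u_fd`,
#'   `theta_fd`, `n`, `residual_norm` (max absolute discrete residual over
#'   both systems), `h`, `x`, `dpdx`.
#' @export
fdSolve <- function(x, dpdx, params, n = 2001, cond_limit = 1e12) {
  validateParams(params)
  stopifnot(length(x) == 1L, length(dpdx) == 1L)
  n <- as.integer(n)
  if (n < 11L) stop("fdSolve needs n >= 11 nodes")
  h <- wallHeight(x, params)
  y <- seq(0, h, length.out = n)
  dy <- h / (n - 1)
  lam <- 1 + params$lambda1
  k2 <- params$Br^2 * params$eta
  a1 <- params$M^2 * lam * cos(params$beta)^2
  a2 <- params$c2 * lam
  cI <- lam * (params$c1 * sin(params$alpha) - dpdx)
  m <- n - 2L
  off <- 1 / dy^2

  # temperature: (theta_{i-1} - 2 theta_i + theta_{i+1})/dy^2 + k2 theta_i = 0
  b_th <- c(rep(0, m - 1L), -off * 1)        # theta(h) = 1 moved to the RHS
  th_sys <- .triSolve(rep(-2 * off + k2, m), off, b_th)
  cond <- Matrix::condest(th_sys$A)$est
  if (!is.finite(cond) || cond > cond_limit)
    stop("near-resonant temperature system: 1-norm condition estimate ",
         signif(cond, 3), " exceeds ", cond_limit)
  theta <- c(0, th_sys$sol, 1)

  # momentum: (u_{i-1} - 2 u_i + u_{i+1})/dy^2 - a1 u_i = a1 - cI - a2 theta_i
  b_u <- (a1 - cI - a2 * theta[2:(n - 1L)])
  b_u[m] <- b_u[m] - off * (-1)              # u(h) = -1 moved to the RHS
  u_sys <- .triSolve(rep(-2 * off - a1, m), off, b_u)
  u <- c(0, u_sys$sol, -1)

  structure(list(y_nodes = y, u_fd = u, theta_fd = theta, n = n,
                 residual_norm = max(th_sys$resid, u_sys$resid),
                 h = h, x = x, dpdx = dpdx),
            class = "peristOracle")
}

#' @export
print.peristOracle <- function(x, ...) {
  cat(sprintf("FD boundary-value solution: n = %d nodes on [0, %g], residual %.3g\n",
              x$n, x$h, x$residual_norm))
  invisible(x)
}

#' Verify the closed-form fields against the finite-difference oracle
#'
#' Recomputes `u`, `theta`, `S_xy` and the flow rate independently by finite
#' differences at `n` nodes and reports the maximum absolute discrepancy of
#' each closed form: the fields at the shared nodes, the shear stress against
#' the central-differenced oracle velocity (interior nodes), and the
#' closed-form flux against the trapezoid rule applied to the oracle
#' velocity.  Failures are report entries, not exceptions.
#'
#' @param params a [flowParams()] object.
#' @param dpdx imposed pressure gradient (scalar).
#' @param x axial coordinate (scalar).
#' @param tol pass/fail tolerance applied to each discrepancy.
#' @param n oracle node count (default 4001).
#' @param degenerate see [velocity()]; `"limit"` lets `M = 0` runs verify
#'   the analytic degenerate path.
#' @return An object of class `"peristVerify"`: list with fields `max_abs`
#'   (named vector: `u`, `theta`, `S_xy`, `flux`), `pass` (named logical),
#'   `tol`, `n`, `x`, `dpdx`, `ok` (overall).
#' @export
verifyClosedForm <- function(params, dpdx, x = 0, tol = 1e-6, n = 4001,
                             degenerate = "error") {
  fd <- fdSolve(x, dpdx, params, n = n)
  y <- fd$y_nodes
  lam <- 1 + params$lambda1
  ev <- .fieldEval(rep(x, length(y)), y, rep(dpdx, length(y)), params,
                   degenerate)
  d_u <- max(abs(ev$u - fd$u_fd))
  d_th <- max(abs(ev$theta - fd$theta_fd))
  interior <- 2:(length(y) - 1L)
  dy <- y[2] - y[1]
  s_fd <- (fd$u_fd[interior + 1L] - fd$u_fd[interior - 1L]) / (2 * dy * lam)
  s_cf <- ev$dudy[interior] / lam
  d_s <- max(abs(s_cf - s_fd))
  flux_fd <- pracma::trapz(y, fd$u_fd)
  flux_cf <- flowRate(x, dpdx, params, degenerate)
  d_f <- abs(flux_cf - flux_fd)
  max_abs <- c(u = d_u, theta = d_th, S_xy = d_s, flux = d_f)
  pass <- max_abs < tol
  structure(list(max_abs = max_abs, pass = pass, tol = tol, n = n,
                 x = x, dpdx = dpdx, params = params,
                 residual_norm = fd$residual_norm, ok = all(pass)),
            class = "peristVerify")
}

#' @export
print.peristVerify <- function(x, ...) {
  cat(sprintf("Closed-form vs FD oracle (n = %d, tol = %g) at x = %g, dp/dx = %g\n",
              x$n, x$tol, x$x, x$dpdx))
  for (nm in names(x$max_abs))
    cat(sprintf("  %-6s max|diff| = %.3e  [%s]\n", nm, x$max_abs[[nm]],
                if (x$pass[[nm]]) "pass" else "FAIL"))
  cat(if (x$ok) "overall: pass\n" else "overall: FAIL\n")
  invisible(x)
}

#' Write a verification report as machine-parseable key: value lines
#'
#' @param report a `"peristVerify"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVerifyReport <- function(report, path) {
  stopifnot(inherits(report, "peristVerify"))
  p <- report$params
  lines <- c(
    sprintf("package_version: %s", as.character(utils::packageVersion("peristMHD"))),
    sprintf("x: %.17g", report$x),
    sprintf("dpdx: %.17g", report$dpdx),
    sprintf("n: %d", report$n),
    sprintf("tol: %.17g", report$tol),
    vapply(names(p), function(nm) sprintf("param_%s: %.17g", nm, p[[nm]]), character(1)),
    sprintf("residual_norm: %.17g", report$residual_norm),
    vapply(names(report$max_abs), function(nm)
      sprintf("max_abs_%s: %.17g", nm, report$max_abs[[nm]]), character(1)),
    vapply(names(report$pass), function(nm)
      sprintf("pass_%s: %s", nm, tolower(report$pass[[nm]])), character(1)),
    sprintf("overall: %s", if (report$ok) "pass" else "fail"))
  writeLines(lines, path)
  invisible(path)
}

#' Observed convergence order of the finite-difference scheme
#'
#' Solves at a doubling ladder of node counts, measures the max-abs error
#' against the closed form, and fits the order as the mean log2 error ratio
#' between successive refinements.
#'
#' @param params a [flowParams()] object.
#' @param dpdx imposed pressure gradient.
#' @param x axial coordinate.
#' @param n_ladder node counts (each roughly doubling).
#' @param degenerate see [velocity()].
#' @return List with `orders_u`, `orders_theta` (per-step observed orders),
#'   `errors_u`, `errors_theta`.
#' @export
fdConvergence <- function(params, dpdx, x = 0,
                          n_ladder = c(201, 401, 801, 1601),
                          degenerate = "error") {
  errs_u <- errs_t <- numeric(length(n_ladder))
  for (i in seq_along(n_ladder)) {
    fd <- fdSolve(x, dpdx, params, n = n_ladder[i])
    y <- fd$y_nodes
    ev <- .fieldEval(rep(x, length(y)), y, rep(dpdx, length(y)), params,
                     degenerate)
    errs_u[i] <- max(abs(ev$u - fd$u_fd))
    errs_t[i] <- max(abs(ev$theta - fd$theta_fd))
  }
  ratio_order <- function(e) {
    e <- pmax(e, .Machine$double.xmin)
    log2(e[-length(e)] / e[-1]) /
      log2((n_ladder[-1] - 1) / (n_ladder[-length(n_ladder)] - 1))
  }
  list(orders_u = ratio_order(errs_u), orders_theta = ratio_order(errs_t),
       errors_u = errs_u, errors_theta = errs_t, n_ladder = n_ladder)
}
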