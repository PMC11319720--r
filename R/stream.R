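# Wave-frame stream function, streamline topology and trapped-bolus metrics.
#
# Psi(x, y) = int_0^y u dy' in closed form, with dp/dx at each station fixed
# by the prescribed flow rate, so Psi(x, 0) = 0 and Psi(x, h(x)) = F: both
# walls are streamlines.  Trapping is quantified by marching-squares contours
# of Psi on a boundary-fitted grid; closed contours not touching either wall
# are grouped into nested families and the outermost contour of each family
# defines one bolus (area by the shoelace formula).

#' Wave-frame stream function
#'
#' \eqn{\Psi(x,y) = \int_0^y u\,dy'} in closed form (term-wise antiderivative
#' of the velocity solution), with the pressure gradient at each station
#' obtained internally from the flux condition [solveDpdx()].  By
#' construction \eqn{\Psi(x,0) = 0} and \eqn{\Psi(x,h(x)) = F}.
#'
#' @param x axial coordinate (vectorized, recycled with `y`).
#' @param y height, `0 <= y <= h(x)`.
#' @param F prescribed wave-frame flow rate (scalar).
#' @param params a [flowParams()] object.
#' @param degenerate see [velocity()].
#' @return Numeric vector of stream-function values.
#' @export
streamFunction <- function(x, y, F, params, degenerate = "error") {
  stopifnot(length(F) == 1L)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  dpdx <- solveDpdx(F, x, params, degenerate)
  .fieldEval(x, y, dpdx, params, degenerate)$psi
}

#' Boundary-fitted field grid over one (or more) wavelengths
#'
#' Samples `u`, `theta`, `S_xy` and `psi` on a grid that follows the wall:
#' `nx` axial stations per period and `ny` heights per column spanning
#' `[0, h(x)]` as a fixed fraction ladder `y = f * h(x)`.  The pressure
#' gradient at each station comes from the flux condition for the prescribed
#' flow rate `F`, so the column-wise boundary rows satisfy the wave-frame
#' boundary conditions and `psi` runs from 0 (centreline) to `F` (wall).
#'
#' @param params a [flowParams()] object.
#' @param F prescribed wave-frame flow rate.
#' @param nx axial stations per period (>= 3).
#' @param ny heights per column (>= 3).
#' @param periods number of wavelengths covered (default 2, which lets the
#'   bolus detector handle contours crossing the periodic seam).
#' @param degenerate see [velocity()].
#' @return An object of class `"peristFieldGrid"`: list with `x` (axial
#'   nodes), `yfrac` (height fractions), `h` (per-column wall height),
#'   matrices `u`, `theta`, `S_xy`, `psi` (`length(x)` by `ny`), plus `F`,
#'   `params`, `nx_per_period`.
#' @export
fieldGrid <- function(params, F = -0.4, nx = 129, ny = 129, periods = 2,
                      degenerate = "error") {
  validateParams(params)
  stopifnot(nx >= 3, ny >= 3, periods >= 1, length(F) == 1L)
  xs <- seq(0, periods, length.out = (nx - 1L) * periods + 1L)
  yfrac <- seq(0, 1, length.out = ny)
  h <- wallHeight(xs, params)
  dpdx <- solveDpdx(F, xs, params, degenerate)
  m <- length(xs)
  u <- theta <- sxy <- psi <- matrix(NA_real_, m, ny)
  for (i in seq_len(m)) {
    ev <- .fieldEval(rep(xs[i], ny), yfrac * h[i], rep(dpdx[i], ny),
                     params, degenerate)
    u[i, ] <- ev$u
    theta[i, ] <- ev$theta
    sxy[i, ] <- ev$dudy / (1 + params$lambda1)
    psi[i, ] <- ev$psi
  }
  structure(list(x = xs, yfrac = yfrac, h = h, u = u, theta = theta,
                 S_xy = sxy, psi = psi, F = F, params = params,
                 nx_per_period = nx, dpdx = dpdx),
            class = "peristFieldGrid")
}

#' @export
print.peristFieldGrid <- function(x, ...) {
  cat(sprintf("Boundary-fitted field grid: %d x %d nodes over %g period(s), F = %g\n",
              length(x$x), length(x$yfrac), max(x$x), x$F))
  invisible(x)
}

#' Coerce a field grid to a long data frame
#'
#' @param x a `"peristFieldGrid"`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A `data.frame` with columns `x`, `y`, `h`, `u`, `theta`, `S_xy`, `psi`.
#' @export
as.data.frame.peristFieldGrid <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  m <- length(x$x); ny <- length(x$yfrac)
  data.frame(x = rep(x$x, ny),
             y = as.vector(outer(x$h, x$yfrac)),
             h = rep(x$h, ny),
             u = as.vector(x$u), theta = as.vector(x$theta),
             S_xy = as.vector(x$S_xy), psi = as.vector(x$psi))
}

# ---- polygon helpers ------------------------------------------------------

# signed shoelace area of a closed polyline (first == last vertex allowed)
.shoelace <- function(px, py) {
  n <- length(px)
  if (px[1] == px[n] && py[1] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1L }
  j <- c(n, seq_len(n - 1L))
  sum(px[j] * py - px * py[j]) / 2
}

.polyCentroid <- function(px, py) {
  n <- length(px)
  if (px[1] == px[n] && py[1] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1L }
  j <- c(2:n, 1L)
  cr <- px * py[j] - px[j] * py
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(c(mean(px), mean(py)))
  c(sum((px + px[j]) * cr) / (6 * a), sum((py + py[j]) * cr) / (6 * a))
}

# even-odd ray casting; boundary points are "inside enough" for nesting tests
.pointInPolygon <- function(x0, y0, px, py) {
  n <- length(px)
  if (px[1] == px[n] && py[1] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1L }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((py[i] > y0) != (py[j] > y0)) {
      xint <- px[j] + (y0 - py[j]) * (px[i] - px[j]) / (py[i] - py[j])
      if (x0 < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# ---- bolus detection ------------------------------------------------------

#' Detect trapped boluses (closed streamline regions)
#'
#' Extracts marching-squares contours of the stream function at `n_levels`
#' evenly spaced levels between its grid minimum and maximum, keeps the
#' closed contours that touch neither wall, groups them into nested families,
#' and reports one bolus per outermost contour.  Contouring runs in the
#' boundary-fitted `(x, y/h)` coordinates (a homeomorphism of the channel, so
#' closedness is preserved); vertices and areas are reported in physical
#' `(x, y)` coordinates, area by the shoelace formula.
#'
#' When the grid spans two periods (the [fieldGrid()] default) contours
#' crossing the periodic seam are handled by keeping the outermost contours
#' whose centroid falls in the central window `[0.5, 1.5)` and reporting the
#' centroid modulo 1, which is equivalent to periodic stitching.
#'
#' @param grid a `"peristFieldGrid"` with at least 64 x 64 nodes per period.
#' @param n_levels number of contour levels (default 41).
#' @return An object of class `"peristBoluses"`: list of bolus regions, each
#'   with `contour` (two-column matrix of vertices), `area`, `centroid`,
#'   `level` and `psi_extremum` (grid extremum of psi inside the contour),
#'   plus a `summary` data frame; `totalArea()` gives the summed area.
#' @export
detectBoluses <- function(grid, n_levels = 41) {
  if (!inherits(grid, "peristFieldGrid")) stop("grid must be a peristFieldGrid")
  ny <- length(grid$yfrac)
  if (grid$nx_per_period < 64 || ny < 64)
    stop("degenerate resolution: bolus detection needs >= 64 x 64 nodes per period")
  periods <- max(grid$x)
  zmin <- min(grid$psi); zmax <- max(grid$psi)
  if (!(zmax > zmin)) {
    return(.emptyBoluses(grid, numeric(0)))
  }
  levels <- seq(zmin, zmax, length.out = n_levels + 2L)
  levels <- levels[-c(1L, n_levels + 2L)]
  cl <- grDevices::contourLines(x = grid$x, y = grid$yfrac, z = grid$psi,
                                levels = levels)
  tolf <- 1e-9
  closed <- Filter(function(cc) {
    nn <- length(cc$x)
    nn >= 4L &&
      abs(cc$x[1] - cc$x[nn]) < 1e-12 && abs(cc$y[1] - cc$y[nn]) < 1e-12 &&
      min(cc$y) > tolf && max(cc$y) < 1 - tolf
  }, cl)
  if (length(closed) == 0L) return(.emptyBoluses(grid, levels))

  # map to physical coordinates
  phys <- lapply(closed, function(cc) {
    h <- wallHeight(cc$x, grid$params)
    list(x = cc$x, y = cc$y * h, level = cc$level)
  })
  areas <- vapply(phys, function(pp) abs(.shoelace(pp$x, pp$y)), numeric(1))
  ord <- order(areas, decreasing = TRUE)

  # outermost = contained in no other closed contour (test a representative
  # vertex against every strictly larger contour, in fitted coordinates)
  outer_idx <- integer(0)
  for (i in ord) {
    contained <- FALSE
    for (j in ord) {
      if (j == i || areas[j] <= areas[i]) next
      if (.pointInPolygon(closed[[i]]$x[1], closed[[i]]$y[1],
                          closed[[j]]$x, closed[[j]]$y)) { contained <- TRUE; break }
    }
    if (!contained) outer_idx <- c(outer_idx, i)
  }

  regions <- lapply(outer_idx, function(i) {
    pp <- phys[[i]]
    cen <- .polyCentroid(pp$x, pp$y)
    # grid extremum of psi strictly inside the contour
    ij <- which(outer(grid$x, rep(1, length(grid$yfrac))) >= min(pp$x) &
                outer(grid$x, rep(1, length(grid$yfrac))) <= max(pp$x),
                arr.ind = TRUE)
    inside_vals <- numeric(0)
    if (nrow(ij) > 0) {
      xs <- grid$x[ij[, 1]]; ys <- grid$yfrac[ij[, 2]]
      keep <- ys >= min(closed[[i]]$y) & ys <= max(closed[[i]]$y)
      ij <- ij[keep, , drop = FALSE]
      if (nrow(ij) > 0) {
        inn <- vapply(seq_len(nrow(ij)), function(r)
          .pointInPolygon(grid$x[ij[r, 1]], grid$yfrac[ij[r, 2]],
                          closed[[i]]$x, closed[[i]]$y), logical(1))
        inside_vals <- grid$psi[ij[inn, , drop = FALSE]]
      }
    }
    lev <- closed[[i]]$level
    ext <- if (length(inside_vals) == 0) lev else {
      inside_vals[which.max(abs(inside_vals - lev))]
    }
    list(contour = cbind(x = pp$x, y = pp$y), area = areas[i],
         centroid = c(x = cen[1], y = cen[2]), level = lev,
         psi_extremum = ext)
  })

  # periodic de-duplication: keep one period's worth of regions
  if (periods >= 2) {
    cx <- vapply(regions, function(r) r$centroid[["x"]], numeric(1))
    keep <- cx >= 0.5 & cx < 1.5
    regions <- regions[keep]
    regions <- lapply(regions, function(r) {
      r$centroid[["x"]] <- r$centroid[["x"]] %% 1
      r
    })
  }
  .makeBoluses(grid, levels, regions)
}

.makeBoluses <- function(grid, levels, regions) {
  summ <- if (length(regions) == 0L) {
    data.frame(region = integer(0), level = numeric(0), area = numeric(0),
               centroid_x = numeric(0), centroid_y = numeric(0),
               psi_extremum = numeric(0))
  } else {
    data.frame(region = seq_along(regions),
               level = vapply(regions, `[[`, numeric(1), "level"),
               area = vapply(regions, `[[`, numeric(1), "area"),
               centroid_x = vapply(regions, function(r) r$centroid[["x"]], numeric(1)),
               centroid_y = vapply(regions, function(r) r$centroid[["y"]], numeric(1)),
               psi_extremum = vapply(regions, `[[`, numeric(1), "psi_extremum"))
  }
  structure(list(regions = regions, summary = summ, levels = levels,
                 F = grid$F, params = grid$params),
            class = "peristBoluses")
}

.emptyBoluses <- function(grid, levels) .makeBoluses(grid, levels, list())

#' @export
print.peristBoluses <- function(x, ...) {
  cat(sprintf("Trapped boluses: %d region(s), total area %.6g (F = %g)\n",
              length(x$regions), totalArea(x), x$F))
  if (nrow(x$summary) > 0) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Total trapped-bolus area
#'
#' @param boluses a `"peristBoluses"` object.
#' @return Summed area of all outermost closed-streamline regions.
#' @export
totalArea <- function(boluses) {
  if (length(boluses$regions) == 0L) return(0)
  sum(vapply(boluses$regions, `[[`, numeric(1), "area"))
}

#' Parameter sweep of trapped-bolus size
#'
#' Runs [detectBoluses()] at each value of one parameter, holding the grid
#' resolution and contour-level count identical across rows.  Per-row errors
#' (e.g. a value that violates the resonance guard) are reported in the table
#' rather than aborting the sweep.
#'
#' @param param_name one of the [flowParams()] field names.
#' @param values numeric vector of values to sweep.
#' @param F prescribed wave-frame flow rate.
#' @param params base configuration; `param_name` is replaced per row.
#' @param nx,ny grid resolution per period (see [fieldGrid()]).
#' @param n_levels contour-level count (see [detectBoluses()]).
#' @param degenerate passed through; `"limit"` lets `M = 0` rows run.
#' @return A `data.frame` with columns `value`, `total_area`, `n_boluses`,
#'   `error` (NA when the row succeeded).
#' @export
bolusSweep <- function(param_name, values, F, params, nx = 129, ny = 129,
                       n_levels = 41, degenerate = "error") {
  stopifnot(param_name %in% setdiff(names(params), NULL))
  rows <- lapply(values, function(v) {
    res <- tryCatch({
      pv <- do.call(modifyParams, c(list(params), stats::setNames(list(v), param_name)))
      b <- detectBoluses(fieldGrid(pv, F = F, nx = nx, ny = ny,
                                   degenerate = degenerate), n_levels)
      data.frame(value = v, total_area = totalArea(b),
                 n_boluses = length(b$regions), error = NA_character_)
    }, error = function(e) {
      data.frame(value = v, total_area = NA_real_, n_boluses = NA_integer_,
                 error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, rows)
}
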