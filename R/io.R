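# Configuration handling, deterministic delimited-text writers and the
# parameter-study drivers behind the command-line front end.

.MODES <- c("fields", "pumping", "streamlines", "sweep", "verify")
.PARAM_KEYS <- c("eps", "M", "beta", "alpha", "lambda1", "Br", "eta", "c1", "c2")
.CONFIG_KEYS <- c(.PARAM_KEYS,
                  "mode", "F", "dpdx", "F_grid", "window", "nx", "ny",
                  "n_levels", "figure", "sweep_param", "sweep_values",
                  "out_dir", "seed", "degrees", "degenerate", "d")

#' Read a run configuration from YAML or JSON
#'
#' Flat keys matching the [flowParams()] field names plus run settings
#' (`mode`, `F`, `dpdx`, `F_grid`, `window`, `nx`, `ny`, `n_levels`,
#' `figure`, `sweep_param`, `sweep_values`, `out_dir`, `seed`, `degrees`,
#' `degenerate`).  Unknown keys produce a warning, never a silent drop; the
#' legacy geometry key `d` is accepted but ignored with a warning (it plays
#' no role in the reduced system).  With `degrees = TRUE` (flag or config
#' key) the angles `alpha` and `beta` are interpreted in degrees.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param degrees interpret configured angles as degrees.
#' @return A validated `"peristConfig"` object (see [asRunConfig()]).
#' @export
readRunConfig <- function(path, degrees = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "' (use YAML or JSON)"))
  asRunConfig(raw, degrees = degrees)
}

#' Validate and normalize a run configuration
#'
#' @param x a named list of configuration values.
#' @param degrees interpret `alpha`/`beta` as degrees.
#' @return An object of class `"peristConfig"`: list with a validated
#'   `params` element plus the run settings, all defaults resolved.
#' @export
asRunConfig <- function(x, degrees = FALSE) {
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), .CONFIG_KEYS)
  if (length(unknown) > 0L)
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  if ("d" %in% names(x))
    warning("config key 'd' is accepted but ignored: the channel-width ",
            "parameter d plays no role in the reduced long-wavelength system")
  if (isTRUE(x$degrees)) degrees <- TRUE
  pargs <- x[intersect(names(x), .PARAM_KEYS)]
  if (degrees) {
    for (ang in intersect(c("alpha", "beta"), names(pargs)))
      pargs[[ang]] <- pargs[[ang]] * pi / 180
  }
  params <- do.call(flowParams, pargs)
  mode <- if (is.null(x$mode)) "fields" else match.arg(x$mode, .MODES)
  cfg <- list(
    params = params,
    mode = mode,
    F = if (is.null(x[["F"]])) -0.4 else as.numeric(x[["F"]]),
    dpdx = if (is.null(x$dpdx)) NULL else as.numeric(x$dpdx),
    F_grid = if (is.null(x$F_grid)) seq(-1, 1, by = 0.2) else as.numeric(x$F_grid),
    window = if (is.null(x$window)) "paper" else match.arg(x$window, c("paper", "one")),
    nx = if (is.null(x$nx)) 129L else as.integer(x$nx),
    ny = if (is.null(x$ny)) 129L else as.integer(x$ny),
    n_levels = if (is.null(x$n_levels)) 41L else as.integer(x$n_levels),
    figure = if (is.null(x$figure)) NULL else as.character(x$figure),
    sweep_param = if (is.null(x$sweep_param)) NULL else as.character(x$sweep_param),
    sweep_values = if (is.null(x$sweep_values)) NULL else as.numeric(x$sweep_values),
    out_dir = if (is.null(x$out_dir)) NULL else as.character(x$out_dir),
    seed = if (is.null(x$seed)) 1L else as.integer(x$seed),
    degenerate = if (is.null(x$degenerate)) "error" else match.arg(x$degenerate, c("error", "limit")))
  class(cfg) <- "peristConfig"
  cfg
}

# deterministic "%.12g" formatting so identical configs give byte-identical files
.fmtNum <- function(v) {
  if (is.numeric(v)) sprintf("%.12g", v) else as.character(v)
}

.metaLines <- function(meta) {
  vapply(names(meta), function(nm) {
    v <- meta[[nm]]
    sprintf("# %s: %s", nm, paste(.fmtNum(v), collapse = " "))
  }, character(1))
}

#' Write a data frame as delimited text with a commented metadata header
#'
#' Every output file embeds the full resolved parameter set and the package
#' version; numbers are formatted with 12 significant digits so identical
#' configurations produce byte-identical files.
#'
#' @param df a data frame.
#' @param path output path.
#' @param meta named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
writeDelimited <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("peristMHD ",
                                  as.character(utils::packageVersion("peristMHD")))),
            meta)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.metaLines(meta), con)
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.paramsMeta <- function(params, ...) {
  c(stats::setNames(lapply(.PARAM_KEYS, function(k) params[[k]]), .PARAM_KEYS),
    list(...))
}

# ---- parameter-study drivers ---------------------------------------------

#' Velocity profiles across a parameter sweep
#'
#' Wave-frame velocity profiles `u(y)` at station `x` for each value of one
#' parameter (`M`, `alpha`, `c1` or `lambda1`), at fixed imposed pressure
#' gradient.  The driver default `dpdx = -1` is a favourable gradient
#' (`dpdx < c1 sin(alpha)`, so the net forcing is forward): the regime in
#' which the characteristic pressure-assisted profile shapes appear.
#'
#' @param vary parameter name to sweep.
#' @param values numeric values of the swept parameter.
#' @param params base configuration.
#' @param dpdx imposed pressure gradient (fixed across the sweep).
#' @param x axial station.
#' @param ny number of heights sampled in `[0, h(x)]`.
#' @param degenerate see [velocity()].
#' @return A `data.frame` with columns `value`, `y`, `u`.
#' @export
velocityProfiles <- function(vary = "M", values, params = defaultParams(),
                             dpdx = -1, x = 0, ny = 101,
                             degenerate = "error") {
  stopifnot(vary %in% .PARAM_KEYS)
  do.call(rbind, lapply(values, function(v) {
    pv <- do.call(modifyParams, c(list(params), stats::setNames(list(v), vary)))
    y <- seq(0, wallHeight(x, pv), length.out = ny)
    data.frame(value = v, y = y, u = velocity(x, y, dpdx, pv, degenerate))
  }))
}

#' Temperature profiles across a parameter sweep
#'
#' @param vary `"Br"` or `"eta"`.
#' @inheritParams velocityProfiles
#' @return A `data.frame` with columns `value`, `y`, `theta`.
#' @export
temperatureProfiles <- function(vary = "Br", values, params = defaultParams(),
                                x = 0, ny = 101) {
  stopifnot(vary %in% c("Br", "eta"))
  do.call(rbind, lapply(values, function(v) {
    pv <- do.call(modifyParams, c(list(params), stats::setNames(list(v), vary)))
    y <- seq(0, wallHeight(x, pv), length.out = ny)
    data.frame(value = v, y = y, theta = temperature(x, y, pv))
  }))
}

#' Axial pressure-gradient profile at fixed flow rate
#'
#' @param F prescribed flow rate.
#' @param params configuration.
#' @param nx stations over one wavelength.
#' @param degenerate see [velocity()].
#' @return A `data.frame` with columns `x`, `dpdx`.
#' @export
pressureGradientProfile <- function(F = -0.4, params = defaultParams(),
                                    nx = 201, degenerate = "error") {
  xs <- seq(0, 1, length.out = nx)
  data.frame(x = xs, dpdx = solveDpdx(F, xs, params, degenerate))
}

#' Wall shear-stress profile at fixed flow rate
#'
#' Shear stress evaluated at the wall `y = h(x)`, with the pressure gradient
#' at each station fixed by the flux condition.
#'
#' @inheritParams pressureGradientProfile
#' @return A `data.frame` with columns `x`, `S_xy`.
#' @export
shearStressProfile <- function(F = -0.4, params = defaultParams(), nx = 201,
                               degenerate = "error") {
  xs <- seq(0, 1, length.out = nx)
  h <- wallHeight(xs, params)
  dpdx <- solveDpdx(F, xs, params, degenerate)
  data.frame(x = xs, S_xy = shearStress(xs, h, dpdx, params, degenerate))
}

#' Pumping curves across a parameter sweep
#'
#' Pressure rise and friction force over a grid of flow rates, for each
#' value of one swept parameter.
#'
#' @param vary parameter name to sweep.
#' @param values numeric values.
#' @param F_grid flow-rate grid.
#' @param params base configuration.
#' @param window see [pressureRise()].
#' @param degenerate see [velocity()].
#' @return A `data.frame` with columns `value`, `F`, `delta_p`, `friction`.
#' @export
pumpingSweep <- function(vary = "M", values, F_grid = seq(-1, 1, by = 0.2),
                         params = defaultParams(), window = "paper",
                         degenerate = "error") {
  stopifnot(vary %in% .PARAM_KEYS)
  do.call(rbind, lapply(values, function(v) {
    pv <- do.call(modifyParams, c(list(params), stats::setNames(list(v), vary)))
    pc <- pumpingCurve(F_grid, pv, window = window, degenerate = degenerate)
    cbind(value = v, as.data.frame(pc))
  }))
}

# Documented bolus-study conditions (package choices, stated in the vignette):
# the studies run at F = 0 (lab-frame mean flow equal to the wave speed, the
# classic trapping condition, inside the regime where closed streamlines
# exist); the Brinkman sweep runs at eta = 0.05 because the thermal resonance
# bound Br*(1+eps)*sqrt(eta) < pi makes Br up to 7 unreachable at eta = 0.5.
.BOLUS_F <- 0
.BOLUS_BR_ETA <- 0.05

#' Standard trapped-bolus studies
#'
#' The three standard sweeps of trapped-bolus size: Hartmann number
#' `M` in `{0, 0.1, 0.5, 0.8}`, Brinkman number `Br` in `{1, 3, 5, 7}` and
#' field inclination `beta` in `{0, 0.1, 0.3, 0.5}` rad.  All run at the
#' documented study flow rate `F = 0` (mean laboratory-frame flow equal to
#' the wave speed, inside the trapping regime).  The `Br` study uses
#' `eta = 0.05`: the resonance bound `Br*(1+eps)*sqrt(eta) < pi` makes
#' `Br >= 3` unreachable at the default `eta = 0.5`.
#'
#' @param which `"M"`, `"Br"` or `"beta"`.
#' @param params base configuration (defaults applied on top as described).
#' @param F study flow rate.
#' @param nx,ny,n_levels see [bolusSweep()].
#' @return The [bolusSweep()] data frame.
#' @export
bolusStudy <- function(which = c("M", "Br", "beta"), params = defaultParams(),
                       F = .BOLUS_F, nx = 129, ny = 129, n_levels = 41) {
  which <- match.arg(which)
  switch(which,
    M = bolusSweep("M", c(0, 0.1, 0.5, 0.8), F, params, nx, ny, n_levels,
                   degenerate = "limit"),
    Br = bolusSweep("Br", c(1, 3, 5, 7), F,
                    modifyParams(params, eta = .BOLUS_BR_ETA),
                    nx, ny, n_levels),
    beta = bolusSweep("beta", c(0, 0.1, 0.3, 0.5), F, params, nx, ny, n_levels))
}

# ---- mode dispatch --------------------------------------------------------

#' Run a configured computation
#'
#' Dispatches on `config$mode`:
#' \describe{
#'   \item{fields}{boundary-fitted field grid export ([fieldGrid()]).}
#'   \item{pumping}{pumping-curve table over the configured `F_grid`.}
#'   \item{streamlines}{stream-function grid, bolus contours and summary.}
#'   \item{sweep}{a parameter-study driver selected by `config$figure`
#'     (`"velocity"`, `"temperature"`, `"pressure_gradient"`,
#'     `"shear_stress"`, `"pumping"`, `"bolus_M"`, `"bolus_Br"`,
#'     `"bolus_beta"`), or a plain [bolusSweep()] when `sweep_param` and
#'     `sweep_values` are given.}
#'   \item{verify}{finite-difference verification report
#'     ([verifyClosedForm()]).}
#' }
#' When `config$out_dir` is set, each result is also written as delimited
#' text with a full metadata header.
#'
#' @param config a `"peristConfig"` (see [asRunConfig()], [readRunConfig()]).
#' @return A named list of results, invisibly when files are written.
#' @export
runModel <- function(config) {
  if (!inherits(config, "peristConfig")) config <- asRunConfig(config)
  p <- config$params
  meta <- .paramsMeta(p, mode = config$mode, F = config$F,
                      window = config$window, seed = config$seed)
  out <- list()
  if (config$mode == "fields") {
    g <- fieldGrid(p, F = config$F, nx = config$nx, ny = config$ny,
                   periods = 1, degenerate = config$degenerate)
    out$fields <- as.data.frame(g)
  } else if (config$mode == "pumping") {
    out$pumping <- as.data.frame(pumpingCurve(config$F_grid, p,
                                              window = config$window,
                                              degenerate = config$degenerate))
  } else if (config$mode == "streamlines") {
    g <- fieldGrid(p, F = config$F, nx = config$nx, ny = config$ny,
                   degenerate = config$degenerate)
    b <- detectBoluses(g, config$n_levels)
    out$bolus_summary <- b$summary
    out$contours <- if (length(b$regions) == 0L) {
      data.frame(region = integer(0), x = numeric(0), y = numeric(0))
    } else {
      do.call(rbind, lapply(seq_along(b$regions), function(i)
        data.frame(region = i, x = b$regions[[i]]$contour[, "x"],
                   y = b$regions[[i]]$contour[, "y"])))
    }
  } else if (config$mode == "sweep") {
    if (!is.null(config$figure)) {
      fig <- config$figure
      out$sweep <- switch(fig,
        velocity = velocityProfiles("M", c(0.5, 1, 1.5, 2), p,
                                    degenerate = config$degenerate),
        temperature = temperatureProfiles("Br", c(1, 1.5, 2), p),
        pressure_gradient = pressureGradientProfile(config$F, p,
                                                    degenerate = config$degenerate),
        shear_stress = shearStressProfile(config$F, p,
                                          degenerate = config$degenerate),
        pumping = pumpingSweep("M", c(1, 1.5, 2), params = p,
                               window = config$window,
                               degenerate = config$degenerate),
        bolus_M = bolusStudy("M", p, nx = config$nx, ny = config$ny,
                             n_levels = config$n_levels),
        bolus_Br = bolusStudy("Br", p, nx = config$nx, ny = config$ny,
                              n_levels = config$n_levels),
        bolus_beta = bolusStudy("beta", p, nx = config$nx, ny = config$ny,
                                n_levels = config$n_levels),
        stop("unknown figure driver: ", fig))
    } else if (!is.null(config$sweep_param)) {
      out$sweep <- bolusSweep(config$sweep_param, config$sweep_values,
                              config$F, p, config$nx, config$ny,
                              config$n_levels, config$degenerate)
    } else {
      stop("sweep mode needs either 'figure' or 'sweep_param' + 'sweep_values'")
    }
  } else if (config$mode == "verify") {
    dpdx <- if (is.null(config$dpdx)) 1 else config$dpdx
    out$verify <- verifyClosedForm(p, dpdx = dpdx,
                                   degenerate = config$degenerate)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      if (inherits(out[[nm]], "peristVerify")) {
        writeVerifyReport(out[[nm]], file.path(config$out_dir, "verify.txt"))
      } else {
        writeDelimited(out[[nm]], file.path(config$out_dir, paste0(nm, ".tsv")),
                       meta)
      }
    }
    return(invisible(out))
  }
  out
}
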