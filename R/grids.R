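#' Thermal and radiometric parameters of the PPTR kernel
#'
#' Bundles the three physical constants that determine the radiometric kernel
#' \eqn{K(z,t)}: the thermal diffusivity of skin, the reduced convective heat
#' transfer coefficient at the surface (Robin boundary), and the effective
#' mid-infrared absorption coefficient that weights subsurface heat by its
#' contribution to surface emission.
#'
#' The defaults are the values established for in vivo human skin with a
#' mid-IR camera detection band: \eqn{D = 0.11} mm\eqn{^2}/s,
#' \eqn{h = 0.02} mm\eqn{^{-1}}, \eqn{\mu = 22.3} mm\eqn{^{-1}}.
#'
#' @param diffusivity Thermal diffusion constant \eqn{D}, mm^2/s. Must be > 0.
#' @param heat_loss Reduced heat transfer coefficient \eqn{h}, mm^-1
#'   (the classical Robin coefficient \eqn{H/k}). Must be >= 0; `0` models an
#'   insulated surface.
#' @param ir_absorption Effective mid-IR absorption coefficient \eqn{\mu},
#'   mm^-1, for the camera detection band. Must be > 0.
#' @return An object of class `thermal_parameters` (a named list).
#' @examples
#' thermal_parameters()
#' thermal_parameters(heat_loss = 0) # insulated surface, conserves heat
#' @export
thermal_parameters <- function(diffusivity = 0.11,
                               heat_loss = 0.02,
                               ir_absorption = 22.3) {
  stopifnot(is.numeric(diffusivity), length(diffusivity) == 1L,
            is.numeric(heat_loss), length(heat_loss) == 1L,
            is.numeric(ir_absorption), length(ir_absorption) == 1L)
  if (!is.finite(diffusivity) || diffusivity <= 0)
    stop("`diffusivity` must be a positive finite number (mm^2/s)", call. = FALSE)
  if (!is.finite(heat_loss) || heat_loss < 0)
    stop("`heat_loss` must be a non-negative finite number (mm^-1)", call. = FALSE)
  if (!is.finite(ir_absorption) || ir_absorption <= 0)
    stop("`ir_absorption` must be a positive finite number (mm^-1)", call. = FALSE)
  structure(
    list(diffusivity = diffusivity,
         heat_loss = heat_loss,
         ir_absorption = ir_absorption),
    class = "thermal_parameters"
  )
}

#' @export
print.thermal_parameters <- function(x, ...) {
  cat("<thermal_parameters>\n")
  cat(sprintf("  diffusivity   D  = %g mm^2/s\n", x$diffusivity))
  cat(sprintf("  heat loss     h  = %g mm^-1\n", x$heat_loss))
  cat(sprintf("  IR absorption mu = %g mm^-1\n", x$ir_absorption))
  invisible(x)
}

#' Equidistant cell-centered depth grid
#'
#' The reconstruction depth grid: `n_points` equidistant cells covering
#' `[0, z_max]`, with cell centers at \eqn{z_j = (j + 1/2)\Delta z},
#' \eqn{j = 0, \dots, n-1}, \eqn{\Delta z = z_{max}/n}. Depth `z = 0` is the
#' skin surface; positive depths point into the tissue.
#'
#' @param n_points Number of depth cells (default 400).
#' @param z_max Maximum depth, mm. Typical values: 1.5-2.0 mm for 532 nm
#'   reconstructions, 3.0-3.5 mm for 1064 nm.
#' @return An object of class `depth_grid` with elements `n_points`, `z_max`,
#'   `dz` and `centers`.
#' @examples
#' g <- depth_grid(400, 2.0)
#' head(g$centers)
#' @export
depth_grid <- function(n_points = 400L, z_max = 2.0) {
  n_points <- as.integer(n_points)
  stopifnot(length(n_points) == 1L, length(z_max) == 1L)
  if (is.na(n_points) || n_points < 2L)
    stop("`n_points` must be an integer >= 2", call. = FALSE)
  if (!is.finite(z_max) || z_max <= 0)
    stop("`z_max` must be a positive finite depth in mm", call. = FALSE)
  dz <- z_max / n_points
  structure(
    list(n_points = n_points, z_max = z_max, dz = dz,
         centers = (seq_len(n_points) - 0.5) * dz),
    class = "depth_grid"
  )
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf("<depth_grid> %d cells over [0, %g] mm (dz = %g mm)\n",
              x$n_points, x$z_max, x$dz))
  invisible(x)
}

#' Uniform acquisition time grid
#'
#' Sample instants of a radiometric transient. The first sample is one frame
#' interval after the pulse (`t = dt`), avoiding the \eqn{t = 0} kernel
#' singularity; samples are `dt` apart.
#'
#' @param duration Total acquisition time, s. Typical values: 3 s for 532 nm,
#'   5 s for 1064 nm.
#' @param dt Frame interval, s (default 0.001, i.e. 1000 frames per second).
#' @return An object of class `time_grid` with elements `n_samples`, `dt` and
#'   `times`.
#' @examples
#' tg <- time_grid(3)
#' tg$n_samples # 3000
#' @export
time_grid <- function(duration = 3.0, dt = 0.001) {
  stopifnot(length(duration) == 1L, length(dt) == 1L)
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be > 0 (s)", call. = FALSE)
  if (!is.finite(duration) || duration < dt)
    stop("`duration` must be >= `dt` (s)", call. = FALSE)
  n <- as.integer(round(duration / dt))
  structure(
    list(n_samples = n, dt = dt, times = seq_len(n) * dt),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d samples, dt = %g s, [%g, %g] s\n",
              x$n_samples, x$dt, x$times[1], x$times[x$n_samples]))
  invisible(x)
}

#' Default per-wavelength acquisition and reconstruction settings
#'
#' Study defaults for the two probe wavelengths: the 532 nm (KTP) pulse is
#' acquired for 3 s and reconstructed over 2.0 mm; the deeper-penetrating
#' 1064 nm (Nd:YAG) pulse for 5 s over 3.0 mm. Both at 1000 frames per second
#' with 400 depth cells.
#'
#' @param wavelength Probe wavelength, nm; one of 532 or 1064.
#' @return A list with `depth_grid`, `time_grid` and `wavelength`.
#' @examples
#' wavelength_defaults(532)$time_grid$n_samples # 3000
#' @export
wavelength_defaults <- function(wavelength) {
  wavelength <- check_wavelength(wavelength)
  if (wavelength == 532) {
    list(depth_grid = depth_grid(400L, 2.0), time_grid = time_grid(3.0),
         wavelength = 532)
  } else {
    list(depth_grid = depth_grid(400L, 3.0), time_grid = time_grid(5.0),
         wavelength = 1064)
  }
}

check_wavelength <- function(wavelength) {
  if (length(wavelength) != 1L || !wavelength %in% c(532, 1064))
    stop("`wavelength` must be 532 or 1064 (nm)", call. = FALSE)
  as.numeric(wavelength)
}
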