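#' Green's function of the half-space heat equation with surface heat loss
#'
#' Temperature response \eqn{G(z, t \mid z_0)} of skin modeled as a 1-D
#' half-space (\eqn{z \ge 0}, surface at \eqn{z = 0}) obeying
#' \eqn{\partial T/\partial t = D\,\partial^2 T/\partial z^2} with the Robin
#' (convective) boundary condition
#' \eqn{\partial T/\partial z|_{z=0} = h\,T(0, t)}, for a unit-strength
#' instantaneous plane source at depth \eqn{z_0}:
#' \deqn{G = \frac{e^{-(z-z_0)^2/4Dt} + e^{-(z+z_0)^2/4Dt}}{\sqrt{4\pi D t}}
#'   - h\, e^{h(z+z_0)+h^2 D t}\,
#'     \mathrm{erfc}\!\left(\frac{z+z_0}{2\sqrt{Dt}} + h\sqrt{Dt}\right).}
#' The last term is evaluated through the scaled complementary error
#' function, so it never overflows. With `heat_loss = 0` the boundary is
#' insulated and \eqn{\int_0^\infty G\,dz = 1} for every \eqn{t}; with
#' \eqn{h > 0} heat escapes through the surface and the integral decays.
#'
#' Arguments `z`, `z0` and `t` are recycled to a common length.
#'
#' @param z Observation depth(s), mm (>= 0).
#' @param z0 Source depth(s), mm (>= 0).
#' @param t Time(s) since the instantaneous source, s (> 0).
#' @param params A [thermal_parameters()] object.
#' @return Temperature density in mm^-1 (per unit source strength).
#' @examples
#' p <- thermal_parameters(heat_loss = 0)
#' z <- seq(0, 6, by = 0.001)
#' sum(greens_function(z, 0.5, 0.5, p)) * 0.001 # ~1: heat is conserved
#' @export
greens_function <- function(z, z0, t, params = thermal_parameters()) {
  stopifnot(inherits(params, "thermal_parameters"))
  if (any(!is.finite(t)) || any(t <= 0))
    stop("`t` must be positive and finite (s)", call. = FALSE)
  if (any(!is.finite(z)) || any(z < 0) || any(!is.finite(z0)) || any(z0 < 0))
    stop("depths `z` and `z0` must be non-negative and finite (mm)", call. = FALSE)
  n <- max(length(z), length(z0), length(t))
  z <- rep_len(z, n); z0 <- rep_len(z0, n); t <- rep_len(t, n)
  D <- params$diffusivity
  h <- params$heat_loss
  s <- sqrt(D * t)
  direct <- exp(-(z - z0)^2 / (4 * D * t))
  image <- exp(-(z + z0)^2 / (4 * D * t))
  g <- (direct + image) / sqrt(4 * pi * D * t)
  if (h > 0) {
    b <- (z + z0) / (2 * s) + h * s
    # h * exp(h(z+z0) + h^2 D t) * erfc(b) == h * erfcx(b) * exp(-(z+z0)^2/4Dt)
    g <- g - h * erfcx(b) * image
  }
  g
}

#' Radiometric kernel K(z, t)
#'
#' Weight linking a unit initial temperature rise at depth \eqn{z} to the
#' radiometric surface signal at time \eqn{t} after the pulse:
#' \deqn{K(z, t) = \mu \int_0^\infty e^{-\mu z'}\, G(z', t \mid z)\, dz',}
#' i.e. the heat deposited at \eqn{z} is diffused by the Green's function and
#' the resulting temperature field is seen by the camera through effective
#' mid-IR emission attenuation \eqn{\mu e^{-\mu z'}}. The measured transient
#' is \eqn{\Delta S(t) = \int_0^\infty K(z,t)\,\Delta T(z,0)\,dz}.
#'
#' The integral has a closed form in scaled complementary error functions,
#' used here (and validated against adaptive quadrature of the defining
#' integral in the test suite). As \eqn{t \to 0^+}, \eqn{K \to \mu e^{-\mu z}};
#' with `heat_loss = 0`, \eqn{\int_0^\infty K\,dz = 1} for every \eqn{t}.
#'
#' `z` and `t` are recycled to a common length.
#'
#' @inheritParams greens_function
#' @return Kernel values, mm^-1.
#' @examples
#' kernel_value(0, 1e-6) # ~ mu = 22.3 mm^-1
#' @export
kernel_value <- function(z, t, params = thermal_parameters()) {
  stopifnot(inherits(params, "thermal_parameters"))
  if (any(!is.finite(t)) || any(t <= 0))
    stop("`t` must be positive and finite (s)", call. = FALSE)
  if (any(!is.finite(z)) || any(z < 0))
    stop("`z` must be non-negative and finite (mm)", call. = FALSE)
  n <- max(length(z), length(t))
  z <- rep_len(z, n); t <- rep_len(t, n)
  kernel_value_closed(z, t, params)
}

# Closed form of mu * int_0^inf exp(-mu z') G(z', t | z) dz'.
# With s = sqrt(D t), E = exp(-z^2 / 4Dt):
#   direct + image parts:
#     I1 = (mu/2) exp(D t mu^2 - mu z) erfc(mu s - z/2s)
#     I2 = (mu/2) erfcx(mu s + z/2s) E
#   Robin part: I3 = mu h / (mu - h) * (erfcx(mu s + z/2s) - erfcx(beta)) E,
#     beta = z/2s + h s.
# Each exp(...)erfc(...) product collapses to erfcx(...) * E, which is
# overflow-safe; I1 falls back to the direct product where its argument is
# negative (there the exponent is provably <= 0).
kernel_value_closed <- function(z, t, params) {
  D <- params$diffusivity
  h <- params$heat_loss
  mu <- params$ir_absorption
  s <- sqrt(D * t)
  E <- exp(-z^2 / (4 * D * t))
  u1 <- mu * s - z / (2 * s)
  u2 <- mu * s + z / (2 * s)
  i1 <- numeric(length(z))
  pos <- u1 >= 0
  if (any(pos)) i1[pos] <- erfcx(u1[pos]) * E[pos]
  if (any(!pos)) {
    # 2Dt*mu < z here, so D t mu^2 - mu z < -mu z / 2 <= 0: safe to exponentiate
    i1[!pos] <- exp(D * t[!pos] * mu^2 - mu * z[!pos]) * erfc_base(u1[!pos])
  }
  k <- (mu / 2) * (i1 + erfcx(u2) * E)
  if (h > 0) {
    beta <- z / (2 * s) + h * s
    if (abs(mu - h) > 1e-8 * mu) {
      k <- k + (mu * h / (mu - h)) * (erfcx(u2) - erfcx(beta)) * E
    } else {
      # degenerate mu == h: first-order limit via d/dx erfcx = 2x erfcx - 2/sqrt(pi)
      k <- k + mu * h * s * (2 * beta * erfcx(beta) - 2 / sqrt(pi)) * E
    }
  }
  k
}

# Defining-integral evaluation by adaptive quadrature; the independent route
# used to validate the closed form. Semi-infinite tail truncated where both
# the emission weight and the Gaussian have decayed below ~1e-8.
kernel_value_quadrature <- function(z, t, params = thermal_parameters(),
                                    rel.tol = 1e-10) {
  stopifnot(length(z) == 1L, length(t) == 1L)
  mu <- params$ir_absorption
  D <- params$diffusivity
  upper <- z + 12 / mu + 6 * sqrt(D * t)
  stats::integrate(function(zp) mu * exp(-mu * zp) * greens_function(zp, z, t, params),
                   lower = 0, upper = upper,
                   rel.tol = rel.tol, abs.tol = 0, subdivisions = 400L)$value
}

#' Discretized forward operator
#'
#' Builds the kernel matrix of the linear radiometric model
#' \eqn{S = K\,T}, with \eqn{K_{i,j} = K(z_j, t_i)\,\Delta z}: rows are time
#' samples, columns are depth cells, and the \eqn{\Delta z} factor folds the
#' depth quadrature into the matrix so that a matrix-vector product
#' discretizes the emission integral.
#'
#' @param depth_grid A [depth_grid()].
#' @param time_grid A [time_grid()].
#' @param params A [thermal_parameters()].
#' @return An object of class `pptr_kernel`: list with `values`
#'   (`n_times x n_depths` matrix), `depth_grid`, `time_grid`, `params` and
#'   `scale` (1 for an unscaled kernel).
#' @examples
#' k <- build_kernel_matrix(depth_grid(50, 2), time_grid(0.5, 0.01))
#' dim(k$values)
#' @export
build_kernel_matrix <- function(depth_grid, time_grid,
                                params = thermal_parameters()) {
  stopifnot(inherits(depth_grid, "depth_grid"), inherits(time_grid, "time_grid"),
            inherits(params, "thermal_parameters"))
  nz <- depth_grid$n_points
  nt <- time_grid$n_samples
  zz <- rep(depth_grid$centers, each = nt)
  tt <- rep(time_grid$times, times = nz)
  values <- matrix(kernel_value_closed(zz, tt, params) * depth_grid$dz,
                   nrow = nt, ncol = nz)
  structure(
    list(values = values, depth_grid = depth_grid, time_grid = time_grid,
         params = params, scale = 1.0),
    class = "pptr_kernel"
  )
}

#' @export
print.pptr_kernel <- function(x, ...) {
  cat(sprintf("<pptr_kernel> %d time samples x %d depth cells\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  depth [0, %g] mm, time [%g, %g] s, scale %g\n",
              x$depth_grid$z_max, x$time_grid$times[1],
              max(x$time_grid$times), x$scale))
  print(x$params)
  invisible(x)
}

#' Forward-project a temperature profile into a radiometric signal
#'
#' Applies the discretized radiometric model \eqn{S = K T}: given an initial
#' laser-induced temperature-depth profile it predicts the noiseless surface
#' transient the camera would record.
#'
#' @param profile A data frame with columns `depth_mm` and `delta_T_K`
#'   (and optional metadata columns such as `wavelength_nm`, `site`,
#'   `time_h`, which are carried through).
#' @param kernel A [build_kernel_matrix()] result; its depth grid must match
#'   the profile's depth column.
#' @return A tibble with columns `time_s`, `delta_T_K` plus carried metadata.
#' @examples
#' k <- build_kernel_matrix(depth_grid(50, 2), time_grid(0.5, 0.01))
#' prof <- tibble::tibble(depth_mm = k$depth_grid$centers,
#'                        delta_T_K = exp(-(depth_mm - 0.5)^2 / 0.02))
#' sig <- forward_project(prof, k)
#' @export
forward_project <- function(profile, kernel) {
  stopifnot(inherits(kernel, "pptr_kernel"))
  check_profile_frame(profile)
  check_grid_match(profile$depth_mm, kernel$depth_grid)
  values <- as.numeric(kernel$values %*% profile$delta_T_K)
  out <- tibble::tibble(time_s = kernel$time_grid$times, delta_T_K = values)
  carry_meta(out, profile)
}

# metadata columns carried from profiles to signals and back
meta_cols <- c("wavelength_nm", "site", "time_h", "repeat")

carry_meta <- function(out, from) {
  for (col in intersect(meta_cols, names(from))) {
    v <- unique(from[[col]])
    if (length(v) == 1L) out[[col]] <- v
  }
  out
}

check_profile_frame <- function(profile) {
  if (!is.data.frame(profile) || !all(c("depth_mm", "delta_T_K") %in% names(profile)))
    stop("`profile` must be a data frame with columns `depth_mm` and `delta_T_K`",
         call. = FALSE)
  if (any(!is.finite(profile$delta_T_K)))
    stop("profile values must be finite", call. = FALSE)
  invisible(profile)
}

check_signal_frame <- function(signal) {
  if (!is.data.frame(signal) || !all(c("time_s", "delta_T_K") %in% names(signal)))
    stop("`signal` must be a data frame with columns `time_s` and `delta_T_K`",
         call. = FALSE)
  if (any(!is.finite(signal$delta_T_K)))
    stop("signal values must be finite", call. = FALSE)
  invisible(signal)
}

check_grid_match <- function(depths, depth_grid, tol = 1e-9) {
  if (length(depths) != depth_grid$n_points ||
      max(abs(depths - depth_grid$centers)) > tol * max(1, depth_grid$z_max))
    stop("profile depth grid does not match the kernel depth grid", call. = FALSE)
  invisible(TRUE)
}

check_time_match <- function(times, time_grid, tol = 1e-9) {
  if (length(times) != time_grid$n_samples ||
      max(abs(times - time_grid$times)) > tol * max(1, max(time_grid$times)))
    stop("signal time grid does not match the kernel time grid", call. = FALSE)
  invisible(TRUE)
}
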