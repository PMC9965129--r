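#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a profile reconstruction
#'
#' @param x A `pptr_fit` from [reconstruct_profile()].
#' @param ... Unused.
#' @return For `tidy()`, the reconstructed profile tibble (`depth_mm`,
#'   `delta_T_K` plus metadata). For `glance()`, a one-row tibble with
#'   `iterations_run`, `converged`, `final_residual_K`, `noise_level_K`,
#'   `nu`, `scale_used`, `iuc_K_mm`.
#' @method tidy pptr_fit
#' @export
tidy.pptr_fit <- function(x, ...) x$profile

#' @rdname tidy.pptr_fit
#' @method glance pptr_fit
#' @export
glance.pptr_fit <- function(x, ...) {
  tibble::tibble(
    iterations_run = x$iterations_run,
    converged = x$converged,
    final_residual_K = x$residual_norms[x$iterations_run],
    noise_level_K = if (is.null(x$noise_level)) NA_real_ else x$noise_level,
    nu = x$nu,
    scale_used = x$scale_used,
    iuc_K_mm = integral_under_curve(x$profile)
  )
}

#' Tidy a kernel matrix
#'
#' @param x A `pptr_kernel`.
#' @param ... Unused.
#' @return For `tidy()`, a long tibble (`time_s`, `depth_mm`, `weight`);
#'   large for full-size kernels. For `glance()`, a one-row summary.
#' @method tidy pptr_kernel
#' @export
tidy.pptr_kernel <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$time_grid$times, times = x$depth_grid$n_points),
    depth_mm = rep(x$depth_grid$centers, each = x$time_grid$n_samples),
    weight = as.numeric(x$values)
  )
}

#' @rdname tidy.pptr_kernel
#' @method glance pptr_kernel
#' @export
glance.pptr_kernel <- function(x, ...) {
  tibble::tibble(
    n_times = x$time_grid$n_samples,
    n_depths = x$depth_grid$n_points,
    dt_s = x$time_grid$dt,
    dz_mm = x$depth_grid$dz,
    z_max_mm = x$depth_grid$z_max,
    diffusivity_mm2_s = x$params$diffusivity,
    heat_loss_per_mm = x$params$heat_loss,
    ir_absorption_per_mm = x$params$ir_absorption,
    scale = x$scale
  )
}
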