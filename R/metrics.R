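#' Integral under the temperature-depth curve (IUC)
#'
#' Trapezoidal integral of \eqn{\Delta T(z, 0)} over the profile's depth
#' grid, in K mm. The IUC estimates how much laser energy was absorbed in
#' the probed tissue, and is the quantity ratioed between bruised and
#' healthy sites by [epsilon_ratio()].
#'
#' @param profile A data frame with columns `depth_mm` and `delta_T_K`
#'   (at least 2 rows).
#' @return The trapezoidal integral, K mm.
#' @examples
#' g <- depth_grid(400, 2)
#' integral_under_curve(tibble::tibble(depth_mm = g$centers, delta_T_K = 1))
#' @export
integral_under_curve <- function(profile) {
  check_profile_frame(profile)
  if (nrow(profile) < 2L)
    stop("at least 2 profile points are required", call. = FALSE)
  pracma::trapz(profile$depth_mm, profile$delta_T_K)
}

#' Bruise-to-healthy contrast ratio epsilon
#'
#' The relative excess of absorbed energy at the bruised site:
#' \deqn{\varepsilon = \mathrm{IUC}_{bruise} / \mathrm{IUC}_{healthy} - 1.}
#' With non-negative profiles \eqn{\varepsilon \ge -1}; equal absorption
#' gives 0, and e.g. 0.8 means 80\% more energy absorbed in the bruise.
#'
#' @param iuc_bruise IUC of the bruised-site profile, K mm.
#' @param iuc_healthy IUC of the healthy reference profile, K mm (> 0).
#' @return Dimensionless ratio minus one.
#' @examples
#' epsilon_ratio(1.8, 1.0) # 0.8
#' @export
epsilon_ratio <- function(iuc_bruise, iuc_healthy) {
  if (any(!is.finite(iuc_healthy)) || any(iuc_healthy <= 0))
    stop("`iuc_healthy` must be positive", call. = FALSE)
  iuc_bruise / iuc_healthy - 1
}

#' Locate peaks in a temperature-depth profile
#'
#' Finds local maxima with topographic prominence at least `min_prominence`,
#' refines each peak depth by three-point parabolic interpolation, and
#' returns them sorted by depth. Prominence of a peak is its height above
#' the highest saddle separating it from any higher peak (the profile ends
#' count as valleys), which rejects reconstruction ripple without a
#' smoothing pass.
#'
#' @param profile A data frame with columns `depth_mm` and `delta_T_K`.
#' @param min_prominence Minimum prominence, K. Defaults to 5\% of the
#'   profile maximum.
#' @return A tibble with columns `depth_mm`, `amplitude_K`, `prominence_K`,
#'   one row per peak (possibly zero rows).
#' @examples
#' g <- depth_grid(200, 2)
#' prof <- tibble::tibble(depth_mm = g$centers,
#'                        delta_T_K = exp(-(depth_mm - 0.5)^2 / (2 * 0.01)))
#' find_profile_peaks(prof)
#' @export
find_profile_peaks <- function(profile,
                               min_prominence = 0.05 * max(profile$delta_T_K)) {
  check_profile_frame(profile)
  y <- profile$delta_T_K
  z <- profile$depth_mm
  n <- length(y)
  empty <- tibble::tibble(depth_mm = numeric(), amplitude_K = numeric(),
                          prominence_K = numeric())
  if (n < 3L || all(y == y[1])) return(empty)
  # interior local maxima, plateau-aware: a run of equal values flanked by
  # lower neighbours on both sides is one peak at the run centre (an exactly
  # grid-symmetric maximum samples its two top values identically)
  runs <- rle(y)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  nr <- length(runs$values)
  is_max <- integer()
  if (nr >= 3L) {
    for (k in 2:(nr - 1L)) {
      if (runs$values[k] > runs$values[k - 1L] &&
          runs$values[k] > runs$values[k + 1L])
        is_max <- c(is_max, as.integer((starts[k] + ends[k]) %/% 2L))
    }
  }
  if (length(is_max) == 0L) return(empty)
  prom <- vapply(is_max, function(i) topographic_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence
  if (!any(keep)) return(empty)
  idx <- is_max[keep]
  refined <- vapply(idx, function(i) parabolic_refine(z, y, i), numeric(1))
  out <- tibble::tibble(depth_mm = refined, amplitude_K = y[idx],
                        prominence_K = prom[keep])
  out[order(out$depth_mm), ]
}

# height above the higher of the two bases, where each base is the minimum
# on that side walking until higher ground or the profile end (ends count
# as valleys, as in common signal-processing prominence implementations)
topographic_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  j <- i
  while (j > 1L && y[j] <= y[i]) {
    j <- j - 1L
    left_min <- min(left_min, y[j])
  }
  right_min <- y[i]
  j <- i
  while (j < n && y[j] <= y[i]) {
    j <- j + 1L
    right_min <- min(right_min, y[j])
  }
  y[i] - max(left_min, right_min)
}

# vertex of the parabola through the three samples around a maximum;
# the shift is clamped to half a cell (a flat top makes the vertex formula
# ill-conditioned, but the true maximum still lies within the cell)
parabolic_refine <- function(z, y, i) {
  if (i <= 1L || i >= length(y)) return(z[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(z[i])
  delta <- max(-0.5, min(0.5, 0.5 * (y[i - 1] - y[i + 1]) / denom))
  z[i] + delta * (z[i + 1] - z[i])
}

#' Epsilon time series from repeated profile reconstructions
#'
#' Groups profiles by wavelength and time since injury, computes the IUC of
#' every repeat, and forms per-session \eqn{\varepsilon} from the mean IUCs
#' (ratio of means). The dispersion `epsilon_sd` is propagated to first
#' order from the standard deviations of the repeat IUCs:
#' \deqn{\sigma_\varepsilon = (1+\varepsilon)
#'   \sqrt{\mathrm{SE}_b^2/\bar b^2 + \mathrm{SE}_h^2/\bar h^2},}
#' with \eqn{\mathrm{SE}} the standard error of the repeat-mean IUC
#' (0 when a site has a single repeat).
#'
#' @param profiles A data frame of stacked profiles with columns `depth_mm`,
#'   `delta_T_K`, `site` (`"bruise"` or `"healthy"`), `wavelength_nm`,
#'   `time_h`, and `repeat` distinguishing repeated measurements.
#' @return A tibble with one row per (`wavelength_nm`, `time_h`):
#'   `epsilon`, `epsilon_sd`, `n_bruise`, `n_healthy`,
#'   `iuc_bruise`, `iuc_healthy`.
#' @export
epsilon_series <- function(profiles) {
  req <- c("depth_mm", "delta_T_K", "site", "wavelength_nm", "time_h", "repeat")
  if (!is.data.frame(profiles) || !all(req %in% names(profiles)))
    stop("`profiles` must contain columns ",
         paste(req, collapse = ", "), call. = FALSE)
  iuc <- profiles |>
    dplyr::group_by(.data$wavelength_nm, .data$time_h, .data$site,
                    .data$`repeat`) |>
    dplyr::summarise(
      iuc = integral_under_curve(dplyr::pick(dplyr::all_of(c("depth_mm", "delta_T_K")))),
      .groups = "drop"
    )
  per_site <- iuc |>
    dplyr::group_by(.data$wavelength_nm, .data$time_h, .data$site) |>
    dplyr::summarise(mean_iuc = mean(.data$iuc),
                     se_iuc = if (dplyr::n() > 1)
                       stats::sd(.data$iuc) / sqrt(dplyr::n()) else 0,
                     n = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(per_site,
                             names_from = "site",
                             values_from = c("mean_iuc", "se_iuc", "n"))
  if (!all(c("mean_iuc_bruise", "mean_iuc_healthy") %in% names(wide)) ||
      any(is.na(wide$mean_iuc_healthy)) || any(is.na(wide$mean_iuc_bruise)))
    stop("every (wavelength, time) point needs both a bruise and a healthy site",
         call. = FALSE)
  wide |>
    dplyr::mutate(
      epsilon = epsilon_ratio(.data$mean_iuc_bruise, .data$mean_iuc_healthy),
      epsilon_sd = (1 + .data$epsilon) *
        sqrt((.data$se_iuc_bruise / .data$mean_iuc_bruise)^2 +
               (.data$se_iuc_healthy / .data$mean_iuc_healthy)^2)
    ) |>
    dplyr::transmute(.data$wavelength_nm, .data$time_h,
                     .data$epsilon, .data$epsilon_sd,
                     n_bruise = .data$n_bruise, n_healthy = .data$n_healthy,
                     iuc_bruise = .data$mean_iuc_bruise,
                     iuc_healthy = .data$mean_iuc_healthy) |>
    dplyr::arrange(.data$wavelength_nm, .data$time_h)
}
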