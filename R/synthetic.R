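#' Parametric model of bruised and healthy skin temperature profiles
#'
#' Gaussian-mixture parameterization of the initial laser-induced
#' temperature rise \eqn{\Delta T(z, 0)} in bruised and healthy skin, with a
#' simple time course of the traumatic blood pool: the pool amplitude rises
#' as extravasated hemoglobin accumulates, the pool center migrates linearly
#' from `pool_depth_initial` toward `pool_depth_final` over
#' `migration_time` as hemoglobin diffuses toward the epidermal-dermal
#' junction, and after migration completes the amplitude decays as the
#' bruise resolves. The 532 nm profile is attenuated exponentially with
#' depth (shallow penetration of green light); the 1064 nm pool is much
#' broader (deep penetration) and may carry an additional wide swelling
#' term at 1.5 mm that is strongest right after the injury.
#'
#' Amplitude defaults keep the synthetic maximum temperature rise well below
#' 1.5 K for non-swelling bruises, and the default time course places the
#' 532 nm contrast maximum several days after injury.
#'
#' @param epidermal_depth,epidermal_width Center and SD of the epidermal
#'   melanin peak, mm.
#' @param epidermal_amp Epidermal peak amplitude, K.
#' @param pool_depth_initial,pool_depth_final Blood-pool center right after
#'   injury and after migration, mm (`final < initial`).
#' @param migration_time Time over which the pool center migrates, h.
#' @param pool_width_532,pool_width_1064 Pool Gaussian SD seen by each
#'   wavelength, mm.
#' @param pool_amp_peak Peak pool amplitude, K.
#' @param pool_rise_time,pool_decay_time Time constants of the pool
#'   amplitude rise and (post-migration) decay, h.
#' @param swelling_amp Amplitude of the 1064 nm swelling term, K (0
#'   disables it; severe bruises with edema are emulated with ~0.2).
#' @param swelling_decay_time Decay time of the swelling term, h.
#' @param attenuation_depth_532 Depth constant of the 532 nm exponential
#'   attenuation, mm.
#' @param max_temp_rise_cap Hard clip on any generated temperature rise, K.
#' @return An object of class `bruise_model` (a named list).
#' @examples
#' bruise_model()
#' bruise_model(swelling_amp = 0.2) # severe bruise with edema
#' @export
bruise_model <- function(epidermal_depth = 0.06,
                         epidermal_width = 0.03,
                         epidermal_amp = 0.6,
                         pool_depth_initial = 0.55,
                         pool_depth_final = 0.30,
                         migration_time = 168,
                         pool_width_532 = 0.15,
                         pool_width_1064 = 0.6,
                         pool_amp_peak = 0.3,
                         pool_rise_time = 24,
                         pool_decay_time = 120,
                         swelling_amp = 0,
                         swelling_decay_time = 72,
                         attenuation_depth_532 = 0.35,
                         max_temp_rise_cap = 4.5) {
  m <- list(epidermal_depth = epidermal_depth, epidermal_width = epidermal_width,
            epidermal_amp = epidermal_amp,
            pool_depth_initial = pool_depth_initial,
            pool_depth_final = pool_depth_final,
            migration_time = migration_time,
            pool_width_532 = pool_width_532, pool_width_1064 = pool_width_1064,
            pool_amp_peak = pool_amp_peak, pool_rise_time = pool_rise_time,
            pool_decay_time = pool_decay_time, swelling_amp = swelling_amp,
            swelling_decay_time = swelling_decay_time,
            attenuation_depth_532 = attenuation_depth_532,
            max_temp_rise_cap = max_temp_rise_cap)
  lengths_ok <- c(m$epidermal_depth, m$epidermal_width, m$pool_depth_initial,
                  m$pool_depth_final, m$pool_width_532, m$pool_width_1064,
                  m$attenuation_depth_532)
  if (any(!is.finite(unlist(m))) || any(lengths_ok <= 0))
    stop("all length parameters must be positive and finite", call. = FALSE)
  if (m$migration_time <= 0 || m$pool_rise_time <= 0 ||
      m$pool_decay_time <= 0 || m$swelling_decay_time <= 0)
    stop("all time constants must be positive", call. = FALSE)
  if (m$epidermal_amp < 0 || m$pool_amp_peak < 0 || m$swelling_amp < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  if (m$pool_depth_final >= m$pool_depth_initial)
    stop("`pool_depth_final` must be shallower than `pool_depth_initial`",
         call. = FALSE)
  structure(m, class = "bruise_model")
}

#' @export
print.bruise_model <- function(x, ...) {
  cat("<bruise_model>\n")
  cat(sprintf("  epidermal peak: %g K at %g mm (SD %g mm)\n",
              x$epidermal_amp, x$epidermal_depth, x$epidermal_width))
  cat(sprintf("  blood pool: %g K peak, %g -> %g mm over %g h\n",
              x$pool_amp_peak, x$pool_depth_initial, x$pool_depth_final,
              x$migration_time))
  cat(sprintf("  swelling: %g K (1064 nm only)\n", x$swelling_amp))
  invisible(x)
}

gauss_peak <- function(z, center, width, amp) {
  amp * exp(-(z - center)^2 / (2 * width^2))
}

# pool center at time tau since injury: linear migration toward the surface
pool_center <- function(model, time_h) {
  frac <- pmin(time_h, model$migration_time) / model$migration_time
  model$pool_depth_initial -
    (model$pool_depth_initial - model$pool_depth_final) * frac
}

# pool amplitude: saturating rise, exponential decay after migration ends
pool_amplitude <- function(model, time_h) {
  model$pool_amp_peak * (1 - exp(-time_h / model$pool_rise_time)) *
    exp(-pmax(0, time_h - model$migration_time) / model$pool_decay_time)
}

#' Ground-truth bruised-skin temperature profile
#'
#' Evaluates the [bruise_model()] at a given wavelength and time since
#' injury: an epidermal melanin Gaussian plus the migrating dermal
#' blood-pool Gaussian. For 532 nm the whole profile is multiplied by
#' \eqn{e^{-z/\lambda_{att}}} and the narrow pool width applies; for
#' 1064 nm the broad pool width applies and, if `swelling_amp > 0`, a wide
#' swelling Gaussian at 1.5 mm decaying with time is added. Values are
#' clipped at `max_temp_rise_cap`.
#'
#' @param model A [bruise_model()].
#' @param wavelength 532 or 1064 (nm).
#' @param time_h Time since injury, h (>= 0).
#' @param grid A [depth_grid()].
#' @return A profile tibble (`depth_mm`, `delta_T_K`, `wavelength_nm`,
#'   `time_h`, `site = "bruise"`).
#' @examples
#' prof <- bruise_profile(bruise_model(), 532, 72, depth_grid(400, 2))
#' find_profile_peaks(prof)
#' @export
bruise_profile <- function(model, wavelength, time_h, grid) {
  stopifnot(inherits(model, "bruise_model"), inherits(grid, "depth_grid"))
  wavelength <- check_wavelength(wavelength)
  if (length(time_h) != 1L || !is.finite(time_h) || time_h < 0)
    stop("`time_h` must be a single non-negative time in hours", call. = FALSE)
  z <- grid$centers
  epi <- gauss_peak(z, model$epidermal_depth, model$epidermal_width,
                    model$epidermal_amp)
  zb <- pool_center(model, time_h)
  ab <- pool_amplitude(model, time_h)
  if (wavelength == 532) {
    pool <- gauss_peak(z, zb, model$pool_width_532, ab)
    values <- (epi + pool) * exp(-z / model$attenuation_depth_532)
  } else {
    pool <- gauss_peak(z, zb, model$pool_width_1064, ab)
    values <- epi + pool
    if (model$swelling_amp > 0) {
      values <- values + gauss_peak(z, 1.5, 0.8,
                                    model$swelling_amp *
                                      exp(-time_h / model$swelling_decay_time))
    }
  }
  tibble::tibble(depth_mm = z, delta_T_K = pmin(values, model$max_temp_rise_cap),
                 wavelength_nm = wavelength, time_h = time_h, site = "bruise")
}

#' Ground-truth healthy-skin temperature profile
#'
#' The uninjured reference site: an epidermal melanin peak, a papillary
#' dermis vascular peak at 0.25 mm, and — for the deep-penetrating 1064 nm
#' probe — a deep blood-net peak at 1.2 mm. Peak amplitudes are fixed
#' fractions of `epidermal_amp` (15\% papillary, 25\% deep net); the 532 nm
#' profile is attenuated with depth like the bruised one. Deterministic per
#' model.
#'
#' @inheritParams bruise_profile
#' @return A profile tibble (`site = "healthy"`, `time_h = NA`).
#' @export
healthy_profile <- function(model, wavelength, grid) {
  stopifnot(inherits(model, "bruise_model"), inherits(grid, "depth_grid"))
  wavelength <- check_wavelength(wavelength)
  z <- grid$centers
  values <- gauss_peak(z, model$epidermal_depth, model$epidermal_width,
                       model$epidermal_amp) +
    gauss_peak(z, 0.25, 0.08, 0.15 * model$epidermal_amp)
  if (wavelength == 1064) {
    values <- values + gauss_peak(z, 1.2, 0.3, 0.25 * model$epidermal_amp)
  } else {
    values <- values * exp(-z / model$attenuation_depth_532)
  }
  tibble::tibble(depth_mm = z, delta_T_K = pmin(values, model$max_temp_rise_cap),
                 wavelength_nm = wavelength, time_h = NA_real_, site = "healthy")
}

#' Simulate repeated noisy PPTR measurements of one profile
#'
#' Forward-projects a ground-truth profile through the kernel and adds
#' i.i.d. Gaussian camera noise per frame, once per repeat — emulating the
#' three to five radiometric transients acquired per site and session.
#' Fully reproducible for a given `seed`.
#'
#' @param profile A ground-truth profile tibble on the kernel's depth grid.
#' @param kernel A [build_kernel_matrix()] result.
#' @param noise_sd Per-frame noise SD, K (>= 0); 0.005 emulates a cooled
#'   mid-IR camera after lateral averaging.
#' @param n_repeats Number of repeats, 1-10.
#' @param seed Integer RNG seed for the noise.
#' @return A signal tibble with columns `time_s`, `delta_T_K`, `repeat`
#'   plus metadata carried from the profile.
#' @examples
#' k <- build_kernel_matrix(depth_grid(50, 2), time_grid(0.5, 0.01))
#' prof <- bruise_profile(bruise_model(), 532, 72, k$depth_grid)
#' sigs <- simulate_measurement(prof, k, noise_sd = 0.005, n_repeats = 3,
#'                              seed = 1)
#' @export
simulate_measurement <- function(profile, kernel, noise_sd = 0.005,
                                 n_repeats = 3L, seed = 1L) {
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be non-negative (K)", call. = FALSE)
  n_repeats <- as.integer(n_repeats)
  if (is.na(n_repeats) || n_repeats < 1L || n_repeats > 10L)
    stop("`n_repeats` must be between 1 and 10", call. = FALSE)
  clean <- forward_project(profile, kernel)
  n <- nrow(clean)
  noise <- with_local_seed(seed, matrix(stats::rnorm(n * n_repeats, sd = noise_sd),
                                        nrow = n))
  purrr::map_dfr(seq_len(n_repeats), function(r) {
    out <- clean
    out$delta_T_K <- clean$delta_T_K + noise[, r]
    out$`repeat` <- r
    out
  })
}

# run code under a temporary RNG state so simulation never disturbs the
# caller's random stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# deterministic substream seed per (study seed, counter); adding sessions
# must not perturb earlier ones, so each unit of work gets its own offset
substream_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(counter)) %% 2147483647)
}

#' Simulate a full two-wavelength bruise monitoring study
#'
#' Generates, for every session time and both wavelengths, ground-truth
#' bruised and healthy profiles and 3-5 noisy measurement repeats per site
#' (the repeat count is drawn deterministically from the seed, emulating
#' the varying number of usable transients per session). Ground truth is
#' retained alongside the signals so reconstruction accuracy can be
#' measured directly.
#'
#' @param model A [bruise_model()].
#' @param session_times Measurement times since injury, h, strictly
#'   increasing (default `c(24, 48, 96, 144, 192, 288)`: daily at first,
#'   sparser as the bruise heals).
#' @param noise_sd Per-frame camera noise SD, K.
#' @param seed Integer seed; one study stream, with per-session/site
#'   substreams derived by counter offsets.
#' @param settings Per-wavelength acquisition settings; a named list
#'   (`"532"`, `"1064"`) of lists with `depth_grid` and `time_grid`.
#'   Defaults to [wavelength_defaults()] for both wavelengths.
#' @return An object of class `bruise_study`: list with `signals` (long
#'   tibble: `site`, `wavelength_nm`, `time_h`, `repeat`, `time_s`,
#'   `delta_T_K`), `truth` (long profile tibble), `kernels` (per
#'   wavelength), `model`, `session_times`, `noise_sd`, `seed`.
#' @examples
#' \donttest{
#' study <- simulate_bruise_study(bruise_model(), seed = 7)
#' dplyr::count(study$signals, wavelength_nm, time_h, site)
#' }
#' @export
simulate_bruise_study <- function(model = bruise_model(),
                                  session_times = c(24, 48, 96, 144, 192, 288),
                                  noise_sd = 0.005, seed = 1L,
                                  settings = NULL) {
  stopifnot(inherits(model, "bruise_model"))
  if (length(session_times) < 1L)
    stop("`session_times` must contain at least one session", call. = FALSE)
  if (any(diff(session_times) <= 0))
    stop("`session_times` must be strictly increasing", call. = FALSE)
  if (is.null(settings))
    settings <- list(`532` = wavelength_defaults(532),
                     `1064` = wavelength_defaults(1064))
  kernels <- purrr::map(settings, function(s)
    build_kernel_matrix(s$depth_grid, s$time_grid))

  counter <- 0L
  signals <- list()
  truth <- list()
  for (si in seq_along(session_times)) {
    th <- session_times[si]
    for (wl in names(settings)) {
      wavelength <- as.numeric(wl)
      kern <- kernels[[wl]]
      profs <- list(
        bruise = bruise_profile(model, wavelength, th, kern$depth_grid),
        healthy = dplyr::mutate(
          healthy_profile(model, wavelength, kern$depth_grid), time_h = th)
      )
      for (site in names(profs)) {
        counter <- counter + 1L
        sub <- substream_seed(seed, counter)
        n_rep <- 3L + with_local_seed(sub, sample.int(3L, 1L)) - 1L # 3..5
        sig <- simulate_measurement(profs[[site]], kern, noise_sd = noise_sd,
                                    n_repeats = n_rep,
                                    seed = substream_seed(sub, 1L))
        signals[[length(signals) + 1L]] <- sig
        truth[[length(truth) + 1L]] <- profs[[site]]
      }
    }
  }
  structure(
    list(signals = dplyr::bind_rows(signals), truth = dplyr::bind_rows(truth),
         kernels = kernels, model = model, session_times = session_times,
         noise_sd = noise_sd, seed = seed),
    class = "bruise_study"
  )
}

#' @export
print.bruise_study <- function(x, ...) {
  cat(sprintf("<bruise_study> %d sessions (%s h), noise %g mK, seed %d\n",
              length(x$session_times),
              paste(x$session_times, collapse = ", "),
              1000 * x$noise_sd, x$seed))
  cat(sprintf("  %d signals across %d wavelengths\n",
              nrow(dplyr::distinct(x$signals, .data$site, .data$wavelength_nm,
                                   .data$time_h, .data$`repeat`)),
              length(x$kernels)))
  invisible(x)
}
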