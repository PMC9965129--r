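#' Average repeated radiometric transients
#'
#' Pointwise mean of repeated measurements of the same site, after an
#' optional baseline subtraction: if `baseline_window > 0` and the signal
#' contains pre-pulse samples (`time_s <= 0`), the mean of the last
#' `baseline_window` pre-pulse samples is subtracted from every repeat.
#' Repeats must share one time grid and wavelength.
#'
#' @param signals A signal tibble with columns `time_s`, `delta_T_K` and
#'   `repeat` (a single-repeat frame without `repeat` is returned after
#'   baseline handling).
#' @param baseline_window Number of pre-pulse samples used for the baseline
#'   estimate (0 disables).
#' @return A signal tibble `time_s`, `delta_T_K` plus carried metadata.
#' @export
average_signals <- function(signals, baseline_window = 0L) {
  check_signal_frame(signals)
  if ("wavelength_nm" %in% names(signals) &&
      length(unique(signals$wavelength_nm)) > 1L)
    stop("cannot average signals of mixed wavelengths", call. = FALSE)
  reps <- if ("repeat" %in% names(signals))
    split(signals, signals$`repeat`) else list(signals)
  times <- reps[[1]]$time_s
  for (r in reps) {
    if (nrow(r) != length(times) || max(abs(r$time_s - times)) > 1e-12)
      stop("all repeats must share an identical time grid", call. = FALSE)
  }
  values <- vapply(reps, function(r) {
    v <- r$delta_T_K
    if (baseline_window > 0L) {
      pre <- which(r$time_s <= 0)
      if (length(pre) > 0L) {
        use <- utils::tail(pre, baseline_window)
        v <- v - mean(v[use])
      }
    }
    v
  }, numeric(length(times)))
  out <- tibble::tibble(time_s = times, delta_T_K = rowMeans(values))
  carry_meta(out, signals)
}

#' Reconstruct every repeat of a simulated or measured study
#'
#' Runs the projected nu-method on each (site, wavelength, session, repeat)
#' signal of a [simulate_bruise_study()] result and stacks the reconstructed
#' profiles into one long tibble ready for [epsilon_series()].
#'
#' By default every signal of a wavelength is reconstructed with the same
#' fixed iteration budget (matched truncation): epsilon ratios IUCs between
#' sites, and the regularization bias of early stopping only cancels in the
#' ratio when bruise and healthy reconstructions are truncated identically.
#' A per-signal discrepancy stop would fire at different iteration counts
#' on the two sites and leave a site-dependent IUC deficit. The default
#' budgets (100 iterations at 532 nm, 600 at 1064 nm, whose signal carries
#' slower deep-heat information) were calibrated on synthetic studies; pass
#' `stop_rule = "discrepancy"` to override.
#'
#' @param study A `bruise_study` object.
#' @param ... Passed to [reconstruct_profile()] (e.g. `nu`, `stop_rule`,
#'   `discrepancy_tau`).
#' @param iterations Named vector of per-wavelength iteration budgets used
#'   with the default fixed-iteration rule.
#' @param noise_level Noise SD handed to the discrepancy stop if selected;
#'   defaults to the study's generating `noise_sd`.
#' @return A tibble of reconstructed profiles: `site`, `wavelength_nm`,
#'   `time_h`, `repeat`, `depth_mm`, `delta_T_K`, `iterations_run`,
#'   `converged`.
#' @export
reconstruct_study <- function(study, ...,
                              iterations = c(`532` = 100L, `1064` = 600L),
                              noise_level = study$noise_sd) {
  stopifnot(inherits(study, "bruise_study"))
  groups <- dplyr::group_split(
    dplyr::group_by(study$signals, .data$site, .data$wavelength_nm,
                    .data$time_h, .data$`repeat`))
  defaults <- list(stop_rule = "fixed_iterations")
  purrr::map_dfr(groups, function(sig) {
    wl <- as.character(sig$wavelength_nm[1])
    kern <- study$kernels[[wl]]
    args <- utils::modifyList(
      list(signal = sig, kernel = kern, noise_level = noise_level,
           stop_rule = "fixed_iterations",
           max_iterations = unname(iterations[wl])),
      list(...))
    fit <- do.call(reconstruct_profile, args)
    dplyr::mutate(fit$profile,
                  site = sig$site[1],
                  `repeat` = sig$`repeat`[1],
                  iterations_run = fit$iterations_run,
                  converged = fit$converged)
  })
}

#' Simulate, reconstruct and summarise a bruise study end-to-end
#'
#' Convenience pipeline: [simulate_bruise_study()] (unless a study is
#' supplied), [reconstruct_study()], then [epsilon_series()] on both the
#' reconstructions and the ground-truth profiles.
#'
#' @param study A `bruise_study`, or `NULL` to simulate one.
#' @param model,session_times,noise_sd,seed Passed to
#'   [simulate_bruise_study()] when `study` is `NULL`.
#' @param ... Passed to [reconstruct_study()].
#' @return A list with `study`, `reconstructions` (long profile tibble),
#'   `epsilon` (from reconstructions), `epsilon_truth` (from ground truth).
#' @examples
#' \donttest{
#' res <- run_bruise_study(seed = 7)
#' res$epsilon
#' }
#' @export
run_bruise_study <- function(study = NULL, model = bruise_model(),
                             session_times = c(24, 48, 96, 144, 192, 288),
                             noise_sd = 0.005, seed = 1L, ...) {
  if (is.null(study))
    study <- simulate_bruise_study(model, session_times, noise_sd, seed)
  recon <- reconstruct_study(study, ...)
  eps <- epsilon_series(recon)
  truth <- dplyr::mutate(study$truth, `repeat` = 1L)
  eps_truth <- epsilon_series(truth)
  list(study = study, reconstructions = recon, epsilon = eps,
       epsilon_truth = eps_truth)
}

#' Dermal blood-pool depth per profile
#'
#' Convenience summary used for recovery checks: for each profile group,
#' the depth of the temperature maximum in the dermal window
#' (`depth_mm >= min_depth`, which excludes the epidermal melanin peak),
#' refined by three-point parabolic interpolation. A windowed argmax is
#' robust for broad, low-prominence pool features (the deep 1064 nm pool
#' rides on the epidermal tail), where a prominence filter would be
#' fragile.
#'
#' @param profiles Long profile tibble with grouping columns `site`,
#'   `wavelength_nm`, `time_h` and optionally `repeat`.
#' @param min_depth Depths at or above this count as dermal, mm.
#' @return A tibble with the grouping columns and `pool_depth_mm`.
#' @export
pool_depths <- function(profiles, min_depth = 0.15) {
  keys <- intersect(c("site", "wavelength_nm", "time_h", "repeat"),
                    names(profiles))
  groups <- dplyr::group_split(dplyr::group_by(
    profiles, dplyr::across(dplyr::all_of(keys))))
  purrr::map_dfr(groups, function(p) {
    p <- p[order(p$depth_mm), ]
    win <- which(p$depth_mm >= min_depth)
    i <- win[which.max(p$delta_T_K[win])]
    depth <- parabolic_refine(p$depth_mm, p$delta_T_K, i)
    dplyr::bind_cols(p[1, keys], tibble::tibble(pool_depth_mm = depth))
  })
}
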