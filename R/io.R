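#' Read and write radiometric signal CSV files
#'
#' Signals are stored as plain CSV with header `time_s,delta_T_K`, one row
#' per frame, preceded by `# key=value` comment lines carrying metadata
#' (`wavelength_nm`, `site`, `time_since_injury_h`, `repeat`). Round trips
#' are value-exact to better than 1e-9.
#'
#' @param path File path.
#' @param signal A signal tibble with columns `time_s`, `delta_T_K` and
#'   optional metadata columns.
#' @return `read_signal_csv()` returns a signal tibble;
#'   `write_signal_csv()` returns `path` invisibly.
#' @export
read_signal_csv <- function(path) {
  parsed <- read_annotated_csv(path, c("time_s", "delta_T_K"))
  df <- parsed$data
  if (any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1] + 1L
    stop(sprintf("non-monotone time column at data row %d of '%s'", bad, path),
         call. = FALSE)
  }
  attach_meta(df, parsed$meta)
}

#' @rdname read_signal_csv
#' @export
write_signal_csv <- function(signal, path) {
  check_signal_frame(signal)
  write_annotated_csv(signal, path, c("time_s", "delta_T_K"))
}

#' Read and write temperature-profile CSV files
#'
#' Profiles use the same scheme as [read_signal_csv()] with header
#' `depth_mm,delta_T_K`. The depth grid must be equidistant; reads validate
#' this.
#'
#' @inheritParams read_signal_csv
#' @param profile A profile tibble with columns `depth_mm`, `delta_T_K`.
#' @return `read_profile_csv()` returns a profile tibble;
#'   `write_profile_csv()` returns `path` invisibly.
#' @export
read_profile_csv <- function(path) {
  parsed <- read_annotated_csv(path, c("depth_mm", "delta_T_K"))
  df <- parsed$data
  dz <- diff(df$depth_mm)
  if (any(dz <= 0) || max(abs(dz - dz[1])) > 1e-9 * max(1, abs(dz[1])))
    stop(sprintf("depth grid in '%s' is not equidistant ascending", path),
         call. = FALSE)
  attach_meta(df, parsed$meta)
}

#' @rdname read_profile_csv
#' @export
write_profile_csv <- function(profile, path) {
  check_profile_frame(profile)
  write_annotated_csv(profile, path, c("depth_mm", "delta_T_K"))
}

# ---- annotated-CSV plumbing -------------------------------------------------

# metadata column <-> file key mapping (time_h is stored under the
# descriptive key time_since_injury_h)
meta_key_of <- c(wavelength_nm = "wavelength_nm", site = "site",
                 time_h = "time_since_injury_h", `repeat` = "repeat")

write_annotated_csv <- function(df, path, value_cols) {
  lines <- character()
  for (col in intersect(names(meta_key_of), names(df))) {
    v <- unique(df[[col]])
    if (length(v) == 1L && !is.na(v))
      lines <- c(lines, sprintf("# %s=%s", meta_key_of[[col]],
                                format(v, digits = 15)))
  }
  body <- vapply(seq_len(nrow(df)), function(i)
    paste(sprintf("%.12g", c(df[[value_cols[1]]][i], df[[value_cols[2]]][i])),
          collapse = ","), character(1))
  writeLines(c(lines, paste(value_cols, collapse = ","), body), path)
  invisible(path)
}

read_annotated_csv <- function(path, value_cols) {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  n_head <- match(FALSE, is_comment) - 1L
  if (is.na(n_head)) stop(sprintf("'%s' contains no data", path), call. = FALSE)
  meta <- list()
  for (i in seq_len(n_head)) {
    kv <- sub("^\\s*#\\s*", "", lines[i])
    if (!grepl("=", kv, fixed = TRUE))
      stop(sprintf("unparsable metadata at line %d of '%s': '%s'",
                   i, path, lines[i]), call. = FALSE)
    key <- sub("=.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^=]*=", "", kv))
  }
  header <- strsplit(lines[n_head + 1L], ",", fixed = TRUE)[[1]]
  if (length(header) < 2L || !all(value_cols == trimws(header[1:2])))
    stop(sprintf("'%s' must have header '%s' (line %d)",
                 path, paste(value_cols, collapse = ","), n_head + 1L),
         call. = FALSE)
  body <- lines[-seq_len(n_head + 1L)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop(sprintf("malformed data at line %d of '%s'",
                 n_head + 1L + bad[1], path), call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2,
              byrow = TRUE)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m[, 1]) | !is.finite(m[, 2]))[1]
    stop(sprintf("non-numeric value at data row %d of '%s'", bad, path),
         call. = FALSE)
  }
  df <- tibble::tibble(!!value_cols[1] := m[, 1], !!value_cols[2] := m[, 2])
  list(data = df, meta = meta)
}

attach_meta <- function(df, meta) {
  for (col in names(meta_key_of)) {
    key <- meta_key_of[[col]]
    if (!is.null(meta[[key]])) {
      v <- meta[[key]]
      num <- suppressWarnings(as.numeric(v))
      df[[col]] <- if (!is.na(num) && col != "site") num else v
    }
  }
  df
}

# ---- kernel matrix persistence ---------------------------------------------

#' Persist a kernel matrix as CSV plus a JSON sidecar
#'
#' The matrix itself is written as a headerless CSV (rows = time samples),
#' and the grids, thermal parameters and scaling state go to
#' `<path>.json` with fields `diffusivity_mm2_s`, `heat_loss_per_mm`,
#' `ir_absorption_per_mm`, `n_depths`, `z_max_mm`, `n_times`, `dt_s`,
#' `scale`.
#'
#' @param kernel A [build_kernel_matrix()] result.
#' @param path Path of the matrix CSV; the sidecar is written next to it.
#' @return `write_kernel_matrix()` returns `path` invisibly;
#'   `read_kernel_matrix()` rebuilds the `pptr_kernel` object.
#' @export
write_kernel_matrix <- function(kernel, path) {
  stopifnot(inherits(kernel, "pptr_kernel"))
  utils::write.table(kernel$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(
    diffusivity_mm2_s = kernel$params$diffusivity,
    heat_loss_per_mm = kernel$params$heat_loss,
    ir_absorption_per_mm = kernel$params$ir_absorption,
    n_depths = kernel$depth_grid$n_points,
    z_max_mm = kernel$depth_grid$z_max,
    n_times = kernel$time_grid$n_samples,
    dt_s = kernel$time_grid$dt,
    scale = kernel$scale
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kernel_matrix
#' @export
read_kernel_matrix <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(values) <- NULL
  dg <- depth_grid(sc$n_depths, sc$z_max_mm)
  tg <- time_grid(sc$n_times * sc$dt_s, sc$dt_s)
  if (nrow(values) != tg$n_samples || ncol(values) != dg$n_points)
    stop(sprintf("matrix in '%s' does not match its sidecar dimensions", path),
         call. = FALSE)
  structure(
    list(values = values, depth_grid = dg, time_grid = tg,
         params = thermal_parameters(sc$diffusivity_mm2_s, sc$heat_loss_per_mm,
                                     sc$ir_absorption_per_mm),
         scale = sc$scale),
    class = "pptr_kernel"
  )
}

#' Write a run manifest
#'
#' Records configuration, seed, package version and MD5 hashes of the input
#' files of a pipeline run so that deterministic stages can be re-run
#' bit-identically from the manifest alone.
#'
#' @param path Output JSON path.
#' @param config A named list of configuration values.
#' @param seed Integer seed used (or `NULL`).
#' @param inputs Character vector of input file paths to hash.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL,
                           inputs = character()) {
  manifest <- list(
    package = "pptrbruise",
    version = as.character(utils::packageVersion("pptrbruise")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_hashes = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
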