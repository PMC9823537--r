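CUBE_MAGIC <- "RGCUBE1\n"

#' Read and write radar cube containers
#'
#' @description
#' Self-describing binary container for raw complex ADC cubes.  Layout:
#'
#' 1. 8-byte magic `"RGCUBE1\n"`;
#' 2. little-endian int32 header length, then that many bytes of JSON
#'    holding the [chirp_config()] block, the dims
#'    `(frames, chirps, samples)` and the sample encoding;
#' 3. payload: complex64 little-endian (float32 I then float32 Q per
#'    sample, 8 bytes each), sample index varying fastest, then chirp,
#'    then frame — `frames * chirps * samples * 8` bytes in total.
#'
#' Samples are stored in single precision, so `write_cube()` followed by
#' `read_cube()` reproduces the cube to float32 precision exactly (and a
#' second round trip is bit-identical).  Complex I/Q sampling is assumed;
#' the encoding string records it.
#'
#' @param cube A `radar_cube`.
#' @param path File path.
#' @return `write_cube()` the path, invisibly; `read_cube()` a
#'   `radar_cube`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "radar_cube"))
  d <- dim(cube$data)
  hdr <- list(
    format = "radargait-cube", version = 1L,
    dims = list(frames = d[3], chirps = d[2], samples = d[1]),
    encoding = "complex64-le-iq",
    config = unclass(cube$cfg)
  )
  hjson <- jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(hjson))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(CUBE_MAGIC), con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  iq <- rbind(Re(cube$data), Im(cube$data))   # interleave I,Q per sample
  dim(iq) <- NULL
  writeBin(iq, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(CUBE_MAGIC)))
  if (!identical(magic, CUBE_MAGIC))
    stop("read_cube: magic mismatch (not a radargait cube container)",
         call. = FALSE)
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L)
    stop("read_cube: corrupt header length", call. = FALSE)
  hraw <- readBin(con, "raw", n = hlen)
  if (length(hraw) != hlen)
    stop("read_cube: truncated header", call. = FALSE)
  hdr <- jsonlite::fromJSON(rawToChar(hraw))
  dims <- hdr$dims
  n_cplx <- as.numeric(dims$frames) * dims$chirps * dims$samples
  vals <- readBin(con, "numeric", n = 2 * n_cplx + 1L, size = 4L,
                  endian = "little")
  if (length(vals) > 2 * n_cplx)
    stop("read_cube: payload size does not match header dims", call. = FALSE)
  if (length(vals) < 2 * n_cplx)
    stop("read_cube: truncated payload", call. = FALSE)
  even <- seq(2L, length(vals), by = 2L)
  data <- complex(real = vals[even - 1L], imaginary = vals[even])
  dim(data) <- c(dims$samples, dims$chirps, dims$frames)
  cfgl <- hdr$config
  cfg <- chirp_config(cfgl$start_frequency, cfgl$slope, cfgl$idle_time,
                      cfgl$tx_start_time, cfgl$adc_start_time,
                      cfgl$adc_samples, cfgl$adc_sample_rate,
                      cfgl$ramp_end_time, cfgl$chirps_per_frame,
                      cfgl$frame_period)
  if (cfg$adc_samples != dims$samples || cfg$chirps_per_frame != dims$chirps)
    stop("read_cube: dims do not match the embedded configuration",
         call. = FALSE)
  structure(list(data = data, cfg = cfg, n_frames = as.integer(dims$frames)),
            class = "radar_cube")
}

#' Raw interleaved int16 I/Q import and export
#'
#' The capture-card dialect: a headerless stream of signed little-endian
#' 16-bit integers, interleaved I then Q (4 bytes per complex sample),
#' sample index fastest, then chirp, then frame; the chirp configuration
#' travels in a sidecar text file (see [read_chirp_config()]).  The frame
#' count is inferred from the file size and must divide evenly.
#'
#' @param path Stream file path.
#' @param cfg The sidecar [chirp_config()].
#' @param scale Multiplier applied to the integer counts on import (and
#'   divided out, with rounding, on export).
#' @param cube A `radar_cube`.
#' @return `read_raw_iq()` a `radar_cube`; `write_raw_iq()` the path,
#'   invisibly.
#' @export
read_raw_iq <- function(path, cfg, scale = 1) {
  validate_chirp_config(cfg)
  nbytes <- file.size(path)
  if (is.na(nbytes) || nbytes %% 4 != 0)
    stop("read_raw_iq: stream length must be a multiple of 4 bytes",
         call. = FALSE)
  n_cplx <- nbytes / 4
  per_frame <- cfg$adc_samples * cfg$chirps_per_frame
  if (n_cplx %% per_frame != 0)
    stop("read_raw_iq: stream does not hold a whole number of frames",
         call. = FALSE)
  n_frames <- as.integer(n_cplx / per_frame)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "integer", n = 2 * n_cplx, size = 2L, signed = TRUE,
                  endian = "little")
  even <- seq(2L, length(vals), by = 2L)
  data <- complex(real = vals[even - 1L] * scale,
                  imaginary = vals[even] * scale)
  dim(data) <- c(cfg$adc_samples, cfg$chirps_per_frame, n_frames)
  structure(list(data = data, cfg = cfg, n_frames = n_frames),
            class = "radar_cube")
}

#' @rdname read_raw_iq
#' @export
write_raw_iq <- function(cube, path, scale = 1) {
  stopifnot(inherits(cube, "radar_cube"))
  iq <- rbind(Re(cube$data), Im(cube$data)) / scale
  dim(iq) <- NULL
  iq <- as.integer(round(iq))
  if (any(iq > 32767L | iq < -32768L))
    stop("write_raw_iq: samples exceed int16 range at this scale", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(iq, con, size = 2L, endian = "little")
  invisible(path)
}

# unit-suffixed key <-> SI field mapping for the flat config text format
CONFIG_KEYS <- list(
  start_frequency_ghz = list(field = "start_frequency", mul = 1e9),
  slope_mhz_per_us = list(field = "slope", mul = 1e12),
  idle_time_us = list(field = "idle_time", mul = 1e-6),
  tx_start_time_us = list(field = "tx_start_time", mul = 1e-6),
  adc_start_time_us = list(field = "adc_start_time", mul = 1e-6),
  adc_samples = list(field = "adc_samples", mul = 1),
  adc_sample_rate_ksps = list(field = "adc_sample_rate", mul = 1e3),
  ramp_end_time_us = list(field = "ramp_end_time", mul = 1e-6),
  chirps_per_frame = list(field = "chirps_per_frame", mul = 1),
  frame_period_ms = list(field = "frame_period", mul = 1e-3)
)

#' Read and write chirp configuration text files
#'
#' Flat `key = value` text with unit-suffixed keys (e.g.
#' `slope_mhz_per_us = 60`) to keep units explicit; `#` starts a comment.
#' Round-trips a [chirp_config()] losslessly.
#'
#' @param cfg A [chirp_config()].
#' @param path File path.
#' @return `write_chirp_config()` the path, invisibly;
#'   `read_chirp_config()` a [chirp_config()].
#' @export
write_chirp_config <- function(cfg, path) {
  validate_chirp_config(cfg)
  lines <- c("# radargait chirp configuration (units in key suffixes)")
  for (key in names(CONFIG_KEYS)) {
    spec <- CONFIG_KEYS[[key]]
    lines <- c(lines, sprintf("%s = %.15g", key, cfg[[spec$field]] / spec$mul))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_chirp_config
#' @export
read_chirp_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("read_chirp_config: malformed line '%s'", ln), call. = FALSE)
    key <- trimws(kv[1])
    if (is.null(CONFIG_KEYS[[key]]))
      stop(sprintf("read_chirp_config: unknown key '%s'", key), call. = FALSE)
    spec <- CONFIG_KEYS[[key]]
    vals[[spec$field]] <- as.numeric(trimws(kv[2])) * spec$mul
  }
  do.call(chirp_config, vals)
}

#' Write a gait report as CSV + JSON
#'
#' Writes `<prefix>_steps.csv` (one data row per detected step: `index`,
#' `pass_id`, `step_time_s`, `step_point_m`, `step_length_m`) and
#' `<prefix>_summary.json` (avg_speed, step_count, cadence, mean step
#' length and per-pass statistics).  No timestamps or host information are
#' included, so identical reports serialize byte-identically.
#'
#' @param report A `gait_report`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_gait_report <- function(report, prefix) {
  stopifnot(inherits(report, "gait_report"))
  csv_path <- paste0(prefix, "_steps.csv")
  json_path <- paste0(prefix, "_summary.json")
  steps <- report$steps
  out <- data.frame(
    index = seq_len(nrow(steps)),
    pass_id = steps$pass_id,
    step_time_s = round(steps$step_time, 6),
    step_point_m = round(steps$step_point, 6),
    step_length_m = round(steps$step_length, 6)
  )
  utils::write.csv(out, csv_path, row.names = FALSE, na = "")
  summary <- list(
    avg_speed_mps = report$avg_speed,
    step_count = report$step_count,
    cadence_spm = report$cadence,
    mean_step_length_m = if (is.nan(report$mean_step_length)) NA
                         else report$mean_step_length,
    n_strides = length(report$stride_lengths),
    passes = if (is.null(report$pass_summary)) list() else report$pass_summary
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(c(csv_path, json_path))
}

#' Read back a gait report summary JSON
#'
#' @param path Path to a `*_summary.json` written by [write_gait_report()].
#' @return A list mirroring the summary fields.
#' @export
read_gait_summary <- function(path) {
  jsonlite::fromJSON(path)
}
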