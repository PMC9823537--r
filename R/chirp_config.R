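#' FMCW chirp and frame configuration
#'
#' Bundles the chirp timing, sampling and frame parameters of a sawtooth
#' FMCW radar and validates their mutual consistency.  All fields are in SI
#' units (Hz, Hz/s, seconds, samples).  Complex (I/Q) ADC sampling is
#' assumed throughout, so the full ADC sample rate is usable as complex
#' bandwidth.
#'
#' @param start_frequency Carrier frequency at the start of the ramp [Hz].
#' @param slope Frequency ramp slope [Hz/s].
#' @param idle_time Idle time between the end of one ramp and the start of
#'   the next [s].
#' @param tx_start_time Time within the chirp at which the transmitter turns
#'   on [s].  Metadata only; not used in any derived quantity.
#' @param adc_start_time Time within the ramp at which ADC sampling starts [s].
#' @param adc_samples Number of complex ADC samples per chirp.
#' @param adc_sample_rate ADC sampling rate [complex samples/s].
#' @param ramp_end_time Duration of the frequency ramp [s].
#' @param chirps_per_frame Number of chirps grouped into one frame.
#' @param frame_period Frame repetition period [s].
#'
#' @return An object of class `chirp_config` (a validated named list).
#' @seealso [default_config()] for the reference 77 GHz configuration.
#' @export
#' @examples
#' cfg <- chirp_config()
#' sweep_bandwidth(cfg) / 1e6   # MHz
chirp_config <- function(start_frequency = 77e9,
                         slope = 60e12,
                         idle_time = 250e-6,
                         tx_start_time = 0,
                         adc_start_time = 10e-6,
                         adc_samples = 64L,
                         adc_sample_rate = 2.2e6,
                         ramp_end_time = 60e-6,
                         chirps_per_frame = 256L,
                         frame_period = 0.1) {
  cfg <- list(
    start_frequency = as.numeric(start_frequency),
    slope = as.numeric(slope),
    idle_time = as.numeric(idle_time),
    tx_start_time = as.numeric(tx_start_time),
    adc_start_time = as.numeric(adc_start_time),
    adc_samples = as.integer(adc_samples),
    adc_sample_rate = as.numeric(adc_sample_rate),
    ramp_end_time = as.numeric(ramp_end_time),
    chirps_per_frame = as.integer(chirps_per_frame),
    frame_period = as.numeric(frame_period)
  )
  class(cfg) <- "chirp_config"
  validate_chirp_config(cfg)
  cfg
}

validate_chirp_config <- function(cfg) {
  stopifnot(inherits(cfg, "chirp_config"))
  if (!is.finite(cfg$slope) || cfg$slope <= 0)
    stop("chirp_config: slope must be > 0", call. = FALSE)
  times <- c(cfg$idle_time, cfg$tx_start_time, cfg$adc_start_time,
             cfg$ramp_end_time, cfg$frame_period)
  if (any(!is.finite(times)) || any(times < 0))
    stop("chirp_config: all times must be finite and >= 0", call. = FALSE)
  if (cfg$adc_samples < 2L)
    stop("chirp_config: adc_samples must be >= 2", call. = FALSE)
  if (cfg$chirps_per_frame < 2L)
    stop("chirp_config: chirps_per_frame must be >= 2", call. = FALSE)
  if (cfg$adc_sample_rate <= 0)
    stop("chirp_config: adc_sample_rate must be > 0", call. = FALSE)
  adc_window <- cfg$adc_samples / cfg$adc_sample_rate
  # allow a hair of floating slack on the window fit
  if (cfg$adc_start_time + adc_window > cfg$ramp_end_time * (1 + 1e-12))
    stop("chirp_config: ADC window (adc_start_time + adc_samples/adc_sample_rate) ",
         "must fit within ramp_end_time", call. = FALSE)
  if (cfg$frame_period < cfg$chirps_per_frame * (cfg$idle_time + cfg$ramp_end_time))
    stop("chirp_config: frame_period must be >= chirps_per_frame * ",
         "(idle_time + ramp_end_time)", call. = FALSE)
  invisible(cfg)
}

#' Reference radar configuration
#'
#' The 77 GHz automotive-band configuration used for hallway gait
#' monitoring: 60 MHz/us slope, 60 us ramp, 250 us idle, 64 complex ADC
#' samples at 2200 ksps, 256 chirps per frame.  The frame period is not part
#' of the chirp timing; the package default is 100 ms (the minimum possible
#' with these timings is 256 x 310 us = 79.4 ms).
#'
#' @param frame_period Frame repetition period [s]; default 0.1.
#' @return A [chirp_config()].
#' @export
default_config <- function(frame_period = 0.1) {
  chirp_config(frame_period = frame_period)
}

#' Derived radar quantities
#'
#' @description
#' Standard FMCW relations derived from a [chirp_config()]:
#'
#' * `sweep_bandwidth()` — full-ramp RF bandwidth `slope * ramp_end_time`
#'   (the conventional figure quoted for a chirp: 3600 MHz for the reference
#'   configuration);
#' * `sampled_bandwidth()` — bandwidth actually swept during the ADC window,
#'   `slope * adc_samples / adc_sample_rate`; this is what sets the range
#'   resolution;
#' * `range_axis()` — metres at each fast-time FFT bin (0-based bin `k` maps
#'   to `k * (adc_sample_rate / n_fft) * c / (2 * slope)`);
#' * `range_bin_spacing()` — spacing of that axis [m];
#' * `max_unambiguous_range()` — range at the complex Nyquist beat
#'   frequency, `adc_sample_rate * c / (2 * slope)`;
#' * `wavelength()` — carrier wavelength [m]; by default at the centre of
#'   the sampled sweep (constant per recording);
#' * `chirp_interval()` — slow-time sampling interval `idle_time +
#'   ramp_end_time` [s];
#' * `max_unambiguous_velocity()` — `lambda / (4 * chirp_interval)` [m/s];
#' * `velocity_resolution()` — `lambda / (2 * chirps_per_frame *
#'   chirp_interval)` [m/s].
#'
#' @param cfg A [chirp_config()].
#' @param n_fft Fast-time FFT length; must be `>= cfg$adc_samples`.
#' @param convention Which carrier frequency defines the wavelength:
#'   `"sampled_centre"` (default; start frequency plus slope times the
#'   middle of the ADC window), `"ramp_centre"`, or `"start"`.
#' @return Numeric scalar (or numeric vector of length `n_fft` for
#'   `range_axis()`).
#' @name radar-derived
NULL

#' @rdname radar-derived
#' @export
sweep_bandwidth <- function(cfg) {
  validate_chirp_config(cfg)
  cfg$slope * cfg$ramp_end_time
}

#' @rdname radar-derived
#' @export
sampled_bandwidth <- function(cfg) {
  validate_chirp_config(cfg)
  cfg$slope * cfg$adc_samples / cfg$adc_sample_rate
}

#' @rdname radar-derived
#' @export
range_axis <- function(cfg, n_fft = cfg$adc_samples) {
  validate_chirp_config(cfg)
  n_fft <- as.integer(n_fft)
  if (n_fft < cfg$adc_samples)
    stop("range_axis: n_fft must be >= adc_samples", call. = FALSE)
  (0:(n_fft - 1L)) * range_bin_spacing(cfg, n_fft)
}

#' @rdname radar-derived
#' @export
range_bin_spacing <- function(cfg, n_fft = cfg$adc_samples) {
  validate_chirp_config(cfg)
  (cfg$adc_sample_rate / n_fft) * C_LIGHT / (2 * cfg$slope)
}

#' @rdname radar-derived
#' @export
max_unambiguous_range <- function(cfg) {
  validate_chirp_config(cfg)
  cfg$adc_sample_rate * C_LIGHT / (2 * cfg$slope)
}

#' @rdname radar-derived
#' @export
wavelength <- function(cfg,
                       convention = c("sampled_centre", "ramp_centre", "start")) {
  validate_chirp_config(cfg)
  convention <- match.arg(convention)
  f <- switch(convention,
    sampled_centre = cfg$start_frequency +
      cfg$slope * (cfg$adc_start_time + 0.5 * cfg$adc_samples / cfg$adc_sample_rate),
    ramp_centre = cfg$start_frequency + 0.5 * cfg$slope * cfg$ramp_end_time,
    start = cfg$start_frequency
  )
  C_LIGHT / f
}

#' @rdname radar-derived
#' @export
chirp_interval <- function(cfg) {
  validate_chirp_config(cfg)
  cfg$idle_time + cfg$ramp_end_time
}

#' @rdname radar-derived
#' @export
max_unambiguous_velocity <- function(cfg) {
  wavelength(cfg) / (4 * chirp_interval(cfg))
}

#' @rdname radar-derived
#' @export
velocity_resolution <- function(cfg) {
  wavelength(cfg) / (2 * cfg$chirps_per_frame * chirp_interval(cfg))
}

#' @export
print.chirp_config <- function(x, ...) {
  cat("<chirp_config>\n")
  cat(sprintf("  start frequency : %.2f GHz\n", x$start_frequency / 1e9))
  cat(sprintf("  slope           : %.2f MHz/us\n", x$slope / 1e12))
  cat(sprintf("  ramp / idle     : %.1f / %.1f us\n",
              x$ramp_end_time * 1e6, x$idle_time * 1e6))
  cat(sprintf("  ADC             : %d samples @ %.0f ksps (start %.1f us)\n",
              x$adc_samples, x$adc_sample_rate / 1e3, x$adc_start_time * 1e6))
  cat(sprintf("  chirps/frame    : %d, frame period %.1f ms\n",
              x$chirps_per_frame, x$frame_period * 1e3))
  cat(sprintf("  bandwidth       : %.0f MHz (sampled %.0f MHz)\n",
              sweep_bandwidth(x) / 1e6, sampled_bandwidth(x) / 1e6))
  cat(sprintf("  range bin       : %.4f m, max range %.2f m\n",
              range_bin_spacing(x), max_unambiguous_range(x)))
  cat(sprintf("  v_max / v_res   : %.3f / %.4f m/s\n",
              max_unambiguous_velocity(x), velocity_resolution(x)))
  invisible(x)
}
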