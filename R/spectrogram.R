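#' Micro-Doppler spectrogram at the torso bin
#'
#' Diagnostic (not part of the parameter-extraction path): for each frame,
#' takes the slow-time samples at the tracked torso range bin, windows
#' them, and transforms to Doppler; the Doppler axis is mapped to radial
#' velocity via `v = f_d * lambda / 2`.  A scatterer moving at constant
#' radial velocity produces a single spectral ridge at that velocity;
#' articulated limb motion spreads energy around it.
#'
#' @param cube A `radar_cube`.
#' @param track A `range_track` for the same cube.
#' @param stft_window Number of chirps per frame used for the transform;
#'   default all.  Must not exceed `chirps_per_frame`.
#' @return A list: `times` [s] (one per frame), `velocity_axis` [m/s]
#'   (centred, length `stft_window`), `magnitude` (matrix
#'   `[stft_window, n_frames]`).
#' @export
micro_doppler_spectrogram <- function(cube, track, stft_window = NULL) {
  stopifnot(inherits(cube, "radar_cube"), inherits(track, "range_track"))
  cfg <- cube$cfg
  if (is.null(stft_window)) stft_window <- cfg$chirps_per_frame
  stft_window <- as.integer(stft_window)
  if (stft_window > cfg$chirps_per_frame)
    stop("micro_doppler_spectrogram: stft_window exceeds chirps per frame",
         call. = FALSE)
  if (stft_window < 2L)
    stop("micro_doppler_spectrogram: stft_window must be >= 2", call. = FALSE)
  rc <- range_fft(cube)
  d <- dim(rc$bins)
  n_frames <- d[3]
  if (length(track$torso_bin) != n_frames)
    stop("micro_doppler_spectrogram: track does not match cube", call. = FALSE)
  w <- window_taper("hann", stft_window)
  lam <- wavelength(cfg)
  tc <- chirp_interval(cfg)
  half <- stft_window %/% 2L
  # fftshift: bins [half+1..N, 1..half] <-> frequencies (-half..N-half-1)/(N*Tc)
  shift_idx <- c((half + 1L):stft_window, seq_len(half))
  vel_axis <- (seq_len(stft_window) - 1L - half) / (stft_window * tc) * lam / 2
  mag <- matrix(NA_real_, nrow = stft_window, ncol = n_frames)
  for (f in seq_len(n_frames)) {
    b <- track$torso_bin[f]
    if (is.na(b)) next
    sp <- abs(stats::fft(rc$bins[b + 1L, seq_len(stft_window), f] * w))
    mag[, f] <- sp[shift_idx]
  }
  list(times = track$times, velocity_axis = vel_axis, magnitude = mag)
}
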