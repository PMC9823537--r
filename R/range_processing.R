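#' Fast-time range FFT
#'
#' Windows each chirp's complex ADC samples and transforms them to range
#' bins.  Bin 0 is zero range; 0-based bin `k` maps to the range given by
#' [range_axis()].
#'
#' @param cube A `radar_cube` from [synthesize_cube()] or [read_cube()].
#' @param window Fast-time window: `"hann"` (default), `"rect"`,
#'   `"hamming"` or `"blackman"`.
#' @param n_fft FFT length, `>= adc_samples`; default the sample count.
#' @return An object of class `range_cube`: complex array
#'   `[n_fft, chirps, frames]` plus `range_axis`, `cfg` and bookkeeping.
#' @export
range_fft <- function(cube, window = "hann", n_fft = NULL) {
  stopifnot(inherits(cube, "radar_cube"))
  cfg <- cube$cfg
  if (is.null(n_fft)) n_fft <- cfg$adc_samples
  n_fft <- as.integer(n_fft)
  if (n_fft < cfg$adc_samples)
    stop("range_fft: n_fft must be >= adc_samples", call. = FALSE)
  w <- window_taper(window, cfg$adc_samples)
  d <- dim(cube$data)
  x <- matrix(cube$data, nrow = d[1]) * w
  if (n_fft > d[1]) {
    xp <- matrix(0 + 0i, nrow = n_fft, ncol = ncol(x))
    xp[seq_len(d[1]), ] <- x
    x <- xp
  }
  bins <- stats::mvfft(x)
  dim(bins) <- c(n_fft, d[2], d[3])
  structure(list(bins = bins, range_axis = range_axis(cfg, n_fft),
                 cfg = cfg, window = window, n_fft = n_fft,
                 filtered = "none"),
            class = "range_cube")
}

window_taper <- function(name, n) {
  k <- seq_len(n) - 1L
  switch(name,
    rect = rep(1, n),
    hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
    blackman = 0.42 - 0.5 * cos(2 * pi * k / (n - 1)) +
      0.08 * cos(4 * pi * k / (n - 1)),
    stop(sprintf("range_fft: unknown window '%s'", name), call. = FALSE)
  )
}

#' Static-clutter filter
#'
#' `"slow_time_mean"` subtracts, per range bin, the complex mean over every
#' chirp of the recording, removing zero-Doppler (static) content such as
#' wall and furniture returns; a scatterer that moves through many bins
#' during the recording is barely affected.  `"none"` is a pass-through for
#' reproducing raw profiles.
#'
#' @param rc A `range_cube` from [range_fft()].
#' @param mode `"slow_time_mean"` (default) or `"none"`.
#' @return The filtered `range_cube`.
#' @export
clutter_filter <- function(rc, mode = c("slow_time_mean", "none")) {
  stopifnot(inherits(rc, "range_cube"))
  mode <- match.arg(mode)
  if (mode == "none") return(rc)
  d <- dim(rc$bins)
  if (d[2] * d[3] < 2L)
    stop("clutter_filter: need at least 2 chirps", call. = FALSE)
  flat <- matrix(rc$bins, nrow = d[1])
  mu <- rowMeans(flat)
  rc$bins <- array(flat - mu, dim = d)
  rc$filtered <- mode
  rc
}

#' Per-frame range magnitude profile
#'
#' Noncoherent accumulation: the mean of the per-chirp bin magnitudes
#' across the frame's chirps.
#'
#' @param rc A `range_cube`.
#' @param frame 1-based frame number.
#' @return An object of class `range_profile`: `frame_index` (1-based),
#'   `magnitudes` (length `n_fft`, linear scale) and `range_axis` [m].
#' @export
frame_profile <- function(rc, frame) {
  stopifnot(inherits(rc, "range_cube"))
  d <- dim(rc$bins)
  frame <- as.integer(frame)
  if (frame < 1L || frame > d[3])
    stop("frame_profile: frame out of bounds", call. = FALSE)
  mags <- rowMeans(abs(rc$bins[, , frame, drop = FALSE])[, , 1, drop = FALSE])
  dim(mags) <- NULL
  structure(list(frame_index = frame, magnitudes = mags,
                 range_axis = rc$range_axis),
            class = "range_profile")
}

# all frames at once: matrix [n_fft, n_frames]
all_frame_profiles <- function(rc) {
  d <- dim(rc$bins)
  m <- abs(rc$bins)
  out <- vapply(seq_len(d[3]),
                function(f) rowMeans(m[, , f, drop = FALSE][, , 1, drop = FALSE]),
                numeric(d[1]))
  matrix(out, nrow = d[1])
}

#' Torso range bin by the maximum-bin rule
#'
#' With a narrow (lens) beam the walking subject's torso dominates the
#' reflected power, so its range bin is simply the argmax of the range
#' profile.  Bins closer than `min_range` (TX leakage / zero-range region)
#' are excluded.  Ties break toward the smaller bin.  An all-zero profile
#' yields `NA` (invalid frame), not an error.
#'
#' @param profile A `range_profile` from [frame_profile()].
#' @param min_range Minimum admissible range [m]; default 0.3.
#' @return 0-based bin index, or `NA_integer_` for an invalid frame.
#' @export
torso_bin <- function(profile, min_range = 0.3) {
  stopifnot(inherits(profile, "range_profile"))
  ok <- profile$range_axis >= min_range
  if (!any(ok)) stop("torso_bin: no bins at or beyond min_range", call. = FALSE)
  mags <- profile$magnitudes[ok]
  if (all(mags == 0) || all(!is.finite(mags))) return(NA_integer_)
  idx <- which(ok)[which.max(mags)]   # which.max takes the first (smaller) tie
  as.integer(idx - 1L)
}

#' Torso range track from a processed cube
#'
#' Applies the maximum-bin rule to every frame's profile.  Each frame is
#' timestamped at the centre of its chirp burst,
#' `(f - 1) * frame_period + chirps_per_frame * chirp_interval / 2`
#' (the burst need not fill the frame period, so the frame centre would be
#' biased).  With `refine = "parabolic"` (the default) the reported range is
#' refined within the selected bin by fitting a parabola to the
#' log-magnitudes of the peak bin and its two neighbours — the standard
#' sub-bin spectral peak interpolation; the torso *selection* remains the
#' plain argmax, and `torso_bin` always holds the unrefined bin.
#' `refine = "none"` reports bin-centre ranges.
#'
#' @param rc A `range_cube` (typically after [clutter_filter()]).
#' @param min_range Minimum admissible range [m].
#' @param refine `"parabolic"` (default) or `"none"`.
#' @return An object of class `range_track`: `times` [s], `torso_range`
#'   [m], `torso_bin` (0-based), `valid` (logical), `cfg`.
#' @export
range_track <- function(rc, min_range = 0.3,
                        refine = c("parabolic", "none")) {
  stopifnot(inherits(rc, "range_cube"))
  refine <- match.arg(refine)
  d <- dim(rc$bins)
  profs <- all_frame_profiles(rc)
  ok <- rc$range_axis >= min_range
  if (!any(ok)) stop("range_track: no bins at or beyond min_range", call. = FALSE)
  sub <- profs[ok, , drop = FALSE]
  peak <- max.col(t(sub), ties.method = "first")
  allzero <- colSums(sub != 0) == 0L
  bin0 <- as.integer(which(ok)[peak] - 1L)
  bin0[allzero] <- NA_integer_
  spacing <- range_bin_spacing(rc$cfg, rc$n_fft)
  rng <- rc$range_axis[bin0 + 1L]
  if (refine == "parabolic") {
    delta <- rep(0, d[3])
    i <- bin0 + 1L   # 1-based peak index
    inner <- which(!allzero & !is.na(i) & i > 1L & i < rc$n_fft)
    if (length(inner)) {
      eps <- .Machine$double.xmin
      m_l <- log(profs[cbind(i[inner] - 1L, inner)] + eps)
      m_c <- log(profs[cbind(i[inner], inner)] + eps)
      m_r <- log(profs[cbind(i[inner] + 1L, inner)] + eps)
      den <- m_l - 2 * m_c + m_r
      dl <- ifelse(abs(den) > 0, 0.5 * (m_l - m_r) / den, 0)
      delta[inner] <- pmax(-0.5, pmin(0.5, dl))
    }
    rng <- rng + delta * spacing
  }
  tf <- rc$cfg$frame_period
  burst_mid <- rc$cfg$chirps_per_frame * chirp_interval(rc$cfg) / 2
  structure(list(times = (seq_len(d[3]) - 1L) * tf + burst_mid,
                 torso_range = rng,
                 torso_bin = bin0,
                 valid = !allzero,
                 bin_spacing = spacing,
                 cfg = rc$cfg),
            class = "range_track")
}

#' Smooth and gate a torso range track
#'
#' Median-filters the raw maximum-bin track (window 5 frames) and then
#' gates on physical plausibility: any frame whose implied frame-to-frame
#' speed exceeds `max_speed` is marked invalid and replaced by linear
#' interpolation from its valid neighbours.
#'
#' @param track A `range_track`.
#' @param max_speed Gating speed [m/s]; defaults to
#'   [max_unambiguous_velocity()] of the track's configuration.
#' @param median_window Median filter window in frames (odd); default 5.
#' @return The smoothed `range_track` (invalid frames interpolated, `valid`
#'   updated).
#' @export
track_smooth <- function(track, max_speed = NULL, median_window = 5L) {
  stopifnot(inherits(track, "range_track"))
  n <- length(track$times)
  if (n < 3L) stop("track_smooth: need at least 3 frames", call. = FALSE)
  if (is.null(max_speed)) max_speed <- max_unambiguous_velocity(track$cfg)
  r <- track$torso_range
  valid <- track$valid & is.finite(r)
  # fill invalid frames before filtering
  if (any(!valid)) {
    if (sum(valid) < 2L)
      stop("track_smooth: fewer than 2 valid frames", call. = FALSE)
    r <- stats::approx(track$times[valid], r[valid], xout = track$times,
                       rule = 2)$y
  }
  r <- stats::runmed(r, k = min(median_window, n - (1 - n %% 2)),
                     endrule = "median")
  dt <- diff(track$times)
  spd <- abs(diff(r)) / dt
  bad <- c(FALSE, spd > max_speed) | c(spd > max_speed, FALSE)
  keep <- !bad
  if (any(bad) && sum(keep) >= 2L) {
    r <- stats::approx(track$times[keep], r[keep], xout = track$times,
                       rule = 2)$y
  }
  track$torso_range <- r
  track$valid <- valid & !bad
  track$torso_bin <- as.integer(round(r / track$bin_spacing))
  track
}

#' @export
print.range_track <- function(x, ...) {
  cat(sprintf("<range_track> %d frames, %.2f-%.2f m, %d invalid\n",
              length(x$times), min(x$torso_range, na.rm = TRUE),
              max(x$torso_range, na.rm = TRUE), sum(!x$valid)))
  invisible(x)
}
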