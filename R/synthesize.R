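#' Synthesize a raw radar data cube from point scatterers
#'
#' Standard stop-and-hop FMCW point-scatterer beat model.  Each scatterer at
#' range `R` (evaluated once per chirp) contributes a complex fast-time tone
#' \deqn{s[k] = A \, G(\theta) R^{-2}
#'   \exp\!\left(i\,(2\pi f_b k / f_s + 4\pi R/\lambda)\right)}
#' with beat frequency `f_b = 2 * slope * R / c`, beam amplitude gain `G` at
#' the scatterer's azimuth and free-space two-way amplitude spreading
#' `R^-2` (received power then scales as `G^2 R^-4`, the radar-equation
#' proportionality).  I.i.d. circular complex Gaussian noise is added with
#' power set by `snr_db` relative to the torso return at its median
#' (mid-path) range.  The output is deterministic given `rng_seed`; the
#' global RNG state is left untouched.
#'
#' @param scatterers Non-empty list of [scatterer()]s.
#' @param cfg A [chirp_config()].
#' @param beam A [beam_pattern()].
#' @param snr_db Signal-to-noise ratio [dB] of the torso reference return
#'   per raw sample; `Inf` for a noiseless cube.
#' @param duration Recording length [s]; at least one frame.
#' @param rng_seed Integer seed for the noise generator.
#' @return An object of class `radar_cube`: list with `data` (complex array
#'   `[adc_samples, chirps_per_frame, n_frames]`; fast time varies fastest),
#'   `cfg`, `n_frames`, `beam`, `snr_db`, `rng_seed`.
#' @export
synthesize_cube <- function(scatterers, cfg, beam = beam_pattern("lens"),
                            snr_db = 20, duration, rng_seed = 1L) {
  validate_chirp_config(cfg)
  stopifnot(inherits(beam, "beam_pattern"))
  if (!length(scatterers))
    stop("synthesize_cube: need at least one scatterer", call. = FALSE)
  if (inherits(scatterers, "scatterer")) scatterers <- list(scatterers)
  if (duration < cfg$frame_period)
    stop("synthesize_cube: duration must cover at least one frame", call. = FALSE)

  n_frames <- as.integer(ceiling(duration / cfg$frame_period))
  n_chirps <- cfg$chirps_per_frame
  n_s <- cfg$adc_samples
  tc <- chirp_interval(cfg)
  lam <- wavelength(cfg)
  r_max <- max_unambiguous_range(cfg)

  # slow-time instants of every chirp (frame-major)
  t_slow <- rep((seq_len(n_frames) - 1L) * cfg$frame_period, each = n_chirps) +
    rep((seq_len(n_chirps) - 1L) * tc, times = n_frames)
  fast <- (seq_len(n_s) - 1L) / cfg$adc_sample_rate

  acc <- matrix(0 + 0i, nrow = n_s, ncol = length(t_slow))
  torso_ref_amp <- NA_real_
  for (s in scatterers) {
    stopifnot(inherits(s, "scatterer"))
    R <- s$range_fn(t_slow)
    if (any(!is.finite(R)) || any(R <= 0))
      stop(sprintf("synthesize_cube: scatterer '%s' has non-positive range",
                   s$label), call. = FALSE)
    if (any(R > r_max))
      stop(sprintf(
        "synthesize_cube: scatterer '%s' exceeds the unambiguous range (%.2f m)",
        s$label, r_max), call. = FALSE)
    az <- s$azimuth_fn(t_slow)
    amp <- s$amplitude * beam_gain(beam, az) / R^2
    fb <- 2 * cfg$slope * R / C_LIGHT
    phase0 <- 4 * pi * R / lam
    tone <- exp(1i * outer(2 * pi * fast, fb))
    acc <- acc + tone * rep(amp * exp(1i * phase0), each = n_s)
    if (s$label == "torso" && is.na(torso_ref_amp)) {
      g0 <- beam_gain(beam, stats::median(az))
      torso_ref_amp <- s$amplitude * g0 / stats::median(R)^2
    }
  }
  if (is.na(torso_ref_amp)) {
    # no torso present: reference the strongest scatterer's median return
    refs <- vapply(scatterers, function(s) {
      R <- s$range_fn(t_slow)
      s$amplitude * beam_gain(beam, stats::median(s$azimuth_fn(t_slow))) /
        stats::median(R)^2
    }, numeric(1))
    torso_ref_amp <- max(refs)
  }
  if (is.finite(snr_db)) {
    sigma <- torso_ref_amp / 10^(snr_db / 20)
    acc <- acc + local_seed(rng_seed, {
      n <- length(acc)
      complex(real = stats::rnorm(n, sd = sigma / sqrt(2)),
              imaginary = stats::rnorm(n, sd = sigma / sqrt(2)))
    })
  }
  dim(acc) <- c(n_s, n_chirps, n_frames)
  structure(list(data = acc, cfg = cfg, n_frames = n_frames,
                 beam = beam, snr_db = snr_db, rng_seed = as.integer(rng_seed)),
            class = "radar_cube")
}

# Evaluate expr with a private RNG stream, restoring the caller's state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a full hallway walk recording
#'
#' Convenience wrapper: builds the torso trajectory from a
#' [walk_scenario()], attaches wall-mirror ghosts and static clutter from a
#' [hallway_clutter()] (and optionally limb scatterers), and synthesizes the
#' raw cube over the whole walk.
#'
#' @param scn A [walk_scenario()].
#' @param cfg A [chirp_config()].
#' @param beam A [beam_pattern()].
#' @param clutter A [hallway_clutter()], or `NULL` for a clutter-free room.
#' @param snr_db Per-sample SNR of the torso reference return [dB].
#' @param torso_amplitude Torso reflectivity (linear); the unit against
#'   which clutter amplitudes are expressed.
#' @param limbs Add limb micro-Doppler scatterers? Default `FALSE`.
#' @return List with `cube` (a `radar_cube`), `trajectory` (a
#'   [torso_trajectory()]) and `ground_truth`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_walk_cube(walk_scenario(rng_seed = 7))
#' rep <- extract_gait(sim$cube)
#' rep$step_count
#' }
simulate_walk_cube <- function(scn, cfg = default_config(),
                               beam = beam_pattern("lens"),
                               clutter = hallway_clutter(),
                               snr_db = 20, torso_amplitude = 1,
                               limbs = FALSE) {
  stopifnot(inherits(scn, "walk_scenario"))
  traj <- torso_trajectory(scn)
  torso <- scatterer(traj$range_fn,
                     function(t) rep_len(scn$walk_azimuth, length(t)),
                     amplitude = torso_amplitude, label = "torso")
  sc <- list(torso)
  if (!is.null(clutter)) sc <- c(sc, ghost_scatterers(torso, clutter))
  if (limbs) sc <- c(sc, limb_scatterers(traj))
  cube <- synthesize_cube(sc, cfg, beam = beam, snr_db = snr_db,
                          duration = traj$duration, rng_seed = scn$rng_seed)
  list(cube = cube, trajectory = traj, ground_truth = traj$ground_truth)
}

#' @export
print.radar_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<radar_cube> %d frames x %d chirps x %d samples (%.1f s)\n",
              d[3], d[2], d[1], d[3] * x$cfg$frame_period))
  invisible(x)
}
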