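#' Point scatterer
#'
#' A point reflector with time-varying radial range and azimuth.  Ranges and
#' azimuths are supplied as vectorised functions of time (seconds from
#' recording start); constants are accepted and wrapped.
#'
#' @param range_fn Function `t -> range [m]` (or a constant).
#' @param azimuth_fn Function `t -> azimuth [deg]` (or a constant).
#' @param amplitude Reflectivity on a linear amplitude scale (range and
#'   beam effects are applied separately by [synthesize_cube()]).
#' @param label One of `"torso"`, `"limb"`, `"static"`, `"ghost"`.
#' @return An object of class `scatterer`.
#' @export
scatterer <- function(range_fn, azimuth_fn = 0, amplitude = 1,
                      label = c("torso", "limb", "static", "ghost")) {
  label <- match.arg(label)
  as_fn <- function(x) if (is.function(x)) x else {
    force(x); function(t) rep_len(as.numeric(x), length(t))
  }
  structure(list(range_fn = as_fn(range_fn), azimuth_fn = as_fn(azimuth_fn),
                 amplitude = as.numeric(amplitude), label = label),
            class = "scatterer")
}

#' Parametric antenna beam pattern
#'
#' A unimodal (Gaussian-in-angle) azimuth power pattern parameterised by its
#' boresight gain and half-power beamwidth.  The lens mode models the
#' dielectric-lens-equipped antenna: a 14 dB boresight gain advantage and a
#' much narrower beam than the bare (no-lens) patch antenna.
#'
#' @param mode `"lens"` or `"no_lens"`.  Defaults: lens = 14 dB boresight,
#'   12 deg HPBW (consistent with the 14 dB gain advantage: a 25-fold
#'   power gain concentrates the 60 deg bare beam into about 60/sqrt(25) deg);
#'   no_lens = 0 dB, 60 deg HPBW.
#' @param boresight_gain_db Boresight gain [dB]; overrides the mode default.
#' @param half_power_beamwidth Half-power beamwidth [deg]; overrides the
#'   mode default.
#' @return An object of class `beam_pattern`.
#' @export
beam_pattern <- function(mode = c("lens", "no_lens"),
                         boresight_gain_db = NULL,
                         half_power_beamwidth = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    lens = list(gain = 14, hpbw = 12),
    no_lens = list(gain = 0, hpbw = 60))
  g <- if (is.null(boresight_gain_db)) defaults$gain else boresight_gain_db
  h <- if (is.null(half_power_beamwidth)) defaults$hpbw else half_power_beamwidth
  if (h <= 0) stop("beam_pattern: half_power_beamwidth must be > 0", call. = FALSE)
  structure(list(mode = mode, boresight_gain_db = g, half_power_beamwidth = h),
            class = "beam_pattern")
}

#' Beam amplitude gain at an azimuth
#'
#' Linear *amplitude* gain; received power scales with the square.  The
#' power pattern is Gaussian in angle with the stated half-power beamwidth:
#' power at `+/- HPBW/2` is half the boresight power.
#'
#' @param beam A [beam_pattern()].
#' @param azimuth Azimuth(s) [deg]; must satisfy `|azimuth| <= 90`.
#' @return Linear amplitude gain(s).
#' @export
beam_gain <- function(beam, azimuth) {
  stopifnot(inherits(beam, "beam_pattern"))
  if (any(abs(azimuth) > 90))
    stop("beam_gain: |azimuth| must be <= 90 degrees", call. = FALSE)
  g0 <- 10^(beam$boresight_gain_db / 20)
  g0 * exp(-2 * log(2) * (azimuth / beam$half_power_beamwidth)^2)
}

#' Hallway clutter description
#'
#' Static reflectors (e.g. metal cabinets) and the corridor walls that give
#' rise to first-order mirror-image multipath ghosts.  Walls run parallel to
#' the walking direction; the i-th wall sits at lateral offset
#' `wall_offsets[i]` on alternating sides of the radar boresight (first
#' left, then right, ...).
#'
#' Default static reflectors emulate the metal cabinets lining the
#' validation hallway: reflectivities several times the torso's, graded
#' with range so that their *received* returns are mutually comparable and
#' overwhelm the distant torso.  With a wide beam and no clutter filtering
#' the range-profile argmax is then contested between cabinets, ghosts and
#' torso — the failure mode that corrupts max-bin gait extraction.
#'
#' @param wall_offsets Lateral wall distances [m], all > 0.  `numeric(0)`
#'   for no walls.
#' @param wall_reflection_loss_db Amplitude loss of one wall bounce [dB].
#' @param static_reflectors data.frame with columns `range` [m],
#'   `azimuth` [deg], `amplitude` (linear, same scale as the torso).
#' @param object_bounce_loss_db Amplitude loss of a subject-to-object
#'   bounce off a static reflector [dB].  Each static reflector spawns a
#'   *moving* ghost at the half round-trip range
#'   `(r_torso + |subject - object| + r_object) / 2`; these
#'   subject-object bounces are what scatters multipath energy across many
#'   range bins as the subject walks.  `Inf` disables them.
#' @return An object of class `hallway_clutter`.
#' @export
hallway_clutter <- function(wall_offsets = c(0.9, 1.4),
                            wall_reflection_loss_db = 6,
                            static_reflectors = data.frame(
                              range = c(1.8, 2.8, 3.8),
                              azimuth = c(-12, 10, -8),
                              amplitude = c(2, 5, 9)),
                            object_bounce_loss_db = 3) {
  if (length(wall_offsets) && any(wall_offsets <= 0))
    stop("hallway_clutter: wall offsets must be > 0", call. = FALSE)
  if (!is.null(static_reflectors) && nrow(static_reflectors) &&
      !all(c("range", "azimuth", "amplitude") %in% names(static_reflectors)))
    stop("hallway_clutter: static_reflectors needs range/azimuth/amplitude",
         call. = FALSE)
  structure(list(wall_offsets = as.numeric(wall_offsets),
                 wall_reflection_loss_db = wall_reflection_loss_db,
                 static_reflectors = static_reflectors,
                 object_bounce_loss_db = object_bounce_loss_db),
            class = "hallway_clutter")
}

#' First-order multipath ghosts of a moving scatterer
#'
#' For each wall, constructs the specular single-bounce ghost by mirror
#' geometry: with the radar at the origin and the subject at
#' `p(t) = r(t) * (cos az, sin az)`, the image of the subject in a wall at
#' lateral offset `w` is `p' = (p_x, 2w - p_y)`.  The bounced path
#' radar -> wall -> subject -> radar has length `|p'| + |p|`, so the ghost
#' appears at range `(|p'| + |p|) / 2` (always >= the direct range while the
#' subject is between radar and wall) from the direction of the image,
#' attenuated by the wall reflection loss.  The reciprocal bounce
#' (radar -> subject -> wall -> radar) has exactly the same path length and
#' adds coherently, so the ghost amplitude carries a factor 2 — which is
#' why, with a lossy-enough wall still, a wide-beam ghost can outshine the
#' torso when phases are constructive.  Static reflectors are passed
#' through as static scatterers.
#'
#' @param torso A moving [scatterer()] (typically the torso).
#' @param clutter A [hallway_clutter()].
#' @return List of [scatterer()]s (ghosts first, then statics).
#' @export
ghost_scatterers <- function(torso, clutter) {
  stopifnot(inherits(torso, "scatterer"), inherits(clutter, "hallway_clutter"))
  out <- list()
  loss <- 10^(-clutter$wall_reflection_loss_db / 20)
  if (length(clutter$wall_offsets)) {
    for (i in seq_along(clutter$wall_offsets)) {
      side <- if (i %% 2L == 1L) 1 else -1
      w <- side * clutter$wall_offsets[i]
      make_ghost <- function(w) {
        force(w)
        mirror <- function(t) {
          r <- torso$range_fn(t)
          az <- torso$azimuth_fn(t) * pi / 180
          px <- r * cos(az); py <- r * sin(az)
          list(px = px, py = py, qx = px, qy = 2 * w - py,
               rdir = r)
        }
        rng <- function(t) {
          m <- mirror(t)
          (sqrt(m$qx^2 + m$qy^2) + m$rdir) / 2
        }
        azf <- function(t) {
          m <- mirror(t)
          atan2(m$qy, m$qx) * 180 / pi
        }
        # factor 2: the two reciprocal single-bounce paths add in phase
        scatterer(rng, azf, amplitude = 2 * torso$amplitude * loss,
                  label = "ghost")
      }
      out[[length(out) + 1L]] <- make_ghost(w)
    }
  }
  sr <- clutter$static_reflectors
  if (!is.null(sr) && nrow(sr)) {
    bounce <- 10^(-clutter$object_bounce_loss_db / 20)
    for (j in seq_len(nrow(sr))) {
      out[[length(out) + 1L]] <- scatterer(sr$range[j], sr$azimuth[j],
                                           amplitude = sr$amplitude[j],
                                           label = "static")
      if (bounce > 0) {
        make_bounce <- function(r_c, az_c) {
          force(r_c); force(az_c)
          cx <- r_c * cos(az_c * pi / 180); cy <- r_c * sin(az_c * pi / 180)
          rng <- function(t) {
            r <- torso$range_fn(t)
            az <- torso$azimuth_fn(t) * pi / 180
            px <- r * cos(az); py <- r * sin(az)
            (r + sqrt((px - cx)^2 + (py - cy)^2) + r_c) / 2
          }
          # last leg arrives from the object's direction; reciprocal path
          # (object first) adds coherently, hence the factor 2
          scatterer(rng, az_c, amplitude = 2 * torso$amplitude * bounce,
                    label = "ghost")
        }
        out[[length(out) + 1L]] <- make_bounce(sr$range[j], sr$azimuth[j])
      }
    }
  }
  out
}

#' Limb micro-Doppler scatterers (optional fidelity layer)
#'
#' Adds low-amplitude scatterers representing swinging limbs: their range
#' oscillates about the torso range in phase with the step cycle, producing
#' radial velocity excursions larger than the torso's (micro-Doppler) while
#' their amplitude stays well below the torso's (the torso dominates the
#' reflected power when illuminated at chest height).  Off by default in
#' [simulate_walk_cube()].
#'
#' @param traj A [torso_trajectory()].
#' @param amplitude_ratio Limb amplitude relative to the torso; must be < 1.
#' @param swing_amplitude Peak limb displacement about the torso [m].
#' @return List of two [scatterer()]s (alternating legs, opposite phase).
#' @export
limb_scatterers <- function(traj, amplitude_ratio = 0.3, swing_amplitude = 0.25) {
  stopifnot(inherits(traj, "torso_trajectory"))
  if (amplitude_ratio >= 1)
    stop("limb_scatterers: amplitude_ratio must be < 1", call. = FALSE)
  scn <- traj$scenario
  t_step <- scn$step_length / scn$avg_speed
  make_leg <- function(phase) {
    force(phase)
    rng <- function(t) {
      moving <- abs(traj$speed_fn(t)) > 0
      traj$range_fn(t) +
        swing_amplitude * moving * sin(2 * pi * t / (2 * t_step) + phase)
    }
    scatterer(rng, function(t) rep_len(scn$walk_azimuth, length(t)),
              amplitude = amplitude_ratio, label = "limb")
  }
  list(make_leg(0), make_leg(pi))
}
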