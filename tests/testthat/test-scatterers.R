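test_that("beam pattern is unimodal with the stated HPBW and lens advantage", {
  lens <- beam_pattern("lens")
  bare <- beam_pattern("no_lens")
  az <- seq(0, 90, by = 1)
  g <- beam_gain(lens, az)
  expect_true(all(diff(g) < 0))                      # monotone off boresight
  expect_equal(beam_gain(lens, 0), max(beam_gain(lens, seq(-90, 90, 0.5))))
  # half the boresight *power* at +/- HPBW/2
  for (b in list(lens, bare)) {
    ratio <- (beam_gain(b, b$half_power_beamwidth / 2) / beam_gain(b, 0))^2
    expect_equal(ratio, 0.5, tolerance = 1e-12)
  }
  # lens boresight advantage >= 14 dB
  adv_db <- 20 * log10(beam_gain(lens, 0) / beam_gain(bare, 0))
  expect_gte(adv_db, 14)
  expect_equal(beam_gain(lens, -10), beam_gain(lens, 10))   # symmetry
  expect_error(beam_gain(lens, 95), "azimuth")
})

test_that("wall ghosts follow mirror-image geometry", {
  # torso fixed at 3.0 m on boresight, wall 1.0 m lateral
  torso <- scatterer(3.0, 0, amplitude = 1, label = "torso")
  cl <- hallway_clutter(wall_offsets = 1.0, wall_reflection_loss_db = 6,
                        static_reflectors = NULL)
  gh <- ghost_scatterers(torso, cl)
  expect_length(gh, 1)
  # oracle: brute-force minimisation of |radar->q| + |q->subject| over wall
  # points q = (x, 1.0) gives the bounce leg; apparent range is half the
  # full bounce path radar->wall->subject (+ direct return)
  p <- c(3, 0)
  xs <- seq(-10, 10, by = 1e-4)
  leg <- sqrt(xs^2 + 1) + sqrt((xs - p[1])^2 + (1 - p[2])^2)
  oracle_range <- (min(leg) + sqrt(sum(p^2))) / 2
  expect_equal(gh[[1]]$range_fn(0), oracle_range, tolerance = 1e-6)
  # closed form: image point (3, 2)
  expect_equal(gh[[1]]$range_fn(0), (sqrt(9 + 4) + 3) / 2)
  expect_equal(gh[[1]]$azimuth_fn(0), atan2(2, 3) * 180 / pi)
  # reciprocal-path doubling times the wall loss
  expect_equal(gh[[1]]$amplitude, 2 * 10^(-6 / 20))
  expect_identical(gh[[1]]$label, "ghost")
})

test_that("ghost range never falls below the direct range", {
  tr <- torso_trajectory(walk_scenario())
  torso <- scatterer(tr$range_fn, 0, 1, "torso")
  cl <- hallway_clutter()
  ghosts <- ghost_scatterers(torso, cl)
  tt <- seq(0, tr$duration, by = 0.05)
  for (g in ghosts) {
    if (g$label != "ghost") next
    expect_true(all(g$range_fn(tt) >= tr$range_fn(tt) - 1e-12))
  }
  # statics pass through; with bounces each reflector appears twice
  labs <- vapply(ghosts, function(s) s$label, character(1))
  expect_equal(sum(labs == "static"), 3)
  # no walls, no statics -> empty list
  empty <- ghost_scatterers(torso, hallway_clutter(
    wall_offsets = numeric(0), static_reflectors = NULL))
  expect_length(empty, 0)
})

test_that("lens suppresses the wall ghost; a wide beam with a low-loss wall does not", {
  tr <- torso_trajectory(walk_scenario())
  torso <- scatterer(tr$range_fn, 0, 1, "torso")
  gh <- ghost_scatterers(torso, hallway_clutter(
    wall_offsets = 1.0, wall_reflection_loss_db = 1,
    static_reflectors = NULL))[[1]]
  tt <- seq(0, tr$duration, by = 0.1)
  received <- function(s, beam, az) s$amplitude * beam_gain(beam, az) /
    s$range_fn(tt)^2
  for (mode in c("lens", "no_lens")) {
    b <- beam_pattern(mode)
    torso_amp <- received(torso, b, 0)
    ghost_amp <- received(gh, b, gh$azimuth_fn(tt))
    if (mode == "lens") {
      expect_true(all(ghost_amp < torso_amp))
    } else {
      expect_gt(sum(ghost_amp > torso_amp), 0)
    }
  }
})

test_that("limb scatterers stay weaker but faster than the torso", {
  tr <- torso_trajectory(walk_scenario())
  limbs <- limb_scatterers(tr)
  expect_length(limbs, 2)
  tt <- seq(1, 4, by = 0.01)
  for (lb in limbs) {
    expect_lt(lb$amplitude, 1)
    # numerical radial speed of the limb exceeds the torso peak speed
    vl <- max(abs(diff(lb$range_fn(tt)) / 0.01))
    expect_gt(vl, max(abs(tr$speed_fn(tt))))
  }
  expect_error(limb_scatterers(tr, amplitude_ratio = 1.2), "amplitude_ratio")
})
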