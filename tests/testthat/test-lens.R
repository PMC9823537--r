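test_that("thickness profile has the collimating-lens properties", {
  sp <- lens_spec(focal_length = 0.038, radius = 0.038)
  expect_equal(sp$refractive_index, sqrt(2.68))
  expect_equal(lens_thickness(0, sp), 0)
  r <- seq(0, sp$radius, length.out = 200)
  t <- lens_thickness(r, sp)
  expect_true(all(diff(t) > 0))            # strictly increasing
  # frozen value: t(R)/F for R = F and eps_r = 2.68 (n = 1.63707)
  expect_equal(lens_thickness(sp$radius, sp) / sp$focal_length,
               0.48048, tolerance = 1e-4)
  # jointly homogeneous of degree 1 in (r, F)
  sp2 <- lens_spec(focal_length = 2 * sp$focal_length, radius = 2 * sp$radius)
  expect_equal(lens_thickness(2 * r, sp2), 2 * t)
  # n -> infinity limit: t -> 0 pointwise
  sp_hi <- lens_spec(sp$focal_length, sp$radius, rel_permittivity = 1e8)
  expect_lt(max(lens_thickness(r, sp_hi)), 1e-3 * max(t))
  expect_error(lens_thickness(-0.001, sp), "r must lie")
  expect_error(lens_thickness(sp$radius * 1.01, sp), "r must lie")
  expect_error(lens_spec(0.038, 0.038, rel_permittivity = 0.9), "permittivity")
})

test_that("equal-optical-path ray oracle validates the closed form", {
  # feed at the focus; ray to the hyperbolic face at radial offset r, then
  # parallel to the axis through the lens to the planar outer face.  The
  # optical path sqrt((F+t)^2 + r^2) + n (t(R) - t(r)) must be equal for
  # every ray.
  for (eps_r in c(2.0, 2.68, 4.0)) {
    sp <- lens_spec(0.04, 0.03, rel_permittivity = eps_r)
    n <- sp$refractive_index
    F <- sp$focal_length
    r <- seq(0, sp$radius, length.out = 101)
    t <- lens_thickness(r, sp)
    tR <- lens_thickness(sp$radius, sp)
    path <- sqrt((F + t)^2 + r^2) + n * (tR - t)
    expect_lt(max(path) - min(path), 1e-9 * F)
    expect_equal(path[1], F + n * tR)      # axial ray
  }
})

test_that("default lens design follows the ten-wavelength rule with PLA", {
  cfg <- default_config()
  sp <- default_lens_spec(cfg)
  lam <- wavelength(cfg)
  expect_equal(sp$focal_length, 10 * lam)
  expect_equal(sp$radius, 10 * lam)
  expect_equal(sp$rel_permittivity, 2.68)
  expect_equal(sp$conductivity, 0.19)
  expect_equal(sp$refractive_index, 1.637, tolerance = 1e-3)
  # ~38 mm aperture at the 77-81 GHz band
  expect_equal(sp$radius, 0.0382, tolerance = 1e-2)
})

test_that("profile table samples the thickness function", {
  sp <- default_lens_spec()
  tab2 <- lens_profile_table(sp, 2)
  expect_equal(tab2$r_m, c(0, sp$radius))
  expect_equal(tab2$t_m, c(0, lens_thickness(sp$radius, sp)))
  tab <- lens_profile_table(sp, 33)
  expect_equal(nrow(tab), 33)
  expect_true(all(diff(tab$t_m) >= 0))
  expect_equal(tab$t_m, lens_thickness(tab$r_m, sp))
  expect_error(lens_profile_table(sp, 1), "n_points")
})

test_that("validity check flags sub-wavelength designs", {
  cfg <- default_config()
  lam <- wavelength(cfg)
  ok <- lens_validity_check(default_lens_spec(cfg), wavelength = lam)
  expect_true(ok$ok)
  expect_equal(ok$radius_wavelengths, 10)
  small <- lens_spec(focal_length = lam, radius = lam)
  res <- suppressWarnings(lens_validity_check(small, wavelength = lam))
  expect_false(res$ok)
  expect_length(res$messages, 2)     # radius and curvature both flagged
  # threshold is configurable: the 10-wavelength design fails at 20
  res20 <- suppressWarnings(
    lens_validity_check(default_lens_spec(cfg), wavelength = lam,
                        threshold = 20))
  expect_false(res20$ok)
  expect_gt(length(res20$messages), 0)
})

test_that("profile exports round-trip (CSV) and tessellate (STL)", {
  sp <- default_lens_spec()
  csv <- tempfile(fileext = ".csv")
  write_lens_profile_csv(sp, csv, n_points = 21)
  tab <- read.csv(csv)
  expect_named(tab, c("r_mm", "t_mm"))
  expect_equal(nrow(tab), 21)
  expect_equal(tab$t_mm / 1e3, lens_thickness(tab$r_mm / 1e3, sp),
               tolerance = 1e-8)
  stl <- tempfile(fileext = ".stl")
  write_lens_profile_stl(sp, stl, n_radial = 6, n_angular = 12)
  lines <- readLines(stl)
  expect_identical(lines[1], "solid lens")
  expect_identical(lines[length(lines)], "endsolid lens")
  n_facets <- sum(grepl("^  facet normal", lines))
  expect_equal(n_facets, sum(grepl("endfacet", lines)))
  expect_gt(n_facets, 100)
})
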