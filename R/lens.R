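#' Hyperbolic dielectric lens specification
#'
#' Describes a plano-hyperbolic collimating lens fed from its focal point:
#' the wave enters through the hyperbolic face and exits the planar outer
#' face as a plane wave.  The profile depends only on the focal length `F`,
#' the radius `R` and the refractive index `n = sqrt(eps_r)`; the
#' conductivity affects loss, not shape, and is stored as metadata.
#'
#' @param focal_length Focal length `F` (feed-to-vertex distance) [m].
#' @param radius Lens radius `R` [m].
#' @param rel_permittivity Relative permittivity `eps_r` of the lens
#'   material; must be > 1.  Default 2.68 (3D-printed PLA, measured).
#' @param conductivity Material conductivity [S/m]; metadata only.
#'   Default 0.19 (3D-printed PLA, measured).
#' @param design_frequency Design frequency [Hz]; metadata.
#' @return An object of class `lens_spec`.
#' @seealso [lens_thickness()], [default_lens_spec()], [lens_profile_table()]
#' @export
lens_spec <- function(focal_length, radius, rel_permittivity = 2.68,
                      conductivity = 0.19, design_frequency = NA_real_) {
  if (!is.finite(focal_length) || focal_length <= 0)
    stop("lens_spec: focal_length must be > 0", call. = FALSE)
  if (!is.finite(radius) || radius <= 0)
    stop("lens_spec: radius must be > 0", call. = FALSE)
  if (!is.finite(rel_permittivity) || rel_permittivity <= 1)
    stop("lens_spec: rel_permittivity must be > 1 (need n > 1)", call. = FALSE)
  spec <- list(
    focal_length = as.numeric(focal_length),
    radius = as.numeric(radius),
    rel_permittivity = as.numeric(rel_permittivity),
    conductivity = as.numeric(conductivity),
    refractive_index = sqrt(as.numeric(rel_permittivity)),
    design_frequency = as.numeric(design_frequency)
  )
  class(spec) <- "lens_spec"
  spec
}

#' Default lens for a radar configuration
#'
#' The reference design: radius and focal length both ten wavelengths at the
#' radar carrier, printed PLA material constants (`eps_r = 2.68`,
#' `sigma = 0.19 S/m`).
#'
#' @param cfg A [chirp_config()].
#' @return A [lens_spec()].
#' @export
default_lens_spec <- function(cfg = default_config()) {
  lam <- wavelength(cfg)
  lens_spec(focal_length = 10 * lam, radius = 10 * lam,
            design_frequency = C_LIGHT / lam)
}

#' Lens thickness profile
#'
#' Axial thickness `t(r)` of the plano-hyperbolic lens at radial offset `r`,
#' obtained from the equal-optical-path (collimation) condition for a point
#' feed at the focus:
#' \deqn{t(r) = \frac{F}{n+1}\left(\sqrt{1 + \frac{n+1}{n-1}
#'   \left(\frac{r}{F}\right)^2} - 1\right)}
#' so that `t(0) = 0` and `t` is strictly increasing in `r`.  `t` is jointly
#' homogeneous of degree 1 in `(r, F)`.
#'
#' @param r Radial offset(s) [m]; each must lie in `[0, radius]`.
#' @param spec A [lens_spec()].
#' @return Thickness [m], vectorised over `r`.
#' @export
#' @examples
#' sp <- lens_spec(focal_length = 0.038, radius = 0.038)
#' lens_thickness(c(0, 0.038), sp)
lens_thickness <- function(r, spec) {
  stopifnot(inherits(spec, "lens_spec"))
  if (any(!is.finite(r)) || any(r < 0) || any(r > spec$radius * (1 + 1e-12)))
    stop("lens_thickness: r must lie in [0, radius]", call. = FALSE)
  n <- spec$refractive_index
  F <- spec$focal_length
  (F / (n + 1)) * (sqrt(1 + ((n + 1) / (n - 1)) * (r / F)^2) - 1)
}

#' Sampled lens profile
#'
#' Uniformly samples the thickness profile on `[0, radius]`.
#'
#' @param spec A [lens_spec()].
#' @param n_points Number of sample points (>= 2).
#' @return A data.frame with columns `r_m` and `t_m`.
#' @export
lens_profile_table <- function(spec, n_points = 101L) {
  stopifnot(inherits(spec, "lens_spec"))
  n_points <- as.integer(n_points)
  if (n_points < 2L)
    stop("lens_profile_table: n_points must be >= 2", call. = FALSE)
  r <- seq(0, spec$radius, length.out = n_points)
  data.frame(r_m = r, t_m = lens_thickness(r, spec))
}

#' Geometric-optics validity check
#'
#' The thin collimating-lens derivation neglects edge diffraction, which is
#' justified when the lens dimensions and the local radius of curvature of
#' the refracting surface are large compared to the wavelength.  This check
#' flags a design whose radius or minimum surface curvature radius falls
#' below `threshold` wavelengths.  It warns; it does not error, since the
#' profile formula itself remains well defined.
#'
#' @param spec A [lens_spec()].
#' @param wavelength Operating wavelength [m]; defaults to the spec's design
#'   frequency when available.
#' @param threshold Minimum acceptable size in wavelengths; default 5.
#' @return A list with elements `ok`, `radius_wavelengths`,
#'   `min_curvature_radius_wavelengths`, `threshold` and `messages`.
#' @export
lens_validity_check <- function(spec, wavelength = NULL, threshold = 5) {
  stopifnot(inherits(spec, "lens_spec"))
  if (is.null(wavelength)) {
    if (!is.finite(spec$design_frequency))
      stop("lens_validity_check: supply wavelength or a design_frequency",
           call. = FALSE)
    wavelength <- C_LIGHT / spec$design_frequency
  }
  # curvature of the meridian profile curve (r, t(r)), numerically
  r <- seq(0, spec$radius, length.out = 512L)
  t <- lens_thickness(r, spec)
  dr <- r[2] - r[1]
  tp <- c(NA, diff(t)) / dr
  tpp <- c(NA, diff(tp)) / dr
  kappa <- abs(tpp) / (1 + tp^2)^1.5
  min_curv_radius <- 1 / max(kappa, na.rm = TRUE)
  r_wl <- spec$radius / wavelength
  c_wl <- min_curv_radius / wavelength
  msgs <- character()
  if (r_wl < threshold)
    msgs <- c(msgs, sprintf(
      "lens radius is %.2f wavelengths (< %g): geometric-optics profile may be inaccurate",
      r_wl, threshold))
  if (c_wl < threshold)
    msgs <- c(msgs, sprintf(
      "minimum surface curvature radius is %.2f wavelengths (< %g)", c_wl, threshold))
  for (m in msgs) warning(m, call. = FALSE)
  list(ok = length(msgs) == 0L,
       radius_wavelengths = r_wl,
       min_curvature_radius_wavelengths = c_wl,
       threshold = threshold,
       messages = msgs)
}

#' Export a lens profile as CSV
#'
#' Writes columns `r_mm`, `t_mm`.
#'
#' @param spec A [lens_spec()].
#' @param path Output file path.
#' @param n_points Number of profile samples.
#' @return The path, invisibly.
#' @export
write_lens_profile_csv <- function(spec, path, n_points = 101L) {
  tab <- lens_profile_table(spec, n_points)
  out <- data.frame(r_mm = tab$r_m * 1e3, t_mm = tab$t_m * 1e3)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a lens as an ASCII STL surface of revolution
#'
#' Triangulates the hyperbolic entry face, the planar outer face and the
#' cylindrical rim of the lens solid.  Coordinates are millimetres; the
#' axis of revolution is z, with the hyperbolic face vertex at z = 0 and
#' the planar face at z = t(R).
#'
#' @param spec A [lens_spec()].
#' @param path Output file path.
#' @param n_radial,n_angular Radial and angular tessellation counts.
#' @return The path, invisibly.
#' @export
write_lens_profile_stl <- function(spec, path, n_radial = 24L, n_angular = 48L) {
  stopifnot(inherits(spec, "lens_spec"))
  n_radial <- max(2L, as.integer(n_radial))
  n_angular <- max(3L, as.integer(n_angular))
  r <- seq(0, spec$radius, length.out = n_radial) * 1e3
  z_face <- lens_thickness(r / 1e3, spec) * 1e3
  z_back <- max(z_face)
  th <- seq(0, 2 * pi, length.out = n_angular + 1L)
  ring <- function(rr, zz) cbind(rr * cos(th[-length(th)]),
                                 rr * sin(th[-length(th)]), zz)
  tris <- list()
  quad <- function(a, b) {
    # a, b: consecutive rings (n_angular x 3); split each quad into 2 tris
    idx <- seq_len(n_angular)
    nxt <- c(idx[-1], 1L)
    rbind(
      cbind(a[idx, , drop = FALSE], a[nxt, , drop = FALSE], b[idx, , drop = FALSE]),
      cbind(b[idx, , drop = FALSE], a[nxt, , drop = FALSE], b[nxt, , drop = FALSE])
    )
  }
  # entry (hyperbolic) face, z = t(r)
  for (i in seq_len(n_radial - 1L))
    tris[[length(tris) + 1L]] <- quad(ring(r[i], z_face[i]), ring(r[i + 1L], z_face[i + 1L]))
  # planar back face at z_back (single fan from axis)
  tris[[length(tris) + 1L]] <- quad(ring(0, z_back), ring(max(r), z_back))
  # rim connecting face edge to back edge
  tris[[length(tris) + 1L]] <- quad(ring(max(r), max(z_face)), ring(max(r), z_back))
  all_tris <- do.call(rbind, tris)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid lens", con)
  apply(all_tris, 1L, function(v) {
    p1 <- v[1:3]; p2 <- v[4:6]; p3 <- v[7:9]
    nrm <- c(
      (p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
      (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
      (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    )
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeLines(c(
      sprintf("  facet normal %e %e %e", nrm[1], nrm[2], nrm[3]),
      "    outer loop",
      sprintf("      vertex %e %e %e", p1[1], p1[2], p1[3]),
      sprintf("      vertex %e %e %e", p2[1], p2[2], p2[3]),
      sprintf("      vertex %e %e %e", p3[1], p3[2], p3[3]),
      "    endloop",
      "  endfacet"), con)
    invisible(NULL)
  })
  writeLines("endsolid lens", con)
  invisible(path)
}

#' @export
print.lens_spec <- function(x, ...) {
  cat("<lens_spec>\n")
  cat(sprintf("  F = %.2f mm, R = %.2f mm\n",
              x$focal_length * 1e3, x$radius * 1e3))
  cat(sprintf("  eps_r = %.3f (n = %.4f), sigma = %.2f S/m\n",
              x$rel_permittivity, x$refractive_index, x$conductivity))
  cat(sprintf("  max thickness t(R) = %.2f mm\n",
              lens_thickness(x$radius, x) * 1e3))
  invisible(x)
}
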