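#' Optical properties of a homogeneous turbid medium
#'
#' @param mu_a absorption coefficient, 1/mm (`>= 0`).
#' @param mu_s scattering coefficient, 1/mm (`>= 0`).
#' @param g scattering anisotropy, `|g| < 1` (Henyey--Greenstein parameter;
#'   the mean scattering cosine).
#' @param n refractive index (`>= 1`); boundaries are index-matched in the
#'   transport model, the index is carried as metadata.
#' @return An object of class `optical_medium`.
#' @seealso [medium_preset()]
#' @export
optical_medium <- function(mu_a, mu_s, g = 0, n = 1.33) {
  check_scalar(mu_a, "mu_a", lower = 0)
  check_scalar(mu_s, "mu_s", lower = 0)
  check_scalar(g, "g", lower = -1, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(n, "n", lower = 1)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_medium")
}

#' Optical medium presets
#'
#' `"milk3"` emulates the 3% milk solution used as the optical scatterer in
#' the wire-phantom tank: reduced scattering `mu_s' = 1/mm` (so
#' `mu_s = mu_s' / (1 - g) = 10/mm` at `g = 0.9`) and weak absorption
#' `mu_a = 0.002/mm`.  These are configuration defaults representative of
#' diluted milk, not asserted measurement values.  `"transparent"` is a
#' vacuum-like reference medium.
#'
#' @param name preset name, `"milk3"` or `"transparent"`.
#' @return An [optical_medium()].
#' @export
medium_preset <- function(name = c("milk3", "transparent")) {
  name <- match.arg(name)
  switch(name,
         milk3 = optical_medium(mu_a = 0.002, mu_s = 10, g = 0.9, n = 1.33),
         transparent = optical_medium(mu_a = 0, mu_s = 0, g = 0, n = 1))
}

#' Sample Henyey--Greenstein deflection cosines
#'
#' Draws deflection cosines from the Henyey--Greenstein phase function with
#' anisotropy `g` by analytic inversion of its CDF; for `g = 0` the cosines
#' are uniform on \[-1, 1\].  `E[cos theta] = g`.
#'
#' @param g anisotropy, `|g| < 1`.
#' @param n number of samples.
#' @return Numeric vector of `n` deflection cosines in \[-1, 1\].
#' @examples
#' set.seed(1); mean(hg_sample(0.9, 1e4))
#' @export
hg_sample <- function(g, n = 1) {
  check_scalar(g, "g", lower = -1, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  u <- runif(n)
  if (abs(g) < 1e-8) return(2 * u - 1)
  s <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - s^2) / (2 * g)))
}

#' Photon packet
#'
#' @param position numeric 3-vector, mm.
#' @param direction unit 3-vector.
#' @param weight weight in (0, 1].
#' @return An object of class `photon_packet`.
#' @export
photon_packet <- function(position, direction, weight = 1) {
  if (length(position) != 3L || !all(is.finite(position))) {
    stop("'position' must be a finite 3-vector", call. = FALSE)
  }
  if (length(direction) != 3L || abs(sqrt(sum(direction^2)) - 1) > 1e-8) {
    stop("'direction' must be a unit 3-vector", call. = FALSE)
  }
  check_scalar(weight, "weight", lower = 0, upper = 1, strict_lower = TRUE)
  structure(list(position = as.numeric(position),
                 direction = as.numeric(direction),
                 weight = weight),
            class = "photon_packet")
}

grid_spec <- function(xlim = c(-40, 40), ylim = c(-10, 10), zlim = c(0, 60),
                      voxel_size_mm = 1) {
  stopifnot(length(xlim) == 2L, length(ylim) == 2L, length(zlim) == 2L,
            diff(xlim) > 0, diff(ylim) > 0, diff(zlim) > 0, voxel_size_mm > 0)
  list(xlim = xlim, ylim = ylim, zlim = zlim, voxel_size_mm = voxel_size_mm,
       nx = as.integer(ceiling(diff(xlim) / voxel_size_mm)),
       ny = as.integer(ceiling(diff(ylim) / voxel_size_mm)),
       nz = as.integer(ceiling(diff(zlim) / voxel_size_mm)))
}

run_transport <- function(pos, dir, w, medium, grid,
                          roulette_threshold = 1e-4, survival_factor = 10,
                          max_events = 2000000L) {
  .mc_transport_cpp(pos, dir, w,
                    medium$mu_a, medium$mu_s, medium$g,
                    grid$xlim, grid$ylim, grid$zlim,
                    grid$nx, grid$ny, grid$nz, grid$voxel_size_mm,
                    roulette_threshold, survival_factor,
                    as.integer(max_events))
}

#' Propagate a single photon packet
#'
#' Runs one weighted packet through the Monte Carlo transport kernel:
#' exponential step lengths with `mu_t = mu_a + mu_s`, a weight deposit of
#' `w * mu_a / mu_t` per interaction, Henyey--Greenstein scattering, and
#' Russian roulette below `roulette_threshold` (survival factor 10).  The
#' packet terminates by absorption, roulette, or leaving the grid box.
#'
#' @param packet a [photon_packet()].
#' @param medium an [optical_medium()].
#' @param grid grid box, as `list(xlim, ylim, zlim, voxel_size_mm)`.
#' @param roulette_threshold weight below which roulette is played.
#' @return A list: `status` (`"absorbed"`, `"transmitted"` for the deep z
#'   face, `"reflected"` for the source-side z face, `"side"`), `weight`
#'   remaining at exit, `exit_position`, `exit_direction`, `deposited`
#'   weight, and the per-voxel `fluence` array.
#' @export
propagate <- function(packet, medium, grid = list(xlim = c(-40, 40),
                                                  ylim = c(-40, 40),
                                                  zlim = c(0, 60),
                                                  voxel_size_mm = 2),
                      roulette_threshold = 1e-4) {
  stopifnot(inherits(packet, "photon_packet"), inherits(medium, "optical_medium"))
  g <- grid_spec(grid$xlim, grid$ylim, grid$zlim, grid$voxel_size_mm)
  res <- run_transport(matrix(packet$position, 1L), matrix(packet$direction, 1L),
                       packet$weight, medium, g, roulette_threshold)
  status <- c("transmitted", "reflected", "side")[res$status[1]]
  if (res$status[1] == 0L) status <- "absorbed"
  list(status = status,
       weight = res$exit_w[1],
       exit_position = c(res$exit_x[1], res$exit_y[1], res$exit_z[1]),
       exit_direction = c(res$exit_ux[1], res$exit_uy[1], res$exit_uz[1]),
       deposited = res$absorbed,
       fluence = array(res$fluence, dim = c(g$nx, g$ny, g$nz)))
}

# Initial photon states for the three source models.  The two fiber bundles
# sit at +/- beam_offset_mm on either side of the imaging plane (y = 0);
# the "collimated" source is a single on-plane rectangular aperture.
source_photons <- function(n_photons, source, lens, na, beam_offset_mm,
                           elevation_aperture_mm = 2,
                           lateral_aperture_mm = 13) {
  xs <- runif(n_photons, -lateral_aperture_mm / 2, lateral_aperture_mm / 2)
  ys <- runif(n_photons, -elevation_aperture_mm / 2, elevation_aperture_mm / 2)
  if (source == "collimated") {
    pos <- cbind(xs, ys, 0)
    dir <- cbind(0, 0, rep(1, n_photons))
    return(list(pos = pos, dir = dir, w = rep(1, n_photons)))
  }
  side <- sample(c(-1, 1), n_photons, replace = TRUE)
  ys <- side * beam_offset_mm + ys
  if (source == "bare") {
    # Gaussian far field with the NA half-angle at the 2-sigma level,
    # the usual approximation for a fiber-bundle output cone.
    sigma <- asin(na) / 2
    tx <- tan(rnorm(n_photons, 0, sigma))
    ty <- tan(rnorm(n_photons, 0, sigma))
    nrm <- sqrt(tx^2 + ty^2 + 1)
    dir <- cbind(tx / nrm, ty / nrm, 1 / nrm)
    pos <- cbind(xs, ys, 0)
  } else {                         # lens-traced exit rays
    tr <- trace_lateral(lens, n_rays = 1001)
    rays <- tr$rays[!tr$rays$tir & !tr$rays$vignetted, , drop = FALSE]
    pick <- rays[sample.int(nrow(rays), n_photons, replace = TRUE), ]
    el <- trace_elevation(lens, beam_offset_mm)
    ty <- -side * tan(deg2rad(el$deviation_angle_deg))
    tx <- pick$dir_x / pick$dir_z
    nrm <- sqrt(tx^2 + ty^2 + 1)
    dir <- cbind(tx / nrm, ty / nrm, 1 / nrm)
    pos <- cbind(pick$exit_x, ys, 0)
  }
  list(pos = pos, dir = dir, w = rep(1, n_photons))
}

#' Monte Carlo fluence map for a lens or bare-fiber source
#'
#' Launches `n_photons` weighted packets from the chosen source model into a
#' homogeneous turbid medium and tallies the deposited weight per voxel.
#' Sources: `"collimated"` (the 13 x 2 mm rectangular fiber aperture on the
#' imaging plane, straight beams), `"bare"` (two bundles at
#' `+/- beam_offset_mm` in elevation with a divergence cone of the given
#' numerical aperture), and `"lens"` (exit rays of the traced
#' concave--convex fan, deflected toward the imaging plane by the
#' planar--oblique profile).  Runs are bit-reproducible for a fixed seed.
#'
#' @param source `"lens"`, `"bare"`, or `"collimated"`.
#' @param medium an [optical_medium()].
#' @param grid grid box `list(xlim, ylim, zlim, voxel_size_mm)`; depth `z`
#'   starts at the source plane.
#' @param n_photons number of packets (`>= 1`).
#' @param seed integer RNG seed.
#' @param lens a [lens_design()] (used by the `"lens"` source).
#' @param na source numerical aperture for the `"bare"` cone (the probe's
#'   measurement bundle: 0.66).
#' @param beam_offset_mm elevation offset of the bundle axes from the
#'   imaging plane.
#' @param depths_mm optional depths at which lateral [screen_profile()]s
#'   are attached to the result.
#' @return An object of class `fluence_grid`: the deposited-weight array
#'   (`fluence[x, y, z]`), voxel-center axes `x_mm`/`y_mm`/`z_mm`,
#'   `photons_launched`, `seed`, conservation `tallies`, and optionally
#'   `profiles`.
#' @export
simulate_fluence <- function(source = c("lens", "bare", "collimated"),
                             medium = medium_preset("milk3"),
                             grid = list(xlim = c(-40, 40), ylim = c(-10, 10),
                                         zlim = c(0, 60), voxel_size_mm = 1),
                             n_photons = 10000, seed = 1,
                             lens = lens_design(), na = 0.66,
                             beam_offset_mm = 2.316, depths_mm = NULL) {
  source <- match.arg(source)
  stopifnot(inherits(medium, "optical_medium"))
  n_photons <- as.integer(n_photons)
  if (n_photons < 1L) stop("'n_photons' must be >= 1", call. = FALSE)
  g <- grid_spec(grid$xlim, grid$ylim, grid$zlim, grid$voxel_size_mm)
  set.seed(seed)
  src <- source_photons(n_photons, source, lens, na, beam_offset_mm)
  inside <- src$pos[, 1] >= g$xlim[1] & src$pos[, 1] <= g$xlim[2] &
    src$pos[, 2] >= g$ylim[1] & src$pos[, 2] <= g$ylim[2]
  if (!all(inside)) stop("source aperture lies outside the grid", call. = FALSE)
  res <- run_transport(src$pos, src$dir, src$w, medium, g)
  out <- structure(list(
    fluence = array(res$fluence, dim = c(g$nx, g$ny, g$nz)),
    x_mm = g$xlim[1] + (seq_len(g$nx) - 0.5) * g$voxel_size_mm,
    y_mm = g$ylim[1] + (seq_len(g$ny) - 0.5) * g$voxel_size_mm,
    z_mm = g$zlim[1] + (seq_len(g$nz) - 0.5) * g$voxel_size_mm,
    voxel_size_mm = g$voxel_size_mm,
    photons_launched = n_photons,
    seed = seed,
    source = source,
    tallies = list(launched = sum(src$w),
                   absorbed = res$absorbed,
                   transmitted = sum(res$exit_w[res$status == 1L]),
                   reflected = sum(res$exit_w[res$status == 2L]),
                   side = sum(res$exit_w[res$status == 3L]),
                   roulette_net = res$roulette_net)),
    class = "fluence_grid")
  if (!is.null(depths_mm)) {
    out$profiles <- lapply(depths_mm, function(d) screen_profile(out, d))
    names(out$profiles) <- paste0("depth_", depths_mm)
  }
  out
}

#' @export
print.fluence_grid <- function(x, ...) {
  cat("<fluence_grid>\n")
  cat(sprintf("  %d x %d x %d voxels (%.2f mm), %d photons, source '%s', seed %d\n",
              dim(x$fluence)[1], dim(x$fluence)[2], dim(x$fluence)[3],
              x$voxel_size_mm, x$photons_launched, x$source, x$seed))
  t <- x$tallies
  cat(sprintf("  absorbed %.4f | transmitted %.4f | reflected %.4f | side %.4f (of %g launched)\n",
              t$absorbed, t$transmitted, t$reflected, t$side, t$launched))
  invisible(x)
}

#' Slab transmission estimate
#'
#' Monte Carlo estimate of the fraction of launched weight transmitted
#' through a slab of the given thickness (pencil beam at normal incidence,
#' laterally unbounded).  In the ballistic limit (`mu_s = 0`) this recovers
#' the Beer--Lambert law `exp(-mu_a * thickness)`.
#'
#' @param medium an [optical_medium()].
#' @param thickness_mm slab thickness (> 0).
#' @param n_photons number of packets.
#' @param seed integer RNG seed.
#' @return A list with `fraction` (in \[0, 1\]), the Monte Carlo standard
#'   error `se`, and `n_photons`.
#' @examples
#' slab_transmission(optical_medium(0.1, 0), 3, n_photons = 1e4, seed = 1)
#' @export
slab_transmission <- function(medium, thickness_mm, n_photons = 1e5, seed = 1) {
  stopifnot(inherits(medium, "optical_medium"))
  check_scalar(thickness_mm, "thickness_mm", lower = 0, strict_lower = TRUE)
  n_photons <- as.integer(n_photons)
  g <- grid_spec(c(-1e5, 1e5), c(-1e5, 1e5), c(0, thickness_mm),
                 voxel_size_mm = max(thickness_mm, 2e5))
  set.seed(seed)
  pos <- cbind(0, 0, rep(0, n_photons))
  dir <- cbind(0, 0, rep(1, n_photons))
  res <- run_transport(pos, dir, rep(1, n_photons), medium, g)
  per <- ifelse(res$status == 1L, res$exit_w, 0)
  list(fraction = sum(per) / n_photons,
       se = stats::sd(per) / sqrt(n_photons),
       n_photons = n_photons)
}
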