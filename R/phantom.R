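#' Specification of a synthetic liver phantom
#'
#' Describes a liver with spherical tumours (each with its own
#' tumour-to-normal uptake ratio) that may contain deliberately under-
#' perfused cold regions, on an imaging grid mirroring a clinical Y-90
#' bremsstrahlung SPECT acquisition: 128 x 128 in-plane at 4.8 mm with
#' 3.0 mm slices, blurred with a 9.0 mm FWHM Gaussian. Positions are in mm
#' in grid physical coordinates; the liver is an ellipsoid (axis ratios
#' 1 : 0.8 : 0.6) centred in the grid and sized to \code{liver_volume_cc}.
#'
#' @param liver_volume_cc whole-liver volume, cc.
#' @param tumors list of tumour specs: each
#'   \code{list(center_mm =, radius_mm =, uptake_ratio =)} with
#'   uptake_ratio > 0. \code{center_mm} is relative to the liver centre.
#' @param cold_spots list of cold-region specs:
#'   \code{list(center_mm =, radius_mm =, multiplier =)} with multiplier in
#'   [0, 1) scaling the local uptake.
#' @param grid_dim integer grid dimensions.
#' @param spacing_mm voxel spacing, mm.
#' @param blur_fwhm_mm SPECT blur FWHM, mm.
#' @param noise_scale scale of signal-proportional noise (0 = noiseless).
#' @param seed integer seed for the simulated acquisition.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(liver_volume_cc = 1600,
                         tumors = list(list(center_mm = c(0, 0, 0),
                                            radius_mm = 25,
                                            uptake_ratio = 4)),
                         cold_spots = list(),
                         grid_dim = c(128, 128, 64),
                         spacing_mm = c(4.8, 4.8, 3.0),
                         blur_fwhm_mm = 9.0,
                         noise_scale = 0.05,
                         seed = 1L) {
  if (liver_volume_cc <= 0) stop("'liver_volume_cc' must be > 0")
  for (tu in tumors)
    if (tu$uptake_ratio <= 0) stop("tumour uptake ratios must be > 0")
  for (cs in cold_spots)
    if (cs$multiplier < 0 || cs$multiplier >= 1)
      stop("cold-spot multipliers must be in [0, 1)")
  if (blur_fwhm_mm < 0) stop("'blur_fwhm_mm' must be >= 0")
  if (noise_scale < 0) stop("'noise_scale' must be >= 0")
  structure(list(liver_volume_cc = liver_volume_cc, tumors = tumors,
                 cold_spots = cold_spots, grid_dim = as.integer(grid_dim),
                 spacing_mm = as.numeric(spacing_mm),
                 blur_fwhm_mm = blur_fwhm_mm, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Rasterize the phantom anatomy
#'
#' Builds the liver and GTV masks on the phantom grid. The liver is an
#' ellipsoid sized to the requested volume; tumours are spheres that must
#' lie entirely inside the liver. A voxel belongs to a structure when its
#' centre lies inside the analytic surface.
#'
#' @param spec a [phantom_spec()].
#' @return \code{list(liver =, gtv =)} of [roi_mask()] objects.
#' @export
make_anatomy <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_dim; sp <- spec$spacing_mm
  centre <- (dm - 1) / 2 * sp            # origin at (0,0,0)
  ax <- liver_semiaxes(spec$liver_volume_cc)
  x <- (seq_len(dm[1]) - 1) * sp[1]
  y <- (seq_len(dm[2]) - 1) * sp[2]
  z <- (seq_len(dm[3]) - 1) * sp[3]
  ex <- ((x - centre[1]) / ax[1])^2
  ey <- ((y - centre[2]) / ax[2])^2
  ez <- ((z - centre[3]) / ax[3])^2
  liver <- outer(outer(ex, ey, "+"), ez, "+") <= 1
  gtv <- array(FALSE, dm)
  for (tu in spec$tumors) {
    s <- sphere_mask(dm, sp, centre + tu$center_mm, tu$radius_mm)
    if (!any(s) || any(s & !liver))
      stop("tumour extends outside the liver")
    gtv <- gtv | s
  }
  for (cs in spec$cold_spots) {
    s <- sphere_mask(dm, sp, centre + cs$center_mm, cs$radius_mm)
    if (any(s & !liver))
      stop("cold spot extends outside the liver")
  }
  list(liver = roi_mask(liver, spacing = sp, label = "liver"),
       gtv = roi_mask(gtv, spacing = sp, label = "GTV"))
}

liver_semiaxes <- function(volume_cc) {
  # V = 4/3 pi a * 0.8a * 0.6a  (mm^3) with axis ratios 1 : 0.8 : 0.6
  a <- (volume_cc * 1000 * 3 / (4 * pi * 0.8 * 0.6))^(1 / 3)
  c(a, 0.8 * a, 0.6 * a)
}

sphere_mask <- function(dm, sp, centre_mm, radius_mm) {
  x <- (seq_len(dm[1]) - 1) * sp[1]
  y <- (seq_len(dm[2]) - 1) * sp[2]
  z <- (seq_len(dm[3]) - 1) * sp[3]
  r2 <- outer(outer((x - centre_mm[1])^2, (y - centre_mm[2])^2, "+"),
              (z - centre_mm[3])^2, "+")
  r2 <= radius_mm^2
}

#' Ground-truth activity field of a phantom
#'
#' Piecewise-constant uptake — normal liver 1, tumour voxels the tumour's
#' uptake ratio, cold-spot voxels the local uptake times the cold
#' multiplier, zero outside the liver — scaled so the grid total equals
#' \code{total_activity_GBq}.
#'
#' @param anatomy result of [make_anatomy()].
#' @param spec the [phantom_spec()].
#' @param total_activity_GBq total activity in the field (> 0).
#' @return A [voxel_grid()] with unit \code{"GBq"}.
#' @export
make_true_activity <- function(anatomy, spec, total_activity_GBq = 1) {
  if (total_activity_GBq <= 0) stop("'total_activity_GBq' must be > 0")
  dm <- spec$grid_dim; sp <- spec$spacing_mm
  centre <- (dm - 1) / 2 * sp
  u <- array(0, dm)
  u[anatomy$liver$values] <- 1
  for (tu in spec$tumors) {
    s <- sphere_mask(dm, sp, centre + tu$center_mm, tu$radius_mm)
    u[s] <- tu$uptake_ratio
  }
  for (cs in spec$cold_spots) {
    s <- sphere_mask(dm, sp, centre + cs$center_mm, cs$radius_mm)
    u[s] <- u[s] * cs$multiplier
  }
  tot <- sum(u)
  if (tot <= 0) stop("phantom has no uptake")
  voxel_grid(u * (total_activity_GBq / tot), spacing = sp, unit = "GBq")
}

#' Simulate a SPECT-like counts map from a true activity field
#'
#' Emulates the imaging chain as a normalized Gaussian blur (the clinical
#' reconstruction applies a 9.0 mm FWHM Gaussian pre-filter) followed by
#' signal-proportional Gaussian noise (variance proportional to the blurred
#' signal, approximating Poisson statistics at SPECT count levels), clamped
#' at zero. Collimator response, attenuation, scatter and OSEM
#' reconstruction are deliberately not modelled.
#'
#' @param true_activity a [voxel_grid()] (any unit; treated as emission
#'   density).
#' @param blur_fwhm_mm Gaussian blur FWHM, mm (>= 0).
#' @param noise_scale noise amplitude: counts = mean + noise_scale *
#'   sqrt(mean) * N(0,1). 0 gives a noiseless map proportional to truth.
#' @param seed integer seed; the same seed gives a bit-identical map.
#' @param counts_per_unit expected total counts per unit total activity.
#' @return A [voxel_grid()] with unit \code{"counts"}.
#' @export
simulate_spect <- function(true_activity, blur_fwhm_mm = 9.0,
                           noise_scale = 0.05, seed = 1L,
                           counts_per_unit = 1e6) {
  stopifnot(inherits(true_activity, "voxel_grid"))
  if (blur_fwhm_mm < 0) stop("'blur_fwhm_mm' must be >= 0")
  if (noise_scale < 0) stop("'noise_scale' must be >= 0")
  k <- gaussian_kernel3d(blur_fwhm_mm, true_activity$spacing)
  mean_counts <- convolve3d(true_activity$values, k) * counts_per_unit
  if (noise_scale > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    mean_counts <- mean_counts +
      noise_scale * sqrt(pmax(mean_counts, 0)) *
        stats::rnorm(length(mean_counts))
  }
  voxel_grid(array(pmax(mean_counts, 0), dim(true_activity$values)),
             spacing = true_activity$spacing, origin = true_activity$origin,
             unit = "counts")
}

#' Run the full phantom imaging chain
#'
#' Convenience wrapper: anatomy, true activity, and simulated counts for
#' one [phantom_spec()], keeping the ground truth alongside the observables
#' so every downstream stage can be scored against it.
#'
#' @param spec a [phantom_spec()].
#' @param total_activity_GBq total true activity.
#' @return \code{list(spec, liver, gtv, true_activity, counts)}.
#' @export
simulate_phantom <- function(spec, total_activity_GBq = 1) {
  anat <- make_anatomy(spec)
  act <- make_true_activity(anat, spec, total_activity_GBq)
  counts <- simulate_spect(act, spec$blur_fwhm_mm, spec$noise_scale,
                           seed = spec$seed)
  list(spec = spec, liver = anat$liver, gtv = anat$gtv,
       true_activity = act, counts = counts)
}

# save/restore the global RNG state so seeded simulators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
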