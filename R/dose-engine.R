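#' Dose-kernel specification
#'
#' Describes how the energy carried by each voxel's activity is spread
#' spatially. Three kinds are supported: \code{delta} (all energy stays in
#' the source voxel — the Local Deposition Model as a kernel), a Gaussian
#' radial kernel (\code{gaussian_dpk}, parameterised by FWHM), and a
#' tabulated radial dose-point kernel (\code{tabulated_dpk}) supplied as a
#' plain-text table of (radius mm, relative energy density). A synthetic
#' Y-90-like table with an 11.3 mm cutoff ships with the package and is the
#' default for \code{tabulated_dpk}.
#'
#' @param kind kernel kind.
#' @param fwhm_mm FWHM for \code{gaussian_dpk}.
#' @param table data.frame with columns \code{radius_mm},
#'   \code{rel_energy_density} for \code{tabulated_dpk}; \code{NULL} loads
#'   the shipped synthetic table.
#' @return An object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(kind = c("delta", "gaussian_dpk", "tabulated_dpk"),
                        fwhm_mm = 6, table = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian_dpk" && fwhm_mm <= 0)
    stop("'fwhm_mm' must be > 0 for a gaussian kernel")
  if (kind == "tabulated_dpk") {
    if (is.null(table)) table <- y90_dpk_table()
    stopifnot(all(c("radius_mm", "rel_energy_density") %in% names(table)))
    if (any(table$radius_mm < 0) || any(table$rel_energy_density < 0))
      stop("dose-point-kernel table must be non-negative")
    if (is.unsorted(table$radius_mm, strictly = TRUE))
      stop("dose-point-kernel radii must be strictly increasing")
  }
  structure(list(kind = kind, fwhm_mm = fwhm_mm, table = table),
            class = "kernel_spec")
}

#' Shipped synthetic Y-90 dose-point-kernel table
#'
#' A smooth, monotone-decreasing radial energy-density profile with an
#' 11.3 mm cutoff (the Y-90 maximum beta range in soft tissue). It is an
#' analytic stand-in constructed for this package — not a Monte-Carlo
#' transport result — and is labelled synthetic accordingly; its role is to
#' provide a realistic short-range spreading kernel for the convolution
#' engine.
#'
#' @return data.frame with columns \code{radius_mm},
#'   \code{rel_energy_density}.
#' @export
y90_dpk_table <- function() {
  path <- system.file("extdata", "y90_dpk_synthetic.tsv",
                      package = "taredose", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#")
}

# Discretize a kernel_spec onto a voxel lattice. Returns an odd-dimension
# array summing to 1 (all emitted energy deposited within support).
discretize_kernel <- function(kernel, spacing) {
  if (kernel$kind == "delta") return(array(1, c(1, 1, 1)))
  if (kernel$kind == "gaussian_dpk")
    return(gaussian_kernel3d(kernel$fwhm_mm, spacing))
  tab <- kernel$table
  support <- max(tab$radius_mm)
  h <- pmax(1L, ceiling(support / spacing))
  ax <- lapply(1:3, function(d) (-h[d]:h[d]) * spacing[d])
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  dens <- stats::approx(tab$radius_mm, tab$rel_energy_density, xout = r,
                        yleft = tab$rel_energy_density[1], yright = 0,
                        rule = 2)$y
  dens[r > support] <- 0
  k <- array(dens, dim = 2L * h + 1L)
  s <- sum(k)
  if (s <= 0) stop("kernel discretizes to zero on this spacing")
  k <- k / s
  stopifnot(abs(sum(k) - 1) < 1e-6)
  k
}

#' Calibrate a counts map to absolute activity
#'
#' Scales a SPECT counts volume so that the total activity over the field
#' of view equals the administered activity net of the lung shunt and any
#' residual vial fraction: voxelwise proportionality to counts is
#' preserved. 1 mCi = 0.037 GBq.
#'
#' @param counts a [voxel_grid()] of counts (all >= 0).
#' @param administered_activity_mCi administered activity in mCi (> 0).
#' @param lsf lung shunt fraction in [0, 1].
#' @param field_mask optional [roi_mask()]: the field of view whose total is
#'   normalized (default: the whole grid).
#' @param residual_fraction fraction of activity left in the vial/tubing,
#'   default 0.
#' @return A [voxel_grid()] with unit \code{"GBq"} (GBq per voxel).
#' @export
calibrate_activity <- function(counts, administered_activity_mCi, lsf = 0,
                               field_mask = NULL, residual_fraction = 0) {
  stopifnot(inherits(counts, "voxel_grid"))
  if (any(counts$values < 0)) stop("counts must be >= 0")
  if (lsf < 0 || lsf > 1) stop("'lsf' must be in [0, 1]")
  if (administered_activity_mCi <= 0)
    stop("'administered_activity_mCi' must be > 0")
  if (residual_fraction < 0 || residual_fraction >= 1)
    stop("'residual_fraction' must be in [0, 1)")
  if (is.null(field_mask)) {
    total_counts <- sum(counts$values)
  } else {
    assert_same_geometry(counts, field_mask)
    total_counts <- sum(counts$values[field_mask$values])
  }
  if (total_counts <= 0) stop("total counts in the field of view are zero")
  total_gbq <- administered_activity_mCi * 0.037 * (1 - lsf) *
    (1 - residual_fraction)
  voxel_grid(counts$values * (total_gbq / total_counts),
             spacing = counts$spacing, origin = counts$origin, unit = "GBq")
}

#' Absorbed dose by the Local Deposition Model
#'
#' Each voxel's activity deposits all of its decay energy in that voxel:
#' \code{D_v = delta * A_v / (density * voxel_volume)}, with \code{delta}
#' the energy-deposition constant in Gy.kg/GBq.
#'
#' @param activity a [voxel_grid()] in GBq per voxel.
#' @param constants a [physics_constants()].
#' @return A [voxel_grid()] of absorbed dose in Gy.
#' @export
ldm_dose <- function(activity, constants = physics_constants()) {
  stopifnot(inherits(activity, "voxel_grid"))
  if (activity$unit != "GBq")
    stop("'activity' must be a GBq-per-voxel grid (run calibrate_activity)")
  mass_kg <- voxel_mass_kg(activity, constants)
  voxel_grid(activity$values * (constants$delta_Gy_kg_per_GBq / mass_kg),
             spacing = activity$spacing, origin = activity$origin,
             unit = "Gy")
}

#' Absorbed dose by dose-point-kernel convolution
#'
#' Converts the activity map to an energy field (delta * A per voxel) and
#' convolves it with the discretized, normalized kernel; the result divided
#' by the voxel mass is the absorbed dose. A \code{delta} kernel reproduces
#' [ldm_dose()] exactly. Zero padding is used at the edges, so total energy
#' is conserved for sources at least one kernel support away from the grid
#' boundary.
#'
#' @param activity a [voxel_grid()] in GBq per voxel.
#' @param kernel a [kernel_spec()].
#' @param constants a [physics_constants()].
#' @return A [voxel_grid()] of absorbed dose in Gy.
#' @export
dpk_dose <- function(activity, kernel = kernel_spec("tabulated_dpk"),
                     constants = physics_constants()) {
  stopifnot(inherits(activity, "voxel_grid"), inherits(kernel, "kernel_spec"))
  if (activity$unit != "GBq")
    stop("'activity' must be a GBq-per-voxel grid (run calibrate_activity)")
  if (kernel$kind == "delta") return(ldm_dose(activity, constants))
  k <- discretize_kernel(kernel, activity$spacing)
  energy <- activity$values * constants$delta_Gy_kg_per_GBq   # joules
  spread <- convolve3d(energy, k)
  mass_kg <- voxel_mass_kg(activity, constants)
  voxel_grid(spread / mass_kg, spacing = activity$spacing,
             origin = activity$origin, unit = "Gy")
}

voxel_mass_kg <- function(grid, constants) {
  v_cc <- voxel_volume_cc(grid)
  if (v_cc <= 0) stop("non-positive voxel volume")
  v_cc * constants$tissue_density_g_per_cc / 1000
}
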