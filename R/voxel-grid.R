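#' Voxel grid: a 3D scalar field with physical geometry
#'
#' The common currency of the dose engine: a 3D array of voxel values
#' (counts, activity in GBq per voxel, or absorbed dose in Gy) together with
#' the voxel spacing and origin in millimetres. The geometry convention is
#' fixed throughout the package: axes are (x, y, z), array element
#' \code{values[i, j, k]} (1-based) has its centre at
#' \code{origin + (c(i, j, k) - 1) * spacing}, and a voxel spans half a
#' spacing on either side of its centre.
#'
#' @param values numeric 3D array; must be finite everywhere.
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin numeric length-3, physical position (mm) of the centre of
#'   voxel \code{[1, 1, 1]}.
#' @param unit one of \code{"counts"}, \code{"GBq"}, \code{"Gy"} — the unit
#'   tag carried with the field.
#'
#' @return An object of class \code{voxel_grid}.
#' @examples
#' g <- voxel_grid(array(1, c(8, 8, 8)), spacing = c(4.8, 4.8, 3.0))
#' voxel_volume_cc(g)
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0),
                       unit = c("counts", "GBq", "Gy")) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("'values' must be finite everywhere")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite values (mm)")
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = unit),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s, %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$unit, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm; voxel volume %.6g cc\n",
              x$origin[1], x$origin[2], x$origin[3], voxel_volume_cc(x)))
  cat(sprintf("  range [%.6g, %.6g], total %.6g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' Voxel volume in cubic centimetres
#'
#' Computed from the grid spacing: \code{prod(spacing) / 1000} (mm^3 to cc).
#'
#' @param x a \code{voxel_grid} or \code{roi_mask}.
#' @return Scalar voxel volume in cc.
#' @export
voxel_volume_cc <- function(x) {
  prod(geometry_of(x)$spacing) / 1000
}

#' Binary region of interest on a voxel lattice
#'
#' A boolean field sharing a \code{voxel_grid} geometry, labelling a
#' structure: the gross tumour volume (GTV), the whole liver, the
#' nontumorous liver (liver minus GTV), or the lungs.
#'
#' @param values logical 3D array (or 0/1 numeric coerced to logical).
#' @param spacing,origin grid geometry (mm), as in [voxel_grid()]; may be
#'   supplied via \code{grid} instead.
#' @param grid optional \code{voxel_grid} (or another \code{roi_mask}) whose
#'   geometry the mask shares; overrides \code{spacing}/\code{origin}.
#' @param label structure label, one of \code{"GTV"}, \code{"liver"},
#'   \code{"nontumorous_liver"}, \code{"lungs"}, \code{"other"}.
#' @return An object of class \code{roi_mask}.
#' @export
roi_mask <- function(values, spacing = NULL, origin = c(0, 0, 0), grid = NULL,
                     label = c("other", "GTV", "liver", "nontumorous_liver",
                               "lungs")) {
  label <- match.arg(label)
  if (!is.null(grid)) {
    geo <- geometry_of(grid)
    spacing <- geo$spacing
    origin <- geo$origin
  }
  if (is.null(spacing)) stop("supply 'spacing' or 'grid'")
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be logical or 0/1")
    values <- array(as.logical(values), dim(values))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive values (mm)")
  if (!is.null(grid) && !is.null(dim_of(grid)) &&
      !identical(dim(values), dim_of(grid)))
    stop("mask shape does not match its grid")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), label = label),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s, %d x %d x %d voxels, %d set (%.4g cc)\n",
              x$label, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              sum(x$values), mask_volume_cc(x)))
  invisible(x)
}

#' Physical volume of a mask in cc
#' @param mask a \code{roi_mask}.
#' @return Number of set voxels times the voxel volume, in cc.
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$values) * voxel_volume_cc(mask)
}

#' Nontumorous liver mask (liver minus GTV)
#'
#' @param liver,gtv \code{roi_mask} objects on the same grid.
#' @return A \code{roi_mask} labelled \code{nontumorous_liver}, equal to
#'   \code{liver AND NOT gtv}.
#' @export
nontumorous_liver <- function(liver, gtv) {
  assert_same_geometry(liver, gtv)
  roi_mask(liver$values & !gtv$values, spacing = liver$spacing,
           origin = liver$origin, label = "nontumorous_liver")
}

# --- internal geometry helpers -------------------------------------------

geometry_of <- function(x) {
  if (inherits(x, "voxel_grid") || inherits(x, "roi_mask"))
    return(list(spacing = x$spacing, origin = x$origin))
  stop("expected a voxel_grid or roi_mask; bare arrays carry no geometry")
}

dim_of <- function(x) dim(x$values)

# all dose/metric operations insist that grids and masks live on one lattice
assert_same_geometry <- function(a, b, tol = 1e-6) {
  if (!identical(dim_of(a), dim_of(b)))
    stop("objects are on different lattices (shape mismatch)")
  ga <- geometry_of(a); gb <- geometry_of(b)
  if (max(abs(ga$spacing - gb$spacing)) > tol ||
      max(abs(ga$origin - gb$origin)) > tol)
    stop("objects are on different lattices (geometry mismatch)")
  invisible(TRUE)
}
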