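#' Cumulative dose-volume histogram of a structure
#'
#' Fraction of the structure volume receiving at least each dose level, on
#' a regular dose axis. The curve starts at 1 at 0 Gy, is non-increasing,
#' and reaches 0 beyond the maximum voxel dose. Binned curves are for
#' export and plotting; the headline Dx metrics are computed on the exact
#' sorted voxel doses by [dose_at_volume()], not from a binned curve.
#'
#' @param dose a [voxel_grid()] of absorbed dose (Gy).
#' @param mask a nonempty [roi_mask()] on the same grid.
#' @param bin_width_Gy dose-axis resolution, Gy.
#' @return An object of class \code{dvh}: data.frame columns \code{dose_gy}
#'   and \code{volume_fraction}, plus attributes \code{structure} and
#'   \code{structure_volume_cc}.
#' @export
cumulative_dvh <- function(dose, mask, bin_width_Gy = 0.5) {
  d <- masked_doses(dose, mask)
  if (bin_width_Gy <= 0) stop("'bin_width_Gy' must be > 0")
  top <- max(d, 0) + bin_width_Gy
  axis <- seq(0, top, by = bin_width_Gy)
  n <- length(d)
  ds <- sort(d)
  # count of voxels with dose < a, via binary search on the sorted doses
  cnt_below <- findInterval(axis, ds, left.open = TRUE)
  frac <- (n - cnt_below) / n
  out <- data.frame(dose_gy = axis, volume_fraction = frac)
  structure(out, class = c("dvh", "data.frame"),
            structure = mask$label,
            structure_volume_cc = n * voxel_volume_cc(mask))
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s, %.4g cc, %d dose bins up to %.4g Gy\n",
              attr(x, "structure"), attr(x, "structure_volume_cc"),
              nrow(x), max(x$dose_gy)))
  invisible(x)
}

#' @export
plot.dvh <- function(x, ...) {
  graphics::plot(x$dose_gy, 100 * x$volume_fraction, type = "s",
                 xlab = "Dose (Gy)", ylab = "Volume (%)",
                 main = sprintf("Cumulative DVH: %s", attr(x, "structure")),
                 ylim = c(0, 100), ...)
  invisible(x)
}

#' Dx: minimum dose covering the hottest x% of a structure
#'
#' The largest dose d such that the fraction of the structure receiving at
#' least d is at least x/100, computed on the exact sorted voxel doses
#' (volume-weighted order statistic, no binning): with n masked voxels this
#' is the ceiling(n*x/100)-th largest voxel dose. Non-increasing in x.
#'
#' @param dose a [voxel_grid()] of dose (Gy).
#' @param mask a nonempty [roi_mask()] on the same grid.
#' @param x_percent coverage percentage in (0, 100].
#' @return Dose in Gy. Vectorised over \code{x_percent}.
#' @examples
#' # equal halves at 50 and 150 Gy: D50 = 150, D70 = 50
#' @export
dose_at_volume <- function(dose, mask, x_percent) {
  if (any(x_percent <= 0) || any(x_percent > 100))
    stop("'x_percent' must be in (0, 100]")
  d <- sort(masked_doses(dose, mask), decreasing = TRUE)
  n <- length(d)
  m <- ceiling(n * x_percent / 100)
  d[pmin(pmax(m, 1L), n)]
}

#' Structure volume receiving less than a dose threshold
#'
#' Count of masked voxels with dose strictly below the threshold, times the
#' voxel volume. The inequality is strict ("receiving less than"): a voxel
#' exactly at the threshold is not counted.
#'
#' @param dose a [voxel_grid()] of dose (Gy).
#' @param mask a nonempty [roi_mask()].
#' @param threshold_Gy dose threshold (> 0). Vectorised.
#' @return Volume in cc.
#' @export
volume_below <- function(dose, mask, threshold_Gy) {
  if (any(threshold_Gy <= 0)) stop("'threshold_Gy' must be > 0")
  d <- masked_doses(dose, mask)
  vv <- voxel_volume_cc(mask)
  vapply(threshold_Gy, function(t) sum(d < t) * vv, numeric(1))
}

#' All per-treatment dosimetric parameters
#'
#' Extracts the full dosimetric parameter set for one treatment: min, max,
#' mean and median GTV dose; D2, D5, D50, D70, D95, D98; GTV volumes below
#' 120/100/70/50 Gy; the heterogeneity index HI = D5/D95 (NA when D95 = 0);
#' the conformity index CI = (tissue volume receiving >= 120 Gy)/GTV,
#' counted over the whole dose grid; the healthy-tissue overdose factor
#' HTOF = (nontumorous liver volume receiving >= 120 Gy)/GTV; the activity
#' density of the nontumorous liver (cc per mCi); the disease burden
#' GTV/liver; and the mean nontumorous-liver dose. The ">=" in CI and HTOF
#' is inclusive while "receiving less than" is strict, mirroring the
#' printed definitions. The 120 Gy reference isodose for CI/HTOF is the
#' glass-sphere prescription level; it is configurable for resin analyses.
#'
#' @param dose a [voxel_grid()] of dose (Gy) covering the imaged field.
#' @param gtv,liver [roi_mask()] objects on the dose grid, GTV inside liver.
#' @param administered_activity_mCi delivered activity (mCi, > 0).
#' @param reference_isodose_Gy isodose used by CI/HTOF (default 120).
#' @return An object of class \code{dose_metrics} (named list).
#' @export
summary_metrics <- function(dose, gtv, liver, administered_activity_mCi,
                            reference_isodose_Gy = 120) {
  assert_same_geometry(dose, gtv)
  assert_same_geometry(dose, liver)
  if (any(gtv$values & !liver$values))
    stop("GTV must be contained in the liver mask")
  if (administered_activity_mCi <= 0)
    stop("activity density undefined for zero administered activity")
  d_gtv <- masked_doses(dose, gtv)
  vv <- voxel_volume_cc(dose)
  ntl <- liver$values & !gtv$values
  d_ntl <- dose$values[ntl]
  gtv_cc <- length(d_gtv) * vv
  liver_cc <- sum(liver$values) * vv

  dx <- dose_at_volume(dose, gtv, c(2, 5, 50, 70, 95, 98))
  names(dx) <- c("d2", "d5", "d50", "d70", "d95", "d98")
  vb <- volume_below(dose, gtv, c(120, 100, 70, 50))
  names(vb) <- c("v_lt_120_cc", "v_lt_100_cc", "v_lt_70_cc", "v_lt_50_cc")

  out <- list(
    dose_min_gy = min(d_gtv), dose_max_gy = max(d_gtv),
    dose_mean_gy = mean(d_gtv), dose_median_gy = stats::median(d_gtv),
    d2_gy = dx[["d2"]], d5_gy = dx[["d5"]], d50_gy = dx[["d50"]],
    d70_gy = dx[["d70"]], d95_gy = dx[["d95"]], d98_gy = dx[["d98"]],
    v_lt_120_cc = vb[["v_lt_120_cc"]], v_lt_100_cc = vb[["v_lt_100_cc"]],
    v_lt_70_cc = vb[["v_lt_70_cc"]], v_lt_50_cc = vb[["v_lt_50_cc"]],
    hi = if (dx[["d95"]] > 0) dx[["d5"]] / dx[["d95"]] else NA_real_,
    ci = sum(dose$values >= reference_isodose_Gy) * vv / gtv_cc,
    htof = sum(d_ntl >= reference_isodose_Gy) * vv / gtv_cc,
    activity_density_cc_per_mci =
      sum(ntl) * vv / administered_activity_mCi,
    burden = gtv_cc / liver_cc,
    mean_nontumorous_liver_dose_gy =
      if (any(ntl)) mean(d_ntl) else NA_real_,
    gtv_cc = gtv_cc, liver_cc = liver_cc,
    reference_isodose_gy = reference_isodose_Gy)
  class(out) <- "dose_metrics"
  out
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf("<dose_metrics> GTV %.4g cc, liver %.4g cc, burden %.3f\n",
              x$gtv_cc, x$liver_cc, x$burden))
  cat(sprintf("  GTV dose Gy: min %.1f  median %.1f  mean %.1f  max %.1f\n",
              x$dose_min_gy, x$dose_median_gy, x$dose_mean_gy, x$dose_max_gy))
  cat(sprintf("  D2 %.1f  D5 %.1f  D50 %.1f  D70 %.1f  D95 %.1f  D98 %.1f\n",
              x$d2_gy, x$d5_gy, x$d50_gy, x$d70_gy, x$d95_gy, x$d98_gy))
  cat(sprintf("  V<120 %.1f  V<100 %.1f  V<70 %.1f  V<50 %.1f cc\n",
              x$v_lt_120_cc, x$v_lt_100_cc, x$v_lt_70_cc, x$v_lt_50_cc))
  cat(sprintf("  HI %.2f  CI %.3f  HTOF %.3f  activity density %.2f cc/mCi\n",
              x$hi, x$ci, x$htof, x$activity_density_cc_per_mci))
  cat(sprintf("  mean nontumorous-liver dose %.1f Gy\n",
              x$mean_nontumorous_liver_dose_gy))
  invisible(x)
}

masked_doses <- function(dose, mask) {
  stopifnot(inherits(dose, "voxel_grid"), inherits(mask, "roi_mask"))
  assert_same_geometry(dose, mask)
  if (!any(mask$values)) stop("mask is empty")
  dose$values[mask$values]
}
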