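#' Lung shunt fraction from planar/SPECT counts
#'
#' LSF = lung counts / (lung + liver counts). A shunt above 20% is an
#' absolute contraindication to radioembolization.
#'
#' @param lung_counts,liver_counts total counts in the lung and liver
#'   regions (each >= 0, not both zero).
#' @return A list with \code{lsf} (fraction in [0, 1]) and
#'   \code{contraindicated} (\code{TRUE} when lsf > 0.20).
#' @examples
#' lung_shunt_fraction(10, 90)   # 0.10
#' @export
lung_shunt_fraction <- function(lung_counts, liver_counts) {
  if (lung_counts < 0 || liver_counts < 0) stop("counts must be >= 0")
  tot <- lung_counts + liver_counts
  if (tot <= 0) stop("lung and liver counts are both zero")
  lsf <- lung_counts / tot
  list(lsf = lsf, contraindicated = lsf > 0.20)
}

#' Glass-microsphere activity by the single-compartment MIRD model
#'
#' \code{A = D * M / (delta_rx * (1 - LSF) * (1 - residual))}: the activity
#' (GBq) that delivers prescription dose \code{D} (Gy, conventionally 120
#' for glass spheres) uniformly to a target of mass \code{M} (kg), after
#' accounting for the lung shunt and any residual vial fraction. This is
#' the single-compartment form; multi-compartment partition dosimetry with
#' separately measured uptake ratios is out of scope.
#'
#' @param prescribed_dose_Gy prescription dose, Gy.
#' @param target_mass_kg target (perfused lobe) mass in kg; alternatively
#'   give \code{target_volume_cc} + \code{density_g_per_cc}.
#' @param target_volume_cc,density_g_per_cc volume route to the mass;
#'   exactly one of mass or volume must be supplied.
#' @param lsf lung shunt fraction in [0, 1).
#' @param residual_fraction residual vial fraction in [0, 1).
#' @param delta_rx energy-deposition constant used for prescription,
#'   Gy.kg/GBq; defaults to the vendor convention 50 (the dose engine's
#'   physics default is the derived ~49.6, see [y90_delta_constant()]).
#' @return Activity in GBq.
#' @examples
#' mird_glass_activity(120, target_mass_kg = 1)   # 2.4 GBq
#' @export
mird_glass_activity <- function(prescribed_dose_Gy, target_mass_kg = NULL,
                                target_volume_cc = NULL,
                                density_g_per_cc = 1.03,
                                lsf = 0, residual_fraction = 0,
                                delta_rx = 50) {
  if (is.null(target_mass_kg) == is.null(target_volume_cc))
    stop("supply exactly one of 'target_mass_kg' or 'target_volume_cc'")
  if (is.null(target_mass_kg))
    target_mass_kg <- target_volume_cc * density_g_per_cc / 1000
  if (prescribed_dose_Gy < 0) stop("'prescribed_dose_Gy' must be >= 0")
  if (target_mass_kg <= 0) stop("target mass must be > 0")
  if (lsf < 0 || lsf >= 1) stop("'lsf' must be in [0, 1)")
  if (residual_fraction < 0 || residual_fraction >= 1)
    stop("'residual_fraction' must be in [0, 1)")
  prescribed_dose_Gy * target_mass_kg /
    (delta_rx * (1 - lsf) * (1 - residual_fraction))
}

#' Resin-microsphere activity by the BSA method
#'
#' \code{A = (BSA - 0.2) + V_tumor / (V_tumor + V_normal_liver)} in GBq,
#' with the empirical stepped lung-shunt reduction: full activity below
#' 10% LSF, 80% for 10-15%, 60% for 15-20%, and contraindicated above 20%
#' (an error, not a number). The 85 Gy prescription quoted for resin
#' spheres is clinical metadata; the BSA formula itself does not consume a
#' dose.
#'
#' @param bsa_m2 body surface area in m2 (> 0.2); alternatively give
#'   \code{height_cm} + \code{weight_kg} (Du Bois).
#' @param height_cm,weight_kg anthropometric route to BSA.
#' @param tumor_volume_cc,liver_volume_cc tumour and whole-liver volumes
#'   (cc); the tumour fraction denominator is total liver (tumour + normal).
#' @param lsf lung shunt fraction in [0, 1].
#' @return Activity in GBq.
#' @examples
#' bsa_resin_activity(bsa_m2 = 1.8, tumor_volume_cc = 50,
#'                    liver_volume_cc = 1000)
#' @export
bsa_resin_activity <- function(bsa_m2 = NULL, height_cm = NULL,
                               weight_kg = NULL, tumor_volume_cc,
                               liver_volume_cc, lsf = 0) {
  if (is.null(bsa_m2)) {
    if (is.null(height_cm) || is.null(weight_kg))
      stop("supply 'bsa_m2' or both 'height_cm' and 'weight_kg'")
    bsa_m2 <- bsa_dubois(height_cm, weight_kg)
  }
  if (bsa_m2 <= 0.2) stop("'bsa_m2' must exceed 0.2")
  if (tumor_volume_cc < 0 || liver_volume_cc < tumor_volume_cc)
    stop("need 0 <= tumor_volume_cc <= liver_volume_cc")
  if (lsf < 0 || lsf > 1) stop("'lsf' must be in [0, 1]")
  if (lsf > 0.20)
    stop("lung shunt fraction > 20%: radioembolization contraindicated")
  tumor_fraction <- if (liver_volume_cc > 0)
    tumor_volume_cc / liver_volume_cc else 0
  base <- (bsa_m2 - 0.2) + tumor_fraction
  base * lsf_reduction_factor(lsf)
}

# stepped LSF reduction for the BSA method; breaks at exactly 0.10/0.15/0.20
lsf_reduction_factor <- function(lsf) {
  if (lsf < 0.10) 1.0
  else if (lsf < 0.15) 0.8
  else if (lsf <= 0.20) 0.6
  else stop("lung shunt fraction > 20%: radioembolization contraindicated")
}

#' Body surface area by the Du Bois formula
#'
#' \code{BSA = 0.007184 * height_cm^0.725 * weight_kg^0.425} (m2).
#'
#' @param height_cm height in cm (> 0).
#' @param weight_kg weight in kg (> 0).
#' @return BSA in m2.
#' @examples
#' bsa_dubois(170, 70)   # ~1.810
#' @export
bsa_dubois <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be > 0")
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Convert activity between GBq and mCi
#' @param gbq,mci activity values.
#' @return The converted activity (1 mCi = 0.037 GBq).
#' @export
gbq_to_mci <- function(gbq) gbq / 0.037

#' @rdname gbq_to_mci
#' @export
mci_to_gbq <- function(mci) mci * 0.037
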