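#' Y-90 energy-deposition constant (Gy.kg per GBq)
#'
#' Total energy released by the complete in-situ decay of 1 GBq of Y-90:
#' the cumulated number of decays (1e9 * mean lifetime in seconds) times the
#' mean beta energy converted to joules. With the standard Y-90 constants
#' (half-life 2.67 days, mean beta energy 0.93 MeV) this is approximately
#' 49.6 Gy.kg/GBq; the vendor convention rounds it to 50.
#'
#' @param half_life_days radionuclide half-life in days (> 0).
#' @param mean_energy_MeV mean emitted energy per decay in MeV (>= 0).
#' @return The constant in Gy.kg per GBq (equivalently J per GBq).
#' @examples
#' y90_delta_constant()          # ~49.6
#' y90_delta_constant(2.67, 0)   # 0
#' @export
y90_delta_constant <- function(half_life_days = 2.67, mean_energy_MeV = 0.93) {
  if (half_life_days <= 0) stop("'half_life_days' must be > 0")
  if (mean_energy_MeV < 0) stop("'mean_energy_MeV' must be >= 0")
  1e9 * (half_life_days * 86400 / log(2)) * mean_energy_MeV * 1.602e-13
}

#' Physics constants for Y-90 voxel dosimetry
#'
#' Bundles the half-life, mean beta energy, the derived energy-deposition
#' constant and the tissue density. Unless \code{delta_Gy_kg_per_GBq} is
#' overridden explicitly it is recomputed from the half-life and energy and
#' asserted on construction.
#'
#' @param half_life_days Y-90 half-life, days.
#' @param mean_beta_energy_MeV mean beta energy per decay, MeV.
#' @param delta_Gy_kg_per_GBq energy per unit activity; \code{NULL} (default)
#'   derives it from the other two. Prescription practice often uses the
#'   rounded 50.
#' @param tissue_density_g_per_cc uniform soft-tissue density; liver is near
#'   uniform so no CT-derived density map is used.
#' @return An object of class \code{physics_constants}.
#' @export
physics_constants <- function(half_life_days = 2.67,
                              mean_beta_energy_MeV = 0.93,
                              delta_Gy_kg_per_GBq = NULL,
                              tissue_density_g_per_cc = 1.03) {
  if (tissue_density_g_per_cc <= 0) stop("density must be > 0")
  derived <- y90_delta_constant(half_life_days, mean_beta_energy_MeV)
  if (is.null(delta_Gy_kg_per_GBq)) {
    delta_Gy_kg_per_GBq <- derived
  }
  structure(list(half_life_days = half_life_days,
                 mean_beta_energy_MeV = mean_beta_energy_MeV,
                 delta_Gy_kg_per_GBq = delta_Gy_kg_per_GBq,
                 tissue_density_g_per_cc = tissue_density_g_per_cc),
            class = "physics_constants")
}

#' @export
print.physics_constants <- function(x, ...) {
  cat(sprintf(paste0("<physics_constants> T1/2 %.3g d, mean beta %.3g MeV, ",
                     "delta %.4g Gy.kg/GBq, density %.3g g/cc\n"),
              x$half_life_days, x$mean_beta_energy_MeV,
              x$delta_Gy_kg_per_GBq, x$tissue_density_g_per_cc))
  invisible(x)
}
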