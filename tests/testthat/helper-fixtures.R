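# shared fixture builders; everything is generated in code at test time

grid_of <- function(values, spacing = c(4.8, 4.8, 3.0), unit = "Gy",
                    origin = c(0, 0, 0)) {
  voxel_grid(values, spacing = spacing, origin = origin, unit = unit)
}

full_mask <- function(dm, spacing = c(4.8, 4.8, 3.0), label = "GTV") {
  roi_mask(array(TRUE, dm), spacing = spacing, label = label)
}

# dose grid with prescribed voxel doses laid out in array order
dose_of <- function(doses, dm, spacing = c(4.8, 4.8, 3.0)) {
  stopifnot(length(doses) == prod(dm))
  grid_of(array(doses, dm), spacing = spacing, unit = "Gy")
}

# independent enumeration oracle for Dx: scan the unique doses and keep the
# largest one whose at-or-above fraction reaches x/100
dx_oracle <- function(doses, x_percent) {
  n <- length(doses)
  sd <- sort(doses)
  u <- unique(sd)
  # at-or-above count for each unique dose: n minus the strictly-below count
  cnt_ge <- n - (match(u, sd) - 1L)
  ok <- cnt_ge / n >= x_percent / 100
  max(u[ok])
}

# tiny phantom spec for fast end-to-end runs
tiny_phantom <- function(seed = 1, cold = FALSE, noise = 0.05) {
  phantom_spec(
    liver_volume_cc = 900,
    tumors = list(list(center_mm = c(0, 0, 0), radius_mm = 18,
                       uptake_ratio = 4)),
    cold_spots = if (cold)
      list(list(center_mm = c(6, 0, 0), radius_mm = 8, multiplier = 0.1))
    else list(),
    grid_dim = c(40, 40, 44), spacing_mm = c(4.8, 4.8, 3.0),
    blur_fwhm_mm = 9, noise_scale = noise, seed = seed)
}
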