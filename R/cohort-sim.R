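#' Generative parameters for a synthetic TARE cohort
#'
#' The generator draws per-treatment anatomy, activity and an intratumoral
#' dose distribution (lognormal within each tumour, so the whole Dx family,
#' cold volume and HI are mutually consistent), then generates outcomes
#' from the dosimetric features with the directional structure the analysis
#' assumes: objective response is logistic in the volume of GTV under
#' 100 Gy, grade >= 3 toxicity is logistic in baseline bilirubin and mean
#' nontumorous-liver dose, and OS/PFS are exponential proportional-hazards
#' in response status and cold volume. Defaults are calibrated so cohort
#' summaries land near clinically reported lobar-TARE values (responder /
#' non-responder OS medians near 22.5 / 7.6 months, PFS near 13.1 / 4.7,
#' D70 medians near 95 / 60 Gy); this is a calibration of the simulator,
#' not ground truth about any patient population.
#'
#' @param n_treatments cohort size (>= 2).
#' @param gtv_meanlog,gtv_sdlog lognormal parameters of GTV volume (cc).
#' @param activity_meanlog,activity_sdlog lognormal parameters of
#'   administered activity (mCi).
#' @param mu_meanlog,mu_sdlog distribution of the per-tumour log-median
#'   dose parameter.
#' @param sigma_range range of the per-tumour lognormal shape (dose
#'   heterogeneity).
#' @param beta0 logistic intercept for objective response.
#' @param beta_coldvol logistic slope on the cold volume (per cc; negative:
#'   more under-dosed tumour, less response).
#' @param beta_cr0,beta_cr_coldvol logistic parameters for complete
#'   response among all treatments.
#' @param tox0,tox_bilirubin,tox_nld logistic parameters for grade >= 3
#'   toxicity (intercept; per mg/dL bilirubin; per Gy mean nontumorous-
#'   liver dose).
#' @param os_median_responder_months,os_hr_nonresponder,os_loghr_coldvol
#'   OS model: responder median, non-responder hazard ratio, log-HR per cc
#'   cold volume.
#' @param pfs_median_responder_months,pfs_hr_nonresponder PFS analogues.
#' @param censoring_rate probability a record is censored, in [0, 1).
#' @param seed integer seed.
#' @return An object of class \code{cohort_gen_params}.
#' @export
cohort_gen_params <- function(n_treatments = 51,
                              gtv_meanlog = log(85), gtv_sdlog = 1.0,
                              activity_meanlog = log(39.25),
                              activity_sdlog = 0.55,
                              mu_meanlog = log(110), mu_sdlog = 0.45,
                              sigma_range = c(0.4, 1.1),
                              beta0 = 1.4, beta_coldvol = -0.015,
                              beta_cr0 = 0.5, beta_cr_coldvol = -0.05,
                              tox0 = -4.5, tox_bilirubin = 0.9,
                              tox_nld = 0.04,
                              os_median_responder_months = 22.5,
                              os_hr_nonresponder = 22.5 / 7.6,
                              os_loghr_coldvol = 0.002,
                              pfs_median_responder_months = 13.1,
                              pfs_hr_nonresponder = 13.1 / 4.7,
                              censoring_rate = 0.25,
                              seed = 1L) {
  if (n_treatments < 2) stop("'n_treatments' must be >= 2")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("'censoring_rate' must be in [0, 1)")
  stopifnot(gtv_sdlog > 0, activity_sdlog > 0, mu_sdlog > 0,
            all(sigma_range > 0), os_median_responder_months > 0,
            pfs_median_responder_months > 0, os_hr_nonresponder > 0,
            pfs_hr_nonresponder > 0)
  p <- as.list(environment())
  structure(p, class = "cohort_gen_params")
}

#' Simulate a synthetic TARE cohort
#'
#' One row per treatment, with procedure metadata, the full dosimetric
#' parameter set, outcomes, and the generating latent truth (true response
#' probability, true toxicity probability, true hazards) retained in
#' \code{true_*} columns so recovery can be scored. All randomness flows
#' through \code{params$seed}: the same parameters give a bit-identical
#' cohort.
#'
#' @param params a [cohort_gen_params()].
#' @return A data.frame cohort table (see [read_cohort()] for the column
#'   dictionary) with additional \code{true_*} latent columns.
#' @export
simulate_cohort <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  n <- params$n_treatments

  sphere <- ifelse(stats::runif(n) < 0.59, "glass", "resin")
  gtv <- pmin(pmax(stats::rlnorm(n, params$gtv_meanlog, params$gtv_sdlog),
                   1.2), 1593)
  liver <- pmax(stats::rnorm(n, 1600, 250), gtv + 200)
  activity <- pmin(pmax(stats::rlnorm(n, params$activity_meanlog,
                                      params$activity_sdlog), 7.5), 132.2)
  lsf <- pmin(stats::rbeta(n, 2, 30), 0.20)
  bili <- stats::rlnorm(n, log(0.9), 0.4)
  albumin <- stats::rnorm(n, 3.8, 0.5)
  portal <- stats::runif(n) < 0.30
  prior_tx <- stats::runif(n) < 0.25
  tnr <- stats::runif(n, 2, 8)

  mu <- stats::rnorm(n, params$mu_meanlog, params$mu_sdlog)
  sigma <- stats::runif(n, params$sigma_range[1], params$sigma_range[2])

  qx <- function(x) exp(mu + sigma * stats::qnorm(1 - x / 100))
  d2 <- qx(2); d5 <- qx(5); d50 <- qx(50); d70 <- qx(70)
  d95 <- qx(95); d98 <- qx(98)
  dmin <- exp(mu + sigma * stats::qnorm(0.001))
  dmax <- exp(mu + sigma * stats::qnorm(0.999))
  dmean <- exp(mu + sigma^2 / 2)
  vlt <- function(t) gtv * stats::pnorm((log(t) - mu) / sigma)
  v120 <- vlt(120); v100 <- vlt(100); v70 <- vlt(70); v50 <- vlt(50)
  hi <- d5 / d95

  ntl <- liver - gtv
  total_gbq <- activity * 0.037 * (1 - lsf)
  share_ntl <- ntl / (ntl + tnr * gtv)
  delta <- y90_delta_constant()
  mean_nld <- delta * total_gbq * share_ntl / (ntl * 1.03 / 1000)
  sd_n <- 0.6
  mu_n <- log(pmax(mean_nld, 1e-6)) - sd_n^2 / 2
  p_n120 <- stats::pnorm((log(120) - mu_n) / sd_n, lower.tail = FALSE)
  ci <- ((gtv - v120) + ntl * p_n120) / gtv
  htof <- ntl * p_n120 / gtv

  p_or <- stats::plogis(params$beta0 + params$beta_coldvol * v100)
  or <- stats::runif(n) < p_or
  p_cr <- stats::plogis(params$beta_cr0 + params$beta_cr_coldvol * v100)
  cr <- or & (stats::runif(n) < p_cr)
  best <- ifelse(cr, "CR", ifelse(or, "PR",
                 ifelse(stats::runif(n) < 0.6, "SD", "PD")))

  p_tox <- stats::plogis(params$tox0 + params$tox_bilirubin * bili +
                           params$tox_nld * mean_nld)
  tox3 <- stats::runif(n) < p_tox
  tox_grade <- ifelse(tox3, 3L + (stats::runif(n) < 0.25) +
                        (stats::runif(n) < 0.05),
                      (stats::runif(n) < 0.5) + (stats::runif(n) < 0.3))

  lam_os <- log(2) / params$os_median_responder_months *
    exp(log(params$os_hr_nonresponder) * (!or) +
          params$os_loghr_coldvol * v100)
  lam_pfs <- log(2) / params$pfs_median_responder_months *
    exp(log(params$pfs_hr_nonresponder) * (!or) +
          params$os_loghr_coldvol * v100)
  t_os <- stats::rexp(n, lam_os)
  t_pfs <- pmin(stats::rexp(n, lam_pfs), t_os)

  cens <- stats::runif(n) < params$censoring_rate
  c_time <- ifelse(cens, stats::runif(n) * t_os, Inf)
  os_months <- pmin(t_os, c_time)
  os_event <- t_os <= c_time
  pfs_months <- pmin(t_pfs, c_time)
  pfs_event <- t_pfs <= c_time

  series <- vapply(seq_len(n), function(i) {
    b <- best[i]
    if (b %in% c("PR", "CR") && stats::runif(1) < 0.3)
      sprintf("90:SD;180:%s", b)          # late migration toward response
    else
      sprintf("90:%s;270:%s", b, b)
  }, character(1))

  df <- data.frame(
    treatment_id = sprintf("T%03d", seq_len(n)),
    sphere_type = sphere,
    administered_activity_mci = activity,
    lsf = lsf,
    bilirubin_mg_dl = bili,
    portal_htn = portal,
    albumin_g_dl = albumin,
    prior_local_treatment = prior_tx,
    gtv_cc = gtv, liver_cc = liver, burden = gtv / liver,
    dose_min_gy = dmin, dose_max_gy = dmax,
    dose_mean_gy = dmean, dose_median_gy = d50,
    d2_gy = d2, d5_gy = d5, d50_gy = d50, d70_gy = d70,
    d95_gy = d95, d98_gy = d98,
    v_lt_120_cc = v120, v_lt_100_cc = v100,
    v_lt_70_cc = v70, v_lt_50_cc = v50,
    hi = hi, ci = ci, htof = htof,
    activity_density_cc_per_mci = ntl / activity,
    mean_nontumorous_liver_dose_gy = mean_nld,
    mrecist_series = series,
    toxicity_grade_max_90d = as.integer(tox_grade),
    pfs_months = pfs_months, pfs_event = pfs_event,
    os_months = os_months, os_event = os_event,
    # latent generating truth, for recovery tests
    true_p_response = p_or,
    true_p_cr = p_cr,
    true_p_tox3 = p_tox,
    true_os_hazard = lam_os,
    true_pfs_hazard = lam_pfs,
    objective_response = or,
    complete_response = cr,
    stringsAsFactors = FALSE)
  df
}
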