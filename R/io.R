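#' Read a volume from a NIfTI file
#'
#' Reads a single scalar 3D volume. Voxel spacing comes from the NIfTI
#' pixdim and the origin from the sform/qform translation; a file without
#' positive spacing metadata is rejected rather than silently defaulted.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param unit unit tag to attach (\code{"counts"}, \code{"GBq"}, \code{"Gy"}).
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path, unit = c("counts", "GBq", "Gy")) {
  unit <- match.arg(unit)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  dm <- dim(vals)
  if (length(dm) == 4L && dm[4] == 1L) dm <- dm[1:3]
  if (length(dm) != 3L)
    stop("expected a single 3D volume in ", path)
  vals <- array(as.double(vals), dm)   # strip image attributes
  # raw header values: the reader API silently repairs bad pixdims
  raw_sp <- RNifti::niftiHeader(path)$pixdim[2:4]
  if (any(!is.finite(raw_sp)) || any(raw_sp <= 0))
    stop("non-positive or missing voxel spacing in ", path,
         "; refusing to default")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  org <- as.numeric(xf[1:3, 4])
  voxel_grid(vals, spacing = as.numeric(sp), origin = org, unit = unit)
}

#' Write a volume to a NIfTI file
#'
#' Values are stored as 64-bit floats so that a read/write round trip is
#' bit-exact; spacing and origin are stored in pixdim and the sform.
#'
#' @param grid a [voxel_grid()].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read / write a binary mask as NIfTI
#'
#' Masks are stored with values in {0, 1}; any other value is rejected.
#'
#' @param path NIfTI file path.
#' @param label structure label (see [roi_mask()]).
#' @return [read_mask()] returns a [roi_mask()]; [write_mask()] returns
#'   \code{path} invisibly.
#' @export
read_mask <- function(path, label = "other") {
  g <- read_volume(path, unit = "counts")
  if (!all(g$values %in% c(0, 1)))
    stop("mask file contains values other than 0/1: ", path)
  roi_mask(g$values == 1, spacing = g$spacing, origin = g$origin,
           label = label)
}

#' @rdname read_mask
#' @param mask a [roi_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  g <- voxel_grid(array(as.double(mask$values), dim(mask$values)),
                  spacing = mask$spacing, origin = mask$origin,
                  unit = "counts")
  write_volume(g, path)
}

#' Resample a mask onto another grid by exact overlap fractions
#'
#' Contours are drawn on one lattice (typically CT) and must land on the
#' dose grid. For axis-aligned grids the fraction of each target voxel
#' covered by the source mask factorises over axes, so it is computed
#' exactly via three 1D interval-overlap matrices; a target voxel is
#' included iff its covered fraction is at least \code{inclusion_fraction}.
#'
#' @param mask source [roi_mask()].
#' @param target_grid a [voxel_grid()] or [roi_mask()] giving the target
#'   geometry.
#' @param inclusion_fraction inclusion threshold in (0, 1]; the default 0.5
#'   is the majority partial-volume rule.
#' @return A [roi_mask()] on the target geometry.
#' @export
resample_mask <- function(mask, target_grid, inclusion_fraction = 0.5) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!(inclusion_fraction > 0 && inclusion_fraction <= 1))
    stop("'inclusion_fraction' must be in (0, 1]")
  tg <- geometry_of(target_grid)
  td <- dim_of(target_grid)
  sd <- dim(mask$values)

  w <- vector("list", 3L)
  for (ax in 1:3) {
    w[[ax]] <- overlap_matrix(
      t_n = td[ax], t_o = tg$origin[ax], t_sp = tg$spacing[ax],
      s_n = sd[ax], s_o = mask$origin[ax], s_sp = mask$spacing[ax])
  }
  if (any(vapply(w, function(m) all(m == 0), logical(1))))
    stop("source and target grids have disjoint physical extents")

  frac <- array(as.double(mask$values), sd)
  # contract each axis in turn: frac[t1,s2,s3] = sum_s1 W1[t1,s1] frac[s1,s2,s3]
  for (ax in 1:3) {
    d <- dim(frac)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(frac, perm), nrow = d[ax])
    res <- w[[ax]] %*% m
    frac <- aperm(array(res, c(td[ax], d[setdiff(1:3, ax)])), order(perm))
  }
  keep <- frac >= inclusion_fraction - 1e-9
  roi_mask(array(keep, td), spacing = tg$spacing, origin = tg$origin,
           label = mask$label)
}

# W[t, s] = length of overlap of target interval t with source interval s,
# divided by the target spacing (so rows sum to <= 1, = 1 under full cover).
overlap_matrix <- function(t_n, t_o, t_sp, s_n, s_o, s_sp) {
  t_lo <- t_o + (seq_len(t_n) - 1.5) * t_sp
  t_hi <- t_lo + t_sp
  s_lo <- s_o + (seq_len(s_n) - 1.5) * s_sp
  s_hi <- s_lo + s_sp
  hi <- pmin(outer(t_hi, rep(1, s_n)), outer(rep(1, t_n), s_hi))
  lo <- pmax(outer(t_lo, rep(1, s_n)), outer(rep(1, t_n), s_lo))
  ov <- pmax(hi - lo, 0)   # first argument keeps the matrix shape
  ov / t_sp
}

# --- cohort tables --------------------------------------------------------

.mrecist_levels <- c("PD", "SD", "PR", "CR")

.cohort_columns <- c(
  "treatment_id", "sphere_type", "administered_activity_mci", "lsf",
  "bilirubin_mg_dl", "portal_htn", "albumin_g_dl", "prior_local_treatment",
  "gtv_cc", "liver_cc", "burden",
  "dose_min_gy", "dose_max_gy", "dose_mean_gy", "dose_median_gy",
  "d2_gy", "d5_gy", "d50_gy", "d70_gy", "d95_gy", "d98_gy",
  "v_lt_120_cc", "v_lt_100_cc", "v_lt_70_cc", "v_lt_50_cc",
  "hi", "ci", "htof", "activity_density_cc_per_mci",
  "mean_nontumorous_liver_dose_gy",
  "mrecist_series", "toxicity_grade_max_90d",
  "pfs_months", "pfs_event", "os_months", "os_event")

#' Read / write a cohort table
#'
#' One row per TARE treatment: procedure metadata, dosimetric metrics, and
#' outcomes. The file is comma-separated UTF-8 with a required header. The
#' mRECIST follow-up series is encoded in one column as
#' \code{"day:LABEL;day:LABEL"} with labels among CR/PR/SD/PD; use
#' [parse_mrecist_series()] to expand it. Survival times are months;
#' doses Gy; volumes cc; activity mCi.
#'
#' Validation is strict: unknown mRECIST tokens and negative survival times
#' are rejected with the offending row named.
#'
#' @param path CSV path.
#' @return [read_cohort()] returns a data.frame with one row per treatment;
#'   [write_cohort()] returns \code{path} invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_columns, names(df))
  if (length(missing_cols))
    stop("cohort table missing columns: ", paste(missing_cols, collapse = ", "))
  validate_cohort(df)
  df
}

#' @rdname read_cohort
#' @param cohort a cohort data.frame as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

validate_cohort <- function(df) {
  for (i in seq_len(nrow(df))) {
    ser <- df$mrecist_series[i]
    labs <- vapply(strsplit(strsplit(ser, ";", fixed = TRUE)[[1]],
                            ":", fixed = TRUE),
                   `[`, character(1), 2L)
    bad <- setdiff(labs, .mrecist_levels)
    if (length(bad))
      stop(sprintf("row %d, column mrecist_series: unknown mRECIST token '%s'",
                   i, bad[1]))
    for (col in c("pfs_months", "os_months")) {
      if (!is.finite(df[[col]][i]) || df[[col]][i] < 0)
        stop(sprintf("row %d, column %s: negative or missing survival time",
                     i, col))
    }
    if (!df$lsf[i] >= 0 || !df$lsf[i] <= 1)
      stop(sprintf("row %d, column lsf: lung shunt fraction outside [0, 1]", i))
  }
  invisible(TRUE)
}

#' Expand an encoded mRECIST series
#'
#' @param series a string like \code{"90:SD;180:CR"}.
#' @return A data.frame with columns \code{day} (numeric, >= 0) and
#'   \code{mrecist} (factor PD < SD < PR < CR).
#' @export
parse_mrecist_series <- function(series) {
  parts <- strsplit(series, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  day <- as.numeric(vapply(kv, `[`, character(1), 1L))
  lab <- vapply(kv, `[`, character(1), 2L)
  if (any(!lab %in% .mrecist_levels))
    stop("unknown mRECIST token: ", setdiff(lab, .mrecist_levels)[1])
  if (any(!is.finite(day)) || any(day < 0))
    stop("mRECIST series days must be non-negative numbers")
  data.frame(day = day,
             mrecist = factor(lab, levels = .mrecist_levels, ordered = TRUE))
}

#' Encode an mRECIST series data.frame as a string
#' @param df data.frame with columns \code{day}, \code{mrecist}.
#' @return The \code{"day:LABEL;..."} encoding.
#' @export
encode_mrecist_series <- function(df) {
  paste(sprintf("%g:%s", df$day, as.character(df$mrecist)), collapse = ";")
}

#' Read a flat key/value configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored. Values that parse as numbers are returned numeric. Used by the
#' command-line driver to override physics constants and thresholds.
#'
#' @param path configuration file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
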