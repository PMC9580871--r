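# gas constant in kcal mol^-1 K^-1; single authoritative definition
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Fit a fluorescence-intensity calibration curve
#'
#' Ordinary least-squares line `intensity = slope * concentration +
#' intercept` from measurements of solutions of known fluorophore
#' concentration, imaged with the same settings as the experiment. The
#' reciprocal slope is the conversion factor from intensity units to
#' micromolar. A warning is raised when the relationship is not close to
#' linear (r-squared below `linearity_r2`), e.g. when the fluorophore
#' saturates at the top of the range.
#'
#' @param conc_uM known concentrations in micromolar (>= 2 distinct values).
#' @param intensity measured mean intensities (>= 0).
#' @param linearity_r2 r-squared below which a linearity warning is raised.
#' @return An object of class `calibration_curve` with `slope`,
#'   `intercept`, `r_squared` and `factor_conc` (uM per intensity unit).
#' @export
#' @examples
#' fit_calibration(c(1, 2, 3), c(10, 20, 30))$factor_conc
fit_calibration <- function(conc_uM, intensity, linearity_r2 = 0.99) {
  if (length(conc_uM) < 2L || length(unique(conc_uM)) < 2L) {
    stop("calibration needs at least 2 distinct concentrations", call. = FALSE)
  }
  stopifnot(length(conc_uM) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  fit <- lm(intensity ~ conc_uM)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((intensity - mean(intensity))^2)
  if (r2 < linearity_r2) {
    warning(sprintf(paste("calibration is not linear (r-squared = %.4f);",
                          "intensity-to-concentration conversion is only",
                          "valid in the linear regime"), r2), call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 factor_conc = 1 / slope),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> intensity = %.4g * conc_uM + %.4g (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  factor_conc = %.6g uM per intensity unit\n", x$factor_conc))
  invisible(x)
}

#' Derive per-ROI thermodynamic parameters of phase separation
#'
#' From a per-ROI measurement table (see [measure_rois()]) computes, for
#' one puncta channel: the dense-phase value `dp` (mean intensity inside
#' the channel's puncta), the light-phase value `lp` (mean intensity
#' outside them, within the ROI), the partition coefficient `kp = dp / lp`,
#' the Gibbs free energy of transfer `dg_tr = -R * T * log(kp)` in kcal/mol
#' (R = 1.9872e-3 kcal mol^-1 K^-1), the puncta volume fraction `f_vol`
#' (total puncta volume / ROI volume), and the mole fraction `f_mol`
#' (integrated intensity inside puncta / integrated ROI intensity). When a
#' calibration factor is given, `dp`, `lp` and the ROI concentration are
#' expressed in micromolar; `kp` and `dg_tr` are invariant to this factor
#' since it cancels in the ratio. ROIs without puncta yield missing values,
#' not zeros.
#'
#' @param roi_records tibble from [measure_rois()].
#' @param puncta_channel name of the puncta (and fluorophore) channel.
#' @param temp_K temperature in Kelvin (required; no default).
#' @param factor_conc optional conversion factor, micromolar per intensity
#'   unit (see [fit_calibration()]).
#' @return Tibble with one row per ROI: `image_name`, `roi_label`,
#'   `roi_concentration_uM`, `dp`, `lp`, `kp`, `dg_tr`, `f_vol`, `f_mol`,
#'   `temperature_K`.
#' @export
compute_thermodynamics <- function(roi_records, puncta_channel, temp_K,
                                   factor_conc = NULL) {
  stopifnot(temp_K > 0)
  col <- function(fmt) {
    nm <- gsub("%s", puncta_channel, fmt, fixed = TRUE)
    if (!nm %in% names(roi_records)) {
      stop("column '", nm, "' not found in roi_records; was '",
           puncta_channel, "' a puncta channel?", call. = FALSE)
    }
    roi_records[[nm]]
  }
  dp_raw <- col("%s mean intensity inside %s puncta")
  lp_raw <- col("%s mean intensity outside %s puncta")
  if (any(dp_raw < 0, na.rm = TRUE) || any(lp_raw < 0, na.rm = TRUE)) {
    stop("negative intensities in roi_records", call. = FALSE)
  }
  fac <- factor_conc %||% 1
  mean_col <- sprintf("%s mean intensity per ROI", puncta_channel)
  conc <- if (mean_col %in% names(roi_records)) {
    roi_records[[mean_col]] * fac
  } else NA_real_
  kp <- ifelse(!is.na(dp_raw) & !is.na(lp_raw) & lp_raw > 0,
               dp_raw / lp_raw, NA_real_)
  dg_tr <- -GAS_CONSTANT_KCAL * temp_K * log(kp)
  total_vol <- col("total %s puncta volume pix per ROI")
  f_vol <- total_vol / roi_records[["ROI volume pix"]]
  int_in <- col("%s integrated intensity inside %s puncta")
  int_roi <- roi_records[[sprintf("%s integrated intensity per ROI",
                                  puncta_channel)]]
  f_mol <- ifelse(!is.na(int_in) & int_roi > 0, int_in / int_roi, NA_real_)
  n_col <- sprintf("number of %s puncta", puncta_channel)
  no_puncta <- roi_records[[n_col]] == 0
  kp[no_puncta] <- NA_real_
  dg_tr[no_puncta] <- NA_real_
  f_vol[no_puncta] <- NA_real_
  f_mol[no_puncta] <- NA_real_
  tibble::tibble(
    image_name = roi_records[["Image name"]],
    roi_label = roi_records[["ROI label"]],
    roi_concentration_uM = conc,
    dp = dp_raw * fac, lp = lp_raw * fac,
    kp = kp, dg_tr = dg_tr, f_vol = f_vol, f_mol = f_mol,
    temperature_K = temp_K)
}
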