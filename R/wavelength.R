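#' @keywords internal
RRM_LAMBDA_CONSTANT <- 201        # nm * normalized frequency
SPEED_OF_LIGHT_NM_S <- 2.998e17   # nm/s, fixed so window classification is deterministic
PROTEIN_WINDOW_HZ <- c(1e13, 1e15)

#' Convert an RRM characteristic frequency to an irradiation wavelength
#'
#' The RRM converts a normalized characteristic frequency (cycles/residue,
#' at most the Nyquist limit 0.5) to a real-space irradiation wavelength
#' through the fixed ratio lambda = 201/f (nm). The equivalent physical
#' frequency c/lambda is checked against the 1e13-1e15 Hz window predicted
#' for protein-light interactions (spanning IR through UV).
#'
#' @param f_rrm Normalized frequency in (0, 0.5].
#' @return Object of class \code{wavelength_prediction}: \code{f_rrm},
#'   \code{lambda_nm} (unrounded), \code{lambda_nm_rounded} (nearest integer,
#'   the conventionally reported value), \code{freq_hz}, \code{in_window}.
#' @examples
#' frequency_to_wavelength(0.0576)$lambda_nm_rounded  # 3490
#' @export
frequency_to_wavelength <- function(f_rrm) {
  if (!is.numeric(f_rrm) || length(f_rrm) != 1L || is.na(f_rrm) ||
      f_rrm <= 0 || f_rrm > 0.5)
    stop("f_rrm must lie in (0, 0.5]")
  lambda <- RRM_LAMBDA_CONSTANT / f_rrm
  freq_hz <- SPEED_OF_LIGHT_NM_S / lambda
  structure(list(f_rrm = f_rrm,
                 lambda_nm = lambda,
                 lambda_nm_rounded = round(lambda),
                 freq_hz = freq_hz,
                 in_window = freq_hz >= PROTEIN_WINDOW_HZ[1] &&
                             freq_hz <= PROTEIN_WINDOW_HZ[2]),
            class = "wavelength_prediction")
}

#' Invert the wavelength conversion (internal helper)
#' @param lambda_nm Wavelength in nm.
#' @return Normalized frequency 201/lambda.
#' @keywords internal
wavelength_to_frequency <- function(lambda_nm) {
  stopifnot(lambda_nm > 0)
  RRM_LAMBDA_CONSTANT / lambda_nm
}

#' Wavelength interval spanned by a pair of characteristic frequencies
#'
#' Two characteristic frequencies (e.g. for an oncogene and a proto-oncogene
#' group) bound a therapeutic wavelength window. Because lambda = 201/f is
#' decreasing, the higher frequency gives the lower wavelength endpoint.
#'
#' @param f_low,f_high Normalized frequencies, 0 < f_low < f_high <= 0.5.
#' @return Numeric length-2 vector, ascending nm (unrounded).
#' @export
wavelength_window <- function(f_low, f_high) {
  if (!(f_low > 0 && f_high > f_low && f_high <= 0.5))
    stop("require 0 < f_low < f_high <= 0.5")
  c(RRM_LAMBDA_CONSTANT / f_high, RRM_LAMBDA_CONSTANT / f_low)
}

#' Load the LED exposure catalog
#'
#' The shipped catalog lists the 12 exposure wavelengths of the study panel
#' (three visible, three near-IR, six far-IR LEDs), each with optical
#' intensity bounds of 15-30 uW and beam angle below 40 degrees. The file is
#' user-replaceable.
#'
#' @param path CSV with columns \code{nominal_wavelength_nm},
#'   \code{intensity_min_uW}, \code{intensity_max_uW}, \code{beam_angle_deg},
#'   \code{band}.
#' @return data.frame of LED specifications.
#' @export
led_catalog <- function(path = system.file("extdata", "led_catalog.csv",
                                           package = "rrmlilt")) {
  cat_df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("nominal_wavelength_nm", "intensity_min_uW",
                  "intensity_max_uW", "beam_angle_deg") %in% names(cat_df)),
            all(cat_df$nominal_wavelength_nm > 0),
            all(cat_df$intensity_min_uW <= cat_df$intensity_max_uW))
  cat_df$paper_compliant <- cat_df$beam_angle_deg < 40
  cat_df
}

#' Select the closest catalog LED for a predicted wavelength
#'
#' Chooses the catalog entry minimizing |nominal - target| nm, ties broken
#' toward the shorter wavelength. A mismatch above \code{tolerance_nm}
#' (default 200 nm) is flagged and warned about rather than hidden: an
#' exposure panel can genuinely lack LEDs near a predicted wavelength, and
#' that gap should be surfaced.
#'
#' @param target A \code{wavelength_prediction} or a wavelength in nm.
#' @param catalog data.frame from [led_catalog()].
#' @param tolerance_nm Mismatch above which the selection is flagged.
#' @return Object of class \code{exposure_panel}: \code{target_nm},
#'   \code{chosen} (one catalog row), \code{mismatch_nm},
#'   \code{within_tolerance}.
#' @export
select_led <- function(target, catalog = led_catalog(), tolerance_nm = 200) {
  target_nm <- if (inherits(target, "wavelength_prediction"))
    target$lambda_nm else target
  stopifnot(is.numeric(target_nm), length(target_nm) == 1L, target_nm > 0)
  if (nrow(catalog) == 0L) stop("empty LED catalog")
  mismatch <- abs(catalog$nominal_wavelength_nm - target_nm)
  # order() on (mismatch, wavelength) breaks ties toward the shorter LED
  k <- order(mismatch, catalog$nominal_wavelength_nm)[1]
  ok <- mismatch[k] <= tolerance_nm
  if (!ok)
    warning(sprintf("closest LED (%g nm) misses target %.0f nm by %.0f nm (> %g nm tolerance)",
                    catalog$nominal_wavelength_nm[k], target_nm, mismatch[k],
                    tolerance_nm))
  structure(list(target_nm = target_nm,
                 chosen = catalog[k, , drop = FALSE],
                 mismatch_nm = mismatch[k],
                 within_tolerance = ok),
            class = "exposure_panel")
}

#' Photometric conversion factor K(lambda)
#'
#' Ratio of luminous intensity I_v (lumen-weighted, i.e. as perceived) to
#' radiant intensity I_e (absolute power) at a given wavelength.
#'
#' @param i_v Luminous intensity.
#' @param i_e Radiant intensity, strictly positive.
#' @return List with \code{luminous_intensity}, \code{radiant_intensity},
#'   \code{k_factor} = i_v / i_e.
#' @export
photometric_k <- function(i_v, i_e) {
  if (!is.numeric(i_e) || i_e <= 0) stop("radiant intensity must be > 0")
  list(luminous_intensity = i_v, radiant_intensity = i_e,
       k_factor = i_v / i_e)
}

#' Optical energy delivered over an exposure
#'
#' Dose bookkeeping for run metadata: energy (uJ) = power (uW) x duration
#' (h) x 3600 s/h.
#'
#' @param power_uW Optical intensity, >= 0.
#' @param hours Exposure duration, >= 0.
#' @return Energy in microjoules.
#' @export
exposure_dose <- function(power_uW, hours) {
  if (any(power_uW < 0) || any(hours < 0)) stop("power and duration must be non-negative")
  power_uW * hours * 3600
}
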