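#' Expansion-microscopy calibration
#'
#' Bundles the per-gel expansion factor and the acquisition pixel geometry
#' used to convert between image pixels (expanded space) and biological
#' nanometres. The expansion factor is the measured expanded gel size divided
#' by the size of the seeding coverslip (12 mm by convention); all distances
#' reported by the measurement stages are expanded-space distances divided by
#' this factor.
#'
#' @param gel_size_mm Measured expanded gel size in mm.
#' @param coverslip_mm Seeding coverslip size in mm (default 12).
#' @param pixel_nm Lateral (x, y) pixel size in expanded-space nm (default 35).
#' @param z_step_nm Axial step in expanded-space nm (default 120).
#'
#' @return An object of class `expansion_calibration` with fields
#'   `gel_size_mm`, `coverslip_mm`, `x_factor`, `pixel_nm`, `z_step_nm`.
#'   `x_factor` keeps full precision; use [format()] or
#'   [expansion_factor()] with `digits` for reporting.
#' @examples
#' calib <- expansion_calibration(gel_size_mm = 53)
#' calib$x_factor            # 4.4166...
#' to_biological_nm(10, calib)
#' @export
expansion_calibration <- function(gel_size_mm, coverslip_mm = 12,
                                  pixel_nm = 35, z_step_nm = 120) {
  if (!is.numeric(gel_size_mm) || length(gel_size_mm) != 1L ||
      !is.finite(gel_size_mm) || gel_size_mm <= 0) {
    stop("invalid calibration: gel_size_mm must be a positive number")
  }
  if (!is.numeric(coverslip_mm) || coverslip_mm <= 0) {
    stop("invalid calibration: coverslip_mm must be positive")
  }
  if (pixel_nm <= 0) stop("invalid calibration: pixel_nm must be positive")
  if (z_step_nm <= 0) stop("invalid calibration: z_step_nm must be positive")
  structure(
    list(
      gel_size_mm = gel_size_mm,
      coverslip_mm = coverslip_mm,
      x_factor = gel_size_mm / coverslip_mm,
      pixel_nm = pixel_nm,
      z_step_nm = z_step_nm
    ),
    class = "expansion_calibration"
  )
}

#' @export
print.expansion_calibration <- function(x, ...) {
  cat(sprintf(
    "Expansion calibration: gel %.1f mm / coverslip %.1f mm -> X = %.2f\n",
    x$gel_size_mm, x$coverslip_mm, x$x_factor
  ))
  cat(sprintf("  pixel %.0f nm, z-step %.0f nm (expanded space)\n",
              x$pixel_nm, x$z_step_nm))
  invisible(x)
}

#' Gel expansion factor
#'
#' Ratio of the measured expanded gel size to the seeding coverslip size.
#' Internally full precision is kept; `digits` rounds half-up for reporting,
#' matching the 2-decimal convention of gel tables.
#'
#' @param gel_size_mm Expanded gel size in mm.
#' @param coverslip_mm Coverslip size in mm (default 12).
#' @param digits If non-`NULL`, round (half-up) the returned factor.
#' @return Dimensionless expansion factor.
#' @examples
#' expansion_factor(53, digits = 2)   # 4.42
#' @export
expansion_factor <- function(gel_size_mm, coverslip_mm = 12, digits = NULL) {
  if (any(!is.finite(gel_size_mm)) || any(gel_size_mm <= 0) ||
      any(!is.finite(coverslip_mm)) || any(coverslip_mm <= 0)) {
    stop("invalid calibration: sizes must be positive and finite")
  }
  x <- gel_size_mm / coverslip_mm
  if (!is.null(digits)) x <- round_half_up(x, digits)
  x
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert an expanded-space pixel distance to biological nanometres
#'
#' @param distance_px Distance in pixels (non-negative).
#' @param calib An [expansion_calibration()].
#' @return Distance in biological nm: `distance_px * pixel_nm / x_factor`.
#' @examples
#' to_biological_nm(10, expansion_calibration(12))  # 350
#' @export
to_biological_nm <- function(distance_px, calib) {
  stopifnot(inherits(calib, "expansion_calibration"))
  if (any(distance_px < 0)) stop("invalid input: negative distance")
  distance_px * calib$pixel_nm / calib$x_factor
}

#' Convert a biological-nm distance to expanded-space pixels
#'
#' Inverse of [to_biological_nm()].
#' @inheritParams to_biological_nm
#' @param distance_nm Distance in biological nm (non-negative).
#' @export
biological_to_px <- function(distance_nm, calib) {
  stopifnot(inherits(calib, "expansion_calibration"))
  if (any(distance_nm < 0)) stop("invalid input: negative distance")
  distance_nm * calib$x_factor / calib$pixel_nm
}
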