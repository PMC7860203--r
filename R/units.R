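# Unit conversions. Internals are SI (m, Pa, m^3/s); clinical units
# (mm, mmHg, mL/min) are accepted and emitted at user-facing interfaces.

#' Unit conversion helpers
#'
#' The package computes in SI units internally but reports in the clinical
#' units of the field: millimetres for diameters, mmHg for pressures and
#' mL/min for flows. Conversion constants: 1 mmHg = 133.322 Pa and
#' 1 mL/min = 1/60 x 1e-6 m^3/s.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' mmhg_to_pa(4.5)        # 599.949 Pa
#' pa_to_mmhg(133.322)    # 1 mmHg
#' mlmin_to_m3s(600)      # 1e-05 m^3/s
#' @name units
NULL

MMHG_PA <- 133.322
MLMIN_M3S <- 1e-6 / 60

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' @rdname units
#' @export
mlmin_to_m3s <- function(x) x * MLMIN_M3S

#' @rdname units
#' @export
m3s_to_mlmin <- function(x) x / MLMIN_M3S

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, positive = TRUE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stopf("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}
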