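#' Measured sinus diameters of the imaging cohort
#'
#' Per-patient hydraulic diameter of the superior sagittal sinus (SSS_Dh)
#' and effective diameters of the transverse (TS_De), proximal sigmoid
#' (PSS_De) and distal sigmoid (DSS_De) sinuses, in mm, for the five adult
#' CT-venogram geometries the model cohort is based on.
#'
#' @return a data frame with columns `patient`, `SSS_Dh`, `TS_De`, `PSS_De`,
#'   `DSS_De` (mm).
#' @examples
#' d <- sinus_diameters()
#' cohort_stats(d$SSS_Dh)$mean   # 5.49 mm cohort average
#' @export
sinus_diameters <- function() {
  data.frame(
    patient = 1:5,
    SSS_Dh = c(5.62, 5.29, 4.99, 5.41, 6.13),
    TS_De  = c(6.55, 4.79, 5.43, 7.81, 6.84),
    PSS_De = c(8.30, 7.84, 6.34, 8.11, 8.28),
    DSS_De = c(6.37, 8.64, 7.53, 12.24, 6.28)
  )
}

#' Average cross-sectional curl at the jugular bulb
#'
#' Average curl (1/s) measured on a cross-section 1.5 cm below the centre of
#' the sigmoid sinus outlet to the jugular bulb, for each of the five cohort
#' patients across the flow sweep. The superlinear growth of these values
#' with flow rate is what the synthetic curl generator emulates.
#'
#' @return a data frame with columns `flow` (mL/min) and `patient1` ...
#'   `patient5` (1/s).
#' @examples
#' jugular_curl()
#' @export
jugular_curl <- function() {
  data.frame(
    flow = c(400, 800, 1200, 1600, 2000),
    patient1 = c(26.41, 78.82, 159.18, 245.55, 337.99),
    patient2 = c(30.66, 82.35, 115.56, 152.81, 192.79),
    patient3 = c(24.07, 64.30, 106.04, 151.00, 204.05),
    patient4 = c(22.96, 54.58, 91.46, 128.62, 162.55),
    patient5 = c(38.08, 92.98, 154.13, 214.52, 269.55)
  )
}

#' Cohort mean and sample standard deviation
#'
#' Arithmetic mean and sample (n-1 denominator) standard deviation; the n-1
#' convention is the one that reproduces the cohort summary rows from the
#' per-patient diameters.
#'
#' @param values numeric vector, length >= 2.
#' @return list with `mean`, `sd` and `n`.
#' @export
cohort_stats <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stopf("cohort_stats needs at least 2 numeric values")
  if (anyNA(values)) stopf("cohort_stats: missing values not allowed")
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}
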