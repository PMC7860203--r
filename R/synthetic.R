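# Seeded synthetic-data generators. These stand in for the CFD stage:
# they produce patient geometries with the cohort's diameter statistics,
# cross-sectional velocity planes with a known analytic curl, and noisy
# pressure/curl series with the quadratic-in-flow and superlinear-curl
# structure the full simulations exhibit, so every downstream stage is
# testable offline with no imaging data.

#' Cohort specification for synthetic patient geometries
#'
#' Per-sinus diameter means/SDs default to the measured cohort statistics
#' ([sinus_diameters()]): SSS 5.49 +/- 0.43, TS 6.28 +/- 1.19, PSS 7.77 +/-
#' 0.82, DSS 8.21 +/- 2.45 mm. Segment length means/SDs default to SSS
#' 107.8 +/- 11.5 mm and StS 42.9 +/- 2.3 mm; the remaining lengths (TS 50,
#' PSS 40, DSS 40, IJV 30 mm) and the StS/IJV diameters (5.0 +/- 0.5, 8.0
#' +/- 1.0 mm) have no measured cohort values and are fixed plausible
#' defaults (SD 0 for the lengths).
#'
#' @param diameter_mean,diameter_sd named numeric vectors (names SSS, StS,
#'   TS, PSS, DSS, IJV), mm.
#' @param length_mean,length_sd named numeric vectors (same names), mm.
#' @param n_patients number of patients to generate.
#' @param min_diameter truncation lower bound for diameters, mm.
#' @param seed integer seed fixing all downstream randomness.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    diameter_mean = c(SSS = 5.49, StS = 5.0, TS = 6.28, PSS = 7.77,
                      DSS = 8.21, IJV = 8.0),
    diameter_sd = c(SSS = 0.43, StS = 0.5, TS = 1.19, PSS = 0.82,
                    DSS = 2.45, IJV = 1.0),
    length_mean = c(SSS = 107.8, StS = 42.9, TS = 50, PSS = 40,
                    DSS = 40, IJV = 30),
    length_sd = c(SSS = 11.5, StS = 2.3, TS = 0, PSS = 0, DSS = 0, IJV = 0),
    n_patients = 5L, min_diameter = 1, seed = 1L) {
  nm <- c("SSS", "StS", "TS", "PSS", "DSS", "IJV")
  for (v in list(diameter_mean, diameter_sd, length_mean, length_sd))
    if (!all(nm %in% names(v))) stopf("cohort_spec vectors need names %s",
                                      paste(nm, collapse = ", "))
  if (any(diameter_mean <= 0) || any(length_mean <= 0)) stopf("means must be > 0")
  if (any(diameter_sd < 0) || any(length_sd < 0)) stopf("SDs must be >= 0")
  structure(list(diameter_mean = diameter_mean[nm], diameter_sd = diameter_sd[nm],
                 length_mean = length_mean[nm], length_sd = length_sd[nm],
                 n_patients = as.integer(n_patients),
                 min_diameter = min_diameter, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Truncated-normal draw (rejection; lower bound only). Prevents unphysical
# non-positive lumens when cohort SDs are large relative to the mean.
rtnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n); k <- 0L
  while (k < n) {
    x <- stats::rnorm(n - k, mean, sd)
    x <- x[x > lower]
    if (length(x)) { out[(k + 1L):(k + length(x))] <- x; k <- k + length(x) }
  }
  out
}

#' Generate one synthetic patient tree
#'
#' Draws per-segment diameters and lengths from truncated normal
#' distributions with the cohort statistics of `spec` (left and right
#' branch segments are drawn independently: anatomy is asymmetric).
#' Deterministic given `(spec$seed, patient_index)`.
#'
#' @param spec a [cohort_spec()].
#' @param patient_index 1-based patient number.
#' @return a [venous_tree()] with the default bend descriptors of
#'   [average_tree()].
#' @export
generate_tree <- function(spec, patient_index = 1L) {
  if (!inherits(spec, "cohort_spec")) stopf("'spec' must be a cohort_spec")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed * 10000L + as.integer(patient_index))
  draw_d <- function(sinus) rtnorm_lower(1L, spec$diameter_mean[[sinus]],
                                         spec$diameter_sd[[sinus]],
                                         spec$min_diameter)
  draw_l <- function(sinus) rtnorm_lower(1L, spec$length_mean[[sinus]],
                                         spec$length_sd[[sinus]], 1)
  template <- average_tree()$segments   # bend descriptors reused
  segs <- lapply(TREE_SEGMENTS, function(nm) {
    sinus <- sub("-[LR]$", "", nm)
    seg <- template[[nm]]
    vessel_segment(nm, draw_l(sinus), draw_d(sinus),
                   bends = seg$bends, extra_K = seg$extra_K)
  })
  venous_tree(segs)
}

#' Generate a cross-sectional velocity plane with known curl
#'
#' A circular lumen carrying a solid-body in-plane swirl: rim tangential
#' speed equals `swirl` times the mean axial velocity `V = Q / (pi R^2)`,
#' so the analytic curl is `2 * swirl * V / R` everywhere on the section —
#' a closed form against which the finite-difference pipeline is tested.
#'
#' @param Q through-plane flow, mL/min (> 0).
#' @param radius lumen radius, mm (> 0).
#' @param swirl ratio of rim tangential speed to mean axial speed (>= 0).
#' @param grid_n grid points per side (odd values centre the axis).
#' @return a [velocity_plane()] with attribute `analytic_curl` (1/s).
#' @export
generate_velocity_plane <- function(Q, radius, swirl, grid_n = 101L) {
  check_scalar(Q, "Q")
  check_scalar(radius, "radius")
  check_scalar(swirl, "swirl", positive = FALSE, nonneg = TRUE)
  R <- mm_to_m(radius)
  V <- mlmin_to_m3s(Q) / (pi * R^2)
  omega <- swirl * V / R
  xs <- seq(-R, R, length.out = grid_n)
  X <- matrix(xs, grid_n, grid_n, byrow = TRUE)   # columns = x
  Y <- matrix(xs, grid_n, grid_n)                 # rows = y
  mask <- X^2 + Y^2 <= R^2
  plane <- velocity_plane(u = -omega * Y, v = omega * X,
                          spacing = xs[2L] - xs[1L], mask = mask,
                          meta = list(Q_mlmin = Q, radius_mm = radius,
                                      swirl = swirl))
  attr(plane, "analytic_curl") <- 2 * omega
  plane
}

#' Surrogate specification for CFD-like pressure and curl series
#'
#' Ground-truth loss coefficients, curl-growth law and noise levels for
#' [generate_surrogate()]. Defaults: `a = 0.003` mmHg/(mL/min) and
#' `b = 1.5e-6` mmHg/(mL/min)^2, which cross the 8.3 mmHg IIH-inducing
#' drop near 1550 mL/min (the observed "approximately 1500" crossing of
#' the cohort-average curve); curl scale `c_curl = 0.006` with exponent
#' `gamma = 1.4`, the midpoint of the 1.2-1.6 range that brackets the
#' measured per-patient curl growth over the 5x flow increase; 2%
#' multiplicative pressure noise and 5% curl noise, the relative-error
#' character of a converged CFD solution.
#'
#' @param a,b true loss coefficients, mmHg/(mL/min) and mmHg/(mL/min)^2.
#' @param c_curl curl scale at Q = 1 mL/min, 1/s.
#' @param gamma curl-flow exponent (> 0; 1.2-1.6 plausible).
#' @param sigma_p,sigma_c multiplicative noise SDs for drops and curls.
#' @param flows flow grid, mL/min.
#' @param n_patients patients per realisation.
#' @param seed integer seed.
#' @return an object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(a = 0.003, b = 1.5e-6, c_curl = 0.006,
                           gamma = 1.4, sigma_p = 0.02, sigma_c = 0.05,
                           flows = default_flow_grid(), n_patients = 1L,
                           seed = 1L) {
  check_scalar(a, "a", positive = FALSE, nonneg = TRUE)
  check_scalar(b, "b", positive = FALSE, nonneg = TRUE)
  check_scalar(c_curl, "c_curl", positive = FALSE, nonneg = TRUE)
  check_scalar(gamma, "gamma")
  check_scalar(sigma_p, "sigma_p", positive = FALSE, nonneg = TRUE)
  check_scalar(sigma_c, "sigma_c", positive = FALSE, nonneg = TRUE)
  if (!length(flows) || any(flows <= 0)) stopf("flows must be positive")
  structure(list(a = a, b = b, c_curl = c_curl, gamma = gamma,
                 sigma_p = sigma_p, sigma_c = sigma_c, flows = flows,
                 n_patients = as.integer(n_patients), seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' Generate surrogate pressure-flow and curl data
#'
#' For each patient: drops `(aQ + bQ^2) * (1 + eps_p)` and curls
#' `c_curl * Q^gamma * (1 + eps_c)` over the flow grid, with independent
#' Gaussian multiplicative noise. `dP(0) = 0` holds by construction (no
#' intercept noise). Bit-reproducible given the seed.
#'
#' @param spec a [surrogate_spec()].
#' @return a list of patients, each a list with `curve` (a
#'   [pressure_flow_curve()]) and `curl` (numeric vector, 1/s, paired with
#'   `curve$flow`).
#' @export
generate_surrogate <- function(spec = surrogate_spec()) {
  if (!inherits(spec, "surrogate_spec")) stopf("'spec' must be a surrogate_spec")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  Q <- spec$flows
  lapply(seq_len(spec$n_patients), function(i) {
    eps_p <- stats::rnorm(length(Q), 0, spec$sigma_p)
    eps_c <- stats::rnorm(length(Q), 0, spec$sigma_c)
    drops <- (spec$a * Q + spec$b * Q^2) * (1 + eps_p)
    curls <- spec$c_curl * Q^spec$gamma * (1 + eps_c)
    list(curve = pressure_flow_curve(Q, drops, patient_id = sprintf("synth-%d", i)),
         curl = curls)
  })
}

#' Synthetic cohort blood-flow list
#'
#' A deterministic synthetic stand-in for a clinical cohort flow list with
#' a prescribed number of patients above a flow threshold: `n - n_high`
#' flows uniform in (0.4, 0.93) x threshold and `n_high` uniform in
#' (1.03, 1.5) x threshold, shuffled. Used to exercise
#' [proportion_above()]; defaults mirror a 42-patient cohort with 13
#' hyperemic flows above 1500 mL/min.
#'
#' @param n cohort size.
#' @param n_high number of flows strictly above `threshold`.
#' @param threshold flow threshold, mL/min.
#' @param seed integer seed.
#' @return numeric vector of `n` flows, mL/min.
#' @export
generate_cohort_flows <- function(n = 42L, n_high = 13L, threshold = 1500,
                                  seed = 1L) {
  if (n_high > n) stopf("n_high cannot exceed n")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  low <- stats::runif(n - n_high, 0.40 * threshold, 0.93 * threshold)
  high <- stats::runif(n_high, 1.03 * threshold, 1.50 * threshold)
  sample(c(low, high))
}
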