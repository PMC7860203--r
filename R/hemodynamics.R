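# Segment-level pressure-loss physics. All functions here are SI
# (m, Pa, m^3/s); unit conversion happens at the tree/sweep interfaces.

RE_LAMINAR_MAX <- 2300

#' Reynolds number of pipe flow
#'
#' `Re = rho * V * D / mu` with the mean velocity `V = Q / (pi D^2 / 4)`,
#' equivalently `Re = 4 rho Q / (pi mu D)`.
#'
#' @param Q volumetric flow, m^3/s (>= 0).
#' @param D internal diameter, m (> 0).
#' @param fluid a [fluid_properties()].
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(Q, D, fluid = fluid_properties()) {
  check_scalar(Q, "Q", positive = FALSE, nonneg = TRUE)
  check_scalar(D, "D")
  4 * fluid$density * Q / (pi * fluid$viscosity * D)
}

#' Poiseuille resistance of a straight segment
#'
#' The constant (flow-independent) laminar resistance `128 mu L / (pi D^4)`
#' of fully developed flow in a straight circular vessel — the building
#' block of the constant-resistance linear venous model.
#'
#' @param L segment length, m (>= 0).
#' @param D internal diameter, m (> 0).
#' @param viscosity dynamic viscosity, Pa.s (> 0).
#' @return resistance in Pa.s/m^3.
#' @export
poiseuille_resistance <- function(L, D, viscosity = 0.0035) {
  check_scalar(L, "L", positive = FALSE, nonneg = TRUE)
  check_scalar(D, "D")
  check_scalar(viscosity, "viscosity")
  128 * viscosity * L / (pi * D^4)
}

#' Darcy-Weisbach friction pressure drop
#'
#' `dP = f * (L/D) * rho V^2 / 2` with the friction factor `f = 64/Re` in
#' the laminar regime (Re <= 2300), where the drop reduces algebraically to
#' the Poiseuille form `32 mu L V / D^2`, and the Blasius smooth-pipe
#' correlation `f = 0.316 Re^-0.25` above. The factor is discontinuous at
#' the regime switch; continuity is not enforced.
#'
#' @param Q volumetric flow, m^3/s (>= 0).
#' @param L segment length, m.
#' @param D internal diameter, m.
#' @param fluid a [fluid_properties()].
#' @return pressure drop, Pa.
#' @export
friction_drop <- function(Q, L, D, fluid = fluid_properties()) {
  check_scalar(Q, "Q", positive = FALSE, nonneg = TRUE)
  check_scalar(L, "L", positive = FALSE, nonneg = TRUE)
  check_scalar(D, "D")
  if (Q == 0 || L == 0) return(0)
  A <- pi * D^2 / 4
  V <- Q / A
  Re <- fluid$density * V * D / fluid$viscosity
  if (Re <= RE_LAMINAR_MAX) {
    32 * fluid$viscosity * L * V / D^2        # == (64/Re) (L/D) rho V^2/2
  } else {
    f <- 0.316 * Re^(-0.25)
    f * (L / D) * fluid$density * V^2 / 2
  }
}

#' Bend loss coefficient
#'
#' Dimensionless minor-loss coefficient of a circular-arc vessel bend,
#' `K = (0.131 + 0.159 * (r/D)^-3.5) * (angle / 90)`: the classical
#' smooth-bend correlation in bend angle and radius-to-diameter ratio.
#' Tight bends (small radius ratio) are strongly penalised, which is what
#' makes the sigmoid-jugular curvature the dominant loss site.
#'
#' @param angle bend angle in degrees, in (0, 180].
#' @param radius_ratio bend radius divided by vessel diameter (> 0).
#' @return dimensionless loss coefficient K.
#' @examples
#' bend_loss_coefficient(90, 1)   # 0.290
#' @export
bend_loss_coefficient <- function(angle, radius_ratio) {
  check_scalar(angle, "angle")
  if (angle > 180) stopf("bend angle must be in (0, 180] degrees (got %g)", angle)
  check_scalar(radius_ratio, "radius_ratio")
  (0.131 + 0.159 * radius_ratio^(-3.5)) * (angle / 90)
}

#' Minor (bend/fitting) pressure drop
#'
#' `dP = K * rho * V^2 / 2` — the localized loss at a bend or junction,
#' quadratic in velocity and hence in flow.
#'
#' @param K dimensionless loss coefficient (>= 0).
#' @param V mean velocity, m/s.
#' @param density fluid density, kg/m^3.
#' @return pressure drop, Pa.
#' @export
minor_loss_drop <- function(K, V, density = 1055) {
  check_scalar(K, "K", positive = FALSE, nonneg = TRUE)
  check_scalar(V, "V", positive = FALSE, nonneg = TRUE)
  check_scalar(density, "density")
  K * density * V^2 / 2
}

#' Total pressure drop across one vessel segment
#'
#' Friction drop plus all minor losses (bends and extra K values, scaled by
#' the segment's calibration factor `k_scale`). In the laminar regime this
#' is exactly `a_seg * Q + b_seg * Q^2` with the coefficients returned by
#' [segment_loss_model()].
#'
#' @param seg a [vessel_segment()].
#' @param Q volumetric flow, m^3/s (>= 0).
#' @param fluid a [fluid_properties()].
#' @return pressure drop, Pa.
#' @export
segment_drop <- function(seg, Q, fluid = fluid_properties()) {
  check_scalar(Q, "Q", positive = FALSE, nonneg = TRUE)
  D <- seg$diameter
  A <- pi * D^2 / 4
  V <- Q / A
  drop <- friction_drop(Q, seg$length, D, fluid)
  K <- segment_total_K(seg)
  if (K > 0) drop <- drop + minor_loss_drop(K, V, fluid$density)
  drop
}

segment_total_K <- function(seg) {
  K <- 0
  for (b in seg$bends) K <- K + bend_loss_coefficient(b$angle, b$radius_ratio)
  K <- K + sum(seg$extra_K)
  K * seg$k_scale
}

#' Linear and quadratic loss coefficients of a segment
#'
#' In the laminar regime the segment drop is exactly
#' `dP(Q) = a_seg Q + b_seg Q^2` with `a_seg` the Poiseuille resistance and
#' `b_seg = 8 rho K_total / (pi^2 D^4)` from the minor losses.
#'
#' @inheritParams segment_drop
#' @return named vector `c(a, b)` in Pa.s/m^3 and Pa.s^2/m^6.
#' @export
segment_loss_model <- function(seg, fluid = fluid_properties()) {
  a <- poiseuille_resistance(seg$length, seg$diameter, fluid$viscosity)
  K <- segment_total_K(seg)
  b <- 8 * fluid$density * K / (pi^2 * seg$diameter^4)
  c(a = a, b = b)
}
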