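# Intracranial-pressure coupling: Davson's equation relates ICP to the CSF
# formation rate, outflow resistance and superior sagittal sinus pressure;
# the venous Ohm analog relates sinus pressure to total cerebral blood flow,
# venous outflow resistance and central venous pressure. A flow-dependent
# resistance R_ven(Q) = a + bQ (from a quadratic pressure-flow fit) makes
# ICP convex in flow, which is what lets hyperemia induce IIH.

#' Intracranial pressure from Davson's equation
#'
#' `ICP = FR_csf * R_out + SSS_p`: CSF formation rate times CSF outflow
#' resistance plus superior sagittal sinus pressure.
#'
#' @param fr_csf CSF formation rate, mL/min (>= 0).
#' @param r_out CSF outflow resistance, mmHg.min/mL (>= 0). Neither this
#'   nor `fr_csf` has a cohort-measured default; values are user-supplied.
#' @param sss_p superior sagittal sinus pressure, mmHg (>= 0).
#' @return ICP, mmHg.
#' @examples
#' davson_icp(0.35, 10, 11.1)   # 14.6 mmHg
#' @export
davson_icp <- function(fr_csf, r_out, sss_p) {
  check_scalar(fr_csf, "fr_csf", positive = FALSE, nonneg = TRUE)
  check_scalar(r_out, "r_out", positive = FALSE, nonneg = TRUE)
  check_scalar(sss_p, "sss_p", positive = FALSE, nonneg = TRUE)
  fr_csf * r_out + sss_p
}

#' Superior sagittal sinus pressure from the venous Ohm analog
#'
#' `SSS_p = TCBF * R_ven + CVP`. The venous outflow resistance is either a
#' constant (`r_ven`, the classical linear model) or flow-dependent through
#' a quadratic fit (`fit`), in which case `R_ven(Q) = a + bQ` and the drop
#' term is the fitted `a*Q + b*Q^2`.
#'
#' @param tcbf total cerebral blood flow, mL/min (>= 0).
#' @param r_ven constant venous outflow resistance, mmHg.min/mL; ignored
#'   when `fit` is given.
#' @param cvp central venous pressure, mmHg (>= 0).
#' @param fit optional [pq_fit()] providing the flow-dependent resistance.
#' @return sinus pressure, mmHg.
#' @export
sss_pressure <- function(tcbf, r_ven = NULL, cvp = 0, fit = NULL) {
  check_scalar(tcbf, "tcbf", positive = FALSE, nonneg = TRUE)
  check_scalar(cvp, "cvp", positive = FALSE, nonneg = TRUE)
  if (!is.null(fit)) {
    if (!inherits(fit, "pq_fit")) stopf("'fit' must be a pq_fit")
    return(predict(fit, tcbf) + cvp)
  }
  if (is.null(r_ven)) stopf("supply either 'r_ven' or 'fit'")
  check_scalar(r_ven, "r_ven", positive = FALSE, nonneg = TRUE)
  tcbf * r_ven + cvp
}

#' IIH induction criteria
#'
#' The paediatric scenario constants: baseline ICP 14.6 mmHg, required ICP
#' increase 3.8 mmHg, baseline venous drop 4.5 mmHg, and the diagnostic ICP
#' definition of 18.34 mmHg. Note baseline + delta = 18.4 mmHg while the
#' diagnostic definition is 18.34 mmHg; both constants are carried as
#' given, without reconciling the 0.06 mmHg difference.
#'
#' @param baseline_icp baseline average ICP, mmHg.
#' @param required_delta ICP increase needed for IIH, mmHg.
#' @param baseline_drop baseline venous system drop, mmHg.
#' @param diagnostic_icp diagnostic ICP threshold, mmHg.
#' @return an object of class `iih_criteria`.
#' @export
iih_criteria <- function(baseline_icp = 14.6, required_delta = 3.8,
                         baseline_drop = 4.5, diagnostic_icp = 18.34) {
  for (v in c(baseline_icp = baseline_icp, required_delta = required_delta,
              baseline_drop = baseline_drop, diagnostic_icp = diagnostic_icp))
    check_scalar(v, "criteria value")
  structure(list(baseline_icp = baseline_icp, required_delta = required_delta,
                 baseline_drop = baseline_drop, diagnostic_icp = diagnostic_icp),
            class = "iih_criteria")
}

#' Venous pressure drop required to induce IIH
#'
#' `baseline_drop + required_delta`: since an ICP increase maps one-to-one
#' onto a venous drop increase (Davson + Ohm analog with fixed CSF terms
#' and CVP), IIH induction by hyperemia alone requires the venous drop to
#' rise from its 4.5 mmHg baseline to 8.3 mmHg.
#'
#' @param criteria an [iih_criteria()].
#' @return required venous drop, mmHg.
#' @examples
#' required_venous_drop()   # 8.3
#' @export
required_venous_drop <- function(criteria = iih_criteria()) {
  criteria$baseline_drop + criteria$required_delta
}

#' Proportion of a cohort above a flow threshold
#'
#' Strict-inequality count of cohort flows above a threshold, with the
#' percentage rounded to the nearest integer.
#'
#' @param flows cohort blood flows, mL/min (non-empty).
#' @param threshold flow threshold, mL/min (> 0); default 1500, the
#'   approximate flow at which the average quadratic curve crosses the
#'   IIH-inducing drop.
#' @return list with `count`, `total` and `percent` (integer).
#' @export
proportion_above <- function(flows, threshold = 1500) {
  if (!is.numeric(flows) || !length(flows)) stopf("'flows' must be non-empty numeric")
  check_scalar(threshold, "threshold")
  count <- sum(flows > threshold)
  list(count = count, total = length(flows),
       percent = as.integer(round(100 * count / length(flows))))
}

#' ICP as a function of total cerebral blood flow
#'
#' Composes the Ohm analog and Davson's equation:
#' `ICP(Q) = FR_csf * R_out + dP(Q) + CVP`, with `dP(Q)` either the fitted
#' quadratic venous drop or `r_ven * Q`. Monotone non-decreasing in flow;
#' strictly convex for the quadratic model.
#'
#' @inheritParams sss_pressure
#' @param fr_csf,r_out Davson parameters (see [davson_icp()]).
#' @return ICP, mmHg.
#' @export
icp_from_flow <- function(tcbf, fit = NULL, r_ven = NULL, cvp = 0,
                          fr_csf = 0, r_out = 0) {
  davson_icp(fr_csf, r_out, sss_pressure(tcbf, r_ven = r_ven, cvp = cvp, fit = fit))
}

#' Flow at which ICP reaches the IIH level
#'
#' Solves `ICP(Q) = baseline_icp + required_delta` by root finding, for the
#' full Davson + Ohm composition with a flow-dependent resistance. The CSF
#' and central-venous terms are partitioned so that ICP equals the baseline
#' ICP when the venous drop equals its baseline: `fr_csf * r_out + cvp =
#' baseline_icp - baseline_drop` (the default splits this entirely into
#' `cvp`; supplying `fr_csf` and `r_out` reapportions it). The result
#' agrees with `threshold_flow(fit, required_venous_drop(criteria))` — the
#' same threshold reached through the pressure-flow curve alone.
#'
#' @param fit a [pq_fit()].
#' @param criteria an [iih_criteria()].
#' @param fr_csf,r_out Davson parameters (user-supplied; no cohort values
#'   exist for them).
#' @return threshold flow, mL/min (possibly `Inf`).
#' @export
icp_threshold_flow <- function(fit, criteria = iih_criteria(),
                               fr_csf = 0, r_out = 0) {
  if (!inherits(fit, "pq_fit")) stopf("'fit' must be a pq_fit")
  cvp <- criteria$baseline_icp - criteria$baseline_drop - fr_csf * r_out
  if (cvp < 0)
    stopf("fr_csf * r_out exceeds baseline_icp - baseline_drop; no non-negative CVP completes the baseline")
  target <- criteria$baseline_icp + criteria$required_delta
  g <- function(q) icp_from_flow(q, fit = fit, cvp = cvp,
                                 fr_csf = fr_csf, r_out = r_out) - target
  hi <- 1
  while (g(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e9) return(Inf)
  }
  stats::uniroot(g, lower = 0, upper = hi, tol = 1e-10)$root
}
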