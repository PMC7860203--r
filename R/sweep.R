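#' Pressure-flow curve
#'
#' Paired flow rates (mL/min) and system pressure drops (mmHg) from a flow
#' sweep of one patient geometry. Flows must be strictly increasing.
#'
#' @param flow numeric vector of flow rates, mL/min, strictly increasing.
#' @param drop numeric vector of system pressure drops, mmHg, same length.
#' @param patient_id optional label.
#' @return a data frame of class `pressure_flow_curve` with columns `flow`
#'   and `drop`.
#' @export
pressure_flow_curve <- function(flow, drop, patient_id = NA_character_) {
  if (length(flow) != length(drop)) stopf("flow and drop lengths differ")
  if (any(!is.finite(flow)) || any(!is.finite(drop))) stopf("non-finite curve values")
  if (any(flow <= 0)) stopf("flows must be positive")
  if (is.unsorted(flow, strictly = TRUE)) stopf("flows must be strictly increasing")
  structure(data.frame(flow = flow, drop = drop),
            patient_id = patient_id,
            class = c("pressure_flow_curve", "data.frame"))
}

#' Default flow sweep grid
#'
#' 200 to 2000 mL/min in steps of 200 — the ten flows spanning very low
#' physiological rates to the hyperemic range.
#' @return numeric vector of length 10, mL/min.
#' @export
default_flow_grid <- function() seq(200, 2000, by = 200)

#' Sweep the venous tree over a range of flows
#'
#' Solves the network once per flow rate and collects the system pressure
#' drops into a [pressure_flow_curve()].
#'
#' @param tree a [venous_tree()].
#' @param flows flow grid, mL/min; default [default_flow_grid()].
#' @inheritParams solve_tree
#' @param patient_id optional label carried on the curve.
#' @return a `pressure_flow_curve`.
#' @export
flow_sweep <- function(tree, flows = default_flow_grid(),
                       straight_fraction = 0.30, fluid = fluid_properties(),
                       patient_id = NA_character_) {
  if (!length(flows)) stopf("empty flow grid")
  drops <- vapply(flows, function(q)
    solve_tree(tree, q, straight_fraction, fluid)$drop, 0)
  pressure_flow_curve(flows, drops, patient_id)
}

#' Read and write pressure-flow curves as CSV
#'
#' Columns `flow_mL_min` and `drop_mmHg`.
#'
#' @param curve a [pressure_flow_curve()].
#' @param path file path.
#' @return `read_curve_csv()` returns a `pressure_flow_curve`;
#'   `write_curve_csv()` returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(flow_mL_min = curve$flow, drop_mmHg = curve$drop),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("flow_mL_min", "drop_mmHg") %in% names(d)))
    stopf("curve CSV must have columns flow_mL_min, drop_mmHg")
  pressure_flow_curve(d$flow_mL_min, d$drop_mmHg)
}
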