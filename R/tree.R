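# The venous tree: superior sagittal (SSS) and straight (StS) sinuses meet
# at the torcula; the combined flow splits into left and right branches,
# each a series chain transverse (TS) -> proximal sigmoid (PSS) -> distal
# sigmoid (DSS) -> internal jugular vein (IJV) to a zero-gauge outlet.

TREE_SEGMENTS <- c("SSS", "StS",
                   "TS-L", "PSS-L", "DSS-L", "IJV-L",
                   "TS-R", "PSS-R", "DSS-R", "IJV-R")
BRANCH_L <- c("TS-L", "PSS-L", "DSS-L", "IJV-L")
BRANCH_R <- c("TS-R", "PSS-R", "DSS-R", "IJV-R")

#' Vessel segment
#'
#' One sinus segment of the venous tree, with its representative internal
#' diameter (the effective diameter at mid-segment), length, bend
#' descriptors and any extra minor-loss coefficients.
#'
#' @param name segment label, one of SSS, StS, TS-L/R, PSS-L/R, DSS-L/R,
#'   IJV-L/R (other labels are allowed for standalone use).
#' @param length segment length (> 0), mm by default.
#' @param diameter internal diameter (> 0), mm by default.
#' @param bends list of bends, each a list/vector with `angle` (degrees, in
#'   (0, 180]) and `radius_ratio` (bend radius / diameter, > 0).
#' @param extra_K numeric vector of additional dimensionless loss
#'   coefficients (junction, expansion, ...).
#' @param units `"mm"` (default) or `"m"` for `length` and `diameter`.
#' @return an object of class `vessel_segment` storing SI units internally.
#' @examples
#' vessel_segment("SSS", length = 107.8, diameter = 5.49,
#'                bends = list(list(angle = 30, radius_ratio = 8)))
#' @export
vessel_segment <- function(name, length, diameter, bends = list(),
                           extra_K = numeric(), units = c("mm", "m")) {
  units <- match.arg(units)
  check_scalar(length, "length")
  check_scalar(diameter, "diameter")
  if (units == "mm") {
    length <- mm_to_m(length)
    diameter <- mm_to_m(diameter)
  }
  bends <- lapply(bends, function(b) {
    b <- as.list(b)
    if (is.null(b$angle) || is.null(b$radius_ratio))
      stopf("each bend needs 'angle' and 'radius_ratio'")
    check_scalar(b$angle, "bend angle")
    if (b$angle > 180) stopf("bend angle must be in (0, 180]")
    check_scalar(b$radius_ratio, "radius_ratio")
    list(angle = b$angle, radius_ratio = b$radius_ratio)
  })
  if (length(extra_K) && any(extra_K < 0)) stopf("extra_K must be >= 0")
  structure(list(name = name, length = length, diameter = diameter,
                 bends = bends, extra_K = as.numeric(extra_K), k_scale = 1),
            class = "vessel_segment")
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<%s> L = %.1f mm, D = %.2f mm, %d bend(s), K_total = %.3f\n",
              x$name, m_to_mm(x$length), m_to_mm(x$diameter),
              length(x$bends), segment_total_K(x)))
  invisible(x)
}

#' Cerebral venous tree
#'
#' The two-inlet (SSS, StS) / two-outlet (IJV-L, IJV-R) network of sinus
#' segments. The topology is fixed by anatomy: both inlets drain to the
#' torcula, which feeds the left and right transverse-sigmoid-jugular
#' chains in parallel.
#'
#' @param segments list of [vessel_segment()]s covering exactly the ten
#'   labels SSS, StS, TS-L, PSS-L, DSS-L, IJV-L, TS-R, PSS-R, DSS-R, IJV-R.
#' @return an object of class `venous_tree`.
#' @seealso [average_tree()], [solve_tree()], [calibrate_tree()]
#' @export
venous_tree <- function(segments) {
  nm <- vapply(segments, function(s) s$name, "")
  missing <- setdiff(TREE_SEGMENTS, nm)
  if (length(missing))
    stopf("venous_tree: missing segment(s): %s", paste(missing, collapse = ", "))
  extra <- setdiff(nm, TREE_SEGMENTS)
  if (length(extra))
    stopf("venous_tree: unknown segment(s): %s", paste(extra, collapse = ", "))
  names(segments) <- nm
  structure(list(segments = segments[TREE_SEGMENTS]), class = "venous_tree")
}

#' @export
print.venous_tree <- function(x, ...) {
  cat("Cerebral venous tree (SSS + StS -> torcula -> L/R -> IJV outlets)\n")
  for (s in x$segments) print(s)
  invisible(x)
}

#' Population-average venous tree
#'
#' A tree built from the cohort-average diameters of [sinus_diameters()]
#' (SSS 5.49, TS 6.28, PSS 7.77, DSS 8.21 mm) and average segment lengths
#' (SSS 107.8 mm, StS 42.9 mm; transverse 50, sigmoid halves 40 each,
#' jugular extension 30 mm). The straight sinus and jugular diameters are
#' not part of the measured cohort table and default to 5.0 and 8.0 mm.
#' Default bend descriptors place gentle curvature on the sagittal and
#' transverse sinuses and tight curvature at the sigmoid-jugular junction,
#' where vortical losses dominate; their absolute scale is set by
#' [calibrate_tree()], not trusted as-is.
#'
#' @param sts_diameter straight sinus diameter, mm.
#' @param ijv_diameter internal jugular vein diameter, mm.
#' @return a `venous_tree`.
#' @export
average_tree <- function(sts_diameter = 5.0, ijv_diameter = 8.0) {
  d <- sinus_diameters()
  mean_d <- vapply(d[-1L], mean, 0)
  side <- function(suffix) list(
    vessel_segment(paste0("TS-", suffix), 50, mean_d[["TS_De"]],
                   bends = list(list(angle = 60, radius_ratio = 4))),
    vessel_segment(paste0("PSS-", suffix), 40, mean_d[["PSS_De"]],
                   bends = list(list(angle = 90, radius_ratio = 1.5))),
    vessel_segment(paste0("DSS-", suffix), 40, mean_d[["DSS_De"]],
                   bends = list(list(angle = 90, radius_ratio = 1))),
    vessel_segment(paste0("IJV-", suffix), 30, ijv_diameter,
                   bends = list(list(angle = 90, radius_ratio = 1)),
                   extra_K = 0.5)   # jugular bulb expansion/contraction
  )
  venous_tree(c(
    list(vessel_segment("SSS", 107.8, mean_d[["SSS_Dh"]],
                        bends = list(list(angle = 45, radius_ratio = 10))),
         vessel_segment("StS", 42.9, sts_diameter,
                        bends = list(list(angle = 45, radius_ratio = 6)))),
    side("L"), side("R")))
}

branch_drop <- function(tree, names, Q, fluid) {
  sum(vapply(names, function(nm) segment_drop(tree$segments[[nm]], Q, fluid), 0))
}

#' Solve the venous tree for a given total inflow
#'
#' Distributes the total cerebral blood flow over the two inlets
#' (`Q_SSS = Q_total / (1 + straight_fraction)`, `Q_StS = straight_fraction
#' * Q_SSS`), finds the left/right split at the torcula by bisection so that
#' the two parallel torcula-to-outlet drops agree to relative tolerance
#' 1e-9, and reports per-segment flows and drops, node pressures (outlet
#' gauge pressure 0) and the system pressure drop from the SSS inlet to the
#' jugular outlets.
#'
#' @param tree a [venous_tree()].
#' @param Q_total total inflow (> 0), mL/min.
#' @param straight_fraction straight sinus flow as a fraction of the SSS
#'   flow, in \[0, 1); default 0.30.
#' @param fluid a [fluid_properties()].
#' @param max_iter bisection iteration cap.
#' @return an object of class `tree_solution`: a list with `segments` (data
#'   frame of flow mL/min, drop mmHg, Re per segment), `nodes` (named vector
#'   of node pressures, mmHg), `drop` (system drop, mmHg), `left_fraction`,
#'   `Q_total`.
#' @export
solve_tree <- function(tree, Q_total, straight_fraction = 0.30,
                       fluid = fluid_properties(), max_iter = 200L) {
  if (!inherits(tree, "venous_tree")) stopf("'tree' must be a venous_tree")
  check_scalar(Q_total, "Q_total")
  check_scalar(straight_fraction, "straight_fraction", positive = FALSE, nonneg = TRUE)
  if (straight_fraction >= 1) stopf("straight_fraction must be in [0, 1)")
  Q_si <- mlmin_to_m3s(Q_total)
  Q_sss <- Q_si / (1 + straight_fraction)
  Q_sts <- straight_fraction * Q_sss

  dL <- function(x) branch_drop(tree, BRANCH_L, x * Q_si, fluid)
  dR <- function(x) branch_drop(tree, BRANCH_R, (1 - x) * Q_si, fluid)
  lo <- 0; hi <- 1; x <- 0.5
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    x <- (lo + hi) / 2
    gl <- dL(x); gr <- dR(x)
    if (abs(gl - gr) <= 1e-9 * max(gl, gr, 1e-300)) { converged <- TRUE; break }
    if (gl < gr) lo <- x else hi <- x
  }
  if (!converged && abs(dL(x) - dR(x)) > 1e-6 * max(dL(x), dR(x), 1e-300))
    stopf("solve_tree: left/right split did not converge in %d bisections", max_iter)

  qmap <- c("SSS" = Q_sss, "StS" = Q_sts,
            stats::setNames(rep(x * Q_si, 4L), BRANCH_L),
            stats::setNames(rep((1 - x) * Q_si, 4L), BRANCH_R))
  drops <- vapply(TREE_SEGMENTS, function(nm)
    segment_drop(tree$segments[[nm]], qmap[[nm]], fluid), 0)
  res <- vapply(TREE_SEGMENTS, function(nm)
    reynolds(qmap[[nm]], tree$segments[[nm]]$diameter, fluid), 0)

  branch_pa <- (dL(x) + dR(x)) / 2     # equal within tolerance
  p_torcula <- branch_pa
  nodes_pa <- c(
    inlet_SSS = p_torcula + drops[["SSS"]],
    inlet_StS = p_torcula + drops[["StS"]],
    torcula = p_torcula,
    "TS-PSS-L" = p_torcula - drops[["TS-L"]],
    "PSS-DSS-L" = p_torcula - drops[["TS-L"]] - drops[["PSS-L"]],
    "DSS-IJV-L" = p_torcula - drops[["TS-L"]] - drops[["PSS-L"]] - drops[["DSS-L"]],
    "outlet-L" = 0,
    "TS-PSS-R" = p_torcula - drops[["TS-R"]],
    "PSS-DSS-R" = p_torcula - drops[["TS-R"]] - drops[["PSS-R"]],
    "DSS-IJV-R" = p_torcula - drops[["TS-R"]] - drops[["PSS-R"]] - drops[["DSS-R"]],
    "outlet-R" = 0)

  structure(list(
    segments = data.frame(
      segment = TREE_SEGMENTS,
      flow = m3s_to_mlmin(unname(qmap[TREE_SEGMENTS])),
      drop = pa_to_mmhg(unname(drops)),
      Re = unname(res),
      row.names = NULL),
    nodes = pa_to_mmhg(nodes_pa),
    drop = pa_to_mmhg(p_torcula + drops[["SSS"]]),
    left_fraction = x,
    Q_total = Q_total,
    straight_fraction = straight_fraction),
    class = "tree_solution")
}

#' @export
print.tree_solution <- function(x, ...) {
  cat(sprintf("Venous tree solution at Q = %g mL/min (StS/SSS = %.2f)\n",
              x$Q_total, x$straight_fraction))
  cat(sprintf("  system drop (SSS inlet -> jugular outlet): %.3f mmHg\n", x$drop))
  cat(sprintf("  left-branch flow fraction: %.4f\n", x$left_fraction))
  print(x$segments, digits = 4)
  invisible(x)
}

#' Calibrate minor losses to a reference pressure drop
#'
#' Uniformly scales every segment's minor-loss coefficients (the quadratic
#' part; friction is untouched) so that the solved system drop at a
#' reference flow matches a reference drop. The default anchor is the
#' literature validation point for young patients: 4.5 mmHg at 620 mL/min.
#'
#' @param tree a [venous_tree()].
#' @param reference_Q reference total flow, mL/min.
#' @param reference_drop reference system drop, mmHg.
#' @inheritParams solve_tree
#' @return the tree with each segment's `k_scale` set; the solved drop at
#'   `reference_Q` then equals `reference_drop` to ~1e-9 relative.
#' @export
calibrate_tree <- function(tree, reference_Q = 620, reference_drop = 4.5,
                           straight_fraction = 0.30, fluid = fluid_properties()) {
  check_scalar(reference_Q, "reference_Q")
  check_scalar(reference_drop, "reference_drop")
  set_scale <- function(tr, s) {
    tr$segments <- lapply(tr$segments, function(seg) { seg$k_scale <- s; seg })
    tr
  }
  drop_at <- function(s)
    solve_tree(set_scale(tree, s), reference_Q, straight_fraction, fluid)$drop
  d0 <- drop_at(0)
  if (d0 >= reference_drop)
    stopf(paste0("infeasible calibration: friction alone gives %.3f mmHg at ",
                 "%g mL/min, already >= the %.3f mmHg reference"),
          d0, reference_Q, reference_drop)
  hi <- 1
  while (drop_at(hi) < reference_drop) {
    hi <- hi * 2
    if (hi > 1e8) stopf("calibration scale search diverged")
  }
  s <- stats::uniroot(function(s) drop_at(s) - reference_drop,
                      lower = 0, upper = hi, tol = 1e-12)$root
  out <- set_scale(tree, s)
  attr(out, "k_scale") <- s
  out
}

#' Read and write venous trees as JSON
#'
#' One JSON document per patient tree: a `segments` array with `name`,
#' `length_mm`, `diameter_mm`, `bends` (angle degrees, radius_ratio),
#' `extra_K` and `k_scale`.
#'
#' @param tree a [venous_tree()].
#' @param path file path.
#' @return `read_tree_json()` returns a `venous_tree`; `write_tree_json()`
#'   returns `path` invisibly.
#' @export
write_tree_json <- function(tree, path) {
  segs <- lapply(tree$segments, function(s) list(
    name = s$name,
    length_mm = m_to_mm(s$length),
    diameter_mm = m_to_mm(s$diameter),
    bends = lapply(s$bends, function(b) list(angle = b$angle,
                                             radius_ratio = b$radius_ratio)),
    extra_K = as.numeric(s$extra_K),
    k_scale = s$k_scale))
  jsonlite::write_json(list(segments = unname(segs)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  doc <- jsonlite::read_json(path)
  segs <- lapply(doc$segments, function(s) {
    seg <- vessel_segment(s$name, s$length_mm, s$diameter_mm,
                          bends = s$bends,
                          extra_K = unlist(s$extra_K) %||% numeric())
    if (!is.null(s$k_scale)) seg$k_scale <- s$k_scale
    seg
  })
  venous_tree(segs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export per-segment solution summary to CSV
#'
#' @param solution a [solve_tree()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  utils::write.csv(solution$segments, path, row.names = FALSE)
  invisible(path)
}
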