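# End-to-end pipeline: generate (or load) patient trees, calibrate,
# sweep, fit the quadratic law, attach surrogate curl series, evaluate
# the ICP/IIH scenario, and write a report bundle.

#' Default pipeline configuration
#'
#' All constants of the study conditions in one overridable list: fluid
#' density 1055 kg/m^3 and viscosity 0.0035 Pa.s, straight-sinus fraction
#' 0.30, flow grid 200-2000 mL/min in steps of 200, calibration anchor
#' (620 mL/min, 4.5 mmHg), the IIH criteria block, and the synthetic
#' cohort settings.
#'
#' @return a named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_patients = 5L,
    flows = default_flow_grid(),
    straight_fraction = 0.30,
    fluid = list(density = 1055, viscosity = 0.0035),
    calibration = list(reference_Q = 620, reference_drop = 4.5),
    iih = list(baseline_icp = 14.6, required_delta = 3.8,
               baseline_drop = 4.5, diagnostic_icp = 18.34,
               hyperemia_factor = 1.35, cohort_threshold = 1500),
    curl = list(c_curl = 0.006, gamma = 1.4),
    geometry_json = NULL,   # optional list of tree JSON paths; NULL => synth
    cohort_flows = NULL,    # optional numeric vector or CSV path; NULL => synth
    output_dir = NULL,
    verbose = TRUE
  )
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected (with the offending key named); missing keys
#' take the [default_config()] values.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return a full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(cfg)
}

merge_config <- function(cfg) {
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      bad <- setdiff(names(cfg[[nm]]), names(base[[nm]]))
      if (length(bad))
        stopf("unknown configuration key(s) under '%s': %s", nm,
              paste(bad, collapse = ", "))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

plog <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain patient trees — synthetic cohort draws under the
#' configured seed, or trees loaded from JSON; (2) calibrate each tree's
#' minor losses to the reference anchor; (3) sweep the flow grid and solve
#' the network at each flow; (4) fit the zero-intercept quadratic law and
#' locate each patient's IIH threshold flow; (5) attach surrogate curl
#' series (scale `c_curl`, exponent `gamma`) and correlate curl with
#' pressure drop; (6) evaluate the ICP scenario (linear vs quadratic
#' hyperemia response, cohort fraction above the flow threshold). When
#' `output_dir` is set, writes per-patient curve CSVs, a fits JSON, a
#' scenario JSON and a plain-text summary.
#'
#' @param config a configuration list (see [default_config()]), or a path
#'   to a JSON/YAML config file. Logging goes to `stderr` via `message()`;
#'   results only to files and the return value.
#' @return invisibly, a list with `trees`, `curves`, `fits`, `thresholds`
#'   (mL/min), `curl` (per-patient series and correlations), `scenario`
#'   and `files` (paths written).
#' @examples
#' res <- run_pipeline(list(n_patients = 2, seed = 7, verbose = FALSE))
#' sapply(res$fits, function(f) f$r)
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  else config <- merge_config(config)
  cfg <- config
  fluid <- fluid_properties(cfg$fluid$density, cfg$fluid$viscosity)
  crit <- iih_criteria(cfg$iih$baseline_icp, cfg$iih$required_delta,
                       cfg$iih$baseline_drop, cfg$iih$diagnostic_icp)
  verbose <- cfg$verbose

  # 1. patient trees
  if (!is.null(cfg$geometry_json)) {
    plog(verbose, "loading %d tree(s) from JSON", length(cfg$geometry_json))
    trees <- lapply(cfg$geometry_json, read_tree_json)
  } else {
    plog(verbose, "generating %d synthetic patient tree(s), seed %d",
         cfg$n_patients, cfg$seed)
    cspec <- cohort_spec(n_patients = cfg$n_patients, seed = cfg$seed)
    trees <- lapply(seq_len(cfg$n_patients), function(i) generate_tree(cspec, i))
  }
  names(trees) <- sprintf("patient%d", seq_along(trees))

  # 2. calibrate, 3. sweep, 4. fit
  curves <- list(); fits <- list(); thresholds <- numeric(0)
  for (nm in names(trees)) {
    trees[[nm]] <- calibrate_tree(trees[[nm]],
                                  cfg$calibration$reference_Q,
                                  cfg$calibration$reference_drop,
                                  cfg$straight_fraction, fluid)
    curves[[nm]] <- flow_sweep(trees[[nm]], cfg$flows, cfg$straight_fraction,
                               fluid, patient_id = nm)
    fits[[nm]] <- pq_fit(curves[[nm]])
    thresholds[nm] <- threshold_flow(fits[[nm]], required_venous_drop(crit))
    plog(verbose, "%s: a=%.4g b=%.4g r=%.5f threshold=%.0f mL/min",
         nm, fits[[nm]]$a, fits[[nm]]$b, fits[[nm]]$r, thresholds[nm])
  }

  # 5. curl series (surrogate law on the same flow grid) + correlation
  curl <- lapply(seq_along(curves), function(i) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(cfg$seed * 1000L + i)
    curls <- cfg$curl$c_curl * cfg$flows^cfg$curl$gamma *
      (1 + stats::rnorm(length(cfg$flows), 0, 0.05))
    list(curl = curls,
         r = curl_pressure_correlation(curls, curves[[i]]$drop))
  })
  names(curl) <- names(curves)

  # 6. ICP scenario
  avg_fit <- pq_fit(pressure_flow_curve(
    cfg$flows, Reduce(`+`, lapply(curves, `[[`, "drop")) / length(curves),
    patient_id = "cohort-average"))
  flows_cohort <- cfg$cohort_flows
  if (is.character(flows_cohort)) flows_cohort <- utils::read.csv(flows_cohort)[[1L]]
  if (is.null(flows_cohort))
    flows_cohort <- generate_cohort_flows(seed = cfg$seed,
                                          threshold = cfg$iih$cohort_threshold)
  scenario <- list(
    required_drop = required_venous_drop(crit),
    hyperemia = compare_hyperemia_models(avg_fit, crit$baseline_drop,
                                         cfg$iih$hyperemia_factor,
                                         crit$required_delta),
    average_threshold_flow = threshold_flow(avg_fit, required_venous_drop(crit)),
    icp_threshold_flow = icp_threshold_flow(avg_fit, crit),
    cohort_threshold = cfg$iih$cohort_threshold,
    cohort = proportion_above(flows_cohort, cfg$iih$cohort_threshold))

  files <- character(0)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(curves)) {
      p <- file.path(cfg$output_dir, paste0("curve_", nm, ".csv"))
      write_curve_csv(curves[[nm]], p)
      files <- c(files, p)
    }
    fits_out <- lapply(names(fits), function(nm) list(
      patient = nm, a = fits[[nm]]$a, b = fits[[nm]]$b, r = fits[[nm]]$r,
      r_squared = fits[[nm]]$r_squared, threshold_flow = thresholds[[nm]],
      curl_pressure_r = curl[[nm]]$r))
    p <- file.path(cfg$output_dir, "fits.json")
    jsonlite::write_json(fits_out, p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
    p <- file.path(cfg$output_dir, "scenario.json")
    jsonlite::write_json(scenario, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, p)
    p <- file.path(cfg$output_dir, "summary.txt")
    writeLines(pipeline_summary_text(fits, thresholds, curl, scenario), p)
    files <- c(files, p)
    plog(verbose, "wrote %d file(s) to %s", length(files), cfg$output_dir)
  }

  invisible(list(config = cfg, trees = trees, curves = curves, fits = fits,
                 thresholds = thresholds, curl = curl, scenario = scenario,
                 average_fit = avg_fit, files = files))
}

pipeline_summary_text <- function(fits, thresholds, curl, scenario) {
  lines <- c("Cerebral venous sinus pressure-flow analysis", "")
  for (nm in names(fits)) {
    f <- fits[[nm]]
    lines <- c(lines, sprintf(
      "%s: dP = %.4g*Q + %.4g*Q^2 mmHg; r = %.4f; curl-drop r = %.4f; IIH threshold %.0f mL/min",
      nm, f$a, f$b, f$r, curl[[nm]]$r, thresholds[[nm]]))
  }
  h <- scenario$hyperemia
  lines <- c(lines, "", sprintf(
    "Required venous drop for IIH: %.1f mmHg", scenario$required_drop),
    sprintf("Hyperemia (linear model): +%.1f mmHg (induces IIH: %s)",
            h$increase_rounded[h$model == "linear"],
            h$induces_iih[h$model == "linear"]),
    if (any(h$model == "quadratic")) sprintf(
      "Hyperemia (quadratic model): +%.1f mmHg (induces IIH: %s)",
      h$increase_rounded[h$model == "quadratic"],
      h$induces_iih[h$model == "quadratic"]),
    sprintf("Cohort-average curve crosses the threshold at %.0f mL/min",
            scenario$average_threshold_flow),
    sprintf("Cohort flows above %g mL/min: %d of %d (%d%%)",
            scenario$cohort_threshold, scenario$cohort$count,
            scenario$cohort$total, scenario$cohort$percent))
  lines[!vapply(lines, is.null, TRUE)]
}
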