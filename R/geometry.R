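#' Blood fluid properties
#'
#' Density and dynamic viscosity of the modelled fluid. Defaults are the
#' standard Newtonian blood values used throughout: density 1055 kg/m^3 and
#' viscosity 0.0035 Pa.s.
#'
#' @param density mass density, kg/m^3; must be > 0.
#' @param viscosity dynamic viscosity, Pa.s; must be > 0.
#' @return an object of class `fluid_properties`.
#' @examples
#' blood <- fluid_properties()
#' blood$density
#' @export
fluid_properties <- function(density = 1055, viscosity = 0.0035) {
  check_scalar(density, "density")
  check_scalar(viscosity, "viscosity")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: density %g kg/m^3, viscosity %g Pa.s\n",
              x$density, x$viscosity))
  invisible(x)
}

#' Vessel cross-section
#'
#' A lumen cross-section described by its area and perimeter, optionally
#' carrying the binary pixel mask it was measured from. Area and perimeter
#' must satisfy the isoperimetric inequality `perimeter^2 >= 4*pi*area`
#' (equality for a circle); violations indicate inconsistent measurements.
#'
#' @param area lumen area. Any consistent length unit may be used (the
#'   derived diameters inherit it); mm^2 in, mm out is the usual convention.
#' @param perimeter lumen perimeter, in the matching length unit.
#' @param mask optional binary matrix marking lumen pixels.
#' @param spacing optional pixel spacing of `mask`, same length unit.
#' @return an object of class `cross_section`.
#' @examples
#' cs <- cross_section(area = pi * 2.745^2, perimeter = 2 * pi * 2.745) # mm
#' hydraulic_diameter(cs)
#' @export
cross_section <- function(area, perimeter, mask = NULL, spacing = NULL) {
  check_scalar(area, "area")
  check_scalar(perimeter, "perimeter")
  if (perimeter^2 < 4 * pi * area * (1 - 1e-9))
    stopf("invalid geometry: perimeter^2 (%g) < 4*pi*area (%g); no planar shape has this",
          perimeter^2, 4 * pi * area)
  structure(list(area = area, perimeter = perimeter,
                 mask = mask, spacing = spacing),
            class = "cross_section")
}

#' Hydraulic diameter of a cross-section
#'
#' `D_h = 4 * area / perimeter`, the standard duct-flow diameter. Equals the
#' geometric diameter for a circular section and never exceeds the effective
#' diameter for convex sections (isoperimetric inequality).
#'
#' @param cs a [cross_section()].
#' @return hydraulic diameter, in the length unit of the section.
#' @seealso [effective_diameter()]
#' @export
hydraulic_diameter <- function(cs) {
  if (!inherits(cs, "cross_section")) stopf("'cs' must be a cross_section")
  4 * cs$area / cs$perimeter
}

#' Effective diameter of a cross-section
#'
#' Diameter of the circle with the same area: `D_e = 2 * sqrt(area / pi)`.
#'
#' @inheritParams hydraulic_diameter
#' @return effective diameter, in the length unit of the section.
#' @export
effective_diameter <- function(cs) {
  if (!inherits(cs, "cross_section")) stopf("'cs' must be a cross_section")
  2 * sqrt(cs$area / pi)
}

# Box-smooth a 0/1 mask `passes` times (3x3 kernel with centre weight 1/2).
# Smoothing before contouring removes the orientation-dependent digitisation
# bias of marching squares on raw binary data, restoring convergence of the
# contour length to the true perimeter under grid refinement.
smooth_mask <- function(z, passes) {
  for (s in seq_len(passes)) {
    zp <- matrix(0, nrow(z) + 2L, ncol(z) + 2L)
    zp[2:(nrow(z) + 1L), 2:(ncol(z) + 1L)] <- z
    i <- 2:(nrow(z) + 1L); j <- 2:(ncol(z) + 1L)
    z <- (zp[i - 1L, j] + zp[i + 1L, j] + zp[i, j - 1L] + zp[i, j + 1L] +
            4 * zp[i, j]) / 8
  }
  z
}

# Marching-squares contour length of the 0.5 level set of a (smoothed) mask.
mask_perimeter <- function(mask, spacing) {
  r_px <- sqrt(sum(mask) / pi)                # equivalent radius in pixels
  passes <- max(3L, as.integer(round(sqrt(r_px))))
  z <- smooth_mask(mask, passes)
  zp <- matrix(0, nrow(z) + 2L, ncol(z) + 2L) # pad so contours close
  zp[2:(nrow(z) + 1L), 2:(ncol(z) + 1L)] <- z
  x <- (seq_len(nrow(zp)) - 1) * spacing
  y <- (seq_len(ncol(zp)) - 1) * spacing
  cl <- grDevices::contourLines(x, y, zp, levels = 0.5)
  if (length(cl) == 0L) stopf("mask has no 0.5-level contour")
  sum(vapply(cl, function(cc) sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)), 0))
}

# 4-connectivity check via flood fill from the first lumen pixel.
mask_connected <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  stack <- list(idx[1L, ])
  seen[idx[1L, 1L], idx[1L, 2L]] <- TRUE
  while (length(stack) > 0L) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      q <- p + d
      if (q[1L] >= 1L && q[1L] <= nrow(mask) && q[2L] >= 1L && q[2L] <= ncol(mask) &&
          mask[q[1L], q[2L]] > 0 && !seen[q[1L], q[2L]]) {
        seen[q[1L], q[2L]] <- TRUE
        stack[[length(stack) + 1L]] <- q
      }
    }
  }
  sum(seen) == nrow(idx)
}

#' Hydraulic and effective diameters from a lumen mask
#'
#' Measures a cross-section from a binary pixel mask: area as pixel count
#' times `spacing^2`, perimeter as the marching-squares contour length of the
#' mask boundary (computed on a lightly smoothed copy so the estimate
#' converges to the true perimeter under grid refinement).
#'
#' @param mask binary matrix (0/1 or logical) marking lumen pixels; must be
#'   non-empty, more than one pixel, and 4-connected.
#' @param spacing pixel spacing (e.g. mm); the diameters inherit this unit.
#' @return a list with `D_h`, `D_e`, `area`, `perimeter` and the
#'   [cross_section()] object under `section`.
#' @examples
#' n <- 61; r <- 25
#' xy <- expand.grid(i = 1:n, j = 1:n) - (n + 1) / 2
#' disk <- matrix(as.numeric(xy$i^2 + xy$j^2 <= r^2), n, n)
#' d <- diameters_from_mask(disk, spacing = 0.1)   # ~5 mm circle
#' c(d$D_h, d$D_e)
#' @export
diameters_from_mask <- function(mask, spacing) {
  if (is.logical(mask)) mask <- mask * 1
  if (!is.matrix(mask) || !is.numeric(mask)) stopf("'mask' must be a numeric or logical matrix")
  check_scalar(spacing, "spacing")
  npix <- sum(mask > 0)
  if (npix == 0L) stopf("empty mask")
  if (npix < 2L) stopf("degenerate mask: a single pixel has no measurable geometry")
  if (!mask_connected(mask > 0)) stopf("mask is not a single connected component")
  area <- npix * spacing^2
  perim <- mask_perimeter((mask > 0) * 1, spacing)
  cs <- cross_section(area, max(perim, sqrt(4 * pi * area)),
                      mask = mask, spacing = spacing)
  list(D_h = hydraulic_diameter(cs), D_e = effective_diameter(cs),
       area = area, perimeter = cs$perimeter, section = cs)
}

#' Read and write lumen masks as delimited text
#'
#' One-line header `spacing_mm=<s>` followed by a whitespace-delimited 0/1
#' grid, one matrix row per line.
#'
#' @param mask binary matrix.
#' @param spacing pixel spacing in mm.
#' @param path file path.
#' @return `read_mask()` returns a list with `mask` and `spacing`;
#'   `write_mask()` returns `path` invisibly.
#' @export
write_mask <- function(mask, spacing, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("spacing_mm=%.10g", spacing), con)
  apply(mask, 1L, function(r) writeLines(paste(as.integer(r > 0), collapse = " "), con))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  if (!grepl("^spacing_mm=", lines[1L])) stopf("mask file missing spacing_mm header")
  spacing <- as.numeric(sub("^spacing_mm=", "", lines[1L]))
  rows <- lapply(lines[-1L], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  mask <- do.call(rbind, rows)
  list(mask = mask, spacing = spacing)
}
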