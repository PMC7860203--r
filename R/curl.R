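# Planar vorticity metrics. The curl of an in-plane velocity field
# (u, v) on a vessel cross-section is dv/dx - du/dy (1/s), evaluated by
# central differences inside the lumen mask and one-sided differences
# where a neighbour leaves the mask. Matrix convention: rows index y,
# columns index x.

#' In-plane velocity field on a vessel cross-section
#'
#' @param u x-velocity matrix, m/s (rows = y, columns = x).
#' @param v y-velocity matrix, m/s, same shape.
#' @param spacing grid step, m (> 0).
#' @param mask binary/logical lumen matrix, same shape; defaults to all
#'   lumen. Must be non-empty.
#' @param meta optional named list of metadata (e.g. section placement).
#' @return an object of class `velocity_plane`.
#' @export
velocity_plane <- function(u, v, spacing, mask = NULL, meta = list()) {
  if (!is.matrix(u) || !is.matrix(v)) stopf("u and v must be matrices")
  if (!all(dim(u) == dim(v))) stopf("u and v shapes differ")
  check_scalar(spacing, "spacing")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(u), ncol(u))
  if (is.numeric(mask)) mask <- mask > 0
  if (!all(dim(mask) == dim(u))) stopf("mask shape differs from u/v")
  if (!any(mask)) stopf("empty mask")
  structure(list(u = u, v = v, spacing = spacing, mask = mask, meta = meta),
            class = "velocity_plane")
}

# Masked partial derivative along columns (x) or rows (y): central where
# both neighbours are in the mask, one-sided where only one is, NA where
# neither is.
masked_deriv <- function(f, mask, h, along = c("x", "y")) {
  along <- match.arg(along)
  if (along == "y") {            # derivative across rows
    return(t(masked_deriv(t(f), t(mask), h, "x")))
  }
  n <- nrow(f); m <- ncol(f)
  fp <- cbind(NA_real_, f, NA_real_)
  mp <- cbind(FALSE, mask, FALSE)
  j <- 2:(m + 1L)
  left_ok <- mp[, j - 1L]; right_ok <- mp[, j + 1L]
  d <- matrix(NA_real_, n, m)
  both <- mask & left_ok & right_ok
  d[both] <- ((fp[, j + 1L] - fp[, j - 1L]) / (2 * h))[both]
  ronly <- mask & !left_ok & right_ok
  d[ronly] <- ((fp[, j + 1L] - fp[, j]) / h)[ronly]
  lonly <- mask & left_ok & !right_ok
  d[lonly] <- ((fp[, j] - fp[, j - 1L]) / h)[lonly]
  d
}

#' Curl of a planar velocity field
#'
#' `curl = dv/dx - du/dy` on the lumen mask, by central differences in the
#' interior and first-order one-sided differences at the mask boundary.
#' Points where a derivative cannot be formed in some direction (no in-mask
#' neighbour) are dropped from the field.
#'
#' @param plane a [velocity_plane()].
#' @return an object of class `curl_field`: list with `values` (matrix,
#'   1/s, NA off-mask or where underivable) and `mask` (logical matrix of
#'   points with a defined curl).
#' @export
curl_field <- function(plane) {
  if (!inherits(plane, "velocity_plane")) stopf("'plane' must be a velocity_plane")
  dvdx <- masked_deriv(plane$v, plane$mask, plane$spacing, "x")
  dudy <- masked_deriv(plane$u, plane$mask, plane$spacing, "y")
  values <- dvdx - dudy
  ok <- !is.na(values)
  if (!any(ok))
    stopf("mask too thin: no point admits both an x and a y difference")
  structure(list(values = values, mask = ok, spacing = plane$spacing),
            class = "curl_field")
}

#' Average curl over a cross-section
#'
#' Mean of the curl magnitude |dv/dx - du/dy| over the lumen — the
#' vorticity statistic reported per cross-section, always non-negative.
#' The magnitude convention keeps counter-rotating vortex pairs from
#' cancelling to zero; set `signed = TRUE` for the signed mean of the
#' normal component instead.
#'
#' @param plane a [velocity_plane()].
#' @param signed average the signed curl instead of |curl| (default FALSE).
#' @return average curl, 1/s.
#' @export
average_curl <- function(plane, signed = FALSE) {
  cf <- curl_field(plane)
  vals <- cf$values[cf$mask]
  if (signed) mean(vals) else mean(abs(vals))
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r between two paired samples, with explicit guards:
#' at least 3 pairs and non-zero variance in both.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3L) stopf("pearson_r needs at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stopf("pearson_r: missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("pearson_r: zero variance in one of the inputs")
  stats::cor(x, y)
}

#' Correlation between sectional curl and system pressure drop
#'
#' Pearson correlation between the average-curl series and the pressure
#' drops across a flow sweep of one patient, paired by flow rate. Values
#' near 1 indicate the vortical losses carry the pressure response.
#'
#' @param curls average curl values, 1/s, one per flow rate.
#' @param drops system pressure drops, mmHg, paired with `curls`.
#' @return Pearson r.
#' @export
curl_pressure_correlation <- function(curls, drops) pearson_r(curls, drops)

#' Read and write velocity planes as delimited text
#'
#' Single file: a header line `spacing_mm=<s>`, then three blocks `# u`,
#' `# v`, `# mask`, each a whitespace-delimited grid, one matrix row per
#' line.
#'
#' @param plane a [velocity_plane()].
#' @param path file path.
#' @return `read_velocity_plane()` returns a `velocity_plane`;
#'   `write_velocity_plane()` returns `path` invisibly.
#' @export
write_velocity_plane <- function(plane, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("spacing_mm=%.17g", m_to_mm(plane$spacing)), con)
  wb <- function(tag, m) {
    writeLines(paste("#", tag), con)
    apply(m, 1L, function(r) writeLines(paste(sprintf("%.17g", r),
                                              collapse = " "), con))
  }
  wb("u", plane$u); wb("v", plane$v); wb("mask", plane$mask * 1)
  invisible(path)
}

#' @rdname write_velocity_plane
#' @export
read_velocity_plane <- function(path) {
  lines <- readLines(path)
  if (!grepl("^spacing_mm=", lines[1L])) stopf("plane file missing spacing_mm header")
  spacing <- mm_to_m(as.numeric(sub("^spacing_mm=", "", lines[1L])))
  marks <- grep("^#", lines)
  if (length(marks) != 3L) stopf("plane file must contain blocks # u, # v, # mask")
  tags <- trimws(sub("^#", "", lines[marks]))
  bounds <- c(marks, length(lines) + 1L)
  blocks <- lapply(seq_len(3L), function(k) {
    rows <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    do.call(rbind, lapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  })
  names(blocks) <- tags
  velocity_plane(blocks$u, blocks$v, spacing, blocks$mask)
}

#' Read a velocity plane from a legacy VTK structured-points file
#'
#' Minimal ASCII reader for `DATASET STRUCTURED_POINTS` files as exported
#' by CFD post-processors: uses `DIMENSIONS nx ny 1`, `SPACING`, and the
#' first `VECTORS` field for (u, v); an optional `SCALARS mask` field
#' supplies the lumen mask (all-lumen otherwise). Point order is the VTK
#' convention (x fastest).
#'
#' @param path file path.
#' @return a [velocity_plane()].
#' @export
read_velocity_plane_vtk <- function(path) {
  lines <- readLines(path)
  need <- function(pat) {
    i <- grep(pat, lines, ignore.case = TRUE)
    if (!length(i)) stopf("VTK file: missing '%s'", pat)
    i[1L]
  }
  if (!any(grepl("STRUCTURED_POINTS", lines, ignore.case = TRUE)))
    stopf("only legacy STRUCTURED_POINTS VTK files are supported")
  dims <- as.numeric(strsplit(trimws(sub(".*DIMENSIONS", "",
           lines[need("^DIMENSIONS")], ignore.case = TRUE)), "\\s+")[[1L]])
  if (length(dims) < 2L || (length(dims) >= 3L && dims[3L] > 1))
    stopf("VTK file must be a single 2D plane (nz = 1)")
  nx <- dims[1L]; ny <- dims[2L]
  sp <- as.numeric(strsplit(trimws(sub(".*SPACING", "",
           lines[need("^SPACING")], ignore.case = TRUE)), "\\s+")[[1L]])
  iv <- need("^VECTORS")
  nums_after <- function(i, count) {
    vals <- numeric(0); j <- i + 1L
    while (length(vals) < count && j <= length(lines)) {
      if (!grepl("^[A-Za-z]", lines[j]))
        vals <- c(vals, as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1L]]))
      else break
      j <- j + 1L
    }
    if (length(vals) < count) stopf("VTK file: truncated data section")
    vals[seq_len(count)]
  }
  vec <- nums_after(iv, 3L * nx * ny)
  u <- matrix(vec[seq(1L, by = 3L, length.out = nx * ny)], ny, nx, byrow = TRUE)
  v <- matrix(vec[seq(2L, by = 3L, length.out = nx * ny)], ny, nx, byrow = TRUE)
  im <- grep("^SCALARS\\s+mask", lines, ignore.case = TRUE)
  mask <- if (length(im)) {
    start <- im[1L] + if (grepl("^LOOKUP_TABLE", lines[im[1L] + 1L],
                                ignore.case = TRUE)) 1L else 0L
    matrix(nums_after(start, nx * ny), ny, nx, byrow = TRUE) > 0
  } else NULL
  velocity_plane(u, v, spacing = sp[1L], mask = mask)
}
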