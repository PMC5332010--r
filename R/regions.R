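# Sub-cellular region geometry.
#
# Border percentages are realised through a per-pixel normalised radial
# coordinate rho: 0 at the cell centroid, 1 on the boundary along the ray
# through the pixel, > 1 outside the cell. Bands are shells in rho, so the
# inner border at 100% encompasses the whole cell and negative outer borders
# extend beyond the edge. For non-star-shaped masks, rays with several
# boundary crossings use the outermost crossing, keeping rho <= 1 inside.

#' Normalised radial coordinate field of a cell mask
#'
#' For every pixel of the raster, `rho = |p - c| / |b(p) - c|`, where `c` is
#' the mask centroid (or, if the centroid falls outside the mask, the most
#' interior point by distance transform) and `b(p)` the outermost boundary
#' point along the ray from `c` through `p`. The boundary radius is sampled
#' in angular bins and interpolated circularly.
#'
#' @param cell_mask logical matrix, non-empty.
#' @param nbins number of angular bins.
#' @return list with `rho` (numeric matrix, same shape as the mask),
#'   `centre` (x, y) and `radius` (boundary radius per bin).
#' @export
radial_field <- function(cell_mask, nbins = 360L) {
  if (!any(cell_mask)) stop("cell mask has zero area")
  d <- dim(cell_mask)
  idx <- which(cell_mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  ci <- round(ctr)
  if (!cell_mask[ci[1], ci[2]]) {
    # pole of inaccessibility fallback
    dm <- mat(EBImage::distmap(cell_mask * 1))
    ctr <- as.numeric(which(dm == max(dm), arr.ind = TRUE)[1, ])
  }
  boundary <- cell_mask & !erode_mask(cell_mask, brush_box1())
  bidx <- which(boundary, arr.ind = TRUE)
  bx <- bidx[, 1] - ctr[1]
  by <- bidx[, 2] - ctr[2]
  br <- sqrt(bx^2 + by^2)
  bth <- atan2(by, bx)
  bin <- pmin(nbins, floor((bth + pi) / (2 * pi) * nbins) + 1L)
  radius <- rep(NA_real_, nbins)
  agg <- tapply(br, bin, max)     # outermost crossing per angular bin
  radius[as.integer(names(agg))] <- agg
  radius <- fill_circular(radius)

  x <- matrix(seq_len(d[1]) - ctr[1], d[1], d[2])
  y <- matrix(seq_len(d[2]) - ctr[2], d[1], d[2], byrow = TRUE)
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  pbin <- pmin(nbins, floor((th + pi) / (2 * pi) * nbins) + 1L)
  rho <- r / radius[pbin]
  list(rho = rho, centre = ctr, radius = radius)
}

#' Band between two fractional borders of a cell
#'
#' Borders are depths measured inward from the cell edge as a percentage of
#' the edge-to-centroid distance: the inner border at 100% starts at the
#' centroid and encompasses the whole cell, 0% is the edge itself, and
#' negative values lie outside the cell. `band_from_borders(mask, 100, 0)`
#' returns exactly the cell mask; `band_from_borders(mask, 10, -5)` is the
#' membrane (protrusion) shell from 10% inside the edge to 5% beyond it.
#'
#' @param cell_mask logical matrix.
#' @param inner_pct inner border depth (%); must be >= `outer_pct`.
#' @param outer_pct outer border depth (%); negative = outside the cell.
#' @param rf optional precomputed [radial_field()] of the mask.
#' @return logical matrix.
#' @export
band_from_borders <- function(cell_mask, inner_pct, outer_pct, rf = NULL) {
  if (inner_pct < outer_pct) {
    stop("inverted borders: inner_pct must be >= outer_pct")
  }
  if (is.null(rf)) rf <- radial_field(cell_mask)
  lo <- 1 - inner_pct / 100
  hi <- 1 - outer_pct / 100
  inside <- cell_mask & rf$rho >= lo
  if (outer_pct >= 0) {
    inside & rf$rho <= hi
  } else {
    inside | (!cell_mask & rf$rho <= hi)
  }
}

#' Perinuclear ring region
#'
#' The ring's inner border sits at 40% of the edge-to-centroid distance
#' (100% = whole cell); its outer border sits 20% of the edge-to-inner-border
#' distance inward from the edge, i.e. at depth `0.20 * 40% = 8%`. The
#' (uneroded) nucleus mask is excluded, so nuclear and ring signal never
#' share pixels. The alternative reading of the outer border (measured from
#' the inner border outward, depth `40% - 8% = 32%`) is available with
#' `outer_from_inner = TRUE`.
#'
#' @param cell_mask,nucleus_mask logical matrices, nucleus inside cell.
#' @param inner_pct ring inner border depth (%).
#' @param outer_frac outer border as a fraction of the edge-to-inner-border
#'   distance.
#' @param outer_from_inner switch to the alternative reading.
#' @param rf optional precomputed [radial_field()].
#' @return logical matrix; empty with a warning if the nucleus fills the shell.
#' @export
build_ring <- function(cell_mask, nucleus_mask, inner_pct = 40,
                       outer_frac = 0.20, outer_from_inner = FALSE,
                       rf = NULL) {
  outer_pct <- if (outer_from_inner) {
    inner_pct * (1 - outer_frac)
  } else {
    inner_pct * outer_frac
  }
  ring <- band_from_borders(cell_mask, inner_pct, outer_pct, rf = rf) &
    !nucleus_mask
  if (!any(ring)) {
    warning("empty ring region after nucleus exclusion; ring features will be NA")
  }
  ring
}

#' Eroded nuclear region
#'
#' Morphological erosion by `max(1, round(pct/100 * equivalent_radius))` px,
#' so the eroded nucleus is a smaller version of the nucleus that cannot
#' touch the ring region. If erosion empties the mask the function falls
#' back to a 1-px erosion, then to the original mask, with a warning.
#'
#' @param nucleus_mask logical matrix, non-empty.
#' @param pct erosion depth as a percentage of the equivalent radius.
#' @return logical matrix.
#' @export
erode_nucleus <- function(nucleus_mask, pct = 2) {
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  req <- sqrt(sum(nucleus_mask) / pi)
  r <- max(1L, round(pct / 100 * req))
  out <- erode_mask(nucleus_mask, brush_disc(r))
  if (!any(out) && r > 1L) out <- erode_mask(nucleus_mask, brush_disc(1))
  if (!any(out)) {
    warning("nucleus too small to erode; using the uneroded mask")
    out <- nucleus_mask
  }
  out
}

#' One-pixel membrane bands inside and outside the cell boundary
#'
#' `membrane1` is the 1-px band just inside the boundary (borders 0 to 1 px);
#' `membrane2` the 1-px band just outside it (-1 to 0 px), excluding pixels
#' occupied by other cell labels, so cell-cell contact clips the outer band.
#'
#' @param cell_mask logical matrix for one cell.
#' @param labels integer label mask of all cells (same raster); pass `NULL`
#'   for an isolated cell.
#' @param label the cell's own label in `labels`.
#' @return list of logical matrices `membrane1`, `membrane2`.
#' @export
neighbour_bands <- function(cell_mask, labels = NULL, label = NULL) {
  dia <- EBImage::makeBrush(3L, shape = "diamond")
  m1 <- cell_mask & !erode_mask(cell_mask, dia)
  m2 <- dilate_mask(cell_mask, dia) & !cell_mask
  if (!is.null(labels)) {
    other <- labels > 0L
    if (!is.null(label)) other <- other & labels != label
    m2 <- m2 & !other
  }
  list(membrane1 = m1, membrane2 = m2)
}

#' Build the full region set of one cell
#'
#' @param cell_mask,nucleus_mask logical matrices (full raster or patch).
#' @param labels optional all-cells label mask aligned with `cell_mask` for
#'   neighbour-band clipping.
#' @param label the cell's label in `labels`.
#' @param config see [default_config()] (`regions$...`).
#' @return a `region_set` list: `nucleus`, `eroded_nucleus`, `cytoplasm`,
#'   `cell`, `ring`, `membrane_protrusion`, `membrane1`, `membrane2`, plus
#'   the `radial` field used.
#' @export
build_region_set <- function(cell_mask, nucleus_mask, labels = NULL,
                             label = NULL, config = default_config()) {
  stopifnot(any(cell_mask), all(dim(cell_mask) == dim(nucleus_mask)))
  p <- config$regions
  rf <- radial_field(cell_mask, nbins = p$radial_bins)
  ring <- build_ring(cell_mask, nucleus_mask, inner_pct = p$ring_inner_pct,
                     outer_frac = p$ring_outer_frac,
                     outer_from_inner = p$ring_outer_from_inner, rf = rf)
  memb <- band_from_borders(cell_mask, p$membrane_inner_pct,
                            p$membrane_outer_pct, rf = rf)
  nb <- neighbour_bands(cell_mask, labels = labels, label = label)
  structure(list(
    nucleus = nucleus_mask,
    eroded_nucleus = if (any(nucleus_mask)) {
      erode_nucleus(nucleus_mask, pct = p$nucleus_erosion_pct)
    } else nucleus_mask,
    cytoplasm = cell_mask & !nucleus_mask,
    cell = cell_mask,
    ring = ring,
    membrane_protrusion = memb,
    membrane1 = nb$membrane1,
    membrane2 = nb$membrane2,
    radial = rf
  ), class = "region_set")
}
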