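# Segmentation: nuclei from the nuclear stain, cells from the tubulin stain
# seeded by nuclei, border filtering and multinucleate detection.
#
# Community-standard algorithms with the same input/output contract as the
# screen's original (proprietary) pipeline: Gaussian pre-smoothing + Otsu
# threshold + distance-transform watershed for nuclei, and intensity-guided
# seeded region growing (EBImage::propagate, a Voronoi region grower on an
# intensity-weighted metric) for the cytoplasm.

otsu_threshold <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(rng[1])
  norm <- (m - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  th * diff(rng) + rng[1]
}

#' Segment nuclei from the nuclear channel
#'
#' Gaussian pre-smooth, global threshold (Otsu by default), split of touching
#' nuclei by watershed on the distance transform, then a minimum-area filter.
#'
#' @param nuclear_channel 2-D numeric raster (nuclear stain).
#' @param config pipeline configuration; see [default_config()]
#'   (`segmentation$nucleus_smooth_sigma`, `$nucleus_threshold`,
#'   `$nucleus_min_area`, `$watershed_tolerance`).
#' @return integer label mask (0 = background, labels contiguous from 1).
#' @export
segment_nuclei <- function(nuclear_channel, config = default_config()) {
  if (length(dim(nuclear_channel)) != 2) stop("nuclear channel must be 2-D")
  if (!all(is.finite(nuclear_channel))) stop("non-finite values in channel")
  p <- config$segmentation
  sm <- if (p$nucleus_smooth_sigma > 0) {
    mat(EBImage::gblur(nuclear_channel, sigma = p$nucleus_smooth_sigma))
  } else nuclear_channel
  th <- if (is.na(p$nucleus_threshold)) otsu_threshold(sm) else p$nucleus_threshold
  fg <- sm > th
  if (!any(fg)) return(matrix(0L, nrow(fg), ncol(fg)))
  dm <- mat(EBImage::distmap(fg * 1))
  lab <- mat(EBImage::watershed(EBImage::Image(dm),
                                tolerance = p$watershed_tolerance))
  storage.mode(lab) <- "integer"
  areas <- label_areas(lab)
  drop <- as.integer(names(areas)[areas < p$nucleus_min_area])
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel(lab)
}

#' Segment cells from the tubulin channel, seeded by nuclei
#'
#' Thresholds the (smoothed) tubulin channel into a cytoplasmic foreground
#' mask and grows exactly one cell label from each nucleus seed by
#' intensity-guided propagation. Every nucleus pixel ends up inside its cell
#' label. A nucleus whose seed falls entirely outside the tubulin foreground
#' is kept as the nucleus dilated by one pixel, with a warning.
#'
#' @param tubulin_channel 2-D numeric raster.
#' @param nuclei integer label mask from [segment_nuclei()].
#' @param config see [default_config()] (`segmentation$cell_threshold`,
#'   `$cell_smooth_sigma`).
#' @return integer label mask of cells, labels matching `nuclei`.
#' @export
segment_cells <- function(tubulin_channel, nuclei, config = default_config()) {
  stopifnot(all(dim(tubulin_channel) == dim(nuclei)))
  if (!any(nuclei > 0L)) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  p <- config$segmentation
  sm <- if (p$cell_smooth_sigma > 0) {
    mat(EBImage::gblur(tubulin_channel, sigma = p$cell_smooth_sigma))
  } else tubulin_channel
  th <- if (is.na(p$cell_threshold)) otsu_threshold(sm) else p$cell_threshold
  fg <- sm > th | nuclei > 0L
  lab <- mat(EBImage::propagate(EBImage::Image(sm), EBImage::Image(nuclei),
                                mask = EBImage::Image(fg * 1), lambda = 1e-4))
  storage.mode(lab) <- "integer"
  # nuclei stranded outside the foreground: fall back to a 1-px dilation
  ids <- label_ids(nuclei)
  got <- label_ids(lab)
  lost <- setdiff(ids, got)
  if (length(lost)) {
    warning("nucleus seed(s) outside tubulin foreground, using dilated nucleus: ",
            toString(lost))
    for (id in lost) {
      nm <- dilate_mask(nuclei == id, brush_disc(1))
      lab[nm & lab == 0L] <- id
    }
  }
  lab
}

#' Remove cells touching the image border
#'
#' Drops every cell label whose mask touches any raster edge, together with
#' its nuclei, and relabels both masks contiguously (labels stay paired).
#'
#' @param cells,nuclei aligned integer label masks.
#' @return list with relabelled `cells` and `nuclei`.
#' @export
filter_border <- function(cells, nuclei) {
  stopifnot(all(dim(cells) == dim(nuclei)))
  d <- dim(cells)
  edge_labels <- unique(c(cells[1, ], cells[d[1], ], cells[, 1], cells[, d[2]]))
  edge_labels <- edge_labels[edge_labels > 0L]
  if (length(edge_labels)) {
    cells[cells %in% edge_labels] <- 0L
    nuclei[nuclei %in% edge_labels] <- 0L
  }
  keep <- label_ids(cells)
  cells_new <- cells
  cells_new[] <- match(as.integer(cells), keep, nomatch = 0L)
  storage.mode(cells_new) <- "integer"
  nuclei_new <- nuclei
  nuclei_new[] <- match(as.integer(nuclei), keep, nomatch = 0L)
  storage.mode(nuclei_new) <- "integer"
  list(cells = cells_new, nuclei = nuclei_new)
}

#' Multinucleate detection by cytoplasm-first segmentation
#'
#' Nucleus-seeded cells are mononucleate by construction, so cytokinesis
#' failure is detected on an unseeded pass: the tubulin foreground is split
#' into connected components and nucleus centroids are counted per component.
#' A component with >= 2 nuclei is multinucleate.
#'
#' @param tubulin_channel 2-D numeric raster.
#' @param nuclei integer label mask from [segment_nuclei()].
#' @param config see [default_config()].
#' @return list with `components` (data.frame: component label, area, nucleus
#'   count) and `percent` (percentage of nucleus-bearing components with >= 2
#'   nuclei; `NA` if there are none).
#' @export
detect_multinucleate <- function(tubulin_channel, nuclei,
                                 config = default_config()) {
  stopifnot(all(dim(tubulin_channel) == dim(nuclei)))
  p <- config$segmentation
  sm <- if (p$cell_smooth_sigma > 0) {
    mat(EBImage::gblur(tubulin_channel, sigma = p$cell_smooth_sigma))
  } else tubulin_channel
  th <- if (is.na(p$cell_threshold)) otsu_threshold(sm) else p$cell_threshold
  fg <- sm > th | nuclei > 0L
  comp <- mat(EBImage::bwlabel(fg * 1))
  storage.mode(comp) <- "integer"
  cent <- label_centroids(nuclei)
  if (!nrow(cent)) {
    return(list(components = data.frame(component = integer(0), area = numeric(0),
                                        n_nuclei = integer(0)),
                percent = NA_real_))
  }
  at <- comp[cbind(pmax(1L, pmin(nrow(comp), round(cent[, "x"]))),
                   pmax(1L, pmin(ncol(comp), round(cent[, "y"]))))]
  ids <- label_ids(comp)
  counts <- tabulate(at[at > 0L], nbins = max(ids))
  areas <- label_areas(comp)
  keep <- ids[counts[ids] > 0L]   # nucleus-bearing components only
  components <- data.frame(component = keep, area = as.numeric(areas[as.character(keep)]),
                           n_nuclei = counts[keep])
  pct <- if (nrow(components)) 100 * mean(components$n_nuclei >= 2L) else NA_real_
  list(components = components, percent = pct)
}
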