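#' Default pipeline configuration
#'
#' Returns the full set of tunables used across the pipeline, with the
#' screen's documented parameters as defaults: membrane (protrusion) band at
#' inner 10% / outer -5% of the radial coordinate, ring region at inner 40%
#' with the outer border at 20% of the edge-to-inner-border distance, nuclear
#' erosion by 2%, SER texture scales {0, 1} px, Haralick co-occurrence
#' distance 1 px, and a hit threshold of |Z| >= 1.5.
#'
#' @param ... named overrides, e.g. `default_config(hit_threshold = 2)`.
#'   Nested lists are merged element-wise.
#' @return a named list of class `ms_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$regions$ring_inner_pct
default_config <- function(...) {
  cfg <- list(
    segmentation = list(
      nucleus_smooth_sigma = 2,     # px, Gaussian pre-smooth of nuclear channel
      nucleus_threshold    = NA,    # NA = Otsu
      nucleus_min_area     = 50,    # px^2
      watershed_tolerance  = 1,     # distance-transform watershed tolerance
      cell_threshold       = NA,    # NA = Otsu on tubulin
      cell_smooth_sigma    = 2
    ),
    regions = list(
      membrane_inner_pct = 10,      # protrusion band: 10% inside the edge
      membrane_outer_pct = -5,      # ... to 5% beyond it
      ring_inner_pct     = 40,      # ring inner border (100 = whole cell)
      ring_outer_frac    = 0.20,    # outer border: fraction of edge->inner dist
      ring_outer_from_inner = FALSE,# alt. reading: outer measured from inner border
      nucleus_erosion_pct = 2,      # eroded nuclear region
      radial_bins        = 360      # angular resolution of the radial field
    ),
    features = list(
      ser_sigma0        = 0.5,      # px, base Gaussian scale (scale s adds s px)
      ser_scales        = c(0, 1),
      haralick_levels   = 64,
      haralick_distance = 1,
      gabor_wavelength  = 4,        # px
      gabor_orientations = 8
    ),
    classify = list(
      lambda = 1e-3                 # ridge penalty of the linear classifier
    ),
    screen = list(
      hit_threshold = 1.5,
      normalise     = "meansd"      # or "medianmad"
    )
  )
  override <- list(...)
  if (length(override)) cfg <- merge_config(cfg, override)
  structure(cfg, class = "ms_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read / write a configuration file
#'
#' Configurations round-trip losslessly through YAML. Values absent from the
#' file fall back to [default_config()].
#'
#' @param path file path.
#' @param cfg a configuration list as returned by [default_config()].
#' @return `read_config()` returns an `ms_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(default_config()), raw)
  structure(cfg, class = "ms_config")
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
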