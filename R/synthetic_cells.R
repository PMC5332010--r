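# Synthetic single-cell renderer.
#
# Cells are smoothed star polygons: the boundary radius is a cosine-modulated
# function of the polar angle, r(theta) = R0 * (1 + amp * cos(k * theta)),
# optionally stretched along a random major axis (elongation) and, for the
# fan class, made asymmetric with the nucleus displaced to one side. The five
# reference morphologies of the screen are parameterised so that they are
# visually distinctive and linearly separable in the extracted feature space:
# spindly (elongated, two protrusions), large spread (large, near-circular),
# triangular (three protrusions), fan (asymmetric, off-centre nucleus) and
# small round (small, high roundness).

#' Shape classes of the reference library
#' @export
SHAPE_CLASSES <- c("spindly", "large_spread", "triangular", "fan", "small_round")

#' Specify a synthetic cell morphology
#'
#' @param shape_class one of `r toString(SHAPE_CLASSES)`.
#' @param cell_area_range length-2 numeric, target cell area range in px^2.
#' @param protrusion_count integer number of boundary lobes.
#' @param protrusion_amp dimensionless lobe amplitude (0 = circle).
#' @param elongation major/minor stretch factor, >= 1.
#' @param asymmetry boundary asymmetry in [0, 1) (fan shape).
#' @param nucleus_area_fraction nucleus area as a fraction of cell area, in (0, 1).
#' @param nucleus_offset nucleus displacement as a fraction of the mean cell
#'   radius (fan shape places the nucleus to one side).
#' @param yaptaz_nuc_ring_ratio target ratio of mean nuclear to mean
#'   perinuclear YAP/TAZ intensity (> 0), realised exactly in the noiseless
#'   render.
#' @param channel_levels named per-channel mean foreground intensity
#'   (arbitrary units) for `hoechst`, `tubulin`, `actin`, `yaptaz`.
#' @param texture_amplitude named per-channel multiplicative texture
#'   amplitude (dimensionless). The YAP/TAZ channel is rendered flat so the
#'   nucleus:ring ratio is exact.
#' @return a `shape_spec` list.
#' @seealso [shape_library()] for the five reference parameterisations.
#' @export
shape_spec <- function(shape_class,
                       cell_area_range = c(800, 1000),
                       protrusion_count = 0L,
                       protrusion_amp = 0.05,
                       elongation = 1,
                       asymmetry = 0,
                       nucleus_area_fraction = 0.22,
                       nucleus_offset = 0,
                       yaptaz_nuc_ring_ratio = 1.5,
                       channel_levels = c(hoechst = 160, tubulin = 120,
                                          actin = 110, yaptaz = 100),
                       texture_amplitude = c(hoechst = 0.12, tubulin = 0.22,
                                             actin = 0.22, yaptaz = 0)) {
  shape_class <- match.arg(shape_class, SHAPE_CLASSES)
  stopifnot(length(cell_area_range) == 2, all(cell_area_range > 0),
            cell_area_range[1] <= cell_area_range[2])
  if (elongation < 1) stop("elongation must be >= 1")
  if (!(nucleus_area_fraction > 0 && nucleus_area_fraction < 1)) {
    stop("nucleus_area_fraction must lie strictly in (0, 1)")
  }
  if (yaptaz_nuc_ring_ratio <= 0) stop("yaptaz_nuc_ring_ratio must be > 0")
  if (asymmetry < 0 || asymmetry >= 1) stop("asymmetry must lie in [0, 1)")
  structure(list(
    shape_class = shape_class,
    cell_area_range = as.numeric(cell_area_range),
    protrusion_count = as.integer(protrusion_count),
    protrusion_amp = protrusion_amp,
    elongation = elongation,
    asymmetry = asymmetry,
    nucleus_area_fraction = nucleus_area_fraction,
    nucleus_offset = nucleus_offset,
    yaptaz_nuc_ring_ratio = yaptaz_nuc_ring_ratio,
    channel_levels = channel_levels,
    texture_amplitude = texture_amplitude
  ), class = "shape_spec")
}

#' Reference library of the five screen morphologies
#'
#' @param yaptaz_nuc_ring_ratio baseline nucleus:ring YAP/TAZ ratio applied to
#'   every class.
#' @return named list of five [shape_spec()] objects.
#' @export
shape_library <- function(yaptaz_nuc_ring_ratio = 1.5) {
  list(
    spindly = shape_spec("spindly", cell_area_range = c(800, 1000),
                         protrusion_count = 2L, protrusion_amp = 0.30,
                         elongation = 4, nucleus_area_fraction = 0.20,
                         yaptaz_nuc_ring_ratio = yaptaz_nuc_ring_ratio),
    large_spread = shape_spec("large_spread", cell_area_range = c(2300, 2900),
                              protrusion_count = 6L, protrusion_amp = 0.06,
                              elongation = 1.1, nucleus_area_fraction = 0.12,
                              yaptaz_nuc_ring_ratio = yaptaz_nuc_ring_ratio),
    triangular = shape_spec("triangular", cell_area_range = c(1000, 1300),
                            protrusion_count = 3L, protrusion_amp = 0.45,
                            elongation = 1.15, nucleus_area_fraction = 0.18,
                            yaptaz_nuc_ring_ratio = yaptaz_nuc_ring_ratio),
    fan = shape_spec("fan", cell_area_range = c(1000, 1300),
                     protrusion_count = 0L, protrusion_amp = 0.04,
                     elongation = 1.25, asymmetry = 0.40,
                     nucleus_area_fraction = 0.18, nucleus_offset = 0.30,
                     yaptaz_nuc_ring_ratio = yaptaz_nuc_ring_ratio),
    small_round = shape_spec("small_round", cell_area_range = c(320, 440),
                             protrusion_count = 0L, protrusion_amp = 0.03,
                             elongation = 1, nucleus_area_fraction = 0.32,
                             yaptaz_nuc_ring_ratio = yaptaz_nuc_ring_ratio)
  )
}

# smooth multiplicative texture field with mean 1
texture_field <- function(d, amplitude, smooth_sigma = 1.5) {
  if (amplitude <= 0) return(matrix(1, d[1], d[2]))
  g <- matrix(rnorm(prod(d)), d[1], d[2])
  g <- mat(EBImage::gblur(g, sigma = smooth_sigma))
  g <- (g - mean(g)) / sd(g)
  1 + amplitude * pmax(pmin(g, 3), -3) / 3 * 0.9
}

#' Render one synthetic cell
#'
#' Draws a cell and nucleus mask realising the class geometry and renders the
#' four channels (`hoechst`, `tubulin`, `actin`, `yaptaz`) noiselessly on a
#' local patch. The YAP/TAZ channel is two-level (cytoplasm level and
#' `ratio * cytoplasm level` in the nucleus) so that the mean nuclear to mean
#' perinuclear intensity ratio equals `spec$yaptaz_nuc_ring_ratio` exactly
#' before noise. Uses the current RNG state; seed with `set.seed()` for
#' reproducibility.
#'
#' @param spec a [shape_spec()].
#' @param n_nuclei number of nuclei to draw (>= 2 emulates cytokinesis
#'   failure); total nuclear area is preserved.
#' @param rotation cell orientation in radians, or `NULL` for random.
#' @return list with elements `cell` (logical matrix), `nuclei` (integer
#'   label matrix, one label per nucleus), `channels` (named list of numeric
#'   matrices) and `truth` (list of ground-truth quantities).
#' @export
render_cell <- function(spec, n_nuclei = 1L, rotation = NULL) {
  stopifnot(inherits(spec, "shape_spec"), n_nuclei >= 1)
  area <- runif(1, spec$cell_area_range[1], spec$cell_area_range[2])
  amp <- spec$protrusion_amp
  asym <- spec$asymmetry
  # area of r(t)=R0(1 + amp*cos(k t) + asym*cos(t)) is
  # pi R0^2 (1 + amp^2/2 + asym^2/2) for k >= 2 (cross terms vanish)
  R0 <- sqrt(area / (pi * (1 + amp^2 / 2 + asym^2 / 2)))
  if (is.null(rotation)) rotation <- runif(1, 0, 2 * pi)
  a <- sqrt(spec$elongation)
  half <- ceiling(R0 * (1 + amp + asym) * a) + 4L
  side <- 2L * half + 1L
  cx <- half + 1L
  xs <- seq_len(side) - cx
  x <- matrix(xs, side, side)
  y <- matrix(xs, side, side, byrow = TRUE)
  # rotate into the cell frame, then undo the (area-preserving) elongation
  xr <- cos(rotation) * x + sin(rotation) * y
  yr <- -sin(rotation) * x + cos(rotation) * y
  xe <- xr / a
  ye <- yr * a
  r <- sqrt(xe^2 + ye^2)
  th <- atan2(ye, xe)
  k <- max(spec$protrusion_count, 0L)
  rb <- R0 * (1 + (if (k > 0) amp * cos(k * th) else 0) + asym * cos(th))
  cell <- r <= rb
  if (sum(cell) < 16) stop("degenerate geometry: cell mask nearly empty")

  # nucleus: ellipse(s) strictly inside the cell
  nuc_area <- spec$nucleus_area_fraction * sum(cell)
  interior <- erode_mask(cell, brush_disc(1))
  nuclei <- matrix(0L, side, side)
  centres <- if (n_nuclei == 1L) {
    off <- spec$nucleus_offset * R0
    list(c(off, 0))
  } else {
    rn1 <- sqrt(nuc_area / n_nuclei / pi)
    ang0 <- runif(1, 0, 2 * pi)
    lapply(seq_len(n_nuclei), function(i) {
      ang <- ang0 + 2 * pi * (i - 1) / n_nuclei
      d0 <- 1.15 * rn1 * (if (n_nuclei == 2) 1 else 1.3)
      c(d0 * cos(ang) + spec$nucleus_offset * R0, d0 * sin(ang))
    })
  }
  rn <- sqrt(nuc_area / n_nuclei / pi)
  ar_n <- sqrt(min(spec$elongation, 2))  # nuclei mildly follow cell elongation
  for (i in seq_along(centres)) {
    cc <- centres[[i]]
    nm <- ((xe - cc[1]) / (rn * ar_n))^2 + ((ye - cc[2]) / (rn / ar_n))^2 <= 1
    nm <- nm & interior & nuclei == 0L
    if (!sum(nm)) stop("degenerate geometry: nucleus does not fit inside cell")
    nuclei[nm] <- i
  }

  lv <- spec$channel_levels
  ta <- spec$texture_amplitude
  nucm <- nuclei > 0L
  cyto <- cell & !nucm
  d <- dim(cell)
  ch <- list(
    hoechst    = lv[["hoechst"]] * nucm * texture_field(d, ta[["hoechst"]]),
    tubulin = lv[["tubulin"]] * cell * texture_field(d, ta[["tubulin"]]),
    actin   = lv[["actin"]] * cell * texture_field(d, ta[["actin"]]),
    yaptaz  = lv[["yaptaz"]] * (cyto + spec$yaptaz_nuc_ring_ratio * nucm)
  )
  list(
    cell = cell,
    nuclei = nuclei,
    channels = ch,
    truth = list(
      shape_class = spec$shape_class,
      area = sum(cell),
      n_nuclei = as.integer(n_nuclei),
      yaptaz_ratio = spec$yaptaz_nuc_ring_ratio,
      yaptaz_level = lv[["yaptaz"]],
      rotation = rotation
    )
  )
}
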