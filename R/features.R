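# The fixed single-cell feature registry and its extraction.
#
# 126 per-cell features: 16 morphology (area, roundness, width, length,
# width/length for nucleus, cell, cytoplasm + membrane protrusion area),
# 8 region-mean intensities, 7 translocation/density ratios, 80 SER textures
# (8 responses x 5 channel-region pairs x 2 scales), 12 Haralick statistics
# (4 x 3 channel-region pairs) and 3 Gabor features. The neighbour fraction
# joins at well level (126 + 1 = 127 well features). Membrane band areas and
# the total-YAP/TAZ hit statistic are carried as auxiliary columns.

#' The fixed feature registry
#'
#' @return data.frame with one row per single-cell feature (`name`, `group`,
#'   `channel`, `region`, `scale`); exactly 126 rows.
#' @export
feature_registry <- function() {
  morph <- expand.grid(
    stat = c("area", "roundness", "width", "length", "width_length_ratio"),
    region = c("nucleus", "cell", "cytoplasm"),
    stringsAsFactors = FALSE)
  morph <- data.frame(
    name = paste(morph$region, morph$stat, sep = "_"),
    group = "morphology", channel = NA_character_, region = morph$region,
    scale = NA_real_)
  morph <- rbind(morph, data.frame(
    name = "membrane_protrusion_area", group = "morphology",
    channel = NA_character_, region = "membrane_protrusion", scale = NA_real_))

  ints <- data.frame(
    name = c("yaptaz_mean_nucleus", "yaptaz_mean_eroded_nucleus",
             "yaptaz_mean_ring", "yaptaz_mean_cytoplasm", "yaptaz_mean_cell",
             "hoechst_mean_nucleus", "tubulin_mean_cytoplasm",
             "tubulin_mean_cell"),
    group = "intensity",
    channel = c(rep("yaptaz", 5), "hoechst", "tubulin", "tubulin"),
    region = c("nucleus", "eroded_nucleus", "ring", "cytoplasm", "cell",
               "nucleus", "cytoplasm", "cell"),
    scale = NA_real_)

  ratios <- data.frame(
    name = c("yaptaz_nuc_ring_ratio", "yaptaz_ratio_log10",
             "yaptaz_erodednuc_ring_ratio", "yaptaz_erodednuc_ratio_log10",
             "yaptaz_nucleus_per_area", "cell_area_per_yaptaz",
             "nuclear_area_per_yaptaz"),
    group = "ratio", channel = "yaptaz", region = NA_character_,
    scale = NA_real_)

  combos <- data.frame(
    channel = c("tubulin", "actin", "hoechst", "tubulin", "actin"),
    region = c("cytoplasm", "cytoplasm", "nucleus", "nucleus", "nucleus"))
  ser <- do.call(rbind, lapply(c(0, 1), function(s) {
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      data.frame(
        name = sprintf("ser_%s_%s_%s_s%d", SER_NAMES, combos$channel[i],
                       combos$region[i], s),
        group = "ser", channel = combos$channel[i], region = combos$region[i],
        scale = s)
    }))
  }))

  hcombos <- combos[c(1, 4, 5), ]
  har <- do.call(rbind, lapply(seq_len(nrow(hcombos)), function(i) {
    data.frame(
      name = sprintf("haralick_%s_%s_%s",
                     c("correlation", "contrast", "variance", "homogeneity"),
                     hcombos$channel[i], hcombos$region[i]),
      group = "haralick", channel = hcombos$channel[i],
      region = hcombos$region[i], scale = 1)
  }))

  gab <- data.frame(
    name = c("gabor_mean_actin_cytoplasm", "gabor_min_actin_cytoplasm",
             "gabor_max_actin_cytoplasm"),
    group = "gabor", channel = "actin", region = "cytoplasm", scale = NA_real_)

  reg <- rbind(morph, ints, ratios, ser, har, gab)
  rownames(reg) <- NULL
  stopifnot(!anyDuplicated(reg$name))
  reg
}

#' Names of the auxiliary (non-registry) per-cell columns
#' @keywords internal
#' @noRd
AUX_COLUMNS <- c("membrane1_area", "membrane2_area", "neighbour_fraction_raw",
                 "neighbour_fraction", "total_yaptaz", "n_nuclei")

mask_moment_axes <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 1) return(c(length = NA_real_, width = NA_real_))
  # 1/12 is the variance of a unit pixel; keeps 1-px-wide masks sane
  v <- cov(idx) * (n - 1) / n + diag(1 / 12, 2)
  if (n == 1) v <- diag(1 / 12, 2)
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  c(length = 4 * sqrt(ev[1]), width = 4 * sqrt(ev[2]))
}

region_shape_stats <- function(mask) {
  a <- sum(mask)
  if (a == 0) {
    return(c(area = NA_real_, roundness = NA_real_, width = NA_real_,
             length = NA_real_, width_length_ratio = NA_real_))
  }
  p <- mask_perimeter(mask)
  ax <- mask_moment_axes(mask)
  c(area = a, roundness = 4 * pi * a / p^2, width = ax[["width"]],
    length = ax[["length"]],
    width_length_ratio = ax[["width"]] / ax[["length"]])
}

#' Morphology features of a region set
#'
#' Area (px^2), roundness `4*pi*A/P^2` (perimeter from exposed pixel edges
#' with the pi/4 digitisation correction), moment-ellipse full axes (length,
#' width) and their ratio, for nucleus, cell and cytoplasm, plus the membrane
#' (protrusion) band area.
#'
#' @param region_set a [build_region_set()] result.
#' @return named numeric vector of 16 values.
#' @export
morphology_features <- function(region_set) {
  out <- c(
    setNames(region_shape_stats(region_set$nucleus),
             paste0("nucleus_", c("area", "roundness", "width", "length",
                                  "width_length_ratio"))),
    setNames(region_shape_stats(region_set$cell),
             paste0("cell_", c("area", "roundness", "width", "length",
                               "width_length_ratio"))),
    setNames(region_shape_stats(region_set$cytoplasm),
             paste0("cytoplasm_", c("area", "roundness", "width", "length",
                                    "width_length_ratio"))),
    membrane_protrusion_area = sum(region_set$membrane_protrusion)
  )
  out
}

region_mean <- function(channel, mask) {
  if (!any(mask)) return(NA_real_)
  mean(channel[mask])
}

#' Region-mean intensity features
#'
#' Mean YAP/TAZ over nucleus, eroded nucleus, ring, cytoplasm and whole
#' cell; mean Hoechst over the nucleus; mean tubulin over cytoplasm and
#' whole cell. Empty regions give `NA`.
#'
#' @param channels named list of rasters (`hoechst`, `tubulin`, `actin`,
#'   `yaptaz`), aligned with the masks.
#' @param region_set a [build_region_set()] result.
#' @return named numeric vector of 8 values.
#' @export
intensity_features <- function(channels, region_set) {
  c(yaptaz_mean_nucleus = region_mean(channels$yaptaz, region_set$nucleus),
    yaptaz_mean_eroded_nucleus = region_mean(channels$yaptaz,
                                             region_set$eroded_nucleus),
    yaptaz_mean_ring = region_mean(channels$yaptaz, region_set$ring),
    yaptaz_mean_cytoplasm = region_mean(channels$yaptaz, region_set$cytoplasm),
    yaptaz_mean_cell = region_mean(channels$yaptaz, region_set$cell),
    hoechst_mean_nucleus = region_mean(channels$hoechst, region_set$nucleus),
    tubulin_mean_cytoplasm = region_mean(channels$tubulin,
                                         region_set$cytoplasm),
    tubulin_mean_cell = region_mean(channels$tubulin, region_set$cell))
}

safe_ratio <- function(num, den) {
  if (is.na(num) || is.na(den) || den <= 0) NA_real_ else num / den
}
safe_log10 <- function(x) if (is.na(x) || x <= 0) NA_real_ else log10(x)

#' Translocation and density ratio features
#'
#' Nucleus:ring and eroded-nucleus:ring YAP/TAZ ratios with their log10
#' ("YAP/TAZ ratio" is `log10(nucleus/ring)`), nuclear YAP/TAZ per nuclear
#' area, and cell/nuclear area per whole-cell YAP/TAZ. Also returns the
#' auxiliary `total_yaptaz` hit statistic: (nuclear + ring mean YAP/TAZ) /
#' nuclear area. Zero or missing denominators give `NA`, never infinity.
#'
#' @param intensities vector from [intensity_features()].
#' @param morphology vector from [morphology_features()].
#' @return named numeric vector of 7 registry ratios + `total_yaptaz`.
#' @export
ratio_features <- function(intensities, morphology) {
  nuc <- intensities[["yaptaz_mean_nucleus"]]
  ring <- intensities[["yaptaz_mean_ring"]]
  ero <- intensities[["yaptaz_mean_eroded_nucleus"]]
  cell_yap <- intensities[["yaptaz_mean_cell"]]
  na <- morphology[["nucleus_area"]]
  ca <- morphology[["cell_area"]]
  r1 <- safe_ratio(nuc, ring)
  r2 <- safe_ratio(ero, ring)
  c(yaptaz_nuc_ring_ratio = r1,
    yaptaz_ratio_log10 = safe_log10(r1),
    yaptaz_erodednuc_ring_ratio = r2,
    yaptaz_erodednuc_ratio_log10 = safe_log10(r2),
    yaptaz_nucleus_per_area = safe_ratio(nuc, na),
    cell_area_per_yaptaz = safe_ratio(ca, cell_yap),
    nuclear_area_per_yaptaz = safe_ratio(na, cell_yap),
    total_yaptaz = safe_ratio(nuc + ring, na))
}

#' Neighbour fraction from membrane band areas
#'
#' The formula-faithful statistic `1 - A1 / (2 * A2)`, clamped to \[0, 1\]
#' (`A2 = 0`, a fully enclosed cell, gives 1). With 1-px bands an isolated
#' cell has `A1 ~ A2`, so the raw value sits near 0.5; see
#' [extract_all()] for the calibrated companion (0 = isolated, 1 =
#' enclosed) computed from the geometric outside band.
#'
#' @param area_m1 inside membrane band area (px^2).
#' @param area_m2 outside membrane band area after neighbour clipping (px^2).
#' @return dimensionless value in \[0, 1\].
#' @export
neighbour_fraction <- function(area_m1, area_m2) {
  if (is.na(area_m1) || is.na(area_m2)) return(NA_real_)
  if (area_m2 <= 0) return(1)
  min(1, max(0, 1 - area_m1 / (2 * area_m2)))
}

# Feature vector (126 registry values + auxiliaries) for one cell patch.
cell_feature_vector <- function(channels, region_set, config) {
  fp <- config$features
  morph <- morphology_features(region_set)
  ints <- intensity_features(channels, region_set)
  rats <- ratio_features(ints, morph)

  combos <- list(c("tubulin", "cytoplasm"), c("actin", "cytoplasm"),
                 c("hoechst", "nucleus"), c("tubulin", "nucleus"),
                 c("actin", "nucleus"))
  ser <- numeric(0)
  for (s in fp$ser_scales) {
    stacks <- list()
    for (cmb in combos) {
      ch <- cmb[1]
      if (is.null(stacks[[ch]])) {
        stacks[[ch]] <- ser_response_stack(channels[[ch]], fp$ser_sigma0 + s)
      }
      region <- region_set[[cmb[2]]]
      vals <- if (any(region)) {
        vapply(stacks[[ch]], function(r) mean(r[region]), numeric(1))
      } else setNames(rep(NA_real_, 8), SER_NAMES)
      names(vals) <- sprintf("ser_%s_%s_%s_s%d", SER_NAMES, cmb[1], cmb[2], s)
      ser <- c(ser, vals)
    }
  }

  har <- numeric(0)
  for (cmb in list(c("tubulin", "cytoplasm"), c("tubulin", "nucleus"),
                   c("actin", "nucleus"))) {
    region <- region_set[[cmb[2]]]
    vals <- if (sum(region) >= 2) {
      haralick_features(channels[[cmb[1]]], region,
                        distance = fp$haralick_distance,
                        levels = fp$haralick_levels)
    } else c(correlation = NA_real_, contrast = NA_real_,
             variance = NA_real_, homogeneity = NA_real_)
    names(vals) <- sprintf("haralick_%s_%s_%s", names(vals), cmb[1], cmb[2])
    har <- c(har, vals)
  }

  gab <- if (any(region_set$cytoplasm)) {
    gabor_features(channels$actin, region_set$cytoplasm,
                   wavelength = fp$gabor_wavelength,
                   n_orient = fp$gabor_orientations)
  } else c(gabor_mean = NA_real_, gabor_min = NA_real_, gabor_max = NA_real_)
  names(gab) <- paste0(names(gab), "_actin_cytoplasm")

  a1 <- sum(region_set$membrane1)
  a2 <- sum(region_set$membrane2)
  # geometric outside band (no neighbour clipping) for the calibrated value
  a2_geom <- sum(dilate_mask(region_set$cell,
                             EBImage::makeBrush(3L, shape = "diamond")) &
                   !region_set$cell)
  aux <- c(membrane1_area = a1, membrane2_area = a2,
           neighbour_fraction_raw = neighbour_fraction(a1, a2),
           neighbour_fraction = if (a2_geom > 0) {
             min(1, max(0, 1 - a2 / a2_geom))
           } else 1,
           total_yaptaz = rats[["total_yaptaz"]])

  c(morph, ints, rats[setdiff(names(rats), "total_yaptaz")], ser, har, gab, aux)
}

#' Extract the full feature table of a segmented field
#'
#' Computes the 126 registry features plus auxiliary columns (membrane band
#' areas, raw and calibrated neighbour fraction, total YAP/TAZ, nucleus
#' count) for every retained cell. Per-feature failures become `NA`; a cell
#' never aborts the field.
#'
#' @param field a `field_image` (list with `$channels`) or a named list of
#'   channel rasters.
#' @param cells,nuclei aligned integer label masks.
#' @param config see [default_config()].
#' @return data.frame with columns `cell`, `x`, `y`, the 126 registry names,
#'   and the auxiliary columns; one row per cell (0 rows, full header, for an
#'   empty field).
#' @export
extract_all <- function(field, cells, nuclei, config = default_config()) {
  channels <- if (!is.null(field$channels)) field$channels else field
  stopifnot(all(dim(channels[[1]]) == dim(cells)),
            all(dim(cells) == dim(nuclei)))
  reg <- feature_registry()
  ids <- label_ids(cells)
  empty <- as.data.frame(setNames(
    rep(list(numeric(0)), 3 + nrow(reg) + length(AUX_COLUMNS)),
    c("cell", "x", "y", reg$name, AUX_COLUMNS)))
  if (!length(ids)) return(empty)
  margin <- 12L
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    own <- cells == id
    bb <- mask_bbox(own, margin = margin)
    cm <- crop_bbox(own, bb)
    nm <- crop_bbox(nuclei, bb) == id
    labs <- crop_bbox(cells, bb)
    chans <- lapply(channels, crop_bbox, bb = bb)
    row <- tryCatch({
      rs <- suppressWarnings(
        build_region_set(cm, nm, labels = labs, label = id, config = config))
      fv <- cell_feature_vector(chans, rs, config)
      n_nuc <- if (any(nm)) max(mat(EBImage::bwlabel(nm * 1))) else 0L
      ctr <- colMeans(which(own, arr.ind = TRUE))
      c(cell = id, x = ctr[[1]], y = ctr[[2]], fv[setdiff(names(fv), "n_nuclei")],
        n_nuclei = n_nuc)
    }, error = function(e) {
      warning(sprintf("cell %d: %s (features set to NA)", id, conditionMessage(e)))
      v <- setNames(rep(NA_real_, 3 + nrow(reg) + length(AUX_COLUMNS)),
                    c("cell", "x", "y", reg$name, AUX_COLUMNS))
      v["cell"] <- id
      v
    })
    rows[[k]] <- row
  }
  out <- as.data.frame(do.call(rbind, rows))
  # enforce registry column order
  out <- out[, c("cell", "x", "y", reg$name, AUX_COLUMNS)]
  rownames(out) <- NULL
  out
}

#' Aggregate a per-cell table to a well profile
#'
#' Per-feature mean over cells, ignoring missing values, for the 126
#' registry features; the well-mean calibrated neighbour fraction joins as
#' the 127th feature. Cell count, shape-class counts (when labels are
#' supplied) and the auxiliary means are appended as metadata columns, and
#' the per-feature missingness fraction is attached as an attribute.
#'
#' @param cell_table a table from [extract_all()].
#' @param well well id to record.
#' @param shape_labels optional per-cell shape labels (factor/character).
#' @return one-row data.frame: `well`, `n_cells`, 126 feature means,
#'   `neighbour_fraction`, auxiliary means, and `n_<class>` counts.
#' @export
aggregate_well <- function(cell_table, well = NA_character_,
                           shape_labels = NULL) {
  reg <- feature_registry()
  feat_names <- c(reg$name, "neighbour_fraction")
  n <- nrow(cell_table)
  means <- if (n) {
    vapply(c(feat_names, "neighbour_fraction_raw", "total_yaptaz"),
           function(f) mean(cell_table[[f]], na.rm = TRUE), numeric(1))
  } else {
    setNames(rep(NA_real_, length(feat_names) + 2),
             c(feat_names, "neighbour_fraction_raw", "total_yaptaz"))
  }
  means[is.nan(means)] <- NA_real_
  multinuc <- if (n) 100 * mean(cell_table$n_nuclei >= 2, na.rm = TRUE) else NA_real_
  prof <- data.frame(well = well, n_cells = n, t(means),
                     multinucleate_pct = multinuc, check.names = FALSE)
  if (!is.null(shape_labels)) {
    for (cls in SHAPE_CLASSES) {
      prof[[paste0("n_", cls)]] <- sum(shape_labels == cls)
    }
  }
  miss <- if (n) {
    vapply(reg$name, function(f) mean(is.na(cell_table[[f]])), numeric(1))
  } else setNames(rep(NA_real_, nrow(reg)), reg$name)
  attr(prof, "missing_fraction") <- miss
  prof
}
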