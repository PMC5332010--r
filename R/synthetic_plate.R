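# Whole-plate simulation: per-well fields with role-driven phenotypes.

#' Specify a plate simulation
#'
#' Wells draw cells from a baseline shape mixture; positive-control roles
#' apply the screen's documented phenotypes: LATS1-like wells raise the
#' nuclear:ring YAP/TAZ ratio (log10 shift), YAP-like wells reduce total
#' YAP/TAZ intensity, and ECT2-like wells raise the multinucleate and
#' large-spread fractions. Density-dilution wells on columns 1, 2, 23 and 24
#' scale the number of rendered cells with the plated density.
#'
#' @param layout plate layout data.frame (see [default_plate_layout()]).
#' @param baseline_weights named mixture weights over [shape_library()]
#'   classes; must sum to 1.
#' @param baseline_ratio baseline nucleus:ring YAP/TAZ ratio.
#' @param n_cells cells per field for non-dilution wells.
#' @param image_shape field size in px.
#' @param noise camera model, as in [field_spec()].
#' @param fields_per_well fields imaged per well.
#' @param effects optional named list (by well id) of per-well effect lists
#'   with any of `log_ratio_shift`, `yap_scale`, `multinucleate_fraction`,
#'   `weight_shift` (named vector added to baseline weights, renormalised),
#'   overriding the role defaults.
#' @param control_effects role-default effects; see source for the defaults.
#' @param dilution_cells_per_plated rendered cells per 1000 plated (dilution
#'   wells).
#' @param contact_probability cell-contact probability per placement.
#' @param rng_seed integer master seed; each well derives its own substream.
#' @param wells optional character vector restricting simulation to a subset
#'   of wells (layout metadata is kept for all 384).
#' @return a `plate_sim_spec` list.
#' @export
plate_sim_spec <- function(layout = default_plate_layout(),
                           baseline_weights = c(spindly = 0.2,
                                                large_spread = 0.2,
                                                triangular = 0.2,
                                                fan = 0.2,
                                                small_round = 0.2),
                           baseline_ratio = 1.5,
                           n_cells = 25L,
                           image_shape = c(320L, 320L),
                           noise = list(gain = 2, sigma = 2),
                           fields_per_well = 1L,
                           effects = list(),
                           control_effects = list(
                             control_lats1 = list(log_ratio_shift = 0.3),
                             control_yap   = list(yap_scale = 0.5),
                             control_ect2  = list(
                               multinucleate_fraction = 0.5,
                               weight_shift = c(large_spread = 0.4))
                           ),
                           dilution_cells_per_plated = 12 / 1000,
                           contact_probability = 0.1,
                           rng_seed = 1L,
                           wells = NULL) {
  validate_layout(layout)
  stopifnot(abs(sum(baseline_weights) - 1) < 1e-8,
            all(names(baseline_weights) %in% SHAPE_CLASSES))
  bad <- setdiff(names(effects), layout$well)
  if (length(bad)) stop("effect map names unknown wells: ", toString(bad))
  if (!is.null(wells)) {
    bad <- setdiff(wells, layout$well)
    if (length(bad)) stop("unknown wells requested: ", toString(bad))
  }
  structure(list(layout = layout, baseline_weights = baseline_weights,
                 baseline_ratio = baseline_ratio, n_cells = as.integer(n_cells),
                 image_shape = as.integer(image_shape), noise = noise,
                 fields_per_well = as.integer(fields_per_well),
                 effects = effects, control_effects = control_effects,
                 dilution_cells_per_plated = dilution_cells_per_plated,
                 contact_probability = contact_probability,
                 rng_seed = as.integer(rng_seed), wells = wells),
            class = "plate_sim_spec")
}

well_effect <- function(pspec, well, role) {
  eff <- list(log_ratio_shift = 0, yap_scale = 1,
              multinucleate_fraction = 0, weight_shift = NULL)
  if (role %in% names(pspec$control_effects)) {
    eff <- modifyList(eff, pspec$control_effects[[role]])
  }
  if (well %in% names(pspec$effects)) {
    eff <- modifyList(eff, pspec$effects[[well]])
  }
  eff
}

#' Simulate a synthetic screening plate
#'
#' Renders one or more fields per well according to the layout roles and
#' effect map of a [plate_sim_spec()]. Deterministic: each well uses a seed
#' derived from `rng_seed` and its position, so simulating a subset of wells
#' reproduces exactly the wells of a full-plate run.
#'
#' @param pspec a [plate_sim_spec()].
#' @return list with `wells` (named list; per well: `fields` = list of
#'   [render_field()] results, `role`, `gene`, `effect`) and `truth` (per-well
#'   bookkeeping data.frame with true mean log10 ratio, multinucleate and
#'   class fractions).
#' @export
simulate_plate <- function(pspec) {
  stopifnot(inherits(pspec, "plate_sim_spec"))
  lay <- pspec$layout
  todo <- if (is.null(pspec$wells)) lay$well else pspec$wells
  lib <- shape_library(pspec$baseline_ratio)
  out <- list()
  truth_rows <- list()
  for (w in todo) {
    i <- match(w, lay$well)
    role <- lay$role[i]
    eff <- well_effect(pspec, w, role)
    wts <- pspec$baseline_weights
    if (!is.null(eff$weight_shift)) {
      wts[names(eff$weight_shift)] <- wts[names(eff$weight_shift)] +
        eff$weight_shift
      wts <- wts / sum(wts)
    }
    ratio <- pspec$baseline_ratio * 10^eff$log_ratio_shift
    specs <- lapply(lib[names(wts)], function(s) {
      s$yaptaz_nuc_ring_ratio <- ratio
      s$channel_levels[["yaptaz"]] <- s$channel_levels[["yaptaz"]] * eff$yap_scale
      s
    })
    n_cells <- if (role == "dilution") {
      max(3L, round(lay$cells_plated[i] * pspec$dilution_cells_per_plated))
    } else pspec$n_cells
    # keep the cell density placeable: grow the field with the cell count
    shape <- pspec$image_shape
    if (n_cells > pspec$n_cells) {
      shape <- as.integer(ceiling(shape * sqrt(n_cells / pspec$n_cells)))
    }
    seed <- (pspec$rng_seed * 7919L + i * 104729L) %% 2147483629L
    fields <- lapply(seq_len(pspec$fields_per_well), function(k) {
      fs <- field_spec(image_shape = shape, n_cells = n_cells,
                       contact_probability = pspec$contact_probability,
                       multinucleate_fraction = eff$multinucleate_fraction,
                       noise = pspec$noise,
                       rng_seed = (seed + k) %% 2147483629L)
      render_field(fs, specs, as.numeric(wts))
    })
    tabs <- do.call(rbind, lapply(fields, function(f) f$truth$table))
    truth_rows[[w]] <- data.frame(
      well = w, role = role, gene = lay$gene[i],
      cells_plated = lay$cells_plated[i],
      n_cells = nrow(tabs),
      mean_log10_ratio = mean(log10(tabs$yaptaz_ratio)),
      multinucleate_fraction = mean(tabs$n_nuclei >= 2),
      prop_spindly = mean(tabs$shape_class == "spindly"),
      prop_large_spread = mean(tabs$shape_class == "large_spread"),
      prop_triangular = mean(tabs$shape_class == "triangular"),
      prop_fan = mean(tabs$shape_class == "fan"),
      prop_small_round = mean(tabs$shape_class == "small_round")
    )
    out[[w]] <- list(fields = fields, role = role, gene = lay$gene[i],
                     effect = eff)
  }
  list(wells = out, truth = do.call(rbind, truth_rows), layout = lay)
}
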