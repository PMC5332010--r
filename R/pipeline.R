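# End-to-end pipeline: plate simulation -> segmentation -> features ->
# shape classification -> screen statistics -> QC.

#' Segment one field and extract its feature table
#'
#' Convenience wrapper chaining [segment_nuclei()], [segment_cells()],
#' [filter_border()] and [extract_all()].
#'
#' @param field a `field_image` or named list of channel rasters.
#' @param config see [default_config()].
#' @return list: `cells`, `nuclei` (label masks after border filtering),
#'   `features` (per-cell table), `multinucleate` (see
#'   [detect_multinucleate()]).
#' @export
process_field <- function(field, config = default_config()) {
  channels <- if (!is.null(field$channels)) field$channels else field
  nuc <- segment_nuclei(channels$hoechst, config)
  cells <- segment_cells(channels$tubulin, nuc, config)
  fb <- filter_border(cells, nuc)
  feats <- extract_all(channels, fb$cells, fb$nuclei, config)
  mn <- detect_multinucleate(channels$tubulin, nuc, config)
  list(cells = fb$cells, nuclei = fb$nuclei, features = feats,
       multinucleate = mn)
}

#' Wells of the bundled demo plate
#'
#' A 34-well subset of the default 384-well layout exercising every role:
#' mock negative controls, sample wells, the three positive-control blocks
#' and a 4-density dilution series.
#'
#' @param layout a plate layout (see [default_plate_layout()]).
#' @return character vector of well ids.
#' @export
demo_wells <- function(layout = default_plate_layout()) {
  pick <- function(role, n) head(layout$well[layout$role == role], n)
  dil <- layout$well[layout$role == "dilution" & layout$col == 1]
  c(pick("mock", 8), pick("sample", 6),
    pick("control_lats1", 4), pick("control_yap", 4), pick("control_ect2", 4),
    dil[c(1, 2, 5, 6, 9, 10, 13, 14)])   # two wells per density block
}

#' Run the full screen pipeline on simulated plates
#'
#' Simulates replicate plates, segments every field, extracts the
#' 126-feature profile, classifies cells into the five reference shapes,
#' aggregates to wells, plate-normalises, computes control-referenced
#' Z-scores and hits, fits the density regression, and assembles the QC
#' report (replicate-plate correlations and Z' factors).
#'
#' @param plates character vector of replicate plate ids to simulate.
#' @param wells wells to simulate per plate (default: the demo subset).
#' @param effects per-well effect map passed to [plate_sim_spec()].
#' @param n_cells cells per field.
#' @param model optional pre-trained `shape_model`; trained from a synthetic
#'   labelled bank when `NULL`.
#' @param train_per_class training cells per class when training here.
#' @param seed master seed (plate simulation, training, QC null draws).
#' @param config see [default_config()].
#' @param outdir optional output directory; when given, writes per-plate
#'   feature tables (tab-delimited), the hit list and QC summary (CSV), the
#'   shape model and the configuration (YAML).
#' @return list: `well_table`, `hits`, `qc`, `density_fit`, `model`,
#'   `truth`, `config`.
#' @export
run_screen_pipeline <- function(plates = c("1A", "1B"),
                                wells = NULL,
                                effects = list(),
                                n_cells = 18L,
                                model = NULL,
                                train_per_class = 120L,
                                seed = 1L,
                                config = default_config(),
                                outdir = NULL) {
  if (is.null(model)) {
    tr <- make_training_set(n_per_class = train_per_class, seed = seed + 101L,
                            config = config)
    model <- train_shape_classifier(tr$features, tr$labels,
                                    lambda = config$classify$lambda)
  }
  reg <- feature_registry()
  well_rows <- list()
  truth_rows <- list()
  feature_mats <- list()
  for (pi in seq_along(plates)) {
    p <- plates[pi]
    layout <- default_plate_layout(plate = p)
    ws <- if (is.null(wells)) demo_wells(layout) else wells
    pspec <- plate_sim_spec(layout = layout, n_cells = n_cells,
                            effects = effects,
                            rng_seed = (seed * 131L + pi) %% 2147483629L,
                            wells = ws)
    sim <- simulate_plate(pspec)
    for (w in names(sim$wells)) {
      wt <- sim$wells[[w]]
      tabs <- list()
      mn_pcts <- numeric(0)
      for (f in wt$fields) {
        pf <- process_field(f$image, config)
        tabs[[length(tabs) + 1L]] <- pf$features
        mn_pcts <- c(mn_pcts, pf$multinucleate$percent)
      }
      cell_tab <- do.call(rbind, tabs)
      labels <- if (nrow(cell_tab)) {
        classify_shapes(model, cell_tab)$class
      } else character(0)
      prof <- aggregate_well(cell_tab, well = w, shape_labels = labels)
      prof$multinucleate_pct <- mean(mn_pcts, na.rm = TRUE)
      i <- match(w, layout$well)
      prof$plate <- p
      prof$role <- layout$role[i]
      prof$gene <- layout$gene[i]
      prof$cells_plated <- layout$cells_plated[i]
      for (cls in SHAPE_CLASSES) {
        prof[[paste0("prop_", cls)]] <-
          prof[[paste0("n_", cls)]] / max(1L, prof$n_cells)
      }
      well_rows[[paste(p, w)]] <- prof
    }
    st <- sim$truth
    st$plate <- p
    truth_rows[[p]] <- st
  }
  well_table <- do.call(rbind, well_rows)
  rownames(well_table) <- NULL

  hit_features <- c(paste0("prop_", SHAPE_CLASSES), "yaptaz_ratio_log10",
                    "total_yaptaz", "multinucleate_pct")
  analysed <- well_table$role %in% c("sample", "mock", "control_lats1",
                                     "control_yap", "control_ect2")
  tab <- well_table[analysed, ]
  tab <- plate_normalise(tab, hit_features, method = config$screen$normalise)
  ctrl <- tab$role == "mock"
  tab <- zscore_to_controls(tab, paste0(hit_features, "_norm"), ctrl)
  # rename z columns back to the raw feature for hit calling
  for (f in hit_features) {
    zc <- paste0(f, "_norm_z")
    if (zc %in% names(tab)) tab[[paste0(f, "_z")]] <- tab[[zc]]
  }
  hits <- call_hits(tab, hit_features, ctrl,
                    threshold = config$screen$hit_threshold)

  dil <- well_table$role == "dilution"
  density_fit <- if (sum(dil) >= 3 &&
                     length(unique(well_table$cells_plated[dil])) >= 3) {
    density_regression(well_table$cells_plated[dil],
                       well_table$yaptaz_ratio_log10[dil])
  } else NULL

  # QC: replicate correlation between consecutive plate pairs on the
  # 126-feature profiles; Z' per positive-control arm on its readout
  qc <- list()
  if (length(plates) >= 2) {
    wA <- well_table[well_table$plate == plates[1], ]
    wB <- well_table[well_table$plate == plates[2], ]
    common <- intersect(wA$well, wB$well)
    qc$replicate <- replicate_correlation(
      wA[match(common, wA$well), reg$name],
      wB[match(common, wB$well), reg$name])
  }
  mock_vals <- function(f) well_table[[f]][well_table$role == "mock"]
  arm <- function(role, f) well_table[[f]][well_table$role == role]
  qc$zprime <- list(
    lats1 = tryCatch(zprime(arm("control_lats1", "yaptaz_ratio_log10"),
                            mock_vals("yaptaz_ratio_log10")),
                     error = function(e) NA_real_),
    yap = tryCatch(zprime(arm("control_yap", "total_yaptaz"),
                          mock_vals("total_yaptaz")),
                   error = function(e) NA_real_),
    ect2 = tryCatch(zprime(arm("control_ect2", "multinucleate_pct"),
                           mock_vals("multinucleate_pct")),
                    error = function(e) NA_real_))

  out <- list(well_table = well_table, hits = hits, qc = qc,
              density_fit = density_fit, model = model,
              truth = do.call(rbind, truth_rows), config = config,
              seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (p in plates) {
      wt <- well_table[well_table$plate == p, ]
      wt$gene[wt$role == "dilution"] <- as.character(
        wt$cells_plated[wt$role == "dilution"])
      write_feature_table(wt, file.path(outdir, paste0("features_", p, ".tsv")))
    }
    write.csv(hits, file.path(outdir, "hits.csv"), row.names = FALSE)
    qc_df <- data.frame(
      metric = c("replicate_diag_median", "replicate_offdiag_median",
                 "replicate_p_value", "zprime_lats1", "zprime_yap",
                 "zprime_ect2"),
      value = c(
        if (!is.null(qc$replicate)) median(qc$replicate$diagonal) else NA,
        if (!is.null(qc$replicate)) median(qc$replicate$off_diagonal) else NA,
        if (!is.null(qc$replicate)) qc$replicate$p_value else NA,
        as.numeric(qc$zprime$lats1), as.numeric(qc$zprime$yap),
        as.numeric(qc$zprime$ect2)))
    write.csv(qc_df, file.path(outdir, "qc_report.csv"), row.names = FALSE)
    write_shape_model(model, file.path(outdir, "shape_model.txt"))
    write_config(config, file.path(outdir, "config.yaml"))
  }
  out
}
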