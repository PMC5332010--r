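# Feature registry, morphology/intensity/ratio features, extraction,
# well aggregation.

test_that("the registry enumerates exactly the fixed feature set", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 126)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_equal(as.vector(table(reg$group)[c("morphology", "intensity",
                                            "ratio", "ser", "haralick",
                                            "gabor")]),
               c(16, 8, 7, 80, 12, 3))
  expect_equal(length(SHAPE_CLASSES), 5)
})

test_that("morphology features match analytic fixtures", {
  cell <- disc_mask(50, 121)
  nuc <- disc_mask(20, 121)
  rs <- build_region_set(cell, nuc)
  m <- morphology_features(rs)
  expect_equal(length(m), 16)
  expect_lt(abs(m[["cell_roundness"]] - 1), 0.05)
  expect_lt(abs(m[["cell_width_length_ratio"]] - 1), 0.02)
  # set identity: cytoplasm area = cell - nucleus, exactly
  expect_equal(m[["cytoplasm_area"]], m[["cell_area"]] - m[["nucleus_area"]])
  # rectangle 100 x 20: width/length ratio 0.2, axes within the documented
  # moment-ellipse convention (15%)
  rect <- rect_mask(100, 20)
  rs2 <- build_region_set(rect, rect_mask(20, 8, S = 120))
  m2 <- morphology_features(rs2)
  expect_lt(abs(m2[["cell_width_length_ratio"]] - 0.2), 0.02)
  # moment-ellipse axis of a uniform 100-px rod: 4 * sqrt((100^2 - 1) / 12)
  expect_lt(abs(m2[["cell_length"]] / (4 * sqrt((100^2 - 1) / 12)) - 1), 0.02)
  expect_lt(abs(m2[["cell_length"]] / 100 - 1), 0.16)
})

test_that("intensity features are region means with NA for empty regions", {
  cell <- disc_mask(40, 101)
  nuc <- disc_mask(16, 101)
  rs <- build_region_set(cell, nuc)
  # constant image: every region mean equals the constant
  ch_const <- matrix(7.5, 101, 101)
  chans <- list(hoechst = ch_const, tubulin = ch_const, actin = ch_const,
                yaptaz = ch_const)
  iv <- intensity_features(chans, rs)
  expect_equal(length(iv), 8)
  expect_true(all(abs(iv - 7.5) < 1e-12))
  # two-level fixture: nucleus 200, elsewhere 100
  two <- matrix(100, 101, 101)
  two[nuc] <- 200
  chans$yaptaz <- two
  iv2 <- intensity_features(chans, rs)
  expect_equal(iv2[["yaptaz_mean_nucleus"]], 200)
  expect_equal(iv2[["yaptaz_mean_ring"]], 100)
  # empty region -> NA
  rs_empty <- rs
  rs_empty$ring <- rs$ring & FALSE
  expect_true(is.na(intensity_features(chans, rs_empty)[["yaptaz_mean_ring"]]))
})

test_that("ratio features follow the arithmetic contract", {
  ints <- c(yaptaz_mean_nucleus = 300, yaptaz_mean_eroded_nucleus = 290,
            yaptaz_mean_ring = 100, yaptaz_mean_cytoplasm = 100,
            yaptaz_mean_cell = 150, hoechst_mean_nucleus = 1,
            tubulin_mean_cytoplasm = 1, tubulin_mean_cell = 1)
  morph <- c(nucleus_area = 200, cell_area = 1000)
  r <- ratio_features(ints, morph)
  expect_equal(r[["yaptaz_nuc_ring_ratio"]], 3)
  expect_equal(r[["yaptaz_ratio_log10"]], log10(3))
  expect_lt(abs(r[["yaptaz_ratio_log10"]] - 0.4771), 1e-3)
  expect_equal(r[["total_yaptaz"]], 400 / 200)
  # uniform image: ratio 1, log 0 exactly
  ints_u <- ints
  ints_u[1:5] <- 100
  r_u <- ratio_features(ints_u, morph)
  expect_equal(r_u[["yaptaz_nuc_ring_ratio"]], 1)
  expect_identical(r_u[["yaptaz_ratio_log10"]], 0)
  # zero ring -> missing, never infinite
  ints_z <- ints
  ints_z[["yaptaz_mean_ring"]] <- 0
  r_z <- ratio_features(ints_z, morph)
  expect_true(is.na(r_z[["yaptaz_nuc_ring_ratio"]]))
  expect_true(is.na(r_z[["yaptaz_ratio_log10"]]))
})

test_that("noiseless renders reproduce the generator translocation ratio", {
  set.seed(5)
  for (target in c(0.5, 1, 2, 4)) {
    sp <- shape_spec("triangular", cell_area_range = c(1000, 1200),
                     protrusion_count = 3L, protrusion_amp = 0.45,
                     yaptaz_nuc_ring_ratio = target)
    rc <- render_cell(sp)
    rs <- build_region_set(rc$cell, rc$nuclei > 0)
    iv <- intensity_features(rc$channels, rs)
    r <- ratio_features(iv, morphology_features(rs))
    expect_lt(abs(r[["yaptaz_nuc_ring_ratio"]] / target - 1), 0.01)
    if (target == 1) expect_identical(r[["yaptaz_ratio_log10"]], 0)
  }
})

test_that("neighbour fraction obeys the formula and the contact oracle", {
  expect_equal(neighbour_fraction(200, 100), 0)
  expect_equal(neighbour_fraction(100, 100), 0.5)
  expect_equal(neighbour_fraction(100, 0), 1)
  # two rendered cells sharing boundary: calibrated value tracks the
  # shared-perimeter oracle within 0.1
  lib <- shape_library()
  fs <- field_spec(image_shape = c(240, 240), n_cells = 2,
                   contact_probability = 1, rng_seed = 19)
  rf <- render_field(fs, lib$large_spread)
  ft <- extract_all(rf$truth$noiseless, rf$truth$cells, rf$truth$nuclei)
  for (id in 1:2) {
    oracle <- shared_boundary_fraction(rf$truth$cells, id)
    expect_lt(abs(ft$neighbour_fraction[ft$cell == id] - oracle), 0.1)
  }
  # isolated cell: raw value near 0.5, calibrated near 0
  fs1 <- field_spec(image_shape = c(160, 160), n_cells = 1, rng_seed = 8)
  rf1 <- render_field(fs1, lib$small_round)
  ft1 <- extract_all(rf1$truth$noiseless, rf1$truth$cells, rf1$truth$nuclei)
  expect_lt(abs(ft1$neighbour_fraction_raw - 0.5), 0.12)
  expect_lt(ft1$neighbour_fraction, 0.05)
})

test_that("extract_all produces the full deterministic table", {
  lib <- shape_library()
  fs <- field_spec(image_shape = c(420, 420), n_cells = 20, rng_seed = 37)
  rf <- render_field(fs, unname(lib), rep(0.2, 5))
  reg <- feature_registry()
  ft <- extract_all(rf$image, rf$truth$cells, rf$truth$nuclei)
  expect_equal(nrow(ft), 20)
  expect_true(all(reg$name %in% names(ft)))
  # empty field keeps the full header
  ft0 <- extract_all(rf$image, matrix(0L, 420, 420), matrix(0L, 420, 420))
  expect_equal(nrow(ft0), 0)
  expect_true(all(reg$name %in% names(ft0)))
  # rerun is bit-identical
  ft2 <- extract_all(rf$image, rf$truth$cells, rf$truth$nuclei)
  expect_identical(ft, ft2)
})

test_that("intensity features shift/scale correctly and textures are local", {
  lib <- shape_library()
  fs <- field_spec(image_shape = c(200, 200), n_cells = 1, rng_seed = 41,
                   noise = list(gain = 0, sigma = 0))
  rf <- render_field(fs, lib$triangular)
  reg <- feature_registry()
  base <- extract_all(rf$image, rf$truth$cells, rf$truth$nuclei)
  # adding a constant outside every mask changes nothing
  out_mask <- rf$truth$cells == 0
  shifted <- lapply(rf$image$channels, function(ch) {
    ch2 <- ch
    ch2[out_mask] <- ch2[out_mask] + 500
    ch2
  })
  ft_s <- extract_all(shifted, rf$truth$cells, rf$truth$nuclei)
  icols <- reg$name[reg$group == "intensity"]
  expect_equal(as.numeric(ft_s[, icols]), as.numeric(base[, icols]))
  # intensity rescaling is linear on the region means
  scaled <- lapply(rf$image$channels, function(ch) ch * 3)
  ft_sc <- extract_all(scaled, rf$truth$cells, rf$truth$nuclei)
  expect_equal(as.numeric(ft_sc[, icols]), 3 * as.numeric(base[, icols]),
               tolerance = 1e-10)
  # translation invariance of textures: shift the whole scene by 7 px
  d <- c(200, 200)
  shift7 <- function(m) {
    out <- matrix(0, d[1], d[2])
    out[8:d[1], 8:d[2]] <- m[1:(d[1] - 7), 1:(d[2] - 7)]
    out
  }
  moved_ch <- lapply(rf$image$channels, shift7)
  moved_cells <- shift7(rf$truth$cells)
  storage.mode(moved_cells) <- "integer"
  moved_nuc <- shift7(rf$truth$nuclei)
  storage.mode(moved_nuc) <- "integer"
  ft_m <- extract_all(moved_ch, moved_cells, moved_nuc)
  tcols <- reg$name[reg$group %in% c("ser", "haralick", "gabor")]
  expect_equal(as.numeric(ft_m[, tcols]), as.numeric(base[, tcols]),
               tolerance = 1e-6)
})

test_that("well aggregation yields the 127-feature profile", {
  lib <- shape_library()
  fs <- field_spec(image_shape = c(300, 300), n_cells = 5, rng_seed = 43)
  rf <- render_field(fs, unname(lib), rep(0.2, 5))
  ft <- extract_all(rf$image, rf$truth$cells, rf$truth$nuclei)
  reg <- feature_registry()
  prof <- aggregate_well(ft, well = "B03",
                         shape_labels = rf$truth$table$shape_class)
  # 126 registry means + neighbour fraction = 127 well-level features
  well_features <- c(reg$name, "neighbour_fraction")
  expect_equal(length(well_features), 127)
  expect_true(all(well_features %in% names(prof)))
  expect_equal(prof$n_cells, 5)
  cnt <- sum(sapply(SHAPE_CLASSES, function(cl) prof[[paste0("n_", cl)]]))
  expect_equal(cnt, 5)
  # mean of two cells with values 1 and 3 is 2
  toy <- ft[1:2, ]
  toy$cell_area <- c(1, 3)
  expect_equal(aggregate_well(toy)$cell_area, 2)
  # single cell: profile equals the cell's vector
  one <- aggregate_well(ft[1, ])
  expect_equal(one$yaptaz_nuc_ring_ratio, ft$yaptaz_nuc_ring_ratio[1])
  # zero cells: NA profile
  empty <- aggregate_well(ft[0, ], well = "A01")
  expect_equal(empty$n_cells, 0)
  expect_true(is.na(empty$cell_area))
})
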