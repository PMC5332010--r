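# Synthetic data generator: single cells, fields, plates.

test_that("rendered cells realise the requested geometry and YAP/TAZ ratio", {
  set.seed(11)
  lib <- shape_library()
  # noiseless nucleus:cytoplasm ratio is exact for every class
  for (target in c(0.5, 1, 2, 4)) {
    sp <- shape_spec("small_round", cell_area_range = c(400, 400),
                     yaptaz_nuc_ring_ratio = target)
    rc <- render_cell(sp)
    nuc <- rc$nuclei > 0
    cyto <- rc$cell & !nuc
    measured <- mean(rc$channels$yaptaz[nuc]) / mean(rc$channels$yaptaz[cyto])
    expect_lt(abs(measured / target - 1), 0.01)
  }
  # spindly elongation 4 -> mask moment axis ratio >= 3
  rc <- render_cell(lib$spindly)
  idx <- which(rc$cell, arr.ind = TRUE)
  ev <- eigen(cov(idx), only.values = TRUE)$values
  expect_gte(sqrt(ev[1] / ev[2]), 3)
  # nucleus strictly inside the cell
  for (cls in names(lib)) {
    rc <- render_cell(lib[[cls]])
    expect_true(all(rc$cell[rc$nuclei > 0]))
    d <- dim(rc$cell)
    expect_false(any(rc$nuclei[c(1, d[1]), ] > 0))
  }
})

test_that("degenerate shape specifications are rejected", {
  expect_error(shape_spec("small_round", nucleus_area_fraction = 0),
               "nucleus_area_fraction")
  expect_error(shape_spec("small_round", elongation = 0.5), "elongation")
  expect_error(shape_spec("small_round", yaptaz_nuc_ring_ratio = -1),
               "yaptaz_nuc_ring_ratio")
  expect_error(shape_spec("small_round", cell_area_range = c(-5, 5)))
})

test_that("fields respect n_cells, mixtures, contacts and determinism", {
  lib <- shape_library()
  # empty field: pure-noise image, empty ground truth
  fs0 <- field_spec(image_shape = c(64, 64), n_cells = 0, rng_seed = 5)
  rf0 <- render_field(fs0, lib$small_round)
  expect_identical(nrow(rf0$truth$table), 0L)
  expect_true(all(rf0$truth$cells == 0L))
  # two-class mixture: class counts inside the exact binomial 99% CI
  fs <- field_spec(image_shape = c(380, 380), n_cells = 25, rng_seed = 7)
  counts <- c(spindly = 0, small_round = 0)
  for (s in 1:8) {
    fs$rng_seed <- 100 + s
    rf <- render_field(fs, list(lib$spindly, lib$small_round), c(0.5, 0.5))
    counts["spindly"] <- counts["spindly"] +
      sum(rf$truth$table$shape_class == "spindly")
    counts["small_round"] <- counts["small_round"] +
      sum(rf$truth$table$shape_class == "small_round")
  }
  n <- sum(counts)
  expect_gte(counts[["spindly"]], qbinom(0.005, n, 0.5))
  expect_lte(counts[["spindly"]], qbinom(0.995, n, 0.5))
  # forced contact: the two masks share an 8-neighbour boundary pair
  fsc <- field_spec(image_shape = c(200, 200), n_cells = 2,
                    contact_probability = 1, rng_seed = 3)
  rfc <- render_field(fsc, lib$small_round)
  m1 <- rfc$truth$cells == 1
  m2 <- rfc$truth$cells == 2
  grown <- morphoscreen:::dilate_mask(m1, EBImage::makeBrush(3, "box"))
  expect_true(any(grown & m2))
  expect_false(any(m1 & m2))
  # identical seeds give bit-identical output
  fsd <- field_spec(image_shape = c(220, 220), n_cells = 5, rng_seed = 42)
  a <- render_field(fsd, unname(lib), rep(0.2, 5))
  b <- render_field(fsd, unname(lib), rep(0.2, 5))
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$table, b$truth$table)
})

test_that("mixture proportions converge to the weights (chi-square GoF)", {
  lib <- shape_library()
  w <- c(0.4, 0.3, 0.2, 0.1)
  specs <- list(lib$spindly, lib$triangular, lib$fan, lib$small_round)
  cls <- c("spindly", "triangular", "fan", "small_round")
  obs <- setNames(numeric(4), cls)
  for (s in 1:25) {
    fs <- field_spec(image_shape = c(380, 380), n_cells = 20,
                     rng_seed = 500 + s)
    rf <- render_field(fs, specs, w)
    tab <- table(factor(rf$truth$table$shape_class, levels = cls))
    obs <- obs + as.numeric(tab)
  }
  gof <- suppressWarnings(chisq.test(obs, p = w))
  expect_gt(gof$p.value, 0.001)
})

test_that("ground truth is recomputable from the noiseless render", {
  lib <- shape_library()
  fs <- field_spec(image_shape = c(300, 300), n_cells = 6, rng_seed = 21)
  rf <- render_field(fs, unname(lib), rep(0.2, 5))
  for (id in rf$truth$table$cell) {
    nuc <- rf$truth$nuclei == id
    cyto <- rf$truth$cells == id & !nuc
    measured <- mean(rf$truth$noiseless$yaptaz[nuc]) /
      mean(rf$truth$noiseless$yaptaz[cyto])
    expect_lt(abs(measured / rf$truth$table$yaptaz_ratio[id] - 1), 0.01)
  }
})

test_that("plate simulation applies the documented control phenotypes", {
  lay <- default_plate_layout()
  lats1 <- head(lay$well[lay$role == "control_lats1"], 1)
  ect2 <- head(lay$well[lay$role == "control_ect2"], 1)
  mock <- head(lay$well[lay$role == "mock"], 3)
  dil <- head(lay$well[lay$role == "dilution"], 1)
  pspec <- plate_sim_spec(layout = lay, n_cells = 12L,
                          image_shape = c(340L, 340L), rng_seed = 9,
                          wells = c(mock, lats1, ect2, dil))
  sim <- simulate_plate(pspec)
  tr <- sim$truth
  base <- mean(tr$mean_log10_ratio[tr$role == "mock"])
  # LATS1-like: +0.3 on the log10 ratio, by generator bookkeeping
  expect_lt(abs((tr$mean_log10_ratio[tr$well == lats1] - base) - 0.3), 0.02)
  # ECT2-like: at least 40% of cells multinucleate under the 0.5 rate
  expect_gte(tr$multinucleate_fraction[tr$well == ect2], 0.3)
  expect_equal(tr$multinucleate_fraction[tr$role == "mock"], rep(0, 3))
  # dilution wells scale cell numbers with plated density
  expect_equal(tr$n_cells[tr$well == dil],
               max(3, round(lay$cells_plated[lay$well == dil] * 12 / 1000)))
  # no-effect wells are exchangeable: Kruskal-Wallis on per-cell areas
  areas <- lapply(mock, function(w) {
    sim$wells[[w]]$fields[[1]]$truth$table$area
  })
  kw <- kruskal.test(areas)
  expect_gt(kw$p.value, 0.01)
})

test_that("subset simulation reproduces the wells of a fuller run", {
  lay <- default_plate_layout()
  mock <- head(lay$well[lay$role == "mock"], 2)
  p1 <- plate_sim_spec(layout = lay, n_cells = 5L, image_shape = c(240L, 240L),
                       rng_seed = 4, wells = mock)
  p2 <- plate_sim_spec(layout = lay, n_cells = 5L, image_shape = c(240L, 240L),
                       rng_seed = 4, wells = mock[2])
  s1 <- simulate_plate(p1)
  s2 <- simulate_plate(p2)
  expect_identical(s1$wells[[mock[2]]]$fields[[1]]$truth$table,
                   s2$wells[[mock[2]]]$fields[[1]]$truth$table)
})
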