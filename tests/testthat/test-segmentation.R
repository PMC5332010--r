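# Segmentation: nuclei, seeded cells, border filtering, multinucleation.

test_that("nucleus segmentation recovers well-separated nuclei with high IoU", {
  set.seed(2)
  S <- 500
  img <- matrix(0, S, S)
  truth <- matrix(0L, S, S)
  centres <- expand.grid(x = seq(40, 460, by = 60), y = seq(40, 460, by = 60))
  centres <- centres[seq_len(50), ]
  for (k in seq_len(nrow(centres))) {
    R <- 9
    x <- matrix(seq_len(S) - centres$x[k], S, S)
    y <- matrix(seq_len(S) - centres$y[k], S, S, byrow = TRUE)
    m <- x^2 + y^2 <= R^2
    img[m] <- 200
    truth[m] <- k
  }
  img <- img + rnorm(S * S, 0, 10)   # SNR = 20
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 50)
  expect_true(all(match_iou(lab, truth) >= 0.8))
})

test_that("touching nuclei are split and degenerate inputs handled", {
  # blank field -> zero nuclei
  expect_equal(max(segment_nuclei(matrix(0, 80, 80))), 0)
  expect_error(segment_nuclei(array(0, c(4, 4, 4))), "2-D")
  # two discs overlapping by a narrow neck -> 2 labels via the
  # distance-transform watershed
  S <- 80
  x <- matrix(seq_len(S), S, S)
  y <- t(x)
  m <- ((x - 30)^2 + (y - 40)^2 <= 100) | ((x - 49)^2 + (y - 40)^2 <= 100)
  lab <- segment_nuclei(m * 200)
  expect_equal(max(lab), 2)
})

test_that("seeded cell segmentation matches ground truth on synthetic fields", {
  lib <- shape_library()
  fs <- field_spec(image_shape = c(220, 220), n_cells = 1, rng_seed = 31)
  rf <- render_field(fs, lib$triangular)
  nuc <- segment_nuclei(rf$image$channels$hoechst)
  cells <- segment_cells(rf$image$channels$tubulin, nuc)
  expect_equal(max(cells), 1)
  expect_gte(iou(cells == 1, rf$truth$cells == 1), 0.8)
  expect_true(all(cells[nuc > 0] == nuc[nuc > 0]))   # nucleus inside its cell
  # empty nuclei mask -> empty cells
  expect_true(all(segment_cells(rf$image$channels$tubulin,
                                matrix(0L, 220, 220)) == 0L))
  # two contacting cells are partitioned into two labels near the truth
  fsc <- field_spec(image_shape = c(260, 260), n_cells = 2,
                    contact_probability = 1, rng_seed = 13)
  rfc <- render_field(fsc, lib$small_round)
  nuc2 <- segment_nuclei(rfc$image$channels$hoechst)
  cells2 <- segment_cells(rfc$image$channels$tubulin, nuc2)
  expect_equal(max(cells2), 2)
  expect_true(all(match_iou(cells2, rfc$truth$cells) >= 0.7))
})

test_that("cells touching the image border are filtered with their nuclei", {
  lib <- shape_library()
  # deliberate placement: 3 of 10 centres on/near the border
  pos <- rbind(c(5, 60), c(60, 3), c(250, 252),     # border cells
               c(60, 120), c(120, 60), c(120, 190), c(190, 120),
               c(190, 190), c(60, 190), c(120, 120))
  fs <- field_spec(image_shape = c(255, 255), n_cells = 10, rng_seed = 17)
  rf <- render_field(fs, lib$small_round, positions = pos, allow_border = TRUE)
  expect_equal(sum(rf$truth$table$touches_border), 3)
  fb <- filter_border(rf$truth$cells, rf$truth$nuclei)
  expect_equal(max(fb$cells), 7)
  # labels contiguous, paired, and nuclei subset of their cells
  expect_identical(sort(unique(as.integer(fb$cells[fb$cells > 0]))), 1:7)
  expect_true(all(fb$cells[fb$nuclei > 0] == fb$nuclei[fb$nuclei > 0]))
  d <- dim(fb$cells)
  expect_true(all(fb$cells[c(1, d[1]), ] == 0) && all(fb$cells[, c(1, d[2])] == 0))
})

test_that("segmentation is deterministic and exact on noiseless fields", {
  lib <- shape_library()
  fs <- field_spec(image_shape = c(300, 300), n_cells = 6,
                   noise = list(gain = 0, sigma = 0), rng_seed = 23)
  rf <- render_field(fs, unname(lib), rep(0.2, 5))
  nuc <- segment_nuclei(rf$image$channels$hoechst)
  cells <- segment_cells(rf$image$channels$tubulin, nuc)
  # 100% recall and precision of cell detection
  expect_equal(max(cells), nrow(rf$truth$table))
  expect_true(all(match_iou(cells, rf$truth$cells) >= 0.9))
  # bijection cells <-> nuclei
  expect_setequal(unique(as.integer(cells[cells > 0])),
                  unique(as.integer(nuc[nuc > 0])))
  nuc2 <- segment_nuclei(rf$image$channels$hoechst)
  expect_identical(nuc, nuc2)
})

test_that("multinucleate percentage is measured cytoplasm-first", {
  lib <- shape_library()
  # mononucleate field -> 0%
  fs <- field_spec(image_shape = c(300, 300), n_cells = 6, rng_seed = 3)
  rf <- render_field(fs, unname(lib), rep(0.2, 5))
  nuc <- segment_nuclei(rf$image$channels$hoechst)
  mn <- detect_multinucleate(rf$image$channels$tubulin, nuc)
  expect_equal(mn$percent, 0)
  # ECT2-like field: measured percentage within 5 points of ground truth
  fsb <- field_spec(image_shape = c(420, 420), n_cells = 30,
                    multinucleate_fraction = 0.5, rng_seed = 29)
  rfb <- render_field(fsb, unname(lib), rep(0.2, 5))
  nucb <- segment_nuclei(rfb$image$channels$hoechst)
  mnb <- detect_multinucleate(rfb$image$channels$tubulin, nucb)
  truth_pct <- 100 * mean(rfb$truth$table$n_nuclei >= 2)
  expect_lte(abs(mnb$percent - truth_pct), 5)
  # one syncytium with 5 nuclei -> 100%, count 5
  S <- 120
  x <- matrix(seq_len(S) - 60, S, S)
  y <- t(x)
  tub <- (sqrt(x^2 + y^2) <= 50) * 120
  hoe <- matrix(0, S, S)
  for (cx in seq(-30, 30, by = 15)) {
    hoe[(x - cx)^2 + y^2 <= 36] <- 200
  }
  nuc5 <- segment_nuclei(hoe)
  expect_equal(max(nuc5), 5)
  mn5 <- detect_multinucleate(tub, nuc5)
  expect_equal(mn5$percent, 100)
  expect_equal(mn5$components$n_nuclei, 5L)
  # zero components -> missing percentage
  mn0 <- detect_multinucleate(matrix(0, 50, 50), matrix(0L, 50, 50))
  expect_true(is.na(mn0$percent))
})
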