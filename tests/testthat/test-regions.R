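# Region geometry: radial coordinate, bands, ring, erosion, membrane bands.

test_that("the radial coordinate is exact on discs and ellipses", {
  R <- 100
  m <- disc_mask(R, 231)
  rf <- radial_field(m)
  c0 <- rf$centre
  # pixel at distance R/2 along +x
  p <- round(c(c0[1] + R / 2, c0[2]))
  expect_lt(abs(rf$rho[p[1], p[2]] - 0.5), 2 / R)
  # boundary pixel
  b <- round(c(c0[1] + R, c0[2]))
  expect_lt(abs(rf$rho[b[1], b[2]] - 1), 2 / R)
  # 2:1 ellipse: half the semi-minor axis along y -> rho = 0.5
  e <- ellipse_mask(80, 40, 181)
  rfe <- radial_field(e)
  q <- round(c(rfe$centre[1], rfe$centre[2] + 20))
  expect_lt(abs(rfe$rho[q[1], q[2]] - 0.5), 0.05)
  expect_error(radial_field(matrix(FALSE, 5, 5)), "zero area")
})

test_that("bands anchor at the documented border cases", {
  m <- disc_mask(100, 231)
  rf <- radial_field(m)
  # inner 100, outer 0 -> exactly the whole cell
  expect_identical(band_from_borders(m, 100, 0, rf = rf), m)
  # inner 10, outer -5 -> annulus between 90 and 105 px, within 5%
  b <- band_from_borders(m, 10, -5, rf = rf)
  expect_lt(abs(sum(b) / (pi * (105^2 - 90^2)) - 1), 0.05)
  # inner 0, outer 0 -> thin boundary shell
  shell <- band_from_borders(m, 0, 0, rf = rf)
  expect_gt(sum(shell), 0)
  expect_lt(sum(shell), 2.5 * 2 * pi * 100)
  expect_error(band_from_borders(m, 0, 10), "inverted")
})

test_that("widening band borders never removes pixels (monotonicity)", {
  m <- ellipse_mask(60, 35, 141)
  rf <- radial_field(m)
  prev <- band_from_borders(m, 10, 0, rf = rf)
  for (inner in c(20, 40, 70, 100)) {
    cur <- band_from_borders(m, inner, 0, rf = rf)
    expect_true(all(cur[prev]))
    prev <- cur
  }
  a <- band_from_borders(m, 40, 8, rf = rf)
  b <- band_from_borders(m, 40, -5, rf = rf)
  expect_true(all(b[a]))
})

test_that("the ring region matches the analytic annulus and excludes the nucleus", {
  cell <- disc_mask(100, 231)
  nuc <- disc_mask(40, 231)
  rf <- radial_field(cell)
  ring <- build_ring(cell, nuc, rf = rf)
  # 0.60 <= rho <= 0.92 -> annulus 60..92 px
  expect_lt(abs(sum(ring) / (pi * (92^2 - 60^2)) - 1), 0.05)
  expect_equal(sum(ring & nuc), 0)
  # nucleus overlapping the shell is excluded exactly
  nuc_big <- disc_mask(70, 231)
  ring2 <- build_ring(cell, nuc_big, rf = rf)
  expect_equal(sum(ring2 & nuc_big), 0)
  shell <- band_from_borders(cell, 40, 8, rf = rf)
  expect_identical(ring2, shell & !nuc_big)
  # alternative outer-border reading is a narrower shell: 0.60..0.68
  ring3 <- build_ring(cell, nuc, outer_from_inner = TRUE, rf = rf)
  expect_lt(abs(sum(ring3) / (pi * (68^2 - 60^2)) - 1), 0.07)
})

test_that("nuclear erosion shrinks by the expected margin with safe fallbacks", {
  nuc <- disc_mask(50, 121)
  er <- erode_nucleus(nuc)
  # 2% of r=50 -> 1 px erosion; the lost area is about one perimeter band
  lost <- sum(nuc) - sum(er)
  expect_gt(lost, 0.8 * 2 * pi * 50)
  expect_lt(lost, 1.6 * 2 * pi * 50)
  expect_true(all(nuc[er]))
  # degenerate 2x2 nucleus falls back with a warning
  tiny <- matrix(FALSE, 10, 10)
  tiny[5:6, 5:6] <- TRUE
  expect_warning(er2 <- erode_nucleus(tiny), "too small")
  expect_identical(er2, tiny)
  # eroded nucleus never touches the ring on the concentric fixture
  cell <- disc_mask(100, 231)
  ring <- build_ring(cell, nuc_conc <- disc_mask(40, 231))
  expect_equal(sum(erode_nucleus(nuc_conc) & ring), 0)
})

test_that("membrane bands are 1-px shells with neighbour clipping", {
  R <- 50
  m <- disc_mask(R, 121)
  nb <- neighbour_bands(m)
  # both bands near one perimeter, and near each other
  expect_lt(abs(sum(nb$membrane1) / (2 * pi * R) - 1), 0.35)
  expect_lt(abs(sum(nb$membrane2) / (2 * pi * R) - 1), 0.35)
  expect_lt(abs(sum(nb$membrane1) / sum(nb$membrane2) - 1), 0.15)
  expect_true(all(m[nb$membrane1]))
  expect_false(any(m[nb$membrane2]))
  # a neighbour occupying the left outside halo halves membrane2
  S <- 121
  labels <- matrix(0L, S, S)
  labels[m] <- 1L
  x <- matrix(seq_len(S) - 61, S, S)
  y <- t(x)
  halo <- !m & x < 0 & sqrt(x^2 + y^2) <= R + 6
  labels[halo] <- 2L
  nb2 <- neighbour_bands(m, labels = labels, label = 1L)
  expect_lt(abs(sum(nb2$membrane2) / (0.5 * sum(nb$membrane2)) - 1), 0.15)
  expect_identical(nb2$membrane1, nb$membrane1)
  # 1-px cell: membrane1 is the cell itself
  one <- matrix(FALSE, 9, 9)
  one[5, 5] <- TRUE
  expect_identical(neighbour_bands(one)$membrane1, one)
})

test_that("region areas are rotation-stable and the builders deterministic", {
  areas <- sapply(c(0, pi / 6, pi / 3, pi / 2), function(th) {
    m <- ellipse_mask(70, 35, 181, theta = th)
    rf <- radial_field(m)
    c(ring = sum(build_ring(m, ellipse_mask(28, 14, 181, theta = th), rf = rf)),
      memb = sum(band_from_borders(m, 10, -5, rf = rf)))
  })
  expect_lt(diff(range(areas["ring", ])) / mean(areas["ring", ]), 0.1)
  expect_lt(diff(range(areas["memb", ])) / mean(areas["memb", ]), 0.1)
  m <- disc_mask(40, 101)
  rs1 <- build_region_set(m, disc_mask(16, 101))
  rs2 <- build_region_set(m, disc_mask(16, 101))
  expect_identical(rs1[names(rs1) != "radial"], rs2[names(rs2) != "radial"])
  # region-set invariants
  expect_identical(rs1$cytoplasm, rs1$cell & !rs1$nucleus)
  expect_true(all(rs1$nucleus[rs1$eroded_nucleus]))
  expect_equal(sum(rs1$ring & rs1$eroded_nucleus), 0)
  expect_true(all(rs1$cell[rs1$membrane1]))
  expect_false(any(rs1$cell[rs1$membrane2]))
})
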