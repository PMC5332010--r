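# Synthetic field renderer: places rendered cells on a canvas without overlap
# (except designed contacts), applies a Poisson-Gaussian camera model, and
# records complete ground truth.

#' Specify a synthetic field
#'
#' @param image_shape length-2 integer, field size in px (x, y).
#' @param n_cells number of cells to place.
#' @param contact_probability probability in \[0, 1\] that a cell is placed in
#'   contact with an already-placed cell (sharing a zero-width boundary, as a
#'   watershed-style space-filling labelling would produce).
#' @param multinucleate_fraction probability in \[0, 1\] that a cell carries
#'   two nuclei instead of one.
#' @param noise list with `gain` (Poisson photon gain, intensity units per
#'   count) and `sigma` (additive Gaussian read noise sd); `gain = 0`
#'   disables shot noise.
#' @param rng_seed integer seed, or `NULL` to use the current RNG state.
#' @return a `field_spec` list.
#' @export
field_spec <- function(image_shape = c(256L, 256L), n_cells = 10L,
                       contact_probability = 0, multinucleate_fraction = 0,
                       noise = list(gain = 2, sigma = 2), rng_seed = NULL) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 16), n_cells >= 0,
            contact_probability >= 0, contact_probability <= 1,
            multinucleate_fraction >= 0, multinucleate_fraction <= 1)
  structure(list(image_shape = as.integer(image_shape),
                 n_cells = as.integer(n_cells),
                 contact_probability = contact_probability,
                 multinucleate_fraction = multinucleate_fraction,
                 noise = noise, rng_seed = rng_seed),
            class = "field_spec")
}

apply_noise <- function(m, gain = 2, sigma = 2) {
  out <- m
  if (!is.null(gain) && gain > 0) {
    out <- rpois(length(m), pmax(m, 0) / gain) * gain
    dim(out) <- dim(m)
  }
  if (!is.null(sigma) && sigma > 0) {
    out <- out + rnorm(length(m), 0, sigma)
    dim(out) <- dim(m)
  }
  out
}

#' Render a synthetic multi-channel field with ground truth
#'
#' Cells are drawn from a mixture of shape specifications and placed
#' sequentially. Non-contact placements keep at least a one-pixel gap from
#' every other cell; contact placements are moved next to an existing cell
#' and clipped against it, so the pair shares a zero-width boundary.
#'
#' @param fspec a [field_spec()].
#' @param specs list of [shape_spec()] objects (the mixture components).
#' @param weights mixture weights, must sum to 1. Defaults to uniform.
#' @param positions optional n x 2 matrix of cell centres; overrides random
#'   placement (overlaps are clipped against earlier cells).
#' @param allow_border if `TRUE`, cells may extend past the field edge
#'   (clipped); used to exercise border filtering.
#' @param max_tries placement retries per cell before giving up.
#' @return list with `image` (a `field_image`: named noisy channel rasters +
#'   `pixel_size`) and `truth` (cell/nucleus label masks, noiseless channels,
#'   and a per-cell truth table).
#' @export
render_field <- function(fspec, specs, weights = NULL, positions = NULL,
                         allow_border = FALSE, max_tries = 200L) {
  stopifnot(inherits(fspec, "field_spec"))
  if (inherits(specs, "shape_spec")) specs <- list(specs)
  if (is.null(weights)) weights <- rep(1 / length(specs), length(specs))
  stopifnot(length(weights) == length(specs))
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (!is.null(fspec$rng_seed)) set.seed(fspec$rng_seed)

  d <- fspec$image_shape
  cells <- matrix(0L, d[1], d[2])
  nuclei <- matrix(0L, d[1], d[2])
  channels <- lapply(setNames(nm = c("hoechst", "tubulin", "actin", "yaptaz")),
                     function(nm) matrix(0, d[1], d[2]))
  rows <- list()
  centres <- list()
  radii <- numeric(0)
  placed <- 0L

  for (i in seq_len(fspec$n_cells)) {
    cls <- sample.int(length(specs), 1L, prob = weights)
    nn <- if (runif(1) < fspec$multinucleate_fraction) 2L else 1L
    rc <- render_cell(specs[[cls]], n_nuclei = nn)
    pd <- dim(rc$cell)
    half <- (pd - 1L) %/% 2L
    ri <- sqrt(sum(rc$cell) / pi)
    want_contact <- is.null(positions) && placed > 0L &&
      runif(1) < fspec$contact_probability

    ok <- FALSE
    for (try in seq_len(max_tries)) {
      # a contact placement that keeps failing falls back to free placement
      if (want_contact && try > max_tries %/% 2L) want_contact <- FALSE
      if (!is.null(positions)) {
        if (i > nrow(positions)) stop("fewer positions than cells requested")
        ctr <- round(positions[i, ])
      } else if (want_contact) {
        j <- sample.int(placed, 1L)
        ang <- runif(1, 0, 2 * pi)
        f <- runif(1, 0.88, 0.98)
        dist <- (ri + radii[j]) * f
        ctr <- round(centres[[j]] + dist * c(cos(ang), sin(ang)))
      } else if (allow_border) {
        ctr <- round(c(runif(1, 1, d[1]), runif(1, 1, d[2])))
      } else {
        lo <- half + 2L
        hi <- d - half - 2L
        if (any(hi < lo)) stop("field too small for cell patch")
        ctr <- c(round(runif(1, lo[1], hi[1])), round(runif(1, lo[2], hi[2])))
      }
      # patch -> canvas index ranges, with clipping
      px <- c(max(1L, ctr[1] - half[1]), min(d[1], ctr[1] + half[1]))
      py <- c(max(1L, ctr[2] - half[2]), min(d[2], ctr[2] + half[2]))
      if (px[1] > px[2] || py[1] > py[2]) next
      qx <- px - (ctr[1] - half[1]) + 1L
      qy <- py - (ctr[2] - half[2]) + 1L
      sub <- function(m) m[qx[1]:qx[2], qy[1]:qy[2], drop = FALSE]
      cm <- sub(rc$cell)
      if (!allow_border && is.null(positions) &&
          (any(px == c(1L, d[1])) || any(py == c(1L, d[2])))) next
      occ <- cells[px[1]:px[2], py[1]:py[2], drop = FALSE]
      if (want_contact) {
        keep <- cm & occ == 0L
        if (sum(keep) < 0.6 * sum(cm)) next   # too much overlap, try again
        touch <- dilate_mask(keep, brush_box1()) & occ > 0L
        if (!any(touch)) next
        cm_new <- keep
      } else {
        grown <- dilate_mask(cm, brush_box1())
        if (any(grown & occ > 0L)) {
          if (!is.null(positions)) cm_new <- cm & occ == 0L else next
        } else cm_new <- cm
      }
      nm <- sub(rc$nuclei)
      nm[!cm_new] <- 0L
      n_left <- length(unique(nm[nm > 0L]))
      if (n_left < nn) next  # a nucleus was clipped away
      # commit
      placed <- placed + 1L
      id <- placed
      occ[cm_new] <- id
      cells[px[1]:px[2], py[1]:py[2]] <- occ
      nocc <- nuclei[px[1]:px[2], py[1]:py[2], drop = FALSE]
      nocc[nm > 0L] <- id
      nuclei[px[1]:px[2], py[1]:py[2]] <- nocc
      for (nmch in names(channels)) {
        chp <- channels[[nmch]][px[1]:px[2], py[1]:py[2], drop = FALSE]
        add <- sub(rc$channels[[nmch]])
        add[!cm_new] <- 0
        channels[[nmch]][px[1]:px[2], py[1]:py[2]] <- chp + add
      }
      centres[[id]] <- ctr
      radii[id] <- ri
      rows[[id]] <- data.frame(
        cell = id, shape_class = rc$truth$shape_class,
        cx = ctr[1], cy = ctr[2], area = sum(cm_new),
        n_nuclei = n_left, yaptaz_ratio = rc$truth$yaptaz_ratio,
        yaptaz_level = rc$truth$yaptaz_level,
        contact = want_contact, touches_border = NA
      )
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf("could not place cell %d of %d (placed %d); %s",
                   i, fspec$n_cells, placed,
                   "enlarge the field or reduce n_cells"))
    }
  }

  truth_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0), shape_class = character(0), cx = numeric(0),
               cy = numeric(0), area = numeric(0), n_nuclei = integer(0),
               yaptaz_ratio = numeric(0), yaptaz_level = numeric(0),
               contact = logical(0), touches_border = logical(0))
  # recompute border contact exactly from the committed masks
  if (nrow(truth_tab)) {
    edge <- matrix(FALSE, d[1], d[2])
    edge[c(1L, d[1]), ] <- TRUE
    edge[, c(1L, d[2])] <- TRUE
    on_edge <- unique(cells[edge & cells > 0L])
    truth_tab$touches_border <- truth_tab$cell %in% on_edge
  }

  noisy <- lapply(channels, apply_noise,
                  gain = fspec$noise$gain, sigma = fspec$noise$sigma)
  image <- structure(list(channels = noisy, pixel_size = 1),
                     class = "field_image")
  truth <- list(cells = cells, nuclei = nuclei, table = truth_tab,
                noiseless = channels)
  list(image = image, truth = truth)
}
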