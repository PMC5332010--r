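# Geometric fixtures and independent oracles used across the suite.

# centred disc mask of radius R on an S x S raster
disc_mask <- function(R, S = 2 * R + 21) {
  c0 <- (S + 1) / 2
  x <- matrix(seq_len(S) - c0, S, S)
  y <- t(x)
  sqrt(x^2 + y^2) <= R
}

# axis-aligned ellipse mask (semi-axes a along x, b along y), optional rotation
ellipse_mask <- function(a, b, S = 2 * max(a, b) + 21, theta = 0) {
  c0 <- (S + 1) / 2
  x <- matrix(seq_len(S) - c0, S, S)
  y <- t(x)
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  (xr / a)^2 + (yr / b)^2 <= 1
}

rect_mask <- function(w, h, S = max(w, h) + 20) {
  m <- matrix(FALSE, S, S)
  x0 <- floor((S - w) / 2)
  y0 <- floor((S - h) / 2)
  m[(x0 + 1):(x0 + w), (y0 + 1):(y0 + h)] <- TRUE
  m
}

# Brute-force GLCM Haralick oracle: explicit loop over pixels and the four
# symmetric offsets, independent of the package implementation.
haralick_oracle <- function(channel, region, distance = 1L, levels = 64L) {
  d <- dim(channel)
  vals <- channel[region]
  rng <- range(vals)
  q <- matrix(NA_integer_, d[1], d[2])
  if (diff(rng) == 0) {
    q[region] <- 0L
  } else {
    q[region] <- pmin(as.integer(floor((vals - rng[1]) / diff(rng) * levels)),
                      levels - 1L)
  }
  P <- matrix(0, levels, levels)
  offs <- distance * rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) {
    if (is.na(q[ix, iy])) next
    for (o in seq_len(4)) {
      jx <- ix + offs[o, 1]; jy <- iy + offs[o, 2]
      if (jx < 1 || jx > d[1] || jy < 1 || jy > d[2]) next
      if (is.na(q[jx, jy])) next
      a <- q[ix, iy] + 1L; b <- q[jx, jy] + 1L
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  if (sum(P) == 0) {
    return(c(correlation = NA_real_, contrast = NA_real_,
             variance = NA_real_, homogeneity = NA_real_))
  }
  P <- P / sum(P)
  lev <- 0:(levels - 1L)
  i <- matrix(lev, levels, levels)
  j <- t(i)
  mu_x <- sum(i * P); mu_y <- sum(j * P)
  s_x <- sqrt(sum((i - mu_x)^2 * P)); s_y <- sqrt(sum((j - mu_y)^2 * P))
  c(correlation = if (s_x > 0 && s_y > 0) {
      sum((i - mu_x) * (j - mu_y) * P) / (s_x * s_y)
    } else NA_real_,
    contrast = sum((i - j)^2 * P),
    variance = sum((i - mu_x)^2 * P),
    homogeneity = sum(P / (1 + (i - j)^2)))
}

# fraction of a cell's boundary pixels that touch another label (8-connected)
shared_boundary_fraction <- function(labels, id) {
  own <- labels == id
  d <- dim(labels)
  bidx <- which(own, arr.ind = TRUE)
  boundary <- logical(nrow(bidx))
  touching <- logical(nrow(bidx))
  for (k in seq_len(nrow(bidx))) {
    ix <- bidx[k, 1]; iy <- bidx[k, 2]
    nbr <- expand.grid(x = max(1, ix - 1):min(d[1], ix + 1),
                       y = max(1, iy - 1):min(d[2], iy + 1))
    vals <- labels[cbind(nbr$x, nbr$y)]
    boundary[k] <- any(vals != id)
    touching[k] <- any(vals != id & vals > 0)
  }
  sum(touching) / max(1, sum(boundary))
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# best-matching ground-truth IoU for each predicted label
match_iou <- function(pred, truth) {
  vapply(label_ids_t(pred), function(id) {
    m <- pred == id
    ov <- truth[m]
    ov <- ov[ov > 0]
    if (!length(ov)) return(0)
    gid <- as.integer(names(which.max(table(ov))))
    iou(m, truth == gid)
  }, numeric(1))
}

label_ids_t <- function(labels) {
  u <- sort(unique(as.integer(labels)))
  u[u > 0]
}
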