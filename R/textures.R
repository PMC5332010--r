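# Texture features: Gaussian-derivative (SER) responses, grey-level
# co-occurrence (Haralick) statistics and a Gabor filter bank.
#
# All filtering is local: kernels are normalised to unit L2 energy (the
# smoothing kernel to unit sum for the bright/dark residuals), so responses
# reflect local structure, not absolute intensity offsets. Convolution uses
# replicate edge-padding, so regions smaller than the kernel support are
# still computed.

conv2 <- function(img, kern) {
  mat(EBImage::filter2(img, kern, boundary = "replicate"))
}

# Separable correlation with replicate edge padding. kx acts along the first
# (x) index, ky along the second.
conv_sep <- function(img, kx, ky) {
  d <- dim(img)
  rx <- (length(kx) - 1L) %/% 2L
  ry <- (length(ky) - 1L) %/% 2L
  P <- img[pmin(pmax(seq_len(d[1] + 2L * rx) - rx, 1L), d[1]), , drop = FALSE]
  out <- matrix(0, d[1], d[2])
  for (i in seq_along(kx)) {
    out <- out + kx[i] * P[i:(i + d[1] - 1L), , drop = FALSE]
  }
  P <- out[, pmin(pmax(seq_len(d[2] + 2L * ry) - ry, 1L), d[2]), drop = FALSE]
  out <- matrix(0, d[1], d[2])
  for (j in seq_along(ky)) {
    out <- out + ky[j] * P[, j:(j + d[2] - 1L), drop = FALSE]
  }
  out
}

# 1-D factor pairs of the Gaussian scale-space kernels. Derivative factors
# are made exactly DC-free, and each 2-D kernel (outer product) has unit L2
# energy; the smoothing kernel has unit sum (so bright/dark residuals vanish
# on constant images).
gaussian_derivative_factors <- function(sigma) {
  r <- max(2L, ceiling(3 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  d1 <- -x / sigma^2 * g
  d2 <- (x^2 / sigma^4 - 1 / sigma^2) * g
  d1 <- d1 - mean(d1)
  d2 <- d2 - mean(d2)
  gs <- g / sum(g)
  unit <- function(kx, ky) {
    nrm <- sqrt(sum(kx^2) * sum(ky^2))
    list(kx = kx / sqrt(nrm), ky = ky / sqrt(nrm))
  }
  list(
    g   = list(kx = gs, ky = gs),
    gx  = unit(d1, g),
    gy  = unit(g, d1),
    gxx = unit(d2, g),
    gyy = unit(g, d2),
    gxy = unit(d1, d1)
  )
}

gaussian_derivative_kernels <- function(sigma) {
  lapply(gaussian_derivative_factors(sigma),
         function(f) outer(f$kx, f$ky))
}

# FFT correlation of one image with a bank of kernels, replicate-padded.
# Kernel spectra are cached per (padded size, bank id).
.conv_cache <- new.env(parent = emptyenv())

conv_fft_bank <- function(img, kernels, bank_id) {
  d <- dim(img)
  r <- (dim(kernels[[1]])[1] - 1L) %/% 2L
  n1 <- stats::nextn(d[1] + 2L * r, c(2L, 3L, 5L))
  n2 <- stats::nextn(d[2] + 2L * r, c(2L, 3L, 5L))
  P <- img[pmin(pmax(seq_len(n1) - r, 1L), d[1]),
           pmin(pmax(seq_len(n2) - r, 1L), d[2]), drop = FALSE]
  FP <- fft(P)
  key <- paste(bank_id, n1, n2, sep = "_")
  KF <- .conv_cache[[key]]
  if (is.null(KF)) {
    KF <- lapply(kernels, function(k) {
      Z <- matrix(0, n1, n2)
      idx <- function(v, n) ((v - 1L) %% n) + 1L
      # embed the flipped kernel centred at (1,1), wrapped: correlation
      Z[idx(1L + (-r:r), n1), idx(1L + (-r:r), n2)] <-
        k[(2L * r + 1L):1L, (2L * r + 1L):1L]
      fft(Z)
    })
    .conv_cache[[key]] <- KF
  }
  lapply(KF, function(Kf) {
    full <- Re(fft(FP * Kf, inverse = TRUE)) / (n1 * n2)
    full[(r + 1L):(r + d[1]), (r + 1L):(r + d[2]), drop = FALSE]
  })
}

#' @importFrom stats fft
NULL

SER_NAMES <- c("spot", "hole", "edge", "ridge", "valley", "saddle",
               "bright", "dark")

#' SER (Saddle-Edge-Ridge) Gaussian-derivative texture features
#'
#' The raster is convolved with a Gaussian kernel and its derivatives at
#' `sigma = sigma0 + scale` px. From the smoothed image `L` and its
#' derivatives, eight per-pixel responses are formed (Hessian eigenvalues
#' `l1 >= l2`): spot `= max(0, -(l1+l2))` where both curvatures are negative
#' (bright blobs), hole the sign-flipped counterpart, edge
#' `= sqrt(Lx^2+Ly^2)`, ridge `= max(0, -l2 - |l1|)`, valley
#' `= max(0, l1 - |l2|)`, saddle `= sqrt(-l1*l2)` on saddle pixels, and
#' bright/dark the rectified residuals `I - L` and `L - I`. Each feature is
#' the mean response over the region pixels.
#'
#' @param channel 2-D numeric raster.
#' @param region logical matrix, non-empty.
#' @param scale texture scale in px (0 = fine, 1 = coarse).
#' @param sigma0 base Gaussian scale in px.
#' @return named numeric vector of the 8 responses.
#' @export
ser_features <- function(channel, region, scale = 0, sigma0 = 0.5) {
  stopifnot(any(region))
  resp <- ser_response_stack(channel, sigma0 + scale)
  vapply(resp, function(r) mean(r[region]), numeric(1))
}

# All SER responses for one channel raster at one sigma, as a named list of
# matrices; shared across regions.
ser_response_stack <- function(channel, sigma) {
  f <- gaussian_derivative_factors(sigma)
  L <- conv_sep(channel, f$g$kx, f$g$ky)
  Lx <- conv_sep(channel, f$gx$kx, f$gx$ky)
  Ly <- conv_sep(channel, f$gy$kx, f$gy$ky)
  Lxx <- conv_sep(channel, f$gxx$kx, f$gxx$ky)
  Lyy <- conv_sep(channel, f$gyy$kx, f$gyy$ky)
  Lxy <- conv_sep(channel, f$gxy$kx, f$gxy$ky)
  tr2 <- (Lxx + Lyy) / 2
  disc <- sqrt(((Lxx - Lyy) / 2)^2 + Lxy^2)
  l1 <- tr2 + disc
  l2 <- tr2 - disc
  list(
    spot   = pmax(0, -(l1 + l2)) * (l1 < 0),
    hole   = pmax(0, l1 + l2) * (l2 > 0),
    edge   = sqrt(Lx^2 + Ly^2),
    ridge  = pmax(0, -l2 - abs(l1)),
    valley = pmax(0, l1 - abs(l2)),
    saddle = sqrt(pmax(0, -l1 * l2)) * (l1 > 0 & l2 < 0),
    bright = pmax(0, channel - L),
    dark   = pmax(0, L - channel)
  )
}

# Quantise region pixels to `levels` grey levels (0-based) over the region's
# intensity range.
quantise_region <- function(vals, levels) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rep(0L, length(vals)))
  q <- floor((vals - rng[1]) / diff(rng) * levels)
  as.integer(pmin(q, levels - 1L))
}

#' Grey-level co-occurrence (Haralick) features
#'
#' Builds the co-occurrence matrix of region pixels at the given offset
#' distance, symmetrised and averaged over the four directions (0, 45, 90,
#' 135 degrees), counting only pairs with both pixels inside the region.
#' Intensities are quantised to `levels` grey levels over the region's
#' range. Reported features (levels 0-based): contrast
#' `sum((i-j)^2 p)`, homogeneity `sum(p / (1+(i-j)^2))`, variance
#' `sum((i-mu)^2 p)` and correlation
#' `sum((i-mux)(j-muy) p) / (sx sy)` (NA for a constant region).
#'
#' @param channel 2-D numeric raster.
#' @param region logical matrix with at least 2 pixels.
#' @param distance offset in px.
#' @param levels number of grey levels.
#' @return named numeric vector: `correlation`, `contrast`, `variance`,
#'   `homogeneity`.
#' @export
haralick_features <- function(channel, region, distance = 1L, levels = 64L) {
  stopifnot(sum(region) >= 2)
  d <- dim(channel)
  q <- matrix(NA_integer_, d[1], d[2])
  q[region] <- quantise_region(channel[region], levels)
  offsets <- distance * rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  counts <- numeric(levels * levels)
  for (o in seq_len(nrow(offsets))) {
    dx <- offsets[o, 1]; dy <- offsets[o, 2]
    x1 <- max(1, 1 - dx):min(d[1], d[1] - dx)
    y1 <- max(1, 1 - dy):min(d[2], d[2] - dy)
    a <- q[x1, y1, drop = FALSE]
    b <- q[x1 + dx, y1 + dy, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    ia <- a[ok]; ib <- b[ok]
    # symmetric: count (a,b) and (b,a)
    idx <- c(ia * levels + ib, ib * levels + ia) + 1L
    counts <- counts + tabulate(idx, nbins = levels * levels)
  }
  tot <- sum(counts)
  if (tot == 0) {
    return(c(correlation = NA_real_, contrast = NA_real_,
             variance = NA_real_, homogeneity = NA_real_))
  }
  p <- counts / tot
  ij <- expand.grid(j = 0:(levels - 1L), i = 0:(levels - 1L))
  i <- ij$i; j <- ij$j   # counts index = i*levels + j
  mu_x <- sum(i * p)
  mu_y <- sum(j * p)
  s_x <- sqrt(sum((i - mu_x)^2 * p))
  s_y <- sqrt(sum((j - mu_y)^2 * p))
  contrast <- sum((i - j)^2 * p)
  homogeneity <- sum(p / (1 + (i - j)^2))
  variance <- sum((i - mu_x)^2 * p)
  correlation <- if (s_x > 0 && s_y > 0) {
    sum((i - mu_x) * (j - mu_y) * p) / (s_x * s_y)
  } else NA_real_
  c(correlation = correlation, contrast = contrast,
    variance = variance, homogeneity = homogeneity)
}

gabor_kernels <- function(wavelength, n_orient, sigma = 0.5 * wavelength,
                          gamma = 1) {
  r <- max(3L, ceiling(2.5 * sigma))
  x <- matrix(-r:r, 2L * r + 1L, 2L * r + 1L)
  y <- t(x)
  lapply(seq_len(n_orient) - 1L, function(k) {
    th <- pi * k / n_orient
    xr <- x * cos(th) + y * sin(th)
    yr <- -x * sin(th) + y * cos(th)
    env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
    re <- env * cos(2 * pi * xr / wavelength)
    im <- env * sin(2 * pi * xr / wavelength)
    re <- re - mean(re)                 # zero DC
    nrm <- sqrt(sum(re^2) + sum(im^2))
    list(re = re / nrm, im = im / nrm)
  })
}

#' Gabor filter-bank features
#'
#' A bank of quadrature Gabor kernels at `n_orient` orientations and one
#' wavelength is applied to the raster; the per-pixel response magnitude is
#' reduced across orientations by mean, min and max and then averaged over
#' the region. Kernels are DC-free and energy-normalised, so a constant
#' image scores ~0 and oriented structure drives `gabor_max` far above
#' `gabor_min`.
#'
#' @param channel 2-D numeric raster (actin stain in the screen).
#' @param region logical matrix (cytoplasm), non-empty.
#' @param wavelength carrier wavelength in px.
#' @param n_orient number of orientations over \[0, pi).
#' @return named numeric vector `gabor_mean`, `gabor_min`, `gabor_max`.
#' @export
gabor_features <- function(channel, region, wavelength = 4, n_orient = 8) {
  stopifnot(any(region))
  kerns <- gabor_kernels(wavelength, n_orient)
  flat <- c(lapply(kerns, `[[`, "re"), lapply(kerns, `[[`, "im"))
  bank_id <- sprintf("gabor_w%g_o%d", wavelength, n_orient)
  conv <- conv_fft_bank(channel, flat, bank_id)
  rid <- which(region)
  sel <- vapply(seq_len(n_orient), function(o) {
    sqrt(conv[[o]][rid]^2 + conv[[o + n_orient]][rid]^2)
  }, numeric(length(rid)))
  if (is.null(dim(sel))) sel <- matrix(sel, nrow = 1)
  c(gabor_mean = mean(rowMeans(sel)),
    gabor_min = mean(do.call(pmin, asplit(sel, 2))),
    gabor_max = mean(do.call(pmax, asplit(sel, 2))))
}
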