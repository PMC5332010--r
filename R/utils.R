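# Shared low-level helpers for label masks and patches.
# Rasters are plain numeric/integer/logical matrices; the first index is x
# (image column), the second y, matching EBImage's convention.

mat <- function(x) {
  d <- dim(x)
  m <- EBImage::imageData(x)
  dim(m) <- d[1:2]
  m
}

brush_disc <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
brush_box1 <- function() EBImage::makeBrush(3L, shape = "box")

erode_mask <- function(mask, brush) mat(EBImage::erode(mask * 1, brush)) > 0.5
dilate_mask <- function(mask, brush) mat(EBImage::dilate(mask * 1, brush)) > 0.5

#' @keywords internal
#' @noRd
label_ids <- function(labels) {
  u <- sort(unique(as.integer(labels)))
  u[u > 0L]
}

# relabel a label mask so labels are contiguous 1..n (order preserved)
relabel <- function(labels) {
  ids <- label_ids(labels)
  if (!length(ids)) return(labels)
  out <- labels
  out[] <- match(as.integer(labels), ids, nomatch = 0L)
  storage.mode(out) <- "integer"
  out
}

# per-label pixel counts, named by label id
label_areas <- function(labels) {
  ids <- label_ids(labels)
  tab <- tabulate(as.integer(labels), nbins = max(ids, 0L))
  setNames(tab[ids], ids)
}

# centroids of labels: matrix with columns x, y and rownames = label id
label_centroids <- function(labels) {
  ids <- label_ids(labels)
  if (!length(ids)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- as.integer(labels[labels > 0L])
  cx <- tapply(idx[, 1], lab, mean)
  cy <- tapply(idx[, 2], lab, mean)
  out <- cbind(x = as.numeric(cx), y = as.numeric(cy))
  rownames(out) <- names(cx)
  out[as.character(ids), , drop = FALSE]
}

# bounding box of a logical mask, expanded by `margin`, clipped to the raster
mask_bbox <- function(mask, margin = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  d <- dim(mask)
  list(
    x = c(max(1L, min(idx[, 1]) - margin), min(d[1], max(idx[, 1]) + margin)),
    y = c(max(1L, min(idx[, 2]) - margin), min(d[2], max(idx[, 2]) + margin))
  )
}

crop_bbox <- function(m, bb) m[bb$x[1]:bb$x[2], bb$y[1]:bb$y[2], drop = FALSE]

# mask touching any raster edge?
touches_border <- function(mask) {
  d <- dim(mask)
  any(mask[1, ]) || any(mask[d[1], ]) || any(mask[, 1]) || any(mask[, d[2]])
}

# perimeter estimate from exposed 4-neighbour edges, with the pi/4 bias
# correction that makes a digitised disc come out at 2*pi*R
mask_perimeter <- function(mask) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)]
  exposed <- (core & !pad[1:d[1], 2:(d[2] + 1L)]) +
    (core & !pad[3:(d[1] + 2L), 2:(d[2] + 1L)]) +
    (core & !pad[2:(d[1] + 1L), 1:d[2]]) +
    (core & !pad[2:(d[1] + 1L), 3:(d[2] + 2L)])
  sum(exposed) * pi / 4
}

# circular fill of NA bins by linear interpolation between nearest non-NA bins
fill_circular <- function(v) {
  n <- length(v)
  if (!anyNA(v)) return(v)
  if (all(is.na(v))) stop("no boundary support in any angular bin")
  v3 <- rep(v, 3L)
  idx <- which(!is.na(v3))
  approx(x = idx, y = v3[idx], xout = (n + 1L):(2L * n), rule = 2)$y
}

#' @importFrom stats approx
NULL

# adjusted Fisher-Pearson standardised third moment
skewness_fp <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s <- sd(x)
  if (s == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / (mean((x - m)^2))^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
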