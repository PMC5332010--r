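# Five-way linear shape classification.
#
# A regularised one-vs-rest linear discriminant on standardised features:
# class indicator targets are regressed on z-scored features with a ridge
# penalty (closed form, deterministic), and cells take the argmax score.
# Ties break by the fixed class order of SHAPE_CLASSES. Constant features
# are dropped with a warning; missing values are imputed with the training
# means and the cell is flagged.

#' Train the shape classifier
#'
#' @param features data.frame or matrix of training features (typically the
#'   126 registry columns of [extract_all()]).
#' @param labels character/factor vector of true shape classes, one per row.
#' @param lambda ridge penalty on the standardised scale.
#' @param classes class order used for score columns and tie-breaking.
#' @return a `shape_model`: feature names, per-feature mean/sd, per-class
#'   weights and bias, training accuracy diagnostics.
#' @export
train_shape_classifier <- function(features, labels,
                                   lambda = default_config()$classify$lambda,
                                   classes = SHAPE_CLASSES) {
  X <- as.matrix(features[, !(colnames(features) %in% c("cell", "x", "y")),
                          drop = FALSE])
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  present <- intersect(classes, unique(labels))
  missing_cls <- setdiff(classes, present)
  if (length(missing_cls)) {
    stop("training data lacks class(es): ", toString(missing_cls))
  }
  if (min(table(labels)) < 20) {
    stop("need at least 20 training cells per class")
  }
  # impute missing with column means, then standardise
  mu0 <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mu0[j]
  }
  sds <- apply(X, 2, sd)
  keep <- is.finite(sds) & sds > 0
  if (any(!keep)) {
    warning("dropping constant feature(s): ", toString(colnames(X)[!keep]))
  }
  X <- X[, keep, drop = FALSE]
  mu <- mu0[keep]
  sds <- sds[keep]
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  Y <- vapply(classes, function(cl) as.numeric(labels == cl),
              numeric(nrow(Z)))
  p <- ncol(Z)
  G <- crossprod(Z) + diag(lambda * nrow(Z), p)
  W <- solve(G, crossprod(Z, sweep(Y, 2, colMeans(Y))))
  b <- colMeans(Y)                       # intercepts (Z is centred)
  model <- structure(list(
    classes = classes, feature_names = colnames(Z),
    mean = mu, sd = sds, weights = W, bias = b, lambda = lambda
  ), class = "shape_model")
  pred <- classify_shapes(model, X)
  model$training_accuracy <- mean(pred$class == labels)
  tab <- table(truth = labels, pred = pred$class)
  model$per_class_accuracy <- diag(prop.table(tab, 1))[classes]
  model
}

#' Classify cells into shapes
#'
#' Scores each cell against every class and assigns the argmax; exactly one
#' label per cell, ties broken by the model's fixed class order. Missing
#' features are imputed with the training means and the cell is flagged in
#' the `imputed` column.
#'
#' @param model a `shape_model` from [train_shape_classifier()].
#' @param features data.frame/matrix containing the model's feature columns.
#' @return data.frame with `class`, per-class score columns, and `imputed`.
#' @export
classify_shapes <- function(model, features) {
  stopifnot(inherits(model, "shape_model"))
  fn <- model$feature_names
  missing_cols <- setdiff(fn, colnames(features))
  if (length(missing_cols)) {
    stop("feature table lacks model column(s): ",
         toString(head(missing_cols, 5)))
  }
  X <- as.matrix(as.data.frame(features)[, fn, drop = FALSE])
  imputed <- apply(X, 1, anyNA)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- model$mean[j]
  }
  Z <- sweep(sweep(X, 2, model$mean), 2, model$sd, "/")
  S <- Z %*% model$weights
  S <- sweep(S, 2, model$bias, "+")
  # argmax with fixed-order tie-break (max.col would break ties at random)
  cls_idx <- apply(S, 1, which.max)
  out <- data.frame(class = model$classes[cls_idx], imputed = imputed,
                    stringsAsFactors = FALSE)
  colnames(S) <- paste0("score_", model$classes)
  cbind(out, as.data.frame(S))
}

#' Tabulate shape counts per well
#'
#' @param labels per-cell shape labels.
#' @param wells per-cell well ids (same length); a single id is recycled.
#' @return data.frame: `well`, one count column per class, `n_cells`, and
#'   `prop_<class>` proportions. Counts always sum to `n_cells`.
#' @export
shape_counts <- function(labels, wells = "well") {
  labels <- as.character(labels)
  if (length(wells) == 1) wells <- rep(wells, length(labels))
  stopifnot(length(wells) == length(labels))
  uw <- unique(wells)
  rows <- lapply(uw, function(w) {
    l <- labels[wells == w]
    cnt <- vapply(SHAPE_CLASSES, function(cl) sum(l == cl), integer(1))
    df <- data.frame(well = w, t(cnt), n_cells = length(l),
                     check.names = FALSE)
    for (cl in SHAPE_CLASSES) {
      df[[paste0("prop_", cl)]] <- df[[cl]] / max(1L, length(l))
    }
    df
  })
  do.call(rbind, rows)
}

#' Save / load a shape model as plain text
#'
#' The model round-trips bit-exactly through a key-value text format
#' (full double precision via `format(..., digits = 17)`).
#'
#' @param model a `shape_model`.
#' @param path file path.
#' @return `read_shape_model()` returns the model.
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  num <- function(x) paste(format(x, digits = 17, trim = TRUE), collapse = "\t")
  lines <- c(
    paste0("classes\t", paste(model$classes, collapse = "\t")),
    paste0("features\t", paste(model$feature_names, collapse = "\t")),
    paste0("lambda\t", num(model$lambda)),
    paste0("mean\t", num(model$mean)),
    paste0("sd\t", num(model$sd)),
    paste0("bias\t", num(model$bias)),
    vapply(seq_along(model$classes), function(k) {
      paste0("weights_", model$classes[k], "\t", num(model$weights[, k]))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  kv <- setNames(lapply(lines, `[`, -1L), vapply(lines, `[`, "", 1L))
  classes <- kv$classes
  fn <- kv$features
  W <- vapply(classes, function(cl) as.numeric(kv[[paste0("weights_", cl)]]),
              numeric(length(fn)))
  rownames(W) <- fn
  structure(list(
    classes = classes, feature_names = fn,
    mean = setNames(as.numeric(kv$mean), fn),
    sd = setNames(as.numeric(kv$sd), fn),
    weights = W, bias = setNames(as.numeric(kv$bias), classes),
    lambda = as.numeric(kv$lambda)
  ), class = "shape_model")
}

#' Generate a labelled training set of synthetic cells
#'
#' Renders `n_per_class` isolated cells per reference shape and extracts
#' their features from the ground-truth masks (no segmentation), giving a
#' clean labelled fixture for [train_shape_classifier()].
#'
#' @param n_per_class cells per class.
#' @param seed RNG seed.
#' @param library shape library (see [shape_library()]).
#' @param noise optional camera model applied to the rendered patches
#'   (`NULL` = noiseless).
#' @param config see [default_config()].
#' @return list with `features` (data.frame, registry columns) and `labels`.
#' @export
make_training_set <- function(n_per_class = 300L, seed = 1L,
                              library = shape_library(),
                              noise = list(gain = 2, sigma = 2),
                              config = default_config()) {
  set.seed(seed)
  rows <- list()
  labels <- character(0)
  for (cls in names(library)) {
    for (i in seq_len(n_per_class)) {
      rc <- render_cell(library[[cls]])
      chans <- rc$channels
      if (!is.null(noise)) {
        chans <- lapply(chans, apply_noise, gain = noise$gain,
                        sigma = noise$sigma)
      }
      rs <- suppressWarnings(build_region_set(rc$cell, rc$nuclei > 0L,
                                              config = config))
      fv <- cell_feature_vector(chans, rs, config)
      rows[[length(rows) + 1L]] <- fv
      labels <- c(labels, cls)
    }
  }
  feats <- as.data.frame(do.call(rbind, rows))
  reg <- feature_registry()
  list(features = feats[, reg$name], labels = labels)
}
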