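# Readers/writers: tab-delimited feature tables (one file per replicate
# plate) and multi-page TIFF images/label masks.

#' Write / read a well feature table
#'
#' Tab-delimited with a header row; one file per replicate plate mirrors the
#' deposited spreadsheet organisation (well id, gene name -- or cells plated
#' for dilution wells -- then features). Missing values are written as `NA`.
#'
#' @param table data.frame of well rows.
#' @param path file path.
#' @return `read_feature_table()` returns the data.frame; dilution wells'
#'   cells-plated values (carried in the `gene` column, per the deposited
#'   convention) are parsed into a numeric `cells_plated_parsed` column.
#' @export
write_feature_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("row length mismatch at row ", bad, " of ", path)
  }
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  known <- feature_registry()$name
  unknown <- setdiff(names(df), c("well", "gene", "plate", "role", "n_cells",
                                  "cells_plated", "neighbour_fraction",
                                  "neighbour_fraction_raw", "total_yaptaz",
                                  "multinucleate_pct",
                                  paste0("n_", SHAPE_CLASSES),
                                  paste0("prop_", SHAPE_CLASSES), known))
  if (length(unknown)) {
    warning("unknown column(s) preserved: ", toString(head(unknown, 8)))
  }
  for (f in intersect(known, names(df))) {
    if (!is.numeric(df[[f]])) {
      v <- suppressWarnings(as.numeric(df[[f]]))
      if (any(is.na(v) & !is.na(df[[f]]))) {
        warning("non-numeric entries in '", f, "' set to NA")
      }
      df[[f]] <- v
    }
  }
  if ("gene" %in% names(df)) {
    df$cells_plated_parsed <- suppressWarnings(as.numeric(df$gene))
  }
  df
}

#' Write / read a multi-channel field as multi-page TIFF
#'
#' One 16-bit page per channel, in the fixed order hoechst, tubulin, actin,
#' yaptaz (channel names are also attached as page descriptions).
#' Intensities are stored as counts 0..65535.
#'
#' @param field a `field_image` (list with `$channels`) or named list of
#'   numeric matrices.
#' @param path file path.
#' @return `read_field_tiff()` returns a `field_image`.
#' @export
write_field_tiff <- function(field, path) {
  channels <- if (!is.null(field$channels)) field$channels else field
  pages <- lapply(names(channels), function(nm) {
    m <- round(pmin(pmax(t(channels[[nm]]), 0), 65535)) / 65535
    attr(m, "description") <- nm
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  nms <- vapply(pages, function(p) {
    d <- attr(p, "description")
    if (is.null(d) || !nzchar(d)) NA_character_ else d
  }, character(1))
  if (anyNA(nms) || anyDuplicated(nms)) {
    nms <- c("hoechst", "tubulin", "actin", "yaptaz")[seq_along(pages)]
  }
  channels <- lapply(pages, function(p) t(p * 65535))
  names(channels) <- nms
  structure(list(channels = channels, pixel_size = 1), class = "field_image")
}

#' Write / read a label mask as 16-bit TIFF
#'
#' @param labels integer label matrix (0 = background; labels < 65536).
#' @param path file path.
#' @return `read_label_tiff()` returns the integer matrix.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  tiff::writeTIFF(t(labels) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- t(tiff::readTIFF(path))
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}
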