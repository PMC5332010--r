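# 384-well plate geometry (rows A-P, columns 1-24) and plate-map I/O.

PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24

WELL_ROLES <- c("sample", "mock", "control_lats1", "control_yap",
                "control_ect2", "dilution")

#' Well identifiers of a 384-well plate
#' @return character vector of length 384, "A1" ... "P24", column-major by row.
#' @export
well_ids <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-P])([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("unknown well id(s): ", toString(well[bad]))
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col < 1 | col > 24)) {
    stop("well column out of range 1-24: ", toString(well[col < 1 | col > 24]))
  }
  data.frame(well = well, row = row, col = col,
             row_index = match(row, PLATE_ROWS))
}

#' Default screen plate layout
#'
#' Builds the documented 384-well layout of the screen: a density-dilution
#' series on columns 1, 2, 23 and 24 (cells plated increasing down the
#' plate), positive-control siRNA wells on columns 23 and 24 (LATS1-like,
#' YAP-like and ECT2-like, at least 4 wells each), mock-transfection negative
#' controls spread within columns 3-22 and rows C-N, and sample (SMARTpool
#' siRNA) wells elsewhere in columns 3-22.
#'
#' @param plate replicate plate id, conventionally one of "1A", "1B", "2A", "2B".
#' @param n_mock number of mock negative-control wells.
#' @param dilution_series cells plated for the four row-blocks of the
#'   dilution columns.
#' @param cells_plated cells plated in sample/control wells (metadata).
#' @return data.frame of 384 rows with columns `well`, `row`, `col`, `role`,
#'   `gene`, `cells_plated`, `plate`. Dilution wells carry their cells-plated
#'   value in the `gene` column, following the deposited-table convention.
#' @export
default_plate_layout <- function(plate = "1A", n_mock = 28L,
                                 dilution_series = c(250, 500, 1000, 2000),
                                 cells_plated = 1000) {
  lay <- parse_well(well_ids())
  lay$role <- "sample"
  lay$gene <- NA_character_
  lay$cells_plated <- cells_plated
  lay$plate <- plate

  dil <- lay$col %in% c(1, 2) |
    (lay$col %in% c(23, 24) & lay$row_index >= 13)
  lay$role[dil] <- "dilution"
  ctrl <- lay$col %in% c(23, 24) & lay$row_index <= 12
  lay$role[ctrl & lay$row_index <= 4] <- "control_lats1"
  lay$role[ctrl & lay$row_index >= 5 & lay$row_index <= 8] <- "control_yap"
  lay$role[ctrl & lay$row_index >= 9] <- "control_ect2"

  # mocks spread deterministically within columns 3-22, rows C-N
  inner <- which(lay$col >= 3 & lay$col <= 22 &
                   lay$row_index >= 3 & lay$row_index <= 14)
  pick <- inner[seq(1L, length(inner), length.out = n_mock)]
  lay$role[pick] <- "mock"

  smp <- lay$role == "sample"
  lay$gene[smp] <- sprintf("gene%03d", seq_len(sum(smp)))
  lay$gene[lay$role == "mock"] <- "mock"
  lay$gene[lay$role == "control_lats1"] <- "LATS1like"
  lay$gene[lay$role == "control_yap"] <- "YAPlike"
  lay$gene[lay$role == "control_ect2"] <- "ECT2like"
  # dilution series: cells plated increases down the rows in four blocks
  blk <- ceiling(lay$row_index / 4)
  lay$cells_plated[dil] <- dilution_series[blk[dil]]
  lay$gene[dil] <- as.character(lay$cells_plated[dil])
  lay[, c("well", "row", "col", "role", "gene", "cells_plated", "plate")]
}

validate_layout <- function(lay) {
  stopifnot(is.data.frame(lay))
  need <- c("well", "row", "col", "role", "gene", "cells_plated", "plate")
  missing <- setdiff(need, names(lay))
  if (length(missing)) stop("plate map lacks column(s): ", toString(missing))
  if (nrow(lay) != 384) stop("a plate layout must have exactly 384 wells, got ",
                             nrow(lay))
  if (anyDuplicated(lay$well)) {
    stop("duplicate well id(s): ",
         toString(unique(lay$well[duplicated(lay$well)])))
  }
  parse_well(lay$well)
  bad <- !lay$role %in% WELL_ROLES
  if (any(bad)) stop("unknown role(s): ", toString(unique(lay$role[bad])))
  invisible(lay)
}

#' Read / write a plate map
#'
#' CSV plate maps round-trip losslessly. Duplicate or malformed well ids are
#' rejected with the offending line numbers.
#'
#' @param path CSV file path.
#' @param lay a layout data.frame as from [default_plate_layout()].
#' @return `read_plate_map()` returns the validated layout data.frame.
#' @export
read_plate_map <- function(path) {
  lay <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(lay)) stop("empty plate map: ", path)
  if (anyDuplicated(lay$well)) {
    lines <- which(duplicated(lay$well)) + 1L  # +1 for header
    stop("duplicate well ids at line(s): ", toString(lines))
  }
  lay$gene <- as.character(lay$gene)
  validate_layout(lay)
  lay
}

#' @rdname read_plate_map
#' @export
write_plate_map <- function(lay, path) {
  validate_layout(lay)
  write.csv(lay, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
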