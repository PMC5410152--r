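#' Developmental timeline matrix
#'
#' A `timeline_matrix` records, for each species, the ordinal stage position
#' at which each developmental event occurs.  Equal positions within a
#' species denote simultaneous events.  Cells may instead be *unknown*
#' (the event was not observed; coded `?` on disk) or *inapplicable* (the
#' species lacks the structure, e.g. limb events in limbless taxa; coded
#' `-` on disk).
#'
#' @param positions Integer matrix, species in rows, events in columns,
#'   with `NA` for cells that are unknown or inapplicable.  Row and column
#'   names are required and must be unique.
#' @param inapplicable Logical matrix of the same shape marking
#'   inapplicable cells, or `NULL` for none.  Inapplicable cells must be
#'   `NA` in `positions`.
#' @return An object of class `timeline_matrix` with elements `positions`
#'   (integer matrix, `NA` = no recorded position), `inapplicable`
#'   (logical matrix), `species` and `events` (character vectors).
#' @examples
#' pos <- rbind(sp1 = c(1L, 2L, 3L), sp2 = c(2L, 1L, NA))
#' colnames(pos) <- c("ev1", "ev2", "ev3")
#' timeline_matrix(pos)
#' @export
timeline_matrix <- function(positions, inapplicable = NULL) {
  if (!is.matrix(positions))
    stop("'positions' must be a matrix")
  if (is.null(rownames(positions)) || is.null(colnames(positions)))
    stop("'positions' needs species row names and event column names")
  if (anyDuplicated(rownames(positions)))
    stop("duplicate species label: ",
         rownames(positions)[duplicated(rownames(positions))][1L])
  if (anyDuplicated(colnames(positions)))
    stop("duplicate event label")
  storage.mode(positions) <- "integer"
  if (any(positions[!is.na(positions)] < 1L))
    stop("stage positions must be positive integers")
  if (is.null(inapplicable)) {
    inapplicable <- matrix(FALSE, nrow(positions), ncol(positions),
                           dimnames = dimnames(positions))
  } else {
    inapplicable <- inapplicable[rownames(positions), colnames(positions),
                                 drop = FALSE]
    if (any(inapplicable & !is.na(positions)))
      stop("inapplicable cells cannot carry a stage position")
  }
  structure(list(positions = positions, inapplicable = inapplicable,
                 species = rownames(positions),
                 events = colnames(positions)),
            class = "timeline_matrix")
}

#' Read a developmental timeline table
#'
#' Reads a delimited text table with species in rows (first column) and
#' events in columns.  Cells hold positive integer stage positions, `?`
#' for unknown, or `-` for inapplicable.
#'
#' @param path Path to the file.
#' @param sep Field separator (default `","`).
#' @return A [timeline_matrix()].
#' @export
read_timeline <- function(path, sep = ",") {
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", comment.char = "",
                   quote = "\"", strip.white = TRUE)
  if (ncol(df) < 2L)
    stop("timeline table needs a species column plus >= 1 event column")
  species <- df[[1L]]
  if (anyDuplicated(species))
    stop("duplicate species label: ", species[duplicated(species)][1L])
  cells <- as.matrix(df[, -1L, drop = FALSE])
  rownames(cells) <- species
  pos <- matrix(NA_integer_, nrow(cells), ncol(cells),
                dimnames = dimnames(cells))
  inap <- matrix(FALSE, nrow(cells), ncol(cells),
                 dimnames = dimnames(cells))
  for (j in seq_len(ncol(cells))) {
    x <- cells[, j]
    ok_int <- grepl("^[0-9]+$", x)
    bad <- !(ok_int | x == "?" | x == "-")
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("invalid cell '%s' at species '%s', event '%s'",
                   x[i], species[i], colnames(cells)[j]))
    }
    pos[ok_int, j] <- as.integer(x[ok_int])
    inap[x == "-", j] <- TRUE
  }
  timeline_matrix(pos, inap)
}

#' Write a timeline matrix to delimited text
#'
#' Inverse of [read_timeline()]: unknown cells become `?`, inapplicable
#' cells `-`.
#'
#' @param timelines A [timeline_matrix()].
#' @param path Output file path.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timelines, path, sep = ",") {
  stopifnot(inherits(timelines, "timeline_matrix"))
  cells <- matrix(as.character(timelines$positions),
                  nrow(timelines$positions), ncol(timelines$positions))
  cells[is.na(timelines$positions)] <- "?"
  cells[timelines$inapplicable] <- "-"
  df <- data.frame(species = timelines$species, cells,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("species", timelines$events)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.timeline_matrix <- function(x, ...) {
  cat(sprintf("Timeline matrix: %d species x %d events\n",
              length(x$species), length(x$events)))
  cat(sprintf("  unknown cells: %d, inapplicable cells: %d\n",
              sum(is.na(x$positions) & !x$inapplicable),
              sum(x$inapplicable)))
  invisible(x)
}

#' @export
dim.timeline_matrix <- function(x) dim(x$positions)
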