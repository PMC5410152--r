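#' Discrete cladistic character matrix
#'
#' Holds integer character states per taxon, with `NA` cells split into
#' missing (`?`) and inapplicable (`-`) exactly as a TNT or NEXUS standard
#' data block would code them.
#'
#' @param states Integer matrix, taxa in rows, characters in columns,
#'   `NA` for missing/inapplicable; states must be in 0..9 (the standard
#'   single-symbol alphabet).
#' @param inapplicable Logical matrix marking which `NA` cells are
#'   inapplicable rather than missing; `NULL` for none.
#' @param ordered Logical; whether characters are treated as ordered
#'   (additive, linear-scale costs) by default in downstream analyses.
#' @param pairs Optional two-column integer matrix giving, for event-pair
#'   characters, the (i, j) event indices behind each column.
#' @return An object of class `char_matrix`.
#' @export
char_matrix <- function(states, inapplicable = NULL, ordered = FALSE,
                        pairs = NULL) {
  if (!is.matrix(states)) stop("'states' must be a matrix")
  if (is.null(rownames(states))) stop("'states' needs taxon row names")
  if (is.null(colnames(states)))
    colnames(states) <- paste0("char", seq_len(ncol(states)))
  storage.mode(states) <- "integer"
  def <- states[!is.na(states)]
  if (length(def) && (min(def) < 0L || max(def) > 9L))
    stop("states must lie in 0..9")
  if (is.null(inapplicable)) {
    inapplicable <- matrix(FALSE, nrow(states), ncol(states),
                           dimnames = dimnames(states))
  } else if (any(inapplicable & !is.na(states))) {
    stop("inapplicable cells cannot carry a state")
  }
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    stopifnot(nrow(pairs) == ncol(states), ncol(pairs) == 2L)
  }
  structure(list(states = states, inapplicable = inapplicable,
                 taxa = rownames(states), ordered = isTRUE(ordered),
                 pairs = pairs),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("Character matrix: %d taxa x %d characters (%s)\n",
              nrow(x$states), ncol(x$states),
              if (x$ordered) "ordered" else "unordered"))
  if (!is.null(x$pairs)) cat("  event-pair characters\n")
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$states)

cm_symbol_rows <- function(cm) {
  sym <- matrix("?", nrow(cm$states), ncol(cm$states))
  def <- !is.na(cm$states)
  sym[def] <- as.character(cm$states[def])
  sym[cm$inapplicable] <- "-"
  apply(sym, 1L, paste0, collapse = "")
}

#' Serialise a character matrix to NEXUS or TNT text
#'
#' Emits a standard-data block that round-trips exactly through
#' [read_character_matrix()], preserving `?` (missing) and `-`
#' (inapplicable) cells.
#'
#' @param cm A [char_matrix()].
#' @param format `"nexus"` or `"tnt"`.
#' @param file Optional path; when given the text is also written there.
#' @return The serialised text, invisibly when `file` is given.
#' @export
write_character_matrix <- function(cm, format = c("nexus", "tnt"),
                                   file = NULL) {
  format <- match.arg(format)
  if (any(grepl("[[:space:]]", cm$taxa)))
    stop("taxon labels must not contain whitespace")
  rows <- cm_symbol_rows(cm)
  pad <- formatC(cm$taxa, width = max(nchar(cm$taxa)) + 2L, flag = "-")
  body <- paste0(pad, rows)
  txt <- if (format == "nexus") {
    paste(c("#NEXUS",
            "BEGIN DATA;",
            sprintf("DIMENSIONS NTAX=%d NCHAR=%d;",
                    nrow(cm$states), ncol(cm$states)),
            "FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"0123456789\";",
            "MATRIX", body, ";", "END;", ""),
          collapse = "\n")
  } else {
    paste(c("xread",
            sprintf("%d %d", ncol(cm$states), nrow(cm$states)),
            body, ";", ""),
          collapse = "\n")
  }
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Parse a NEXUS or TNT character matrix
#'
#' @param text Character matrix text (a single string or lines); exactly
#'   the dialect emitted by [write_character_matrix()].
#' @param format `"nexus"` or `"tnt"`.
#' @inheritParams char_matrix
#' @return A [char_matrix()].
#' @export
read_character_matrix <- function(text, format = c("nexus", "tnt"),
                                  ordered = FALSE) {
  format <- match.arg(format)
  if (length(text) == 1L && file.exists(text))
    text <- readLines(text)
  lines <- trimws(unlist(strsplit(text, "\n", fixed = TRUE)))
  lines <- lines[nzchar(lines)]
  if (format == "nexus") {
    i0 <- which(toupper(lines) == "MATRIX")
    if (length(i0) != 1L) stop("no MATRIX block found")
    i1 <- which(lines == ";" & seq_along(lines) > i0)[1L]
    body <- lines[(i0 + 1L):(i1 - 1L)]
  } else {
    i0 <- which(tolower(lines) == "xread")
    if (length(i0) != 1L) stop("no xread block found")
    body <- lines[(i0 + 2L):(which(lines == ";")[1L] - 1L)]
  }
  parts <- strsplit(body, "[[:space:]]+")
  taxa <- vapply(parts, `[`, "", 1L)
  rows <- vapply(parts, `[`, "", 2L)
  chars <- strsplit(rows, "", fixed = TRUE)
  ncharacter <- unique(lengths(chars))
  if (length(ncharacter) != 1L) stop("ragged matrix rows")
  sym <- do.call(rbind, chars)
  bad <- !(sym %in% c(as.character(0:9), "?", "-"))
  if (any(bad)) stop("unexpected symbol: ", sym[bad][1L])
  states <- matrix(NA_integer_, nrow(sym), ncol(sym),
                   dimnames = list(taxa, paste0("char", seq_len(ncol(sym)))))
  num <- sym %in% as.character(0:9)
  states[num] <- as.integer(sym[num])
  char_matrix(states, inapplicable = sym == "-", ordered = ordered)
}
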