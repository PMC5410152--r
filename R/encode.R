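#' Scale developmental sequences to continuous characters
#'
#' Within each species the recorded stage positions are collapsed to
#' ranks 1..P (simultaneous events share a rank) and rescaled so the
#' first event takes the value 0 and the last the value 1:
#' value = (rank - 1) / (P - 1).  Unknown and inapplicable cells
#' propagate; unknown events do not shift the ranks of recorded events.
#'
#' @param timelines A [timeline_matrix()].
#' @return An object of class `continuous_matrix` with elements `values`
#'   (numeric matrix in \[0, 1\], `NA` for unknown/inapplicable),
#'   `inapplicable`, `species`, `events`.
#' @examples
#' pos <- rbind(sp = c(1L, 1L, 2L))
#' colnames(pos) <- c("a", "b", "c")
#' to_continuous(timeline_matrix(pos))$values  # 0, 0, 1
#' @export
to_continuous <- function(timelines) {
  stopifnot(inherits(timelines, "timeline_matrix"))
  pos <- timelines$positions
  vals <- matrix(NA_real_, nrow(pos), ncol(pos), dimnames = dimnames(pos))
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    rec <- !is.na(p)
    lev <- sort(unique(p[rec]))
    if (length(lev) < 2L) {
      if (any(rec))
        warning(sprintf(
          "species '%s' has < 2 distinct positions; values set unknown",
          rownames(pos)[i]))
      next
    }
    rank <- match(p[rec], lev)
    vals[i, rec] <- (rank - 1) / (length(lev) - 1)
  }
  structure(list(values = vals, inapplicable = timelines$inapplicable,
                 species = timelines$species, events = timelines$events),
            class = "continuous_matrix")
}

#' @export
print.continuous_matrix <- function(x, ...) {
  cat(sprintf("Continuous timing matrix: %d species x %d events\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Decile-bin continuous timing values into cladistic characters
#'
#' Values between 0 and 0.09 become state 0, between 0.1 and 0.19 state 1,
#' and so on; a value of exactly 1 is clamped into the top bin (state 9).
#' The resulting characters are flagged orderable.
#'
#' @param continuous A `continuous_matrix` from [to_continuous()].
#' @return A [char_matrix()] with `ordered = TRUE`.
#' @export
discretize <- function(continuous) {
  stopifnot(inherits(continuous, "continuous_matrix"))
  v <- continuous$values
  def <- !is.na(v)
  if (any(v[def] < 0 | v[def] > 1))
    stop("continuous values must lie in [0, 1]")
  st <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  st[def] <- pmin(as.integer(floor(10 * v[def])), 9L)
  char_matrix(st, inapplicable = continuous$inapplicable, ordered = TRUE)
}

#' Encode timelines as event-pair characters
#'
#' One character per unordered event pair (i < j), with state 0 when
#' event i occurs earlier than j, 1 when they are simultaneous, and 2
#' when i occurs later.  A pair is missing (`?`) when either event is
#' unknown and inapplicable (`-`) when either is inapplicable.  E events
#' yield E(E-1)/2 characters.
#'
#' @param timelines A [timeline_matrix()].
#' @return A [char_matrix()] whose `pairs` element maps each character to
#'   its (i, j) event indices.
#' @export
event_pair_encode <- function(timelines) {
  stopifnot(inherits(timelines, "timeline_matrix"))
  pos <- timelines$positions
  inap <- timelines$inapplicable
  E <- ncol(pos)
  if (E < 2L) stop("need at least 2 events")
  pr <- t(combn(E, 2L))
  st <- matrix(NA_integer_, nrow(pos), nrow(pr),
               dimnames = list(rownames(pos),
                               sprintf("ep_%d_%d", pr[, 1L], pr[, 2L])))
  ina <- matrix(FALSE, nrow(pos), nrow(pr), dimnames = dimnames(st))
  for (k in seq_len(nrow(pr))) {
    pi <- pos[, pr[k, 1L]]; pj <- pos[, pr[k, 2L]]
    known <- !is.na(pi) & !is.na(pj)
    st[known, k] <- 1L + sign(pi[known] - pj[known])
    ina[, k] <- inap[, pr[k, 1L]] | inap[, pr[k, 2L]]
    st[ina[, k], k] <- NA_integer_
  }
  char_matrix(st, inapplicable = ina, ordered = FALSE, pairs = pr)
}
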