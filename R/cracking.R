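# Event-pair cracking: decompose a node's event-pair character changes
# into per-event total relative change (TRC) scores and flag events whose
# TRC lies beyond the 95% confidence interval of the node's mean TRC.

#' Extract event-pair changes on the branch into a node
#'
#' Filters the branch-change table of an [mp_reconstruct()] or
#' [ml_mk_reconstruct()] result (on event-pair characters) down to one
#' node.  Magnitudes follow ordered state semantics (child minus parent);
#' when a set-valued endpoint makes the degree of change ambiguous but
#' the direction is consistent (e.g. 0 to 1-or-2) the magnitude is the
#' mean of the consistent values (1.5 in that example); when the
#' direction itself is ambiguous (e.g. 1 to 0-or-2) the change carries
#' `excluded = TRUE` and takes no part in cracking.
#'
#' @param reconstruction An `mp_reconstruction` or `mk_reconstruction`
#'   built from event-pair characters.
#' @param node Node label (internal `N<k>` name or tip label).
#' @return The subset of the change table for that node.
#' @export
extract_branch_changes <- function(reconstruction, node) {
  ch <- reconstruction$changes
  if (is.null(ch$event_i))
    stop("reconstruction does not carry event-pair characters")
  ch[ch$node == node, , drop = FALSE]
}

#' Is a node's change set informative enough to crack?
#'
#' A node is crackable when at least one event participates in two or
#' more non-excluded changes; a single synapomorphy, or two synapomorphies
#' involving four different events, leave no background pattern to
#' estimate and are excluded.
#'
#' @param changes Change table for one node
#'   (see [extract_branch_changes()]).
#' @return Logical.
#' @export
node_is_crackable <- function(changes) {
  ch <- changes[!changes$excluded, , drop = FALSE]
  if (nrow(ch) < 2L) return(FALSE)
  any(table(c(ch$event_i, ch$event_j)) >= 2L)
}

#' Crack one node: per-event total relative change with CI
#'
#' Every non-excluded change of pair (i, j) with magnitude m contributes
#' +m to event i and -m to event j (positive = the event shifts later).
#' An event's TRC is its summed contribution divided by the number of
#' changed pairs it participates in; events in no change are omitted.
#' The mean TRC over the participating events gets a two-tailed Student-t
#' confidence interval; with fewer than 3 participating events the CI is
#' undefined and the node is reported without flags.
#'
#' @inheritParams node_is_crackable
#' @param node Optional node label stored in the result.
#' @param level Confidence level (default 0.95).
#' @return An object of class `crack_result`: list with `node`, `trc`
#'   (named per-event vector), `n_pairs` (per-event change counts),
#'   `mean_trc`, `ci_lower`, `ci_upper`, `n_events`, `level`.
#' @export
crack_node <- function(changes, node = NULL, level = 0.95) {
  ch <- changes[!changes$excluded & !is.na(changes$magnitude), ,
                drop = FALSE]
  if (!node_is_crackable(changes))
    stop("node is not crackable (see node_is_crackable)")
  if (is.null(node))
    node <- if (nrow(ch)) ch$node[1L] else NA_character_
  ev <- sort(unique(c(ch$event_i, ch$event_j)))
  contrib <- setNames(numeric(length(ev)), ev)
  npair <- setNames(integer(length(ev)), ev)
  for (r in seq_len(nrow(ch))) {
    i <- as.character(ch$event_i[r]); j <- as.character(ch$event_j[r])
    contrib[i] <- contrib[i] + ch$magnitude[r]
    contrib[j] <- contrib[j] - ch$magnitude[r]
    npair[i] <- npair[i] + 1L
    npair[j] <- npair[j] + 1L
  }
  trc <- contrib / npair
  n <- length(trc)
  if (n >= 3L) {
    m <- mean(trc)
    s <- sd(trc)
    tq <- qt(1 - (1 - level) / 2, n - 1L)
    lo <- m - tq * s / sqrt(n)
    hi <- m + tq * s / sqrt(n)
  } else {
    m <- mean(trc); lo <- NA_real_; hi <- NA_real_
  }
  structure(list(node = node, trc = trc, n_pairs = npair, mean_trc = m,
                 ci_lower = lo, ci_upper = hi, n_events = n,
                 level = level),
            class = "crack_result")
}

#' @export
print.crack_result <- function(x, ...) {
  cat(sprintf("Event-pair cracking at node %s: %d events, mean TRC %.3f",
              x$node, x$n_events, x$mean_trc))
  if (!is.na(x$ci_lower))
    cat(sprintf(", %g%% CI [%.3f, %.3f]", 100 * x$level,
                x$ci_lower, x$ci_upper))
  cat("\n")
  print(round(x$trc, 3))
  invisible(x)
}

#' Flag heterochronic events from a crack result
#'
#' Events whose TRC lies strictly beyond the confidence interval of the
#' node's mean TRC are heterochronic: above the upper bound = later
#' development, below the lower bound = earlier development.
#'
#' @param result A `crack_result` from [crack_node()].
#' @return A `heterochrony_report` data frame (possibly empty; always
#'   empty when the CI is undefined).
#' @export
flag_heterochronic_events <- function(result) {
  stopifnot(inherits(result, "crack_result"))
  out <- empty_heterochrony_report()
  if (is.na(result$ci_lower)) return(out)
  for (e in names(result$trc)) {
    v <- result$trc[[e]]
    dir <- if (v > result$ci_upper) "later"
           else if (v < result$ci_lower) "earlier" else next
    out[nrow(out) + 1L, ] <- list(result$node, e, dir, v,
                                  result$ci_lower, result$ci_upper,
                                  "event-pair cracking")
  }
  out
}

#' Crack every branch of a reconstruction
#'
#' Applies [extract_branch_changes()], [node_is_crackable()],
#' [crack_node()] and [flag_heterochronic_events()] to the branch into
#' every non-root node (tips included) of an event-pair reconstruction.
#'
#' @inheritParams extract_branch_changes
#' @param level Confidence level (default 0.95).
#' @return List with `report` (a `heterochrony_report` of all flags),
#'   `cracks` (per-node `crack_result`s), `skipped` (data frame of nodes
#'   with changes that were not crackable, with reasons).
#' @export
crack_tree <- function(reconstruction, level = 0.95) {
  nodes <- unique(reconstruction$changes$node)
  cracks <- list()
  reports <- list()
  skipped <- data.frame(node = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (nd in nodes) {
    ch <- extract_branch_changes(reconstruction, nd)
    if (!node_is_crackable(ch)) {
      skipped[nrow(skipped) + 1L, ] <-
        list(nd, if (all(ch$excluded)) "all changes direction-ambiguous"
                 else "too few linked event-pair changes")
      next
    }
    cr <- crack_node(ch, node = nd, level = level)
    cracks[[nd]] <- cr
    reports[[nd]] <- flag_heterochronic_events(cr)
  }
  report <- if (length(reports)) do.call(rbind, reports) else
    empty_heterochrony_report()
  rownames(report) <- NULL
  class(report) <- c("heterochrony_report", "data.frame")
  list(report = report, cracks = cracks, skipped = skipped)
}
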