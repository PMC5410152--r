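# Simulator of developmental-sequence evolution along a phylogeny, with
# known injected heterochronic shifts, so every pipeline stage can be
# validated against a truth log.

#' Simulation configuration
#'
#' @param tree A rooted `phylo`; branches without lengths get unit
#'   lengths.
#' @param n_events Number of developmental events E (ancestral order is
#'   the identity permutation 1..E).
#' @param swap_rate Expected number of random adjacent transpositions per
#'   unit branch length (neutral background churn).
#' @param shifts List of injected heterochronic shifts, each a list with
#'   `node` (label of the child end of the branch: a tip label or
#'   internal `N<k>` name), `event` (index), `delta` (signed positions;
#'   positive = later).  Applied after the branch's background swaps,
#'   clamped to the sequence ends.
#' @param tie_rate Probability that each boundary between adjacent
#'   positions of a tip sequence is collapsed into a tie.
#' @param missing_rate Per-cell probability of recoding as unknown
#'   (applied by [apply_missingness()]).
#' @param limbless_tips Tips whose `limb_events` are inapplicable.
#' @param limb_events Event indices that require limbs.
#' @param seed Integer seed governing all stochastic stages.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree, n_events = 10L, swap_rate = 0.5,
                       shifts = list(), tie_rate = 0, missing_rate = 0,
                       limbless_tips = character(0),
                       limb_events = integer(0), seed = 1L) {
  stopifnot(n_events >= 2L, swap_rate >= 0,
            tie_rate >= 0, tie_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  for (s in shifts)
    stopifnot(s$event >= 1L, s$event <= n_events)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  structure(list(tree = name_internal_nodes(tree), n_events = n_events,
                 swap_rate = swap_rate, shifts = shifts,
                 tie_rate = tie_rate, missing_rate = missing_rate,
                 limbless_tips = limbless_tips, limb_events = limb_events,
                 seed = seed),
            class = "sim_config")
}

# order = permutation vector: order[k] is the event at sequence slot k
ranks_of <- function(ord) match(seq_along(ord), ord)

#' Simulate developmental timelines along a phylogeny
#'
#' The ancestral event order is the identity permutation.  Along each
#' branch, Poisson(`swap_rate` x branch length) random adjacent
#' transpositions are applied, then any injected shifts for that branch
#' (the named event moves by `delta` positions, clamped).  Tip sequences
#' become stage positions; with `tie_rate` > 0 adjacent positions may be
#' merged into ties.  The truth log records, per branch, the net rank
#' displacement of every event that moved.
#'
#' @param config A [sim_config()].
#' @return List with `timelines` (a [timeline_matrix()]) and `truth`
#'   (data frame: `node` = child end of the branch, `event`, `delta` =
#'   signed net rank displacement, `injected`).
#' @export
simulate_timelines <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  E <- config$n_events
  ntip <- length(tree$tip.label)
  labs <- node_label_vector(tree)
  shift_node <- vapply(config$shifts, function(s) as.character(s$node), "")
  pre <- ape::reorder.phylo(tree, "cladewise")
  orders <- vector("list", ntip + tree$Nnode)
  orders[[ntip + 1L]] <- seq_len(E)
  truth <- list()
  for (r in seq_len(nrow(pre$edge))) {
    p <- pre$edge[r, 1L]; ch <- pre$edge[r, 2L]
    ord <- orders[[p]]
    nsw <- rpois(1L, config$swap_rate * pre$edge.length[r])
    if (nsw > 0) for (k in seq_len(nsw)) {
      i <- sample.int(E - 1L, 1L)
      ord[c(i, i + 1L)] <- ord[c(i + 1L, i)]
    }
    injected_ev <- integer(0)
    for (si in which(shift_node == labs[ch])) {
      s <- config$shifts[[si]]
      pos <- match(s$event, ord)
      newpos <- min(max(pos + s$delta, 1L), E)
      ord <- append(ord[-pos], s$event, after = newpos - 1L)
      injected_ev <- c(injected_ev, s$event)
    }
    orders[[ch]] <- ord
    dr <- ranks_of(ord) - ranks_of(orders[[p]])
    moved <- which(dr != 0L)
    if (length(moved))
      truth[[length(truth) + 1L]] <- data.frame(
        node = labs[ch], event = moved, delta = dr[moved],
        injected = moved %in% injected_ev, stringsAsFactors = FALSE)
  }
  pos <- matrix(NA_integer_, ntip, E,
                dimnames = list(tree$tip.label, paste0("ev", seq_len(E))))
  for (t in seq_len(ntip)) {
    rk <- ranks_of(orders[[t]])
    if (config$tie_rate > 0) {
      merge <- runif(E - 1L) < config$tie_rate
      # collapse position boundaries flagged for merging
      grp <- cumsum(c(1L, as.integer(!merge)))
      rk <- grp[rk]
    }
    pos[t, ] <- rk
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(node = character(), event = integer(), delta = integer(),
               injected = logical(), stringsAsFactors = FALSE)
  list(timelines = timeline_matrix(pos), truth = truth)
}

#' Apply missingness and inapplicability to simulated timelines
#'
#' Each cell independently becomes unknown with probability
#' `missing_rate`; limb events in limbless tips become inapplicable.
#'
#' @param timelines A [timeline_matrix()].
#' @param config A [sim_config()] (its `missing_rate`, `limbless_tips`,
#'   `limb_events` and `seed` are used).
#' @return A [timeline_matrix()].
#' @export
apply_missingness <- function(timelines, config) {
  stopifnot(inherits(timelines, "timeline_matrix"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  pos <- timelines$positions
  inap <- timelines$inapplicable
  if (config$missing_rate > 0) {
    drop <- matrix(runif(length(pos)) < config$missing_rate,
                   nrow(pos), ncol(pos))
    pos[drop] <- NA_integer_
  }
  if (length(config$limbless_tips) && length(config$limb_events)) {
    tips <- intersect(config$limbless_tips, rownames(pos))
    pos[tips, config$limb_events] <- NA_integer_
    inap[tips, config$limb_events] <- TRUE
  }
  timeline_matrix(pos, inap)
}

#' Seeded recovery benchmark for both heterochrony detectors
#'
#' Simulates replicate datasets, each with a single strong heterochronic
#' shift injected on a random pendant branch, and asks whether each
#' detector flags the shifted event on the shifted taxon with the right
#' direction: event-pair cracking on the ordered most-parsimonious
#' reconstruction, and the continuous root-CI criterion.
#'
#' @param n_seeds Number of replicates (default 50).
#' @param ntaxa,n_events Size of each simulated dataset (defaults 12
#'   taxa, 10 events).
#' @param swap_rate Background adjacent-transposition rate per unit
#'   branch length (default 0.5).
#' @param shift Injected displacement in positions (default +4, a shift
#'   to later development).
#' @param seed Master seed; replicate seeds are derived from it.
#' @return List with `cracking_recall`, `continuous_recall`,
#'   `cracking_precision` (mean per-seed precision of the cracking report
#'   against the full truth log at the injected tolerance), and `detail`
#'   (per-seed data frame).
#' @export
recovery_benchmark <- function(n_seeds = 50L, ntaxa = 12L, n_events = 10L,
                               swap_rate = 0.5, shift = 4L, seed = 1L) {
  detail <- data.frame(seed = integer(), tip = character(),
                       event = integer(), cracking = logical(),
                       continuous = logical(), precision = numeric(),
                       stringsAsFactors = FALSE)
  for (s in seq_len(n_seeds)) {
    rs <- (seed * 1000L + s) %% .Machine$integer.max
    set.seed(rs)
    tre <- unit_branch_lengths(
      ape::rtree(ntaxa, tip.label = paste0("t", seq_len(ntaxa))))
    tip <- sample(tre$tip.label, 1L)
    event <- sample.int(n_events - shift, 1L)
    cfg <- sim_config(tre, n_events = n_events, swap_rate = swap_rate,
                      shifts = list(list(node = tip, event = event,
                                         delta = shift)),
                      seed = rs)
    sim <- simulate_timelines(cfg)
    ep <- event_pair_encode(sim$timelines)
    mpr <- mp_reconstruct(ep, tre, ordered = TRUE)
    crk <- crack_tree(mpr)$report
    hit_crk <- any(crk$node == tip & crk$event == as.character(event) &
                   crk$direction == "later")
    prec <- evaluate_recovery(crk, sim$truth, tolerance = shift)$precision
    ct <- to_continuous(sim$timelines)
    cont <- flag_continuous_heterochrony(ct, tre)
    hit_cont <- any(cont$node == tip &
                    cont$event == paste0("ev", event) &
                    cont$direction == "later")
    detail[nrow(detail) + 1L, ] <- list(rs, tip, event, hit_crk,
                                        hit_cont, prec)
  }
  list(cracking_recall = mean(detail$cracking),
       continuous_recall = mean(detail$continuous),
       cracking_precision = mean(detail$precision),
       detail = detail)
}

#' Precision and recall of a heterochrony report against simulation truth
#'
#' A flagged (node, event, direction) record is a true positive when the
#' truth log holds a move of that event on the branch into that node, in
#' the same direction, with |delta| at least `tolerance`.  Truth moves of
#' at least `tolerance` positions that were not flagged are false
#' negatives.  Empty report and empty truth give precision = recall = 1.
#'
#' @param report A `heterochrony_report` (from either detector).
#' @param truth Truth data frame from [simulate_timelines()].
#' @param tolerance Minimum |delta| for a truth move to count as a real
#'   heterochrony (default 1).
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`, and the
#'   matched report rows.
#' @export
evaluate_recovery <- function(report, truth, tolerance = 1) {
  truth <- truth[abs(truth$delta) >= tolerance, , drop = FALSE]
  truth_key <- paste(truth$node,
                     truth$event,
                     ifelse(truth$delta > 0, "later", "earlier"))
  ev_num <- suppressWarnings(as.integer(sub("^ev", "", report$event)))
  rep_key <- paste(report$node, ev_num, report$direction)
  tp <- sum(rep_key %in% truth_key)
  fp <- nrow(report) - tp
  fn <- sum(!(truth_key %in% rep_key))
  precision <- if (nrow(report) == 0L) 1 else tp / (tp + fp)
  recall <- if (nrow(truth) == 0L) 1 else tp / (tp + fn)
  list(precision = precision, recall = recall, tp = tp, fp = fp, fn = fn,
       matched = report[rep_key %in% truth_key, , drop = FALSE])
}
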