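# Heuristic and exhaustive maximum-parsimony tree search.
#
# Internally trees are held UNROOTED as a 2-column matrix of undirected
# edges; tips keep the fixed ids 1..ntip (row order of the character
# matrix), internal nodes any ids above ntip.  Scoring orients the edges
# away from an arbitrary internal node (parsimony length is invariant
# under rerooting) and calls the compiled Fitch/Sankoff kernel.

u_adjacency <- function(ue) {
  nmax <- max(ue)
  adj <- vector("list", nmax)
  for (r in seq_len(nrow(ue))) {
    a <- ue[r, 1L]; b <- ue[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# orient undirected edges away from the internal node attached to the
# smallest tip present -> (parent, child); deterministic across
# topologies so returned trees are rooted compatibly
u_orient <- function(ue, ntip) {
  adj <- u_adjacency(ue)
  t0 <- min(ue[ue <= ntip])
  root <- adj[[t0]][1L]
  if (root <= ntip) root <- ue[ue > ntip][1L]
  if (is.na(root)) stop("tree has no internal node")
  nmax <- length(adj)
  parent <- rep(0L, nmax)
  seen <- rep(FALSE, nmax)
  queue <- root; seen[root] <- TRUE; head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
    }
  }
  nodes <- which(parent > 0L)
  cbind(parent[nodes], nodes, deparse.level = 0L)
}

# renumber internal nodes to consecutive ids starting at ntip + 1
u_canon <- function(ue, ntip) {
  ints <- sort(unique(ue[ue > ntip]))
  if (!length(ints)) return(ue)
  map <- integer(max(ue))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[ints] <- ntip + seq_along(ints)
  matrix(map[ue], ncol = 2L)
}

# replace edge row r by two edges through a new node carrying `tip`
u_graft_tip <- function(ue, r, tip, newnode) {
  u <- ue[r, 1L]; v <- ue[r, 2L]
  rbind(ue[-r, , drop = FALSE],
        c(u, newnode), c(newnode, v), c(newnode, tip))
}

# splice out a degree-2 internal node, if x is one
u_suppress <- function(ue, x, ntip) {
  if (x <= ntip) return(ue)
  rows <- which(ue[, 1L] == x | ue[, 2L] == x)
  if (length(rows) != 2L) return(ue)
  nb <- setdiff(as.vector(ue[rows, ]), x)
  rbind(ue[-rows, , drop = FALSE], nb)
}

# connected component (node set) containing `start` in an edge matrix
u_component <- function(ue, start) {
  if (!nrow(ue)) return(start)
  nodes <- start
  repeat {
    hit <- ue[, 1L] %in% nodes | ue[, 2L] %in% nodes
    nxt <- unique(c(nodes, as.vector(ue[hit, ])))
    if (length(nxt) == length(nodes)) return(nodes)
    nodes <- nxt
  }
}

# All tree bisection-reconnection rearrangements of an unrooted tree:
# every edge is bisected and the two fragments rejoined by a new edge
# between every pair of (subdivided) edges, one in each fragment.
tbr_neighbors <- function(ue, ntip) {
  res <- list()
  nmax0 <- max(ue, ntip)
  for (r in seq_len(nrow(ue))) {
    a <- ue[r, 1L]; b <- ue[r, 2L]
    rest <- ue[-r, , drop = FALSE]
    nodesA <- u_component(rest, a)
    inA <- rest[, 1L] %in% nodesA
    eA <- rest[inA, , drop = FALSE]
    eB <- rest[!inA, , drop = FALSE]
    eA <- u_suppress(eA, a, ntip)
    eB <- u_suppress(eB, b, ntip)
    x <- nmax0 + 1L; y <- nmax0 + 2L
    attachA <- if (nrow(eA)) seq_len(nrow(eA)) else NA_integer_
    attachB <- if (nrow(eB)) seq_len(nrow(eB)) else NA_integer_
    for (ga in attachA) for (gb in attachB) {
      if (is.na(ga) && is.na(gb)) next
      if (is.na(ga)) {             # fragment A is the single tip `a`
        u <- eB[gb, 1L]; v <- eB[gb, 2L]
        cand <- rbind(eB[-gb, , drop = FALSE], c(u, x), c(x, v), c(x, a))
      } else if (is.na(gb)) {      # fragment B is the single tip `b`
        u <- eA[ga, 1L]; v <- eA[ga, 2L]
        cand <- rbind(eA[-ga, , drop = FALSE], c(u, x), c(x, v), c(x, b))
      } else {
        u1 <- eA[ga, 1L]; v1 <- eA[ga, 2L]
        u2 <- eB[gb, 1L]; v2 <- eB[gb, 2L]
        cand <- rbind(eA[-ga, , drop = FALSE], eB[-gb, , drop = FALSE],
                      c(u1, x), c(x, v1), c(u2, y), c(y, v2), c(x, y))
      }
      res[[length(res) + 1L]] <- u_canon(cand, ntip)
    }
  }
  res
}

# canonical string of the tree's splits, for duplicate-topology detection
u_split_hash <- function(ue, ntip) {
  de <- u_orient(ue, ntip)
  ord <- de[order(-pmax(de[, 1L], de[, 2L])), , drop = FALSE] # not postorder
  # accumulate tip sets below each node via repeated passes (trees are tiny)
  below <- vector("list", max(de))
  for (t in seq_len(ntip)) below[[t]] <- t
  pending <- de
  while (nrow(pending)) {
    ready <- vapply(seq_len(nrow(pending)), function(i)
      !is.null(below[[pending[i, 2L]]]), TRUE)
    for (i in which(ready)) {
      p <- pending[i, 1L]; chn <- pending[i, 2L]
      below[[p]] <- c(below[[p]], below[[chn]])
    }
    pending <- pending[!ready, , drop = FALSE]
  }
  splits <- character(0)
  full <- seq_len(ntip)
  for (i in seq_len(nrow(de))) {
    chn <- de[i, 2L]
    if (chn <= ntip) next
    s <- sort(below[[chn]])
    if (1L %in% s) s <- setdiff(full, s)
    if (length(s) < 2L || length(s) > ntip - 2L) next
    splits <- c(splits, paste(s, collapse = ","))
  }
  paste(sort(splits), collapse = ";")
}

u_to_phylo <- function(ue, ntip, tip_labels) {
  de <- u_orient(ue, ntip)
  root <- setdiff(de[, 1L], de[, 2L])[1L]
  ints <- unique(c(root, de[de[, 1L] != root, 1L], de[de[, 2L] > ntip, 2L]))
  map <- integer(max(de))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[ints] <- ntip + seq_along(ints)
  edge <- cbind(map[de[, 1L]], map[de[, 2L]])
  tr <- structure(list(edge = edge, Nnode = length(ints),
                       tip.label = tip_labels), class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  name_internal_nodes(tr)
}

score_ue_batch <- function(ues, ntip, tipmask, nstates, ordered) {
  .pars_total_multi_cpp(lapply(ues, u_orient, ntip = ntip), ntip, tipmask,
                        nstates, ordered)
}

#' Heuristic maximum-parsimony tree search
#'
#' Performs replicated random-addition Wagner tree building (greedy
#' stepwise addition minimising tree length) followed by tree
#' bisection-reconnection (TBR) branch swapping to a local optimum,
#' holding up to `hold` equally parsimonious trees per replicate.  Unique
#' topologies at the globally best length, pooled over replicates, are
#' returned.  Seeded and reproducible.
#'
#' @inheritParams tree_length
#' @param replicates Number of random-addition replicates (default 10).
#' @param hold Maximum number of equally best trees held per replicate
#'   (default 10).
#' @param seed Optional integer seed governing the addition orders.
#' @return An object of class `parsimony_search`: list with `trees`
#'   (list of `phylo`), `best_length`, `score` (a `tree_score` for the
#'   first best tree), `replicate_lengths`.
#' @export
heuristic_search <- function(cm, ordered = cm$ordered, replicates = 10L,
                             hold = 10L, seed = NULL) {
  stopifnot(replicates >= 1L, hold >= 1L)
  ntip <- nrow(cm$states)
  if (ntip < 4L) stop("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  ns <- cm_nstates(cm)
  tm <- cm_tipmask(cm, cm$taxa, ns)
  ordered <- isTRUE(ordered)
  score1 <- function(ue) score_ue_batch(list(ue), ntip, tm, ns, ordered)

  pool <- list(); pool_hash <- character(0); pool_len <- numeric(0)
  rep_best <- numeric(replicates)
  for (rep in seq_len(replicates)) {
    ord <- sample.int(ntip)
    ue <- matrix(c(ord[1L], ord[2L]), 1L, 2L)
    nextnode <- ntip
    for (t in ord[-(1:2)]) {
      nextnode <- nextnode + 1L
      cands <- lapply(seq_len(nrow(ue)), function(r)
        u_graft_tip(ue, r, t, nextnode))
      lens <- score_ue_batch(cands, ntip, tm, ns, ordered)
      ue <- cands[[which.min(lens)]]
    }
    ue <- u_canon(ue, ntip)
    held <- list(ue); hashes <- u_split_hash(ue, ntip)
    best <- score1(ue); swapped <- FALSE
    while (any(!swapped)) {
      i <- which(!swapped)[1L]; swapped[i] <- TRUE
      nbs <- tbr_neighbors(held[[i]], ntip)
      lens <- score_ue_batch(nbs, ntip, tm, ns, ordered)
      lo <- min(lens)
      if (lo < best) {
        best <- lo
        keep <- which(lens == lo)
        held <- list(); hashes <- character(0)
        for (k in keep) {
          h <- u_split_hash(nbs[[k]], ntip)
          if (!(h %in% hashes) && length(held) < hold) {
            held <- c(held, nbs[k]); hashes <- c(hashes, h)
          }
        }
        swapped <- rep(FALSE, length(held))
      } else {
        for (k in which(lens == best)) {
          if (length(held) >= hold) break
          h <- u_split_hash(nbs[[k]], ntip)
          if (!(h %in% hashes)) {
            held <- c(held, nbs[k]); hashes <- c(hashes, h)
            swapped <- c(swapped, FALSE)
          }
        }
      }
    }
    rep_best[rep] <- best
    for (k in seq_along(held)) {
      if (!(hashes[k] %in% pool_hash)) {
        pool <- c(pool, held[k])
        pool_hash <- c(pool_hash, hashes[k])
        pool_len <- c(pool_len, best)
      }
    }
  }
  gbest <- min(pool_len)
  keep <- pool_len == gbest
  trees <- lapply(pool[keep], u_to_phylo, ntip = ntip, tip_labels = cm$taxa)
  structure(list(trees = trees, best_length = gbest,
                 score = tree_length(cm, trees[[1L]], ordered),
                 replicate_lengths = rep_best),
            class = "parsimony_search")
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat(sprintf("Parsimony search: best length %g, %d tree(s) retained\n",
              x$best_length, length(x$trees)))
  print(x$score)
  invisible(x)
}

#' Enumerate all unrooted binary topologies
#'
#' @param ntip Number of tips (labelled 1..ntip); feasible for small trees
#'   only (10,395 topologies at 8 tips).
#' @return List of undirected edge matrices (internal representation; see
#'   [exhaustive_search()] for scoring them against a matrix).
#' @keywords internal
all_unrooted_topologies <- function(ntip) {
  stopifnot(ntip >= 3L)
  trees <- list(cbind(rep(ntip + 1L, 3L), 1:3))
  if (ntip == 3L) return(trees)
  for (t in seq(4L, ntip)) {
    newnode <- ntip + t - 2L
    trees <- unlist(lapply(trees, function(ue)
      lapply(seq_len(nrow(ue)), function(r)
        u_graft_tip(ue, r, t, newnode))), recursive = FALSE)
  }
  trees
}

#' Exhaustive maximum-parsimony search
#'
#' Scores every unrooted binary topology; intended as a ground-truth
#' optimum for small taxon sets (<= 9 tips).
#'
#' @inheritParams tree_length
#' @return List with `best_length` and `trees` (list of `phylo` at the
#'   optimum).
#' @export
exhaustive_search <- function(cm, ordered = cm$ordered) {
  ntip <- nrow(cm$states)
  if (ntip > 9L) stop("exhaustive search is limited to 9 taxa")
  ns <- cm_nstates(cm)
  tm <- cm_tipmask(cm, cm$taxa, ns)
  topos <- all_unrooted_topologies(ntip)
  lens <- score_ue_batch(topos, ntip, tm, ns, isTRUE(ordered))
  keep <- which(lens == min(lens))
  list(best_length = min(lens),
       trees = lapply(topos[keep], u_to_phylo, ntip = ntip,
                      tip_labels = cm$taxa))
}

#' Consensus of a set of trees
#'
#' @param trees List of `phylo` trees (or a `multiPhylo`) over identical
#'   tip sets.
#' @param kind `"strict"` (clades present in all trees) or `"majority50"`
#'   (clades in more than half of the trees).
#' @return A `phylo` consensus tree.
#' @export
consensus_tree <- function(trees, kind = c("strict", "majority50")) {
  kind <- match.arg(kind)
  if (inherits(trees, "phylo")) trees <- list(trees)
  tips <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(tips, paste, "", collapse = "\r"))) != 1L)
    stop("trees must share an identical tip set")
  if (length(trees) == 1L) return(trees[[1L]])
  class(trees) <- "multiPhylo"
  # splits are compared unrooted so differently rooted representations of
  # the same topology agree
  ape::consensus(trees, p = if (kind == "strict") 1 else 0.5,
                 rooted = FALSE)
}
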