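# -- matrix <-> engine plumbing ---------------------------------------------

# number of states the engine runs with: 0..max observed state
cm_nstates <- function(cm) {
  mx <- suppressWarnings(max(cm$states, na.rm = TRUE))
  if (!is.finite(mx)) 1L else max(1L, mx + 1L)
}

# state bitmasks aligned with the tree's tip order; '?' and '-' are both
# scored as full ambiguity
cm_tipmask <- function(cm, tip_labels, nstates = cm_nstates(cm)) {
  miss <- setdiff(tip_labels, cm$taxa)
  if (length(miss))
    stop("tree tip missing from matrix: ", paste(miss, collapse = ", "))
  extra <- setdiff(cm$taxa, tip_labels)
  if (length(extra))
    stop("matrix taxa missing from tree: ", paste(extra, collapse = ", "))
  st <- cm$states[tip_labels, , drop = FALSE]
  full <- bitwShiftL(1L, nstates) - 1L
  m <- matrix(full, nrow(st), ncol(st))
  def <- !is.na(st)
  m[def] <- bitwShiftL(1L, st[def])
  m
}

check_tree_for_pars <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo object")
  tree
}

# per-character minimum conceivable steps and star-tree (maximum) steps,
# the m_i and g_i of the ensemble indices
char_min_steps <- function(cm, ordered) {
  vapply(seq_len(ncol(cm$states)), function(j) {
    d <- cm$states[, j]; d <- d[!is.na(d)]
    if (length(d) < 2L) return(0)
    if (ordered) diff(range(d)) else length(unique(d)) - 1
  }, 0)
}

char_max_steps <- function(cm, ordered) {
  vapply(seq_len(ncol(cm$states)), function(j) {
    d <- cm$states[, j]; d <- d[!is.na(d)]
    if (length(d) < 2L) return(0)
    if (ordered) {
      centre <- floor(median(d))
      sum(abs(d - centre))
    } else {
      length(d) - max(tabulate(d + 1L))
    }
  }, 0)
}

# -- tree length and ensemble indices ---------------------------------------

#' Parsimony length of a tree with ensemble indices
#'
#' Computes the minimum number of character changes required by `tree`
#' under Fitch (unordered/non-additive) or linear-cost Sankoff
#' (ordered/additive, cost |a - b|) parsimony.  Missing (`?`) and
#' inapplicable (`-`) cells are scored as full ambiguity.  The ensemble
#' consistency index CI = sum(m_i)/sum(s_i) and retention index
#' RI = (sum(g_i) - sum(s_i)) / (sum(g_i) - sum(m_i)) are reported, where
#' m_i is the minimum conceivable number of steps of character i, s_i its
#' observed steps, and g_i its maximum steps on a star tree.
#'
#' @param cm A [char_matrix()].
#' @param tree An `ape::phylo` tree whose tip set equals the matrix taxa.
#'   Lengths are invariant under rerooting.
#' @param ordered Logical; linear-cost (additive) scoring.  Defaults to
#'   the matrix's `ordered` flag.
#' @return An object of class `tree_score`: list with `total`,
#'   `per_character`, `min_steps`, `max_steps`, `ci`, `ri`, `ordered`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' st <- cbind(ch = c(A = 0L, B = 0L, C = 1L, D = 1L))
#' tree_length(char_matrix(st), tr)$total  # 1
#' @export
tree_length <- function(cm, tree, ordered = cm$ordered) {
  tree <- check_tree_for_pars(tree)
  ns <- cm_nstates(cm)
  tm <- cm_tipmask(cm, tree$tip.label, ns)
  s <- .pars_char_lengths_cpp(tree$edge, length(tree$tip.label), tm, ns,
                              isTRUE(ordered))
  m <- char_min_steps(cm, ordered)
  g <- char_max_steps(cm, ordered)
  ci <- if (sum(s) > 0) sum(m) / sum(s) else NA_real_
  ri <- if (sum(g) - sum(m) > 0) (sum(g) - sum(s)) / (sum(g) - sum(m))
        else NA_real_
  structure(list(total = sum(s), per_character = s, min_steps = m,
                 max_steps = g, ci = ci, ri = ri, ordered = isTRUE(ordered)),
            class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat(sprintf("Tree length = %g (%s characters)\n", x$total,
              if (x$ordered) "ordered" else "unordered"))
  cat(sprintf("  ensemble CI = %.3f, RI = %.3f\n", x$ci, x$ri))
  invisible(x)
}

# -- most-parsimonious reconstruction ---------------------------------------

# Sankoff down/up pass for one character; returns the per-node total cost
# matrix (nodes x states).  costm is the k x k step matrix; root_prior is
# an optional additive cost vector constraining the root state.
sankoff_node_costs <- function(tree, allowed, costm, root_prior = NULL) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  k <- ncol(costm)
  BIG <- 1e9
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  D <- matrix(0, nnode, k)
  for (t in seq_len(ntip)) D[t, ] <- ifelse(allowed[t, ], 0, BIG)
  # M[[row]] = per-edge min-plus message from child to parent
  M <- vector("list", nrow(edge))
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    msg <- apply(costm + rep(D[ch, ], each = k), 1L, min)
    M[[r]] <- msg
    D[p, ] <- D[p, ] + msg
  }
  U <- matrix(0, nnode, k)          # cost of the rest of the tree
  if (!is.null(root_prior)) U[ntip + 1L, ] <- root_prior
  pre <- rev(seq_len(nrow(edge)))   # preorder over edges
  for (r in pre) {
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    Tp <- U[p, ] + D[p, ] - M[[r]]
    U[ch, ] <- apply(costm + Tp, 2L, min)
  }
  D + U
}

#' Most-parsimonious ancestral state sets and branch changes
#'
#' For every character, computes the set of states each node takes in at
#' least one most-parsimonious reconstruction (the MPR set), via a
#' Sankoff down/up pass with unit costs (unordered) or |a - b| costs
#' (ordered).  A branch carries an unambiguous change when the parent and
#' child MPR sets are disjoint, i.e. the change is present in every
#' most-parsimonious reconstruction (hence under both ACCTRAN and
#' DELTRAN); such changes are the synapomorphies reported.  Set-valued
#' endpoints are kept so downstream event-pair cracking can apply its
#' averaging and exclusion rules.
#'
#' @inheritParams tree_length
#' @param outgroup Optional outgroup tip label.  When given, and the
#'   outgroup's state is itself among the root's most-parsimonious
#'   states, the root is polarised to the outgroup state before the MPR
#'   sets are finalised (the usual outgroup-rooting convention for
#'   reading character polarity).
#' @return An object of class `mp_reconstruction`: list with
#'   `node_states` (per character, a list of MPR state vectors indexed by
#'   node), `changes` (data frame: `node` label of the child end of the
#'   branch, `character`, optional `event_i`/`event_j`, `parent_states`,
#'   `child_states`, `magnitude`, `excluded`, `ambiguous`),
#'   `per_character` lengths, `tree`, `ordered`.
#' @export
mp_reconstruct <- function(cm, tree, ordered = cm$ordered,
                           outgroup = NULL) {
  tree <- name_internal_nodes(check_tree_for_pars(tree))
  ntip <- length(tree$tip.label)
  st <- cm$states[tree$tip.label, , drop = FALSE]
  labs <- node_label_vector(tree)
  node_states <- vector("list", ncol(st))
  lens <- numeric(ncol(st))
  chg <- list()
  for (j in seq_len(ncol(st))) {
    d <- st[, j]
    obs <- sort(unique(d[!is.na(d)]))
    if (length(obs) < 2L) {
      alpha <- if (length(obs)) obs else 0L
      node_states[[j]] <- rep(list(alpha), ntip + tree$Nnode)
      next
    }
    # ordered characters may pass through unobserved intermediate states
    alpha <- if (isTRUE(ordered)) seq(min(obs), max(obs)) else obs
    k <- length(alpha)
    costm <- if (isTRUE(ordered)) abs(outer(alpha, alpha, "-"))
             else 1 - diag(k)
    allowed <- matrix(TRUE, ntip, k)
    def <- !is.na(d)
    allowed[def, ] <- outer(d[def], alpha, "==")
    tot <- sankoff_node_costs(tree, allowed, costm)
    best <- apply(tot, 1L, min)
    lens[j] <- best[ntip + 1L]
    if (!is.null(outgroup)) {
      og <- match(outgroup, tree$tip.label)
      if (is.na(og)) stop("outgroup not found in tree")
      s0 <- st[og, j]
      if (!is.na(s0) &&
          s0 %in% alpha[tot[ntip + 1L, ] <= lens[j] + 1e-9]) {
        prior <- ifelse(alpha == s0, 0, 1e9)
        tot <- sankoff_node_costs(tree, allowed, costm, prior)
        best <- apply(tot, 1L, min)
      }
    }
    sets <- lapply(seq_len(nrow(tot)),
                   function(v) alpha[tot[v, ] <= best[v] + 1e-9])
    node_states[[j]] <- sets
    for (r in seq_len(nrow(tree$edge))) {
      p <- tree$edge[r, 1L]; chn <- tree$edge[r, 2L]
      Sp <- sets[[p]]; Sc <- sets[[chn]]
      if (length(intersect(Sp, Sc))) next
      deltas <- as.vector(outer(Sc, Sp, "-"))
      excl <- min(deltas) < 0 && max(deltas) > 0
      chg[[length(chg) + 1L]] <- data.frame(
        node = labs[chn],
        character = colnames(st)[j],
        char_index = j,
        parent_states = paste(Sp, collapse = "/"),
        child_states = paste(Sc, collapse = "/"),
        magnitude = if (excl) NA_real_ else mean(deltas),
        excluded = excl,
        reason = if (excl) "direction-ambiguous" else "",
        ambiguous = length(Sp) > 1L || length(Sc) > 1L,
        stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(chg)) do.call(rbind, chg) else
    data.frame(node = character(), character = character(),
               char_index = integer(), parent_states = character(),
               child_states = character(), magnitude = numeric(),
               excluded = logical(), reason = character(),
               ambiguous = logical(), stringsAsFactors = FALSE)
  if (!is.null(cm$pairs) && nrow(changes)) {
    changes$event_i <- cm$pairs[changes$char_index, 1L]
    changes$event_j <- cm$pairs[changes$char_index, 2L]
  }
  structure(list(node_states = node_states, changes = changes,
                 per_character = lens, tree = tree,
                 ordered = isTRUE(ordered), taxa = tree$tip.label,
                 pairs = cm$pairs),
            class = "mp_reconstruction")
}

#' @export
print.mp_reconstruction <- function(x, ...) {
  cat(sprintf(
    "MP reconstruction: %d characters on %d tips (%s); %d branch changes (%d excluded)\n",
    length(x$node_states), length(x$taxa),
    if (x$ordered) "ordered" else "unordered",
    nrow(x$changes), sum(x$changes$excluded)))
  invisible(x)
}
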