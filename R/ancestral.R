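# -- squared-change parsimony -----------------------------------------------

#' Squared-change parsimony reconstruction of a continuous character
#'
#' Internal node values minimise the (optionally branch-length-weighted)
#' sum of squared changes over branches, sum((x_parent - x_child)^2 / l),
#' solved exactly as the sparse linear system given by stationarity at
#' each internal node.  The minimised criterion is reported as the
#' character's "steps" on the tree.
#'
#' @param values Named numeric vector of tip values; tips with `NA` (or
#'   absent names) are pruned before reconstruction.
#' @param tree A rooted `phylo`.  When `weighted` is `TRUE` the tree must
#'   carry strictly positive branch lengths.
#' @param weighted Divide squared changes by branch length.  Defaults to
#'   `TRUE` when the tree has branch lengths, `FALSE` (all branches
#'   treated as length 1) otherwise.
#' @return An object of class `node_values`: list with `values` (named
#'   vector over all nodes, tips included), `score` (minimised weighted
#'   sum of squared changes), `tree` (the possibly pruned tree),
#'   `weighted`.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1,C:1);")
#' squared_change_reconstruct(c(A = 0, B = 0.5, C = 1), tr)$score  # 0.5
#' @export
squared_change_reconstruct <- function(values, tree,
                                       weighted = !is.null(tree$edge.length)) {
  tree <- check_tree_for_pars(tree)
  x <- values[tree$tip.label]
  drop <- tree$tip.label[is.na(x)]
  if (length(drop)) {
    if (length(tree$tip.label) - length(drop) < 2L)
      stop("fewer than 2 tips carry a value")
    tree <- prune_taxa(tree, drop)
    x <- values[tree$tip.label]
  }
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  len <- if (weighted) {
    if (is.null(tree$edge.length))
      stop("weighted reconstruction needs branch lengths")
    tree$edge.length
  } else rep(1, nrow(tree$edge))
  if (any(len <= 0))
    stop("zero or negative branch length; calibrate the tree or use unit lengths")
  w <- 1 / len
  # stationarity: for each internal node i, sum_j w_ij (x_i - x_j) = 0
  A <- matrix(0, nint, nint)
  b <- numeric(nint)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1L] - ntip
    ch <- tree$edge[r, 2L]
    A[p, p] <- A[p, p] + w[r]
    if (ch > ntip) {
      ci <- ch - ntip
      A[p, ci] <- A[p, ci] - w[r]
      A[ci, p] <- A[ci, p] - w[r]
      A[ci, ci] <- A[ci, ci] + w[r]
    } else {
      b[p] <- b[p] + w[r] * x[ch]
    }
  }
  xi <- solve(A, b)
  all_vals <- c(x, xi)
  names(all_vals) <- node_label_vector(tree)
  dx <- all_vals[tree$edge[, 1L]] - all_vals[tree$edge[, 2L]]
  structure(list(values = all_vals, score = sum(dx^2 * w), tree = tree,
                 weighted = weighted),
            class = "node_values")
}

#' @export
print.node_values <- function(x, ...) {
  cat(sprintf("Squared-change reconstruction (%s): score = %.8g\n",
              if (x$weighted) "branch-length weighted" else "unit weights",
              x$score))
  invisible(x)
}

# -- independent-contrasts root CI ------------------------------------------

# Felsenstein pruning over a rooted tree, returning per-node conditional
# means, extra variances, and the standardised contrasts (binary nodes).
pic_prune <- function(x, tree, len) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  lenp <- po$edge.length
  if (is.null(lenp)) lenp <- rep(1, nrow(edge))
  nall <- ntip + tree$Nnode
  mu <- numeric(nall); mu[seq_len(ntip)] <- x
  v <- numeric(nall)                 # extra variance accumulated at node
  vb <- lenp                         # working branch lengths
  contrasts <- numeric(0)
  kids <- split(seq_len(nrow(edge)), edge[, 1L])
  for (p in unique(edge[, 1L])) {
    rows <- kids[[as.character(p)]]
    ch <- edge[rows, 2L]
    vv <- vb[rows] + v[ch]
    if (length(ch) != 2L)
      stop("independent contrasts require a fully bifurcating tree")
    contrasts <- c(contrasts,
                   (mu[ch[1L]] - mu[ch[2L]]) / sqrt(sum(vv)))
    mu[p] <- (mu[ch[1L]] / vv[1L] + mu[ch[2L]] / vv[2L]) /
             (1 / vv[1L] + 1 / vv[2L])
    v[p] <- prod(vv) / sum(vv)
  }
  root <- ntip + 1L
  list(root_estimate = mu[root], root_variance = v[root],
       contrasts = contrasts)
}

#' Root estimate with confidence interval from independent contrasts
#'
#' The root value is the GLS (contrast-weighted) mean obtained from the
#' Felsenstein pruning recursion; the Brownian rate is estimated from the
#' n - 1 standardised independent contrasts, and the root standard error
#' is sqrt(rate * v_root) with v_root the residual root variance of the
#' recursion.  The confidence interval uses Student's t.
#'
#' @inheritParams squared_change_reconstruct
#' @param level Confidence level (default 0.95).
#' @param df `"n-1"` (default; the number of contrasts) or `"n-2"`.
#' @return An object of class `root_reconstruction`: list with
#'   `estimate`, `se`, `lower`, `upper`, `df`, `rate`, `n_tips`.
#' @export
pic_root_ci <- function(values, tree, level = 0.95, df = c("n-1", "n-2")) {
  df <- match.arg(df)
  tree <- check_tree_for_pars(tree)
  x <- values[tree$tip.label]
  drop <- tree$tip.label[is.na(x)]
  if (length(drop)) {
    if (length(tree$tip.label) - length(drop) < 3L)
      stop("need at least 3 tips with values")
    tree <- prune_taxa(tree, drop)
    x <- values[tree$tip.label]
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 tips with values")
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree)
  len <- tree$edge.length
  if (is.null(len)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else if (any(len <= 0)) {
    stop("branch lengths must be strictly positive")
  }
  pr <- pic_prune(x, tree, tree$edge.length)
  nu <- if (df == "n-1") n - 1L else n - 2L
  rate <- sum(pr$contrasts^2) / nu
  se <- sqrt(rate * pr$root_variance)
  tq <- qt(1 - (1 - level) / 2, nu)
  structure(list(estimate = pr$root_estimate, se = se,
                 lower = pr$root_estimate - tq * se,
                 upper = pr$root_estimate + tq * se,
                 df = nu, rate = rate, n_tips = n, level = level),
            class = "root_reconstruction")
}

#' @export
print.root_reconstruction <- function(x, ...) {
  cat(sprintf("Root reconstruction: %.4f (SE %.4f), %g%% CI [%.4f, %.4f], df = %d\n",
              x$estimate, x$se, 100 * x$level, x$lower, x$upper, x$df))
  invisible(x)
}

# -- continuous heterochrony criterion --------------------------------------

empty_heterochrony_report <- function() {
  structure(data.frame(node = character(), event = character(),
                       direction = character(), statistic = numeric(),
                       ci_lower = numeric(), ci_upper = numeric(),
                       method = character(), stringsAsFactors = FALSE),
            class = c("heterochrony_report", "data.frame"))
}

#' Flag heterochronic taxa against the reconstructed root interval
#'
#' For every event the root value of the continuous timing character is
#' reconstructed with its 95% confidence interval ([pic_root_ci()]); a
#' taxon whose value falls strictly below the lower bound shows *earlier*
#' development of that event, strictly above the upper bound *later*
#' development.  With `reference = "squamate"` the outgroup is pruned
#' before reconstruction so the comparison is against the ancestral
#' ingroup node.
#'
#' @param continuous A `continuous_matrix` from [to_continuous()].
#' @param tree A rooted `phylo` over the species.
#' @param reference `"lepidosaur"` (full tree) or `"squamate"` (prune the
#'   outgroup first).
#' @param outgroup Outgroup tip label; required for
#'   `reference = "squamate"`.
#' @param level Confidence level (default 0.95).
#' @inheritParams pic_root_ci
#' @return A `heterochrony_report` data frame with columns `node`
#'   (flagged taxon), `event`, `direction` (`"earlier"`/`"later"`),
#'   `statistic` (the taxon's value), `ci_lower`, `ci_upper`, `method`.
#' @export
flag_continuous_heterochrony <- function(continuous, tree,
                                         reference = c("lepidosaur", "squamate"),
                                         outgroup = NULL, level = 0.95,
                                         df = "n-1") {
  reference <- match.arg(reference)
  stopifnot(inherits(continuous, "continuous_matrix"))
  if (reference == "squamate") {
    if (is.null(outgroup))
      stop("reference = 'squamate' needs the outgroup label")
    tree <- prune_taxa(tree, outgroup)
  }
  rows <- list()
  for (ev in continuous$events) {
    vals <- continuous$values[, ev]
    names(vals) <- continuous$species
    vals <- vals[tree$tip.label]
    if (sum(!is.na(vals)) < 3L) next
    ci <- pic_root_ci(vals, tree, level = level, df = df)
    for (sp in names(vals)[!is.na(vals)]) {
      v <- vals[[sp]]
      dir <- if (v < ci$lower) "earlier" else if (v > ci$upper) "later"
             else next
      rows[[length(rows) + 1L]] <- data.frame(
        node = sp, event = ev, direction = dir, statistic = v,
        ci_lower = ci$lower, ci_upper = ci$upper,
        method = "continuous", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    empty_heterochrony_report()
  class(out) <- c("heterochrony_report", "data.frame")
  out
}

#' @export
print.heterochrony_report <- function(x, ...) {
  cat(sprintf("Heterochrony report: %d flagged (node, event) records\n",
              nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# -- maximum-likelihood Mk reconstruction -----------------------------------

# transition probability matrix of the k-state one-rate symmetric Mk
# model: every off-diagonal rate r, so
# P_ii = 1/k + (k-1)/k exp(-k r t),  P_ij = 1/k - 1/k exp(-k r t)
mk_pmat <- function(k, rate, t) {
  e <- exp(-k * rate * t)
  m <- matrix((1 - e) / k, k, k)
  diag(m) <- 1 / k + (k - 1) * e / k
  m
}

mk_loglik_partials <- function(tree, allowed, rate, len) {
  ntip <- nrow(allowed)
  k <- ncol(allowed)
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  L <- matrix(1, ntip + tree$Nnode, k)
  L[seq_len(ntip), ] <- ifelse(allowed, 1, 0)
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    P <- mk_pmat(k, rate, len[r])
    L[p, ] <- L[p, ] * as.vector(P %*% L[ch, ])
  }
  list(L = L, edge = edge, loglik = log(sum(L[ntip + 1L, ] / k)))
}

#' Maximum-likelihood ancestral states under the Mk model
#'
#' Fits, independently for every variable character, a one-rate symmetric
#' k-state Markov (Mk) model with k equal to the character's observed
#' state alphabet, maximising the likelihood over the rate by bounded 1-D
#' optimisation of Felsenstein's pruning likelihood.  Marginal ancestral
#' state probabilities are obtained by combining down-pass and up-pass
#' partial likelihoods (equivalent to rerooting at each node).  Constant
#' characters are skipped.
#'
#' @inheritParams tree_length
#' @param tree A rooted `phylo` with strictly positive branch lengths
#'   (unit lengths are assigned, with a message, when absent).
#' @param rate_bounds Search interval for the rate (default
#'   `c(1e-8, 100)`).
#' @return An object of class `mk_reconstruction`: list with
#'   `marginals` (per character, nodes x states probability matrix),
#'   `map_state` (per character, most probable state per node, original
#'   state values), `rate`, `loglik`, `changes` (branch change table in
#'   the same layout as [mp_reconstruct()]), `tree`.
#' @export
ml_mk_reconstruct <- function(cm, tree, rate_bounds = c(1e-8, 100)) {
  tree <- name_internal_nodes(check_tree_for_pars(tree))
  if (is.null(tree$edge.length)) {
    message("tree has no branch lengths; using unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length <= 0))
    stop("branch lengths must be strictly positive")
  ntip <- length(tree$tip.label)
  st <- cm$states[tree$tip.label, , drop = FALSE]
  labs <- node_label_vector(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  len <- po$edge.length
  nall <- ntip + tree$Nnode
  marginals <- vector("list", ncol(st))
  map_state <- vector("list", ncol(st))
  rates <- rep(NA_real_, ncol(st))
  logliks <- rep(NA_real_, ncol(st))
  chg <- list()
  for (j in seq_len(ncol(st))) {
    d <- st[, j]
    alpha <- sort(unique(d[!is.na(d)]))
    k <- length(alpha)
    if (k < 2L) next
    allowed <- matrix(TRUE, ntip, k)
    def <- !is.na(d)
    allowed[def, ] <- outer(d[def], alpha, "==")
    nll <- function(lr)
      -mk_loglik_partials(tree, allowed, exp(lr), len)$loglik
    opt <- optimize(nll, interval = log(rate_bounds), tol = 1e-8)
    rate <- exp(opt$minimum)
    if (opt$minimum < log(rate_bounds[1L]) + 1e-4 ||
        opt$minimum > log(rate_bounds[2L]) - 1e-4)
      warning(sprintf(
        "character %s: rate %.3g at optimisation bound [%g, %g]",
        colnames(st)[j], rate, rate_bounds[1L], rate_bounds[2L]))
    fit <- mk_loglik_partials(tree, allowed, rate, len)
    # up-pass: U[node, s] = likelihood of the rest of the tree given the
    # node's state; D * U renormalised gives the marginals
    edge <- fit$edge
    U <- matrix(NA_real_, nall, k)
    U[ntip + 1L, ] <- 1 / k
    Pr <- lapply(seq_len(nrow(edge)),
                 function(r) mk_pmat(k, rate, len[r]))
    for (r in rev(seq_len(nrow(edge)))) {
      p <- edge[r, 1L]; ch <- edge[r, 2L]
      down_msg <- as.vector(Pr[[r]] %*% fit$L[ch, ])
      rest_p <- U[p, ] * fit$L[p, ] / down_msg
      U[ch, ] <- as.vector(t(Pr[[r]]) %*% rest_p)
    }
    marg <- fit$L * U
    marg <- marg / rowSums(marg)
    colnames(marg) <- alpha
    rownames(marg) <- labs
    marginals[[j]] <- marg
    map_state[[j]] <- alpha[max.col(marg, ties.method = "first")]
    rates[j] <- rate
    logliks[j] <- fit$loglik
    ms <- map_state[[j]]
    for (r in seq_len(nrow(tree$edge))) {
      p <- tree$edge[r, 1L]; chn <- tree$edge[r, 2L]
      if (ms[p] == ms[chn]) next
      chg[[length(chg) + 1L]] <- data.frame(
        node = labs[chn], character = colnames(st)[j], char_index = j,
        parent_states = as.character(ms[p]),
        child_states = as.character(ms[chn]),
        magnitude = ms[chn] - ms[p], excluded = FALSE, reason = "",
        ambiguous = FALSE, stringsAsFactors = FALSE)
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
  structure(list(marginals = marginals, map_state = map_state,
                 rate = rates, loglik = logliks, changes = changes,
                 tree = tree, pairs = cm$pairs),
            class = "mk_reconstruction")
}

#' @export
print.mk_reconstruction <- function(x, ...) {
  fitted <- sum(!is.na(x$rate))
  cat(sprintf(
    "Mk reconstruction: %d characters fitted (%d constant skipped); %d branch changes\n",
    fitted, length(x$rate) - fitted, nrow(x$changes)))
  invisible(x)
}
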