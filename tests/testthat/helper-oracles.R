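# Independent brute-force oracles and small fixture generators used
# across the test files.  All oracles enumerate exhaustively and share no
# code with the package's algorithms.

# Minimum parsimony length of one character by exhaustive enumeration of
# every internal-node labelling.  `states` is a named vector over the
# tips (NA = fully ambiguous); alphabet is 0..(nstates-1).
oracle_char_length <- function(tree, states, nstates, ordered) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  alpha <- 0:(nstates - 1L)
  cost <- function(a, b) if (ordered) abs(a - b) else as.numeric(a != b)
  grid <- as.matrix(expand.grid(rep(list(alpha), nint)))
  x <- states[tree$tip.label]
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- c(rep(NA, ntip), grid[g, ])
    tot <- 0
    for (r in seq_len(nrow(tree$edge))) {
      p <- lab[tree$edge[r, 1L]]
      ch <- tree$edge[r, 2L]
      if (ch <= ntip) {
        tot <- tot + if (is.na(x[ch])) 0 else cost(p, x[ch])
      } else {
        tot <- tot + cost(p, lab[ch])
      }
    }
    best <- min(best, tot)
  }
  best
}

oracle_matrix_length <- function(tree, cm, ordered) {
  ns <- max(cm$states, 1L, na.rm = TRUE) + 1L
  sum(vapply(seq_len(ncol(cm$states)), function(j)
    oracle_char_length(tree, cm$states[, j], ns, ordered), 0))
}

# Marginal ancestral probabilities of a k-state equal-rates Markov model
# by direct summation over every internal state assignment.
oracle_mk_marginals <- function(tree, tip_states, k, rate) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  pm <- function(t) {
    e <- exp(-k * rate * t)
    m <- matrix((1 - e) / k, k, k); diag(m) <- 1 / k + (k - 1) * e / k
    m
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  joint <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    lab <- c(tip_states[tree$tip.label], grid[g, ])
    pr <- 1 / k
    for (r in seq_len(nrow(tree$edge))) {
      P <- pm(tree$edge.length[r])
      pr <- pr * P[lab[tree$edge[r, 1L]], lab[tree$edge[r, 2L]]]
    }
    joint[g] <- pr
  }
  marg <- matrix(0, nint, k)
  for (g in seq_len(nrow(grid)))
    for (i in seq_len(nint))
      marg[i, grid[g, i]] <- marg[i, grid[g, i]] + joint[g]
  list(marginals = marg / sum(joint), loglik = log(sum(joint)))
}

# Exact two-tailed signed-rank p-value by full enumeration of the 2^n
# sign patterns (average ranks for ties).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% ranks)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  p_le <- mean(w_all <= w_obs + 1e-12)
  min(1, 2 * min(p_ge, p_le))
}

# Random discrete character matrix over `ntaxa` taxa
random_char_matrix <- function(ntaxa, nchar, nstates = 3L,
                               na_rate = 0.1) {
  st <- matrix(sample(0:(nstates - 1L), ntaxa * nchar, replace = TRUE),
               ntaxa, nchar,
               dimnames = list(paste0("t", seq_len(ntaxa)),
                               paste0("c", seq_len(nchar))))
  st[matrix(runif(ntaxa * nchar) < na_rate, ntaxa, nchar)] <- NA_integer_
  char_matrix(st)
}

random_rooted_tree <- function(ntip, lengths = TRUE) {
  tr <- ape::rtree(ntip, tip.label = paste0("t", seq_len(ntip)))
  if (!lengths) tr$edge.length <- NULL
  tr
}
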