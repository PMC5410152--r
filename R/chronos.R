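# Branch-length assignment: equal lengths, or node ages propagated from a
# fossil calibration table.

#' Assign unit branch lengths
#'
#' @param tree A `phylo` tree.
#' @return The tree with every branch length set to 1.  Idempotent.
#' @export
unit_branch_lengths <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Read a fossil calibration table
#'
#' CSV with columns `clade`, `tips` (tip labels separated by `;`; the
#' calibrated node is their most recent common ancestor), `age_ma`
#' (positive, oldest total-group fossil age in Ma), and optionally
#' `note`.
#'
#' @param path Path to the CSV file.
#' @return A data frame of calibrations.
#' @export
read_calibrations <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"")
  need <- c("clade", "tips", "age_ma")
  if (!all(need %in% names(df)))
    stop("calibration table needs columns: ", paste(need, collapse = ", "))
  if (any(df$age_ma <= 0)) stop("calibration ages must be positive")
  df
}

#' Calibrate branch lengths from fossil node ages
#'
#' Calibrated nodes (the MRCA of each calibration's tip set) are fixed at
#' the given age; extant tips have age 0; every uncalibrated node is aged
#' bottom-up as the oldest descendant node age plus `default_step` per
#' intervening branch (the arbitrary length used where the fossil record
#' gives no information).  Branch lengths are parent age minus child age,
#' so the result is ultrametric over the tips, with calibrated ages
#' reproduced exactly.
#'
#' @param tree A rooted `phylo` tree.
#' @param calibrations Data frame from [read_calibrations()] (or with the
#'   same columns).
#' @param default_step Age increment (Ma) per uncalibrated branch
#'   (default 3).
#' @return The tree with branch lengths set and a `node.age` attribute
#'   (named vector of ages over all nodes).  Calibrations whose tip set
#'   resolves to fewer than 2 tips in the tree are skipped with a
#'   warning; a calibrated node older than its calibrated parent allows,
#'   but a calibrated node younger than (or equal to) any child's age is
#'   a hard error naming the pair.
#' @export
calibrate_branch_lengths <- function(tree, calibrations, default_step = 3) {
  tree <- name_internal_nodes(check_tree_for_pars(tree))
  ntip <- length(tree$tip.label)
  nall <- ntip + tree$Nnode
  fixed <- rep(NA_real_, nall)
  for (r in seq_len(nrow(calibrations))) {
    tips <- trimws(strsplit(calibrations$tips[r], ";")[[1L]])
    tips <- intersect(tips, tree$tip.label)
    if (length(tips) < 2L) {
      warning(sprintf(
        "calibration '%s' matches %d tip(s) in the tree; skipped",
        calibrations$clade[r], length(tips)))
      next
    }
    node <- ape::getMRCA(tree, tips)
    age <- calibrations$age_ma[r]
    if (!is.na(fixed[node]) && fixed[node] != age) {
      warning(sprintf(
        "node has two calibrations ('%s'); keeping the older age",
        calibrations$clade[r]))
      age <- max(age, fixed[node])
    }
    fixed[node] <- age
  }
  if (all(is.na(fixed))) stop("no usable calibration")
  age <- rep(NA_real_, nall)
  age[seq_len(ntip)] <- 0
  po <- ape::reorder.phylo(tree, "postorder")$edge
  labs <- node_label_vector(tree)
  for (p in unique(po[, 1L])) {
    ch <- po[po[, 1L] == p, 2L]
    cand <- max(age[ch]) + default_step
    if (!is.na(fixed[p])) {
      conflict <- ch[age[ch] >= fixed[p]]
      if (length(conflict))
        stop(sprintf(
          "calibration conflict: node '%s' (%g Ma) is not older than descendant '%s' (%g Ma)",
          labs[p], fixed[p], labs[conflict[1L]], age[conflict[1L]]))
      age[p] <- fixed[p]
    } else {
      age[p] <- cand
    }
  }
  tree$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  if (any(tree$edge.length <= 0))
    stop("calibration produced a non-positive branch length")
  names(age) <- labs
  attr(tree, "node.age") <- age
  tree
}
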