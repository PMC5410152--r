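mk_changes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(node = "X", character = sprintf("ep_%d_%d", r[1], r[2]),
               char_index = 1L,
               parent_states = as.character(r[3]),
               child_states = as.character(r[4]),
               magnitude = r[4] - r[3], excluded = FALSE, reason = "",
               ambiguous = FALSE, event_i = r[1], event_j = r[2],
               stringsAsFactors = FALSE)))
}

test_that("set-valued endpoints follow the averaging and exclusion rules", {
  # engineered tree: outgroup-polarised ordered reconstruction where a
  # tip jumps from parent 0 to state 2 across intermediate 1
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  pos <- rbind(A = c(1L, 2L, 3L), B = c(1L, 2L, 3L),
               C = c(1L, 2L, 3L), D = c(3L, 2L, 1L))
  colnames(pos) <- paste0("e", 1:3)
  ep <- event_pair_encode(timeline_matrix(pos))
  mpr <- mp_reconstruct(ep, tr, ordered = TRUE, outgroup = "A")
  chg <- extract_branch_changes(mpr, "D")
  expect_true(all(chg$magnitude == 2))
  expect_true(all(!chg$excluded))
  # magnitude -2 for a 2 -> 0 drop
  chg_manual <- mk_changes(c(1, 2, 2, 0))
  expect_equal(chg_manual$magnitude, -2)
})

test_that("direction-ambiguous reconstructions are excluded from cracking", {
  ch <- data.frame(node = "X", character = "ep_1_2", char_index = 1L,
                   parent_states = "1", child_states = "0/2",
                   magnitude = NA_real_, excluded = TRUE,
                   reason = "direction-ambiguous", ambiguous = TRUE,
                   event_i = 1L, event_j = 2L, stringsAsFactors = FALSE)
  ch2 <- rbind(ch, mk_changes(c(1, 3, 0, 2), c(1, 4, 0, 2)))
  cr <- crack_node(ch2, node = "X")
  # excluded change contributes nothing: event 2 absent from the tally
  expect_false("2" %in% names(cr$trc))
  expect_equal(cr$trc[["1"]], 2)
})

test_that("the averaged magnitude 1.5 arises from a 0 to 1-or-2 endpoint", {
  # direct check of the rule as mp_reconstruct encodes it
  deltas <- as.vector(outer(c(1L, 2L), 0L, "-"))
  expect_equal(mean(deltas), 1.5)
  # and through the engine: parent {0}, child {1,2} marks magnitude 1.5
  tr <- ape::read.tree(text = "((((A,B),C),D),E);")
  st <- cbind(c1 = c(A = 0L, B = 0L, C = 0L, D = 1L, E = 2L))
  cm <- char_matrix(st, ordered = TRUE)
  mpr <- mp_reconstruct(cm, tr, ordered = TRUE, outgroup = "A")
  dch <- mpr$changes[mpr$changes$parent_states == "0" &
                     mpr$changes$child_states == "1/2", ]
  if (nrow(dch)) expect_equal(dch$magnitude, 1.5)
  expect_gte(nrow(mpr$changes), 1L)
})

test_that("crackability requires linked event pairs", {
  expect_false(node_is_crackable(mk_changes(c(1, 2, 0, 2))))
  expect_false(node_is_crackable(mk_changes(c(1, 2, 0, 2), c(3, 4, 0, 2))))
  expect_true(node_is_crackable(mk_changes(c(1, 2, 0, 2), c(1, 5, 0, 2))))
})

test_that("TRC contributions follow the signed sharing rule", {
  cr <- crack_node(mk_changes(c(1, 5, 0, 2), c(1, 7, 0, 2)), node = "X")
  expect_equal(cr$trc[["1"]], 2)
  expect_equal(cr$trc[["5"]], -2)
  expect_equal(cr$trc[["7"]], -2)
  expect_equal(unname(cr$n_pairs), c(2L, 1L, 1L))
  # antisymmetry of a duplicated single pair
  cr2 <- crack_node(mk_changes(c(2, 6, 0, 1), c(2, 6, 0, 1)), node = "X")
  expect_equal(cr2$trc[["2"]], -cr2$trc[["6"]])
})

test_that("every change's contributions conserve to zero across events", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    rows <- lapply(seq_len(n), function(k) {
      ij <- sort(sample(1:6, 2))
      c(ij, 0, sample(c(1, 2), 1))
    })
    ch <- do.call(mk_changes, rows)
    if (!node_is_crackable(ch)) next
    cr <- crack_node(ch, node = "X")
    expect_equal(sum(cr$trc * cr$n_pairs), 0, tolerance = 1e-12)
    # order invariance
    cr2 <- crack_node(ch[sample(nrow(ch)), ], node = "X")
    expect_equal(cr2$trc[names(cr$trc)], cr$trc)
  }
})

test_that("flags use a strict Student-t interval over the participating events", {
  ch <- do.call(mk_changes, list(c(1, 2, 0, 2), c(1, 3, 0, 2),
                                 c(1, 4, 0, 2), c(1, 5, 0, 2)))
  cr <- crack_node(ch, node = "X")
  # TRCs: event1 = +2, events 2..5 = -2 each; hand-computed t interval
  trc <- c(2, -2, -2, -2, -2)
  m <- mean(trc); s <- sd(trc)
  expect_equal(cr$mean_trc, m)
  expect_equal(cr$ci_upper, m + qt(0.975, 4) * s / sqrt(5))
  fl <- flag_heterochronic_events(cr)
  expect_equal(fl$event, "1")
  expect_equal(fl$direction, "later")
  # all-equal TRCs produce no flags
  cr0 <- crack_node(do.call(mk_changes,
    list(c(1, 2, 0, 1), c(2, 3, 0, 1), c(3, 1, 0, 1))), node = "X")
  expect_equal(nrow(flag_heterochronic_events(cr0)), 0L)
})

test_that("nodes with too few participating events report without flags", {
  ch <- mk_changes(c(1, 2, 0, 2), c(1, 2, 0, 1))
  cr <- crack_node(ch, node = "X")
  expect_equal(cr$n_events, 2L)
  expect_true(is.na(cr$ci_lower))
  expect_equal(nrow(flag_heterochronic_events(cr)), 0L)
})

test_that("crack_tree summarises all crackable branches of a reconstruction", {
  set.seed(73)
  tre <- unit_branch_lengths(random_rooted_tree(10))
  cfg <- sim_config(tre, n_events = 8, swap_rate = 0.3,
                    shifts = list(list(node = "t2", event = 3, delta = 4)),
                    seed = 73L)
  sim <- simulate_timelines(cfg)
  ep <- event_pair_encode(sim$timelines)
  mpr <- mp_reconstruct(ep, tre, ordered = TRUE)
  ct <- crack_tree(mpr)
  expect_true(all(c("report", "cracks", "skipped") %in% names(ct)))
  expect_true(any(ct$report$node == "t2" & ct$report$event == "3" &
                  ct$report$direction == "later"))
})
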