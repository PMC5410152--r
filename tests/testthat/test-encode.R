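test_that("continuous scaling fixes the endpoints and shares values at ties", {
  pos <- rbind(s1 = c(1L, 2L, 3L), s2 = c(1L, 1L, 2L))
  colnames(pos) <- paste0("e", 1:3)
  ct <- to_continuous(timeline_matrix(pos))
  expect_equal(unname(ct$values["s1", ]), c(0, 0.5, 1))
  expect_equal(unname(ct$values["s2", ]), c(0, 0, 1))
  # event at rank 4 of 11 distinct ranks -> 0.3
  pos2 <- matrix(1:11, 1, dimnames = list("s", paste0("e", 1:11)))
  ct2 <- to_continuous(timeline_matrix(pos2))
  expect_equal(ct2$values[1, 4], 0.3)
})

test_that("continuous scaling is invariant under strictly monotone relabelling of stages", {
  set.seed(11)
  for (i in 1:10) {
    raw <- sample(1:6, 8, replace = TRUE)
    pos <- rbind(s = raw); colnames(pos) <- paste0("e", 1:8)
    stages <- sort(unique(raw))
    relab <- cumsum(sample(1:5, length(stages), replace = TRUE))
    pos2 <- rbind(s = relab[match(raw, stages)])
    colnames(pos2) <- colnames(pos)
    expect_equal(to_continuous(timeline_matrix(pos))$values,
                 to_continuous(timeline_matrix(pos2))$values)
  }
})

test_that("a species with fewer than two distinct positions becomes unknown with a warning", {
  pos <- rbind(s1 = c(2L, 2L, 2L), s2 = c(1L, 2L, 3L))
  colnames(pos) <- paste0("e", 1:3)
  expect_warning(ct <- to_continuous(timeline_matrix(pos)), "distinct positions")
  expect_true(all(is.na(ct$values["s1", ])))
})

test_that("decile binning follows the published cut points with the top bin clamped", {
  vals <- rbind(s = c(0, 0.09, 0.099, 0.1, 0.15, 0.95, 1))
  colnames(vals) <- paste0("e", 1:7)
  ct <- structure(list(values = vals,
                       inapplicable = matrix(FALSE, 1, 7, dimnames = dimnames(vals)),
                       species = "s", events = colnames(vals)),
                  class = "continuous_matrix")
  expect_equal(unname(discretize(ct)$states[1, ]),
               c(0L, 0L, 0L, 1L, 1L, 9L, 9L))
  ct$values[1, 1] <- 1.2
  expect_error(discretize(ct), "\\[0, 1\\]")
})

test_that("first and last events of every species map to states 0 and 9", {
  set.seed(5)
  cfg <- sim_config(random_rooted_tree(10), n_events = 12L,
                    swap_rate = 1, seed = 5L)
  tl <- simulate_timelines(cfg)$timelines
  st <- discretize(to_continuous(tl))$states
  for (i in seq_len(nrow(st))) {
    p <- tl$positions[i, ]
    expect_equal(unname(st[i, which.min(p)]), 0L)
    expect_equal(unname(st[i, which.max(p)]), 9L)
  }
})

test_that("event-pair coding yields choose(E,2) characters with the documented states", {
  pos <- rbind(s = c(2L, 5L, 5L))
  colnames(pos) <- paste0("e", 1:3)
  ep <- event_pair_encode(timeline_matrix(pos))
  expect_equal(ncol(ep$states), 3L)
  expect_equal(unname(ep$states[1, ]), c(0L, 0L, 1L))  # 2<5, 2<5, 5==5
  set.seed(2)
  cfg <- sim_config(random_rooted_tree(5), n_events = 20L, seed = 2L)
  ep20 <- event_pair_encode(simulate_timelines(cfg)$timelines)
  expect_equal(ncol(ep20$states), 190L)
  expect_error(event_pair_encode(
    timeline_matrix(rbind(s = c(e1 = 1L)))), "at least 2 events")
})

test_that("unknown and inapplicable cells propagate into event pairs", {
  pos <- rbind(s = c(1L, NA, NA, 2L))
  colnames(pos) <- paste0("e", 1:4)
  inap <- matrix(FALSE, 1, 4, dimnames = dimnames(pos))
  inap[1, 3] <- TRUE
  ep <- event_pair_encode(timeline_matrix(pos, inap))
  get <- function(i, j) ep$states[1, sprintf("ep_%d_%d", i, j)]
  expect_true(is.na(get(1, 2)))                      # unknown partner
  expect_false(ep$inapplicable[1, "ep_1_2"])
  expect_true(is.na(get(1, 3)))                      # inapplicable partner
  expect_true(ep$inapplicable[1, "ep_1_3"])
  expect_equal(unname(get(1, 4)), 0L)
})

test_that("tie-free timelines encode a transitively consistent (acyclic) tournament", {
  set.seed(9)
  for (rep in 1:5) {
    ord <- sample(6)
    pos <- rbind(s = match(seq_len(6), ord))
    colnames(pos) <- paste0("e", 1:6)
    ep <- event_pair_encode(timeline_matrix(pos))
    st <- ep$states[1, ]
    pr <- ep$pairs
    state_of <- function(i, j) {
      if (i < j) st[[sprintf("ep_%d_%d", i, j)]]
      else 2L - st[[sprintf("ep_%d_%d", j, i)]]
    }
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      if (i != j && j != k && i != k &&
          state_of(i, j) == 0L && state_of(j, k) == 0L)
        expect_equal(state_of(i, k), 0L)
  }
})
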