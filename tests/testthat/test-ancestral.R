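test_that("squared-change parsimony solves the closed-form small cases", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  s <- squared_change_reconstruct(c(A = 0, B = 0.5, C = 1), star)
  expect_equal(unname(s$values["N1"]), 0.5)
  expect_equal(s$score, 0.5)
  # two tips, lengths 1 and 3: root is the 1/l-weighted mean
  two <- ape::read.tree(text = "(A:1,B:3);")
  s2 <- squared_change_reconstruct(c(A = 0, B = 1), two)
  expect_equal(unname(s2$values["N1"]), 0.25)
  expect_equal(s2$score, 0.25)
  # constant tips reconstruct constant everywhere with zero score
  tr <- random_rooted_tree(6)
  s3 <- squared_change_reconstruct(setNames(rep(0.3, 6), tr$tip.label), tr)
  expect_equal(unname(s3$values), rep(0.3, 6 + tr$Nnode))
  expect_equal(s3$score, 0)
  # zero-length branches are refused
  bad <- ape::read.tree(text = "(A:0,B:1);")
  expect_error(squared_change_reconstruct(c(A = 0, B = 1), bad),
               "branch length")
})

test_that("squared-change reconstruction matches a generic numerical minimiser", {
  set.seed(41)
  for (i in 1:8) {
    ntip <- sample(4:8, 1)
    tr <- random_rooted_tree(ntip)
    x <- setNames(runif(ntip), tr$tip.label)
    fit <- squared_change_reconstruct(x, tr)
    ntot <- ntip + tr$Nnode
    obj <- function(z) {
      vals <- c(x[tr$tip.label], z)
      sum((vals[tr$edge[, 1]] - vals[tr$edge[, 2]])^2 / tr$edge.length)
    }
    opt <- optim(rep(mean(x), tr$Nnode), obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(fit$score, opt$value, tolerance = 1e-8)
    expect_equal(unname(fit$values[(ntip + 1):ntot]), unname(opt$par),
                 tolerance = 1e-5)
  }
})

test_that("the squared-change root equals the contrasts (GLS) root estimate", {
  set.seed(47)
  for (i in 1:5) {
    tr <- random_rooted_tree(8)
    x <- setNames(rnorm(8), tr$tip.label)
    scp <- squared_change_reconstruct(x, tr)
    ci <- pic_root_ci(x, tr)
    expect_equal(unname(scp$values[["N1"]]), ci$estimate, tolerance = 1e-10)
  }
})

test_that("root confidence intervals are exact on hand-computed cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ci <- pic_root_ci(c(A = 0, B = 0, C = 1, D = 1), tr)
  # contrasts: 0, 0, -1/sqrt(3); rate = (1/3)/3; v_root = 0.75
  expect_equal(ci$estimate, 0.5)
  expect_equal(ci$rate, (1 / 3) / 3)
  expect_equal(ci$se, sqrt((1 / 9) * 0.75))
  expect_equal(ci$df, 3L)
  expect_equal(ci$upper - ci$estimate, qt(0.975, 3) * ci$se)
  # equal tip values give a degenerate zero-width interval
  ci0 <- pic_root_ci(c(A = 1, B = 1, C = 1, D = 1), tr)
  expect_equal(ci0$se, 0)
  expect_equal(c(ci0$lower, ci0$upper), c(1, 1))
  expect_error(pic_root_ci(c(A = 1, B = 2, C = NA, D = NA), tr),
               "at least 3 tips")
})

test_that("standardised contrasts agree with ape::pic", {
  set.seed(53)
  tr <- random_rooted_tree(10)
  x <- setNames(rnorm(10), tr$tip.label)
  pr <- heterochron:::pic_prune(x, tr, tr$edge.length)
  expect_equal(sort(abs(pr$contrasts)),
               sort(abs(unname(ape::pic(x, tr)))), tolerance = 1e-10)
})

test_that("root CI coverage is near nominal under Brownian simulation", {
  set.seed(59)
  tr <- random_rooted_tree(20)
  hits <- 0L; nrep <- 300L
  for (i in seq_len(nrep)) {
    x <- ape::rTraitCont(tr, model = "BM", sigma = 1, root.value = 0)
    ci <- pic_root_ci(x, tr)
    if (ci$lower < 0 && 0 < ci$upper) hits <- hits + 1L
  }
  expect_gt(hits / nrep, 0.90)
  expect_lt(hits / nrep, 0.99)
})

test_that("continuous heterochrony flags taxa strictly beyond the root interval", {
  set.seed(61)
  tr <- unit_branch_lengths(random_rooted_tree(10))
  cfg <- sim_config(tr, n_events = 8, swap_rate = 0.2,
                    shifts = list(list(node = "t3", event = 4, delta = 4)),
                    seed = 61L)
  sim <- simulate_timelines(cfg)
  ct <- to_continuous(sim$timelines)
  rp <- flag_continuous_heterochrony(ct, tr)
  expect_s3_class(rp, "heterochrony_report")
  expect_true(any(rp$node == "t3" & rp$event == "ev4" &
                  rp$direction == "later"))
  # squamate reference requires an outgroup and prunes it
  expect_error(flag_continuous_heterochrony(ct, tr, reference = "squamate"),
               "outgroup")
  rp2 <- flag_continuous_heterochrony(ct, tr, reference = "squamate",
                                      outgroup = "t1")
  expect_false("t1" %in% rp2$node)
})

test_that("Mk marginals match brute-force summation over internal states", {
  set.seed(67)
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:0.5):2);")
  cm <- char_matrix(cbind(c1 = c(A = 0L, B = 1L, C = 0L, D = 1L),
                          c2 = c(A = 0L, B = 2L, C = 1L, D = 2L)))
  mk <- ml_mk_reconstruct(cm, tr)
  for (j in 1:2) {
    k <- length(unique(cm$states[, j]))
    tips <- setNames(match(cm$states[tr$tip.label, j],
                           sort(unique(cm$states[, j]))), tr$tip.label)
    orc <- oracle_mk_marginals(tr, tips, k, mk$rate[j])
    expect_equal(unname(mk$marginals[[j]][5:7, ]), unname(orc$marginals),
                 tolerance = 1e-9)
    expect_equal(mk$loglik[j], orc$loglik, tolerance = 1e-9)
  }
  expect_true(all(abs(rowSums(mk$marginals[[1]]) - 1) < 1e-9))
})

test_that("Mk likelihood is invariant under rerooting along the central edge", {
  cm <- char_matrix(cbind(c1 = c(A = 0L, B = 0L, C = 1L, D = 1L)))
  t1 <- ape::read.tree(text = "((A:1,B:2):0.3,(C:1.5,D:0.5):0.7);")
  t2 <- ape::read.tree(text = "((A:1,B:2):0.8,(C:1.5,D:0.5):0.2);")
  m1 <- ml_mk_reconstruct(cm, t1)
  m2 <- ml_mk_reconstruct(cm, t2)
  expect_equal(m1$loglik, m2$loglik, tolerance = 1e-6)
  expect_equal(m1$rate, m2$rate, tolerance = 1e-3)
})

test_that("Mk degenerate cases: shared tip states and exchangeable tips", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  cm <- char_matrix(cbind(c1 = c(A = 0L, B = 1L)))
  mk <- suppressWarnings(ml_mk_reconstruct(cm, two))
  expect_equal(unname(mk$marginals[[1]]["N1", ]), c(0.5, 0.5))
  # near-zero rate with unanimous tips concentrates the root
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cmu <- char_matrix(cbind(c1 = c(A = 0L, B = 0L, C = 0L, D = 1L)))
  mku <- suppressWarnings(ml_mk_reconstruct(cmu, tr))
  expect_gt(mku$marginals[[1]]["N1", "0"], 0.5)
  # constant characters are skipped
  cmc <- char_matrix(cbind(c1 = c(A = 0L, B = 0L, C = 0L, D = 0L)))
  mkc <- ml_mk_reconstruct(cmc, tr)
  expect_true(is.na(mkc$rate[1]))
})
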