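two_area_space <- build_state_space(c("X", "Y"), 2)
two_area_model <- function(d = 0.07, e = 0.03)
  dec_model(c("X", "Y"), numeric(0), matrix(1, 2, 2), d = d, e = e)

test_that("state space has the expected size and ordering", {
  sp <- build_state_space(LETTERS[1:6], 2)
  expect_equal(sp$n_states, 22L)                 # null + 6 singletons + 15 pairs
  expect_equal(build_state_space(LETTERS[1:6], 3)$n_states, 42L)
  expect_equal(build_state_space(LETTERS[1:6], 2, excluded = "AF")$n_states, 21L)
  expect_equal(sp$labels[1], "0")
  expect_equal(sp$labels[2:7], c("A", "B", "C", "D", "E", "F"))
  expect_true(all(diff(sp$sizes) >= 0))
  expect_error(build_state_space(LETTERS[1:6], 2, excluded = "ABC"),
               "not a valid subset")
})

test_that("anagenetic rate matrix has the DEC structure", {
  sp <- two_area_space
  Q <- build_q(sp, dec_model(c("X", "Y"), numeric(0), matrix(1, 2, 2),
                             d = 0.1, e = 0.05))
  expect_equal(Q["X", "XY"], 0.1)
  expect_equal(Q["XY", "X"], 0.05)
  expect_equal(Q["X", "0"], 0.05)
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  expect_true(all(Q["0", ] == 0))                # null range absorbing
  ## d = e = 0 -> zero matrix
  Q0 <- build_q(sp, dec_model(c("X", "Y"), numeric(0), matrix(1, 2, 2), 0, 0))
  expect_equal(max(abs(Q0)), 0)
  ## dispersal into b sums contributions over source areas
  sp6 <- build_state_space(LETTERS[1:6], 2)
  m6 <- dec_model(LETTERS[1:6], numeric(0),
                  matrix(0.5, 6, 6), d = 0.2, e = 0)
  Q6 <- build_q(sp6, m6)
  expect_equal(Q6["AB", ], stats::setNames(rep(0, 22), sp6$labels))  # maxareas caps growth
  expect_equal(Q6["A", "AB"], 0.2 * 0.5)
})

test_that("branch transitions agree with an independent matrix exponential", {
  sp <- two_area_space
  m <- two_area_model()
  Q <- build_q(sp, m)
  P <- branch_transition(m, sp, 2.5, 0.5)
  P_oracle <- as.matrix(Matrix::expm(Q * 2))
  expect_equal(unname(P), unname(P_oracle), tolerance = 1e-9)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-9)
  ## zero-duration branch
  expect_equal(unname(branch_transition(m, sp, 1, 1)), diag(4))
  ## identical slice matrices reproduce the unstratified exponential
  ms <- dec_model(c("X", "Y"), c(1.5, 0.8),
                  list(matrix(1, 2, 2), matrix(1, 2, 2), matrix(1, 2, 2)),
                  d = m$d, e = m$e)
  expect_equal(unname(branch_transition(ms, sp, 2.5, 0.5)),
               unname(P_oracle), tolerance = 1e-9)
})

test_that("pruning likelihood equals brute-force enumeration", {
  sp <- two_area_space
  m <- two_area_model()
  cases <- list(
    list(t = "((t1:1,t2:1):1,t3:2);", r = c(t1 = "X", t2 = "XY", t3 = "Y")),
    list(t = "((t1:1,t2:1):1.5,(t3:2,t4:2):0.5);",
         r = c(t1 = "X", t2 = "Y", t3 = "XY", t4 = "Y")),
    list(t = "(((t1:0.5,t2:0.5):1,t3:1.5):1,t4:2.5);",
         r = c(t1 = "X", t2 = "X", t3 = "Y", t4 = "XY")),
    list(t = "(t1:1,t2:1);", r = c(t1 = "X", t2 = "Y")))
  for (cs in cases) {
    tr <- parse_tree(cs$t)
    for (root in list(NULL, "X")) {
      expect_equal(dec_loglik(tr, cs$r, m, sp, root_range = root),
                   brute_dec_loglik(tr, cs$r, m, sp, root_range = root),
                   tolerance = 1e-9)
    }
  }
  ## stratified model against the same oracle
  ms <- dec_model(c("X", "Y"), c(1.2, 0.4),
                  list(matrix(c(1, .2, .2, 1), 2), matrix(1, 2, 2),
                       matrix(c(1, .5, .5, 1), 2)), d = 0.07, e = 0.03)
  tr <- parse_tree(cases[[2]]$t)
  expect_equal(dec_loglik(tr, cases[[2]]$r, ms, sp, "X"),
               brute_dec_loglik(tr, cases[[2]]$r, ms, sp, "X"),
               tolerance = 1e-9)
})

test_that("likelihood is invariant to a consistent relabeling of areas", {
  sp <- two_area_space
  m <- dec_model(c("X", "Y"), numeric(0), matrix(c(1, 0.4, 0.7, 1), 2,
                                                 byrow = TRUE), 0.05, 0.02)
  tr <- parse_tree("((t1:1,t2:1):1.5,(t3:2,t4:2):0.5);")
  r <- c(t1 = "X", t2 = "Y", t3 = "XY", t4 = "Y")
  l1 <- dec_loglik(tr, r, m, sp, "X")
  ## swap X and Y everywhere (matrix rows/cols, tip ranges, root)
  m_swap <- dec_model(c("X", "Y"), numeric(0),
                      matrix(c(1, 0.7, 0.4, 1), 2, byrow = TRUE), 0.05, 0.02)
  r_swap <- c(t1 = "Y", t2 = "X", t3 = "XY", t4 = "X")
  expect_equal(dec_loglik(tr, r_swap, m_swap, sp, "Y"), l1, tolerance = 1e-12)
})

test_that("trivial cases: identical single-area data", {
  sp <- two_area_space
  tr <- parse_tree("((t1:1,t2:1):1,t3:2);")
  r <- c(t1 = "X", t2 = "X", t3 = "X")
  ## d = e = 0, root fixed: probability one
  expect_equal(dec_loglik(tr, r, two_area_model(0, 0), sp, "X"), 0)
  ## single-area data: that area is the unique significant state everywhere
  fit <- suppressWarnings(dec_optimize(tr, r, two_area_model(), sp, "X"))
  best <- fit$nodes[fit$nodes$rel_lnL == 0, ]
  expect_true(all(best$range == "X"))
  exp_states <- fit$nodes[fit$nodes$rel_lnL <= 2, ]
  expect_true(all(exp_states$range == "X"))
})

test_that("per-node constrained likelihoods integrate back to the global", {
  sp <- two_area_space
  m <- two_area_model()
  tr <- parse_tree("((t1:1,t2:1):1.5,(t3:2,t4:2):0.5);")
  r <- c(t1 = "X", t2 = "Y", t3 = "XY", t4 = "Y")
  tipidx <- museumdiv:::resolve_tip_ranges(tr, r, sp)
  rec <- museumdiv:::dec_node_reconstructions(tr, tipidx, m, sp, NULL,
                                              report_delta = Inf)
  glob <- dec_loglik(tr, r, m, sp)
  expect_equal(attr(rec, "global_lnL"), glob, tolerance = 1e-9)
  for (v in unique(rec$node)) {
    l <- rec$lnL[rec$node == v]
    expect_equal(log(sum(exp(l))), glob, tolerance = 1e-9)
    expect_true(all(l <= glob + 1e-9))
  }
})

test_that("dispersal rate is recovered within a factor of two", {
  set.seed(30)
  sp <- two_area_space
  m <- two_area_model(d = 0.05, e = 0.01)
  d_hat <- replicate(25, {
    tr <- sim_yule(100)
    simr <- sim_dec_ranges(tr, m, sp, "X")
    suppressWarnings(dec_optimize(tr, simr$tip_ranges, m, sp, "X"))$d
  })
  expect_lt(abs(log2(stats::median(d_hat) / 0.05)), 1)
})

test_that("extinction simulated at zero is estimated at the boundary", {
  set.seed(31)
  sp <- two_area_space
  m <- two_area_model(d = 0.05, e = 0)
  e_hat <- replicate(15, {
    tr <- sim_yule(60)
    simr <- sim_dec_ranges(tr, m, sp, "X")
    suppressWarnings(dec_optimize(tr, simr$tip_ranges, m, sp, "X"))$e
  })
  expect_gte(mean(e_hat <= 1e-3), 0.8)
})

test_that("maxareas 2 and 3 analyses give closely similar fits", {
  ## the two state spaces are not nested models, so the optimized lnL can
  ## move slightly in either direction; they should agree closely and rank
  ## the same reconstructions on 2-area-limited data
  set.seed(32)
  areas <- c("X", "Y", "Z")
  sp2 <- build_state_space(areas, 2)
  sp3 <- build_state_space(areas, 3)
  m <- dec_model(areas, numeric(0), matrix(1, 3, 3), d = 0.05, e = 0.01)
  tr <- sim_yule(30)
  simr <- sim_dec_ranges(tr, m, sp2, "X")
  f2 <- suppressWarnings(dec_optimize(tr, simr$tip_ranges, m, sp2, "X"))
  f3 <- suppressWarnings(dec_optimize(tr, simr$tip_ranges, m, sp3, "X"))
  expect_lt(abs(f3$lnL - f2$lnL), 1)
  expect_lt(abs(log2(f3$d / f2$d)), 0.5)
  b2 <- f2$nodes[f2$nodes$rel_lnL == 0, ]
  b3 <- f3$nodes[f3$nodes$rel_lnL == 0, ]
  agree <- mean(b2$range[!duplicated(b2$node)] ==
                  b3$range[match(unique(b2$node), b3$node)])
  expect_gt(agree, 0.8)
})

test_that("dec config and tip-range files round-trip", {
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(c(
    "areas: [\"X\", \"Y\"]",
    "boundaries: [1.0]",
    "matrices:",
    "  - [[1.0, 0.5], [0.5, 1.0]]",
    "  - [[1.0, 1.0], [1.0, 1.0]]",
    "d: 0.05", "e: 0.01", "maxareas: 2", "root_range: X"), cfg_file)
  cfg <- read_dec_config(cfg_file)
  expect_equal(cfg$model$n_slices, 2L)
  expect_equal(cfg$model$matrices[[1]]["X", "Y"], 0.5)
  expect_equal(cfg$space$n_states, 4L)
  expect_equal(cfg$root_range, "X")
  rng_file <- tempfile(fileext = ".tsv")
  writeLines(c("tip\tX\tY", "t1\t1\t0", "t2\t1\t1"), rng_file)
  masks <- read_tip_ranges(rng_file, cfg$space)
  expect_equal(unname(masks), c(1L, 3L))
  unlink(c(cfg_file, rng_file))
})
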