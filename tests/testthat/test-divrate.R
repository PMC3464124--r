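test_that("gamma statistic matches direct formula evaluation and ape", {
  g <- gamma_stat(as_branching_times(c(3, 2, 1)))
  ## T = 9, interior means (2 + 5)/2 = 3.5: gamma = (3.5 - 4.5)/(9 sqrt(1/24))
  expect_equal(g$gamma, (3.5 - 4.5) / (9 * sqrt(1 / 24)), tolerance = 1e-12)
  expect_equal(g$p_one_tailed, stats::pnorm(g$gamma))

  ## exact zero on the tree with k * g_k = 1 for all k
  expect_equal(gamma_stat(branching_times(gamma_zero_tree(12)))$gamma, 0,
               tolerance = 1e-9)

  ## agreement with ape's implementation, and rescaling invariance
  set.seed(40)
  for (i in 1:10) {
    tr <- sim_yule(sample(10:60, 1))
    bt <- branching_times(tr)
    expect_equal(gamma_stat(bt)$gamma, ape::gammaStat(tr), tolerance = 1e-8)
    expect_equal(gamma_stat(as_branching_times(bt$ages * 13.7))$gamma,
                 gamma_stat(bt)$gamma, tolerance = 1e-9)
  }
  expect_error(gamma_stat(as_branching_times(2)), "3 tips")
})

test_that("gamma is approximately standard normal under complete pure birth", {
  set.seed(41)
  gs <- replicate(1000, gamma_stat(branching_times(sim_yule(50)))$gamma)
  expect_lt(abs(mean(gs)), 0.1)
  expect_lt(abs(stats::sd(gs) - 1), 0.1)
})

test_that("MCCR test is seeded, sensible at complete sampling, and monotone", {
  m1 <- mccr_test(-0.5, 25, 20, replicates = 300, seed = 42)
  m2 <- mccr_test(-0.5, 25, 20, replicates = 300, seed = 42)
  expect_identical(m1$null_gamma, m2$null_gamma)
  expect_identical(m1$critical_value, m2$critical_value)

  ## complete sampling at large n: asymptotic 5% point of a standard normal
  mc <- mccr_test(0, 200, 200, replicates = 4000, seed = 43)
  expect_lt(abs(mc$critical_value - (-1.645)), 0.08)

  ## critical value non-increasing in the missing fraction
  crit <- vapply(c(30, 40, 47), function(nt)
    mccr_test(0, nt, 30, replicates = 2000, seed = 44)$critical_value, 0)
  expect_true(all(diff(crit) < 0.05))
  expect_error(mccr_test(0, 10, 2), "at least 3")
})

test_that("pure-birth fit matches the closed form; birth-death nests it", {
  f <- fit_rate_constant(as_branching_times(c(3, 2, 1)))
  expect_equal(f$pureBirth$params$lambda, 2 / 9, tolerance = 1e-12)
  expect_equal(f$pureBirth$lnL, 2 * log(2 / 9) - 2, tolerance = 1e-12)
  expect_equal(f$pureBirth$AIC, -2 * (2 * log(2 / 9) - 2) + 2, tolerance = 1e-12)
  expect_gte(f$bd$lnL, f$pureBirth$lnL)

  ## on pure-birth data the bd fit should sit at (or near) a = 0 and
  ## reproduce the pure-birth likelihood when constrained there
  set.seed(45)
  bt <- branching_times(sim_yule(50, lambda = 2))
  f2 <- fit_rate_constant(bt)
  expect_gte(f2$bd$lnL, f2$pureBirth$lnL)
  expect_lt(f2$bd$lnL - f2$pureBirth$lnL, 3)
})

test_that("rate-variable fits nest the pure-birth model", {
  set.seed(46)
  for (i in 1:5) {
    bt <- branching_times(sim_yule(30))
    rc <- fit_rate_constant(bt)
    rv <- fit_rate_variable(bt)
    for (m in rv) expect_gte(m$lnL, rc$pureBirth$lnL - 1e-6)
    expect_equal(vapply(rv, `[[`, 0L, "k"),
                 c(DDL = 2L, DDX = 2L, yule2rate = 3L, yule3rate = 5L))
    for (m in rv) expect_equal(m$AIC, -2 * m$lnL + 2 * m$k)
    ## shift times lie on observed branching times
    expect_true(rv$yule2rate$params$shift %in% bt$ages)
  }
})

test_that("yule2rate recovers a simulated rate shift", {
  set.seed(47)
  ok <- replicate(30, {
    sim <- sim_yule2(80, lam1 = 0.1, lam2 = 0.4, t_switch = 10)
    rv <- fit_rate_variable(sim$bt)
    est <- rv$yule2rate$params$shift
    ## within the central half of the tree depth around the truth
    abs(est - sim$shift_age) < 0.25 * sim$crown
  })
  expect_gte(mean(ok), 0.7)
})

test_that("delta AIC comparison and LR bookkeeping", {
  set.seed(48)
  bt <- branching_times(sim_yule(30))
  fits <- c(fit_rate_constant(bt), fit_rate_variable(bt))
  da <- delta_aic_rc(fits)
  aics <- vapply(fits, `[[`, 0, "AIC")
  rc_min <- min(aics[c("pureBirth", "bd")])
  rv_min <- min(aics[c("DDL", "DDX", "yule2rate", "yule3rate")])
  expect_equal(da$delta_aic_rc, rc_min - rv_min)
  expect_equal(da$LR, 2 * (da$best_rv$lnL - da$best_rc$lnL))
  expect_equal(da$p, stats::pchisq(da$LR, 1, lower.tail = FALSE))
  expect_error(delta_aic_rc(fit_rate_constant(bt)), "RC and one RV")
})

test_that("fixed-time shift test is calibrated and detects true shifts", {
  set.seed(49)
  ps <- replicate(400, {
    bt <- branching_times(sim_yule(40))
    tau <- sqrt(bt$ages[2] * bt$ages[length(bt$ages)])
    shift_at_time_test(bt, tau)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)

  ## 4x drop in rate at the switch: ratio of fitted rates recovers it
  ratios <- replicate(25, {
    sim <- sim_yule2(80, lam1 = 0.4, lam2 = 0.1, t_switch = 6)
    s <- shift_at_time_test(sim$bt, sim$shift_age)
    expect_gte(s$LR, 0)
    s$lambda_before / s$lambda_after
  })
  expect_true(stats::median(ratios) > 2.5 && stats::median(ratios) < 6)

  bt <- as_branching_times(c(3, 2, 1))
  expect_error(shift_at_time_test(bt, 5), "inside")
  expect_error(shift_at_time_test(bt, 0.5), "no branching events")
})

test_that("relative cladogenesis tail probabilities match enumeration", {
  ## k = 2, N = 5: compositions (1,4),(2,3),(3,2),(4,1) -> P(>= 4) = 1/4
  expect_equal(museumdiv:::rc_tail_prob(4, 2, 5), 0.25)
  for (N in c(6, 9, 12)) {
    for (k in 2:min(4, N - 1)) {
      for (r in 1:(N - k + 1)) {
        expect_equal(museumdiv:::rc_tail_prob(r, k, N),
                     brute_rc_tail(r, k, N), tolerance = 1e-12,
                     info = sprintf("N=%d k=%d r=%d", N, k, r))
      }
    }
  }
})

test_that("relative cladogenesis test flags imbalance, not balance", {
  ## perfectly balanced tree: nothing significant
  bal <- ape::stree(16, type = "balanced")
  bal$edge.length <- rep(1, nrow(bal$edge))
  bal <- snap_ultrametric(ape::compute.brlen(bal, 1))
  rc <- rel_cladogenesis_test(bal)
  expect_false(any(rc$significant))
  ## strongly imbalanced: a comb lineage carrying nearly all tips
  cat_tree <- comb_tree(seq(40, 1, by = -1) / 10)
  rc2 <- rel_cladogenesis_test(cat_tree)
  expect_true(all(rc2$p <= 1) && all(rc2$p >= 0))
  expect_true(all(rc2$p_bonferroni >= rc2$p))
})

test_that("net diversification estimators match closed forms and ordering", {
  nd <- ms_netdiv(30, t_crown = 27, t_stem = 37, epsilon = c(0, 0.5, 0.9))
  expect_equal(nd$r_crown[1], log(15) / 27, tolerance = 1e-12)
  expect_equal(nd$r_stem[1], log(30) / 37, tolerance = 1e-12)
  expect_true(all(diff(nd$r_crown) < 0))
  expect_true(all(diff(nd$r_stem) < 0))
  ## monotone in epsilon across a sweep
  sweep <- ms_netdiv(100, t_crown = 10, epsilon = seq(0, 0.95, by = 0.05))
  expect_true(all(diff(sweep$r_crown) < 0))
  expect_error(ms_netdiv(30, t_crown = 5, epsilon = 1), "epsilon")
})
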