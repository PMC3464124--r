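test_that("interval table classifies events and counts lineages correctly", {
  tr <- comb_tree(c(3, 2, 1))
  tab <- interval_table(tr, 1.5)
  ## events at 3 (crown, conditioned on) and 2 are diversification; 3 branches
  ## cross T = 1.5 -> 3 entities with one coalescent event at age 1
  expect_equal(tab$n_entities, 3L)
  expect_equal(tab$events$type, c("div", "coal"))
  expect_equal(sort(tab$cluster_sizes, decreasing = TRUE), c(2, 1, 1))
  ## boundary: everything diversification
  expect_equal(interval_table(tr, 0)$n_entities, 4L)
  ## boundary: threshold older than the crown, single cluster, n_div = 1
  thi <- interval_table(tr, 5)
  expect_equal(thi$n_entities, 1L)
  expect_true(all(thi$n_div == 1L))
  expect_error(interval_table(tr, -1), "non-negative")
})

test_that("mixed log-likelihood reduces to the coalescent form on one cluster", {
  set.seed(20)
  tr <- sim_yule(10)
  crown <- max(museumdiv:::node_ages(tr))
  tab <- interval_table(tr, crown * 1.5)
  ## p1 = p2 = 1, lambda1 -> 0: pure n(n-1) coalescent likelihood
  bt <- branching_times(tr)
  g <- bt$ages - c(bt$ages[-1], 0)
  cnt <- 2:10
  lam2 <- 0.7
  manual <- sum(log(lam2 * (cnt[1:8] * (cnt[1:8] - 1)))) -
    lam2 * sum(cnt * (cnt - 1) * g)
  expect_equal(
    gmyc_loglik(tab, list(lambda1 = 1e-300, lambda2 = lam2, p1 = 1, p2 = 1)),
    manual, tolerance = 1e-9)
})

test_that("log-likelihood obeys the age/rate change of variables", {
  set.seed(21)
  tr <- sim_yule(12)
  crown <- max(museumdiv:::node_ages(tr))
  T_age <- crown * 0.3
  tab1 <- interval_table(tr, T_age)
  cc <- 3
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * cc
  tab2 <- interval_table(tr2, T_age * cc)
  p <- list(lambda1 = 2, lambda2 = 5, p1 = 1, p2 = 1)
  p_scaled <- list(lambda1 = 2 / cc, lambda2 = 5 / cc, p1 = 1, p2 = 1)
  ## density transforms by one Jacobian factor log(c) per event
  expect_equal(gmyc_loglik(tab1, p),
               gmyc_loglik(tab2, p_scaled) + nrow(tab1$events) * log(cc),
               tolerance = 1e-9)
})

test_that("null-model rate estimate recovers a simulated coalescent rate", {
  set.seed(22)
  theta <- 0.5
  ratios <- replicate(100, {
    tr <- museumdiv:::coalescent_cluster(100, theta)
    bt <- branching_times(tr)
    g <- bt$ages - c(bt$ages[-1], 0)
    cnt <- 2:100
    lam_hat <- (100 - 2) / sum(cnt * (cnt - 1) * g)   # p fixed at 1
    lam_hat * theta                                    # true lambda = 1 / theta
  })
  expect_lt(abs(stats::median(ratios) - 1), 0.15)
})

test_that("gmyc_fit recovers the species count on well-separated clusters", {
  set.seed(23)
  hits <- replicate(40, {
    s <- sim_gmyc(5, lambda_sp = 1, m_per_species = 4, theta = 0.005,
                  crown_age = 1, min_split = 0.1)
    f <- suppressWarnings(gmyc_fit(s$tree))
    f$n_entities == s$k_species
  })
  expect_gte(mean(hits), 0.9)
})

test_that("gmyc_fit structure invariants hold", {
  s <- sim_gmyc(4, m_per_species = 3, theta = 0.01, crown_age = 1,
                min_split = 0.1, seed = 24)
  f <- suppressWarnings(gmyc_fit(s$tree))
  expect_gte(f$logL_gmyc, f$logL_null)
  expect_gte(f$LR, 0)
  expect_equal(f$df, 3L)
  expect_equal(nrow(f$clusters), ape::Ntip(s$tree))
  expect_equal(sum(table(f$clusters$cluster)), ape::Ntip(s$tree))
  ## entity count is monotone non-increasing in the threshold age
  ages <- sort(museumdiv:::node_ages(s$tree)[13:23], decreasing = TRUE)
  cand <- c(0, (ages[-1] + ages[-length(ages)]) / 2, max(ages) * 1.1)
  ents <- vapply(sort(cand), function(T) interval_table(s$tree, T)$n_entities, 0L)
  expect_true(all(diff(ents) <= 0))
  ## confidence set contains the ML entity count
  expect_true(f$n_entities >= f$confidence$entity_range[1] &&
                f$n_entities <= f$confidence$entity_range[2])
})

test_that("single-process trees are rejected at roughly the nominal rate", {
  set.seed(25)
  rej <- replicate(120, {
    tr <- museumdiv:::coalescent_cluster(15, 1)
    tr$tip.label <- paste0("t", 1:15)
    suppressWarnings(gmyc_fit(tr))$p < 0.05
  })
  ## d.f. = 3 LRT should not be wildly miscalibrated
  expect_lt(mean(rej), 0.12)
})

test_that("consensus reduction applies the IUPAC column rules", {
  expect_equal(unname(consensus_reduce(
    c(a = "ACGT", b = "ACGT"), c(a = 1, b = 1))), "ACGT")
  expect_equal(unname(consensus_reduce(
    c(a = "AAAA", b = "AAAG"), c(a = 1, b = 1))), "AAAR")
  expect_equal(unname(consensus_reduce(
    c(a = "A-CT", b = "AGCT"), c(a = 1, b = 1))), "AGCT")
  expect_equal(unname(consensus_reduce(
    c(a = "A--T", b = "A--T"), c(a = 1, b = 1))), "A--T")
  ## two clusters, singleton keeps its own name
  out <- consensus_reduce(c(a = "AC", b = "AT", c = "GG"),
                          c(a = 1, b = 1, c = 2))
  expect_equal(out[["cluster_1"]], "AY")
  expect_equal(out[["c"]], "GG")
  expect_error(consensus_reduce(c(a = "AC"), c(a = 1, b = 1)), "missing")
  expect_error(consensus_reduce(c(a = "AC", b = "ACG"), c(a = 1, b = 1)),
               "equal length")
})

test_that("fasta round-trip preserves sequences", {
  tf <- tempfile(fileext = ".fasta")
  seqs <- c(s1 = "ACGTACGT", s2 = "TTTTAAAA")
  write_fasta(seqs, tf)
  expect_equal(read_fasta(tf), seqs)
  unlink(tf)
})
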