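# Diversification-rate battery: gamma/MCCR, rate-constant vs rate-variable
# model selection, fixed-time shift tests, relative cladogenesis, and
# Magallon-Sanderson net-diversification estimators.
#
# Likelihood convention for all Yule-family fits (after Rabosky 2006): with
# internode intervals g_k (time spent with exactly k lineages, k = 2..n) the
# log-likelihood counts the n-2 observable branching events (the crown split is
# conditioned upon) and uses the full normalizer sum(k * lambda(k) * g_k).

## internode intervals g_k, k = 2..n, from descending ages
internode_intervals <- function(bt) {
  bt <- as_branching_times(bt)
  list(g = bt$ages - c(bt$ages[-1L], 0), n = bt$n_tips, ages = bt$ages)
}

#' Gamma statistic (constant-rates test)
#'
#' Pybus-Harvey standardized summary of branching-time spread. Negative values
#' indicate branching concentrated toward the root. Under a completely sampled
#' pure-birth tree gamma is standard normal; the one-tailed p-value (toward
#' negative gamma, i.e. deceleration) is `pnorm(gamma)`.
#'
#' @param bt Branching times ([as_branching_times()] input), n >= 3.
#' @return Object of class `gamma_stat`: list(`gamma`, `p_one_tailed`, `n_tips`).
#' @export
gamma_stat <- function(bt) {
  iv <- internode_intervals(bt)
  n <- iv$n
  if (n < 3L) stop("gamma statistic needs at least 3 tips")
  kg <- (2:n) * iv$g
  Tn <- sum(kg)
  if (Tn <= 0) stop("total weighted tree length is zero")
  Ti <- cumsum(kg)                       # T_i for i = 2..n
  gam <- (mean(Ti[seq_len(n - 2L)]) - Tn / 2) / (Tn * sqrt(1 / (12 * (n - 2L))))
  structure(list(gamma = gam, p_one_tailed = stats::pnorm(gam), n_tips = n),
            class = "gamma_stat")
}

#' @export
print.gamma_stat <- function(x, ...) {
  cat(sprintf("gamma = %.4f (n = %d tips), one-tailed p = %.4f\n",
              x$gamma, x$n_tips, x$p_one_tailed))
  invisible(x)
}

#' MCCR test: gamma null distribution under incomplete sampling
#'
#' Simulates `replicates` completely sampled pure-birth trees of `n_total`
#' tips, prunes each uniformly at random to `n_sampled` tips, and computes the
#' gamma statistic of the induced subtree. Reports the 5th-percentile critical
#' value and the one-tailed p-value of the observed gamma (fraction of null
#' values at or below it). The simulation rate is fixed at 1: gamma is
#' invariant to time rescaling.
#'
#' @param observed_gamma Observed gamma statistic.
#' @param n_total True clade size (sampled + missing).
#' @param n_sampled Number of sampled tips (3 <= n_sampled <= n_total).
#' @param replicates Number of null replicates (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `mccr_test`: list with `null_gamma`,
#'   `critical_value` (5th percentile), `p`, and the settings.
#' @export
mccr_test <- function(observed_gamma, n_total, n_sampled,
                      replicates = 10000L, seed = NULL) {
  n_total <- as.integer(n_total); n_sampled <- as.integer(n_sampled)
  if (n_sampled < 3L) stop("n_sampled must be at least 3")
  if (n_sampled > n_total) stop("n_sampled cannot exceed n_total")
  if (!is.null(seed)) set.seed(seed)
  null_gamma <- vapply(seq_len(replicates), function(i) {
    raw <- yule_raw(n_total, 1)
    bt <- if (n_sampled == n_total) {
      sort(raw$node_age[(n_total + 1L):(2L * n_total - 1L)], decreasing = TRUE)
    } else {
      yule_induced_bt(raw, sample.int(n_total, n_sampled))
    }
    gamma_stat(new_branching_times(bt, n_sampled))$gamma
  }, numeric(1L))
  structure(list(observed_gamma = observed_gamma,
                 n_total = n_total, n_sampled = n_sampled,
                 replicates = as.integer(replicates),
                 null_gamma = null_gamma,
                 critical_value = unname(stats::quantile(null_gamma, 0.05)),
                 p = mean(null_gamma <= observed_gamma)),
            class = "mccr_test")
}

#' @export
print.mccr_test <- function(x, ...) {
  cat(sprintf(paste0("MCCR test: %d of %d species sampled, %d replicates\n",
                     "  5%% critical value = %.3f; observed gamma = %.4f, p = %.3f\n"),
              x$n_sampled, x$n_total, x$replicates,
              x$critical_value, x$observed_gamma, x$p))
  invisible(x)
}

## ---- model fits ------------------------------------------------------------

new_model_fit <- function(model, k, lnL, params) {
  structure(list(model = model, k = as.integer(k), lnL = lnL,
                 AIC = -2 * lnL + 2 * k, params = params),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%-10s k=%d  lnL=%.4f  AIC=%.4f  [%s]\n", x$model, x$k, x$lnL,
              x$AIC, paste(names(x$params),
                           vapply(x$params, function(p) format(p, digits = 5), ""),
                           sep = "=", collapse = ", ")))
  invisible(x)
}

## lnL for piecewise/variable per-lineage rate lam_k over lineage counts:
## events have pre-event counts 2..n-1
yule_varying_lnL <- function(g, n, lam_of_k) {
  lam <- lam_of_k(2:n)
  if (any(lam <= 0)) return(-Inf)
  sum(log(lam[seq_len(n - 2L)])) - sum((2:n) * lam * g)
}

#' Fit rate-constant diversification models
#'
#' Pure-birth (Yule) in closed form and the two-parameter birth-death model
#' (net rate r and relative extinction a = mu/lambda, Nee-type likelihood on
#' branching times).
#'
#' @param bt Branching times (n >= 3).
#' @return List of two `model_fit` objects: `pureBirth`, `bd`.
#' @export
fit_rate_constant <- function(bt) {
  iv <- internode_intervals(bt)
  g <- iv$g; n <- iv$n; x <- iv$ages
  if (n < 3L) stop("need at least 3 tips")
  S <- sum((2:n) * g)
  if (S <= 0 || any(g < 0)) stop("degenerate branching times")
  lam <- (n - 2L) / S
  pb <- new_model_fit("pureBirth", 1L, (n - 2L) * log(lam) - lam * S,
                      list(lambda = lam))
  bd_lnL <- function(r, a) {
    if (r <= 0 || a < 0 || a >= 1) return(-Inf)
    (n - 2L) * log(r) + r * sum(x[-1L]) + n * log1p(-a) -
      2 * sum(log(exp(r * x) - a))
  }
  obj <- function(p) -bd_lnL(exp(p[1L]), stats::plogis(p[2L]))
  best <- NULL
  for (start in list(c(log(lam), -3), c(log(lam / 2), 0), c(log(lam * 2), 2))) {
    o <- try(stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
             silent = TRUE)
    if (!inherits(o, "try-error") && (is.null(best) || o$value < best$value))
      best <- o
  }
  r_hat <- exp(best$par[1L]); a_hat <- stats::plogis(best$par[2L])
  lnl_bd <- max(-best$value, pb$lnL)   # pure birth nested at a = 0
  if (-best$value < pb$lnL) { r_hat <- lam; a_hat <- 0 }
  bd <- new_model_fit("bd", 2L, lnl_bd, list(r = r_hat, a = a_hat))
  list(pureBirth = pb, bd = bd)
}

## profile lnL of a multi-rate Yule given cut ages (shift times on event grid);
## event at exactly a shift age belongs to the older segment
yule_segments_profile <- function(ages, n, cuts) {
  bounds <- c(Inf, sort(cuts, decreasing = TRUE), 0)
  ev <- ages[-1L]                      # event ages x_3..x_n (pre-count 2..n-1)
  lnL <- 0
  rates <- numeric(length(bounds) - 1L)
  mesh <- sort(unique(c(ages, cuts, 0)), decreasing = TRUE)
  upper <- mesh[-length(mesh)]; lower <- mesh[-1L]
  cnt <- vapply(upper, function(u) sum(ages >= u) + 1L, integer(1L))
  ## lineage count during (lower, upper): 1 + number of events with age >= upper
  for (s in seq_len(length(bounds) - 1L)) {
    hi <- bounds[s]; lo <- bounds[s + 1L]
    nev <- sum(ev <= hi & ev > lo)
    if (is.infinite(hi)) nev <- sum(ev > lo)   # oldest segment
    sel <- upper <= hi & upper > lo
    if (is.infinite(hi)) sel <- upper > lo
    Sseg <- sum(cnt[sel] * (upper[sel] - lower[sel]))
    if (nev > 0L) {
      if (Sseg <= 0) return(list(lnL = -Inf, rates = rates))
      lam <- nev / Sseg
      lnL <- lnL + nev * (log(lam) - 1)
      rates[s] <- lam
    } else rates[s] <- 0
  }
  list(lnL = lnL, rates = rates)
}

#' Fit rate-variable diversification models
#'
#' Density-dependent (logistic `DDL`: lambda(N) = r (1 - N/K); exponential
#' `DDX`: lambda(N) = r N^-x) and piecewise-constant Yule models with one
#' (`yule2rate`, k = 3) or two (`yule3rate`, k = 5) shift times, shifts
#' searched over the observed branching times with closed-form per-segment
#' rates.
#'
#' @param bt Branching times (n >= 4; n >= 6 for yule3rate).
#' @return Named list of `model_fit` objects.
#' @export
fit_rate_variable <- function(bt) {
  iv <- internode_intervals(bt)
  g <- iv$g; n <- iv$n; ages <- iv$ages
  if (n < 4L) stop("need at least 4 tips")
  out <- list()

  ## DDL: given K, rate profile known up to r -> closed-form r
  ddl_prof <- function(K) {
    w <- 1 - (2:n) / K
    if (any(w[seq_len(n - 2L)] <= 0)) return(list(lnL = -Inf))
    S <- sum((2:n) * pmax(w, 0) * g)
    r <- (n - 2L) / S
    list(lnL = sum(log(r * w[seq_len(n - 2L)])) - r * S, r = r)
  }
  oK <- stats::optimize(function(u) -ddl_prof(n + exp(u))$lnL,
                        interval = c(log(1e-3), log(1e6)), tol = 1e-10)
  K_hat <- n + exp(oK$minimum)
  pK <- ddl_prof(K_hat)
  ## K -> infinity is pure birth; report that boundary when it is the supremum
  S <- sum((2:n) * g)
  pb_lnL <- (n - 2L) * log((n - 2L) / S) - (n - 2L)
  if (pb_lnL >= pK$lnL) {
    out$DDL <- new_model_fit("DDL", 2L, pb_lnL, list(r = (n - 2L) / S, K = Inf))
  } else {
    out$DDL <- new_model_fit("DDL", 2L, pK$lnL, list(r = pK$r, K = K_hat))
  }

  ## DDX: given x, closed-form r
  ddx_prof <- function(xx) {
    S <- sum((2:n)^(1 - xx) * g)
    r <- (n - 2L) / S
    list(lnL = (n - 2L) * log(r) - xx * sum(log(2:(n - 1L))) - r * S, r = r)
  }
  ox <- stats::optimize(function(xx) -ddx_prof(xx)$lnL, interval = c(-3, 5),
                        tol = 1e-10)
  x_hat <- ox$minimum
  if (ddx_prof(0)$lnL >= ddx_prof(x_hat)$lnL) x_hat <- 0   # pure-birth nested
  px <- ddx_prof(x_hat)
  out$DDX <- new_model_fit("DDX", 2L, px$lnL, list(r = px$r, x = x_hat))

  ## multi-rate Yule: shift times on the event grid (interior events only)
  grid <- ages[-1L]
  best2 <- list(lnL = -Inf)
  for (st in grid) {
    pr <- yule_segments_profile(ages, n, st)
    if (pr$lnL > best2$lnL) best2 <- c(pr, list(st = st))
  }
  out$yule2rate <- new_model_fit("yule2rate", 3L, best2$lnL,
                                 list(lambda1 = best2$rates[1L],
                                      lambda2 = best2$rates[2L],
                                      shift = best2$st))
  if (n >= 6L) {
    best3 <- list(lnL = -Inf)
    m <- length(grid)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      pr <- yule_segments_profile(ages, n, c(grid[i], grid[j]))
      if (pr$lnL > best3$lnL) best3 <- c(pr, list(st = c(grid[i], grid[j])))
    }
    out$yule3rate <- new_model_fit("yule3rate", 5L, best3$lnL,
                                   list(lambda1 = best3$rates[1L],
                                        lambda2 = best3$rates[2L],
                                        lambda3 = best3$rates[3L],
                                        shift1 = best3$st[1L],
                                        shift2 = best3$st[2L]))
  }
  out
}

#' Compare rate-constant against rate-variable fits
#'
#' `dAIC_RC = min AIC among RC models - min AIC among RV models`; negative
#' values favour the rate-constant model. Also reports the likelihood ratio
#' between the two best models with a chi-square (d.f. = 1) p-value, and the
#' small/large-phylogeny decision thresholds (4.0 at n ~ 30, 5.5 at n ~ 100).
#'
#' @param fits A (possibly concatenated) list of `model_fit` objects containing
#'   at least one rate-constant (`pureBirth`/`bd`) and one rate-variable fit.
#' @return Object of class `daic_rc`.
#' @export
delta_aic_rc <- function(fits) {
  if (inherits(fits, "model_fit")) fits <- list(fits)
  while (!all(vapply(fits, inherits, TRUE, "model_fit")))
    fits <- unlist(fits, recursive = FALSE)
  models <- vapply(fits, `[[`, "", "model")
  rc_names <- c("pureBirth", "bd")
  rc <- fits[models %in% rc_names]
  rv <- fits[!(models %in% rc_names)]
  if (!length(rc) || !length(rv)) stop("need at least one RC and one RV fit")
  aic <- function(l) vapply(l, `[[`, 0, "AIC")
  best_rc <- rc[[which.min(aic(rc))]]
  best_rv <- rv[[which.min(aic(rv))]]
  lr <- 2 * (best_rv$lnL - best_rc$lnL)
  structure(list(best_rc = best_rc, best_rv = best_rv,
                 delta_aic_rc = best_rc$AIC - best_rv$AIC,
                 LR = lr, p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 thresholds = c(n30 = 4.0, n100 = 5.5)),
            class = "daic_rc")
}

#' @export
print.daic_rc <- function(x, ...) {
  cat(sprintf("dAIC_RC = %.3f (best RC: %s, AIC %.3f; best RV: %s, AIC %.3f)\n",
              x$delta_aic_rc, x$best_rc$model, x$best_rc$AIC,
              x$best_rv$model, x$best_rv$AIC))
  cat(sprintf("LR = %.3f, chi-square d.f.=1 p = %.4g\n", x$LR, x$p))
  invisible(x)
}

#' Test a diversification-rate shift at a fixed time
#'
#' Yule likelihood with one rate before and one after the candidate shift age
#' `tau` (the interval straddling `tau` is split there), compared against the
#' constant-rate fit by a likelihood ratio with a chi-square d.f. = 1 p-value.
#'
#' @param bt Branching times.
#' @param tau Shift age, strictly inside (0, crown age), with at least one
#'   branching event on each side.
#' @return Object of class `shift_test`: list with `tau`, `lambda_before`,
#'   `lambda_after`, `lnL_shift`, `lnL_constant`, `LR`, `p`.
#' @export
shift_at_time_test <- function(bt, tau) {
  iv <- internode_intervals(bt)
  n <- iv$n; ages <- iv$ages
  if (tau <= 0 || tau >= ages[1L])
    stop("tau must lie strictly inside (0, crown age)")
  ev <- ages[-1L]
  if (!any(ev > tau) || !any(ev <= tau))
    stop("shift test undefined: no branching events on one side of tau")
  pr <- yule_segments_profile(ages, n, tau)
  S <- sum((2:n) * iv$g)
  lam <- (n - 2L) / S
  lnl0 <- (n - 2L) * log(lam) - lam * S
  lr <- 2 * (pr$lnL - lnl0)
  structure(list(tau = tau,
                 lambda_before = pr$rates[1L], lambda_after = pr$rates[2L],
                 lnL_shift = pr$lnL, lnL_constant = lnl0, LR = lr,
                 p = stats::pchisq(lr, df = 1, lower.tail = FALSE)),
            class = "shift_test")
}

#' @export
print.shift_test <- function(x, ...) {
  cat(sprintf("shift at %.3f: lambda %.4f -> %.4f, LR = %.3f, p = %.4g\n",
              x$tau, x$lambda_before, x$lambda_after, x$LR, x$p))
  invisible(x)
}

## tail probability that one of k equal-rate lineages jointly leaving N tips
## leaves >= r of them (uniform over compositions of N into k positive parts)
rc_tail_prob <- function(r, k, N) {
  if (r <= 1L) return(1)
  if (r > N - k + 1L) return(0)
  m <- r:(N - k + 1L)
  sum(exp(lchoose(N - m - 1L, k - 2L) - lchoose(N - 1L, k - 1L)))
}

#' Relative cladogenesis test
#'
#' For each non-root internal node, considers the time slice immediately after
#' its parent's split: with k ancestral lineages jointly leaving the tree's N
#' tips, the descendant partition is uniform over compositions of N into k
#' positive parts under the equal-rates Markov null, and the node's p-value is
#' the tail probability that one named lineage leaves at least the observed
#' number of tips. Bonferroni correction over the number of tested nodes.
#'
#' @param tree A binary chronogram.
#' @param alpha Significance cut-off applied after Bonferroni correction.
#' @return Object of class `rel_clad`: data frame with one row per tested node
#'   (`node`, `slice_age`, `k`, `n_desc`, `p`, `p_bonferroni`, `significant`).
#' @export
rel_cladogenesis_test <- function(tree, alpha = 0.05) {
  assert_binary(tree, "relative cladogenesis test")
  assert_ultrametric(tree, what = "relative cladogenesis test")
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  node_ids <- (ntip + 1L):(ntip + tree$Nnode)
  root <- ntip + 1L
  n_desc <- integer(ntip + tree$Nnode)
  n_desc[seq_len(ntip)] <- 1L
  for (e in ape::postorder(tree)) {
    n_desc[tree$edge[e, 1L]] <- n_desc[tree$edge[e, 1L]] + n_desc[tree$edge[e, 2L]]
  }
  int_ages <- ages[node_ids]
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  test_nodes <- setdiff(node_ids, root)
  res <- lapply(test_nodes, function(v) {
    t_slice <- ages[parent[v]]
    ## lineages alive just after the parent's split: 1 + #internal nodes with
    ## age >= t_slice (ties = simultaneous splits counted in)
    k <- 1L + sum(int_ages >= t_slice)
    data.frame(node = v, slice_age = t_slice, k = k, n_desc = n_desc[v],
               p = rc_tail_prob(n_desc[v], k, ntip))
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res$significant <- res$p_bonferroni < alpha
  class(res) <- c("rel_clad", "data.frame")
  res
}

#' Magallon-Sanderson net diversification estimators
#'
#' Whole-clade net diversification rate r = lambda - mu from a standing
#' richness `n` and a clade age, for an assumed relative extinction fraction
#' epsilon = mu/lambda. At epsilon = 0 the estimators reduce to `log(n)/t`
#' (stem) and `log(n/2)/t` (crown).
#'
#' @param n Number of extant species (>= 2).
#' @param t_crown,t_stem Crown and/or stem age (> 0); at least one.
#' @param epsilon Relative extinction, `0 <= epsilon < 1` (vectorized).
#' @return Object of class `netdiv`: data frame with columns `epsilon`,
#'   `r_crown`, `r_stem` (NA where the corresponding age was not given).
#' @export
ms_netdiv <- function(n, t_crown = NA, t_stem = NA, epsilon = c(0, 0.5, 0.9)) {
  stopifnot(n >= 2)
  if (any(epsilon < 0 | epsilon >= 1)) stop("epsilon must lie in [0, 1)")
  if (is.na(t_crown) && is.na(t_stem)) stop("provide t_crown and/or t_stem")
  r_stem <- if (is.na(t_stem)) rep(NA_real_, length(epsilon)) else
    log(n * (1 - epsilon) + epsilon) / t_stem
  r_crown <- if (is.na(t_crown)) rep(NA_real_, length(epsilon)) else {
    vapply(epsilon, function(e) {
      inner <- n * (1 - e^2) / 2 + 2 * e +
        (1 - e) / 2 * sqrt(n * (n * e^2 - 8 * e + 2 * n * e + n) + 4 * e^2)
      (log(inner) - log(2)) / t_crown
    }, numeric(1L))
  }
  structure(data.frame(epsilon = epsilon, r_crown = r_crown, r_stem = r_stem),
            class = c("netdiv", "data.frame"))
}
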