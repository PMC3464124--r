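# Shared fixtures and independent oracles, built in code at test time.

## comb (caterpillar) chronogram with the given internal node ages (descending)
comb_tree <- function(ages) {
  n <- length(ages) + 1L
  nwk <- sprintf("(t1:%.12g,t2:%.12g)", ages[n - 1L], ages[n - 1L])
  for (k in seq(n - 2L, 1L)) {
    nwk <- sprintf("(%s:%.12g,t%d:%.12g)", nwk, ages[k] - ages[k + 1L],
                   n - k + 1L, ages[k])
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

## tree whose internode intervals are g_k = 1/k (gamma exactly zero)
gamma_zero_tree <- function(n) {
  g <- 1 / (2:n)
  comb_tree(rev(cumsum(rev(g))))
}

## brute-force DEC likelihood: enumerate every internal (range, scenario)
## assignment and sum products of branch transition entries
brute_dec_loglik <- function(tree, tip_ranges, model, space, root_range = NULL) {
  ntip <- ape::Ntip(tree)
  ages <- museumdiv:::node_ages(tree)
  scen <- museumdiv:::dec_scenarios(space)
  tipidx <- museumdiv:::resolve_tip_ranges(tree, tip_ranges, space)
  pr <- museumdiv:::root_prior(space, root_range)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  opts <- lapply(internal, function(v) {
    do.call(rbind, lapply(seq_len(space$n_states), function(i) {
      rws <- scen[[i]]
      if (!nrow(rws)) return(NULL)
      cbind(range = i, s1 = rws[, 1L], s2 = rws[, 2L], w = 1 / nrow(rws))
    }))
  })
  kids <- lapply(internal, function(v) tree$edge[tree$edge[, 1L] == v, 2L])
  Pedge <- lapply(seq_len(nrow(tree$edge)), function(e)
    branch_transition(model, space, ages[tree$edge[e, 1L]],
                      ages[tree$edge[e, 2L]]))
  edge_of <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2L])
  grid <- expand.grid(lapply(opts, function(o) seq_len(nrow(o))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    p <- 1
    rng <- integer(ntip + tree$Nnode)
    top <- integer(ntip + tree$Nnode)
    for (j in seq_along(internal)) {
      o <- opts[[j]][grid[g, j], ]
      rng[internal[j]] <- o["range"]
      p <- p * o["w"]
      top[kids[[j]][1L]] <- o["s1"]
      top[kids[[j]][2L]] <- o["s2"]
    }
    rng[seq_len(ntip)] <- tipidx
    for (v in seq_len(ntip + tree$Nnode)) {
      e <- edge_of[v]
      p <- p * if (is.na(e)) pr[rng[v]] else Pedge[[e]][top[v], rng[v]]
      if (p == 0) break
    }
    tot <- tot + p
  }
  log(unname(tot))
}

## enumerate all compositions of N into k positive parts; tail P(part1 >= r)
brute_rc_tail <- function(r, k, N) {
  comps <- function(N, k) {
    if (k == 1L) return(matrix(N, 1L, 1L))
    do.call(rbind, lapply(seq_len(N - k + 1L), function(f)
      cbind(f, comps(N - f, k - 1L))))
  }
  cc <- comps(N, k)
  mean(cc[, 1L] >= r)
}

## forward two-rate pure-birth simulation: rate lam1 until the switch time,
## lam2 afterwards, stopped at the n-th birth; returns branching times object
## and the true shift age
sim_yule2 <- function(n, lam1, lam2, t_switch) {
  repeat {
    t <- 0; k <- 2L
    births <- numeric(0)
    repeat {
      rate <- if (t < t_switch) lam1 else lam2
      dt <- stats::rexp(1L, k * rate)
      if (t < t_switch && t + dt > t_switch) { t <- t_switch; next }
      t <- t + dt
      births <- c(births, t)
      k <- k + 1L
      if (k == n) break
    }
    if (any(births < t_switch) && any(births > t_switch)) break
  }
  height <- t + stats::rexp(1L, n * lam2)   # memoryless observation time
  list(bt = as_branching_times(height - c(0, births)),
       shift_age = height - t_switch, crown = height)
}
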