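# Seeded generators for every input the pipeline consumes, with ground truth.
#
# All draws flow through R's RNG; pass `seed` (or call set.seed() yourself) for
# byte-identical outputs. No generator touches global options.

## ---- internal fast pure-birth machinery -----------------------------------
##
## A constant-rates tree conditioned on n extant tips: independent internode
## intervals g_k ~ Exp(k * lambda) for k = 2..n (the memoryless "observed now"
## conditioning under which the gamma statistic is exactly standard normal),
## topology by uniform random lineage splitting.

yule_raw <- function(n, lambda = 1) {
  g <- stats::rexp(n - 1L, rate = lambda * (2:n))
  ages <- rev(cumsum(rev(g)))              # age of k-th branching event, k=2..n
  act_par <- c(n + 1L, n + 1L)             # active lineages: parent node ids
  node_age <- numeric(2L * n - 1L)
  node_age[n + 1L] <- ages[1L]
  e_par <- integer(2L * n - 2L)
  e_chi <- integer(2L * n - 2L)
  m <- 0L
  if (n > 2L) for (k in 2:(n - 1L)) {
    i <- sample.int(length(act_par), 1L)
    nid <- n + k
    node_age[nid] <- ages[k]
    m <- m + 1L
    e_par[m] <- act_par[i]; e_chi[m] <- nid
    act_par <- c(act_par[-i], nid, nid)
  }
  tip <- 0L
  for (p in act_par) {
    m <- m + 1L; tip <- tip + 1L
    e_par[m] <- p; e_chi[m] <- tip
  }
  list(e_par = e_par, e_chi = e_chi, node_age = node_age, n = n)
}

## branching times of the subtree induced by a tip subset, without building
## a phylo object: a node is retained iff both children hold sampled tips
yule_induced_bt <- function(raw, keep_tips) {
  n <- raw$n
  cnt <- integer(2L * n - 1L)
  cnt[keep_tips] <- 1L
  nd <- integer(2L * n - 1L)
  ord <- order(raw$node_age[raw$e_chi])    # tips (age 0) first, then young->old
  for (e in ord) {
    ch <- raw$e_chi[e]; pa <- raw$e_par[e]
    if (cnt[ch] > 0L) nd[pa] <- nd[pa] + 1L
    cnt[pa] <- cnt[pa] + cnt[ch]
  }
  sort(raw$node_age[nd == 2L], decreasing = TRUE)
}

raw_to_phylo <- function(raw, tip_prefix = "t") {
  n <- raw$n
  el <- raw$node_age[raw$e_par] - raw$node_age[raw$e_chi]
  tr <- structure(list(edge = cbind(raw$e_par, raw$e_chi),
                       edge.length = el,
                       tip.label = paste0(tip_prefix, seq_len(n)),
                       Nnode = n - 1L),
                  class = "phylo")
  stats::reorder(tr, "cladewise")
}

#' Simulate a pure-birth (Yule) chronogram
#'
#' Constant-rate tree conditioned on `n` extant tips: internode intervals are
#' independent exponentials with rate `k * lambda` while `k` lineages exist,
#' and each branching splits a uniformly chosen lineage. Under this null the
#' gamma statistic is standard normal.
#'
#' @param n Number of tips (>= 2).
#' @param lambda Speciation rate (> 0).
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` with `n` tips.
#' @export
sim_yule <- function(n, lambda = 1, seed = NULL) {
  stopifnot(n >= 2, lambda > 0)
  if (!is.null(seed)) set.seed(seed)
  raw_to_phylo(yule_raw(as.integer(n), lambda))
}

#' Simulate a birth-death chronogram conditioned on n extant tips
#'
#' Forward Gillespie simulation from two crown lineages, stopped when the
#' extant count first reaches `n`; runs going extinct are retried (cap
#' `max_tries`). Extinct lineages are pruned, so the returned reconstructed
#' tree is ultrametric with exactly `n` tips.
#'
#' @param n Number of extant tips (>= 2).
#' @param lambda Speciation rate (> 0).
#' @param mu Extinction rate, `0 <= mu < lambda`.
#' @param seed Optional integer seed.
#' @param max_tries Retry cap for runs that go extinct.
#' @return An ultrametric `phylo` with `n` tips.
#' @export
sim_bd <- function(n, lambda = 1, mu = 0, seed = NULL, max_tries = 10000L) {
  stopifnot(n >= 2, lambda > 0, mu >= 0, mu < lambda)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (mu == 0) return(raw_to_phylo(yule_raw(n, lambda)))
  for (try in seq_len(max_tries)) {
    res <- bd_forward_once(n, lambda, mu)
    if (!is.null(res)) return(res)
  }
  stop("birth-death simulation failed to reach ", n,
       " extant tips in ", max_tries, " tries")
}

## one forward run; NULL on extinction before reaching n extant lineages
bd_forward_once <- function(n, lambda, mu) {
  max_nodes <- 8L * n + 16L
  parent <- integer(max_nodes); t_birth <- numeric(max_nodes)
  t_death <- rep(NA_real_, max_nodes)
  parent[1:2] <- 0L; t_birth[1:2] <- 0
  alive <- c(1L, 2L); nn <- 2L; t <- 0
  repeat {
    k <- length(alive)
    if (k == 0L) return(NULL)
    if (k == n) break
    t <- t + stats::rexp(1L, rate = k * (lambda + mu))
    i <- alive[sample.int(k, 1L)]
    if (stats::runif(1L) < lambda / (lambda + mu)) {
      if (nn + 2L > max_nodes) return(NULL)   # runaway; treat as retry
      c1 <- nn + 1L; c2 <- nn + 2L; nn <- nn + 2L
      parent[c(c1, c2)] <- i; t_birth[c(c1, c2)] <- t
      t_death[i] <- t
      alive <- c(setdiff(alive, i), c1, c2)
    } else {
      t_death[i] <- t
      alive <- setdiff(alive, i)
    }
  }
  ## build full tree then prune extinct; time axis: ages = t - time
  present <- t
  lab <- character(nn)
  is_tip <- logical(nn)
  for (i in seq_len(nn)) is_tip[i] <- !(i %in% parent[seq_len(nn)])
  ## assemble edges into phylo via newick-free construction
  ids <- seq_len(nn)
  tipids <- ids[is_tip]
  extant <- intersect(tipids, alive)
  if (length(extant) != n) return(NULL)
  ## map: phylo tips 1..ntip, internals ntip+1..; root is a synthetic node
  ## joining lineages 1 and 2 at time 0
  ntip <- length(tipids)
  nodeid <- integer(nn + 1L)                # +1 for synthetic root (index nn+1)
  nodeid[tipids] <- seq_len(ntip)
  internals <- c(nn + 1L, ids[!is_tip])
  nodeid[internals] <- ntip + seq_along(internals)
  e_par <- integer(nn); e_chi <- integer(nn); el <- numeric(nn); m <- 0L
  for (i in ids) {
    pa <- if (parent[i] == 0L) nn + 1L else parent[i]
    m <- m + 1L
    e_par[m] <- nodeid[pa]; e_chi[m] <- nodeid[i]
    t0 <- if (parent[i] == 0L) 0 else t_death[parent[i]]
    t1 <- if (is_tip[i]) (if (i %in% alive) present else t_death[i]) else t_death[i]
    el[m] <- t1 - t0
  }
  tr <- structure(list(edge = cbind(e_par, e_chi), edge.length = el,
                       tip.label = paste0("t", seq_len(ntip)),
                       Nnode = length(internals)),
                  class = "phylo")
  tr <- stats::reorder(tr, "cladewise")
  drop <- tr$tip.label[nodeid[setdiff(tipids, extant)]]
  if (length(drop)) tr <- ape::drop.tip(tr, drop)
  tr$tip.label <- paste0("t", seq_len(ape::Ntip(tr)))
  tr
}

#' Simulate a tree with GMYC structure
#'
#' A Yule species tree of `k_species` tips (rate `lambda_sp`) whose tips are
#' each replaced by an `m_per_species`-sample coalescent cluster. Within-species
#' trees are standard n-coalescents rescaled so the expected cluster root height
#' equals `theta`. The output is ultrametric with `k_species * m_per_species`
#' tips labelled `sp<i>_<j>` and carries the true species map.
#'
#' @param k_species Number of species (>= 2).
#' @param lambda_sp Speciation rate of the species tree.
#' @param m_per_species Samples per species (>= 1).
#' @param theta Expected within-species coalescent depth, in species-tree time
#'   units. Clusters deeper than the available terminal branch are redrawn and,
#'   failing that, truncated; such scenarios are flagged unidentifiable.
#' @param crown_age If given, the species tree is rescaled so its crown age
#'   equals this value before grafting, making `theta` directly comparable
#'   across replicates.
#' @param min_split If positive, the species tree is redrawn until its
#'   youngest split is at least this old (after any `crown_age` rescaling):
#'   a "deep" species tree whose clusters are identifiable whenever
#'   `min_split` comfortably exceeds `theta`.
#' @param seed Optional integer seed.
#' @return List with `tree` (ultrametric `phylo`), `species` (named character
#'   vector: tip -> true species), `k_species`, and `flag_unidentifiable`.
#' @export
sim_gmyc <- function(k_species, lambda_sp = 1, m_per_species = 1, theta = 0.01,
                     crown_age = NULL, min_split = 0, seed = NULL) {
  stopifnot(k_species >= 2, m_per_species >= 1, theta >= 0)
  if (!is.null(seed)) set.seed(seed)
  for (try in 1:1000) {
    sp_tree <- sim_yule(k_species, lambda_sp)
    if (!is.null(crown_age))
      sp_tree$edge.length <- sp_tree$edge.length *
        (crown_age / max(node_ages(sp_tree)))
    ages_int <- node_ages(sp_tree)[(k_species + 1L):(2L * k_species - 1L)]
    if (min_split <= 0 || min(ages_int) >= min_split) break
    if (try == 1000L)
      stop("could not draw a species tree with youngest split >= ", min_split)
  }
  sp_tree$tip.label <- paste0("sp", seq_len(k_species))
  m <- as.integer(m_per_species)
  if (m == 1L) {
    tips <- paste0(sp_tree$tip.label, "_1")
    out <- sp_tree
    out$tip.label <- tips
    sp <- stats::setNames(sp_tree$tip.label, tips)
    return(list(tree = out, species = sp, k_species = k_species,
                flag_unidentifiable = FALSE))
  }
  term <- match(seq_len(k_species), sp_tree$edge[, 2L])
  term_len <- sp_tree$edge.length[term]           # = parent node age (tips at 0)
  flag <- theta >= min(term_len)
  ## graft clusters by newick splicing: replace "spI:len" with "(cluster):len-h"
  nwk <- ape::write.tree(sp_tree, digits = 12)
  for (i in seq_len(k_species)) {
    lab <- paste0("sp", i)
    sub <- NULL
    for (try in 1:100) {
      cand <- coalescent_cluster(m, theta)
      if (max(node_ages(cand)) < term_len[i]) { sub <- cand; break }
    }
    if (is.null(sub)) {                           # truncate below the parent node
      sub <- cand
      sub$edge.length <- sub$edge.length *
        (0.95 * term_len[i] / max(node_ages(cand)))
      flag <- TRUE
    }
    sub$tip.label <- paste0(lab, "_", seq_len(m))
    h <- max(node_ages(sub))
    sub_nwk <- ape::write.tree(sub, digits = 12)
    sub_nwk <- sub(";\\s*$", "", sub_nwk)
    nwk <- sub(paste0(lab, ":[0-9.eE+-]+"),
               paste0(sub_nwk, ":", format(term_len[i] - h, digits = 12)),
               nwk, fixed = FALSE)
  }
  tree <- ape::read.tree(text = nwk)
  tips <- tree$tip.label
  sp <- stats::setNames(sub("_[0-9]+$", "", tips), tips)
  list(tree = tree, species = sp, k_species = k_species,
       flag_unidentifiable = flag)
}

coalescent_cluster <- function(m, theta) {
  if (theta <= 0) theta <- 1e-12
  ## waiting times Exp(j(j-1)/theta') give E[TMRCA] = theta' (1 - 1/m);
  ## rescale so E[TMRCA] = theta exactly
  theta_eff <- theta / (1 - 1 / m)
  g <- stats::rexp(m - 1L, rate = (m:2) * ((m:2) - 1L) / theta_eff)
  ## build a random-join coalescent topology with these event times
  ages_internal <- cumsum(g)               # from tips toward root
  act <- as.list(seq_len(m))
  act_age <- numeric(m)
  node_age <- numeric(2L * m - 1L)
  e_par <- integer(2L * m - 2L); e_chi <- integer(2L * m - 2L); cnt <- 0L
  nid <- m + 1L
  ## assign internal ids so the first coalescence gets the largest id? ape wants
  ## root = m+1; do a two-pass: record joins, then relabel
  joins <- vector("list", m - 1L)
  act_id <- seq_len(m)
  for (j in seq_len(m - 1L)) {
    pick <- sample.int(length(act_id), 2L)
    joins[[j]] <- act_id[pick]
    new_id <- m + j                        # provisional; root ends with id 2m-1
    node_age[new_id] <- ages_internal[j]
    act_id <- c(act_id[-pick], new_id)
  }
  ## relabel internals so root (last join, id 2m-1) becomes m+1, preserving ages
  prov <- (m + 1L):(2L * m - 1L)
  newlab <- integer(2L * m - 1L)
  newlab[seq_len(m)] <- seq_len(m)
  newlab[prov] <- m + rev(seq_len(m - 1L)) # last join -> m+1 (root)
  for (j in seq_len(m - 1L)) {
    pa <- newlab[m + j]
    for (ch in joins[[j]]) {
      cnt <- cnt + 1L
      e_par[cnt] <- pa; e_chi[cnt] <- newlab[ch]
    }
  }
  age2 <- numeric(2L * m - 1L)
  age2[newlab[prov]] <- node_age[prov]
  el <- age2[e_par] - age2[e_chi]
  tr <- structure(list(edge = cbind(e_par, e_chi), edge.length = el,
                       tip.label = paste0("x", seq_len(m)), Nnode = m - 1L),
                  class = "phylo")
  stats::reorder(tr, "cladewise")
}

#' Simulate DEC range evolution along a chronogram
#'
#' Forward Gillespie simulation of the per-slice anagenetic rate matrices along
#' every branch, with cladogenetic ranges drawn uniformly from the permitted
#' DEC scenarios at every node. Whole-tree runs in which any lineage hits the
#' null (extinct) range are rejected and redrawn so all tips are observable;
#' the rejection count is reported.
#'
#' @param tree A binary chronogram.
#' @param model A `dec_model`.
#' @param space A `dec_space`.
#' @param root_range Range label or mask for the root state (must be permitted).
#' @param seed Optional integer seed.
#' @param max_reject Abort after this many rejected runs (near-certain
#'   extinction under the requested rates).
#' @return List with `tip_ranges` (named character labels), `node_ranges`
#'   (labels for internal nodes, named by node id), `rejections`.
#' @export
sim_dec_ranges <- function(tree, model, space, root_range, seed = NULL,
                           max_reject = 500L) {
  assert_binary(tree, "sim_dec_ranges")
  if (!is.null(seed)) set.seed(seed)
  mask <- if (is.character(root_range))
    label_to_mask(root_range, space$areas) else as.integer(root_range)
  iroot <- match(mask, space$masks)
  if (is.na(iroot) || mask == 0L) stop("root range not permitted in the space")
  qs <- lapply(seq_len(model$n_slices), function(s) build_q(space, model, s))
  scen <- dec_scenarios(space)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  cw <- stats::reorder(tree, "cladewise")
  nullmask <- match(0L, space$masks)
  evolve <- function(i, t_hi, t_lo) {
    t <- t_hi
    while (t > t_lo + 1e-12) {
      lower_bounds <- model$boundaries[model$boundaries < t]
      seg_lo <- max(c(t_lo, lower_bounds))
      row <- qs[[slice_of(model, (t + seg_lo) / 2)]][i, ]
      total <- -row[i]
      if (total <= 0) { t <- seg_lo; next }
      dt <- stats::rexp(1L, rate = total)
      if (t - dt <= seg_lo) { t <- seg_lo; next }
      t <- t - dt
      p <- row; p[i] <- 0
      i <- sample.int(length(p), 1L, prob = p)
      if (!is.na(nullmask) && i == nullmask) return(NA_integer_)
      if (space$masks[i] == 0L) return(NA_integer_)
    }
    i
  }
  for (rej in 0:max_reject) {
    state <- integer(ntip + tree$Nnode)
    state[ntip + 1L] <- iroot
    ok <- TRUE
    ## preorder: at each internal node split, then evolve each daughter branch
    for (v in unique(cw$edge[, 1L])) {
      rows <- scen[[state[v]]]
      pick <- rows[sample.int(nrow(rows), 1L), ]
      kids <- tree$edge[tree$edge[, 1L] == v, 2L]
      for (ci in 1:2) {
        res <- evolve(pick[ci], ages[v], ages[kids[ci]])
        if (is.na(res)) { ok <- FALSE; break }
        state[kids[ci]] <- res
      }
      if (!ok) break
    }
    if (ok) {
      tips <- stats::setNames(space$labels[state[seq_len(ntip)]], tree$tip.label)
      nodes <- stats::setNames(
        space$labels[state[(ntip + 1L):(ntip + tree$Nnode)]],
        (ntip + 1L):(ntip + tree$Nnode))
      return(list(tip_ranges = tips, node_ranges = nodes, rejections = rej))
    }
  }
  stop("simulation rejected ", max_reject, " times: parameters imply ",
       "near-certain range extinction")
}

#' Perturb branch rates of a chronogram
#'
#' Multiplies every branch length by an independent lognormal factor with mean
#' 1 and standard deviation `sigma`, emulating a non-clocklike gene tree.
#'
#' @param tree A `phylo` object.
#' @param sigma Standard deviation of the multiplicative rate factor (>= 0).
#' @param seed Optional integer seed.
#' @return A `phylo` phylogram.
#' @export
perturb_rates <- function(tree, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(tree)
  s2 <- log(1 + sigma^2)
  f <- stats::rlnorm(length(tree$edge.length), meanlog = -s2 / 2, sdlog = sqrt(s2))
  tree$edge.length <- tree$edge.length * f
  tree
}

#' Simulate sequences under Jukes-Cantor
#'
#' Evolves DNA along the tree under the Jukes-Cantor model (branch lengths in
#' expected substitutions per site) via phangorn's sequence simulator.
#'
#' @param tree A `phylo` object.
#' @param length Number of sites (>= 1).
#' @param seed Optional integer seed.
#' @return Named character vector of upper-case sequences keyed by tip label.
#' @export
sim_seqs <- function(tree, length, seed = NULL) {
  stopifnot(length >= 1)
  if (!is.null(seed)) set.seed(seed)
  dat <- phangorn::simSeq(tree, l = as.integer(length), type = "DNA")
  m <- toupper(as.character(dat))
  stats::setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
}
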