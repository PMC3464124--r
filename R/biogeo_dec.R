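# Time-stratified Dispersal-Extinction-Cladogenesis (DEC) range evolution.
#
# Ranges are subsets of a small ordered area list, encoded as bitmasks. Along
# branches ranges evolve by a CTMC (dispersal adds areas at rate
# d * sum_{a in R} m_s[a, b], extinction removes them at rate e per occupied
# area; the empty range is absorbing). At speciation the ancestral range is
# inherited under the DEC cladogenesis rules: single-area ranges are copied;
# wider ranges split by vicariance ({a}, R \ {a}) or subset sympatry ({a}, R),
# ordered scenarios weighted uniformly. Dispersal multipliers are stratified
# into geological time slices.

## ---- state space -----------------------------------------------------------

mask_size <- function(mask) {
  vapply(mask, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:30)) > 0L), integer(1L))
}

mask_to_label <- function(mask, areas) {
  vapply(mask, function(m) {
    if (m == 0L) return("0")
    paste(areas[bitwAnd(m, bitwShiftL(1L, seq_along(areas) - 1L)) > 0L],
          collapse = "")
  }, "")
}

label_to_mask <- function(label, areas) {
  vapply(label, function(l) {
    if (l %in% c("0", "")) return(0L)
    parts <- strsplit(l, "")[[1L]]
    bad <- setdiff(parts, areas)
    if (length(bad)) stop("unknown area(s): ", paste(bad, collapse = ", "))
    sum(bitwShiftL(1L, match(parts, areas) - 1L))
  }, integer(1L), USE.NAMES = FALSE)
}

#' Build the DEC range state space
#'
#' All non-empty subsets of the area list up to `maxareas` areas, minus an
#' optional exclusion list, plus the empty (null) range as the first state.
#' States are ordered deterministically by size, then by bitmask.
#'
#' @param areas Character vector of single-letter area names (ordered).
#' @param maxareas Maximum range size (1 <= maxareas <= length(areas)).
#' @param excluded Optional character vector of range labels (e.g. `"AF"`) to
#'   drop as biologically implausible.
#' @return Object of class `dec_space`: list with `areas`, `masks`, `labels`,
#'   `sizes`, `maxareas`, `n_states`.
#' @export
build_state_space <- function(areas, maxareas = 2L, excluded = NULL) {
  n <- length(areas)
  stopifnot(maxareas >= 1L, maxareas <= n, n <= 16L)
  if (anyDuplicated(areas)) stop("area names must be unique")
  all_masks <- 0:(2^n - 1)
  sz <- mask_size(all_masks)
  keep <- sz <= maxareas
  masks <- all_masks[keep]
  sz <- sz[keep]
  if (!is.null(excluded) && length(excluded)) {
    ex <- label_to_mask(excluded, areas)
    if (any(ex == 0L)) stop("cannot exclude the null range")
    if (any(!(ex %in% masks)))
      stop("excluded range not a valid subset of the state space")
    drop <- masks %in% ex
    masks <- masks[!drop]; sz <- sz[!drop]
  }
  ord <- order(sz, masks)
  masks <- as.integer(masks[ord]); sz <- sz[ord]
  structure(list(areas = areas, masks = masks,
                 labels = mask_to_label(masks, areas), sizes = sz,
                 maxareas = as.integer(maxareas),
                 n_states = length(masks)),
            class = "dec_space")
}

#' @export
print.dec_space <- function(x, ...) {
  cat("DEC state space:", length(x$areas), "areas, maxareas", x$maxareas,
      "->", x$n_states, "states (incl. null range)\n")
  invisible(x)
}

#' Time-stratified dispersal model
#'
#' @param areas Character vector of area names.
#' @param boundaries Strictly decreasing ages (Ma) separating the time slices;
#'   `length(boundaries) + 1` slices; times older than the first boundary fall
#'   in slice 1 (slice 1 also covers anything older than the root).
#' @param matrices List of per-slice square dispersal scaling matrices (values
#'   in `[0, 1]`, rows = source area, cols = sink area), oldest slice first.
#' @param d Global dispersal rate (>= 0).
#' @param e Global per-area extinction rate (>= 0).
#' @return Object of class `dec_model`.
#' @export
dec_model <- function(areas, boundaries, matrices, d = 0.01, e = 0.01) {
  k <- length(areas)
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (length(matrices) != length(boundaries) + 1L)
    stop("need one scaling matrix per time slice (boundaries + 1)")
  if (length(boundaries) && any(diff(boundaries) >= 0))
    stop("slice boundaries must be strictly decreasing ages")
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == k)) stop("scaling matrices must be ", k, "x", k)
    if (any(m < 0 | m > 1)) stop("scaling factors must lie in [0, 1]")
    dimnames(m) <- list(areas, areas)
    m
  })
  if (d < 0 || e < 0) stop("rates must be non-negative")
  structure(list(areas = areas, boundaries = as.numeric(boundaries),
                 matrices = matrices, d = d, e = e,
                 n_slices = length(matrices)),
            class = "dec_model")
}

## slice index for an age; ages at a boundary belong to the younger slice
slice_of <- function(model, age) {
  1L + sum(age <= model$boundaries)
}

#' Anagenetic DEC rate matrix for one time slice
#'
#' @param space A `dec_space`.
#' @param model A `dec_model` over the same areas.
#' @param slice Slice index (1 = oldest).
#' @return Dense rate matrix over the range states (rows sum to zero; the null
#'   range is absorbing).
#' @export
build_q <- function(space, model, slice = 1L) {
  if (slice < 1L || slice > model$n_slices) stop("invalid slice index")
  if (!identical(space$areas, model$areas))
    stop("state space and model use different area sets")
  ms <- model$matrices[[slice]]
  ns <- space$n_states
  k <- length(space$areas)
  Q <- matrix(0, ns, ns, dimnames = list(space$labels, space$labels))
  idx <- stats::setNames(seq_len(ns), as.character(space$masks))
  for (i in seq_len(ns)) {
    R <- space$masks[i]
    if (R == 0L) next                     # null range absorbing
    occupied <- which(bitwAnd(R, bitwShiftL(1L, 0:(k - 1L))) > 0L)
    ## dispersal: add area b
    for (b in setdiff(seq_len(k), occupied)) {
      to <- bitwOr(R, bitwShiftL(1L, b - 1L))
      j <- idx[as.character(to)]
      if (is.na(j)) next                  # beyond maxareas or excluded
      Q[i, j] <- Q[i, j] + model$d * sum(ms[occupied, b])
    }
    ## extinction: remove area a
    for (a in occupied) {
      to <- bitwAnd(R, bitwNot(bitwShiftL(1L, a - 1L)))
      j <- idx[as.character(to)]
      if (is.na(j)) next                  # contraction into an excluded range
      Q[i, j] <- Q[i, j] + model$e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## per-slice Q matrices with cached eigendecompositions, so repeated branch
## exponentials cost two small matrix products each
transition_cache <- function(model, space) {
  slices <- lapply(seq_len(model$n_slices), function(s) {
    Q <- build_q(space, model, s)
    ev <- tryCatch(eigen(Q), error = function(e) NULL)
    usable <- FALSE
    Vi <- NULL
    if (!is.null(ev) && all(is.finite(ev$values))) {
      Vi <- tryCatch(solve(ev$vectors), error = function(e) NULL)
      if (!is.null(Vi)) {
        ## accept the decomposition only if it reconstructs Q accurately
        err <- max(Mod(ev$vectors %*% (ev$values * Vi) - Q))
        usable <- is.finite(err) && err <= 1e-9 * max(1, max(abs(Q)))
      }
    }
    list(Q = Q, ev = ev, Vi = Vi, usable = usable)
  })
  seg_exp <- function(s, dt) {
    sl <- slices[[s]]
    if (dt == 0) return(diag(space$n_states))
    P <- if (sl$usable) {
      Re(sl$ev$vectors %*% (exp(sl$ev$values * dt) * sl$Vi))
    } else pracma::expm(sl$Q * dt)
    P[P < 0] <- 0
    P
  }
  fun <- function(t_parent, t_child) {
    if (t_parent < t_child) stop("t_parent must not be younger than t_child")
    cuts <- model$boundaries[model$boundaries < t_parent &
                               model$boundaries > t_child]
    pts <- c(t_parent, cuts, t_child)
    P <- seg_exp(slice_of(model, (pts[1L] + pts[2L]) / 2), pts[1L] - pts[2L])
    if (length(pts) > 2L) for (s in 2:(length(pts) - 1L)) {
      hi <- pts[s]; lo <- pts[s + 1L]
      P <- P %*% seg_exp(slice_of(model, (hi + lo) / 2), hi - lo)
    }
    dimnames(P) <- list(space$labels, space$labels)
    P
  }
  fun
}

#' Branch transition probabilities under the stratified model
#'
#' Partitions the branch at the slice boundaries it spans and returns the
#' ordered (oldest-first) product of segment matrix exponentials. Time older
#' than the oldest boundary uses slice 1's matrix.
#'
#' @param model A `dec_model`.
#' @param space A `dec_space`.
#' @param t_parent,t_child Ages of the branch ends, `t_parent >= t_child >= 0`.
#' @return Transition probability matrix (rows: state at the older end).
#' @export
branch_transition <- function(model, space, t_parent, t_child) {
  transition_cache(model, space)(t_parent, t_child)
}

## ---- cladogenesis ----------------------------------------------------------

## ordered daughter scenarios for each ancestral range; uniform weights
## per-ancestor; returns list indexed by state: matrix (s1, s2) of state indices
dec_scenarios <- function(space) {
  idx <- stats::setNames(seq_len(space$n_states), as.character(space$masks))
  lapply(seq_len(space$n_states), function(i) {
    R <- space$masks[i]
    if (R == 0L) return(matrix(integer(0), 0L, 2L))
    if (space$sizes[i] == 1L) return(matrix(c(i, i), 1L, 2L))
    bits <- bitwShiftL(1L, 0:30)
    singles <- bits[bitwAnd(R, bits) > 0L]
    out <- NULL
    for (a in singles) {
      rest <- bitwAnd(R, bitwNot(a))
      ia <- idx[as.character(a)]; irest <- idx[as.character(rest)]
      iR <- i
      if (!is.na(irest)) out <- rbind(out, c(ia, irest), c(irest, ia))
      out <- rbind(out, c(ia, iR), c(iR, ia))
    }
    ## drop scenarios whose daughters fall outside the state space, and
    ## deduplicate (two-area vicariance pairs arise twice)
    out <- out[stats::complete.cases(out), , drop = FALSE]
    out <- unique(out)
    dimnames(out) <- NULL
    out
  })
}

## ---- pruning likelihood ----------------------------------------------------

## tip ranges: named integer masks or named character labels
resolve_tip_ranges <- function(tree, tip_ranges, space) {
  if (is.data.frame(tip_ranges)) tip_ranges <- ranges_df_to_masks(tip_ranges, space)
  if (is.character(tip_ranges))
    tip_ranges <- stats::setNames(label_to_mask(tip_ranges, space$areas),
                                  names(tip_ranges))
  miss <- setdiff(tree$tip.label, names(tip_ranges))
  if (length(miss)) stop("no range given for tip(s): ", paste(miss, collapse = ", "))
  m <- tip_ranges[tree$tip.label]
  bad <- !(m %in% space$masks) | m == 0L
  if (any(bad))
    stop("tip range not in state space for: ",
         paste(tree$tip.label[bad], collapse = ", "))
  match(m, space$masks)
}

ranges_df_to_masks <- function(df, space) {
  stopifnot(all(space$areas %in% colnames(df)))
  m <- as.matrix(df[, space$areas]) > 0
  stats::setNames(as.integer(m %*% bitwShiftL(1L, seq_along(space$areas) - 1L)),
                  df[[1L]])
}

## down (pruning) pass; returns per-node scaled conditional likelihoods,
## log scaling factors, and per-child branch transition matrices
dec_down_pass <- function(tree, tip_idx, model, space, tf = NULL, scen = NULL) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  ages <- node_ages(tree)
  if (is.null(tf)) tf <- transition_cache(model, space)
  if (is.null(scen)) scen <- dec_scenarios(space)
  CL <- matrix(0, ntot, space$n_states)
  logscale <- numeric(ntot)
  CL[cbind(seq_len(ntip), tip_idx)] <- 1
  Pm <- vector("list", nrow(tree$edge))    # transition matrix per edge
  D <- matrix(0, ntot, space$n_states)     # branch-top messages per child node
  kids_of <- function(v) tree$edge[tree$edge[, 1L] == v, 2L]
  combine <- function(v) {
    kids <- kids_of(v)
    if (length(kids) != 2L) stop("DEC requires a binary tree")
    d1 <- D[kids[1L], ]; d2 <- D[kids[2L], ]
    cl <- vapply(seq_len(space$n_states), function(i) {
      rows <- scen[[i]]
      if (!nrow(rows)) return(0)
      mean(d1[rows[, 1L]] * d2[rows[, 2L]])
    }, 0)
    sc <- max(cl)
    if (sc <= 0) {
      logscale[v] <<- -Inf
      CL[v, ] <<- 0
    } else {
      CL[v, ] <<- cl / sc
      logscale[v] <<- log(sc) + sum(logscale[kids])
    }
  }
  ## postorder edges: a child's own subtree is complete before its branch
  for (e in ape::postorder(tree)) {
    pa <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    if (ch > ntip) combine(ch)
    Pm[[e]] <- tf(ages[pa], ages[ch])
    D[ch, ] <- as.numeric(Pm[[e]] %*% CL[ch, ])
  }
  combine(ntip + 1L)                       # root
  list(CL = CL, logscale = logscale, D = D, Pm = Pm, ages = ages, scen = scen)
}

root_prior <- function(space, root_range) {
  pr <- numeric(space$n_states)
  if (is.null(root_range)) {
    pr[space$masks != 0L] <- 1 / sum(space$masks != 0L)
  } else {
    mask <- if (is.character(root_range))
      label_to_mask(root_range, space$areas) else as.integer(root_range)
    j <- match(mask, space$masks)
    if (is.na(j) || mask == 0L) stop("root range not in the state space")
    pr[j] <- 1
  }
  pr
}

#' Time-stratified DEC log-likelihood
#'
#' Felsenstein pruning over the range state space with DEC cladogenetic
#' inheritance at internal nodes. The root is either fixed to `root_range` or
#' averaged over permitted ranges under a flat prior.
#'
#' @param tree A binary chronogram.
#' @param tip_ranges Named character vector of range labels (e.g. `c(t1 = "A",
#'   t2 = "AE")`), named integer masks, or a data frame whose first column is
#'   the tip id with one 0/1 column per area.
#' @param model A `dec_model`.
#' @param space A `dec_space`.
#' @param root_range Range label/mask to fix the root to, or `NULL` (free).
#' @return Log-likelihood (scalar).
#' @export
dec_loglik <- function(tree, tip_ranges, model, space, root_range = NULL) {
  assert_binary(tree, "DEC")
  tip_idx <- resolve_tip_ranges(tree, tip_ranges, space)
  dp <- dec_down_pass(tree, tip_idx, model, space)
  root <- ape::Ntip(tree) + 1L
  pr <- root_prior(space, root_range)
  lik <- sum(pr * dp$CL[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + dp$logscale[root]
}

#' Fit the DEC model and reconstruct ancestral ranges
#'
#' Maximizes the likelihood over the global dispersal and extinction rates
#' (bounded derivative-free search on log scale), then scores every candidate
#' (range, daughter-split) reconstruction at every internal node by fixing it
#' and recomputing the global likelihood (via an outside pass), reporting all
#' candidates within `report_delta` log-likelihood units of each node's best.
#'
#' @inheritParams dec_loglik
#' @param d_init,e_init Starting rates.
#' @param bounds Lower/upper bounds for both rates.
#' @param report_delta Log-likelihood window for reported reconstructions
#'   (default 2, the paper-standard significance rule).
#' @return Object of class `dec_fit`: list with `d`, `e`, `lnL`, `nodes`
#'   (data frame of candidate reconstructions), `model`, `space`,
#'   `boundary_warning`.
#' @export
dec_optimize <- function(tree, tip_ranges, model, space, root_range = NULL,
                         d_init = 0.01, e_init = 0.01,
                         bounds = c(1e-9, 10), report_delta = 2) {
  assert_binary(tree, "DEC")
  tip_idx <- resolve_tip_ranges(tree, tip_ranges, space)
  scen <- dec_scenarios(space)
  prior <- root_prior(space, root_range)
  obj <- function(p) {
    m <- model
    m$d <- exp(p[1L]); m$e <- exp(p[2L])
    dp <- dec_down_pass(tree, tip_idx, m, space, scen = scen)
    root <- ape::Ntip(tree) + 1L
    lik <- sum(prior * dp$CL[root, ])
    if (lik <= 0 || !is.finite(dp$logscale[root])) return(1e10)
    -(log(lik) + dp$logscale[root])
  }
  lb <- log(bounds[1L]); ub <- log(bounds[2L])
  o <- stats::nlminb(c(log(d_init), log(e_init)), obj,
                     lower = lb, upper = ub,
                     control = list(rel.tol = 1e-7))
  d_hat <- exp(o$par[1L]); e_hat <- exp(o$par[2L])
  boundary <- any(abs(o$par - lb) < 1e-6) || any(abs(o$par - ub) < 1e-6)
  if (boundary)
    warning("rate estimate at optimization boundary (flat likelihood?)")
  fit_model <- model
  fit_model$d <- d_hat; fit_model$e <- e_hat
  recon <- dec_node_reconstructions(tree, tip_idx, fit_model, space,
                                    root_range, report_delta)
  structure(list(d = d_hat, e = e_hat, lnL = -o$objective,
                 nodes = recon, model = fit_model, space = space,
                 root_range = root_range, boundary_warning = boundary),
            class = "dec_fit")
}

## outside pass: constrained global lnL for every (node, range, scenario)
dec_node_reconstructions <- function(tree, tip_idx, model, space, root_range,
                                     report_delta = 2) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  dp <- dec_down_pass(tree, tip_idx, model, space)
  scen <- dp$scen
  root <- ntip + 1L
  pr <- root_prior(space, root_range)
  ## outside likelihood O[v, R]: data outside v's subtree given v in R
  ## (scaled; log-scales tracked per node)
  O <- matrix(0, ntot, space$n_states)
  Olog <- numeric(ntot)
  O[root, ] <- pr
  total_lnL <- log(sum(pr * dp$CL[root, ])) + dp$logscale[root]
  ## preorder over internal nodes: first appearance as parent in cladewise
  ## edge order guarantees parents before children
  cw <- stats::reorder(tree, "cladewise")
  node_order <- unique(cw$edge[, 1L])
  rows <- list()
  for (v in node_order) {
    eidx <- which(tree$edge[, 1L] == v)
    kids <- tree$edge[eidx, 2L]
    d1 <- dp$D[kids[1L], ]; d2 <- dp$D[kids[2L], ]
    sibling_logscale <- vapply(kids, function(k) dp$logscale[k], 0)
    ## candidate (range, scenario) table at v
    for (i in seq_len(space$n_states)) {
      rws <- scen[[i]]
      if (!nrow(rws) || O[v, i] <= 0) next
      w <- 1 / nrow(rws)
      val <- O[v, i] * w * d1[rws[, 1L]] * d2[rws[, 2L]]
      keep <- val > 0
      if (!any(keep)) next
      lnl <- log(val[keep]) + Olog[v] + sum(sibling_logscale)
      rows[[length(rows) + 1L]] <- data.frame(
        node = v, range = space$labels[i],
        left = space$labels[rws[keep, 1L]],
        right = space$labels[rws[keep, 2L]],
        lnL = lnl)
    }
    ## propagate outside to children
    for (ci in 1:2) {
      ch <- kids[ci]
      sib <- kids[3L - ci]
      ot <- numeric(space$n_states)      # outside at the top of ch's branch
      dsib <- dp$D[sib, ]
      for (i in seq_len(space$n_states)) {
        rws <- scen[[i]]
        if (!nrow(rws) || O[v, i] <= 0) next
        w <- 1 / nrow(rws)
        own <- rws[, ci]; other <- rws[, 3L - ci]
        contrib <- O[v, i] * w * dsib[other]
        for (r in seq_len(nrow(rws)))
          ot[own[r]] <- ot[own[r]] + contrib[r]
      }
      if (ch > ntip) {
        e_ch <- which(tree$edge[, 2L] == ch)
        ob <- as.numeric(t(dp$Pm[[e_ch]]) %*% ot)
        sc <- max(ob)
        if (sc > 0) {
          O[ch, ] <- ob / sc
          Olog[ch] <- log(sc) + Olog[v] + dp$logscale[sib]
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  ## per-node relative support and the 2-lnL reporting rule
  tab <- do.call(rbind, lapply(split(tab, tab$node), function(df) {
    best <- max(df$lnL)
    df$rel_lnL <- best - df$lnL
    df <- df[df$rel_lnL <= report_delta, , drop = FALSE]
    df[order(df$rel_lnL), ]
  }))
  rownames(tab) <- NULL
  attr(tab, "global_lnL") <- total_lnL
  tab
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("DEC fit: d = %.5g, e = %.5g, lnL = %.4f\n", x$d, x$e, x$lnL))
  nb <- x$nodes[x$nodes$rel_lnL == 0, ]
  cat("best ranges at", nrow(nb), "node-scenarios;",
      length(unique(x$nodes$node)), "internal nodes\n")
  invisible(x)
}

## ---- configuration and I/O -------------------------------------------------

#' Read a stratified DEC configuration (YAML or JSON)
#'
#' Expected fields: `areas` (letters), `boundaries` (ages), `matrices` (list
#' of per-slice square matrices, oldest first), optional `d`, `e`,
#' `excluded` (range labels), `maxareas`, `root_range`.
#'
#' @param file Path to the configuration file.
#' @return List with `model` (`dec_model`), `space` (`dec_space`), and
#'   `root_range`.
#' @export
read_dec_config <- function(file) {
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE) else yaml::read_yaml(file)
  areas <- as.character(cfg$areas)
  mats <- lapply(cfg$matrices, function(m) {
    m <- do.call(rbind, lapply(m, as.numeric))
    m
  })
  model <- dec_model(areas, as.numeric(cfg$boundaries), mats,
                     d = cfg$d %||% 0.01, e = cfg$e %||% 0.01)
  space <- build_state_space(areas, cfg$maxareas %||% 2L,
                             excluded = cfg$excluded)
  list(model = model, space = space, root_range = cfg$root_range)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read tip ranges from a TSV (tip id column + one 0/1 column per area)
#'
#' @param file Path to the TSV.
#' @param space A `dec_space` naming the expected area columns.
#' @return Named integer vector of range bitmasks.
#' @export
read_tip_ranges <- function(file, space) {
  df <- utils::read.delim(file, check.names = FALSE)
  ranges_df_to_masks(df, space)
}
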