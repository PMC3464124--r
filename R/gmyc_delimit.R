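# Single-threshold General Mixed Yule Coalescent (GMYC) species delimitation.
#
# A threshold age T splits the branching events of a single-locus ultrametric
# tree into an interspecific (diversification) process older than T and
# per-cluster intraspecific (coalescent) processes younger than T; clusters are
# the branches crossing T. The branching ages form a single point process whose
# intensity within an inter-event interval is the mixture
#   b = lambda1 * n_d^p1 + lambda2 * sum_j [n_j (n_j - 1)]^p2,
# and the likelihood is prod_i b_i exp(-b_i x_i) over intervals (intervals cut
# by the threshold or ending at the present contribute waiting terms only).
# The null model is a single process with rate lambda * [n (n - 1)]^p over the
# whole tree, which the mixture reproduces exactly when T exceeds the crown,
# so the maximized mixed likelihood can never fall below the null.

## branch crossing/cluster bookkeeping at threshold T
## returns: cluster id per tip (0 = none yet), cluster id per internal node
## (nodes younger than T), crossing branch count
gmyc_clusters <- function(tree, T_age) {
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  ntot <- length(ages)
  parent <- integer(ntot)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  if (ages[root] < T_age) {
    heads <- root                        # whole tree is a single cluster
  } else {
    v <- setdiff(seq_len(ntot), root)
    heads <- v[ages[v] < T_age & ages[parent[v]] >= T_age]
  }
  cluster <- integer(ntot)
  cluster[heads] <- seq_along(heads)
  ## push cluster membership down the tree (edges parent-before-child)
  for (e in rev(ape::postorder(tree))) {
    pa <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    if (cluster[ch] == 0L) cluster[ch] <- cluster[pa]
  }
  list(heads = heads, cluster = cluster, ages = ages)
}

#' Inter-event interval table for the GMYC likelihood
#'
#' Classifies every branching event of an ultrametric tree as diversification
#' (older than the threshold) or coalescent (younger, assigned to the cluster
#' of branches crossing the threshold), and tabulates, for every interval
#' between consecutive time points (events plus the threshold itself), its
#' duration, the diversification lineage count, and the per-cluster coalescent
#' lineage counts.
#'
#' @param tree A binary ultrametric `phylo`.
#' @param T_age Threshold age within `[0, crown age]` (values above the crown
#'   are allowed and make the whole tree a single coalescent cluster).
#' @return Object of class `gmyc_intervals`: list with `x` (durations),
#'   `n_div` (diversification lineages per interval), `coal_counts` (interval x
#'   cluster matrix of lineage counts), `events` (data frame: node, age,
#'   interval closed, type "div"/"coal", cluster), `n_entities`, `clusters`
#'   (tip assignment), `cluster_sizes`, `T_age`, `n_tips`, `crown`.
#' @export
interval_table <- function(tree, T_age) {
  assert_binary(tree, "GMYC")
  assert_ultrametric(tree, what = "GMYC")
  ntip <- ape::Ntip(tree)
  cl <- gmyc_clusters(tree, T_age)
  ages <- cl$ages
  crown <- ages[ntip + 1L]
  if (T_age < 0) stop("threshold must be non-negative")
  node_ages_int <- ages[(ntip + 1L):(ntip + tree$Nnode)]
  ev_age <- sort(node_ages_int, decreasing = TRUE)
  ## mesh: crown down to 0, breaking at events and at T
  mesh <- sort(unique(c(ev_age, if (T_age < crown) T_age, 0)),
               decreasing = TRUE)
  mesh <- mesh[mesh <= crown]
  upper <- mesh[-length(mesh)]; lower <- mesh[-1L]
  nint <- length(upper)
  n_heads <- length(cl$heads)
  n_div <- integer(nint)
  coal_counts <- matrix(0L, nint, max(n_heads, 0L))
  ## per node: cluster id (0 = diversification part) and age
  int_nodes <- (ntip + 1L):(ntip + tree$Nnode)
  int_cl <- cl$cluster[int_nodes]
  int_cl[ages[int_nodes] >= T_age] <- 0L    # nodes at/above T are divers. events
  head_sizes <- vapply(seq_len(n_heads), function(j)
    sum(cl$cluster[seq_len(ntip)] == j), integer(1L))
  for (i in seq_len(nint)) {
    u <- upper[i]
    mid <- (u + lower[i]) / 2
    if (mid >= T_age) {
      ## all lineages belong to the diversification process
      n_div[i] <- 1L + sum(node_ages_int >= u)
    } else {
      n_div[i] <- max(1L, n_heads)
      ## cluster j lineage count in this interval: 1 + within-cluster events
      ## at or above the interval's upper bound (below the threshold)
      for (j in seq_len(n_heads)) {
        if (head_sizes[j] <= 1L) next
        coal_counts[i, j] <- 1L + sum(int_cl == j & ages[int_nodes] >= u &
                                        ages[int_nodes] < T_age)
      }
    }
  }
  ## events: every internal node younger than the crown closes the interval
  ## above it; its rate is the mixture intensity during that interval
  ## (simultaneous events share an interval)
  ev_nodes <- int_nodes[node_ages_int < crown]
  events <- data.frame(
    node = ev_nodes,
    age = ages[ev_nodes],
    interval = match(ages[ev_nodes], lower),
    type = ifelse(ages[ev_nodes] >= T_age, "div", "coal"),
    cluster = ifelse(ages[ev_nodes] >= T_age, 0L, cl$cluster[ev_nodes]))
  tips_cluster <- cl$cluster[seq_len(ntip)]
  names(tips_cluster) <- tree$tip.label
  structure(list(x = upper - lower, n_div = n_div, coal_counts = coal_counts,
                 events = events,
                 n_entities = if (T_age >= crown) 1L else
                   if (T_age <= 0) ntip else length(cl$heads),
                 clusters = tips_cluster, cluster_sizes = head_sizes,
                 T_age = T_age, n_tips = ntip, crown = crown),
            class = "gmyc_intervals")
}

#' GMYC mixed log-likelihood
#'
#' @param table A `gmyc_intervals` object.
#' @param params List/vector with `lambda1`, `lambda2`, `p1`, `p2`.
#' @return Log-likelihood (scalar).
#' @export
gmyc_loglik <- function(table, params) {
  params <- as.list(params)
  l1 <- params$lambda1; l2 <- params$lambda2
  p1 <- params$p1; p2 <- params$p2
  if (any(c(l1, l2) <= 0)) stop("rates must be positive")
  C <- table$coal_counts * (table$coal_counts - 1L)
  Cp <- C^p2
  Cp[C == 0L] <- 0                      # 0^0 stays 0: empty process, no rate
  B <- if (ncol(Cp)) rowSums(Cp) else numeric(length(table$x))
  A <- table$n_div^p1
  b <- l1 * A + l2 * B
  lnL <- sum(log(b[table$events$interval])) - sum(b * table$x)
  if (!is.finite(lnL)) -Inf else lnL
}

## maximized mixed lnL at a fixed threshold: bounded quasi-Newton search over
## (log lambda1, log lambda2, p1, p2), multi-start; also used by the scan
gmyc_profile <- function(table, lambda_bounds = c(1e-8, 1e6),
                         p_bounds = c(0, 5)) {
  C <- table$coal_counts * (table$coal_counts - 1L)
  ev_iv <- table$events$interval
  nev <- length(ev_iv)
  has_coal <- ncol(C) > 0 && any(C > 0)
  obj <- function(par) {
    l1 <- exp(par[1L]); l2 <- exp(par[2L])
    A <- table$n_div^par[3L]
    B <- if (has_coal) {
      Cp <- C^par[4L]; Cp[C == 0L] <- 0
      rowSums(Cp)
    } else 0
    b <- l1 * A + l2 * B
    val <- sum(log(b[ev_iv])) - sum(b * table$x)
    if (!is.finite(val)) return(1e12)
    -val
  }
  lo <- c(log(lambda_bounds[1L]), log(lambda_bounds[1L]), p_bounds[1L], p_bounds[1L])
  hi <- c(log(lambda_bounds[2L]), log(lambda_bounds[2L]), p_bounds[2L], p_bounds[2L])
  ## crude scale for starting rates: events per unit of weighted tree length
  l0 <- max(nev, 1L) / max(sum(table$n_div * table$x), 1e-12)
  starts <- list(c(log(l0), log(l0), 1, 1),
                 c(log(l0 / 10), log(l0 * 10), 1, 1),
                 c(log(l0), log(l0 * 100), 0.5, 2))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lo), hi)
    o <- try(stats::optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                          control = list(factr = 1e4, maxit = 500)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || !is.finite(best$value)) return(NULL)
  list(lnL = -best$value,
       params = list(lambda1 = exp(best$par[1L]), lambda2 = exp(best$par[2L]),
                     p1 = best$par[3L], p2 = best$par[4L]))
}

## null model: single process, rate lambda * [n(n-1)]^p across the whole tree;
## closed-form lambda given p (n-2 events, counts 2..n-1; crown conditioned on,
## last interval open)
gmyc_null_fit <- function(tree, p_bounds = c(0, 5)) {
  bt <- branching_times(tree)
  n <- bt$n_tips
  g <- bt$ages - c(bt$ages[-1L], 0)
  cnt <- 2:n                              # lineages during each interval
  ev_cnt <- cnt[seq_len(n - 2L)]
  obj <- function(p) {
    w <- (cnt * (cnt - 1L))^p
    S <- sum(w * g)
    if (S <= 0) return(Inf)
    k <- n - 2L
    -(k * (log(k / S) - 1) + p * sum(log(ev_cnt * (ev_cnt - 1L))))
  }
  o <- stats::optimize(obj, interval = p_bounds)
  p <- o$minimum
  S <- sum(((cnt * (cnt - 1L))^p) * g)
  list(lnL = -o$objective, params = list(lambda1 = (n - 2L) / S, p1 = p))
}

#' Fit the single-threshold GMYC model
#'
#' Scans candidate thresholds (midpoints between consecutive distinct node
#' ages plus the two boundary cases: everything-diversification at T = 0 and
#' everything-coalescent above the crown), profiles the scaling exponents with
#' closed-form rate estimates at each threshold, and compares the best mixed
#' model against the single-process null by a likelihood ratio test with 3
#' degrees of freedom. Among equal-likelihood thresholds the one delimiting
#' the fewest entities is preferred (conservative splitting).
#'
#' @param tree A binary ultrametric `phylo` with >= 4 tips.
#' @param conf_delta Log-likelihood drop defining the threshold confidence set
#'   (default 2).
#' @return Object of class `gmyc_fit`: list with `threshold`, `params`,
#'   `logL_gmyc`, `logL_null`, `null_params`, `LR` (2 delta L), `df`, `p`,
#'   `n_entities`, `clusters` (data frame tip/cluster/type), `confidence`
#'   (scanned thresholds within `conf_delta`, with entity counts), and `scan`
#'   (all thresholds with profile log-likelihoods).
#' @export
gmyc_fit <- function(tree, conf_delta = 2, lambda_bounds = c(1e-8, 1e6),
                     p_bounds = c(0, 5)) {
  assert_binary(tree, "GMYC")
  assert_ultrametric(tree, what = "GMYC")
  ntip <- ape::Ntip(tree)
  if (ntip < 4L) stop("GMYC needs at least 4 tips")
  ages <- sort(unique(node_ages(tree)[(ntip + 1L):(2L * ntip - 1L)]),
               decreasing = TRUE)
  crown <- ages[1L]
  cand <- c(crown * 1.01,                          # single cluster (null-like)
            (ages[-length(ages)] + ages[-1L]) / 2, # midpoints
            min(ages) / 2,                         # below youngest node
            0)                                     # every tip its own entity
  scan <- data.frame(T_age = cand, lnL = NA_real_, entities = NA_integer_)
  fits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    tab <- interval_table(tree, cand[i])
    pr <- gmyc_profile(tab, lambda_bounds, p_bounds)
    if (is.null(pr)) {
      warning("optimizer failed at threshold ", format(cand[i]), "; skipped")
      next
    }
    fits[[i]] <- c(pr, list(table = tab))
    scan$lnL[i] <- pr$lnL
    scan$entities[i] <- tab$n_entities
  }
  ok <- !is.na(scan$lnL)
  if (!any(ok)) stop("GMYC optimization failed at every threshold")
  best_lnL <- max(scan$lnL[ok])
  ## ties: fewest entities (conservative splitting)
  tied <- which(ok & scan$lnL >= best_lnL - 1e-9)
  ibest <- tied[which.min(scan$entities[tied])]
  best <- fits[[ibest]]
  null <- gmyc_null_fit(tree, p_bounds)
  lr <- 2 * (best$lnL - null$lnL)
  conf <- scan[ok & scan$lnL >= best_lnL - conf_delta, ]
  tab <- best$table
  cl_sizes <- tab$cluster_sizes
  clusters <- data.frame(
    tip = names(tab$clusters),
    cluster = unname(tab$clusters),
    type = ifelse(cl_sizes[pmax(tab$clusters, 1L)] > 1L, "cluster", "singleton"),
    stringsAsFactors = FALSE)
  if (tab$T_age <= 0) {                    # boundary: every tip a singleton
    clusters$cluster <- seq_len(ntip)
    clusters$type <- "singleton"
  }
  structure(list(threshold = scan$T_age[ibest],
                 params = best$params,
                 logL_gmyc = best$lnL, logL_null = null$lnL,
                 null_params = null$params,
                 LR = lr, df = 3L,
                 p = stats::pchisq(lr, df = 3, lower.tail = FALSE),
                 n_entities = scan$entities[ibest],
                 clusters = clusters,
                 confidence = list(thresholds = conf$T_age,
                                   entity_range = range(conf$entities),
                                   delta = conf_delta),
                 scan = scan[ok, ]),
            class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(sprintf(paste0("GMYC single-threshold fit\n",
                     "  threshold age = %.4g; entities = %d\n",
                     "  logL = %.4f vs null %.4f; 2dL = %.3f (d.f. = %d), p = %.4g\n",
                     "  confidence set (within %.1f logL): %d-%d entities\n"),
              x$threshold, x$n_entities, x$logL_gmyc, x$logL_null, x$LR, x$df,
              x$p, x$confidence$delta,
              x$confidence$entity_range[1L], x$confidence$entity_range[2L]))
  invisible(x)
}

## ---- consensus reduction ---------------------------------------------------

iupac_code <- c(A = "A", C = "C", G = "G", T = "T",
                AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Collapse clustered sequences to IUPAC consensus sequences
#'
#' One consensus per cluster: per alignment column, the unanimous base
#' (gaps and Ns ignored), otherwise the IUPAC ambiguity code of the observed
#' bases; columns with no called base at all become gaps.
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (or a named list of single strings).
#' @param clusters Named vector/map tip -> cluster id, or the `clusters` data
#'   frame of a [gmyc_fit()].
#' @return Named character vector, one consensus sequence per cluster
#'   (names `cluster_<id>` or the single member's name for singletons).
#' @export
consensus_reduce <- function(alignment, clusters) {
  if (is.data.frame(clusters))
    clusters <- stats::setNames(clusters$cluster, clusters$tip)
  alignment <- vapply(alignment, toupper, "")
  missing <- setdiff(names(clusters), names(alignment))
  if (length(missing))
    stop("tips missing from alignment: ", paste(missing, collapse = ", "))
  lens <- nchar(alignment[names(clusters)])
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must all have equal length")
  out <- character(0)
  for (cl in unique(clusters)) {
    members <- names(clusters)[clusters == cl]
    mat <- do.call(rbind, strsplit(alignment[members], ""))
    cons <- apply(mat, 2L, function(col) {
      obs <- sort(unique(col[col %in% c("A", "C", "G", "T")]))
      if (length(obs) == 0L) return("-")
      code <- iupac_code[[paste(obs, collapse = "")]]
      code
    })
    nm <- if (length(members) == 1L) members else paste0("cluster_", cl)
    out[nm] <- paste(cons, collapse = "")
  }
  out
}

#' Read / write a FASTA alignment as named character vector
#'
#' @param file Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(file) {
  d <- ape::read.FASTA(file)
  m <- toupper(vapply(as.character(d), paste0, "", collapse = ""))
  stats::setNames(m, names(d))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  invisible(file)
}
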