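# Mean-path-length (MPL) dating: turn a non-clocklike phylogram into a
# relative-time chronogram, plus the classical MPL molecular-clock test.

## per-node mean path length to descendant tips, with tip counts; postorder
mpl_node_stats <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  ## raw accumulators: sum of node-to-tip paths, and the Poisson variance of
  ## that sum (each branch contributes (tips below)^2 * length)
  pathsum <- numeric(ntot)
  varsum <- numeric(ntot)
  ntips_below <- integer(ntot)
  ntips_below[seq_len(ntip)] <- 1L
  for (e in ape::postorder(tree)) {         # children edges first
    pa <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    b <- tree$edge.length[e]
    w <- ntips_below[ch]
    pathsum[pa] <- pathsum[pa] + pathsum[ch] + w * b
    varsum[pa] <- varsum[pa] + varsum[ch] + w^2 * b
    ntips_below[pa] <- ntips_below[pa] + w
  }
  n <- pmax(ntips_below, 1L)
  list(mpl = pathsum / n, var = varsum / n^2, ntips_below = ntips_below)
}

#' Ultrametricize a phylogram by mean path lengths
#'
#' Each internal node is assigned the mean over its descendant tips of the
#' node-to-tip path length (its MPL). Rate heterogeneity can make a child's MPL
#' exceed its parent's; such conflicts are repaired tips-to-root by raising the
#' parent to `child + delta`, the minimal monotone adjustment. Ages are finally
#' rescaled so the root equals `root_age` (relative time; default 1, the
#' convention used when a chronogram feeds GMYC delimitation).
#'
#' @param tree A rooted `phylo` phylogram with positive height.
#' @param root_age Positive number the root age is rescaled to.
#' @param delta Minimal parent-child age separation used in monotone repair.
#' @return An object of class `mpl_result`: list with `chronogram` (ultrametric
#'   `phylo`), `ages` (per internal node, in the node numbering of the input),
#'   `raw_mpl`, and `root_age`.
#' @export
mpl_ultrametricize <- function(tree, root_age = 1, delta = 1e-9) {
  validate_tree(tree)
  stopifnot(root_age > 0)
  ntip <- ape::Ntip(tree)
  if (sum(tree$edge.length) <= 0) stop("tree height is zero")
  st <- mpl_node_stats(tree)
  age <- st$mpl
  age[seq_len(ntip)] <- 0
  ## monotone repair: visit edges children-before-parents
  for (e in ape::postorder(tree)) {
    pa <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    if (ch > ntip && age[pa] < age[ch] + delta)
      age[pa] <- age[ch] + delta
  }
  root <- ntip + 1L
  if (age[root] <= 0) stop("tree height is zero")
  age <- age * (root_age / age[root])
  chrono <- tree
  chrono$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  structure(list(chronogram = chrono,
                 ages = age[(ntip + 1L):(ntip + tree$Nnode)],
                 raw_mpl = st$mpl[(ntip + 1L):(ntip + tree$Nnode)],
                 root_age = root_age),
            class = "mpl_result")
}

#' @export
print.mpl_result <- function(x, ...) {
  cat("MPL ultrametricization:", ape::Ntip(x$chronogram), "tips, root age",
      format(x$root_age), "\n")
  invisible(x)
}

#' Per-node molecular clock test
#'
#' The classical mean-path-length clock test: at each internal node the MPLs of
#' the two child subtrees (measured from the node) are compared with a
#' z-statistic whose variance follows from treating each branch's substitution
#' count as Poisson (variance equal to the expectation), propagated through the
#' MPL recursion. Branch lengths are interpreted as counts when `sites = 1`;
#' give the alignment length in `sites` when branch lengths are in
#' substitutions per site. Two-tailed p-values per node; the tree-wide clock is
#' rejected when any node survives Bonferroni correction at `alpha`.
#'
#' @param tree A binary rooted `phylo` phylogram.
#' @param alpha Tree-wide significance level (Bonferroni over tested nodes).
#' @param sites Number of alignment sites behind the branch lengths (default 1:
#'   lengths are substitution counts).
#' @return An object of class `clock_test`: data frame of per-node results
#'   (`node`, `z`, `p`) with attributes `rejected` (logical) and `alpha`.
#' @export
clock_test <- function(tree, alpha = 0.05, sites = 1) {
  validate_tree(tree)
  assert_binary(tree, "clock_test")
  stopifnot(sites > 0)
  ntip <- ape::Ntip(tree)
  st <- mpl_node_stats(tree)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  z <- p <- rep(NA_real_, length(nodes))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    kid_edges <- which(tree$edge[, 1L] == v)
    ch <- tree$edge[kid_edges, 2L]
    b <- tree$edge.length[kid_edges]
    m <- st$mpl[ch] + b
    s2 <- st$var[ch] + b
    if (sum(s2) <= 0) next
    z[i] <- sqrt(sites) * (m[1L] - m[2L]) / sqrt(sum(s2))
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  tested <- sum(!is.na(p))
  rejected <- tested > 0 && any(p < alpha / tested, na.rm = TRUE)
  structure(data.frame(node = nodes, z = z, p = p),
            class = c("clock_test", "data.frame"),
            rejected = rejected, alpha = alpha, n_tested = tested)
}
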