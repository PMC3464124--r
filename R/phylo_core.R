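# Tree data model and utilities shared by every stage.
#
# Trees are ape "phylo" objects throughout. Ages are measured backward from the
# present: tips sit at age 0 and the crown node carries the largest age.

#' Parse a newick or NEXUS tree
#'
#' Reads a single rooted tree from a newick string or a NEXUS `TREES` block
#' (translate tables supported, read-only). Bracketed metadata comments such as
#' BEAST's `[&height_median=...]` annotations are stripped before parsing, so a
#' maximum-clade-credibility tree and its comment-free newick yield identical
#' topology and branch lengths.
#'
#' @param text Character scalar: newick/NEXUS content, or the path of a file
#'   holding it.
#' @return A rooted `phylo` object with branch lengths.
#' @export
parse_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[(;]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  stripped <- strip_tree_comments(text)
  tr <- if (grepl("^\\s*#NEXUS", stripped, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(stripped, tf)
    out <- ape::read.nexus(tf)
    if (inherits(out, "multiPhylo")) out[[1L]] else out
  } else {
    check_newick_balance(stripped)
    ape::read.tree(text = stripped)
  }
  if (is.null(tr)) stop("could not parse tree text")
  validate_tree(tr)
  tr
}

## drop "[...]" comments; brackets never nest in newick metadata but guard anyway
strip_tree_comments <- function(text) {
  gsub("\\[[^]]*\\]", "", text)
}

check_newick_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed newick: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' at end of string")
  invisible(TRUE)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tr$tip.label))
    stop("tip labels are not unique: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("validation error: negative branch length(s), smallest = ",
         format(min(tr$edge.length)))
  invisible(tr)
}

#' Write a tree as newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to `file`.
#' @export
write_tree <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

## node ages from root-to-node path lengths; works for any rooted tree
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Test ultrametricity within a relative tolerance
#'
#' A tree is accepted as ultrametric when all root-to-tip path lengths agree
#' within `tol` times the tree height (MCC trees carry rounding noise).
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance, default `1e-6`.
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depth)
  if (h <= 0) return(FALSE)
  (h - min(depth)) <= tol * h
}

assert_ultrametric <- function(tree, tol = 1e-6, what = "analysis") {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depth)
  if (h <= 0) stop("tree has zero height")
  if ((h - min(depth)) > tol * h) {
    worst <- c(which.max(depth), which.min(depth))
    stop(what, " requires an ultrametric tree; worst offending tip pair: ",
         tree$tip.label[worst[1L]], " (depth ", format(depth[worst[1L]]), ") vs ",
         tree$tip.label[worst[2L]], " (depth ", format(depth[worst[2L]]), ")")
  }
  invisible(tree)
}

assert_binary <- function(tree, what = "analysis") {
  if (!ape::is.binary.phylo(tree))
    stop(what, " requires a fully bifurcating tree; this tree has polytomies")
  invisible(tree)
}

#' Snap a nearly ultrametric tree onto an exact ultrametric grid
#'
#' Adjusts terminal branch lengths so every tip sits exactly at age 0. Refuses
#' trees whose relative deviation exceeds `max_dev`: larger departures signal a
#' genuinely non-clocklike tree that should go through [mpl_ultrametricize()].
#'
#' @param tree A `phylo` object.
#' @param max_dev Maximum relative root-to-tip deviation allowed (default 1e-3).
#' @return The adjusted `phylo`.
#' @export
snap_ultrametric <- function(tree, max_dev = 1e-3) {
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  h <- max(depth)
  if ((h - min(depth)) > max_dev * h)
    stop("tree deviates from ultrametric by more than ", max_dev,
         " relative to height; refusing to snap")
  term <- match(seq_len(ntip), tree$edge[, 2L])
  tree$edge.length[term] <- tree$edge.length[term] + (h - depth)
  tree
}

#' Branching times of a chronogram
#'
#' Internal node ages (time before present), sorted descending so the first
#' element is the crown age.
#'
#' @param tree A binary ultrametric `phylo` with at least 3 tips.
#' @param tol Relative ultrametricity tolerance.
#' @return An object of class `branching_times`: list with `ages` (length
#'   `n_tips - 1`, strictly positive, descending) and `n_tips`.
#' @export
branching_times <- function(tree, tol = 1e-6) {
  assert_binary(tree, "branching_times")
  if (ape::Ntip(tree) < 3L) stop("need at least 3 tips")
  assert_ultrametric(tree, tol, "branching_times")
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)[(ntip + 1L):(2L * ntip - 1L)]
  new_branching_times(sort(ages, decreasing = TRUE), ntip)
}

new_branching_times <- function(ages, n_tips) {
  structure(list(ages = as.numeric(ages), n_tips = as.integer(n_tips)),
            class = "branching_times")
}

#' Coerce to branching times
#'
#' Accepts a `branching_times` object, a chronogram, or a bare numeric vector
#' of internal node ages (assumed to come from a binary tree with
#' `length(x) + 1` tips).
#'
#' @param x Input to coerce.
#' @return A `branching_times` object.
#' @export
as_branching_times <- function(x) {
  if (inherits(x, "branching_times")) return(x)
  if (inherits(x, "phylo")) return(branching_times(x))
  if (is.numeric(x)) {
    ages <- sort(as.numeric(x), decreasing = TRUE)
    if (any(ages <= 0)) stop("branching times must be strictly positive ages")
    return(new_branching_times(ages, length(ages) + 1L))
  }
  stop("cannot coerce ", class(x)[1L], " to branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat("Branching times:", x$n_tips, "tips, crown age",
      format(x$ages[1L]), "\n")
  invisible(x)
}

#' Prune tips from a tree
#'
#' Removes the named tips, suppressing any resulting degree-2 nodes so path
#' lengths among the retained tips are conserved. Pruning a chronogram yields a
#' chronogram.
#'
#' @param tree A `phylo` object.
#' @param drop Character vector of tip labels to remove (may be empty).
#' @return The pruned `phylo`.
#' @export
prune_tips <- function(tree, drop) {
  drop <- as.character(drop)
  if (length(drop) == 0L) return(tree)
  unknown <- setdiff(drop, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (ape::Ntip(tree) - length(unique(drop)) < 2L)
    stop("pruning would leave fewer than 2 tips")
  ape::drop.tip(tree, unique(drop))
}

#' Lineages-through-time curve
#'
#' Step function of reconstructed lineage count against age. Counts start at 2
#' at the crown and increase by exactly one per branching event, reaching the
#' tip count at age 0.
#'
#' @param bt A `branching_times` object (or anything [as_branching_times()]
#'   accepts).
#' @return An object of class `ltt_curve`: data frame with columns `age`
#'   (descending, final row at 0) and `lineages`.
#' @export
ltt_curve <- function(bt) {
  bt <- as_branching_times(bt)
  n <- bt$n_tips
  out <- data.frame(age = c(bt$ages, 0), lineages = c(2:n, n))
  class(out) <- c("ltt_curve", "data.frame")
  out
}

#' @export
plot.ltt_curve <- function(x, log_lineages = TRUE, xlab = "age before present",
                           ylab = "lineages", ...) {
  graphics::plot(x$age, x$lineages, type = "s", xlim = rev(range(x$age)),
                 log = if (log_lineages) "y" else "", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Export branching times or an LTT curve as TSV
#'
#' @param x A `branching_times` or `ltt_curve` object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_tsv_report <- function(x, file) {
  df <- if (inherits(x, "branching_times")) {
    data.frame(event = seq_along(x$ages), age = x$ages)
  } else if (is.data.frame(x)) {
    as.data.frame(x)
  } else stop("unsupported object for TSV export")
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
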