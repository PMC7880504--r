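# Rooted binary time trees.
#
# Nodes are indexed 1..2N-1: tips are 1..N (in input order), internal nodes
# N+1..2N-1.  Heights are in time units with the youngest tip at 0 and the
# root maximal; every edge satisfies t_child < t_parent strictly.

#' Construct a time tree from component vectors
#'
#' @param parent integer vector, length 2N-1; `NA` for the root.
#' @param height numeric node heights (time units, root maximal).
#' @param tip.label character vector of the N taxon labels (nodes 1..N).
#' @param validate check structural invariants.
#' @return an object of class `timetree` with fields `N`, `nnode`, `parent`,
#'   `child` (2 x nnode matrix, `NA` for tips), `height`, `tip.label`, `root`,
#'   `postorder`.
#' @export
timetree <- function(parent, height, tip.label, validate = TRUE) {
  nnode <- length(parent)
  N <- length(tip.label)
  if (nnode != 2L * N - 1L) stop("a binary rooted tree on ", N, " taxa needs ",
                                 2L * N - 1L, " nodes, got ", nnode)
  child <- matrix(NA_integer_, 2L, nnode)
  for (i in seq_len(nnode)) {
    p <- parent[i]
    if (is.na(p)) next
    if (is.na(child[1L, p])) child[1L, p] <- i
    else if (is.na(child[2L, p])) child[2L, p] <- i
    else stop("node ", p, " has more than two children: tree is not binary")
  }
  tr <- structure(list(N = N, nnode = nnode, parent = as.integer(parent),
                       child = child, height = as.numeric(height),
                       tip.label = tip.label, root = which(is.na(parent))[1L]),
                  class = "timetree")
  tr$postorder <- tt_postorder(tr)
  if (validate) tt_validate(tr)
  tr
}

tt_postorder <- function(tr) {
  out <- integer(tr$nnode)
  k <- 0L
  # iterative DFS
  stack <- tr$root
  visit <- integer(tr$nnode)
  while (length(stack)) {
    u <- stack[length(stack)]
    if (u <= tr$N || visit[u] == 1L) {
      stack <- stack[-length(stack)]
      k <- k + 1L
      out[k] <- u
    } else {
      visit[u] <- 1L
      stack <- c(stack, tr$child[2L, u], tr$child[1L, u])
    }
  }
  out
}

tt_validate <- function(tr) {
  if (sum(is.na(tr$parent)) != 1L) stop("tree must have exactly one root")
  internals <- (tr$N + 1L):tr$nnode
  if (any(is.na(tr$child[, internals]))) stop("internal node without two children")
  for (i in seq_len(tr$nnode)) {
    p <- tr$parent[i]
    if (is.na(p)) next
    if (tr$height[i] >= tr$height[p])
      stop("node ", i, " is not strictly younger than its parent")
  }
  invisible(tr)
}

#' @export
print.timetree <- function(x, ...) {
  cat("timetree:", x$N, "taxa, root height",
      format(x$height[x$root], digits = 6), "\n")
  invisible(x)
}

# ---- newick I/O (via ape) ----------------------------------------------------

#' Parse a newick string into a time tree
#'
#' Branch lengths are required on every edge.  Node heights are derived from
#' root-to-node depths as `max depth - depth`, so an ultrametric input places
#' all tips at height 0 and non-ultrametric tips retain positive heights.
#'
#' @param text a newick string (single tree, with branch lengths).
#' @return a [timetree()].
#' @export
parse_newick <- function(text) {
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed newick: ", conditionMessage(e)))
  if (is.null(ph)) stop("malformed newick string")
  as_timetree(ph)
}

#' Convert an `ape::phylo` tree to a time tree
#' @param ph a rooted binary `phylo` object with edge lengths.
#' @return a [timetree()].
#' @export
as_timetree <- function(ph) {
  if (is.null(ph$edge.length)) stop("tree has no branch lengths")
  if (any(ph$edge.length < 0)) stop("negative branch length")
  deg <- tabulate(ph$edge[, 1L], nbins = max(ph$edge))
  bad <- which(deg > 2L)
  if (length(bad)) stop("non-binary node in newick input: node ", bad[1L])
  N <- length(ph$tip.label)
  if (ph$Nnode != N - 1L) stop("tree is not binary and rooted (",
                               ph$Nnode, " internal nodes for ", N, " taxa)")
  nnode <- 2L * N - 1L
  # ape uses tips 1..N, root N+1; depths from root
  depth <- numeric(nnode)
  parent <- rep(NA_integer_, nnode)
  # edges are not ordered; walk from root
  kids <- split(seq_len(nrow(ph$edge)), ph$edge[, 1L])
  root <- N + 1L
  stack <- root
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (ei in kids[[as.character(u)]]) {
      v <- ph$edge[ei, 2L]
      parent[v] <- u
      depth[v] <- depth[u] + ph$edge.length[ei]
      if (v > N) stack <- c(stack, v)
    }
  }
  height <- max(depth) - depth
  timetree(parent, height, ph$tip.label)
}

#' Convert a time tree to an `ape::phylo` object
#' @param tr a [timetree()].
#' @return a `phylo` object.
#' @export
as_phylo <- function(tr) {
  nonroot <- setdiff(seq_len(tr$nnode), tr$root)
  edge <- cbind(tr$parent[nonroot], nonroot)
  len <- tr$height[edge[, 1L]] - tr$height[edge[, 2L]]
  # relabel so internal indices follow ape's convention (root = N+1)
  ph <- list(edge = edge, edge.length = len, tip.label = tr$tip.label,
             Nnode = tr$N - 1L)
  # ape requires internal nodes numbered N+1.. with root first
  map <- integer(tr$nnode)
  map[seq_len(tr$N)] <- seq_len(tr$N)
  internals <- c(tr$root, setdiff((tr$N + 1L):tr$nnode, tr$root))
  map[internals] <- tr$N + seq_along(internals)
  ph$edge <- cbind(map[edge[, 1L]], map[edge[, 2L]])
  class(ph) <- "phylo"
  ph <- ape::reorder.phylo(ph, "cladewise")
  ph
}

#' Write a time tree as a newick string
#' @param tr a [timetree()].
#' @param digits significant digits for branch lengths.
#' @return a newick string.
#' @export
write_newick <- function(tr, digits = 12) {
  ape::write.tree(as_phylo(tr), digits = digits)
}

# ---- metrics -----------------------------------------------------------------

# Bitmask clades (tip sets below internal nodes, root excluded), keyed by a
# canonical string over the reference label ordering.
tt_clades <- function(tr, labels) {
  idx <- match(tr$tip.label, labels)
  below <- vector("list", tr$nnode)
  for (u in tr$postorder) {
    below[[u]] <- if (u <= tr$N) idx[u]
                  else sort(c(below[[tr$child[1L, u]]], below[[tr$child[2L, u]]]))
  }
  internals <- setdiff((tr$N + 1L):tr$nnode, tr$root)
  vapply(internals, function(u) paste(below[[u]], collapse = ","), character(1))
}

#' Robinson-Foulds distance between two time trees
#'
#' The one-sided clade-difference count: the number of internal (non-root)
#' clades present in exactly one of the two trees, divided by 2.  Under this
#' convention a single narrow-exchange move yields distance exactly 1.
#'
#' @param a,b [timetree()] objects on the same leaf label set.
#' @return a non-negative number.
#' @export
robinson_foulds <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have different leaf label sets")
  ca <- tt_clades(a, a$tip.label)
  cb <- tt_clades(b, a$tip.label)
  (sum(!(ca %in% cb)) + sum(!(cb %in% ca))) / 2
}

#' Tree length: the sum of all branch lengths
#' @param tr a [timetree()].
#' @return positive real, sum of parental branch lengths over non-root nodes.
#' @export
tree_length <- function(tr) {
  sum(tr$height[tr$parent] - tr$height, na.rm = TRUE)
}

# Branch (parental edge) duration per node; NA at the root (NA parent link).
tt_branch_lengths <- function(tr) {
  tr$height[tr$parent] - tr$height
}

tt_is_ultrametric <- function(tr, tol = 1e-8) {
  all(abs(tr$height[seq_len(tr$N)]) < tol)
}
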