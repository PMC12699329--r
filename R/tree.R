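# Rooted-tree plumbing on top of ape's phylo: indexed traversals, stable
# internal-node labels, polytomy resolution, and branch rotation.

#' Index a rooted tree for traversal
#'
#' Builds parent/children/branch-length lookup tables and depth-first node
#' orders from an [ape::phylo] object. The stored child order (the order in
#' which children appear in the edge matrix) is preserved; all downstream
#' methods that depend on leaf order use it.
#'
#' @param phy A rooted `phylo` object.
#' @return A list with elements `ntip`, `nnode`, `nn` (total nodes), `root`,
#'   `parent` (integer vector, 0 for the root), `children` (list of integer
#'   vectors, empty for leaves), `blen` (incoming branch length per node, `NA`
#'   for the root), `preorder`, `postorder` (node index vectors), and `labels`
#'   (tip labels followed by internal labels).
#' @keywords internal
tree_index <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  nn <- ntip + nnode
  e1 <- phy$edge[, 1L]
  e2 <- phy$edge[, 2L]
  parent <- integer(nn)
  parent[e2] <- e1
  blen <- rep(NA_real_, nn)
  if (!is.null(phy$edge.length)) blen[e2] <- phy$edge.length
  children <- split(e2, factor(e1, levels = seq_len(nn)))
  names(children) <- NULL
  root <- setdiff(e1, e2)
  if (length(root) != 1L) stop("tree must have exactly one root")
  # DFS: push children in stored order; popping order then visits the last
  # child first, so the reverse of the visit sequence is a postorder in which
  # the first-stored child's subtree comes first.
  visit <- integer(nn)
  stack <- integer(nn)
  stack[1L] <- root
  sp <- 1L
  k <- 0L
  while (sp > 0L) {
    v <- stack[sp]
    sp <- sp - 1L
    k <- k + 1L
    visit[k] <- v
    ch <- children[[v]]
    for (c in ch) {
      sp <- sp + 1L
      stack[sp] <- c
    }
  }
  postorder <- rev(visit)
  # true preorder: children pushed reversed so first child is popped first
  stack[1L] <- root
  sp <- 1L
  k <- 0L
  while (sp > 0L) {
    v <- stack[sp]
    sp <- sp - 1L
    k <- k + 1L
    visit[k] <- v
    ch <- children[[v]]
    for (c in rev(ch)) {
      sp <- sp + 1L
      stack[sp] <- c
    }
  }
  labels <- c(phy$tip.label,
              if (is.null(phy$node.label)) rep(NA_character_, nnode)
              else phy$node.label)
  list(ntip = ntip, nnode = nnode, nn = nn, root = root, parent = parent,
       children = children, blen = blen, preorder = visit,
       postorder = postorder, labels = labels)
}

# Rebuild a phylo object from a children list (node ids may exceed the
# original range after polytomy resolution). Internal nodes are renumbered in
# preorder; tips keep their numbers. `labels` is indexed by old node id.
rebuild_phylo <- function(ntip, root, children, blen, tip_label, labels) {
  n_internal <- sum(lengths(children) > 0L)
  new_id <- integer(length(children))
  new_id[seq_len(ntip)] <- seq_len(ntip)
  nxt <- ntip
  order_old <- integer(n_internal)
  # preorder pass assigning new internal numbers (root becomes ntip + 1)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- children[[v]]
    if (length(ch) > 0L) {
      nxt <- nxt + 1L
      new_id[v] <- nxt
      order_old[nxt - ntip] <- v
      stack <- c(stack, rev(ch))
    }
  }
  # emit edges in preorder (cladewise) following stored child order
  n_edge <- ntip + n_internal - 1L
  edges <- matrix(0L, nrow = n_edge, ncol = 2L)
  elen <- numeric(n_edge)
  k <- 0L
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- children[[v]]
    for (c in ch) {
      k <- k + 1L
      edges[k, ] <- c(new_id[v], new_id[c])
      elen[k] <- blen[c]
    }
    stack <- c(stack, rev(ch))
  }
  phy <- list(edge = edges, edge.length = elen, Nnode = n_internal,
              tip.label = tip_label,
              node.label = labels[order_old])
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' Parse a newick string into a validated rooted tree
#'
#' Thin wrapper around [ape::read.tree] that enforces the conventions the
#' scoring methods rely on: unique leaf names, branch lengths (missing ones
#' default to `default_branch_length` with a warning), binary topology
#' (polytomies resolved by [resolve_polytomies]), and deterministic internal
#' node labels (`N0`, `N1`, ... assigned by postorder index to unlabeled
#' internal nodes).
#'
#' @param text A newick string (must end with `;`).
#' @param default_branch_length Length substituted for missing branch lengths.
#' @param resolve Resolve polytomies to binary (default `TRUE`).
#' @return A rooted, labeled `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$node.label
#' @export
parse_newick <- function(text, default_branch_length = 1, resolve = TRUE) {
  check_newick_syntax(text)
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("malformed newick string")
  prepare_tree(phy, default_branch_length = default_branch_length,
               resolve = resolve)
}

# cheap syntax pre-check so errors carry a character offset
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed newick: unbalanced ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed newick: %d unclosed '(' (string length %d)",
                 depth, length(chars)))
  if (!grepl(";\\s*$", text))
    stop(sprintf("malformed newick: missing terminal ';' at character %d",
                 length(chars)))
  invisible(TRUE)
}

#' Validate and normalize a tree for profiling
#'
#' @param phy A `phylo` object.
#' @inheritParams parse_newick
#' @return A binary (if `resolve`) rooted `phylo` with all branch lengths set
#'   and every internal node labeled.
#' @export
prepare_tree <- function(phy, default_branch_length = 1, resolve = TRUE) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  if (length(phy$tip.label) == 1L)
    warning("single-leaf tree: all pair statistics are degenerate")
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; defaulting all to ",
            default_branch_length)
    phy$edge.length <- rep(default_branch_length, nrow(phy$edge))
  } else if (anyNA(phy$edge.length)) {
    warning("missing branch lengths defaulted to ", default_branch_length)
    phy$edge.length[is.na(phy$edge.length)] <- default_branch_length
  }
  if (any(phy$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (resolve) phy <- resolve_polytomies(phy)
  label_internal_nodes(phy)
}

#' Resolve polytomies to a binary tree
#'
#' Each node with more than two children is replaced by a left-fold of
#' zero-length cherries: children grouped in stored order, so
#' `(c1,c2,c3)` becomes `((c1,c2):0,c3)`. Leaf-to-leaf path lengths are
#' unchanged.
#'
#' @param phy A rooted `phylo`.
#' @return A binary `phylo`; inserted internal nodes are unlabeled (label
#'   them with [label_internal_nodes] or via [prepare_tree]).
#' @export
resolve_polytomies <- function(phy) {
  idx <- tree_index(phy)
  if (all(lengths(idx$children) %in% c(0L, 2L))) return(phy)
  if (idx$ntip < 2L) return(phy)
  children <- idx$children
  blen <- idx$blen
  labels <- idx$labels
  nn <- idx$nn
  for (v in seq_len(nn)) {
    ch <- children[[v]]
    while (length(children[[v]]) > 2L) {
      ch <- children[[v]]
      nn <- nn + 1L
      children[[nn]] <- ch[1:2]                 # left-fold the first two
      children[[v]] <- c(nn, ch[-(1:2)])
      blen[nn] <- 0
      labels[nn] <- NA_character_
    }
  }
  rebuild_phylo(idx$ntip, idx$root, children, blen, phy$tip.label, labels)
}

#' Assign deterministic labels to unlabeled internal nodes
#'
#' The k-th internal node in postorder (respecting stored child order,
#' counting from 0) receives label `N<k>` if it has none. Existing labels are
#' kept; duplicates are an error. This makes internal node ids reproducible,
#' so externally computed ancestral-state tables can be keyed to them.
#'
#' @param phy A rooted `phylo`.
#' @return The relabeled `phylo`.
#' @export
label_internal_nodes <- function(phy) {
  idx <- tree_index(phy)
  lab <- idx$labels
  internals <- idx$postorder[idx$postorder > idx$ntip]
  k <- 0L
  for (v in internals) {
    if (is.na(lab[v]) || lab[v] == "")
      lab[v] <- paste0("N", k)
    k <- k + 1L
  }
  if (anyDuplicated(lab[-seq_len(idx$ntip)]))
    stop("duplicate internal node labels after auto-labeling")
  if (length(intersect(lab[seq_len(idx$ntip)], lab[-seq_len(idx$ntip)])) > 0L)
    stop("internal node labels collide with leaf names")
  phy$node.label <- lab[(idx$ntip + 1L):idx$nn]
  phy
}

#' Reverse the child order of an internal node
#'
#' Branch rotation: the topology, branch lengths and all leaf-to-leaf path
#' lengths are unchanged; only the drawn (depth-first) leaf order changes.
#' Methods that depend on leaf order (RLE, cotransitions) are sensitive to
#' rotation; naive, CWA, ASA and SEV are invariant.
#'
#' @param phy A rooted `phylo`.
#' @param node An internal node, given as its label or its integer index.
#' @return The rotated `phylo`.
#' @export
rotate_node <- function(phy, node) {
  idx <- tree_index(phy)
  v <- resolve_node_id(idx, node)
  if (v <= idx$ntip) stop("cannot rotate a leaf: ", node)
  children <- idx$children
  children[[v]] <- rev(children[[v]])
  rebuild_phylo(idx$ntip, idx$root, children, idx$blen, phy$tip.label,
                idx$labels)
}

resolve_node_id <- function(idx, node) {
  if (is.character(node)) {
    v <- match(node, idx$labels)
    if (is.na(v)) stop("unknown node label: ", node)
    return(v)
  }
  v <- as.integer(node)
  if (v < 1L || v > idx$nn) stop("node index out of range: ", node)
  v
}

#' Depth-first leaf order of a tree
#'
#' Leaves in the order they appear in a depth-first traversal respecting the
#' stored child order — the order in which profiles are laid out by RLE and
#' cotransitions.
#'
#' @param phy A rooted `phylo`.
#' @return Character vector of leaf names.
#' @export
leaf_order <- function(phy) {
  idx <- tree_index(phy)
  tips <- idx$preorder[idx$preorder <= idx$ntip]
  phy$tip.label[tips]
}

#' Number of internal nodes of a tree
#' @param phy A rooted `phylo`.
#' @return Integer count.
#' @export
n_internal_nodes <- function(phy) phy$Nnode
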