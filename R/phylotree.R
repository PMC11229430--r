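# Leaf-labeled trees are kept in a light parent/children structure so that
# leaf insertion and pruning do not fight ape's contiguous node numbering.
# All topology semantics (branch identity, equality) are unrooted: a branch
# is named by its bipartition's smaller-side leaf list, which is stable
# across rerooting and surgery. Integer node ids are internal only.

new_phylotree <- function(parent, children, label, edge_len, root,
                          note = NULL) {
  n <- length(parent)
  structure(list(parent = parent, children = children, label = label,
                 edge_len = edge_len, root = root,
                 note = note %||% rep(NA_character_, n)),
            class = "phylotree")
}

#' @export
print.phylotree <- function(x, ...) {
  cat(sprintf("phylotree: %d leaves, %d scorable branches\n",
              n_leaves(x), length(enumerate_branches(x))))
  cat(write_newick(x), "\n")
  invisible(x)
}

is_leaf <- function(pt, v) length(pt$children[[v]]) == 0L

#' Leaf labels of a tree
#' @param pt a `phylotree`.
#' @export
leaf_labels <- function(pt) {
  pt$label[vapply(seq_along(pt$parent), function(v) is_leaf(pt, v), logical(1L))]
}

#' Number of leaves
#' @inheritParams leaf_labels
#' @export
n_leaves <- function(pt) sum(!is.na(pt$label) & vapply(seq_along(pt$parent),
  function(v) is_leaf(pt, v), logical(1L)))

# Children-before-parent node order; iterative so deep trees are safe.
postorder_nodes <- function(pt) {
  out <- integer(0)
  stack <- pt$root
  seen <- logical(length(pt$parent))
  while (length(stack)) {
    v <- stack[length(stack)]
    kids <- pt$children[[v]]
    if (length(kids) == 0L || seen[v]) {
      out <- c(out, v)
      stack <- stack[-length(stack)]
    } else {
      seen[v] <- TRUE
      stack <- c(stack, rev(kids))
    }
  }
  out
}

# Sorted leaf-label set under every node.
leafsets <- function(pt) {
  sets <- vector("list", length(pt$parent))
  for (v in postorder_nodes(pt)) {
    kids <- pt$children[[v]]
    sets[[v]] <- if (length(kids) == 0L) pt$label[v]
                 else sort(unlist(sets[kids], use.names = FALSE))
  }
  sets
}

# Canonical bipartition id: the smaller side's sorted labels, comma-joined;
# ties broken by the lexicographically smaller joined string.
canonical_split_id <- function(side, all_leaves) {
  other <- setdiff(all_leaves, side)
  a <- paste(sort(side), collapse = ",")
  b <- paste(sort(other), collapse = ",")
  if (length(side) < length(other)) return(a)
  if (length(other) < length(side)) return(b)
  if (a <= b) a else b
}

# Internal branch table: one row per scorable branch (node = edge's child).
# A degree-2 root's two edges define the same unrooted branch; the later
# postorder child is dropped so 2n-3 branches remain on binary trees.
branch_table <- function(pt) {
  po <- postorder_nodes(pt)
  sets <- leafsets(pt)
  all_leaves <- sets[[pt$root]]
  nodes <- setdiff(po, pt$root)
  if (length(pt$children[[pt$root]]) == 2L) {
    drop <- pt$children[[pt$root]]
    keep1 <- drop[which.min(match(drop, po))]  # earlier in postorder
    nodes <- setdiff(nodes, setdiff(drop, keep1))
  }
  ids <- vapply(nodes, function(v) canonical_split_id(sets[[v]], all_leaves),
                character(1L))
  data.frame(node = nodes, id = ids, stringsAsFactors = FALSE)
}

#' Enumerate scorable branches
#'
#' Returns branch identifiers in deterministic postorder. Branches are named
#' by the smaller side of their bipartition (sorted leaf labels joined by
#' commas), an identity that is invariant to rerooting. On an unrooted
#' binary tree with n leaves there are exactly `2n - 3` branches; the two
#' edges incident to a degree-2 root are merged into one branch.
#'
#' @param pt a `phylotree` with at least 2 leaves.
#' @return character vector of branch ids.
#' @export
enumerate_branches <- function(pt) {
  if (n_leaves(pt) < 2L) stop("single-leaf tree has no scorable branches")
  branch_table(pt)$id
}

#' Nontrivial bipartitions of a tree
#'
#' The set of splits with at least two leaves on each side; the currency of
#' unrooted topology comparison.
#'
#' @inheritParams enumerate_branches
#' @export
bipartition_set <- function(pt) {
  sets <- leafsets(pt)
  all_leaves <- sets[[pt$root]]
  tab <- branch_table(pt)
  keep <- vapply(tab$node, function(v) {
    k <- length(sets[[v]])
    k >= 2L && (length(all_leaves) - k) >= 2L
  }, logical(1L))
  unique(tab$id[keep])
}

## ---- Newick I/O (plain parsing via ape) -------------------------------

as_phylotree_phylo <- function(phy) {
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  parent <- integer(N)
  children <- rep(list(integer(0)), N)
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1L]; c <- phy$edge[r, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  label <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    nl[!nzchar(nl)] <- NA_character_
    label[(n + 1L):N] <- nl
  }
  edge_len <- rep(NA_real_, N)
  if (!is.null(phy$edge.length)) edge_len[phy$edge[, 2L]] <- phy$edge.length
  new_phylotree(parent, children, label, edge_len, root = n + 1L)
}

#' Convert a phylotree to an ape "phylo"
#' @param x a `phylotree`.
#' @param ... unused.
#' @export
as.phylo.phylotree <- function(x, ...) {
  # preorder renumbering into ape's tip/internal id convention
  pre <- rev(postorder_nodes(x))
  tips <- pre[vapply(pre, function(v) is_leaf(x, v), logical(1L))]
  ints <- pre[!pre %in% tips]
  id <- integer(length(x$parent))
  id[tips] <- seq_along(tips)
  id[ints] <- length(tips) + seq_along(ints)
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  for (v in pre) {
    for (k in x$children[[v]]) {
      edges <- rbind(edges, c(id[v], id[k]))
      lens <- c(lens, x$edge_len[k])
    }
  }
  phy <- list(edge = edges, tip.label = x$label[tips],
              Nnode = length(ints))
  if (any(!is.na(lens))) phy$edge.length <- ifelse(is.na(lens), 0, lens)
  nl <- x$label[ints]
  if (any(!is.na(nl))) phy$node.label <- ifelse(is.na(nl), "", nl)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Parse a Newick string
#'
#' Thin validated wrapper around [ape::read.tree()]: polytomies are allowed,
#' branch lengths and internal labels are preserved (and ignored by all
#' scoring), duplicate leaf labels are rejected.
#'
#' @param text a Newick string ending in `;`.
#' @return a `phylotree`.
#' @export
parse_newick <- function(text) {
  if (!grepl(";", text, fixed = TRUE)) stop("Newick string lacks ';'")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("malformed Newick string")
  }
  if (anyDuplicated(phy$tip.label)) {
    stop(sprintf("duplicate leaf label: '%s'",
                 phy$tip.label[duplicated(phy$tip.label)][1L]))
  }
  if (any(!nzchar(phy$tip.label))) stop("empty leaf label")
  as_phylotree(phy)
}

#' Read a Newick tree from a file
#' @param file path to a Newick file.
#' @export
read_newick <- function(file) {
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""))
}

#' Coerce to phylotree
#' @param x an ape `phylo`, a Newick string, or a `phylotree`.
#' @export
as_phylotree <- function(x) {
  if (inherits(x, "phylotree")) return(x)
  if (inherits(x, "phylo")) return(as_phylotree_phylo(x))
  if (is.character(x) && length(x) == 1L) return(parse_newick(x))
  stop("cannot coerce to phylotree")
}

#' Write Newick
#'
#' Plain trees are written through [ape::write.tree()]. Trees carrying
#' branch annotations (from [map_scores()]) are written with each branch's
#' annotation in a square-bracket comment after the subtending node, a
#' flavour [read_annotated_newick()] parses back losslessly.
#'
#' @param pt a `phylotree`.
#' @param file optional output path.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(pt, file = NULL, digits = 6) {
  txt <- if (any(!is.na(pt$note))) write_annotated(pt, digits)
         else ape::write.tree(as.phylo.phylotree(pt), digits = digits)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

write_annotated <- function(pt, digits = 6) {
  wr <- function(v) {
    s <- if (is_leaf(pt, v)) pt$label[v]
         else sprintf("(%s)%s", paste(vapply(pt$children[[v]], wr, character(1L)),
                                      collapse = ","),
                      if (!is.na(pt$label[v])) pt$label[v] else "")
    if (!is.na(pt$edge_len[v])) s <- sprintf("%s:%.*g", s, digits, pt$edge_len[v])
    if (!is.na(pt$note[v])) s <- sprintf("%s[%s]", s, pt$note[v])
    s
  }
  paste0(wr(pt$root), ";")
}

#' Read score-annotated Newick
#'
#' Parses the annotated flavour produced by [write_newick()] on a
#' [map_scores()] result: standard Newick in which any node (leaf or
#' internal) may be followed by a `[...]` comment holding that branch's
#' score. ape drops comments, so this small recursive-descent reader exists
#' solely to round-trip the package's own annotation format.
#'
#' @param text annotated Newick string.
#' @return a `phylotree` whose `note` field carries the annotations.
#' @export
read_annotated_newick <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  pos <- 1L
  peek <- function() if (pos <= nchar(s)) substring(s, pos, pos) else ""
  nodes <- list()
  add_node <- function(label, kids, len, note) {
    nodes[[length(nodes) + 1L]] <<- list(label = label, kids = kids,
                                         len = len, note = note)
    length(nodes)
  }
  read_label <- function() {
    m <- regexpr("^[^(),:;\\[\\]]+", substring(s, pos), perl = TRUE)
    if (m == -1L) return("")
    lab <- regmatches(substring(s, pos), m)
    pos <<- pos + nchar(lab)
    lab
  }
  read_clade <- function() {
    kids <- integer(0)
    label <- NA_character_; len <- NA_real_; note <- NA_character_
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids <- c(kids, read_clade())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("unbalanced parentheses in annotated Newick")
      }
      lab <- read_label(); if (nzchar(lab)) label <- lab
    } else {
      lab <- read_label()
      if (!nzchar(lab)) stop("expected leaf label")
      label <- lab
    }
    if (peek() == ":") {
      pos <<- pos + 1L
      m <- regexpr("^[-+0-9.eE]+", substring(s, pos))
      if (m == -1L) stop("bad branch length")
      tok <- regmatches(substring(s, pos), m)
      len <- as.numeric(tok); pos <<- pos + nchar(tok)
    }
    if (peek() == "[") {
      close <- regexpr("]", substring(s, pos), fixed = TRUE)
      if (close == -1L) stop("unterminated [annotation]")
      note <- substring(s, pos + 1L, pos + close - 2L)
      pos <<- pos + close
    }
    add_node(label, kids, len, note)
  }
  root <- read_clade()
  if (peek() != ";") stop("annotated Newick lacks terminating ';'")
  N <- length(nodes)
  parent <- integer(N); children <- rep(list(integer(0)), N)
  label <- rep(NA_character_, N); edge_len <- rep(NA_real_, N)
  note <- rep(NA_character_, N)
  for (v in seq_len(N)) {
    nd <- nodes[[v]]
    label[v] <- nd$label; edge_len[v] <- nd$len; note[v] <- nd$note
    children[[v]] <- nd$kids
    for (k in nd$kids) parent[k] <- v
  }
  pt <- new_phylotree(parent, children, label, edge_len, root, note)
  if (anyDuplicated(leaf_labels(pt))) stop("duplicate leaf label")
  pt
}

## ---- surgery ----------------------------------------------------------

node_for_branch <- function(pt, branch) {
  tab <- branch_table(pt)
  if (is.numeric(branch)) {
    if (branch < 1L || branch > nrow(tab)) stop("unknown branch index")
    return(tab$node[branch])
  }
  i <- match(branch, tab$id)
  if (is.na(i)) stop(sprintf("unknown branch '%s'", branch))
  tab$node[i]
}

#' Insert a leaf on a branch
#'
#' Returns a new tree (the input is untouched) in which the named branch is
#' subdivided by a fresh degree-3 node carrying the new leaf — the
#' elementary move of exhaustive fossil placement.
#'
#' @param pt a `phylotree`.
#' @param branch a branch id string from [enumerate_branches()] or an index
#'   into that vector.
#' @param label new leaf label, not already in the tree.
#' @export
insert_leaf <- function(pt, branch, label) {
  if (label %in% pt$label) stop(sprintf("label '%s' already on tree", label))
  child <- node_for_branch(pt, branch)
  N <- length(pt$parent)
  u <- N + 1L; w <- N + 2L
  parent <- c(pt$parent, 0L, 0L)
  children <- c(pt$children, list(integer(0)), list(integer(0)))
  lab <- c(pt$label, NA_character_, label)
  len <- c(pt$edge_len, NA_real_, NA_real_)
  p <- pt$parent[child]
  children[[p]][children[[p]] == child] <- u
  parent[u] <- p
  parent[child] <- u
  parent[w] <- u
  children[[u]] <- c(child, w)
  if (!is.na(len[child])) {
    len[u] <- len[child] / 2
    len[child] <- len[child] / 2
  }
  new_phylotree(parent, children, lab, len, pt$root)
}

compact_tree <- function(pt, keep) {
  # renumber after surgery; 'keep' is a logical mask of surviving nodes
  map <- integer(length(keep)); map[keep] <- seq_len(sum(keep))
  p0 <- pt$parent[keep]
  newp <- integer(length(p0))
  nz <- p0 != 0L
  newp[nz] <- map[p0[nz]]
  new_phylotree(
    parent = newp,
    children = lapply(pt$children[keep], function(k) map[k]),
    label = pt$label[keep],
    edge_len = pt$edge_len[keep],
    root = map[pt$root],
    note = pt$note[keep])
}

#' Prune a leaf, returning its former attachment branch
#'
#' Removes the leaf and its attachment node, fusing the two incident
#' branches, and reports the fused branch's id in the pruned tree —
#' reinserting the leaf there (see [insert_leaf()]) restores the original
#' unrooted topology when the leaf was attached at a degree-3 node.
#'
#' @param pt a `phylotree` with at least 3 leaves.
#' @param label leaf to remove.
#' @return list with `tree` (the pruned `phylotree`) and `branch` (id).
#' @export
prune_leaf <- function(pt, label) {
  v <- which(!is.na(pt$label) & pt$label == label &
               vapply(seq_along(pt$parent), function(x) is_leaf(pt, x), logical(1L)))
  if (length(v) != 1L) stop(sprintf("unknown leaf '%s'", label))
  if (n_leaves(pt) < 3L) stop("tree too small to prune")
  p <- pt$parent[v]
  parent <- pt$parent; children <- pt$children
  keep <- rep(TRUE, length(parent)); keep[v] <- FALSE
  children[[p]] <- setdiff(children[[p]], v)
  root <- pt$root
  sib_for_id <- NA_integer_
  if (length(children[[p]]) == 1L) {
    c1 <- children[[p]]
    if (p == root) {
      # root had two children; the surviving child becomes the root
      parent[c1] <- 0L
      root <- c1
      keep[p] <- FALSE
      sib_for_id <- NA_integer_   # use merged root branch afterwards
    } else {
      q <- parent[p]
      children[[q]][children[[q]] == p] <- c1
      parent[c1] <- q
      if (!is.na(pt$edge_len[p]) || !is.na(pt$edge_len[c1])) {
        el <- sum(pt$edge_len[c(p, c1)], na.rm = TRUE)
        pt$edge_len[c1] <- el
      }
      keep[p] <- FALSE
      sib_for_id <- c1
    }
  }
  out <- new_phylotree(parent, children, pt$label, pt$edge_len, root, pt$note)
  out <- compact_tree(out, keep)
  sets <- leafsets(out)
  all_leaves <- sets[[out$root]]
  id <- if (is.na(sib_for_id)) {
    # attachment was at the (old) root: the restoring branch is the merged
    # root branch of the pruned tree
    tab <- branch_table(out)
    first_child <- out$children[[out$root]][1L]
    tab$id[match(first_child, tab$node)]
  } else {
    # sib_for_id indexed the uncompacted tree; recover it by leaf set
    side <- sort(leafsets(pt)[[sib_for_id]])
    canonical_split_id(side, all_leaves)
  }
  list(tree = out, branch = id)
}

#' Drop several leaves
#'
#' Restriction used by topology comparison: leaves outside `keep` are
#' removed and degree-2 internal nodes are spliced out.
#'
#' @param pt a `phylotree`.
#' @param keep leaf labels to retain (at least 2).
#' @export
restrict_tree <- function(pt, keep) {
  drop <- setdiff(leaf_labels(pt), keep)
  if (length(intersect(leaf_labels(pt), keep)) < 2L) {
    stop("restriction leaves fewer than 2 leaves")
  }
  for (lab in drop) {
    if (n_leaves(pt) < 3L) break
    pt <- prune_leaf(pt, lab)$tree
  }
  pt
}

#' Unrooted topological equality
#'
#' `TRUE` iff the two trees, optionally restricted to a common leaf subset,
#' induce the same set of nontrivial bipartitions (equivalently, Robinson-
#' Foulds distance 0). Root placement is immaterial.
#'
#' @param a,b `phylotree` objects.
#' @param restrict_to optional leaf labels to restrict both trees to before
#'   comparing.
#' @export
same_topology <- function(a, b, restrict_to = NULL) {
  la <- leaf_labels(a); lb <- leaf_labels(b)
  shared <- intersect(la, lb)
  if (!is.null(restrict_to)) shared <- intersect(shared, restrict_to)
  if (length(shared) == 0L) stop("trees share no leaves after restriction")
  if (length(shared) < 2L) stop("fewer than 2 shared leaves")
  ra <- restrict_tree(a, shared)
  rb <- restrict_tree(b, shared)
  if (!setequal(leaf_labels(ra), leaf_labels(rb))) {
    stop("leaf sets differ after restriction")
  }
  setequal(bipartition_set(ra), bipartition_set(rb))
}

#' Reroot at a leaf's pendant branch
#'
#' Convenience wrapper (via [ape::root()]) used to test that scoring and
#' branch identity are invariant to root placement.
#'
#' @param pt a `phylotree`.
#' @param outgroup a leaf label.
#' @export
reroot_tree <- function(pt, outgroup) {
  phy <- as.phylo.phylotree(pt)
  as_phylotree(ape::root(phy, outgroup = outgroup, resolve.root = TRUE))
}
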