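# Clade assignment: map each molecular feature to the minimal phylogenetic
# clade that contains at least P percent (default 80) of the microbial
# features positively associated with it.
#
# "Minimal clade" is read as the internal node whose subtree (i) contains at
# least P% of ALL marked leaves and (ii) has the fewest leaves; ties go to
# the deeper node, then the earlier node in postorder.  Only internal nodes
# are admitted as clades (a single leaf is a species, not a clade), so
# single-leaf evidence maps to the leaf's parent.  The root never qualifies:
# an assignment must be a proper subtree.

# iterative postorder traversal of an ape phylo tree; returns node order
.postorder_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], factor(tree$edge[, 1L],
                                        levels = seq_len(n_tip + tree$Nnode)))
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  order <- integer(n_tip + tree$Nnode)
  k <- 0L
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$stage == 1L) {
      stack[[length(stack) + 1L]] <- list(node = top$node, stage = 2L)
      for (ch in rev(kids[[top$node]]))
        stack[[length(stack) + 1L]] <- list(node = ch, stage = 1L)
    } else {
      k <- k + 1L
      order[k] <- top$node
    }
  }
  list(order = order, kids = kids, root = root)
}

# per-node leaf counts, marked-leaf counts, and depth
.clade_stats <- function(tree, marked_tips) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  po <- .postorder_nodes(tree)
  n_leaves <- integer(n_all)
  n_marked <- integer(n_all)
  n_leaves[seq_len(n_tip)] <- 1L
  n_marked[match(marked_tips, tree$tip.label)] <- 1L
  for (node in po$order) {
    ch <- po$kids[[node]]
    if (length(ch)) {
      n_leaves[node] <- sum(n_leaves[ch])
      n_marked[node] <- sum(n_marked[ch])
    }
  }
  # cladewise edge order lists every parent before its children
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  depth <- integer(n_all)
  for (i in seq_len(nrow(tree_cw$edge)))
    depth[tree_cw$edge[i, 2L]] <- depth[tree_cw$edge[i, 1L]] + 1L
  po_rank <- integer(n_all)
  po_rank[po$order] <- seq_along(po$order)
  list(n_leaves = n_leaves, n_marked = n_marked, depth = depth,
       po_rank = po_rank, root = po$root, n_tip = n_tip)
}

# leaf labels under a node
.clade_leaves <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  tree$tip.label[sort(phy_descendant_tips(tree, node))]
}

phy_descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], factor(tree$edge[, 1L],
                                        levels = seq_len(n_tip + tree$Nnode)))
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v <= n_tip) acc <- c(acc, v) else stack <- c(stack, kids[[v]])
  }
  acc
}

#' Prune a phylogenetic tree to a leaf subset
#'
#' Smallest topology-preserving tree on the kept leaves: dropped leaves are
#' removed, unary internal nodes are suppressed, and branch lengths are
#' summed across suppressed nodes (via [ape::keep.tip()]).  Unrooted input
#' is midpoint-rooted first, with a warning.
#'
#' @param tree An [ape::phylo] tree with unique leaf labels.
#' @param keep Character vector of leaf labels to keep; must intersect the
#'   tree's leaves.
#' @return The pruned `phylo` tree.
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) abort("leaf labels must be unique")
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) == 0L)
    abort("no requested leaf is present in the tree")
  tree <- .ensure_rooted(tree)
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

.ensure_rooted <- function(tree) {
  if (ape::is.rooted(tree)) return(tree)
  if (!requireNamespace("phangorn", quietly = TRUE))
    abort("unrooted tree: install `phangorn` for midpoint rooting, ",
          "or supply a rooted tree")
  warning("unrooted input tree was midpoint-rooted", call. = FALSE)
  phangorn::midpoint(tree)
}

#' Assign marked leaves to their minimal covering clade
#'
#' Among all internal nodes whose subtree contains at least `percent`% of
#' the marked leaves, returns the one with the fewest leaves (ties: greater
#' depth, then earlier postorder position).  Returns `NULL` when the only
#' qualifying clade is the root (the whole tree) or when `marked` is empty.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param marked Character vector of marked leaf labels (the microbes
#'   positively associated with one molecule); must be a subset of the
#'   tree's leaves.
#' @param percent Required coverage, in percent (default 80).
#' @return A `clade_assignment` list (`node`, `node_label`, `leaves`,
#'   `n_leaves`, `n_marked_total`, `n_marked_in_clade`, `fraction`) or
#'   `NULL`.
#' @export
assign_clade <- function(tree, marked, percent = 80) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(percent) || percent <= 0 || percent > 100)
    abort("`percent` must lie in (0, 100]")
  if (length(marked) == 0L) {
    message("no marked leaves: no clade assigned")
    return(NULL)
  }
  if (length(setdiff(marked, tree$tip.label)))
    abort("marked leaves missing from the tree: ",
          paste(utils::head(setdiff(marked, tree$tip.label), 3L),
                collapse = ", "))
  tree <- .ensure_rooted(tree)
  st <- .clade_stats(tree, unique(marked))
  total <- sum(st$n_marked[seq_len(st$n_tip)])
  internal <- setdiff((st$n_tip + 1L):(st$n_tip + tree$Nnode), st$root)
  # integer comparison avoids float trouble: marked/total >= percent/100
  ok <- internal[st$n_marked[internal] * 100 >= percent * total]
  if (length(ok) == 0L) return(NULL)
  ord <- order(st$n_leaves[ok], -st$depth[ok], st$po_rank[ok])
  node <- ok[ord[1L]]
  label <- if (!is.null(tree$node.label))
    tree$node.label[node - st$n_tip] else NA_character_
  structure(list(node = node,
                 node_label = label,
                 leaves = .clade_leaves(tree, node),
                 n_leaves = st$n_leaves[node],
                 n_marked_total = total,
                 n_marked_in_clade = st$n_marked[node],
                 fraction = st$n_marked[node] / total),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf("<clade_assignment> node %d (%d leaves), %d/%d marked (%.0f%%)\n",
              x$node, x$n_leaves, x$n_marked_in_clade, x$n_marked_total,
              100 * x$fraction))
  invisible(x)
}

#' Assign every molecule to its phylogenetic clade
#'
#' Filters the edges to positive associations, prunes the tree to the
#' microbes carrying at least one positive edge, and runs [assign_clade()]
#' per molecule.  Each assignment reports the clade identifier
#' (smallest leaf label plus leaf count), the marked-leaf coverage, and the
#' minimal P value among the molecule's edges into the clade (the heat
#' value `-log10(P)` is left to the caller).
#'
#' @param tree A rooted [ape::phylo] tree over the microbial feature ids.
#' @param edges Edge table from [association_scan()].
#' @param percent Coverage requirement, in percent (default 80).
#' @return Tibble: `molecule_id`, `clade`, `node`, `n_leaves`,
#'   `n_marked_total`, `n_marked_in_clade`, `fraction`, `min_p`.
#' @export
assign_all <- function(tree, edges, percent = 80) {
  stopifnot(inherits(tree, "phylo"))
  pos <- edges[edges$sign == "positive", , drop = FALSE]
  pos <- pos[pos$microbe_id %in% tree$tip.label, , drop = FALSE]
  if (nrow(pos) == 0L)
    return(tibble::tibble(molecule_id = character(), clade = character(),
                          node = integer(), n_leaves = integer(),
                          n_marked_total = integer(),
                          n_marked_in_clade = integer(),
                          fraction = numeric(), min_p = numeric()))
  pruned <- prune_tree(tree, unique(pos$microbe_id))
  rows <- lapply(split(pos, pos$molecule_id), function(e) {
    marked <- unique(e$microbe_id)
    ca <- assign_clade(pruned, marked, percent)
    if (is.null(ca)) return(NULL)
    in_clade <- e$microbe_id %in% ca$leaves
    tibble::tibble(molecule_id = e$molecule_id[1L],
                   clade = paste0(min(ca$leaves), "|n=", ca$n_leaves),
                   node = ca$node,
                   n_leaves = ca$n_leaves,
                   n_marked_total = ca$n_marked_total,
                   n_marked_in_clade = ca$n_marked_in_clade,
                   fraction = ca$fraction,
                   min_p = if (any(in_clade))
                     min(e$p_value[in_clade]) else NA_real_)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- tibble::tibble(
    molecule_id = character(), clade = character(), node = integer(),
    n_leaves = integer(), n_marked_total = integer(),
    n_marked_in_clade = integer(), fraction = numeric(), min_p = numeric())
  out[order(out$molecule_id), ]
}
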