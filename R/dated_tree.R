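#' Dated phylogenetic tree
#'
#' A `dated_tree` wraps an [ape::phylo] object (rooted, branch lengths in
#' substitutions/site) together with one decimal-year sampling date per tip
#' and a deterministic node numbering. Node ids are assigned by a preorder
#' traversal (root = 1, then children left to right as they appear in the
#' input file), so re-reading the same file always yields the same ids.
#'
#' Dates may be absent (`dates = NULL`) for trees that have been read but not
#' yet dated; operations that need dates check for them.
#'
#' @param phy an [ape::phylo] object with branch lengths.
#' @param dates numeric vector of decimal years (negative allowed for
#'   B.C.E. samples), either named by tip label or aligned with
#'   `phy$tip.label`; or `NULL` for an undated tree.
#' @return an object of class `dated_tree` with components `phy`, `dates`
#'   (named by tip label, or `NULL`), `node_id` (ape node number ->
#'   preorder id), `preorder` (preorder id -> ape node number), `depths`
#'   (root-to-node path lengths, by ape node number) and `desc` (descendant
#'   tip ape numbers per node).
#' @export
dated_tree <- function(phy, dates = NULL) {
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape 'phylo' object")
  phy <- ape::reorder.phylo(phy, "cladewise")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (ntip < 2L) stop("tree must have at least 2 tips")

  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }

  el <- phy$edge.length
  if (is.null(el)) el <- rep(NA_real_, nrow(phy$edge))
  bad <- !is.finite(el)
  if (any(bad)) {
    stop("missing branch length on ", sum(bad), " edge(s): ",
         paste(describe_edges(phy, which(bad)), collapse = ", "))
  }
  neg <- el < 0
  if (any(neg)) {
    stop("negative branch length on ", sum(neg), " edge(s): ",
         paste(describe_edges(phy, which(neg)), collapse = ", "))
  }
  phy$edge.length <- el

  root <- ntip + 1L
  root_children <- phy$edge[phy$edge[, 1L] == root, 2L]
  if (length(root_children) < 2L) {
    stop("tree is not rooted: root has ", length(root_children), " child")
  }
  if (length(root_children) >= 3L) {
    warning("basal polytomy at the root (degree ", length(root_children),
            "): the rooting may be arbitrary", call. = FALSE)
  }

  # preorder over all nodes: in cladewise edge order every parent's edge
  # precedes its children's edges, so c(root, edge[,2]) is a preorder.
  preorder <- c(root, phy$edge[, 2L])
  node_id <- integer(ntip + nnode)
  node_id[preorder] <- seq_along(preorder)

  depths <- numeric(ntip + nnode)
  for (i in seq_len(nrow(phy$edge))) {
    depths[phy$edge[i, 2L]] <- depths[phy$edge[i, 1L]] + phy$edge.length[i]
  }

  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (i in rev(seq_len(nrow(phy$edge)))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  # tips are numbered left-to-right in cladewise order; sorting restores the
  # tree's own left-to-right tip order within each clade
  desc <- lapply(desc, sort)

  if (!is.null(dates)) {
    if (!is.null(names(dates))) {
      missing <- setdiff(phy$tip.label, names(dates))
      if (length(missing) > 0L) {
        stop("no date for tip(s): ", paste(missing, collapse = ", "))
      }
      dvals <- as.numeric(dates[phy$tip.label])
    } else {
      if (length(dates) != ntip) stop("`dates` must have one entry per tip")
      dvals <- as.numeric(dates)
    }
    if (any(!is.finite(dvals))) {
      stop("non-finite date for tip(s): ",
           paste(phy$tip.label[!is.finite(dvals)], collapse = ", "))
    }
    dates <- stats::setNames(dvals, phy$tip.label)
  }

  structure(
    list(phy = phy, dates = dates, node_id = node_id, preorder = preorder,
         depths = depths, desc = desc),
    class = "dated_tree"
  )
}

describe_edges <- function(phy, rows) {
  ntip <- length(phy$tip.label)
  lab <- function(v) {
    ifelse(v <= ntip, phy$tip.label[v], paste0("node", v))
  }
  paste0(lab(phy$edge[rows, 1L]), "->", lab(phy$edge[rows, 2L]))
}

#' @export
print.dated_tree <- function(x, ...) {
  ntip <- length(x$phy$tip.label)
  cat("Dated phylogenetic tree: ", ntip, " tips, ", x$phy$Nnode,
      " internal nodes\n", sep = "")
  if (is.null(x$dates)) {
    cat("Tip dates: none parsed yet\n")
  } else {
    cat("Tip dates: ", fmt_num(min(x$dates)), " to ", fmt_num(max(x$dates)),
        " (decimal years)\n", sep = "")
  }
  invisible(x)
}

#' Number of tips of a dated tree
#' @param tree a [dated_tree].
#' @return integer tip count.
#' @export
n_tips <- function(tree) length(tree$phy$tip.label)

#' Internal-node ids of a dated tree, in preorder
#' @param tree a [dated_tree].
#' @return integer vector of node ids (root first).
#' @export
internal_nodes <- function(tree) {
  ntip <- n_tips(tree)
  sort(tree$node_id[tree$preorder[tree$preorder > ntip]])
}

# preorder node_id -> ape node number
ape_node <- function(tree, node_id) {
  node_id <- as.integer(node_id)
  if (any(node_id < 1L | node_id > length(tree$preorder))) {
    stop("node_id out of range: ", paste(node_id, collapse = ", "))
  }
  tree$preorder[node_id]
}

is_internal_id <- function(tree, node_id) {
  ape_node(tree, node_id) > n_tips(tree)
}

#' Descendant tips of a node
#' @param tree a [dated_tree].
#' @param node_id preorder node id (see [dated_tree]).
#' @return character vector of tip labels, in the tree's left-to-right order.
#' @export
descendant_tips <- function(tree, node_id) {
  v <- ape_node(tree, node_id)
  tree$phy$tip.label[tree$desc[[v]]]
}

#' Node id of the most recent common ancestor of a set of tips
#' @param tree a [dated_tree].
#' @param tips character vector of at least two tip labels.
#' @return preorder node id of the MRCA.
#' @export
mrca_node <- function(tree, tips) {
  missing <- setdiff(tips, tree$phy$tip.label)
  if (length(missing) > 0L) {
    stop("unknown tip label(s): ", paste(missing, collapse = ", "))
  }
  if (length(tips) < 2L) stop("need at least two tips to define an MRCA")
  tree$node_id[ape::getMRCA(tree$phy, tips)]
}

#' Path lengths from a node to each of its descendant tips
#'
#' Distances are sums of branch lengths (substitutions/site) on the unique
#' path from the focal node down to each descendant tip. All node depths are
#' accumulated in one preorder pass when the tree is built, so this is a
#' constant-time lookup per tip.
#'
#' @param tree a [dated_tree].
#' @param node_id preorder id of an internal node.
#' @return named numeric vector, one entry per descendant tip.
#' @export
node_to_tip_distances <- function(tree, node_id) {
  v <- ape_node(tree, node_id)
  if (v <= n_tips(tree)) {
    stop("node_id ", node_id, " is a tip, not an internal node")
  }
  tips <- tree$desc[[v]]
  stats::setNames(tree$depths[tips] - tree$depths[v], tree$phy$tip.label[tips])
}

# Canonical fingerprint of topology + branch lengths + dates; used to check
# that a scan result and a tree actually belong together.
tree_fingerprint <- function(tree) {
  s <- paste0(
    write_newick_string(tree), "|",
    if (is.null(tree$dates)) "undated"
    else paste(fmt_num(tree$dates), collapse = ",")
  )
  md5_string(s)
}
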