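#' Time-calibrated trees
#'
#' A `timetree` is a rooted, strictly binary [ape::phylo] tree whose branch
#' lengths are in units of time (Ma by convention) and whose extant tips all
#' sit at age 0, so that every node has a well-defined age: the sum of branch
#' durations from the node down to any descendant tip. Polytomies are
#' rejected rather than resolved.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @param tol tolerance (Ma) for the ultrametricity check.
#' @return an object of class `c("timetree", "phylo")`.
#' @export
timetree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be strictly binary (no polytomies)")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  n <- length(tree$tip.label)
  if (diff(range(depth[seq_len(n)])) > tol)
    stop("tree is not ultrametric within tolerance; tips must be extant (age 0)")
  class(tree) <- c("timetree", "phylo")
  tree
}

#' Parse a newick string into a timetree
#'
#' @param text a newick string with branch lengths.
#' @param tol ultrametricity tolerance in Ma.
#' @return a [timetree].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
parse_newick <- function(text, tol = 1e-6) {
  depth <- 0L
  for (i in seq_len(nchar(text))) {
    ch <- substr(text, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " unclosed at end of string")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse failure: ", conditionMessage(e)))
  if (is.null(tr)) stop("newick parse failure")
  timetree(tr, tol = tol)
}

#' Write a timetree as newick
#'
#' @param tree a [timetree].
#' @param file optional path; when `NULL` the newick string is returned.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Node ages of a timetree
#'
#' @param tree a [timetree].
#' @return a numeric vector of ages (Ma) indexed by node id (tips
#'   `1..n`, then internal nodes ape-style); tips are exactly 0.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  n <- length(tree$tip.label)
  ages <- max(depth[seq_len(n)]) - depth
  ages[seq_len(n)] <- 0
  ages[abs(ages) < 1e-9] <- 0
  ages
}

#' Rebuild a timetree from a topology and node ages
#'
#' @param tree a rooted binary phylo giving the topology.
#' @param ages numeric vector of node ages (Ma) indexed by node id.
#' @export
tree_with_ages <- function(tree, ages) {
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  timetree(tree)
}

#' Most recent common ancestor
#'
#' @param tree a phylo/timetree.
#' @param tips character vector of tip labels (a single tip returns the tip
#'   itself).
#' @return the node id of the MRCA.
#' @export
mrca_node <- function(tree, tips) {
  if (length(tips) == 0) stop("tips must be nonempty")
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss)) stop("unknown tip label(s): ", paste(miss, collapse = ", "))
  if (length(unique(tips)) == 1) return(match(tips[1], tree$tip.label))
  ape::getMRCA(tree, unique(tips))
}

#' Reference to a named clade
#'
#' A clade is anchored by two tip labels; `scope` selects the crown node
#' (their MRCA) or the total-group node (the parent of the crown node, i.e.
#' the stem).
#'
#' @param name clade name.
#' @param tip_a,tip_b defining tip labels.
#' @param scope `"crown"` or `"total"`.
#' @export
clade_ref <- function(name, tip_a, tip_b, scope = c("crown", "total")) {
  scope <- match.arg(scope)
  structure(list(name = name, tip_a = tip_a, tip_b = tip_b, scope = scope),
            class = "clade_ref")
}

#' Resolve a clade reference to a node id
#'
#' @param tree a phylo/timetree.
#' @param clade a [clade_ref].
#' @export
clade_node <- function(tree, clade) {
  crown <- mrca_node(tree, c(clade$tip_a, clade$tip_b))
  if (clade$scope == "crown") return(crown)
  root <- length(tree$tip.label) + 1L
  if (crown == root) stop("total group undefined at root")
  tree$edge[tree$edge[, 2] == crown, 1]
}

# Index form of a rooted tree for the C++ kernels (1-based, postorder with
# children before parents, tip_row mapping tips to alignment rows).
tree_index <- function(tree, taxa = NULL) {
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  root <- n + 1L
  children <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge)))
    children[[tree$edge[i, 1]]] <- c(children[[tree$edge[i, 1]]], tree$edge[i, 2])
  children[vapply(children, is.null, TRUE)] <- list(integer(0))
  parent <- integer(n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # iterative DFS postorder
  post <- integer(n_nodes); top <- 0L
  stack <- c(root); state <- integer(0)
  visited <- logical(n_nodes)
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]
    ch <- children[[nd]]
    unv <- ch[!visited[ch]]
    if (length(unv) == 0) {
      visited[nd] <- TRUE
      ord <- c(ord, nd)
      stack <- stack[-length(stack)]
    } else {
      stack <- c(stack, unv)
    }
  }
  tip_row <- integer(n_nodes)
  if (is.null(taxa)) taxa <- tree$tip.label
  tip_row[seq_len(n)] <- match(tree$tip.label, taxa)
  if (anyNA(tip_row[seq_len(n)])) stop("taxa mismatch between alignment and tree")
  list(n_nodes = n_nodes, root = root, children = children,
       postorder = ord, parent = parent, tip_row = tip_row)
}

#' Per-draw ages of a clade from a posterior sample
#'
#' Returns one age per retained MCMC draw for the crown or total-group node
#' of a clade, in Ma.
#'
#' @param posterior a `chrono_posterior` from [run_chain()].
#' @param clade a [clade_ref].
#' @export
clade_ages <- function(posterior, clade) {
  nd <- clade_node(posterior$tree, clade)
  col <- paste0("n", nd)
  if (!col %in% colnames(posterior$ages))
    stop("node ", nd, " not sampled (is it a tip?)")
  posterior$ages[, col]
}
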