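# Unrooted tree utilities. Trees are ape "phylo" objects treated as unrooted;
# support values live in phy$node.label (the common newick dialect where an
# internal node label carries the support of its parent edge).

#' Parse a newick string or file into an unrooted tree
#'
#' Internal node labels are interpreted as percent support values where
#' numeric.
#'
#' @param text A newick string (must contain "(") or a file path.
#' @return An ape `phylo` object.
#' @export
parse_newick <- function(text) {
  phy <- if (grepl("\\(", text)) ape::read.tree(text = text) else ape::read.tree(text)
  if (is.null(phy)) stop("newick parse error")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels in newick input")
  phy
}

#' Serialise a tree to newick
#'
#' @param tree A `phylo`.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Per-edge support values of a tree
#'
#' @param tree A `phylo` with node labels carrying support.
#' @return Numeric vector over internal nodes (NA where unlabelled).
#' @export
tree_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

n_tips <- function(tree) length(tree$tip.label)

#' Resolution of an unrooted tree
#'
#' The number of internal vertices divided by N - 2 (a binary unrooted tree
#' on N tips has N - 2 internal vertices, hence resolution 1).
#'
#' @param tree A `phylo`, treated as unrooted.
#' @return A fraction in (0, 1].
#' @export
resolution <- function(tree) {
  n <- n_tips(tree)
  if (n < 3L) stop("resolution is undefined for fewer than 3 tips")
  tree <- ape::unroot(tree)
  tree$Nnode / (n - 2)
}

#' Nontrivial splits of an unrooted tree
#'
#' @param tree A `phylo`.
#' @param tip_order Tip label order for the columns (default: sorted labels).
#' @return Logical matrix (splits x tips), canonicalised so the first column
#'   is always `FALSE`; trivial splits excluded. Attribute `support` carries
#'   per-split support when node labels are numeric.
#' @export
tree_splits <- function(tree, tip_order = sort(tree$tip.label)) {
  # splits are read off the tree as given (without unrooting) so that a
  # support label sitting on either side of the root edge is preserved;
  # duplicate splits arising from a degree-2 root are merged
  n <- n_tips(tree)
  stopifnot(setequal(tip_order, tree$tip.label))
  desc <- tip_descendants(tree)
  sup <- tree_support(tree)
  rows <- list(); supp <- numeric(0)
  root <- n + 1L
  for (nd in seq_len(tree$Nnode)) {
    node <- n + nd
    if (node == root) next
    side <- logical(n)
    side[desc[[node]]] <- TRUE
    sz <- sum(side)
    if (sz <= 1L || sz >= n - 1L) next
    rows[[length(rows) + 1L]] <- side
    supp <- c(supp, sup[nd])
  }
  if (length(rows) == 0L) {
    m <- matrix(logical(0), 0L, n, dimnames = list(NULL, tip_order))
    attr(m, "support") <- numeric(0)
    return(m)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- tree$tip.label
  m <- m[, tip_order, drop = FALSE]
  flip <- m[, 1L]
  m[flip, ] <- !m[flip, , drop = FALSE]
  keys <- split_keys(m)
  keep <- !duplicated(keys)
  merged_sup <- vapply(keys[keep], function(k) {
    vals <- supp[keys == k]
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }, 0)
  m <- m[keep, , drop = FALSE]
  attr(m, "support") <- unname(merged_sup)
  m
}

split_keys <- function(m) apply(m, 1L, function(r) paste(as.integer(r), collapse = ""))

# tips (integer ids) below each node in the rooted representation
tip_descendants <- function(tree) {
  n <- n_tips(tree)
  total <- n + tree$Nnode
  desc <- vector("list", total)
  for (i in seq_len(n)) desc[[i]] <- i
  edges <- tree$edge
  # postorder: process edges so children come before parents
  ord <- rev(postorder_nodes(tree))
  for (node in ord) {
    if (node <= n) next
    kids <- edges[edges[, 1] == node, 2]
    desc[[node]] <- sort(unlist(desc[kids]))
  }
  desc
}

# nodes in an order where parents precede children (preorder from root)
postorder_nodes <- function(tree) {
  n <- n_tips(tree)
  root <- n + 1L
  edges <- tree$edge
  out <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, node)
    stack <- c(stack, edges[edges[, 1] == node, 2])
  }
  out
}

# two splits (logical vectors) are compatible iff one of the four pairwise
# side intersections is empty
splits_compatible <- function(a, b) {
  !(any(a & b) && any(a & !b) && any(!a & b) && any(!a & !b))
}

#' Collapse weakly supported branches
#'
#' Contracts every internal edge whose support is below `threshold`
#' (missing support counts as 0, with a warning).
#'
#' @param tree A `phylo` with support in its node labels.
#' @param threshold Percent support below which edges are collapsed.
#' @return The collapsed `phylo`.
#' @export
collapse_by_support <- function(tree, threshold) {
  splits <- tree_splits(tree)
  ssup <- attr(splits, "support")
  if (any(is.na(ssup))) {
    warning("internal edges without support treated as 0")
    ssup[is.na(ssup)] <- 0
  }
  keep <- ssup >= threshold
  tree_from_splits(splits[keep, , drop = FALSE],
                         support = ssup[keep],
                         tip_labels = colnames(splits))
}

#' Restrict a tree to a species subset
#'
#' Induced subtree with degree-2 vertices suppressed.
#'
#' @param tree A `phylo`.
#' @param species Character vector, subset of the tip labels.
#' @return The restricted `phylo`.
#' @export
restrict_tree <- function(tree, species) {
  if (length(species) == 0L) stop("empty species set")
  stopifnot(all(species %in% tree$tip.label))
  if (setequal(species, tree$tip.label)) return(tree)
  ape::unroot(ape::keep.tip(tree, species))
}

#' Uniform sequential-addition random topology
#'
#' Builds a binary unrooted tree by adding tips in order, each attached to an
#' edge drawn uniformly at random. Used as the null model for the
#' topological-accuracy statistic.
#'
#' @param tip_labels Character vector (>= 3).
#' @param seed Optional integer seed (local to this call).
#' @return A binary unrooted `phylo`.
#' @export
random_topology <- function(tip_labels, seed = NULL) {
  n <- length(tip_labels)
  if (n < 3L) stop("need at least 3 tips")
  with_local_seed(seed, {
    # adjacency over ids: tips 1..n, internals n+1..2n-2
    total <- 2L * n - 2L
    adj <- vector("list", total)
    v <- n + 1L           # first internal node: star on tips 1..3
    adj[[v]] <- c(1L, 2L, 3L)
    adj[[1L]] <- v; adj[[2L]] <- v; adj[[3L]] <- v
    edges <- rbind(c(1L, v), c(2L, v), c(3L, v))
    next_internal <- n + 2L
    for (tip in seq(4L, length.out = n - 3L)) {
      e <- sample.int(nrow(edges), 1L)
      a <- edges[e, 1L]; b <- edges[e, 2L]
      w <- next_internal; next_internal <- next_internal + 1L
      adj[[a]] <- c(setdiff(adj[[a]], b), w)
      adj[[b]] <- c(setdiff(adj[[b]], a), w)
      adj[[w]] <- c(a, b, tip)
      adj[[tip]] <- w
      edges <- rbind(edges[-e, , drop = FALSE], c(a, w), c(b, w), c(tip, w))
    }
    adj_to_phylo(adj, tip_labels)
  })
}

#' Majority-rule consensus of trees
#'
#' Contains exactly the nontrivial splits whose frequency across the input
#' trees is at least `threshold`; split frequencies (in percent) are recorded
#' as support.
#'
#' @param trees List of `phylo` objects on the same tip set.
#' @param threshold Frequency threshold (default 0.70, the conventional
#'   bootstrap support cut-off).
#' @return A `phylo` with support node labels.
#' @export
majority_consensus <- function(trees, threshold = 0.70) {
  stopifnot(length(trees) >= 1L)
  tips <- sort(trees[[1]]$tip.label)
  counts <- new.env(parent = emptyenv())
  masks <- list()
  for (tr in trees) {
    if (!setequal(tr$tip.label, tips)) stop("trees have inconsistent tip sets")
    sp <- tree_splits(tr, tip_order = tips)
    for (key in split_keys(sp)) {
      cur <- counts[[key]] %||% 0L
      counts[[key]] <- cur + 1L
      if (cur == 0L) masks[[key]] <- sp[match(key, split_keys(sp)), ]
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]] / length(trees), 0)
  sel <- keys[freq >= threshold]
  m <- if (length(sel) > 0L) do.call(rbind, masks[sel]) else
    matrix(logical(0), 0L, length(tips))
  colnames(m) <- tips
  tree_from_splits(m, support = 100 * freq[match(sel, keys)],
                   tip_labels = tips)
}

#' Build an unrooted tree from a compatible split set
#'
#' Constructs the (unique, minimally resolved) unrooted tree containing
#' exactly the given pairwise-compatible nontrivial splits. Splits are given
#' as a logical matrix (splits x tips) canonicalised so the first column is
#' `FALSE`, the format produced by [tree_splits()].
#'
#' @param splits Logical split matrix.
#' @param support Optional per-split support values (percent).
#' @param tip_labels Tip labels, in the column order of `splits`.
#' @return A `phylo`.
#' @export
tree_from_splits <- function(splits, support = NULL, tip_labels) {
  n <- length(tip_labels)
  nsp <- nrow(splits)
  if (nsp > 1L) for (i in seq_len(nsp - 1L)) for (j in seq(i + 1L, nsp)) {
    if (!splits_compatible(splits[i, ], splits[j, ]))
      stop("split set is not pairwise compatible")
  }
  # clades = TRUE sides (tip 1 is FALSE by canonicalisation), laminar family
  sizes <- if (nsp > 0L) rowSums(splits) else integer(0)
  ord <- order(sizes, decreasing = TRUE)  # parents created before children
  total <- n + 1L + nsp
  adj <- vector("list", total)
  root <- n + 1L
  node_of_clade <- integer(nsp)
  node_support_old <- rep(NA_real_, total)
  for (idx in seq_along(ord)) {
    i <- ord[idx]
    node <- n + 1L + idx
    node_of_clade[i] <- node
    if (!is.null(support)) node_support_old[node] <- support[i]
    par <- root; best <- n + 1L
    for (jdx in seq_len(idx - 1L)) {
      j <- ord[jdx]
      contains <- all(splits[j, ] | !splits[i, ])  # C_i subset of C_j
      if (contains && sizes[j] < best) { par <- node_of_clade[j]; best <- sizes[j] }
    }
    adj[[par]] <- c(adj[[par]], node)
    adj[[node]] <- c(adj[[node]], par)
  }
  # attach tips to the smallest clade containing them (or the root)
  for (tip in seq_len(n)) {
    par <- root; best <- n + 1L
    for (i in seq_len(nsp)) {
      if (splits[i, tip] && sizes[i] < best) { par <- node_of_clade[i]; best <- sizes[i] }
    }
    adj[[par]] <- c(adj[[par]], tip)
    adj[[tip]] <- par
  }
  phy <- adj_to_phylo(adj, tip_labels, node_support = node_support_old)
  ape::unroot(phy)
}

# ---- adjacency <-> phylo conversion ------------------------------------

# phylo -> adjacency list (ids: tips 1..n, internals per ape numbering)
tree_adjacency <- function(tree) {
  tree <- ape::unroot(tree)
  total <- n_tips(tree) + tree$Nnode
  adj <- vector("list", total)
  for (r in seq_len(nrow(tree$edge))) {
    a <- tree$edge[r, 1]; b <- tree$edge[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# adjacency list -> phylo. By default tips are ids 1..n in label order;
# arbitrary tip ids can be given via tip_ids. Internal nodes are renumbered
# in DFS preorder. Optional node_support is indexed by old node id and
# carried through the renumbering.
adj_to_phylo <- function(adj, tip_labels, node_support = NULL,
                         tip_ids = seq_along(tip_labels)) {
  n <- length(tip_labels)
  is_tip <- logical(length(adj))
  is_tip[tip_ids] <- TRUE
  old_internal <- which(!is_tip & lengths(adj) > 0L)
  n_int <- length(old_internal)
  if (n_int == 0L) stop("adjacency has no internal node")
  root_old <- old_internal[1L]
  newid <- integer(length(adj))
  newid[tip_ids] <- seq_len(n)
  nxt <- n + 1L
  edges <- matrix(0L, 0L, 2L)
  sup <- rep(NA_real_, n_int)
  # iterative DFS from root
  stack_node <- root_old; stack_parent <- 0L
  while (length(stack_node) > 0L) {
    i <- length(stack_node)
    node <- stack_node[i]; par <- stack_parent[i]
    stack_node <- stack_node[-i]; stack_parent <- stack_parent[-i]
    newid[node] <- nxt
    if (!is.null(node_support)) sup[nxt - n] <- node_support[node]
    nxt <- nxt + 1L
    if (par != 0L) edges <- rbind(edges, c(newid[par], newid[node]))
    kids <- setdiff(adj[[node]], par)
    for (kid in rev(kids)) {
      if (is_tip[kid]) {
        edges <- rbind(edges, c(newid[node], newid[kid]))
      } else {
        stack_node <- c(stack_node, kid)
        stack_parent <- c(stack_parent, node)
      }
    }
  }
  phy <- list(edge = edges, Nnode = n_int, tip.label = tip_labels)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  if (!is.null(node_support) && any(!is.na(sup))) {
    phy$node.label <- ifelse(is.na(sup), "", format_support(sup))
  }
  phy <- reorder_safe(phy)
  phy
}

format_support <- function(x) {
  out <- character(length(x))
  out[!is.na(x)] <- formatC(x[!is.na(x)], format = "fg")
  out
}

reorder_safe <- function(phy) {
  out <- tryCatch(stats::reorder(phy, "cladewise"), error = function(e) phy)
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
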