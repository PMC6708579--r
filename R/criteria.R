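# Tree scoring under the native optimality criteria. All criteria accept a
# fixed (binary or multifurcating) unrooted topology whose tips are a subset
# of the dataset's species.

#' Criterion score container
#'
#' @param criterion Criterion name.
#' @param value Scalar score (summed squared change, summed Manhattan change,
#'   summed Euclidean displacement, or log-likelihood).
#' @param ancestral_states Optional internal-node reconstructions.
#' @param branch_lengths Optional per-edge lengths (criterion units).
#' @param extra Free-form extras (iteration traces etc.).
#' @return An object of class `criterion_score`.
#' @export
criterion_score <- function(criterion, value, ancestral_states = NULL,
                            branch_lengths = NULL, extra = list()) {
  structure(list(criterion = criterion, value = value,
                 ancestral_states = ancestral_states,
                 branch_lengths = branch_lengths, extra = extra),
            class = "criterion_score")
}

#' @export
print.criterion_score <- function(x, ...) {
  cat(sprintf("<criterion_score> %s: %.6g\n", x$criterion, x$value))
  invisible(x)
}

# tip data for a tree: rows in tree tip order, columns = flattened coords
tip_matrix <- function(tree, dataset) {
  missing <- setdiff(tree$tip.label, dataset$species)
  if (length(missing) > 0L)
    stop(sprintf("tips without landmark data: %s", paste(missing, collapse = ", ")))
  dataset_flat(dataset)[tree$tip.label, , drop = FALSE]
}

#' Squared-change parsimony score
#'
#' The global minimum over ancestral configurations of the sum of squared
#' coordinate changes over all edges, with unit branch lengths (unweighted
#' squared-change parsimony). Solved exactly through the normal equations of
#' the quadratic problem (graph Laplacian linear system), jointly for all
#' coordinates.
#'
#' @param tree Unrooted `phylo` (binary or multifurcating).
#' @param dataset A [landmark_dataset()].
#' @return A `criterion_score` with ancestral states attached.
#' @export
scp_score <- function(tree, dataset) {
  tree <- ape::unroot(tree)
  X <- tip_matrix(tree, dataset)
  n <- n_tips(tree)
  total <- n + tree$Nnode
  edges <- tree$edge
  if (tree$Nnode == 0L) stop("degenerate tree")
  # Laplacian with unit edge weights
  L <- matrix(0, total, total)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    L[a, a] <- L[a, a] + 1; L[b, b] <- L[b, b] + 1
    L[a, b] <- L[a, b] - 1; L[b, a] <- L[b, a] - 1
  }
  intern <- seq(n + 1L, total)
  A <- solve(L[intern, intern, drop = FALSE],
             -L[intern, seq_len(n), drop = FALSE] %*% X)
  states <- rbind(X, A)
  diffs <- states[edges[, 1], , drop = FALSE] - states[edges[, 2], , drop = FALSE]
  elen <- rowSums(diffs^2)
  criterion_score("scp", sum(elen), ancestral_states = A,
                  branch_lengths = elen)
}

#' Linear (Farris) parsimony score
#'
#' Treats every coordinate as an independent continuous character and sums
#' the minimal total absolute change over the tree. Binary trees use the
#' exact interval down-pass (intersection of child intervals, or the gap
#' between them with the gap length added); multifurcating trees fall back to
#' an exact dynamic programme over the per-coordinate tip-value state set.
#'
#' @param tree Unrooted `phylo`.
#' @param dataset A [landmark_dataset()].
#' @return A `criterion_score`.
#' @export
linear_parsimony_score <- function(tree, dataset) {
  tree <- ape::unroot(tree)
  X <- tip_matrix(tree, dataset)
  if (is_binary_unrooted(tree)) {
    val <- lp_interval_score(tree, X)
  } else {
    val <- sum(vapply(seq_len(ncol(X)), function(j) lp_sankoff_1d(tree, X[, j]), 0))
  }
  criterion_score("linear_parsimony", val)
}

is_binary_unrooted <- function(tree) {
  n <- n_tips(tree)
  if (n < 4L) return(tree$Nnode == max(1L, n - 2L))
  tree$Nnode == n - 2L
}

# Farris interval down-pass, vectorised over characters. The unrooted binary
# tree is rooted on the edge next to tip 1 so that every internal node of the
# traversal has exactly two children.
lp_interval_score <- function(tree, X) {
  n <- n_tips(tree)
  if (n == 2L) return(sum(abs(X[1, ] - X[2, ])))
  rooted <- root_on_tip_edge(tree)
  m <- ncol(X)
  total <- rooted$n_nodes
  lo <- matrix(NA_real_, total, m)
  hi <- matrix(NA_real_, total, m)
  lo[seq_len(n), ] <- X
  hi[seq_len(n), ] <- X
  cost <- numeric(m)
  for (node in rooted$postorder) {
    kids <- rooted$children[[node]]
    l <- lo[kids[1], ]; h <- hi[kids[1], ]
    for (kid in kids[-1]) {
      l2 <- lo[kid, ]; h2 <- hi[kid, ]
      nl <- pmax(l, l2); nh <- pmin(h, h2)
      gap <- nl > nh
      cost <- cost + ifelse(gap, nl - nh, 0)
      l <- ifelse(gap, nh, nl)
      h <- ifelse(gap, nl, nh)
    }
    lo[node, ] <- l; hi[node, ] <- h
  }
  sum(cost)
}

# exact single-character L1 parsimony by Sankoff DP over tip-value states
# (for L1 costs an optimal labelling exists with all ancestral values drawn
# from the tip values)
lp_sankoff_1d <- function(tree, x) {
  states <- sort(unique(x))
  s <- length(states)
  if (s == 1L) return(0)
  n <- n_tips(tree)
  rooted <- root_at_internal(tree)
  total <- rooted$n_nodes
  cost <- matrix(0, total, s)
  for (tip in seq_len(n)) cost[tip, ] <- ifelse(states == x[tip], 0, Inf)
  D <- abs(outer(states, states, `-`))
  for (node in rooted$postorder) {
    acc <- numeric(s)
    for (kid in rooted$children[[node]]) {
      acc <- acc + apply(D + matrix(cost[kid, ], s, s, byrow = TRUE), 1L, min)
    }
    cost[node, ] <- acc
  }
  min(cost[rooted$root, ])
}

# ---- rooted traversal helpers ------------------------------------------

# root the unrooted tree at its ape root node (n+1); children lists and a
# postorder over internal nodes (children before parents)
root_at_internal <- function(tree) {
  n <- n_tips(tree)
  total <- n + tree$Nnode
  children <- vector("list", total)
  edges <- tree$edge
  for (r in seq_len(nrow(edges)))
    children[[edges[r, 1]]] <- c(children[[edges[r, 1]]], edges[r, 2])
  pre <- postorder_nodes(tree)           # parents before children
  internals <- pre[pre > n]
  list(root = n + 1L, children = children, postorder = rev(internals),
       n_nodes = total)
}

# root the unrooted binary tree on the edge adjacent to tip 1, so every
# traversal-internal node has exactly two children; the "root" is a virtual
# node whose two children are tip 1 and the rest of the tree.
root_on_tip_edge <- function(tree) {
  n <- n_tips(tree)
  adj <- tree_adjacency(tree)
  total <- length(adj) + 1L
  virtual <- total
  u <- adj[[1L]]                          # internal neighbour of tip 1
  children <- vector("list", total)
  children[[virtual]] <- c(1L, u)
  post <- integer(0)
  # DFS from u with parent "tip 1 side"
  stack_node <- u; stack_parent <- 1L
  order_nodes <- integer(0)
  parent_of <- integer(length(adj)); parent_of[u] <- virtual
  while (length(stack_node) > 0L) {
    i <- length(stack_node)
    node <- stack_node[i]; par <- stack_parent[i]
    stack_node <- stack_node[-i]; stack_parent <- stack_parent[-i]
    kids <- setdiff(adj[[node]], par)
    children[[node]] <- kids
    if (node > n) order_nodes <- c(order_nodes, node)
    for (kid in kids) {
      if (kid > n) { stack_node <- c(stack_node, kid); stack_parent <- c(stack_parent, node) }
    }
  }
  list(root = virtual, children = children,
       postorder = c(rev(order_nodes), virtual), n_nodes = total)
}
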