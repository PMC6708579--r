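#' Brownian-motion maximum likelihood score of a tree
#'
#' Treats every superposed coordinate as an independent character evolving by
#' Brownian motion with common rate 1 (the rate scale is absorbed into the
#' branch lengths). The restricted (contrast-based) log-likelihood is computed
#' by pruning and maximised over all branch lengths on the log scale with
#' L-BFGS-B. Binary unrooted trees only; zero-variance characters are dropped
#' with a warning.
#'
#' @param tree Binary unrooted `phylo`.
#' @param dataset A [landmark_dataset()].
#' @param init Optional initial branch lengths (edge order of the internally
#'   rooted tree); defaults to a crude Procrustes-distance-based guess.
#' @param control Passed to [stats::optim()].
#' @return A `criterion_score` with the maximised log-likelihood as value and
#'   the fitted branch lengths attached.
#' @export
brownian_ml <- function(tree, dataset, init = NULL,
                        control = list(maxit = 200L)) {
  X <- tip_matrix(tree, dataset)
  keep <- apply(X, 2L, function(v) stats::var(v) > 0)
  if (!all(keep)) {
    warning(sprintf("%d zero-variance characters dropped", sum(!keep)))
    X <- X[, keep, drop = FALSE]
  }
  n <- nrow(X)
  if (n == 2L) {
    # single edge: closed form, v-hat = ||d||^2 / k
    d2 <- sum((X[1, ] - X[2, ])^2)
    k <- ncol(X)
    v <- max(d2 / k, 1e-12)
    ll <- -0.5 * (k * log(2 * pi * v) + d2 / v)
    return(criterion_score("brownian_ml", ll, branch_lengths = v))
  }
  tree <- ape::unroot(tree)
  if (!is_binary_unrooted(tree))
    stop("brownian_ml requires a binary unrooted tree")
  rooted <- root_on_tip_edge(tree)
  ne <- 2L * n - 3L
  edge_ids <- rooted_edge_index(rooted, n)
  if (is.null(init)) {
    # crude start: mean squared character difference between a tip pair,
    # spread evenly over the edges
    scale0 <- max(mean((X[1, ] - X[2, ])^2), 1e-6)
    init <- rep(scale0, ne)
  }
  negll <- function(theta) {
    v <- exp(theta)
    -contrast_loglik(rooted, X, v, edge_ids, n)
  }
  fit <- stats::optim(log(init), negll, method = "L-BFGS-B",
                      lower = log(1e-10), upper = log(1e6), control = control)
  v <- exp(fit$par)
  criterion_score("brownian_ml", -fit$value, branch_lengths = v,
                  extra = list(convergence = fit$convergence))
}

# Map each (parent -> child) relation of the rooted traversal to a branch
# length slot. The two root children share the root edge of the unrooted
# tree: the edge is assigned to the non-tip child and the tip child gets
# length 0 (only the sum is identifiable).
rooted_edge_index <- function(rooted, n) {
  total <- rooted$n_nodes
  idx <- integer(total)        # edge slot for the branch above each node
  kids <- rooted$children[[rooted$root]]
  tipkid <- kids[kids <= n][1] # shares the root edge: length fixed at 0
  slot <- 0L
  for (node in seq_len(total)) {
    if (node == rooted$root || node == tipkid) next
    slot <- slot + 1L
    idx[node] <- slot
  }
  idx
}

# REML (contrast) log-likelihood via pruning: each internal node combines its
# two children; every combination contributes one multivariate contrast.
contrast_loglik <- function(rooted, X, v, edge_ids, n) {
  k <- ncol(X)
  total <- rooted$n_nodes
  xhat <- matrix(NA_real_, total, k)
  delta <- numeric(total)
  xhat[seq_len(n), ] <- X
  vlen <- function(node) if (edge_ids[node] == 0L) 0 else v[edge_ids[node]]
  ll <- 0
  for (node in rooted$postorder) {
    kids <- rooted$children[[node]]
    a <- kids[1]; b <- kids[2]
    va <- vlen(a) + delta[a]
    vb <- vlen(b) + delta[b]
    s <- va + vb
    if (s <= 0) s <- 1e-12
    d <- xhat[a, ] - xhat[b, ]
    ll <- ll - 0.5 * (k * log(2 * pi * s) + sum(d^2) / s)
    if (va <= 0) {
      xhat[node, ] <- xhat[a, ]; delta[node] <- 0
    } else if (vb <= 0) {
      xhat[node, ] <- xhat[b, ]; delta[node] <- 0
    } else {
      xhat[node, ] <- (xhat[a, ] / va + xhat[b, ] / vb) / (1 / va + 1 / vb)
      delta[node] <- va * vb / s
    }
  }
  ll
}
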