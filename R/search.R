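# Heuristic tree searches. Rearrangements are performed by surgery on an
# adjacency-list representation of the unrooted tree; scoring is delegated to
# the criterion functions.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via ape) with negative branch lengths clamped
#' to zero.
#'
#' @param d Symmetric zero-diagonal distance matrix with row/col names.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(is.na(d))) stop("distance matrix contains NA")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  phy <- ape::nj(stats::as.dist(d))
  if (any(phy$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  ape::unroot(phy)
}

# ---- rearrangement neighbourhoods --------------------------------------

internal_edges <- function(adj, is_tip) {
  out <- matrix(0L, 0L, 2L)
  for (u in which(!is_tip & lengths(adj) > 0L)) {
    for (v in adj[[u]]) if (!is_tip[v] && u < v) out <- rbind(out, c(u, v))
  }
  out
}

all_edges <- function(adj) {
  out <- matrix(0L, 0L, 2L)
  for (u in which(lengths(adj) > 0L)) {
    for (v in adj[[u]]) if (u < v) out <- rbind(out, c(u, v))
  }
  out
}

phylo_to_surgery <- function(tree) {
  tree <- ape::unroot(tree)
  adj <- tree_adjacency(tree)
  n <- n_tips(tree)
  list(adj = adj, n = n, labels = tree$tip.label,
       is_tip = seq_along(adj) <= n)
}

surgery_to_phylo <- function(s) {
  adj_to_phylo(s$adj, s$labels, tip_ids = seq_len(s$n))
}

replace_adj <- function(s, adj) {
  s$adj <- adj
  s
}

adj_drop_edge <- function(adj, u, v) {
  adj[[u]] <- setdiff(adj[[u]], v)
  adj[[v]] <- setdiff(adj[[v]], u)
  adj
}

adj_add_edge <- function(adj, u, v) {
  adj[[u]] <- c(adj[[u]], v)
  adj[[v]] <- c(adj[[v]], u)
  adj
}

# suppress a degree-2 vertex, returning the new direct edge
adj_suppress <- function(adj, u) {
  nb <- adj[[u]]
  stopifnot(length(nb) == 2L)
  adj <- adj_drop_edge(adj, u, nb[1])
  adj <- adj_drop_edge(adj, u, nb[2])
  adj <- adj_add_edge(adj, nb[1], nb[2])
  list(adj = adj, edge = nb)
}

#' All nearest-neighbour-interchange neighbours of a tree
#'
#' @param tree Binary unrooted `phylo`.
#' @return List of `phylo` objects (two per internal edge).
#' @export
nni_neighbours <- function(tree) {
  s <- phylo_to_surgery(tree)
  ie <- internal_edges(s$adj, s$is_tip)
  out <- list()
  for (r in seq_len(nrow(ie))) {
    u <- ie[r, 1]; v <- ie[r, 2]
    bs <- setdiff(s$adj[[u]], v)
    cs <- setdiff(s$adj[[v]], u)
    for (cc in cs) {
      b <- bs[1]
      adj <- s$adj
      adj <- adj_drop_edge(adj, u, b)
      adj <- adj_drop_edge(adj, v, cc)
      adj <- adj_add_edge(adj, u, cc)
      adj <- adj_add_edge(adj, v, b)
      out[[length(out) + 1L]] <- surgery_to_phylo(replace_adj(s, adj))
    }
  }
  out
}

# component of `start` in adj with the edge (start, blocked) removed
reach_component <- function(adj, start, blocked) {
  seen <- integer(0)
  stack <- start
  prev <- blocked
  visited <- logical(length(adj))
  visited[blocked] <- TRUE
  stack <- start
  while (length(stack) > 0L) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (visited[node]) next
    visited[node] <- TRUE
    seen <- c(seen, node)
    stack <- c(stack, adj[[node]])
  }
  seen
}

#' All subtree-pruning-and-regrafting neighbours of a tree
#'
#' @param tree Binary unrooted `phylo`.
#' @return List of `phylo` objects.
#' @export
spr_neighbours <- function(tree) {
  s <- phylo_to_surgery(tree)
  out <- list()
  edges <- all_edges(s$adj)
  for (r in seq_len(nrow(edges))) {
    for (dir in 1:2) {
      u <- edges[r, dir]; v <- edges[r, 3 - dir]   # prune v-side subtree
      if (s$is_tip[u]) next                         # u must be internal
      adj0 <- adj_drop_edge(s$adj, u, v)
      sup <- adj_suppress(adj0, u)
      adj0 <- sup$adj
      rest <- reach_component(adj0, sup$edge[1], 0L)
      rest_edges <- all_edges_within(adj0, rest)
      for (rr in seq_len(nrow(rest_edges))) {
        x <- rest_edges[rr, 1]; y <- rest_edges[rr, 2]
        if ((x == sup$edge[1] && y == sup$edge[2]) ||
            (x == sup$edge[2] && y == sup$edge[1])) next  # original position
        adj1 <- adj_drop_edge(adj0, x, y)
        adj1 <- adj_add_edge(adj1, x, u)
        adj1 <- adj_add_edge(adj1, y, u)
        adj1 <- adj_add_edge(adj1, u, v)
        out[[length(out) + 1L]] <- surgery_to_phylo(replace_adj(s, adj1))
      }
    }
  }
  out
}

all_edges_within <- function(adj, nodes) {
  out <- matrix(0L, 0L, 2L)
  inset <- logical(length(adj)); inset[nodes] <- TRUE
  for (u in nodes) for (v in adj[[u]]) if (inset[v] && u < v) out <- rbind(out, c(u, v))
  out
}

#' All tree-bisection-and-reconnection neighbours of a tree
#'
#' Every internal edge is cut, the cut ends are suppressed, and the two parts
#' are reconnected across every pair of their edges.
#'
#' @param tree Binary unrooted `phylo`.
#' @return List of `phylo` objects (includes the SPR neighbourhood).
#' @export
tbr_neighbours <- function(tree) {
  s <- phylo_to_surgery(tree)
  out <- spr_neighbours(tree)        # covers pendant-edge prunes
  ie <- internal_edges(s$adj, s$is_tip)
  for (r in seq_len(nrow(ie))) {
    u <- ie[r, 1]; v <- ie[r, 2]
    adj0 <- adj_drop_edge(s$adj, u, v)
    supu <- adj_suppress(adj0, u); adj0 <- supu$adj
    supv <- adj_suppress(adj0, v); adj0 <- supv$adj
    compA <- reach_component(adj0, supu$edge[1], 0L)
    edgesA <- all_edges_within(adj0, compA)
    compB <- reach_component(adj0, supv$edge[1], 0L)
    edgesB <- all_edges_within(adj0, compB)
    for (ra in seq_len(nrow(edgesA))) for (rb in seq_len(nrow(edgesB))) {
      ea <- edgesA[ra, ]; eb <- edgesB[rb, ]
      same_a <- setequal(ea, supu$edge); same_b <- setequal(eb, supv$edge)
      if (same_a && same_b) next     # reconstructs the original tree
      adj1 <- adj_drop_edge(adj0, ea[1], ea[2])
      adj1 <- adj_add_edge(adj1, ea[1], u); adj1 <- adj_add_edge(adj1, ea[2], u)
      adj1 <- adj_drop_edge(adj1, eb[1], eb[2])
      adj1 <- adj_add_edge(adj1, eb[1], v); adj1 <- adj_add_edge(adj1, eb[2], v)
      adj1 <- adj_add_edge(adj1, u, v)
      out[[length(out) + 1L]] <- surgery_to_phylo(replace_adj(s, adj1))
    }
  }
  out
}

move_neighbourhood <- function(tree, move_set) {
  moves <- list()
  if ("TBR" %in% move_set) return(tbr_neighbours(tree))
  if ("SPR" %in% move_set) moves <- c(moves, spr_neighbours(tree))
  if ("NNI" %in% move_set && !("SPR" %in% move_set))
    moves <- c(moves, nni_neighbours(tree))
  moves
}

# ---- criterion scorers --------------------------------------------------

#' Build a minimising scorer for a criterion
#'
#' Returns `function(tree) -> value` where smaller is always better
#' (log-likelihoods are negated).
#'
#' @param dataset A [landmark_dataset()].
#' @param criterion One of `"scp"`, `"lp"`, `"laup"`, `"ml"`.
#' @param grid [grid_spec()] for `"laup"`.
#' @param ml_control Control list for [brownian_ml()].
#' @return A scoring closure.
#' @export
criterion_scorer <- function(dataset, criterion = c("scp", "lp", "laup", "ml"),
                             grid = grid_spec(), ml_control = list(maxit = 100L)) {
  criterion <- match.arg(criterion)
  switch(criterion,
    scp = function(tree) scp_score(tree, dataset)$value,
    lp = function(tree) linear_parsimony_score(tree, dataset)$value,
    laup = function(tree) laup_score(tree, dataset, grid)$value,
    ml = function(tree) -brownian_ml(tree, dataset, control = ml_control)$value)
}

#' Search settings
#'
#' @param n_random_addition Number of random addition sequences.
#' @param move_set Rearrangements for hill climbing (subset of NNI/SPR/TBR).
#' @param keep_best Trees kept for the stochastic-perturbation stage.
#' @param stochastic_rounds Stochastic NNI perturbation restarts (0 = none).
#' @param seed Integer seed.
#' @param grid [grid_spec()] (spatial parsimony only).
#' @param ml_control Control list for the Brownian-ML optimiser.
#' @return An object of class `search_settings`.
#' @export
search_settings <- function(n_random_addition = 10L, move_set = c("SPR", "NNI"),
                            keep_best = 5L, stochastic_rounds = 0L, seed = 1L,
                            grid = grid_spec(), ml_control = list(maxit = 100L)) {
  stopifnot(n_random_addition >= 1L, keep_best >= 1L, stochastic_rounds >= 0L,
            all(move_set %in% c("NNI", "SPR", "TBR")))
  structure(list(n_random_addition = n_random_addition, move_set = move_set,
                 keep_best = keep_best, stochastic_rounds = stochastic_rounds,
                 seed = seed, grid = grid, ml_control = ml_control),
            class = "search_settings")
}

#' Random-addition-sequence starting tree
#'
#' Species are inserted in seeded random order, each on the edge minimising
#' the criterion score (first-encountered tie winner).
#'
#' @param dataset A [landmark_dataset()].
#' @param scorer A scoring closure from [criterion_scorer()] (or any
#'   `function(tree) -> value`, smaller better).
#' @param seed Integer seed.
#' @param species Optional subset/order pool (default: all dataset species).
#' @return A binary unrooted `phylo`.
#' @export
random_addition_tree <- function(dataset, scorer, seed = 1L,
                                 species = dataset$species) {
  n <- length(species)
  if (n < 3L) stop("need at least 3 species")
  with_local_seed(seed, {
    ord <- sample(species)
    tree <- star3(ord[1:3])
    for (i in seq(4L, length.out = n - 3L)) {
      cands <- attach_tip_everywhere(tree, ord[i])
      vals <- vapply(cands, scorer, 0)
      tree <- cands[[which.min(vals)]]
    }
    tree
  })
}

star3 <- function(labels) {
  adj <- vector("list", 4L)
  adj[[4L]] <- c(1L, 2L, 3L)
  adj[[1L]] <- 4L; adj[[2L]] <- 4L; adj[[3L]] <- 4L
  adj_to_phylo(adj, labels, tip_ids = 1:3)
}

# all trees obtained by attaching a new tip on each edge
attach_tip_everywhere <- function(tree, label) {
  s <- phylo_to_surgery(tree)
  total <- length(s$adj)
  edges <- all_edges(s$adj)
  newtip <- s$n + 1L
  out <- vector("list", nrow(edges))
  for (r in seq_len(nrow(edges))) {
    adj <- lapply(s$adj, function(x) ifelse(x > s$n, x + 1L, x))
    adj <- c(adj[seq_len(s$n)], list(integer(0)), adj[seq(s$n + 1L, total)])
    u <- shift_id(edges[r, 1], s$n); v <- shift_id(edges[r, 2], s$n)
    w <- total + 2L
    adj[[w]] <- integer(0)
    adj <- adj_drop_edge(adj, u, v)
    adj <- adj_add_edge(adj, u, w)
    adj <- adj_add_edge(adj, v, w)
    adj <- adj_add_edge(adj, newtip, w)
    out[[r]] <- adj_to_phylo(adj, c(s$labels, label), tip_ids = seq_len(newtip))
  }
  out
}

shift_id <- function(id, n) if (id > n) id + 1L else id

#' Hill-climbing rearrangement search
#'
#' First-improvement hill climb over the requested move neighbourhood, with a
#' seeded shuffle of the evaluation order, until no neighbour improves.
#'
#' @param start_tree Starting `phylo`.
#' @param scorer Scoring closure (smaller better).
#' @param move_set Subset of `c("NNI","SPR","TBR")`.
#' @param seed Integer seed for the evaluation order.
#' @param tol Minimal improvement accepted.
#' @return List with `tree`, `value` and the monotone `trace`.
#' @export
swap_search <- function(start_tree, scorer, move_set = "NNI", seed = 1L,
                        tol = 1e-9) {
  best <- ape::unroot(start_tree)
  best_val <- scorer(best)
  trace <- best_val
  with_local_seed(seed, {
    repeat {
      nbrs <- move_neighbourhood(best, move_set)
      if (length(nbrs) == 0L) break
      ord <- sample.int(length(nbrs))
      improved <- FALSE
      for (i in ord) {
        v <- scorer(nbrs[[i]])
        if (v < best_val - tol) {
          best <- nbrs[[i]]; best_val <- v
          trace <- c(trace, v)
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  })
  list(tree = best, value = best_val, trace = trace)
}

# apply r random NNI moves
perturb_nni <- function(tree, r = 2L) {
  for (i in seq_len(r)) {
    nbrs <- nni_neighbours(tree)
    tree <- nbrs[[sample.int(length(nbrs), 1L)]]
  }
  tree
}

# shared driver: RAS starts + hill climbs (+ optional stochastic NNI stage)
ras_swap_driver <- function(dataset, scorer, settings, move_sets,
                            start_tree = NULL) {
  pool <- list()
  for (i in seq_len(settings$n_random_addition)) {
    tr <- random_addition_tree(dataset, scorer, seed = settings$seed + i)
    val <- scorer(tr)
    for (ms in move_sets) {
      res <- swap_search(tr, scorer, move_set = ms, seed = settings$seed + i)
      tr <- res$tree; val <- res$value
    }
    pool[[i]] <- list(tree = tr, value = val)
  }
  if (!is.null(start_tree)) {
    tr <- ape::unroot(start_tree); val <- scorer(tr)
    for (ms in move_sets) {
      res <- swap_search(tr, scorer, move_set = ms, seed = settings$seed)
      tr <- res$tree; val <- res$value
    }
    pool[[length(pool) + 1L]] <- list(tree = tr, value = val)
  }
  vals <- vapply(pool, `[[`, 0, "value")
  ord <- order(vals)
  keep <- pool[ord[seq_len(min(settings$keep_best, length(pool)))]]
  best <- keep[[1]]
  if (settings$stochastic_rounds > 0L) {
    with_local_seed(settings$seed + 10000L, {
      for (round in seq_len(settings$stochastic_rounds)) {
        base <- keep[[1L + (round - 1L) %% length(keep)]]
        pert <- perturb_nni(base$tree, r = 2L)
        res <- swap_search(pert, scorer, move_set = "NNI",
                           seed = settings$seed + 20000L + round)
        if (res$value < best$value) best <- list(tree = res$tree, value = res$value)
      }
    })
  }
  best
}

#' Squared-change parsimony tree search
#'
#' Random addition sequences, each improved by SPR then NNI hill climbing,
#' followed by stochastic NNI perturbation restarts from the best trees.
#'
#' @param dataset A [landmark_dataset()].
#' @param settings A [search_settings()].
#' @return List with `tree` and `value`.
#' @export
scp_search <- function(dataset, settings = search_settings()) {
  scorer <- criterion_scorer(dataset, "scp")
  ras_swap_driver(dataset, scorer, settings,
                  move_sets = as.list(settings$move_set))
}

#' Linear parsimony tree search (RAS + TBR)
#'
#' @inheritParams scp_search
#' @return List with `tree` and `value`.
#' @export
lp_search <- function(dataset, settings = search_settings(move_set = "TBR")) {
  scorer <- criterion_scorer(dataset, "lp")
  ras_swap_driver(dataset, scorer, settings,
                  move_sets = as.list(settings$move_set))
}

#' Brownian maximum-likelihood tree search (RAS + SPR)
#'
#' @inheritParams scp_search
#' @return List with `tree` and `value` (`value` is the negated
#'   log-likelihood; `loglik` carries the log-likelihood).
#' @export
ml_search <- function(dataset, settings = search_settings()) {
  scorer <- criterion_scorer(dataset, "ml", ml_control = settings$ml_control)
  out <- ras_swap_driver(dataset, scorer, settings,
                         move_sets = as.list(settings$move_set))
  out$loglik <- -out$value
  out
}

#' Landmark-parsimony tree search
#'
#' `gpa` mode searches on the fixed superposition (RAS + TBR). `dynamic` mode
#' starts each restart from randomly rotated configurations, then alternates
#' dynamic alignment and TBR search until the same topology is found in two
#' successive iterations; an optional `start_tree` adds one further run. The
#' best tree by score is returned.
#'
#' @param dataset A [landmark_dataset()].
#' @param alignment_mode `"gpa"` or `"dynamic"`.
#' @param settings A [search_settings()] (`n_random_addition` doubles as the
#'   number of dynamic restarts).
#' @param start_tree Optional `phylo` used as an additional starting tree.
#' @return List with `tree`, `value` and (dynamic mode) the final aligned
#'   `dataset`.
#' @export
laup_search <- function(dataset, alignment_mode = c("gpa", "dynamic"),
                        settings = search_settings(move_set = "TBR"),
                        start_tree = NULL) {
  alignment_mode <- match.arg(alignment_mode)
  moves <- settings$move_set[1]
  if (alignment_mode == "gpa") {
    scorer <- criterion_scorer(dataset, "laup", grid = settings$grid)
    return(ras_swap_driver(dataset, scorer, settings,
                           move_sets = as.list(settings$move_set),
                           start_tree = start_tree))
  }
  best <- NULL
  runs <- seq_len(settings$n_random_addition)
  starts <- c(as.list(runs), if (!is.null(start_tree)) list(start_tree))
  for (ri in seq_along(starts)) {
    st <- starts[[ri]]
    run_seed <- settings$seed + 100L * ri
    data_i <- if (is.numeric(st)) random_rotation_start(dataset, run_seed) else dataset
    scorer <- criterion_scorer(data_i, "laup", grid = settings$grid)
    tree <- if (is.numeric(st)) {
      res0 <- swap_search(random_addition_tree(data_i, scorer, seed = run_seed),
                          scorer, move_set = moves, seed = run_seed)
      res0$tree
    } else ape::unroot(st)
    prev <- NULL
    val <- scorer(tree)
    for (it in seq_len(10L)) {
      al <- dynamic_align(data_i, tree, grid = settings$grid)
      data_i <- al$dataset
      scorer <- criterion_scorer(data_i, "laup", grid = settings$grid)
      res <- swap_search(tree, scorer, move_set = moves, seed = run_seed + it)
      val <- res$value
      if (!is.null(prev) && robinson_foulds(res$tree, prev) == 0L) {
        tree <- res$tree
        break
      }
      prev <- tree
      tree <- res$tree
    }
    if (is.null(best) || val < best$value)
      best <- list(tree = tree, value = val, dataset = data_i)
  }
  best
}

# apply an independent uniform random rotation to every configuration
random_rotation_start <- function(dataset, seed) {
  with_local_seed(seed, {
    data <- dataset$data
    k <- dataset$dims
    for (sp in dataset$species) {
      R <- random_rotation(k)
      data[sp, , ] <- matrix(data[sp, , ], dataset$n_landmarks, k) %*% R
    }
    landmark_dataset(dataset$name, data, dataset$blocks)
  })
}

random_rotation <- function(k) {
  q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
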