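#' Spatial grid specification for landmark parsimony
#'
#' @param divisions Subdivisions per axis of the search lattice (the lattice
#'   has `divisions + 1` points per non-degenerate axis).
#' @param nesting_levels Number of grid passes: 1 = the initial lattice over
#'   the observed bounding box; each further level re-runs the optimisation on
#'   a finer lattice around the incumbent position.
#' @param window_cells Half-width, in cells of the previous lattice, of the
#'   nested grid around the incumbent.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(divisions = 6L, nesting_levels = 2L, window_cells = 1L) {
  stopifnot(divisions >= 1L, nesting_levels >= 1L, window_cells >= 1L)
  structure(list(divisions = as.integer(divisions),
                 nesting_levels = as.integer(nesting_levels),
                 window_cells = as.integer(window_cells)),
            class = "grid_spec")
}

#' Landmark analysis under parsimony: tree score
#'
#' Scores a tree by the minimal summed Euclidean displacement of every
#' landmark between ancestor and descendant configurations, treating each
#' landmark (not each coordinate) as the optimisation unit. Candidate
#' ancestral positions are a lattice over the landmark's bounding box across
#' the terminals; the minimum over candidates is found exactly by dynamic
#' programming, and optional grid nesting refines the lattice around the
#' incumbent positions (the incumbent is kept among the candidates, so the
#' score never increases with an extra nesting level).
#'
#' @param tree Unrooted `phylo` (binary or multifurcating).
#' @param dataset A [landmark_dataset()].
#' @param grid A [grid_spec()].
#' @return A `criterion_score`; `ancestral_states` is an internal-nodes x
#'   landmarks x dims array.
#' @export
laup_score <- function(tree, dataset, grid = grid_spec()) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- n_tips(tree)
  k <- dataset$dims
  p <- dataset$n_landmarks
  if (n == 2L) {
    a <- matrix(dataset$data[tree$tip.label[1], , ], p, k)
    b <- matrix(dataset$data[tree$tip.label[2], , ], p, k)
    val <- sum(sqrt(rowSums((a - b)^2)))
    return(criterion_score("laup", val))
  }
  tree <- ape::unroot(tree)
  missing <- setdiff(tree$tip.label, dataset$species)
  if (length(missing) > 0L)
    stop(sprintf("tips without landmark data: %s", paste(missing, collapse = ", ")))
  rooted <- root_at_internal(tree)
  n_int <- tree$Nnode
  internals <- seq(n + 1L, n + n_int)
  children <- lapply(internals, function(nd) as.integer(rooted$children[[nd]]))
  postorder <- as.integer(rooted$postorder)
  total <- 0
  anc <- array(NA_real_, c(n_int, p, k))
  g <- grid$divisions
  for (l in seq_len(p)) {
    tips <- matrix(dataset$data[tree$tip.label, l, ], n, k)
    box_lo <- apply(tips, 2L, min)
    box_hi <- apply(tips, 2L, max)
    cell <- (box_hi - box_lo) / g
    cand0 <- lattice_points(box_lo, box_hi, g)
    cands <- rep(list(cand0), n_int)
    res <- laup_dp_landmark(tips, children, cands, postorder, n, rooted$root)
    best <- res$score
    chosen <- t(vapply(seq_len(n_int),
                       function(i) cands[[i]][res$choice[i], ], numeric(k)))
    if (grid$nesting_levels > 1L) {
      for (lev in seq(2L, grid$nesting_levels)) {
        half <- grid$window_cells * cell
        cands <- lapply(seq_len(n_int), function(i) {
          ctr <- chosen[i, ]
          rbind(lattice_points(ctr - half, ctr + half, g), ctr)
        })
        cell <- 2 * half / g
        res <- laup_dp_landmark(tips, children, cands, postorder, n, rooted$root)
        if (res$score <= best) {
          best <- res$score
          chosen <- t(vapply(seq_len(n_int),
                             function(i) cands[[i]][res$choice[i], ], numeric(k)))
        }
      }
    }
    total <- total + best
    anc[, l, ] <- chosen
  }
  criterion_score("laup", total, ancestral_states = anc)
}

# axis-aligned lattice with g subdivisions per axis; axes with zero extent
# collapse to a single coordinate
lattice_points <- function(lo, hi, g) {
  axes <- lapply(seq_along(lo), function(d) {
    if (hi[d] - lo[d] <= 0) lo[d] else seq(lo[d], hi[d], length.out = g + 1L)
  })
  as.matrix(do.call(expand.grid, axes))
}

#' Dynamic alignment of configurations to a tree
#'
#' Alternates landmark-parsimony ancestral reconstruction with a per-terminal
#' rigid rotation (about the centroid, no rescaling) that reduces the summed
#' Euclidean distance between the terminal and its reconstructed ancestor.
#' Rotations are accepted only when the tree score improves, so the score
#' trace is non-increasing.
#'
#' @param dataset A [landmark_dataset()].
#' @param tree Unrooted `phylo`.
#' @param grid A [grid_spec()].
#' @param tol Convergence tolerance on the score improvement.
#' @param max_iter Iteration cap.
#' @return A list with the realigned `dataset`, per-species accumulated
#'   `rotations`, the final `score` (a `criterion_score`), the score `trace`
#'   and a `converged` flag.
#' @export
dynamic_align <- function(dataset, tree, grid = grid_spec(),
                          tol = 1e-8, max_iter = 25L) {
  tree <- ape::unroot(tree)
  k <- dataset$dims
  rotations <- rep(list(diag(k)), length(dataset$species))
  names(rotations) <- dataset$species
  sc <- laup_score(tree, dataset, grid)
  trace <- sc$value
  converged <- FALSE
  rooted <- root_at_internal(tree)
  n <- n_tips(tree)
  for (iter in seq_len(max_iter)) {
    anc <- sc$ancestral_states
    # ancestor configuration of each terminal
    parent <- rooted_parents(rooted, n)
    new_data <- dataset$data
    for (ti in seq_len(n)) {
      sp <- tree$tip.label[ti]
      target <- matrix(anc[parent[ti] - n, , ], dataset$n_landmarks, k)
      x <- matrix(dataset$data[sp, , ], dataset$n_landmarks, k)
      R <- l1_rotation(x, target)
      new_data[sp, , ] <- x %*% R
    }
    cand <- landmark_dataset(dataset$name, new_data, dataset$blocks)
    cand_sc <- laup_score(tree, cand, grid)
    if (cand_sc$value < sc$value - tol) {
      for (ti in seq_len(n)) {
        sp <- tree$tip.label[ti]
        x <- matrix(dataset$data[sp, , ], dataset$n_landmarks, k)
        # recompute accepted rotation to accumulate it
        target <- matrix(anc[parent[ti] - n, , ], dataset$n_landmarks, k)
        rotations[[sp]] <- rotations[[sp]] %*% l1_rotation(x, target)
      }
      dataset <- cand
      sc <- cand_sc
      trace <- c(trace, sc$value)
    } else {
      converged <- TRUE
      break
    }
  }
  list(dataset = dataset, rotations = rotations, score = sc,
       trace = trace, converged = converged)
}

rooted_parents <- function(rooted, n) {
  parent <- integer(rooted$n_nodes)
  for (node in seq_along(rooted$children)) {
    for (kid in rooted$children[[node]]) parent[kid] <- node
  }
  parent
}

# rotation (det +1) minimising the summed Euclidean (not squared) distance of
# the rows of x to the rows of target: iteratively reweighted Kabsch
# (Weiszfeld weights 1/distance)
l1_rotation <- function(x, target, iters = 10L, eps = 1e-9) {
  R <- kabsch(x, target)
  for (i in seq_len(iters)) {
    d <- sqrt(rowSums((x %*% R - target)^2))
    w <- sqrt(1 / pmax(d, eps))
    R2 <- kabsch(x * w, target * w)
    if (sum(abs(R2 - R)) < 1e-12) { R <- R2; break }
    R <- R2
  }
  R
}

kabsch <- function(x, target) {
  s <- svd(crossprod(x, target))
  d <- sign(det(s$v %*% t(s$u)))
  sig <- diag(c(rep(1, ncol(x) - 1L), d))
  s$u %*% sig %*% t(s$v)
}
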