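# Shared fixture builders and independent oracles.

# single-landmark 1-D-style dataset: landmark x coordinate carries the value,
# y and z are zero
toy_1d_dataset <- function(values) {
  landmark_dataset("toy1d", lapply(values, function(v) matrix(c(v, 0, 0), 1, 3)))
}

# dataset of random configurations
random_dataset <- function(n_species, p, k = 3, sd = 1, seed = NULL,
                           names_prefix = "sp") {
  if (!is.null(seed)) set.seed(seed)
  shapes <- lapply(seq_len(n_species), function(i) matrix(rnorm(p * k, sd = sd), p, k))
  names(shapes) <- paste0(names_prefix, seq_len(n_species))
  landmark_dataset("random", shapes)
}

# strong-signal noise-free Brownian study on a random tree
signal_study <- function(n_taxa, p, seed, rate = 1, noise = 0) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- tr$edge.length + 0.5
  spec <- simulation_spec(tr, n_landmarks = p, rate = rate,
                          replicate_noise_sd = noise, seed = seed + 1L)
  list(tree = ape::unroot(tr), shapes = simulate_species_shapes(spec),
       spec = spec)
}

# proper random rotation
rand_rot <- function(k = 3) {
  q <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# --- independent per-quartet oracle ------------------------------------
# classify the induced 4-taxon topology by pruning (ape::keep.tip) and
# reading the single nontrivial split; 0 = unresolved star
quartet_class_oracle <- function(tree, tips4) {
  kt <- ape::unroot(ape::keep.tip(tree, tips4))
  if (kt$Nnode < 2L) return(0L)
  sp <- tree_splits(kt, sort(tips4))
  if (nrow(sp) == 0L) return(0L)
  pair <- sort(tips4)[which(sp[1, ])]
  # classes keyed on the sorted quartet (a b c d): 1 = ab|cd, 2 = ac|bd, 3 = ad|bc
  a <- sort(tips4)
  if (setequal(pair, a[c(3, 4)]) || setequal(pair, a[c(1, 2)])) return(1L)
  if (setequal(pair, a[c(2, 4)]) || setequal(pair, a[c(1, 3)])) return(2L)
  3L
}

quartet_comparison_oracle <- function(t1, t2) {
  tips <- sort(t1$tip.label)
  combos <- utils::combn(tips, 4L)
  c1 <- apply(combos, 2L, function(q) quartet_class_oracle(t1, q))
  c2 <- apply(combos, 2L, function(q) quartet_class_oracle(t2, q))
  list(s = sum(c1 > 0 & c1 == c2), d = sum(c1 > 0 & c2 > 0 & c1 != c2),
       r1 = sum(c1 > 0 & c2 == 0), r2 = sum(c1 == 0 & c2 > 0),
       u = sum(c1 == 0 & c2 == 0))
}

# --- exhaustive topologies on few taxa (phangorn) -----------------------
all_topologies <- function(tip_labels) {
  trees <- phangorn::allTrees(length(tip_labels), rooted = FALSE,
                              tip.label = tip_labels)
  lapply(trees, ape::unroot)
}

# numeric-optimisation oracle for squared-change parsimony: minimise the sum
# of squared edge differences over free ancestral states with BFGS
scp_oracle <- function(tree, dataset) {
  tree <- ape::unroot(tree)
  X <- dataset$data
  flat <- t(vapply(tree$tip.label, function(s)
    as.vector(t(dataset$data[s, , ])), numeric(dataset$n_landmarks * dataset$dims)))
  n <- nrow(flat); m <- ncol(flat)
  n_int <- tree$Nnode
  edges <- tree$edge
  obj <- function(par) {
    A <- matrix(par, n_int, m)
    states <- rbind(flat, A)
    sum((states[edges[, 1], , drop = FALSE] - states[edges[, 2], , drop = FALSE])^2)
  }
  init <- matrix(colMeans(flat), n_int, m, byrow = TRUE)
  fit <- optim(as.vector(init), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$value
}

# brute-force 1-D linear parsimony over integer ancestral candidates
lp_bruteforce_1d <- function(tree, values) {
  tree <- ape::unroot(tree)
  n <- length(values)
  cand <- seq(min(values), max(values))
  n_int <- tree$Nnode
  edges <- tree$edge
  grid <- as.matrix(do.call(expand.grid, rep(list(cand), n_int)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    states <- c(values, grid[r, ])
    v <- sum(abs(states[edges[, 1]] - states[edges[, 2]]))
    best <- min(best, v)
  }
  best
}

# Weiszfeld geometric median (continuous optimum of a 3-point star landmark)
geometric_median <- function(pts, iters = 200) {
  x <- colMeans(pts)
  for (i in seq_len(iters)) {
    d <- sqrt(rowSums(sweep(pts, 2, x)^2))
    if (any(d < 1e-12)) return(pts[which.min(d), ])
    w <- 1 / d
    x <- colSums(pts * w) / sum(w)
  }
  x
}

sum_dist <- function(pts, x) sum(sqrt(rowSums(sweep(pts, 2, x)^2)))

# collapse a binary tree's internal edges (lowest first) until the target
# internal node count is reached; helper for the resolution examples
collapse_to_nodes <- function(tree, target_nodes) {
  tree <- ape::unroot(tree)
  while (tree$Nnode > target_nodes) {
    sp <- tree_splits(tree)
    keep <- sp[-1, , drop = FALSE]
    tree <- tree_from_splits(keep, tip_labels = colnames(sp))
  }
  tree
}

# internal helpers exercised directly by the tests
opa_residual <- morphotree:::opa_residual
retained_indices <- morphotree:::retained_indices
splits_compatible <- morphotree:::splits_compatible
split_keys <- morphotree:::split_keys

# canonical topology key
write_sorted_splits <- function(tree) {
  paste(sort(split_keys(tree_splits(tree))), collapse = "|")
}

# symmetric 12-taxon recovery design: three 4-taxon subclades, unit branch
# lengths throughout (the study conditions for the end-to-end recovery check)
balanced_recovery_tree <- function() {
  txt <- "((((t1,t2),(t3,t4)),((t5,t6),(t7,t8))),((t9,t10),(t11,t12)));"
  tr <- ape::unroot(ape::read.tree(text = txt))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}
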