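# Synthetic landmark studies with known truth: species mean configurations
# evolve by Brownian motion on a known tree; specimens and digitisation
# replicates add isotropic noise; bilateral mode emits mirrored left-side
# counterparts plus medial landmarks so the full processing pipeline
# (replicate consensus, symmetrisation, GPA) has real work to do.

#' Simulation specification
#'
#' @param tree `phylo` with branch lengths in Brownian time units.
#' @param n_landmarks Number of effective (right + medial) landmarks.
#' @param dims 2 or 3.
#' @param rate Brownian variance per unit branch length, per coordinate.
#' @param replicate_noise_sd Isotropic digitisation noise sd per coordinate.
#' @param n_specimens_per_species,n_replicates_per_specimen Sampling design.
#' @param bilateral Emit mirrored left-side landmarks plus medial landmarks.
#' @param n_medial Number of medial landmarks (bilateral mode).
#' @param asymmetry_sd Fluctuating-asymmetry noise added to the left side.
#' @param abnormalities List of `list(specimen, landmark, offset)` entries;
#'   the offset (length `dims`) displaces that landmark in every replicate.
#' @param convergence List of `list(tips, shift)` entries; the shift vector
#'   (length `n_landmarks * dims`) is added to every listed tip's mean shape,
#'   emulating convergent morphology shared by distant clades.
#' @param seed Integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, n_landmarks = 30L, dims = 3L, rate = 1,
                            replicate_noise_sd = 0.02,
                            n_specimens_per_species = 1L,
                            n_replicates_per_specimen = 2L,
                            bilateral = FALSE, n_medial = 2L,
                            asymmetry_sd = 0, abnormalities = list(),
                            convergence = list(), seed = 1L) {
  stopifnot(rate > 0, replicate_noise_sd >= 0, asymmetry_sd >= 0,
            dims %in% c(2L, 3L), n_landmarks >= 3L)
  if (is.null(tree$edge.length)) stop("simulation tree needs branch lengths")
  for (cv in convergence) stopifnot(all(cv$tips %in% tree$tip.label))
  structure(list(tree = tree, n_landmarks = as.integer(n_landmarks),
                 dims = as.integer(dims), rate = rate,
                 replicate_noise_sd = replicate_noise_sd,
                 n_specimens_per_species = as.integer(n_specimens_per_species),
                 n_replicates_per_specimen = as.integer(n_replicates_per_specimen),
                 bilateral = bilateral, n_medial = as.integer(n_medial),
                 asymmetry_sd = asymmetry_sd, abnormalities = abnormalities,
                 convergence = convergence, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate species mean configurations by Brownian motion
#'
#' The root configuration is drawn once, then every coordinate evolves
#' independently along the tree with variance `rate` x branch length;
#' convergence shifts are added to the designated tips afterwards.
#'
#' @param spec A [simulation_spec()].
#' @return A [landmark_dataset()] of true species shapes (name
#'   `"true_shapes"`), plus attribute `root_shape`.
#' @export
simulate_species_shapes <- function(spec) {
  tree <- spec$tree
  m <- spec$n_landmarks * spec$dims
  with_local_seed(spec$seed, {
    root_shape <- root_configuration(spec$n_landmarks, spec$dims)
    tips <- bm_tips(tree, as.vector(t(root_shape)), spec$rate)
    for (cv in spec$convergence) {
      for (tp in cv$tips) tips[tp, ] <- tips[tp, ] + cv$shift
    }
    arr <- array(NA_real_, c(nrow(tips), spec$n_landmarks, spec$dims),
                 dimnames = list(rownames(tips), NULL, NULL))
    for (i in seq_len(nrow(tips))) {
      x <- matrix(tips[i, ], spec$n_landmarks, spec$dims, byrow = TRUE)
      # in bilateral use the last n_medial landmarks sit on the midplane
      if (spec$bilateral) x <- medialise(x, spec$n_medial)
      arr[i, , ] <- x
    }
    ds <- landmark_dataset("true_shapes", arr)
    attr(ds, "root_shape") <- root_shape
    ds
  })
}

# deterministic-ish root: landmarks spread on a sphere-like cloud; in
# bilateral use the x axis is the left-right axis, so the right side gets
# positive x and medial landmarks x = 0
root_configuration <- function(p, k) {
  x <- matrix(stats::rnorm(p * k), p, k)
  x[, 1] <- abs(x[, 1]) + 0.5        # keep the configuration on one side
  x <- center_config(x)
  x / centroid_size(x) * sqrt(p)
}

# Brownian tips: recursion over the rooted ape tree
bm_tips <- function(tree, root_state, rate) {
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  states <- matrix(NA_real_, total, length(root_state))
  states[n + 1L, ] <- root_state
  pre <- postorder_nodes(tree)             # parents before children
  edges <- tree$edge
  for (node in pre) {
    if (node == n + 1L) next
    r <- which(edges[, 2] == node)
    parent <- edges[r, 1]
    v <- tree$edge.length[r] * rate
    states[node, ] <- states[parent, ] +
      stats::rnorm(length(root_state), sd = sqrt(max(v, 0)))
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Generate digitised specimens from species shapes
#'
#' Per species, `n_specimens_per_species` specimens each digitised
#' `n_replicates_per_specimen` times with isotropic noise; every digitisation
#' receives a random similarity transform (rotation, scale, translation) so
#' superposition is non-trivial. In bilateral mode the right-side landmarks
#' (all but the last `n_medial`, whose x coordinate is zeroed to make them
#' medial) are mirrored across the x = 0 plane to construct the left side,
#' with optional fluctuating-asymmetry noise; abnormality offsets are applied
#' per specimen/landmark.
#'
#' @param shapes Output of [simulate_species_shapes()].
#' @param spec The same [simulation_spec()].
#' @return List with `configs` (specimen configurations) and `defs` (the
#'   matching `landmark_defs` table in bilateral mode, else `NULL`).
#' @export
make_specimens <- function(shapes, spec) {
  k <- spec$dims
  with_local_seed(spec$seed + 1L, {
    defs <- if (spec$bilateral) bilateral_defs(spec) else NULL
    configs <- list()
    for (sp in shapes$species) {
      true_shape <- matrix(shapes$data[sp, , ], spec$n_landmarks, k)
      for (si in seq_len(spec$n_specimens_per_species)) {
        spec_id <- sprintf("%s_s%d", sp, si)
        for (ri in seq_len(spec$n_replicates_per_specimen)) {
          x <- true_shape
          if (spec$bilateral) {
            left <- x[seq_len(spec$n_landmarks - spec$n_medial), , drop = FALSE]
            left[, 1] <- -left[, 1]
            if (spec$asymmetry_sd > 0)
              left <- left + matrix(stats::rnorm(length(left),
                                                 sd = spec$asymmetry_sd),
                                    nrow(left), k)
            x <- rbind(x, left)
          }
          if (spec$replicate_noise_sd > 0)
            x <- x + matrix(stats::rnorm(length(x), sd = spec$replicate_noise_sd),
                            nrow(x), k)
          for (ab in spec$abnormalities) {
            if (identical(ab$specimen, spec_id))
              x[ab$landmark, ] <- x[ab$landmark, ] + ab$offset
          }
          # random similarity transform per digitisation
          R <- random_rotation(k)
          scl <- stats::runif(1, 0.75, 1.5)
          shift <- stats::rnorm(k, sd = 2)
          x <- scl * (x %*% R) + matrix(shift, nrow(x), k, byrow = TRUE)
          tag <- if (spec$n_replicates_per_specimen == 2L) c("a", "b")[ri]
                 else if (spec$n_replicates_per_specimen == 1L) "none"
                 else as.character(ri)
          configs[[length(configs) + 1L]] <-
            specimen_config(spec_id, sp, "synthetic", tag, x)
        }
      }
    }
    list(configs = configs, defs = defs)
  })
}

# force the last n_medial landmarks onto the x = 0 plane
medialise <- function(x, n_medial) {
  p <- nrow(x)
  med <- seq(p - n_medial + 1L, p)
  x[med, 1] <- 0
  x
}

# definition table for the bilateral layout emitted by make_specimens:
# landmarks 1..(p - n_medial) right, then n_medial medial, then the mirrored
# left block appended at the end
bilateral_defs <- function(spec) {
  p <- spec$n_landmarks
  nm <- spec$n_medial
  nr <- p - nm
  landmark_defs(data.frame(
    index = seq_len(p + nr),
    name = sprintf("lm%d", seq_len(p + nr)),
    side = c(rep("right", nr), rep("medial", nm), rep("left", nr)),
    lobe = "none",
    pair_index = c(p + seq_len(nr), rep(NA_integer_, nm), seq_len(nr)),
    excluded = FALSE))
}

#' Emit a complete synthetic study to disk
#'
#' Writes the specimen TPS file, the truth tree (newick), the definition
#' table (bilateral mode) and a JSON manifest; regenerating from the manifest
#' reproduces the files bit for bit.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the study pieces and file paths.
#' @export
emit_study <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shapes <- simulate_species_shapes(spec)
  specimens <- make_specimens(shapes, spec)
  tps <- file.path(dir, "specimens.tps")
  write_tps(specimens$configs, tps)
  nwk <- file.path(dir, "true_tree.nwk")
  write_newick(spec$tree, nwk)
  defs_path <- NULL
  if (!is.null(specimens$defs)) {
    defs_path <- file.path(dir, "definitions.csv")
    utils::write.csv(specimens$defs, defs_path, row.names = FALSE, na = "")
  }
  manifest <- list(
    seed = spec$seed, n_landmarks = spec$n_landmarks, dims = spec$dims,
    rate = spec$rate, replicate_noise_sd = spec$replicate_noise_sd,
    n_specimens_per_species = spec$n_specimens_per_species,
    n_replicates_per_specimen = spec$n_replicates_per_specimen,
    bilateral = spec$bilateral, n_medial = spec$n_medial,
    asymmetry_sd = spec$asymmetry_sd,
    tree = write_newick(spec$tree),
    edge_lengths = sprintf("%.17g", spec$tree$edge.length),
    species = spec$tree$tip.label,
    files = basename(c(tps, nwk, defs_path)))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(spec = spec, shapes = shapes, specimens = specimens,
                 paths = list(tps = tps, tree = nwk, defs = defs_path,
                              manifest = manifest_path)))
}
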