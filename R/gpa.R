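#' Generalised Procrustes analysis
#'
#' Iterative superposition of a set of landmark configurations: each is
#' centred at the origin, optionally scaled to unit centroid size, and rotated
#' (proper rotation, det +1) onto the running consensus; the consensus is the
#' arithmetic mean of the superposed members and the loop repeats until it
#' stabilises. No tangent-space projection is applied; distances between the
#' superposed configurations are the partial Procrustes distances used
#' throughout the package.
#'
#' @param configs A list of `specimen_config` objects or of p x k coordinate
#'   matrices (identical landmark sets, no missing values).
#' @param scale Scale members to unit centroid size (default `TRUE`).
#' @param tol Convergence tolerance on the consensus change.
#' @param max_iter Iteration cap.
#' @return An object of class `superposed_set` with elements `members`
#'   (aligned matrices), `consensus`, `centroid_sizes`, `total_variance`
#'   (summed coordinate variances across members) and `meta` (original
#'   configuration metadata, if any).
#' @export
gpa <- function(configs, scale = TRUE, tol = 1e-10, max_iter = 200L) {
  meta <- NULL
  if (length(configs) > 0L && inherits(configs[[1]], "specimen_config")) {
    meta <- lapply(configs, function(cfg) cfg[c("specimen_id", "species",
                                                "structure", "replicate_tag")])
    configs <- lapply(configs, `[[`, "coords")
  }
  if (length(configs) < 2L) stop("gpa needs at least 2 configurations")
  p <- nrow(configs[[1]]); k <- ncol(configs[[1]])
  for (x in configs) {
    if (!identical(dim(x), c(p, k))) stop("configurations differ in landmark count")
    if (any(is.na(x))) stop("gpa requires complete configurations (no missing landmarks)")
  }
  centred <- lapply(configs, center_config)
  cs <- vapply(centred, centroid_size, 0)
  if (any(cs < .Machine$double.eps))
    stop("degenerate configuration with zero centroid size")
  members <- if (scale) Map(function(x, s) x / s, centred, cs) else centred
  consensus <- members[[1]]
  for (iter in seq_len(max_iter)) {
    members <- lapply(members, rotate_onto, target = consensus)
    new_consensus <- Reduce(`+`, members) / length(members)
    if (scale) {
      # keep the consensus on the unit-size hemisphere so rotations stay stable
      new_consensus <- new_consensus / centroid_size(new_consensus)
    }
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) break
  }
  members <- lapply(members, rotate_onto, target = consensus)
  consensus <- Reduce(`+`, members) / length(members)
  flat <- do.call(rbind, lapply(members, as.vector))
  tv <- if (nrow(flat) > 1L) sum(apply(flat, 2L, stats::var)) else 0
  structure(list(members = members, consensus = consensus,
                 centroid_sizes = cs, total_variance = tv, meta = meta),
            class = "superposed_set")
}

#' @export
print.superposed_set <- function(x, ...) {
  cat(sprintf("<superposed_set> %d configurations, %d landmarks x %dD, total variance %.6g\n",
              length(x$members), nrow(x$consensus), ncol(x$consensus),
              x$total_variance))
  invisible(x)
}

center_config <- function(x) sweep(x, 2L, colMeans(x))

centroid_size <- function(x) {
  xc <- center_config(x)
  sqrt(sum(xc^2))
}

# optimal proper rotation of x onto target (both centred), Kabsch with
# determinant sign correction
rotate_onto <- function(x, target) {
  s <- svd(crossprod(x, target))
  d <- sign(det(s$v %*% t(s$u)))
  sig <- diag(c(rep(1, ncol(x) - 1L), d))
  x %*% (s$u %*% sig %*% t(s$v))
}

# ordinary (pairwise) Procrustes residual sum of squares between two centred,
# optionally scaled configurations; closed form via SVD
opa_residual <- function(x, y, scale = TRUE) {
  x <- center_config(x); y <- center_config(y)
  if (scale) { x <- x / centroid_size(x); y <- y / centroid_size(y) }
  sum((rotate_onto(x, y) - y)^2)
}

#' Pairwise Procrustes distance matrix of a landmark dataset
#'
#' Entry (i, j) is the Euclidean distance between the flattened superposed
#' configurations of species i and j (partial Procrustes distance).
#'
#' @param dataset A [landmark_dataset()].
#' @return A symmetric matrix with species names on both margins.
#' @export
procrustes_distance_matrix <- function(dataset) {
  flat <- dataset_flat(dataset)
  d <- as.matrix(stats::dist(flat))
  dimnames(d) <- list(dataset$species, dataset$species)
  d
}

#' Between-species total variance of a landmark dataset
#'
#' Sum over all coordinates of the across-species sample variance
#' (divisor N - 1).
#'
#' @param dataset A [landmark_dataset()].
#' @return A scalar.
#' @export
total_variance <- function(dataset) {
  flat <- dataset_flat(dataset)
  if (nrow(flat) < 2L) stop("total_variance needs at least 2 species")
  sum(apply(flat, 2L, stats::var))
}
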