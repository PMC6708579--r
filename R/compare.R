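# Tree dissimilarities and the topological-accuracy statistic.

# unit-branch-length cophenetic matrix, rows/cols in sorted tip label order
topo_dist_matrix <- function(tree) {
  tree <- ape::unroot(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  d <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(d))
  d[ord, ord]
}

quartet_index_cache <- new.env(parent = emptyenv())

quartet_indices <- function(n) {
  key <- as.character(n)
  if (!is.null(quartet_index_cache[[key]])) return(quartet_index_cache[[key]])
  q <- utils::combn(n, 4L)
  quartet_index_cache[[key]] <- q
  q
}

# per-quartet resolution class under the four-point condition:
# 0 = unresolved, 1 = ab|cd, 2 = ac|bd, 3 = ad|bc (a<b<c<d in sorted order)
quartet_classes <- function(tree) {
  d <- topo_dist_matrix(tree)
  n <- nrow(d)
  q <- quartet_indices(n)
  a <- q[1, ]; b <- q[2, ]; cc <- q[3, ]; dd <- q[4, ]
  s1 <- d[cbind(a, b)] + d[cbind(cc, dd)]
  s2 <- d[cbind(a, cc)] + d[cbind(b, dd)]
  s3 <- d[cbind(a, dd)] + d[cbind(b, cc)]
  m <- pmin(s1, s2, s3)
  cls <- integer(length(m))
  tol <- 1e-9
  one <- (s1 < s2 - tol) & (s1 < s3 - tol)
  two <- (s2 < s1 - tol) & (s2 < s3 - tol)
  three <- (s3 < s1 - tol) & (s3 < s2 - tol)
  cls[one] <- 1L; cls[two] <- 2L; cls[three] <- 3L
  cls
}

#' Quartet-by-quartet comparison of two trees
#'
#' Classifies every tip quartet of the shared tip set as identically
#' resolved, differently resolved, resolved in only one tree, or unresolved
#' in both.
#'
#' @param t1,t2 `phylo` objects on the same tip set.
#' @return A list with counts `s`, `d`, `r1`, `r2`, `u` and `n_quartets`.
#' @export
quartet_comparison <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same tip set")
  c1 <- quartet_classes(t1)
  c2 <- quartet_classes(t2)
  list(s = sum(c1 > 0L & c1 == c2),
       d = sum(c1 > 0L & c2 > 0L & c1 != c2),
       r1 = sum(c1 > 0L & c2 == 0L),
       r2 = sum(c1 == 0L & c2 > 0L),
       u = sum(c1 == 0L & c2 == 0L),
       n_quartets = length(c1))
}

#' Count of differently resolved quartets (dQ)
#'
#' The conflict-only quartet dissimilarity: quartets resolved in both trees
#' but differently. Polytomies are soft (unresolved quartets never count).
#'
#' @param t1,t2 `phylo` objects on the same tip set.
#' @return Integer count.
#' @export
quartet_conflict <- function(t1, t2) quartet_comparison(t1, t2)$d

#' Scaled quartet distance
#'
#' Quartet disagreement divided by the number of quartets. With
#' `metric = FALSE` (default) only conflicting quartets count (the statistic
#' used for topological accuracy); with `metric = TRUE` quartets resolved in
#' only one tree also count, which makes the quantity a metric on polytomous
#' trees (the convention used for tree-space distance matrices).
#'
#' @param t1,t2 `phylo` objects on the same tip set.
#' @param metric Include one-sided resolutions.
#' @return Fraction between 0 and 1.
#' @export
scaled_quartet_distance <- function(t1, t2, metric = FALSE) {
  qc <- quartet_comparison(t1, t2)
  num <- qc$d + if (metric) qc$r1 + qc$r2 else 0L
  num / qc$n_quartets
}

#' Contradiction difference between two trees
#'
#' The number of nontrivial splits of each tree incompatible with the other
#' tree (soft polytomies: splits absent from a less resolved tree contradict
#' nothing).
#'
#' @param t1,t2 `phylo` objects on the same tip set.
#' @return Integer count (symmetric in its arguments).
#' @export
contradiction_difference <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same tip set")
  tips <- sort(t1$tip.label)
  s1 <- tree_splits(t1, tips)
  s2 <- tree_splits(t2, tips)
  incompat <- function(a, b) {
    sum(vapply(seq_len(nrow(a)), function(i) {
      any(vapply(seq_len(nrow(b)), function(j)
        !splits_compatible(a[i, ], b[j, ]), TRUE))
    }, TRUE))
  }
  if (nrow(s1) == 0L || nrow(s2) == 0L) return(0L)
  incompat(s1, s2) + incompat(s2, s1)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the nontrivial split sets.
#'
#' @param t1,t2 `phylo` objects on the same tip set.
#' @return Integer count.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same tip set")
  tips <- sort(t1$tip.label)
  k1 <- split_keys(tree_splits(t1, tips))
  k2 <- split_keys(tree_splits(t2, tips))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Topological accuracy of an estimated tree
#'
#' TA = (d0 - d) / d0, where d is the dissimilarity between the estimated
#' and the reference tree and d0 is the median dissimilarity between the
#' reference tree and random binary topologies on the same tips. TA is 1 for
#' perfect agreement and near 0 when the estimate is no closer to the
#' reference than random trees; it is invariant to positive rescaling of the
#' dissimilarity.
#'
#' @param t_m Estimated `phylo`.
#' @param t_ref Reference `phylo` (may contain soft polytomies).
#' @param measure `"dQ"` (quartet conflict) or `"CD"` (contradiction
#'   difference).
#' @param n_rand Number of random topologies for the null median.
#' @param seed Integer seed for the null sample.
#' @return A list with `ta`, `observed_d`, `null_median`, `measure`,
#'   `n_rand`, `seed`.
#' @export
topological_accuracy <- function(t_m, t_ref, measure = c("dQ", "CD"),
                                 n_rand = 10000L, seed = 1L) {
  measure <- match.arg(measure)
  if (!setequal(t_m$tip.label, t_ref$tip.label))
    stop("trees must share the same tip set")
  dfun <- if (measure == "dQ") quartet_conflict else contradiction_difference
  observed <- dfun(t_ref, t_m)
  tips <- t_ref$tip.label
  nulls <- vapply(seq_len(n_rand), function(i) {
    dfun(t_ref, random_topology(tips, seed = seed + i))
  }, 0)
  null_median <- stats::median(nulls)
  if (null_median == 0) stop("degenerate null (median dissimilarity 0)")
  list(ta = (null_median - observed) / null_median, observed_d = observed,
       null_median = null_median, measure = measure, n_rand = n_rand,
       seed = seed)
}

#' Summaries of a topological-accuracy table
#'
#' @param ta_table data.frame with columns `dataset`, `ta_dq`, `ta_cd`.
#' @return A list with `medians` (per-dataset medians of both measures) and
#'   `correlation` (Pearson correlation between the two TA columns; `NA` with
#'   a warning when a column is constant).
#' @export
ta_summary <- function(ta_table) {
  stopifnot(all(c("dataset", "ta_dq", "ta_cd") %in% names(ta_table)))
  if (nrow(ta_table) < 2L) stop("need at least 2 rows")
  med <- do.call(rbind, lapply(split(ta_table, ta_table$dataset), function(g) {
    data.frame(dataset = g$dataset[1],
               median_ta_dq = stats::median(g$ta_dq),
               median_ta_cd = stats::median(g$ta_cd))
  }))
  rownames(med) <- NULL
  corr <- if (stats::sd(ta_table$ta_dq) == 0 || stats::sd(ta_table$ta_cd) == 0) {
    warning("constant TA column; correlation undefined")
    NA_real_
  } else stats::cor(ta_table$ta_dq, ta_table$ta_cd)
  list(medians = med, correlation = corr)
}

# ---- tree space ---------------------------------------------------------

#' Pairwise tree distance matrix
#'
#' @param trees Named list of `phylo` objects on the same tip set.
#' @param measure `"quartet"` (metric scaled quartet distance) or `"RF"`.
#' @return Symmetric matrix.
#' @export
tree_distance_matrix <- function(trees, measure = c("quartet", "RF")) {
  measure <- match.arg(measure)
  n <- length(trees)
  d <- matrix(0, n, n, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d[i, j] <- d[j, i] <- if (measure == "quartet")
      scaled_quartet_distance(trees[[i]], trees[[j]], metric = TRUE)
    else robinson_foulds(trees[[i]], trees[[j]])
  }
  d
}

#' Metric multidimensional scaling of a tree distance matrix
#'
#' Classical MDS (double centering + eigendecomposition) with the Pearson
#' correlation between original and projected distances as a quality index.
#'
#' @param d Symmetric distance matrix.
#' @param dims Projection dimension.
#' @return List with `coords` and `rho`.
#' @export
tree_mds <- function(d, dims = 2L) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  coords <- stats::cmdscale(d, k = dims)
  proj <- as.matrix(stats::dist(coords))
  lower <- lower.tri(d)
  # rho is undefined when all pairwise distances coincide
  rho <- if (stats::sd(d[lower]) == 0 || stats::sd(proj[lower]) == 0)
    NA_real_ else stats::cor(d[lower], proj[lower])
  list(coords = coords, rho = rho)
}

#' Partition a tree distance matrix around medoids
#'
#' @param d Symmetric distance matrix.
#' @param k Number of clusters (< n).
#' @return List with `clustering` (assignments) and `medoids` (indices).
#' @export
pam_cluster <- function(d, k) {
  n <- nrow(as.matrix(d))
  if (k >= n) stop("k must be smaller than the number of trees")
  fit <- cluster::pam(stats::as.dist(as.matrix(d)), k = k, diss = TRUE)
  list(clustering = fit$clustering, medoids = fit$id.med,
       objective = fit$objective[["swap"]])
}

#' Elbow choice of the cluster count
#'
#' Picks the k maximising the curvature (second difference) of the
#' PAM-cost-versus-k curve.
#'
#' @param d Symmetric distance matrix.
#' @param k_range Candidate k values (consecutive integers).
#' @return The chosen k.
#' @export
elbow_k <- function(d, k_range = 2:6) {
  k_range <- sort(k_range)
  cost <- vapply(k_range, function(k) pam_cluster(d, k)$objective, 0)
  if (length(k_range) < 3L) return(k_range[which.min(cost)])
  curv <- diff(cost, differences = 2L)     # at interior k values
  k_range[which.max(curv) + 1L]
}
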