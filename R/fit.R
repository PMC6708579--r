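#' Estimate a phylogeny from a landmark dataset
#'
#' Unified front end over the criterion-specific searches: spatial landmark
#' parsimony on a fixed or dynamically re-aligned superposition, linear
#' parsimony, squared-change parsimony, Brownian-motion maximum likelihood,
#' or neighbour joining on Procrustes distances.
#'
#' @param dataset A [landmark_dataset()].
#' @param method One of `"scp"`, `"lp"`, `"laup-gpa"`, `"laup-dynamic"`,
#'   `"ml"`, `"nj"`.
#' @param settings A [search_settings()] (ignored by `"nj"`).
#' @param start_tree Optional starting tree (spatial-parsimony modes).
#' @return An object of class `morphotree_fit` with components `tree`
#'   (unrooted `phylo`), `value` (criterion score; negated log-likelihood for
#'   ML so that smaller is always better), `method`, `settings`, `dataset_name`.
#' @examples
#' tr <- ape::rtree(6)
#' spec <- simulation_spec(tr, n_landmarks = 10, replicate_noise_sd = 0, seed = 2)
#' shapes <- simulate_species_shapes(spec)
#' fit <- infer_tree(shapes, "scp", search_settings(n_random_addition = 2))
#' print(fit)
#' @export
infer_tree <- function(dataset, method = c("scp", "lp", "laup-gpa",
                                           "laup-dynamic", "ml", "nj"),
                       settings = search_settings(), start_tree = NULL) {
  method <- match.arg(method)
  res <- switch(method,
    "scp" = scp_search(dataset, settings),
    "lp" = lp_search(dataset, settings),
    "laup-gpa" = laup_search(dataset, "gpa", settings, start_tree = start_tree),
    "laup-dynamic" = laup_search(dataset, "dynamic", settings,
                                 start_tree = start_tree),
    "ml" = ml_search(dataset, settings),
    "nj" = {
      tree <- nj_tree(procrustes_distance_matrix(dataset))
      list(tree = tree, value = NA_real_)
    })
  structure(list(tree = ape::unroot(res$tree), value = res$value,
                 loglik = res$loglik, method = method, settings = settings,
                 dataset_name = dataset$name,
                 n_species = length(dataset$species)),
            class = "morphotree_fit")
}

#' @export
print.morphotree_fit <- function(x, ...) {
  cat(sprintf("<morphotree_fit> method %s on '%s' (%d species)\n",
              x$method, x$dataset_name, x$n_species))
  if (!is.na(x$value %||% NA_real_)) {
    lab <- if (x$method == "ml") "log-likelihood" else "score"
    val <- if (x$method == "ml") -x$value else x$value
    cat(sprintf("  %s: %.6g\n", lab, val))
  }
  cat(sprintf("  tree: %s\n", write_newick(x$tree)))
  invisible(x)
}

#' @export
summary.morphotree_fit <- function(object, ...) {
  out <- list(method = object$method, value = object$value,
              n_species = object$n_species,
              resolution = resolution(object$tree),
              newick = write_newick(object$tree))
  class(out) <- "summary.morphotree_fit"
  out
}

#' @export
print.summary.morphotree_fit <- function(x, ...) {
  cat(sprintf("morphotree fit (%s): %d species, resolution %.3f, score %.6g\n",
              x$method, x$n_species, x$resolution, x$value))
  cat(x$newick, "\n")
  invisible(x)
}

#' @export
plot.morphotree_fit <- function(x, ...) {
  tr <- x$tree
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  ape::plot.phylo(tr, type = "unrooted", ...)
  invisible(x)
}
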