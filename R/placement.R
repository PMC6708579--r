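# Leave-one-out placement of single species on a fixed reference scaffold.

# attach `label` on edge row r of the pruned tree; edges enumerated via
# attach_tip_everywhere, which also defines the candidate order
candidate_attachments <- function(pruned, label) attach_tip_everywhere(pruned, label)

# number of nodes separating two edges of a tree: 0 for the same edge, m + 1
# otherwise, where m is the smallest topological node distance between their
# endpoints (adjacent edges share a node and are 1 apart)
edge_nodal_distance <- function(tree, e1, e2) {
  if (setequal(e1, e2)) return(0L)
  tree$edge.length <- rep(1, nrow(tree$edge))
  d <- ape::dist.nodes(tree)
  m <- min(d[e1[1], e2[1]], d[e1[1], e2[2]], d[e1[2], e2[1]], d[e1[2], e2[2]])
  as.integer(m) + 1L
}

# edges of the pruned tree in the same enumeration order used for
# candidate attachments (surgery ids mapped to ape node ids)
pruned_edge_list <- function(pruned) {
  s <- phylo_to_surgery(pruned)
  all_edges(s$adj)
}

# edge of `pruned` where `species` was attached in `ref_tree`
original_attachment_edge <- function(ref_tree, pruned, species) {
  # neighbours of the species' attachment node, excluding the species itself,
  # identify the edge created by suppression
  s <- phylo_to_surgery(ape::unroot(ref_tree))
  tip_id <- match(species, s$labels)
  u <- s$adj[[tip_id]]
  nb <- setdiff(s$adj[[u]], tip_id)
  nb_labels <- lapply(nb, function(v) sort(component_tips(s, v, u)))
  # map to pruned-tree node ids via the tip bipartition each side induces
  sp <- phylo_to_surgery(pruned)
  edges <- all_edges(sp$adj)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    ta <- sort(component_tips(sp, a, b))
    tb <- sort(component_tips(sp, b, a))
    if ((identical(ta, nb_labels[[1]]) && identical(tb, nb_labels[[2]])) ||
        (identical(ta, nb_labels[[2]]) && identical(tb, nb_labels[[1]])))
      return(edges[r, ])
  }
  stop("original attachment edge not found")  # should be unreachable
}

component_tips <- function(s, start, blocked) {
  nodes <- reach_component(s$adj, start, blocked)
  s$labels[nodes[nodes <= s$n]]
}

#' Place one species on a reference scaffold
#'
#' Prunes the species from the reference tree and scores its attachment on
#' every edge of the pruned tree under the chosen criterion (the scaffold
#' topology is otherwise fixed; criterion-internal quantities are
#' re-optimised per candidate edge). The placement error is the number of
#' nodes separating the original from the chosen attachment edge, scaled by
#' the farthest possible reinsertion point; ties over equally optimal edges
#' are summarised by the median scaled error.
#'
#' @param dataset A [landmark_dataset()].
#' @param ref_tree Reference `phylo` (binary; tips in the dataset).
#' @param species Species to place (must be a tip of `ref_tree`).
#' @param criterion One of `"scp"`, `"lp"`, `"laup"`, `"ml"`.
#' @param grid,ml_control Criterion settings.
#' @param tol Score tolerance for ties.
#' @return An object of class `placement_record`.
#' @export
place_species <- function(dataset, ref_tree, species,
                          criterion = c("scp", "lp", "laup", "ml"),
                          grid = grid_spec(), ml_control = list(maxit = 100L),
                          tol = 1e-9) {
  criterion <- match.arg(criterion)
  ref_tree <- ape::unroot(ref_tree)
  if (!species %in% ref_tree$tip.label) stop("species not in the reference tree")
  pruned <- restrict_tree(ref_tree, setdiff(ref_tree$tip.label, species))
  scorer <- criterion_scorer(dataset, criterion, grid = grid,
                             ml_control = ml_control)
  cands <- candidate_attachments(pruned, species)
  edges <- pruned_edge_list(pruned)
  vals <- vapply(cands, scorer, 0)
  best <- which(vals <= min(vals) + tol)
  # node ids used by edge_nodal_distance refer to the pruned ape tree; the
  # surgery enumeration shares its ids (tips 1..n, internals as in ape)
  orig <- original_attachment_edge(ref_tree, pruned, species)
  nodal <- vapply(seq_len(nrow(edges)), function(r)
    edge_nodal_distance(pruned, edges[r, ], orig), 0L)
  max_err <- max(nodal)
  records <- nodal[best]
  scaled <- stats::median(records) / max_err
  structure(list(species = species, criterion = criterion,
                 best_edges = best, scores = vals,
                 nodal_errors = records, all_nodal = nodal,
                 max_nodal_error = max_err,
                 scaled_error = scaled),
            class = "placement_record")
}

#' @export
print.placement_record <- function(x, ...) {
  cat(sprintf("<placement_record> %s (%s): %d optimal edge(s), scaled error %.3f\n",
              x$species, x$criterion, length(x$best_edges), x$scaled_error))
  invisible(x)
}

#' Leave-one-out placement over all species
#'
#' Runs [place_species()] for every tip of the reference tree except the
#' outgroup and summarises the scaled errors.
#'
#' @inheritParams place_species
#' @param outgroup Tip name(s) excluded from placement (default none).
#' @return An object of class `placement_summary` with `records`,
#'   `median_scaled_error` and `auc` (area under the empirical CDF of the
#'   scaled errors on the unit interval).
#' @export
leave_one_out <- function(dataset, ref_tree, criterion = "scp",
                          outgroup = character(0), grid = grid_spec(),
                          ml_control = list(maxit = 100L)) {
  species <- setdiff(ref_tree$tip.label, outgroup)
  records <- lapply(species, function(sp)
    place_species(dataset, ref_tree, sp, criterion, grid = grid,
                  ml_control = ml_control))
  errs <- vapply(records, `[[`, 0, "scaled_error")
  structure(list(records = records, scaled_errors = errs,
                 median_scaled_error = stats::median(errs),
                 auc = ecdf_auc(errs)),
            class = "placement_summary")
}

#' @export
print.placement_summary <- function(x, ...) {
  cat(sprintf("<placement_summary> %d species, median scaled error %.3f, AUC %.3f\n",
              length(x$records), x$median_scaled_error, x$auc))
  invisible(x)
}

# area under the empirical CDF of values in [0, 1]; equals 1 - mean(x)
ecdf_auc <- function(x) {
  stopifnot(all(x >= 0 & x <= 1))
  xs <- sort(unique(c(x, 1)))
  F <- stats::ecdf(x)
  grid <- c(0, xs)
  sum(F(grid[-length(grid)]) * diff(grid))
}

#' Null distribution of scaled placement errors
#'
#' For every species, the scaled nodal distances of all possible reinsertion
#' edges (the distribution a random placement would draw from), pooled.
#'
#' @param ref_tree Reference `phylo`.
#' @param outgroup Tips excluded.
#' @return List with `per_species` (named list of scaled-distance vectors)
#'   and `pooled`.
#' @export
placement_null <- function(ref_tree, outgroup = character(0)) {
  species <- setdiff(ref_tree$tip.label, outgroup)
  per <- lapply(species, function(sp) {
    pruned <- restrict_tree(ref_tree, setdiff(ref_tree$tip.label, sp))
    edges <- pruned_edge_list(pruned)
    orig <- original_attachment_edge(ape::unroot(ref_tree), pruned, sp)
    nodal <- vapply(seq_len(nrow(edges)), function(r)
      edge_nodal_distance(pruned, edges[r, ], orig), 0L)
    nodal / max(nodal)
  })
  names(per) <- species
  list(per_species = per, pooled = unlist(per, use.names = FALSE))
}
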