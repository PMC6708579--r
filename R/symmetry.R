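# Midsagittal plane estimation and reflection utilities.
#
# The symmetry plane of a bilaterally landmarked configuration is estimated
# from the medial landmarks together with the midpoints of the bilateral
# pairs: the plane passes through the mean of those points and its normal is
# the principal direction of the right-minus-left difference vectors (these
# are perpendicular to the true plane for a symmetric shape, so the estimate
# is exact in the noise-free case).

estimate_symmetry_plane <- function(coords, defs, exclude = integer(0)) {
  keep <- !defs$excluded
  med <- defs$index[keep & defs$side == "medial"]
  right <- defs$index[keep & defs$side == "right"]
  pts <- coords[med, , drop = FALSE]
  diffs <- NULL
  for (i in right) {
    j <- defs$pair_index[defs$index == i]
    if (i %in% exclude || j %in% exclude) next
    if (any(is.na(coords[i, ])) || any(is.na(coords[j, ]))) next
    pts <- rbind(pts, (coords[i, ] + coords[j, ]) / 2)
    diffs <- rbind(diffs, coords[i, ] - coords[j, ])
  }
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (is.null(diffs) || nrow(pts) < 3L)
    stop("not enough medial landmarks or bilateral pairs to define a symmetry plane")
  normal <- svd(diffs)$v[, 1L]
  normal <- normal / sqrt(sum(normal^2))
  list(point = colMeans(pts), normal = normal)
}

reflect_point <- function(x, plane) {
  x - 2 * sum((x - plane$point) * plane$normal) * plane$normal
}

project_point <- function(x, plane) {
  x - sum((x - plane$point) * plane$normal) * plane$normal
}

#' Repair developmentally abnormal landmarks by reflection
#'
#' Each flagged landmark is replaced by the mirror image of its bilateral
#' counterpart across the configuration's estimated midsagittal plane. Used to
#' exclude localised developmental abnormalities (e.g. asymmetric carapace
#' regions) without discarding the specimen.
#'
#' @param config A `specimen_config`.
#' @param defs The matching `landmark_defs` table.
#' @param dont_use Integer indices of landmarks to repair.
#' @return The repaired `specimen_config`.
#' @export
repair_abnormalities <- function(config, defs, dont_use = integer(0)) {
  if (length(dont_use) == 0L) return(config)
  coords <- config$coords
  plane <- estimate_symmetry_plane(coords, defs, exclude = dont_use)
  for (i in dont_use) {
    j <- defs$pair_index[defs$index == i]
    if (length(j) != 1L || is.na(j))
      stop(sprintf("landmark %d has no bilateral counterpart; cannot repair", i))
    if (any(is.na(coords[j, ])))
      stop(sprintf("counterpart %d of landmark %d is missing; cannot repair", j, i))
    coords[i, ] <- reflect_point(coords[j, ], plane)
  }
  specimen_config(config$specimen_id, config$species, config$structure,
                  config$replicate_tag, coords)
}

#' Symmetrise a configuration
#'
#' Removes bilateral asymmetry: every retained bilateral landmark becomes the
#' average of the right-side landmark and the reflection of its left
#' counterpart across the estimated midsagittal plane; medial landmarks are
#' projected onto the plane. Only right-side and medial landmarks are
#' retained, in ascending original index order (excluded landmarks dropped).
#'
#' @param config A `specimen_config` with the full bilateral landmark set.
#' @param defs The matching `landmark_defs` table.
#' @return A `specimen_config` with `length(retained)` landmarks.
#' @export
symmetrise <- function(config, defs) {
  coords <- config$coords
  if (nrow(coords) != nrow(defs))
    stop("configuration landmark count does not match the definition table")
  plane <- estimate_symmetry_plane(coords, defs)
  retained <- retained_indices(defs)
  out <- matrix(NA_real_, length(retained), ncol(coords))
  for (r in seq_along(retained)) {
    i <- retained[r]
    if (defs$side[defs$index == i] == "medial") {
      out[r, ] <- project_point(coords[i, ], plane)
    } else {
      j <- defs$pair_index[defs$index == i]
      out[r, ] <- (coords[i, ] + reflect_point(coords[j, ], plane)) / 2
    }
  }
  cfg <- specimen_config(config$specimen_id, config$species, config$structure,
                         config$replicate_tag, out)
  attr(cfg, "retained") <- retained
  cfg
}

#' Split a symmetrised plastron configuration into lobes
#'
#' Plastra of hinged turtles cannot be superposed whole, so all plastra are
#' divided into anterior and posterior lobe configurations that are
#' superposed independently across species.
#'
#' @param config A symmetrised plastron `specimen_config`.
#' @param defs The plastron `landmark_defs` table.
#' @return A list with elements `anterior` and `posterior`.
#' @export
split_lobes <- function(config, defs) {
  retained <- attr(config, "retained")
  if (is.null(retained)) retained <- retained_indices(defs)
  if (nrow(config$coords) != length(retained))
    stop("expected a symmetrised plastron configuration")
  lobes <- defs$lobe[match(retained, defs$index)]
  if (any(lobes == "none"))
    stop(sprintf("landmarks without lobe assignment: %s",
                 paste(retained[lobes == "none"], collapse = ", ")))
  out <- lapply(c(anterior = "anterior", posterior = "posterior"), function(lb) {
    cfg <- specimen_config(config$specimen_id, config$species,
                           paste0(lb, "_lobe"), config$replicate_tag,
                           config$coords[lobes == lb, , drop = FALSE])
    attr(cfg, "retained") <- retained[lobes == lb]
    cfg
  })
  out
}
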