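#' Consensus of digitisation replicates
#'
#' Superposes the replicate digitisations of one specimen by GPA and returns
#' their mean shape, carrying over the specimen metadata. A single replicate
#' is returned unchanged with a warning.
#'
#' @param replicates List of `specimen_config` objects of the same specimen.
#' @param scale Passed to [gpa()].
#' @return One `specimen_config`.
#' @export
consensus_of_replicates <- function(replicates, scale = TRUE) {
  if (length(replicates) == 1L) {
    warning(sprintf("specimen %s has a single replicate; returned unchanged",
                    replicates[[1]]$specimen_id))
    return(replicates[[1]])
  }
  p <- nrow(replicates[[1]]$coords)
  for (r in replicates)
    if (nrow(r$coords) != p) stop("replicates differ in landmark count")
  sup <- gpa(replicates, scale = scale)
  specimen_config(replicates[[1]]$specimen_id, replicates[[1]]$species,
                  replicates[[1]]$structure, "none", sup$consensus)
}

#' Per-species consensus configurations
#'
#' For each species, its specimens are superposed by GPA and the mean shape is
#' taken. Species with a single specimen contribute that specimen's centred
#' (and optionally unit-size) shape.
#'
#' @param configs List of `specimen_config` objects with species assigned.
#' @param scale Passed to [gpa()].
#' @return A named list of p x k matrices, one per species (sorted by name).
#' @export
species_consensus <- function(configs, scale = TRUE) {
  spp <- vapply(configs, function(cfg) cfg$species, "")
  if (any(is.na(spp))) stop("all configurations need a species assignment")
  out <- lapply(split(configs, spp), function(group) {
    if (length(group) == 1L) {
      x <- center_config(group[[1]]$coords)
      if (scale) x <- x / centroid_size(x)
      return(x)
    }
    gpa(group, scale = scale)$consensus
  })
  out[order(names(out))]
}

#' Assemble a landmark dataset from superposed species blocks
#'
#' A block is a set of per-species configurations that were superposed
#' together (one GPA). Composite datasets (`plastron` = anterior + posterior
#' lobes, `shell` = carapace + plastron) concatenate blocks landmark-wise,
#' restricted to the intersection of the blocks' species; the blocks are
#' deliberately not re-superposed jointly.
#'
#' @param name Dataset name.
#' @param blocks Named list of blocks; each block is a named list of p x k
#'   species matrices (as returned by [species_consensus()] after a joint
#'   GPA).
#' @return A `landmark_dataset`.
#' @export
assemble_dataset <- function(name, blocks) {
  stopifnot(length(blocks) >= 1L)
  species <- Reduce(intersect, lapply(blocks, names))
  if (length(species) == 0L) stop("empty species intersection across blocks")
  species <- sort(species)
  block_sizes <- vapply(blocks, function(b) nrow(b[[1]]), 0L)
  k <- ncol(blocks[[1]][[1]])
  p <- sum(block_sizes)
  data <- array(NA_real_, c(length(species), p, k),
                dimnames = list(species, NULL, NULL))
  for (si in seq_along(species)) {
    rows <- do.call(rbind, lapply(blocks, function(b) b[[species[si]]]))
    data[si, , ] <- rows
  }
  if (any(is.na(data))) stop("assembled dataset contains missing values")
  landmark_dataset(name, data,
                   blocks = rep(names(blocks) %||% as.character(seq_along(blocks)),
                                block_sizes))
}

#' Construct a landmark dataset
#'
#' The container consumed by every optimality criterion: a species x
#' landmarks x dims array of superposed coordinates.
#'
#' @param name Dataset name.
#' @param data 3-d array (species x landmarks x dims) with species dimnames,
#'   or a named list of p x k matrices.
#' @param blocks Optional character vector of block provenance per landmark.
#' @return An object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(name, data, blocks = NULL) {
  if (is.list(data)) {
    species <- names(data)
    arr <- array(NA_real_, c(length(data), nrow(data[[1]]), ncol(data[[1]])),
                 dimnames = list(species, NULL, NULL))
    for (i in seq_along(data)) arr[i, , ] <- data[[i]]
    data <- arr
  }
  stopifnot(length(dim(data)) == 3L)
  if (any(is.na(data))) stop("landmark datasets must be complete (no missing data)")
  if (is.null(dimnames(data)[[1]])) stop("species dimnames required")
  structure(list(name = name, species = dimnames(data)[[1]], data = data,
                 blocks = blocks %||% rep("all", dim(data)[2]),
                 n_landmarks = dim(data)[2], dims = dim(data)[3]),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("<landmark_dataset> '%s': %d species, %d landmarks x %dD\n",
              x$name, length(x$species), x$n_landmarks, x$dims))
  invisible(x)
}

# species x (landmarks*dims) matrix, coordinates in landmark-major order
dataset_flat <- function(dataset) {
  n <- length(dataset$species)
  out <- matrix(NA_real_, n, dataset$n_landmarks * dataset$dims)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(dataset$data[i, , ]))
  rownames(out) <- dataset$species
  out
}

# restrict a dataset to a species subset
dataset_subset <- function(dataset, species) {
  stopifnot(all(species %in% dataset$species))
  landmark_dataset(dataset$name,
                   dataset$data[species, , , drop = FALSE],
                   blocks = dataset$blocks)
}

# extract per-species matrix
dataset_config <- function(dataset, sp) dataset$data[sp, , ]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full landmark processing pipeline
#'
#' From raw specimen configurations to the five analysis datasets: replicate
#' consensus per specimen, abnormality repair (carapace), symmetrisation,
#' species consensus, lobe splitting (plastron), independent GPA of the
#' anterior lobe, posterior lobe and carapace blocks across species, and
#' assembly of the composite plastron and shell datasets on the species
#' intersection.
#'
#' @param carapace_configs List of carapace `specimen_config`s (replicates
#'   tagged, species assigned); may be `NULL`.
#' @param plastron_configs List of plastron `specimen_config`s; may be `NULL`.
#' @param carapace_defs,plastron_defs Definition tables (defaults: built-in).
#' @param abnormality_repairs Named list: specimen id -> integer vector of
#'   carapace landmarks to repair by reflection.
#' @return Named list of `landmark_dataset`s (subset of `carapace`,
#'   `anterior_lobe`, `posterior_lobe`, `plastron`, `shell`).
#' @export
process_study <- function(carapace_configs = NULL, plastron_configs = NULL,
                          carapace_defs = builtin_definitions("carapace"),
                          plastron_defs = builtin_definitions("plastron"),
                          abnormality_repairs = list()) {
  datasets <- list()
  blocks <- list()
  if (!is.null(carapace_configs)) {
    cons <- replicate_consensus_all(carapace_configs)
    cons <- lapply(cons, function(cfg) {
      fix <- abnormality_repairs[[cfg$specimen_id]]
      if (!is.null(fix)) repair_abnormalities(cfg, carapace_defs, fix) else cfg
    })
    sym <- lapply(cons, symmetrise, defs = carapace_defs)
    spp <- species_consensus(sym)
    blocks$carapace <- gpa_block(spp)
    datasets$carapace <- assemble_dataset("carapace", blocks["carapace"])
  }
  if (!is.null(plastron_configs)) {
    cons <- replicate_consensus_all(plastron_configs)
    sym <- lapply(cons, symmetrise, defs = plastron_defs)
    lobes <- lapply(sym, split_lobes, defs = plastron_defs)
    for (lb in c("anterior", "posterior")) {
      spp <- species_consensus(lapply(lobes, `[[`, lb))
      blocks[[paste0(lb, "_lobe")]] <- gpa_block(spp)
      datasets[[paste0(lb, "_lobe")]] <-
        assemble_dataset(paste0(lb, "_lobe"), blocks[paste0(lb, "_lobe")])
    }
    datasets$plastron <- assemble_dataset(
      "plastron", blocks[c("anterior_lobe", "posterior_lobe")])
  }
  if (!is.null(carapace_configs) && !is.null(plastron_configs)) {
    datasets$shell <- assemble_dataset(
      "shell", blocks[c("carapace", "anterior_lobe", "posterior_lobe")])
  }
  datasets
}

# group configs by specimen and collapse replicates
replicate_consensus_all <- function(configs) {
  ids <- vapply(configs, function(cfg) cfg$specimen_id, "")
  out <- lapply(split(configs, ids), function(group) {
    if (length(group) == 1L) group[[1]] else consensus_of_replicates(group)
  })
  unname(out)
}

# joint GPA of per-species configurations, returned as a named block
gpa_block <- function(species_shapes) {
  if (length(species_shapes) == 1L) {
    x <- center_config(species_shapes[[1]])
    return(stats::setNames(list(x / centroid_size(x)), names(species_shapes)))
  }
  sup <- gpa(unname(species_shapes), scale = TRUE)
  out <- sup$members
  names(out) <- names(species_shapes)
  out
}

#' Export / import a landmark dataset as long-format CSV
#'
#' Columns species, landmark, axis, value, block; coordinates are written
#' with full precision so a write/read cycle is exact.
#'
#' @param dataset A [landmark_dataset()].
#' @param path CSV path.
#' @return `path` (write) or the rebuilt `landmark_dataset` (read).
#' @export
write_dataset_csv <- function(dataset, path) {
  n <- length(dataset$species); p <- dataset$n_landmarks; k <- dataset$dims
  long <- data.frame(
    species = rep(dataset$species, each = p * k),
    landmark = rep(rep(seq_len(p), each = k), times = n),
    axis = rep(c("x", "y", "z")[seq_len(k)], times = n * p),
    value = sprintf("%.17g", as.vector(vapply(seq_len(n), function(i)
      as.vector(t(dataset$data[i, , ])), numeric(p * k)))),
    block = rep(rep(dataset$blocks, each = k), times = n))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @param name Dataset name for the rebuilt object.
#' @export
read_dataset_csv <- function(path, name = "imported") {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(value = "character"))
  species <- unique(long$species)
  p <- max(long$landmark)
  k <- length(unique(long$axis))
  arr <- array(NA_real_, c(length(species), p, k),
               dimnames = list(species, NULL, NULL))
  for (i in seq_along(species)) {
    v <- as.numeric(long$value[long$species == species[i]])
    arr[i, , ] <- matrix(v, p, k, byrow = TRUE)
  }
  blocks <- long$block[long$species == species[1]][seq(1, p * k, by = k)]
  landmark_dataset(name, arr, blocks = blocks)
}
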