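#' Resampling specification
#'
#' @param mode `"bootstrap"` (landmarks drawn with replacement to the
#'   original count) or `"symmetric"` (each landmark independently reweighted
#'   to 0 or 2 with probability `change_probability/2` each, else 1).
#' @param replicates Number of replicates.
#' @param change_probability Symmetric-mode perturbation probability.
#' @param seed Integer seed.
#' @return An object of class `resampling_spec`.
#' @export
resampling_spec <- function(mode = c("bootstrap", "symmetric"),
                            replicates = 100L, change_probability = 0.33,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(replicates >= 1L, change_probability > 0, change_probability < 1)
  structure(list(mode = mode, replicates = as.integer(replicates),
                 change_probability = change_probability,
                 seed = as.integer(seed)),
            class = "resampling_spec")
}

#' Resample the landmarks of a dataset
#'
#' The unit of resampling is the whole landmark (its coordinates move
#' together); the superposition is not recomputed. An all-zero-weight
#' symmetric draw is redrawn (with a message).
#'
#' @param dataset A [landmark_dataset()].
#' @param spec A [resampling_spec()].
#' @param replicate Which replicate to generate (determines the sub-seed).
#' @return A resampled `landmark_dataset`; attribute `landmark_index` records
#'   the drawn landmark multiset.
#' @export
resample_landmarks <- function(dataset, spec, replicate = 1L) {
  p <- dataset$n_landmarks
  with_local_seed(spec$seed + replicate, {
    idx <- if (spec$mode == "bootstrap") {
      sort(sample.int(p, p, replace = TRUE))
    } else {
      repeat {
        u <- stats::runif(p)
        w <- ifelse(u < spec$change_probability / 2, 0L,
                    ifelse(u < spec$change_probability, 2L, 1L))
        if (sum(w) > 0L) break
        message("all-zero-weight symmetric draw redrawn")
      }
      rep(seq_len(p), times = w)
    }
    out <- landmark_dataset(dataset$name,
                            dataset$data[, idx, , drop = FALSE],
                            blocks = dataset$blocks[idx])
    attr(out, "landmark_index") <- idx
    out
  })
}

#' Bootstrap branch support
#'
#' Runs one (typically lighter-settings) search per resampled dataset,
#' records split frequencies, and returns the majority-rule consensus at the
#' requested threshold with frequencies as support.
#'
#' @param dataset A [landmark_dataset()].
#' @param search_fun `function(dataset, seed) -> phylo` run on each
#'   replicate.
#' @param spec A [resampling_spec()].
#' @param consensus_threshold Consensus frequency threshold (default 0.70).
#' @return List with `trees` (per-replicate) and `consensus` (support in %).
#' @export
bootstrap_support <- function(dataset, search_fun, spec = resampling_spec(),
                              consensus_threshold = 0.70) {
  trees <- vector("list", spec$replicates)
  for (b in seq_len(spec$replicates)) {
    rep_data <- resample_landmarks(dataset, spec, replicate = b)
    trees[[b]] <- search_fun(rep_data, spec$seed + b)
  }
  list(trees = trees,
       consensus = majority_consensus(trees, threshold = consensus_threshold))
}
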