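#' Read a landmark definition table
#'
#' A definition table assigns every digitised landmark an index, a side
#' (`right`, `left`, `medial`), an optional plastral lobe (`anterior`,
#' `posterior`, `none`), the index of its bilateral counterpart (`NA` for
#' medial landmarks) and an exclusion flag for landmarks digitised but not
#' analysed.
#'
#' @param path CSV with columns index, name, side, lobe, pair_index, excluded.
#' @return A validated `data.frame` of class `landmark_defs`.
#' @export
read_landmark_definitions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  landmark_defs(d)
}

#' Construct and validate a landmark definition table
#'
#' @param d data.frame with columns index, name, side, lobe, pair_index,
#'   excluded (lobe and excluded optional; default "none"/FALSE).
#' @return The validated table, classed `landmark_defs`.
#' @export
landmark_defs <- function(d) {
  if (is.null(d$lobe)) d$lobe <- "none"
  if (is.null(d$excluded)) d$excluded <- FALSE
  d$excluded <- as.logical(d$excluded)
  d$lobe[is.na(d$lobe) | d$lobe == ""] <- "none"
  stopifnot(all(c("index", "side", "pair_index") %in% names(d)))
  stopifnot(all(d$side %in% c("right", "left", "medial")))
  stopifnot(all(d$lobe %in% c("anterior", "posterior", "none")))
  stopifnot(identical(sort(d$index), seq_len(nrow(d))))
  d <- d[order(d$index), , drop = FALSE]
  med <- d$side == "medial"
  if (any(med & !is.na(d$pair_index)))
    stop("medial landmarks must not have a pair_index")
  if (any(!med & is.na(d$pair_index)))
    stop("non-medial landmarks must have a pair_index")
  paired <- d$index[!med]
  # pairing must be an involution linking opposite sides
  for (i in paired) {
    j <- d$pair_index[d$index == i]
    if (!(j %in% d$index)) stop(sprintf("pair_index %d of landmark %d undefined", j, i))
    if (d$pair_index[d$index == j] != i)
      stop(sprintf("pairing is not an involution at landmarks %d/%d", i, j))
    if (d$side[d$index == j] == d$side[d$index == i])
      stop(sprintf("landmarks %d and %d are paired but on the same side", i, j))
  }
  class(d) <- c("landmark_defs", "data.frame")
  d
}

#' Built-in carapace and plastron landmark definition tables
#'
#' The carapace scheme has 152 landmarks (150 bilaterally paired on bone
#' sutures and scute sulci, 2 medial) and the plastron scheme 52 (46 paired +
#' 2 medial analysed, plus 4 excluded bridge landmarks digitised only to allow
#' carapace realignment). After symmetrisation these reduce to 77 and 25
#' effective landmarks.
#'
#' @param structure `"carapace"` or `"plastron"`.
#' @return A `landmark_defs` table.
#' @export
builtin_definitions <- function(structure = c("carapace", "plastron")) {
  structure <- match.arg(structure)
  path <- system.file("extdata", paste0(structure, "_landmarks.csv"),
                      package = "morphotree")
  read_landmark_definitions(path)
}

# indices retained after symmetrisation (right + medial, non-excluded),
# in ascending original order
retained_indices <- function(defs) {
  keep <- !defs$excluded & defs$side %in% c("right", "medial")
  sort(defs$index[keep])
}

#' Effective landmark counts of the built-in definition scheme
#'
#' Counts of landmarks retained after symmetrisation (right side + medial,
#' excluded landmarks dropped), per analysis dataset: carapace, plastron,
#' anterior lobe, posterior lobe, and the composite shell.
#'
#' @return Named integer vector.
#' @export
landmark_counts <- function() {
  car <- builtin_definitions("carapace")
  pla <- builtin_definitions("plastron")
  ret <- retained_indices(pla)
  lobes <- pla$lobe[match(ret, pla$index)]
  counts <- c(carapace = length(retained_indices(car)),
              plastron = length(ret),
              anterior_lobe = sum(lobes == "anterior"),
              posterior_lobe = sum(lobes == "posterior"))
  c(counts, shell = unname(counts["carapace"] + counts["plastron"]))
}
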