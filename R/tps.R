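#' Read landmark configurations from a TPS file
#'
#' Parses the plain-text TPS dialect used for 3D digitised landmark data:
#' records start with an `LM=` or `LM3=` line giving the landmark count,
#' followed by one whitespace-separated coordinate row per landmark, and an
#' `ID=` line naming the specimen. Replicate digitisations of the same
#' specimen are tagged by a `$a` / `$b` suffix on the ID. `SCALE=` and
#' `IMAGE=` lines are ignored. Missing landmarks may be encoded as `NA`
#' coordinate rows.
#'
#' @param path Path to a TPS file.
#' @param structure Structure label attached to every configuration
#'   (`"carapace"`, `"plastron"`, or any free label).
#' @param species Optional named character vector mapping specimen ids to
#'   species names; unmatched specimens get species `NA`.
#' @return A list of specimen configurations (see [specimen_config()]).
#' @export
read_tps <- function(path, structure = "carapace", species = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  configs <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    header <- lines[i]
    m <- regmatches(header, regexec("^LM3?=([0-9]+)$", header))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("malformed TPS record near line %d: expected LM=/LM3= header, got '%s'",
                   i, header))
    }
    rec <- rec + 1L
    p <- as.integer(m[2])
    if (i + p > length(lines)) {
      stop(sprintf("malformed TPS record %d: header declares %d landmarks but file ends early",
                   rec, p))
    }
    coord_lines <- lines[(i + 1L):(i + p)]
    bad <- grep("^(LM3?=|ID=|SCALE=|IMAGE=)", coord_lines)
    if (length(bad) > 0L) {
      stop(sprintf("malformed TPS record %d: header declares %d landmarks but only %d coordinate rows found",
                   rec, p, bad[1] - 1L))
    }
    coords <- do.call(rbind, lapply(coord_lines, function(l) {
      as.numeric(strsplit(l, "[ \t]+")[[1]])
    }))
    ncols <- ncol(coords)
    if (!ncols %in% c(2L, 3L)) {
      stop(sprintf("malformed TPS record %d: coordinate rows have %d columns", rec, ncols))
    }
    i <- i + p + 1L
    id <- NA_character_
    while (i <= length(lines) && !grepl("^LM3?=", lines[i])) {
      if (grepl("^ID=", lines[i])) id <- sub("^ID=", "", lines[i])
      i <- i + 1L
    }
    if (is.na(id)) stop(sprintf("malformed TPS record %d: no ID= line", rec))
    parsed <- parse_replicate_id(id)
    sp <- if (!is.null(species) && parsed$specimen_id %in% names(species)) {
      unname(species[parsed$specimen_id])
    } else NA_character_
    configs[[length(configs) + 1L]] <- specimen_config(
      specimen_id = parsed$specimen_id, species = sp, structure = structure,
      replicate_tag = parsed$replicate_tag, coords = coords)
  }
  configs
}

# "FMNH 12345$b" -> specimen "FMNH 12345", replicate "b"; unknown suffixes
# warn and fall back to replicate "none".
parse_replicate_id <- function(id) {
  if (grepl("\\$", id)) {
    parts <- strsplit(id, "\\$")[[1]]
    tag <- parts[length(parts)]
    base <- paste(parts[-length(parts)], collapse = "$")
    if (tag %in% c("a", "b")) {
      return(list(specimen_id = base, replicate_tag = tag))
    }
    warning(sprintf("unknown replicate suffix '$%s' on '%s'; treating as untagged", tag, id))
    return(list(specimen_id = base, replicate_tag = "none"))
  }
  list(specimen_id = id, replicate_tag = "none")
}

#' Construct a specimen landmark configuration
#'
#' @param specimen_id Specimen identifier (e.g. a collection number).
#' @param species Species name or `NA`.
#' @param structure Free structure label ("carapace", "plastron", ...).
#' @param replicate_tag `"a"`, `"b"` or `"none"`.
#' @param coords Numeric p x 2 or p x 3 matrix; rows with any `NA` are
#'   recorded in the missing mask.
#' @return An object of class `specimen_config`.
#' @export
specimen_config <- function(specimen_id, species = NA_character_,
                            structure = "carapace",
                            replicate_tag = "none", coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) %in% c(2L, 3L))
  missing_mask <- which(apply(coords, 1L, function(r) any(is.na(r))))
  structure(list(specimen_id = specimen_id, species = species,
                 structure = structure, replicate_tag = replicate_tag,
                 coords = coords, missing_mask = missing_mask),
            class = "specimen_config")
}

#' @export
print.specimen_config <- function(x, ...) {
  cat(sprintf("<specimen_config> %s (%s, replicate %s): %d landmarks x %dD",
              x$specimen_id, x$structure, x$replicate_tag,
              nrow(x$coords), ncol(x$coords)))
  if (length(x$missing_mask) > 0L)
    cat(sprintf(", %d missing", length(x$missing_mask)))
  cat("\n")
  invisible(x)
}

#' Write configurations to a TPS file
#'
#' Inverse of [read_tps()]: coordinates are written with full precision
#' (`%.17g`) so that a write/read cycle is bit-for-bit stable.
#'
#' @param configs A list of `specimen_config` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    coords <- cfg$coords
    writeLines(sprintf("LM3=%d", nrow(coords)), con)
    rows <- apply(coords, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(rows, con)
    id <- cfg$specimen_id
    if (!identical(cfg$replicate_tag, "none"))
      id <- paste0(id, "$", cfg$replicate_tag)
    writeLines(sprintf("ID=%s", id), con)
  }
  invisible(path)
}
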