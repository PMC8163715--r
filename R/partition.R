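#' Construct a specimen-to-species partition
#'
#' Maps sequence ids to species labels, inducing the query group (the
#' species being diagnosed) and the reference group (everything else) for
#' the diagnostic-character search, and the groups of the distance matrix.
#'
#' @param ids Character vector of sequence ids.
#' @param species Character vector of species labels, parallel to `ids`.
#' @return An object of class `species_partition` with `assignments`
#'   (named character vector, id -> species) and `species` (labels in
#'   first-appearance order).
#' @examples
#' species_partition(c("s1", "s2", "s3"), c("SpA", "SpA", "SpB"))
#' @export
species_partition <- function(ids, species) {
  ids <- trimws(as.character(ids))
  species <- trimws(as.character(species))
  if (length(ids) == 0L) {
    stop("partition is empty", call. = FALSE)
  }
  if (length(ids) != length(species)) {
    stop("ids and species differ in length", call. = FALSE)
  }
  if (any(ids == "") || any(species == "")) {
    stop("blank sequence id or species label in partition", call. = FALSE)
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    for (id in unique(ids[dup])) {
      sp <- unique(species[ids == id])
      if (length(sp) > 1L) {
        stop("conflicting species assignment for sequence '", id, "': ",
             paste(sp, collapse = " vs "), call. = FALSE)
      }
    }
    species <- species[!dup]
    ids <- ids[!dup]
  }
  assignments <- stats::setNames(species, ids)
  structure(
    list(assignments = assignments, species = unique(species)),
    class = "species_partition"
  )
}

#' Read a partition file
#'
#' Tab-separated lines `sequence_id<TAB>species[<TAB>marker]`. Lines that
#' are blank or start with `#` are ignored, so a commented header is fine.
#' A sequence id listed twice with different species labels is an error.
#'
#' @param source Path to a TSV file.
#' @return A [species_partition()] object.
#' @export
read_partition <- function(source) {
  if (!file.exists(source)) {
    stop("partition file not found: ", source, call. = FALSE)
  }
  lines <- readLines(source, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("empty partition file: ", source, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 2L)) {
    stop("malformed partition line (need id<TAB>species): '",
         lines[which(n < 2L)[1L]], "'", call. = FALSE)
  }
  species_partition(
    ids = vapply(fields, `[[`, character(1), 1L),
    species = vapply(fields, `[[`, character(1), 2L)
  )
}

#' Write a partition file
#'
#' @param part A [species_partition()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "species_partition"))
  writeLines(
    c("#sequence_id\tspecies",
      paste(names(part$assignments), part$assignments, sep = "\t")),
    path
  )
  invisible(path)
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("<species_partition> %d sequences in %d species\n",
              length(x$assignments), length(x$species)))
  invisible(x)
}

# ids belonging to one species, in alignment order
species_ids <- function(aln, part, species) {
  aln$ids[!is.na(part$assignments[aln$ids]) &
            part$assignments[aln$ids] == species]
}
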