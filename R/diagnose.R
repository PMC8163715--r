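#' Compute molecular diagnoses for every species
#'
#' The package's central fitting function. For each species and each marker
#' in which it has at least one sequence, it collects the single-position
#' diagnostic characters followed by the combined adjacent-duo characters
#' against the reference group, together with the number of query sequences
#' the diagnosis is based on. The result prints in the style of the
#' "Molecular diagnosis" paragraph of a species description, e.g.
#' `COI: 220: G. 28S: 545-546: AC (based on 36 COI sequences and 19 28S
#' sequences)`.
#'
#' Characters are listed deterministically: singles ascending by position,
#' then duos ascending by first position. Markers are analysed
#' independently; a species missing from a marker's alignment simply has no
#' entry for that marker.
#'
#' @param alignments A [dna_alignment()] or a named list of them (names are
#'   marker labels; unnamed entries fall back to each alignment's own
#'   `marker` field).
#' @param part A [species_partition()].
#' @param policy Ambiguity/gap policy, `"conservative"` (default) or
#'   `"strict"`; see [find_single_diagnostics()].
#' @param k_window Combined-character window; only adjacent duos
#'   (`k_window = 2`) are supported.
#' @param reference Optional species labels restricting the reference group
#'   (default: all other species in the partition).
#' @param strict_ids If `TRUE`, alignment sequences absent from the
#'   partition are an error instead of being dropped with a warning.
#' @return An object of class `diagnosis`: per-species, per-marker character
#'   tables plus query-group sizes and the configuration used. Methods:
#'   [print.diagnosis()], [summary.diagnosis()], [predict.diagnosis()].
#' @seealso [format_diagnosis_text()], [classify_sequence()]
#' @export
diagnose <- function(alignments, part, policy = c("conservative", "strict"),
                     k_window = 2L, reference = NULL, strict_ids = FALSE) {
  policy <- match.arg(policy)
  if (!identical(as.integer(k_window), 2L)) {
    stop("only k_window = 2 (adjacent duos) is supported", call. = FALSE)
  }
  if (inherits(alignments, "dna_alignment")) {
    alignments <- stats::setNames(list(alignments), alignments$marker)
  }
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    names(alignments) <- vapply(alignments, `[[`, character(1), "marker")
  }
  stopifnot(inherits(part, "species_partition"))
  if (length(part$species) < 2L) {
    stop("need at least 2 species: no reference group exists", call. = FALSE)
  }

  alignments <- lapply(alignments, prepare_dataset, part = part,
                       strict = strict_ids)

  species <- part$species
  per_species <- lapply(species, function(sp) {
    markers <- list()
    for (m in names(alignments)) {
      aln <- alignments[[m]]
      q_ids <- species_ids(aln, part, sp)
      if (length(q_ids) == 0L) next
      singles <- find_single_diagnostics(aln, part, sp, policy = policy,
                                         reference = reference)
      combined <- find_combined_diagnostics(aln, part, sp, policy = policy,
                                            reference = reference)
      chars <- rbind(singles[order(singles$pos), , drop = FALSE],
                     combined[order(combined$pos), , drop = FALSE])
      rownames(chars) <- NULL
      markers[[m]] <- list(characters = chars, n_sequences = length(q_ids))
    }
    markers
  })
  names(per_species) <- species

  structure(
    list(species = per_species,
         markers = names(alignments),
         config = list(policy = policy, k_window = 2L, reference = reference),
         alignment_lengths = vapply(alignments, `[[`, integer(1), "length")),
    class = "diagnosis"
  )
}

#' @describeIn diagnose Number of species in a diagnosis set.
#' @param object,x A `diagnosis` object.
#' @param ... Unused.
#' @export
print.diagnosis <- function(x, ...) {
  cat(sprintf("Molecular diagnoses (%s policy, k-window 2) for %d species\n\n",
              x$config$policy, length(x$species)))
  for (sp in names(x$species)) {
    cat(sp, "\n  ", format_diagnosis_text(x, sp), "\n", sep = "")
  }
  invisible(x)
}

#' Summarise a diagnosis set
#'
#' Per species and marker: query-group size and numbers of single and
#' combined diagnostic characters.
#'
#' @param object A `diagnosis` object.
#' @param ... Unused.
#' @return A data frame with one row per (species, marker).
#' @export
summary.diagnosis <- function(object, ...) {
  rows <- list()
  for (sp in names(object$species)) {
    for (m in names(object$species[[sp]])) {
      entry <- object$species[[sp]][[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, marker = m, n_sequences = entry$n_sequences,
        n_single = sum(entry$characters$kind == "single"),
        n_combined = sum(entry$characters$kind == "combined")
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), marker = character(),
               n_sequences = integer(), n_single = integer(),
               n_combined = integer())
  class(out) <- c("summary.diagnosis", class(out))
  out
}

#' @export
print.summary.diagnosis <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
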