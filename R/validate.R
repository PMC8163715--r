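#' Validate an alignment against a partition
#'
#' Cross-checks the two inputs before any analysis and returns a report
#' rather than failing piecemeal. Errors make the dataset unusable
#' downstream; warnings flag conditions the analyses handle but the user
#' should know about (species with a single sequence have no defined
#' within-group distance; all-gap columns carry no information).
#'
#' @param aln A [dna_alignment()].
#' @param part A [species_partition()].
#' @param strict If `TRUE`, alignment sequences absent from the partition
#'   are errors; by default they are warnings and downstream functions drop
#'   them (real datasets often carry outgroups or unassigned specimens).
#' @return An object of class `validation_report`: data frames `errors` and
#'   `warnings` with columns `code`, `message`, `context`. Empty `errors`
#'   means the dataset is usable.
#' @export
validate_dataset <- function(aln, part, strict = FALSE) {
  stopifnot(inherits(aln, "dna_alignment"), inherits(part, "species_partition"))
  errors <- list()
  warnings <- list()
  add <- function(lst, code, message, context) {
    lst[[length(lst) + 1L]] <- data.frame(code = code, message = message,
                                          context = context)
    lst
  }

  unassigned <- setdiff(aln$ids, names(part$assignments))
  for (id in unassigned) {
    msg <- "sequence in alignment but not in partition"
    if (strict) {
      errors <- add(errors, "unassigned_sequence", msg, id)
    } else {
      warnings <- add(warnings, "unassigned_sequence",
                      paste(msg, "(will be dropped)"), id)
    }
  }

  present <- intersect(aln$ids, names(part$assignments))
  counts <- table(part$assignments[present])
  for (sp in names(counts)[counts == 1L]) {
    warnings <- add(warnings, "single_sequence_species",
                    "species has one sequence: within-group distance undefined",
                    sp)
  }

  if (length(present) > 0L) {
    sub <- aln$mat[present, , drop = FALSE]
    allgap <- which(colSums(sub != "-") == 0L)
    for (j in allgap) {
      warnings <- add(warnings, "all_gap_column", "column is entirely gaps",
                      as.character(j))
    }
  }

  empty <- data.frame(code = character(), message = character(),
                      context = character())
  structure(
    list(errors = if (length(errors)) do.call(rbind, errors) else empty,
         warnings = if (length(warnings)) do.call(rbind, warnings) else empty),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) {
    cat("errors:\n")
    for (i in seq_len(nrow(x$errors)))
      cat(sprintf("  [%s] %s (%s)\n", x$errors$code[i], x$errors$message[i],
                  x$errors$context[i]))
  }
  if (nrow(x$warnings)) {
    cat("warnings:\n")
    for (i in seq_len(nrow(x$warnings)))
      cat(sprintf("  [%s] %s (%s)\n", x$warnings$code[i],
                  x$warnings$message[i], x$warnings$context[i]))
  }
  invisible(x)
}

# Shared entry gate for analyses: validate, fail on errors, drop
# unassigned sequences (default mode) with a warning.
prepare_dataset <- function(aln, part, strict = FALSE) {
  report <- validate_dataset(aln, part, strict = strict)
  if (nrow(report$errors) > 0L) {
    stop("dataset validation failed: ", report$errors$message[1L], " (",
         report$errors$context[1L], ")", call. = FALSE)
  }
  present <- intersect(aln$ids, names(part$assignments))
  if (length(present) < length(aln$ids)) {
    warning(sprintf("dropping %d sequence(s) absent from the partition",
                    length(aln$ids) - length(present)), call. = FALSE)
    aln <- subset_alignment(aln, present)
  }
  aln
}
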