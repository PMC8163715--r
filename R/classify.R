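#' Classify one sequence against a diagnosis set
#'
#' Checks an unknown sequence, pre-aligned to the same coordinates as the
#' alignment the diagnoses were computed from, against every species'
#' diagnostic characters for one marker. For each species the score is the
#' fraction of its applicable diagnostics the sequence matches; a
#' diagnostic is not applicable when the sequence has a gap at (any of) its
#' position(s). Under the `"strict"` policy an ambiguity code in the
#' sequence counts as a non-match; under `"conservative"` it counts as a
#' possible match when its expansion contains the diagnostic state.
#'
#' @param seq A single aligned sequence: character string or a
#'   [dna_alignment()] with one record.
#' @param diag A `diagnosis` object from [diagnose()].
#' @param marker Marker label present in `diag`.
#' @param policy Matching policy; defaults to the policy the diagnosis was
#'   computed under.
#' @return An object of class `classification`: `scores` (data frame with
#'   `species`, `matched`, `applicable`, `fraction`), `verdict`
#'   (`"unique"` if exactly one species matches all of its applicable
#'   diagnostics, `"ambiguous"` if several do, `"no_call"` if none does)
#'   and `species` (the uniquely matching species, or `NA`).
#' @export
classify_sequence <- function(seq, diag, marker, policy = NULL) {
  stopifnot(inherits(diag, "diagnosis"))
  if (is.null(policy)) policy <- diag$config$policy
  policy <- match.arg(policy, c("conservative", "strict"))
  if (!marker %in% names(diag$alignment_lengths)) {
    stop("marker '", marker, "' not in diagnosis set", call. = FALSE)
  }
  if (inherits(seq, "dna_alignment")) {
    if (length(seq$ids) != 1L) {
      stop("classify_sequence() takes one sequence; see predict.diagnosis()",
           call. = FALSE)
    }
    seq <- unname(seq$residues[[1L]])
  }
  seq <- chartr("U", "T", toupper(seq))
  L <- diag$alignment_lengths[[marker]]
  if (nchar(seq) != L) {
    stop("sequence length ", nchar(seq), " does not match alignment length ",
         L, " for marker ", marker, call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), IUPAC_SYMBOLS)
  if (length(bad) > 0L) {
    stop("non-IUPAC residue character '", bad[[1L]], "' in query sequence",
         call. = FALSE)
  }

  match_state <- function(sym, state) {
    if (sym == "-") return(NA)        # not applicable
    if (policy == "strict") return(sym == state)
    state %in% IUPAC_EXPANSION[[sym]]
  }

  rows <- list()
  skipped <- character(0)
  for (sp in names(diag$species)) {
    entry <- diag$species[[sp]][[marker]]
    if (is.null(entry)) next
    cdf <- entry$characters
    if (nrow(cdf) == 0L) {
      skipped <- c(skipped, sp)
      next
    }
    matched <- 0L
    applicable <- 0L
    for (i in seq_len(nrow(cdf))) {
      states <- strsplit(cdf$states[[i]], "", fixed = TRUE)[[1L]]
      pos <- c(cdf$pos[[i]], cdf$pos2[[i]])
      pos <- pos[!is.na(pos)]
      m <- vapply(seq_along(pos),
                  function(k) match_state(chars[[pos[[k]]]], states[[k]]),
                  logical(1))
      if (anyNA(m)) next               # gap at a member position
      applicable <- applicable + 1L
      if (all(m)) matched <- matched + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, matched = matched, applicable = applicable,
      fraction = if (applicable > 0L) matched / applicable else NA_real_
    )
  }
  if (length(skipped) > 0L) {
    warning("species without diagnostics for marker ", marker,
            " excluded from classification: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  scores <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), matched = integer(),
               applicable = integer(), fraction = numeric())
  full <- scores$species[!is.na(scores$fraction) & scores$fraction == 1]
  verdict <- if (length(full) == 1L) "unique"
             else if (length(full) > 1L) "ambiguous" else "no_call"
  structure(
    list(scores = scores, verdict = verdict,
         species = if (verdict == "unique") full else NA_character_),
    class = "classification"
  )
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> verdict: %s%s\n", x$verdict,
              if (!is.na(x$species)) paste0(" (", x$species, ")") else ""))
  print.data.frame(x$scores, row.names = FALSE)
  invisible(x)
}

#' Classify new sequences against a fitted diagnosis set
#'
#' `predict()` method for [diagnose()] results: runs
#' [classify_sequence()] on every sequence of `newdata`.
#'
#' @param object A `diagnosis` object.
#' @param newdata A [dna_alignment()] (sequences pre-aligned to the marker's
#'   coordinates) or a named character vector of aligned sequences.
#' @param marker Marker label to classify against.
#' @param policy Matching policy; defaults to the fitting policy.
#' @param ... Unused.
#' @return Data frame with one row per query sequence: `id`, `verdict`,
#'   `species` (`NA` unless the verdict is `"unique"`), `fraction` (best
#'   match fraction observed).
#' @export
predict.diagnosis <- function(object, newdata, marker, policy = NULL, ...) {
  if (inherits(newdata, "dna_alignment")) {
    seqs <- newdata$residues
  } else {
    seqs <- newdata
    if (is.null(names(seqs))) names(seqs) <- paste0("query", seq_along(seqs))
  }
  rows <- lapply(names(seqs), function(id) {
    cl <- classify_sequence(seqs[[id]], object, marker, policy = policy)
    best <- if (nrow(cl$scores) > 0L && any(!is.na(cl$scores$fraction)))
      max(cl$scores$fraction, na.rm = TRUE) else NA_real_
    data.frame(id = id, verdict = cl$verdict, species = cl$species,
               fraction = best)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
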