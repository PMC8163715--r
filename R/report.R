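# Rendering diagnoses and distance tables the way taxonomic papers print
# them, plus machine-readable JSON. JSON is the canonical output; the text
# rendering is derived from it and is inverse-parseable.

format_characters <- function(cdf, dash = "-") {
  if (nrow(cdf) == 0L) return("none")
  items <- ifelse(is.na(cdf$pos2),
                  paste0(cdf$pos, ": ", cdf$states),
                  paste0(cdf$pos, dash, cdf$pos2, ": ", cdf$states))
  paste(items, collapse = "; ")
}

#' Render one species' molecular diagnosis as text
#'
#' Produces the one-line diagnosis paragraph of a species description:
#' per marker, singles as `position: base` and duos as
#' `first-second: bases`, `; `-separated, marker blocks joined by `. `,
#' followed by the query-group sizes, e.g.
#' `"COI: 220: G. 28S: 545-546: AC (based on 36 COI sequences and 19 28S
#' sequences)"`. Characters appear in the canonical sorted order (singles
#' by position, then duos by first position). Machine output uses an ASCII
#' hyphen between duo positions; `unicode = TRUE` restores the en dash of
#' printed diagnoses.
#'
#' @param diag A `diagnosis` from [diagnose()].
#' @param species Species label present in the diagnosis set.
#' @param unicode Use an en dash between duo positions.
#' @return A character scalar.
#' @export
format_diagnosis_text <- function(diag, species, unicode = FALSE) {
  stopifnot(inherits(diag, "diagnosis"))
  entry <- diag$species[[species]]
  if (is.null(entry)) {
    stop("species '", species, "' not in diagnosis set", call. = FALSE)
  }
  dash <- if (unicode) "–" else "-"
  markers <- intersect(diag$markers, names(entry))
  if (length(markers) == 0L) return("no marker data")
  blocks <- vapply(markers, function(m) {
    paste0(m, ": ", format_characters(entry[[m]]$characters, dash))
  }, character(1))
  basis <- paste(vapply(markers, function(m) {
    paste0(entry[[m]]$n_sequences, " ", m, " sequences")
  }, character(1)), collapse = " and ")
  paste0(paste(blocks, collapse = ". "), " (based on ", basis, ")")
}

#' Parse a formatted molecular diagnosis back into a diagnosis set
#'
#' Inverse of [format_diagnosis_text()]: accepts both the ASCII-hyphen and
#' en-dash renderings. Used by the classification workflow when a diagnosis
#' is supplied as published text rather than JSON.
#'
#' @param text Diagnosis string, e.g.
#'   `"COI: 220: G. 28S: 545-546: AC (based on 36 COI sequences and 19 28S
#'   sequences)"`.
#' @param species Species label to attach.
#' @return A `diagnosis` object containing this single species. Alignment
#'   lengths are unknown from text alone and are set to `NA`.
#' @export
parse_diagnosis_text <- function(text, species = "unknown") {
  text <- trimws(gsub("–", "-", text))
  text <- sub("\\.\\s*$", "", text)
  n_seq <- list()
  m_basis <- regmatches(text, regexec("\\(based on (.*)\\)\\s*$", text))[[1L]]
  if (length(m_basis) == 2L) {
    for (part in strsplit(m_basis[[2L]], " and ", fixed = TRUE)[[1L]]) {
      hit <- regmatches(part, regexec("^([0-9]+) (\\S+) sequences?", part))[[1L]]
      if (length(hit) == 3L) n_seq[[hit[[3L]]]] <- as.integer(hit[[2L]])
    }
    text <- trimws(sub("\\(based on .*\\)\\s*$", "", text))
  }
  blocks <- strsplit(text, "\\.\\s+")[[1L]]
  markers <- list()
  for (block in blocks) {
    colon <- regexpr(":", block, fixed = TRUE)
    if (colon < 1L) stop("cannot parse diagnosis block: '", block, "'",
                         call. = FALSE)
    marker <- trimws(substr(block, 1L, colon - 1L))
    body <- trimws(substr(block, colon + 1L, nchar(block)))
    cdf <- character_df()
    if (!identical(body, "none")) {
      for (item in trimws(strsplit(body, ";", fixed = TRUE)[[1L]])) {
        duo <- regmatches(item,
                          regexec("^([0-9]+)-([0-9]+):\\s*([ACGT]{2})$", item))[[1L]]
        single <- regmatches(item,
                             regexec("^([0-9]+):\\s*([ACGT])$", item))[[1L]]
        if (length(duo) == 4L) {
          cdf <- rbind(cdf, character_df("combined", as.integer(duo[[2L]]),
                                         as.integer(duo[[3L]]), duo[[4L]]))
        } else if (length(single) == 3L) {
          cdf <- rbind(cdf, character_df("single", as.integer(single[[2L]]),
                                         NA_integer_, single[[3L]]))
        } else {
          stop("cannot parse diagnostic character: '", item, "'", call. = FALSE)
        }
      }
    }
    rownames(cdf) <- NULL
    markers[[marker]] <- list(characters = cdf,
                              n_sequences = if (!is.null(n_seq[[marker]]))
                                n_seq[[marker]] else NA_integer_)
  }
  lens <- stats::setNames(rep(NA_integer_, length(markers)), names(markers))
  structure(
    list(species = stats::setNames(list(markers), species),
         markers = names(markers),
         config = list(policy = "conservative", k_window = 2L, reference = NULL),
         alignment_lengths = lens),
    class = "diagnosis"
  )
}

#' Write / read a diagnosis set as JSON
#'
#' The canonical machine-readable form of a [diagnose()] result.
#'
#' @param diag A `diagnosis` object.
#' @param path File path.
#' @return `write_diagnosis_json()` returns `path` invisibly;
#'   `read_diagnosis_json()` returns the reconstructed `diagnosis`.
#' @export
write_diagnosis_json <- function(diag, path) {
  stopifnot(inherits(diag, "diagnosis"))
  payload <- list(
    config = diag$config,
    markers = as.list(diag$markers),
    alignment_lengths = as.list(diag$alignment_lengths),
    species = lapply(diag$species, function(entry) {
      lapply(entry, function(e) {
        list(n_sequences = e$n_sequences, characters = e$characters)
      })
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_diagnosis_json
#' @export
read_diagnosis_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  markers <- unlist(payload$markers, use.names = FALSE)
  lens <- vapply(payload$alignment_lengths, function(x)
    if (is.null(x)) NA_integer_ else as.integer(x), integer(1))
  species <- lapply(payload$species, function(entry) {
    lapply(entry, function(e) {
      rows <- e$characters
      cdf <- character_df(
        kind = vapply(rows, function(r) r$kind, character(1)),
        pos = vapply(rows, function(r) as.integer(r$pos), integer(1)),
        pos2 = vapply(rows, function(r)
          if (is.null(r$pos2)) NA_integer_ else as.integer(r$pos2), integer(1)),
        states = vapply(rows, function(r) r$states, character(1))
      )
      list(characters = cdf, n_sequences = as.integer(e$n_sequences))
    })
  })
  ref <- payload$config$reference
  structure(
    list(species = species, markers = markers,
         config = list(policy = payload$config$policy,
                       k_window = as.integer(payload$config$k_window),
                       reference = if (is.null(ref)) NULL else
                         unlist(ref, use.names = FALSE)),
         alignment_lengths = lens),
    class = "diagnosis"
  )
}

#' Write / read a species distance table
#'
#' TSV in the style of a published p-distance table: one row and one column
#' per species, between-species means off the diagonal, within-species
#' means on the diagonal, values at 4 decimals, `NA` where undefined, both
#' symmetric cells written.
#'
#' @param dm A `species_dist` from [distance_matrix()].
#' @param path File path.
#' @param digits Decimal places (default 4, table convention).
#' @return `write_distance_table()` returns `path` invisibly;
#'   `read_distance_table()` returns a `species_dist` (pair counts are not
#'   stored in the table and come back as `NA`).
#' @export
write_distance_table <- function(dm, path, digits = 4) {
  stopifnot(inherits(dm, "species_dist"))
  vals <- ifelse(is.na(dm$means), "NA",
                 formatC(dm$means, digits = digits, format = "f"))
  df <- data.frame(species = dm$labels, vals, check.names = FALSE)
  colnames(df) <- c("species", dm$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_table
#' @export
read_distance_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  means <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(means) <- "double"
  dimnames(means) <- list(labels, labels)
  n_pairs <- matrix(NA_integer_, length(labels), length(labels),
                    dimnames = dimnames(means))
  new_species_dist(labels, means, n_pairs)
}
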