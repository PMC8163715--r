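# Diagnostic-character search.
#
# A single diagnostic character for a query species is an alignment column
# where all query sequences carry one and the same unambiguous base, and no
# reference sequence can carry that base. A combined character is a duo of
# adjacent columns that is diagnostic as a pair (the query's two-base string
# occurs in no reference sequence) while neither member column is diagnostic
# alone. Characters are reported with 1-based alignment coordinates.
#
# Ambiguity/gap policy:
#   conservative (default) - a query column containing any gap or ambiguity
#     code is ineligible; a reference ambiguity code blocks diagnosis
#     whenever its IUPAC expansion contains the query state; a reference gap
#     is the distinct symbol "-" and never equals a base. A character
#     reported under this policy cannot be falsified by resolving an
#     ambiguity.
#   strict - every code is taken literally as its own symbol, so a reference
#     Y does not block a query C or T.

#' Profile one alignment column for a group of sequences
#'
#' The shared primitive of the diagnostic-character finders. Viewed as a
#' query group, the column's useful summary is whether the group is uniform
#' for one unambiguous base; viewed as a reference group, it is the set of
#' states the group could realise at that column.
#'
#' @param aln A [dna_alignment()].
#' @param position 1-based column index.
#' @param group Character vector of sequence ids (must be in the alignment).
#' @param policy `"conservative"` or `"strict"` (see package details).
#' @return A list with `query_state` (the single shared unambiguous base, or
#'   `NA` if the group is not uniform or carries gaps/ambiguities) and
#'   `possible` (character vector: the union of the expansions of all
#'   observed codes; gaps contribute `"-"`).
#' @examples
#' aln <- dna_alignment(c("a", "b", "c"), c("AC", "AY", "A-"))
#' column_profile(aln, 1, c("a", "b", "c"))$query_state  # "A"
#' column_profile(aln, 2, c("a", "b", "c"))$possible     # "C" "T" "-"
#' @export
column_profile <- function(aln, position, group,
                           policy = c("conservative", "strict")) {
  policy <- match.arg(policy)
  stopifnot(inherits(aln, "dna_alignment"))
  if (position < 1L || position > aln$length) {
    stop("column ", position, " outside alignment (1..", aln$length, ")",
         call. = FALSE)
  }
  missing <- setdiff(group, aln$ids)
  if (length(missing) > 0L) {
    stop("sequence id(s) not in alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  col <- aln$mat[group, position]
  syms <- unique(col)
  bad <- setdiff(syms, IUPAC_SYMBOLS)
  if (length(bad) > 0L) {
    stop("unknown residue code: '", bad[[1L]], "'", call. = FALSE)
  }
  query_state <- if (length(syms) == 1L && is_base(syms)) syms else NA_character_
  possible <- unique(unlist(lapply(syms, iupac_expand, policy = policy),
                            use.names = FALSE))
  list(query_state = query_state, possible = possible)
}

# Per-column uniform unambiguous query state for a set of rows;
# NA where the group is not uniform or the shared symbol is not A/C/G/T.
query_states <- function(mat, rows) {
  sub <- mat[rows, , drop = FALSE]
  first <- sub[1L, ]
  uniform <- colSums(sub != matrix(first, nrow = nrow(sub), ncol = ncol(sub),
                                   byrow = TRUE)) == 0L
  out <- ifelse(uniform & first %in% BASES, first, NA_character_)
  out
}

# Does query base s at a column get blocked by the reference symbols?
blocks_single <- function(ref_syms, s, policy) {
  if (policy == "strict") {
    return(s %in% ref_syms)
  }
  for (sym in ref_syms) {
    if (s %in% IUPAC_EXPANSION[[sym]]) return(TRUE)
  }
  FALSE
}

# Can a single reference symbol realise base s?
admits <- function(sym, s, policy) {
  if (policy == "strict") sym == s else s %in% IUPAC_EXPANSION[[sym]]
}

character_df <- function(kind = character(), pos = integer(),
                         pos2 = integer(), states = character()) {
  data.frame(kind = kind, pos = as.integer(pos), pos2 = as.integer(pos2),
             states = states, stringsAsFactors = FALSE)
}

resolve_groups <- function(aln, part, species, reference = NULL) {
  if (!species %in% part$species) {
    stop("species '", species, "' not in partition", call. = FALSE)
  }
  q_ids <- species_ids(aln, part, species)
  if (length(q_ids) == 0L) {
    stop("no query sequences for species '", species,
         "' in this alignment", call. = FALSE)
  }
  ref_species <- setdiff(part$species, species)
  if (!is.null(reference)) {
    unknown <- setdiff(reference, part$species)
    if (length(unknown) > 0L) {
      stop("reference species not in partition: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    ref_species <- setdiff(reference, species)
  }
  r_ids <- unlist(lapply(ref_species, species_ids, aln = aln, part = part),
                  use.names = FALSE)
  if (length(r_ids) == 0L) {
    stop("no reference sequences for species '", species,
         "' (need at least one other species)", call. = FALSE)
  }
  list(q_ids = q_ids, r_ids = r_ids)
}

#' Find single-position diagnostic characters for one species
#'
#' Scans every alignment column and returns those where (a) all query
#' sequences share one unambiguous base and (b) no reference sequence can
#' realise that base under the chosen policy. The reference group defaults
#' to all other species in the partition (the complete-dataset convention);
#' `reference` restricts it to a subset, exposing the trade-off between a
#' large reference group (fewer but more reliable characters) and a small
#' one.
#'
#' @inheritParams column_profile
#' @param part A [species_partition()].
#' @param species Query species label.
#' @param reference Optional character vector of species labels to use as
#'   the reference group (default: all other species).
#' @return Data frame with columns `kind` (`"single"`), `pos` (1-based
#'   column), `pos2` (`NA`), `states` (the diagnostic base), sorted
#'   ascending by position.
#' @export
find_single_diagnostics <- function(aln, part, species,
                                    policy = c("conservative", "strict"),
                                    reference = NULL) {
  policy <- match.arg(policy)
  g <- resolve_groups(aln, part, species, reference)
  qs <- query_states(aln$mat, g$q_ids)
  rmat <- aln$mat[g$r_ids, , drop = FALSE]
  hits <- integer(0)
  states <- character(0)
  for (j in which(!is.na(qs))) {
    if (!blocks_single(unique(rmat[, j]), qs[[j]], policy)) {
      hits <- c(hits, j)
      states <- c(states, qs[[j]])
    }
  }
  character_df(rep("single", length(hits)), hits, rep(NA_integer_, length(hits)),
               states)
}

#' Find combined (adjacent duo) diagnostic characters for one species
#'
#' Returns adjacent column pairs (i, i+1) where the query is uniform and
#' unambiguous at both columns with dinucleotide ss', no reference sequence
#' can realise ss' (under the conservative policy a reference row whose
#' expansions at i and i+1 jointly admit ss' disqualifies the pair), and
#' neither member column is single-diagnostic on its own. This corresponds
#' to running the character search with a k-window of 2: the duo is in
#' effect a short diagnostic sequence of two bases.
#'
#' @inheritParams find_single_diagnostics
#' @return Data frame as in [find_single_diagnostics()] with `kind`
#'   `"combined"`, `pos`/`pos2` the two adjacent columns and `states` the
#'   two-base string, sorted ascending by first position.
#' @export
find_combined_diagnostics <- function(aln, part, species,
                                      policy = c("conservative", "strict"),
                                      reference = NULL) {
  policy <- match.arg(policy)
  g <- resolve_groups(aln, part, species, reference)
  qs <- query_states(aln$mat, g$q_ids)
  rmat <- aln$mat[g$r_ids, , drop = FALSE]
  singles <- find_single_diagnostics(aln, part, species, policy = policy,
                                     reference = reference)$pos
  starts <- integer(0)
  states <- character(0)
  if (aln$length >= 2L) {
    for (i in seq_len(aln$length - 1L)) {
      j <- i + 1L
      if (is.na(qs[[i]]) || is.na(qs[[j]])) next
      if (i %in% singles || j %in% singles) next
      s1 <- qs[[i]]; s2 <- qs[[j]]
      realized <- FALSE
      for (r in seq_len(nrow(rmat))) {
        if (admits(rmat[r, i], s1, policy) && admits(rmat[r, j], s2, policy)) {
          realized <- TRUE
          break
        }
      }
      if (!realized) {
        starts <- c(starts, i)
        states <- c(states, paste0(s1, s2))
      }
    }
  }
  character_df(rep("combined", length(starts)), starts, starts + 1L, states)
}
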