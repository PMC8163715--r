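#' Construct a gapped nucleotide alignment
#'
#' The basic container used by every downstream step: an ordered set of
#' equal-length gapped sequences for one marker (e.g. COI or 28S D1-D2).
#' Residues are normalised to upper case and `U` is mapped to `T`; only
#' `-` is accepted as the gap symbol. Alignment columns are 1-based in all
#' reported coordinates, matching the convention used when diagnostic
#' positions are printed in species descriptions.
#'
#' @param ids Character vector of unique sequence identifiers (voucher or
#'   accession codes; treated as opaque).
#' @param residues Character vector of aligned sequences, same length as
#'   `ids`, all of identical width.
#' @param marker Marker label, e.g. `"COI"`.
#' @return An object of class `dna_alignment` with elements `ids`,
#'   `residues` (named character vector), `marker`, `length` (number of
#'   columns) and `mat` (sequence-by-column character matrix).
#' @examples
#' aln <- dna_alignment(c("a", "b"), c("ACGT", "A-GT"), marker = "COI")
#' aln$length
#' @export
dna_alignment <- function(ids, residues, marker = "unknown") {
  ids <- as.character(ids)
  residues <- as.character(residues)
  if (length(ids) == 0L) {
    stop("alignment has no sequences", call. = FALSE)
  }
  if (length(ids) != length(residues)) {
    stop("ids and residues differ in length", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  residues <- chartr("u", "t", residues)
  residues <- toupper(residues)
  residues <- chartr("U", "T", residues)
  widths <- nchar(residues)
  if (length(unique(widths)) != 1L) {
    stop("sequences have unequal lengths (input looks unaligned): ",
         paste(range(widths), collapse = "-"), call. = FALSE)
  }
  check_residues(residues, ids)
  mat <- matrix(unlist(strsplit(residues, "", fixed = TRUE), use.names = FALSE),
                nrow = length(ids), byrow = TRUE,
                dimnames = list(ids, NULL))
  names(residues) <- ids
  structure(
    list(ids = ids, residues = residues, marker = marker,
         length = widths[[1L]], mat = mat),
    class = "dna_alignment"
  )
}

#' Read an aligned FASTA file
#'
#' Reads a gapped FASTA alignment (the format of published barcode
#' alignments) and normalises it: upper case, `U` mapped to `T`, `-` the
#' only gap symbol. Record order is preserved; the sequence id is the
#' FASTA header up to the first whitespace.
#'
#' @param source Path to a FASTA file.
#' @param marker Marker label attached to the alignment.
#' @return A [dna_alignment()] object.
#' @export
read_alignment <- function(source, marker = "unknown") {
  if (!file.exists(source)) {
    stop("alignment file not found: ", source, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(source)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", source, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  dna_alignment(ids, as.character(set), marker = marker)
}

#' Write an alignment to FASTA
#'
#' Inverse of [read_alignment()]: ids and residues round-trip unchanged.
#'
#' @param aln A [dna_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  set <- Biostrings::BStringSet(aln$residues)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> marker %s: %d sequences x %d columns\n",
              x$marker, length(x$ids), x$length))
  invisible(x)
}

# Subset an alignment to a set of ids, preserving order of `ids`.
subset_alignment <- function(aln, ids) {
  keep <- aln$ids[aln$ids %in% ids]
  dna_alignment(keep, unname(aln$residues[keep]), marker = aln$marker)
}
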