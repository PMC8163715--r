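# Canonical nucleotide alphabet used throughout the package.
# After ingestion every residue is one of these symbols; "." is rejected,
# "U" has been mapped to "T", and everything is upper case.

BASES <- c("A", "C", "G", "T")

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"),
  "-" = "-"
)

IUPAC_SYMBOLS <- names(IUPAC_EXPANSION)
AMBIGUITY_CODES <- setdiff(IUPAC_SYMBOLS, c(BASES, "-"))

#' Expand an IUPAC nucleotide code
#'
#' Returns the set of unambiguous bases a code may stand for. Under the
#' `"conservative"` policy ambiguity codes expand to their full base sets
#' (e.g. `Y` to `C, T`; `N` to all four) and the gap symbol `-` stays the
#' distinct symbol `-` (a gap is never equal to a base). Under `"strict"`
#' every code is treated literally as its own symbol.
#'
#' @param code Single residue symbol (one of `A C G T R Y S W K M B D H V N -`).
#' @param policy `"conservative"` (default) or `"strict"`.
#' @return Character vector of symbols the code may realise.
#' @examples
#' iupac_expand("Y")            # "C" "T"
#' iupac_expand("Y", "strict")  # "Y"
#' @export
iupac_expand <- function(code, policy = c("conservative", "strict")) {
  policy <- match.arg(policy)
  if (policy == "strict") {
    return(code)
  }
  exp <- IUPAC_EXPANSION[[code]]
  if (is.null(exp)) {
    stop("unknown residue code: '", code, "'", call. = FALSE)
  }
  exp
}

# Residue-level checks, vectorised.
is_base <- function(x) x %in% BASES

check_residues <- function(residues, ids) {
  for (i in seq_along(residues)) {
    chars <- unique(strsplit(residues[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, IUPAC_SYMBOLS)
    if (length(bad) > 0L) {
      stop("non-IUPAC residue character(s) ", paste0("'", bad, "'", collapse = ", "),
           " in sequence '", ids[[i]], "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}
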