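# Uncorrected p-distances and species-level distance summaries.
#
# A p-distance is the proportion of differing sites between two aligned
# sequences over the sites compared. Sites compared are those where both
# residues are unambiguous bases (A/C/G/T): gaps and ambiguity codes are
# excluded pair by pair (pairwise deletion, the common default for
# p-distances) so that "number of base differences per site" is literal
# base counting. A complete-deletion mode, which first drops every column
# containing any gap/ambiguity in the whole alignment, is available for
# sensitivity checks.

#' p-distance between two aligned sequences
#'
#' @param seq_a,seq_b Aligned sequences of equal length (character strings).
#' @return A list with `value` (proportion of differing compared sites;
#'   `NA` with a warning when no site is comparable) and `compared_sites`.
#' @examples
#' p_distance("AAAA", "AAAT")$value        # 0.25
#' p_distance("AA-AN", "AAAAA")            # 0 over 3 sites
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) {
    stop("sequences have unequal lengths (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  ok <- is_base(a) & is_base(b)
  n <- sum(ok)
  if (n == 0L) {
    warning("no comparable sites between the two sequences", call. = FALSE)
    return(list(value = NA_real_, compared_sites = 0L))
  }
  list(value = sum(a[ok] != b[ok]) / n, compared_sites = n)
}

# All pairwise p-distances of an alignment at once.
# Counts matches per pair as sum over the four bases of indicator
# cross-products, so the whole matrix is a handful of BLAS calls.
pairwise_pdist <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  mat <- aln$mat
  if (deletion == "complete") {
    keep <- colSums(!matrix(is_base(mat), nrow = nrow(mat))) == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  valid <- matrix(as.numeric(is_base(mat)), nrow = n)
  sites <- tcrossprod(valid)
  matches <- matrix(0, n, n)
  for (b in BASES) {
    ind <- matrix(as.numeric(mat == b), nrow = n)
    matches <- matches + tcrossprod(ind)
  }
  sites_i <- round(sites)
  d <- ifelse(sites_i > 0, (sites_i - round(matches)) / sites_i, NA_real_)
  diag(d) <- ifelse(diag(sites_i) > 0, 0, NA_real_)
  dimnames(d) <- dimnames(sites_i) <- list(aln$ids, aln$ids)
  list(d = d, sites = sites_i)
}

mean_over_pairs <- function(vals) {
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Mean within-species p-distance
#'
#' Arithmetic mean of the p-distance over all unordered pairs of sequences
#' of one species; `NA` when the species has fewer than two sequences or no
#' pair shares a comparable site. Pairs with no comparable sites are
#' excluded from the mean.
#'
#' @param aln A [dna_alignment()].
#' @param part A [species_partition()].
#' @param species Species label.
#' @param deletion `"pairwise"` (default) or `"complete"` site deletion.
#' @return Numeric scalar or `NA`.
#' @export
group_mean_within <- function(aln, part, species,
                              deletion = c("pairwise", "complete")) {
  ids <- species_ids(aln, part, species)
  if (!species %in% part$species) {
    stop("unknown species '", species, "'", call. = FALSE)
  }
  if (length(ids) < 2L) return(NA_real_)
  pw <- pairwise_pdist(subset_alignment(aln, ids), deletion)
  mean_over_pairs(pw$d[upper.tri(pw$d)])
}

#' Mean between-species p-distance
#'
#' Arithmetic mean of the p-distance over all cross pairs of two species;
#' symmetric in its arguments.
#'
#' @inheritParams group_mean_within
#' @param species_a,species_b Distinct species labels.
#' @return Numeric scalar or `NA`.
#' @export
group_mean_between <- function(aln, part, species_a, species_b,
                               deletion = c("pairwise", "complete")) {
  if (identical(species_a, species_b)) {
    stop("species_a and species_b must differ; use group_mean_within()",
         call. = FALSE)
  }
  for (sp in c(species_a, species_b)) {
    if (!sp %in% part$species) stop("unknown species '", sp, "'", call. = FALSE)
  }
  ids_a <- species_ids(aln, part, species_a)
  ids_b <- species_ids(aln, part, species_b)
  if (length(ids_a) == 0L || length(ids_b) == 0L) return(NA_real_)
  pw <- pairwise_pdist(subset_alignment(aln, c(ids_a, ids_b)), deletion)
  mean_over_pairs(as.vector(pw$d[ids_a, ids_b, drop = FALSE]))
}

#' Species-level mean p-distance matrix
#'
#' The distance table of a taxonomic revision: mean between-species
#' p-distances off the diagonal and mean within-species p-distances on the
#' diagonal (`NA` for species with fewer than two sequences). Row and
#' column order follow the first appearance of each species in the
#' partition.
#'
#' @inheritParams group_mean_within
#' @param strict_ids Passed to dataset validation; see [diagnose()].
#' @return An object of class `species_dist`: `labels`, `means` (K x K
#'   symmetric matrix, within on the diagonal), `n_pairs` (pairs averaged
#'   per cell, same shape) and `deletion`.
#' @seealso [nearest_neighbor()], [write_distance_table()]
#' @export
distance_matrix <- function(aln, part, deletion = c("pairwise", "complete"),
                            strict_ids = FALSE) {
  deletion <- match.arg(deletion)
  aln <- prepare_dataset(aln, part, strict = strict_ids)
  species <- part$species[part$species %in% part$assignments[aln$ids]]
  if (length(species) < 1L) stop("no species present in alignment", call. = FALSE)
  pw <- pairwise_pdist(aln, deletion)
  K <- length(species)
  means <- matrix(NA_real_, K, K, dimnames = list(species, species))
  n_pairs <- matrix(0L, K, K, dimnames = list(species, species))
  idlist <- lapply(species, species_ids, aln = aln, part = part)
  names(idlist) <- species
  for (i in seq_len(K)) {
    ids_i <- idlist[[i]]
    if (length(ids_i) >= 2L) {
      block <- pw$d[ids_i, ids_i, drop = FALSE]
      vals <- block[upper.tri(block)]
      means[i, i] <- mean_over_pairs(vals)
      n_pairs[i, i] <- sum(!is.na(vals))
    }
    if (i < K) for (j in seq((i + 1L), K)) {
      vals <- as.vector(pw$d[ids_i, idlist[[j]], drop = FALSE])
      means[i, j] <- means[j, i] <- mean_over_pairs(vals)
      n_pairs[i, j] <- n_pairs[j, i] <- sum(!is.na(vals))
    }
  }
  new_species_dist(species, means, n_pairs, deletion)
}

new_species_dist <- function(labels, means, n_pairs, deletion = "pairwise") {
  structure(list(labels = labels, means = means, n_pairs = n_pairs,
                 deletion = deletion),
            class = "species_dist")
}

#' @export
print.species_dist <- function(x, digits = 4, ...) {
  cat(sprintf("<species_dist> %d species (%s deletion); within on diagonal\n",
              length(x$labels), x$deletion))
  fmt <- ifelse(is.na(x$means), "NA", formatC(x$means, digits = digits,
                                              format = "f"))
  print(matrix(fmt, nrow = length(x$labels),
               dimnames = dimnames(x$means)), quote = FALSE)
  invisible(x)
}

#' Nearest neighbour of a species in a distance matrix
#'
#' The other species with the smallest mean between-species distance: the
#' "minimum divergence" figure quoted when discussing how distinct a new
#' species is. Ties are broken by matrix label order.
#'
#' @param dm A `species_dist` from [distance_matrix()].
#' @param species Species label present in `dm`.
#' @return List with `species` (the neighbour's label) and `value`.
#' @export
nearest_neighbor <- function(dm, species) {
  stopifnot(inherits(dm, "species_dist"))
  if (!species %in% dm$labels) {
    stop("species '", species, "' not in distance matrix", call. = FALSE)
  }
  row <- dm$means[species, ]
  row[species] <- NA_real_
  if (all(is.na(row))) {
    stop("no defined neighbour distance for '", species, "'", call. = FALSE)
  }
  k <- which.min(row)                      # first minimum = label-order tie-break
  list(species = names(row)[[k]], value = unname(row[[k]]))
}

#' Truncated percentage for prose-style divergence reporting
#'
#' Taxonomic remarks quote divergences as whole percentages obtained by
#' truncation (e.g. a mean p-distance of 0.0889 is quoted as "8%").
#'
#' @param x Proportion(s) in `[0, 1]`.
#' @return Integer percentage(s), floored.
#' @export
floor_percent <- function(x) {
  as.integer(floor(100 * x))
}
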