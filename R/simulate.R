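# Seeded alignment simulator with planted diagnostic characters.
#
# Star-phylogeny scheme: a uniform random root sequence; each species
# ancestor mutates each unlocked site with probability delta (to a
# uniformly chosen different base); each individual mutates each unlocked
# site of its ancestor with probability epsilon. Planted diagnostic columns
# are constructed directly and locked against further mutation, gaps and
# ambiguity injection, so recovery of planted characters is exact rather
# than probabilistic. The star shape gives simple closed forms for the
# expected pairwise distances; it does not attempt realistic tree shape or
# rate heterogeneity.

#' Specify a synthetic barcode dataset
#'
#' Defaults emulate the structure of a typical single-marker barcode study
#' of a cryptic species complex: 13 species of 2-45 sequences each over 650
#' columns, within-species mean p-distance around 0.006 and between-species
#' means around 0.20, sparse gaps and ambiguity codes, and a few planted
#' single and combined diagnostic characters per species.
#'
#' @param n_species Number of species.
#' @param seqs_per_species Integer vector (recycled to `n_species`) of
#'   sequences per species, or `NULL` to draw each uniformly from
#'   `seq_range` at generation time.
#' @param seq_range Range sequences per species are drawn from when
#'   `seqs_per_species` is `NULL`.
#' @param length Alignment columns.
#' @param within_rate Per-site substitution probability between an
#'   individual and its species ancestor (epsilon).
#' @param between_rate Per-site substitution probability between a species
#'   ancestor and the root (delta).
#' @param n_planted_single,n_planted_combined Planted diagnostic characters
#'   per species (singles, adjacent duos).
#' @param gap_fraction,ambiguity_fraction Per-site probabilities of
#'   replacing a residue by a gap / an ambiguity code, applied only outside
#'   locked (planted) columns.
#' @param marker Marker label for the generated alignment.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `simulation_spec` (a validated list).
#' @export
simulation_spec <- function(n_species = 13L, seqs_per_species = NULL,
                            seq_range = c(2L, 45L), length = 650L,
                            within_rate = 0.003, between_rate = 0.11,
                            n_planted_single = 2L, n_planted_combined = 1L,
                            gap_fraction = 0.01, ambiguity_fraction = 0.002,
                            marker = "SIM", seed = 1L) {
  spec <- list(n_species = as.integer(n_species),
               seqs_per_species = seqs_per_species,
               seq_range = as.integer(seq_range),
               length = as.integer(length),
               within_rate = within_rate, between_rate = between_rate,
               n_planted_single = as.integer(n_planted_single),
               n_planted_combined = as.integer(n_planted_combined),
               gap_fraction = gap_fraction,
               ambiguity_fraction = ambiguity_fraction,
               marker = marker, seed = as.integer(seed))
  rates <- c(spec$within_rate, spec$between_rate, spec$gap_fraction,
             spec$ambiguity_fraction)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("rates must lie in [0, 1)", call. = FALSE)
  }
  if (spec$n_species < 1L) stop("need at least one species", call. = FALSE)
  demand <- spec$n_species * (spec$n_planted_single + 2L * spec$n_planted_combined)
  if (demand > spec$length) {
    stop("planted columns (", demand, ") exceed alignment length (",
         spec$length, ")", call. = FALSE)
  }
  if (spec$n_planted_combined > 0L && spec$n_species < 3L) {
    stop("planted combined duos need at least 2 reference species",
         call. = FALSE)
  }
  structure(spec, class = "simulation_spec")
}

other_bases <- function(b) BASES[BASES != b]

mutate_sites <- function(seqmat, rate, open) {
  # mutate each open site with probability `rate`, always to a different base
  hit <- which(open & matrix(stats::runif(length(seqmat)) < rate,
                             nrow = nrow(seqmat)))
  for (k in hit) {
    seqmat[k] <- sample(other_bases(seqmat[k]), 1L)
  }
  seqmat
}

#' Generate a synthetic alignment with planted diagnostics
#'
#' Runs the star-phylogeny simulation of a [simulation_spec()] and returns
#' the alignment, the species partition, and a truth record listing the
#' planted diagnostic characters and locked columns. Every planted
#' character is re-verified against the diagnostic-character definition
#' before the function returns.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `synthetic_dataset`: `alignment`
#'   ([dna_alignment()]), `partition` ([species_partition()]), `truth`
#'   (class `planted_truth`: per-species planted character tables, the set
#'   of locked columns, and the spec echoed back).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  K <- spec$n_species
  L <- spec$length
  sp_labels <- sprintf("sp%02d", seq_len(K))
  n_seqs <- if (is.null(spec$seqs_per_species)) {
    sample(seq(spec$seq_range[[1L]], spec$seq_range[[2L]]), K, replace = TRUE)
  } else {
    rep_len(as.integer(spec$seqs_per_species), K)
  }

  # choose planted columns first, then lock them
  free <- rep(TRUE, L)
  plants <- vector("list", K)
  names(plants) <- sp_labels
  for (sp in sp_labels) {
    plant <- character_df()
    if (spec$n_planted_combined > 0L) {
      for (r in seq_len(spec$n_planted_combined)) {
        starts <- which(free[-L] & free[-1L])
        if (length(starts) == 0L) stop("no room left for a planted duo",
                                       call. = FALSE)
        i <- if (length(starts) == 1L) starts else sample(starts, 1L)
        free[c(i, i + 1L)] <- FALSE
        plant <- rbind(plant, character_df("combined", i, i + 1L,
                                           paste(sample(BASES, 2L, replace = TRUE),
                                                 collapse = "")))
      }
    }
    if (spec$n_planted_single > 0L) {
      cols <- which(free)
      pick <- if (length(cols) == 1L) cols else
        sample(cols, spec$n_planted_single)
      free[pick] <- FALSE
      plant <- rbind(plant, character_df(rep("single", length(pick)),
                                         sort(pick),
                                         rep(NA_integer_, length(pick)),
                                         sample(BASES, length(pick),
                                                replace = TRUE)))
    }
    plants[[sp]] <- plant
  }
  locked <- which(!free)
  open_cols <- free

  # root and species ancestors on unlocked columns
  root <- sample(BASES, L, replace = TRUE)
  ancestors <- matrix(rep(root, each = K), nrow = K,
                      dimnames = list(sp_labels, NULL))
  ancestors <- mutate_sites(ancestors,
                            spec$between_rate,
                            matrix(open_cols, nrow = K, ncol = L, byrow = TRUE))

  # individuals from ancestors on unlocked columns
  ids <- character(0)
  owner <- character(0)
  for (k in seq_len(K)) {
    ids <- c(ids, sprintf("%s_%02d", sp_labels[[k]], seq_len(n_seqs[[k]])))
    owner <- c(owner, rep(sp_labels[[k]], n_seqs[[k]]))
  }
  N <- length(ids)
  mat <- ancestors[owner, , drop = FALSE]
  rownames(mat) <- ids
  mat <- mutate_sites(mat, spec$within_rate,
                      matrix(open_cols, nrow = N, ncol = L, byrow = TRUE))

  # carve the planted characters into the locked columns
  for (sp in sp_labels) {
    plant <- plants[[sp]]
    others <- setdiff(sp_labels, sp)
    q_rows <- owner == sp
    for (i in seq_len(nrow(plant))) {
      if (plant$kind[[i]] == "single") {
        pos <- plant$pos[[i]]
        s <- plant$states[[i]]
        mat[q_rows, pos] <- s
        for (o in others) {
          mat[owner == o, pos] <- sample(other_bases(s), 1L)
        }
      } else {
        i1 <- plant$pos[[i]]; i2 <- plant$pos2[[i]]
        s <- strsplit(plant$states[[i]], "", fixed = TRUE)[[1L]]
        mat[q_rows, i1] <- s[[1L]]
        mat[q_rows, i2] <- s[[2L]]
        # first reference species shares the first base, second shares the
        # second, so neither column is single-diagnostic; no reference row
        # carries the full duo
        mat[owner == others[[1L]], i1] <- s[[1L]]
        mat[owner == others[[1L]], i2] <- sample(other_bases(s[[2L]]), 1L)
        mat[owner == others[[2L]], i1] <- sample(other_bases(s[[1L]]), 1L)
        mat[owner == others[[2L]], i2] <- s[[2L]]
        for (o in others[-(1:2)]) {
          repeat {
            pair <- sample(BASES, 2L, replace = TRUE)
            if (!identical(pair, s)) break
          }
          mat[owner == o, i1] <- pair[[1L]]
          mat[owner == o, i2] <- pair[[2L]]
        }
      }
    }
  }

  # gaps and ambiguity codes, unlocked columns only
  if (spec$gap_fraction > 0 || spec$ambiguity_fraction > 0) {
    open_mat <- matrix(open_cols, nrow = N, ncol = L, byrow = TRUE)
    u <- matrix(stats::runif(N * L), nrow = N)
    gap_hit <- open_mat & u < spec$gap_fraction
    amb_hit <- open_mat & !gap_hit &
      u < spec$gap_fraction + spec$ambiguity_fraction
    mat[gap_hit] <- "-"
    n_amb <- sum(amb_hit)
    if (n_amb > 0L) {
      mat[which(amb_hit)] <- sample(AMBIGUITY_CODES, n_amb, replace = TRUE)
    }
  }

  residues <- apply(mat, 1L, paste, collapse = "")
  aln <- dna_alignment(ids, residues, marker = spec$marker)
  part <- species_partition(ids, owner)
  truth <- structure(
    list(planted = plants, locked_columns = locked, spec = spec),
    class = "planted_truth"
  )

  verify_planted(aln, part, truth)

  structure(list(alignment = aln, partition = part, truth = truth),
            class = "synthetic_dataset")
}

# In-generator invariant: every planted character satisfies the
# diagnostic-character definition when re-checked by the finders.
verify_planted <- function(aln, part, truth) {
  if (length(part$species) < 2L) return(invisible(TRUE))
  for (sp in names(truth$planted)) {
    plant <- truth$planted[[sp]]
    if (nrow(plant) == 0L) next
    singles <- find_single_diagnostics(aln, part, sp)
    combined <- find_combined_diagnostics(aln, part, sp)
    want_s <- plant[plant$kind == "single", , drop = FALSE]
    want_c <- plant[plant$kind == "combined", , drop = FALSE]
    ok_s <- all(paste(want_s$pos, want_s$states) %in%
                  paste(singles$pos, singles$states))
    ok_c <- all(paste(want_c$pos, want_c$states) %in%
                  paste(combined$pos, combined$states))
    if (!ok_s || !ok_c) {
      stop("internal error: planted character for ", sp,
           " failed verification", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  n_single <- sum(vapply(x$truth$planted,
                         function(p) sum(p$kind == "single"), integer(1)))
  n_comb <- sum(vapply(x$truth$planted,
                       function(p) sum(p$kind == "combined"), integer(1)))
  cat(sprintf(paste0("<synthetic_dataset> %d sequences, %d species, %d columns; ",
                     "%d planted singles, %d planted duos (seed %d)\n"),
              length(x$alignment$ids), length(x$partition$species),
              x$alignment$length, n_single, n_comb, x$truth$spec$seed))
  invisible(x)
}

#' Expected pairwise divergences under the simulation model
#'
#' Closed forms for the per-site probability that two sequences differ,
#' used to check that realized group means converge to their targets.
#' Within one species, both tips descend independently from the species
#' ancestor, each site mutating with probability `eps` to a uniformly
#' chosen different base, giving `2*eps*(1-eps) + (2/3)*eps^2`. Between
#' species, each tip's root-to-tip channel keeps the root base with
#' probability `a = (1-delta)*(1-eps) + delta*eps/3` and is uniform over
#' the other three bases otherwise (by symmetry of uniform replacement);
#' two independent tips then differ with probability
#' `1 - a^2 - (1-a)^2/3`. Setting `delta = 0` recovers the within form.
#'
#' @param eps Individual-vs-ancestor substitution probability.
#' @param delta Ancestor-vs-root substitution probability.
#' @return Expected proportion of differing sites.
#' @examples
#' expected_within(0.005)           # 0.00996667
#' expected_between(0.005, 0)       # same: no between-species signal
#' @export
expected_within <- function(eps) {
  2 * eps * (1 - eps) + (2 / 3) * eps^2
}

#' @rdname expected_within
#' @export
expected_between <- function(eps, delta) {
  a <- (1 - delta) * (1 - eps) + delta * eps / 3
  1 - a^2 - (1 - a)^2 / 3
}
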