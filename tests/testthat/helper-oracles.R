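# Independent brute-force oracles: straight re-statements of the
# definitions as per-column / per-pair loops over raw characters, kept
# deliberately naive and separate from the package's vectorised code.

ORACLE_EXP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), "-" = "-"
)

oracle_expand <- function(sym, policy) {
  if (policy == "strict") sym else ORACLE_EXP[[sym]]
}

oracle_chars <- function(aln, id) strsplit(unname(aln$residues[id]), "")[[1]]

oracle_rows <- function(aln, ids) {
  do.call(rbind, lapply(ids, function(id) oracle_chars(aln, id)))
}

# query state at a column: the shared base, or NA
oracle_qstate <- function(qmat, j) {
  col <- qmat[, j]
  if (length(unique(col)) == 1 && col[1] %in% c("A", "C", "G", "T")) col[1]
  else NA_character_
}

oracle_single <- function(aln, part, sp, policy = "conservative") {
  q_ids <- names(part$assignments)[part$assignments == sp]
  q_ids <- intersect(aln$ids, q_ids)
  r_ids <- setdiff(intersect(aln$ids, names(part$assignments)), q_ids)
  qmat <- oracle_rows(aln, q_ids)
  rmat <- oracle_rows(aln, r_ids)
  hits <- list()
  for (j in seq_len(aln$length)) {
    s <- oracle_qstate(qmat, j)
    if (is.na(s)) next
    blocked <- FALSE
    for (r in seq_len(nrow(rmat))) {
      if (s %in% oracle_expand(rmat[r, j], policy)) { blocked <- TRUE; break }
    }
    if (!blocked) hits[[length(hits) + 1]] <- list(pos = j, state = s)
  }
  hits
}

oracle_combined <- function(aln, part, sp, policy = "conservative") {
  q_ids <- names(part$assignments)[part$assignments == sp]
  q_ids <- intersect(aln$ids, q_ids)
  r_ids <- setdiff(intersect(aln$ids, names(part$assignments)), q_ids)
  qmat <- oracle_rows(aln, q_ids)
  rmat <- oracle_rows(aln, r_ids)
  single_pos <- vapply(oracle_single(aln, part, sp, policy),
                       function(h) h$pos, numeric(1))
  hits <- list()
  for (i in seq_len(aln$length - 1)) {
    j <- i + 1
    s1 <- oracle_qstate(qmat, i)
    s2 <- oracle_qstate(qmat, j)
    if (is.na(s1) || is.na(s2)) next
    if (i %in% single_pos || j %in% single_pos) next
    realized <- FALSE
    for (r in seq_len(nrow(rmat))) {
      if (s1 %in% oracle_expand(rmat[r, i], policy) &&
          s2 %in% oracle_expand(rmat[r, j], policy)) { realized <- TRUE; break }
    }
    if (!realized) hits[[length(hits) + 1]] <-
      list(pos = c(i, j), state = paste0(s1, s2))
  }
  hits
}

# adjacent duos satisfying joint uniformity + joint absence only (no
# single-position exclusion); this raw pair-level set is the monotone form
# used by the antitonicity property
oracle_pair_raw <- function(aln, part, sp, policy = "conservative") {
  q_ids <- names(part$assignments)[part$assignments == sp]
  q_ids <- intersect(aln$ids, q_ids)
  r_ids <- setdiff(intersect(aln$ids, names(part$assignments)), q_ids)
  qmat <- oracle_rows(aln, q_ids)
  rmat <- oracle_rows(aln, r_ids)
  hits <- character(0)
  for (i in seq_len(aln$length - 1)) {
    s1 <- oracle_qstate(qmat, i)
    s2 <- oracle_qstate(qmat, i + 1)
    if (is.na(s1) || is.na(s2)) next
    realized <- FALSE
    for (r in seq_len(nrow(rmat))) {
      if (s1 %in% oracle_expand(rmat[r, i], policy) &&
          s2 %in% oracle_expand(rmat[r, i + 1], policy)) {
        realized <- TRUE
        break
      }
    }
    if (!realized) hits <- c(hits, paste0(i, ":", s1, s2))
  }
  hits
}

# character-by-character p-distance, pairwise deletion
oracle_pdist <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  used <- 0; diff <- 0
  for (k in seq_along(a)) {
    if (a[k] %in% c("A", "C", "G", "T") && b[k] %in% c("A", "C", "G", "T")) {
      used <- used + 1
      if (a[k] != b[k]) diff <- diff + 1
    }
  }
  if (used == 0) NA_real_ else diff / used
}

oracle_group_mean <- function(aln, part, sp_a, sp_b = NULL) {
  ids_a <- intersect(aln$ids,
                     names(part$assignments)[part$assignments == sp_a])
  vals <- c()
  if (is.null(sp_b)) {
    if (length(ids_a) < 2) return(NA_real_)
    for (i in seq_along(ids_a)) for (j in seq_along(ids_a)) {
      if (i < j) vals <- c(vals, oracle_pdist(aln$residues[[ids_a[i]]],
                                              aln$residues[[ids_a[j]]]))
    }
  } else {
    ids_b <- intersect(aln$ids,
                       names(part$assignments)[part$assignments == sp_b])
    for (i in ids_a) for (j in ids_b) {
      vals <- c(vals, oracle_pdist(aln$residues[[i]], aln$residues[[j]]))
    }
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# convert finder data frames to the oracle's comparable form
chars_as_keys <- function(cdf) {
  if (nrow(cdf) == 0) return(character(0))
  ifelse(is.na(cdf$pos2),
         paste0("S", cdf$pos, ":", cdf$states),
         paste0("C", cdf$pos, "-", cdf$pos2, ":", cdf$states))
}

oracle_as_keys <- function(hits, combined = FALSE) {
  if (length(hits) == 0) return(character(0))
  vapply(hits, function(h) {
    if (combined) paste0("C", h$pos[1], "-", h$pos[2], ":", h$state)
    else paste0("S", h$pos, ":", h$state)
  }, character(1))
}

# random small test instance: 3 species, optional gaps/ambiguities
rand_instance <- function(seed, n_max = 10, l_max = 50, noisy = TRUE) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  L <- sample(6:l_max, 1)
  syms <- c("A", "C", "G", "T")
  probs <- rep(0.25, 4)
  if (noisy) {
    syms <- c(syms, "-", "N", "Y", "R")
    probs <- c(rep(0.23, 4), 0.04, 0.02, 0.01, 0.01)
  }
  mat <- matrix(sample(syms, n * L, replace = TRUE, prob = probs), nrow = n)
  # sharpen columns so some are near-uniform and diagnostics actually occur
  for (j in seq_len(L)) {
    if (runif(1) < 0.5) {
      base <- sample(c("A", "C", "G", "T"), 1)
      keep <- runif(n) < 0.85
      mat[keep, j] <- base
    }
  }
  ids <- paste0("s", seq_len(n))
  species <- sample(paste0("sp", 1:3), n, replace = TRUE)
  species[1:3] <- paste0("sp", 1:3)   # every species non-empty
  list(
    aln = dna_alignment(ids, apply(mat, 1, paste, collapse = "")),
    part = species_partition(ids, species)
  )
}

# Monte-Carlo oracle for the between-species divergence closed form:
# simulate root -> two ancestors -> two tips at L independent sites.
mc_between <- function(eps, delta, L, seed = 1) {
  set.seed(seed)
  bases <- 1:4
  mutate <- function(x, rate) {
    hit <- runif(length(x)) < rate
    x[hit] <- vapply(x[hit], function(b) sample(bases[bases != b], 1),
                     integer(1))
    x
  }
  root <- sample(bases, L, replace = TRUE)
  tip1 <- mutate(mutate(root, delta), eps)
  tip2 <- mutate(mutate(root, delta), eps)
  mean(tip1 != tip2)
}
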