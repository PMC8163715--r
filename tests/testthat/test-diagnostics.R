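toy <- function(residues, species) {
  ids <- paste0("s", seq_along(residues))
  list(aln = dna_alignment(ids, residues),
       part = species_partition(ids, species))
}

test_that("column_profile summarises query uniformity and reference states", {
  t <- toy(c("AC", "AY", "A-"), c("X", "X", "X"))
  all_ids <- t$aln$ids
  expect_equal(column_profile(t$aln, 1, all_ids)$query_state, "A")
  # not uniform / ambiguous columns yield no query state
  expect_true(is.na(column_profile(t$aln, 2, all_ids)$query_state))
  expect_setequal(column_profile(t$aln, 2, all_ids)$possible, c("C", "T", "-"))
  # strict policy keeps codes literal
  expect_setequal(column_profile(t$aln, 2, all_ids, policy = "strict")$possible,
                  c("C", "Y", "-"))
  expect_error(column_profile(t$aln, 3, all_ids), "outside alignment")
  expect_error(column_profile(t$aln, 1, c("s1", "zz")), "not in alignment")
})

test_that("single diagnostics follow the uniform-and-absent definition", {
  # query fixed A, reference fixed C at column 1; identical elsewhere
  t <- toy(c("AG", "AG", "CG", "CG"), c("X", "X", "Y", "Y"))
  got <- find_single_diagnostics(t$aln, t$part, "X")
  expect_equal(got$pos, 1L)
  expect_equal(got$states, "A")
  # and symmetrically for the other species
  expect_equal(find_single_diagnostics(t$aln, t$part, "Y")$states, "C")

  # query identical to reference everywhere: nothing
  t2 <- toy(c("ACGT", "ACGT"), c("X", "Y"))
  expect_equal(nrow(find_single_diagnostics(t2$aln, t2$part, "X")), 0L)

  # non-uniform query column is never diagnostic
  t3 <- toy(c("A", "G", "C"), c("X", "X", "Y"))
  expect_equal(nrow(find_single_diagnostics(t3$aln, t3$part, "X")), 0L)

  expect_error(find_single_diagnostics(t$aln, t$part, "Z"), "not in partition")
})

test_that("gap and ambiguity policy is conservative by default", {
  # reference Y expands to {C,T}: blocks a query C conservatively, not strictly
  t <- toy(c("C", "C", "Y"), c("X", "X", "Y"))
  expect_equal(nrow(find_single_diagnostics(t$aln, t$part, "X")), 0L)
  expect_equal(find_single_diagnostics(t$aln, t$part, "X",
                                       policy = "strict")$pos, 1L)

  # a gap in the reference never equals a base
  t2 <- toy(c("C", "C", "-"), c("X", "X", "Y"))
  expect_equal(find_single_diagnostics(t2$aln, t2$part, "X")$pos, 1L)

  # a query column containing a gap or ambiguity is ineligible
  t3 <- toy(c("C", "-", "G"), c("X", "X", "Y"))
  expect_equal(nrow(find_single_diagnostics(t3$aln, t3$part, "X")), 0L)
  t4 <- toy(c("C", "M", "G"), c("X", "X", "Y"))
  expect_equal(nrow(find_single_diagnostics(t4$aln, t4$part, "X")), 0L)
})

test_that("combined duos are diagnostic jointly but not singly", {
  # classic constructed case: query AG; reference rows AT and CG share each
  # single base but never the duo
  t <- toy(c("AG", "AG", "AT", "CG"), c("X", "X", "Y", "Y"))
  singles <- find_single_diagnostics(t$aln, t$part, "X")
  expect_equal(nrow(singles), 0L)
  got <- find_combined_diagnostics(t$aln, t$part, "X")
  expect_equal(got$pos, 1L)
  expect_equal(got$pos2, 2L)
  expect_equal(got$states, "AG")

  # a reference row carrying the duo kills it
  t2 <- toy(c("AG", "AG", "AG", "CG"), c("X", "X", "Y", "Y"))
  expect_equal(nrow(find_combined_diagnostics(t2$aln, t2$part, "X")), 0L)

  # under the conservative policy a reference row whose expansions jointly
  # admit the duo (row RG: R = A/G at column 1, G at column 2) kills it;
  # strict reads R literally, so the duo survives. Rows AT and CG keep both
  # columns non-single under either policy.
  t3 <- toy(c("AG", "AG", "AT", "CG", "RG"), c("X", "X", "Y", "Y", "Y"))
  expect_equal(nrow(find_single_diagnostics(t3$aln, t3$part, "X")), 0L)
  expect_equal(nrow(find_combined_diagnostics(t3$aln, t3$part, "X")), 0L)
  expect_equal(find_combined_diagnostics(t3$aln, t3$part, "X",
                                         policy = "strict")$states, "AG")

  # duos containing a single-diagnostic member position are excluded
  t4 <- toy(c("AG", "AG", "CT", "CG"), c("X", "X", "Y", "Y"))
  expect_equal(find_single_diagnostics(t4$aln, t4$part, "X")$pos, 1L)
  expect_equal(nrow(find_combined_diagnostics(t4$aln, t4$part, "X")), 0L)
})

test_that("finders agree with the brute-force oracle on random instances", {
  for (seed in 1:40) {
    inst <- rand_instance(seed)
    policy <- if (seed %% 2 == 0) "conservative" else "strict"
    for (sp in inst$part$species) {
      got_s <- find_single_diagnostics(inst$aln, inst$part, sp, policy = policy)
      want_s <- oracle_single(inst$aln, inst$part, sp, policy)
      expect_identical(chars_as_keys(got_s), oracle_as_keys(want_s),
                       label = sprintf("singles seed %d %s %s", seed, sp, policy))
      got_c <- find_combined_diagnostics(inst$aln, inst$part, sp,
                                         policy = policy)
      want_c <- oracle_combined(inst$aln, inst$part, sp, policy)
      expect_identical(chars_as_keys(got_c),
                       oracle_as_keys(want_c, combined = TRUE),
                       label = sprintf("duos seed %d %s %s", seed, sp, policy))
    }
  }
})

test_that("diagnose() assembles sorted per-species, per-marker diagnoses", {
  t <- toy(c("AGT", "AGT", "CGT", "CGA"), c("X", "X", "Y", "Y"))
  fit <- diagnose(t$aln, t$part)
  expect_s3_class(fit, "diagnosis")
  entry <- fit$species$X[[t$aln$marker]]
  expect_equal(entry$n_sequences, 2L)
  expect_equal(entry$characters$kind,
               rep("single", nrow(entry$characters)))
  # singles come before duos and both are position-sorted
  sim <- generate_dataset(simulation_spec(n_species = 4,
                                          seqs_per_species = 3, length = 80,
                                          seed = 11))
  fit2 <- diagnose(sim$alignment, sim$partition)
  for (sp in names(fit2$species)) {
    cdf <- fit2$species[[sp]]$SIM$characters
    ks <- cdf$kind
    expect_true(all(diff(match(ks, c("single", "combined"))) >= 0))
    for (k in unique(ks)) {
      expect_true(!is.unsorted(cdf$pos[ks == k]))
    }
    # disjointness: single positions never reappear inside duos
    expect_length(intersect(cdf$pos[ks == "single"],
                            c(cdf$pos[ks == "combined"],
                              cdf$pos2[ks == "combined"])), 0)
  }
  # determinism: identical inputs give byte-identical results
  expect_identical(fit2, diagnose(sim$alignment, sim$partition))

  # a single-species dataset has no reference group
  t1 <- toy(c("A", "A"), c("X", "X"))
  expect_error(diagnose(t1$aln, t1$part), "at least 2 species")
})

test_that("restricting the reference group can only add characters", {
  sim <- generate_dataset(simulation_spec(n_species = 5, seqs_per_species = 4,
                                          length = 100, seed = 3))
  full <- find_single_diagnostics(sim$alignment, sim$partition, "sp01")
  restricted <- find_single_diagnostics(sim$alignment, sim$partition, "sp01",
                                        reference = c("sp02", "sp03"))
  expect_true(all(chars_as_keys(full) %in% chars_as_keys(restricted)))
})

test_that("classification recovers training sequences and handles gaps", {
  t <- toy(c("AGT", "AGT", "CGT", "CGT"), c("X", "X", "Y", "Y"))
  fit <- diagnose(t$aln, t$part)
  cl <- classify_sequence("AGT", fit, t$aln$marker)
  expect_equal(cl$verdict, "unique")
  expect_equal(cl$species, "X")
  expect_equal(cl$scores$fraction[cl$scores$species == "X"], 1)

  # gap at the only diagnostic position of every species: no call
  cl2 <- classify_sequence("-GT", fit, t$aln$marker)
  expect_equal(cl2$verdict, "no_call")

  # conservative policy scores an ambiguity covering the state as a match,
  # strict does not
  cl3 <- classify_sequence("MGT", fit, t$aln$marker)
  expect_equal(cl3$verdict, "ambiguous")   # M = {A,C} matches X and Y
  cl4 <- classify_sequence("MGT", fit, t$aln$marker, policy = "strict")
  expect_equal(cl4$verdict, "no_call")

  expect_error(classify_sequence("AG", fit, t$aln$marker), "length")

  # predict() vectorises over a whole alignment
  res <- predict(fit, t$aln, marker = t$aln$marker)
  expect_equal(res$species, c("X", "X", "Y", "Y"))
  expect_true(all(res$verdict == "unique"))
})
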