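test_that("p-distance counts differing bases over compared sites only", {
  expect_equal(p_distance("ACGT", "ACGT"),
               list(value = 0, compared_sites = 4L))
  expect_equal(p_distance("AAAA", "AAAT"),
               list(value = 0.25, compared_sites = 4L))
  # gap and ambiguity columns are deleted pair by pair
  expect_equal(p_distance("AA-AN", "AAAAA"),
               list(value = 0, compared_sites = 3L))
  expect_equal(p_distance("AY-T", "AC-T")$compared_sites, 2L)
  expect_error(p_distance("ACG", "AC"), "unequal lengths")
  expect_warning(d <- p_distance("--N", "AC-"), "no comparable sites")
  expect_true(is.na(d$value))
  # symmetry
  expect_equal(p_distance("ACGTAC", "ATGTCC")$value,
               p_distance("ATGTCC", "ACGTAC")$value)
})

test_that("group means average the pairwise distances", {
  # three sequences engineered to pairwise distances 0.1, 0.2, 0.3
  aln <- dna_alignment(c("a", "b", "c"),
                       c("AAAAAAAAAA", "CAAAAAAAAA", "ACCAAAAAAA"))
  part <- species_partition(c("a", "b", "c"), c("X", "X", "X"))
  expect_equal(p_distance(aln$residues[["a"]], aln$residues[["b"]])$value, 0.1)
  expect_equal(p_distance(aln$residues[["a"]], aln$residues[["c"]])$value, 0.2)
  expect_equal(p_distance(aln$residues[["b"]], aln$residues[["c"]])$value, 0.3)
  expect_equal(group_mean_within(aln, part, "X"), 0.2)

  # identical sequences: zero; singleton species: undefined
  aln2 <- dna_alignment(c("a", "b", "c"), c("ACGT", "ACGT", "AGGT"))
  part2 <- species_partition(c("a", "b", "c"), c("X", "X", "Y"))
  expect_equal(group_mean_within(aln2, part2, "X"), 0)
  expect_true(is.na(group_mean_within(aln2, part2, "Y")))
  expect_error(group_mean_within(aln2, part2, "Z"), "unknown species")

  # between: mean of the 4 cross pairs of a 2x2 toy, symmetric in arguments
  aln3 <- dna_alignment(c("a1", "a2", "b1", "b2"),
                        c("AAAA", "AAAT", "CAAA", "CAAT"))
  part3 <- species_partition(c("a1", "a2", "b1", "b2"), c("X", "X", "Y", "Y"))
  want <- mean(c(0.25, 0.5, 0.5, 0.25))   # the four cross pairs
  expect_equal(group_mean_between(aln3, part3, "X", "Y"), want)
  expect_equal(group_mean_between(aln3, part3, "Y", "X"), want)
  expect_error(group_mean_between(aln3, part3, "X", "X"), "must differ")
})

test_that("group means and matrix cells match the double-loop oracle", {
  for (seed in 101:115) {
    set.seed(seed)
    inst <- rand_instance(seed, n_max = 20, l_max = 40)
    dm <- suppressWarnings(distance_matrix(inst$aln, inst$part))
    sps <- inst$part$species
    for (a in sps) {
      expect_equal(dm$means[a, a], oracle_group_mean(inst$aln, inst$part, a),
                   label = sprintf("within %s seed %d", a, seed))
      expect_equal(group_mean_within(inst$aln, inst$part, a),
                   oracle_group_mean(inst$aln, inst$part, a))
      for (b in sps) {
        if (a == b) next
        expect_equal(dm$means[a, b],
                     oracle_group_mean(inst$aln, inst$part, a, b),
                     label = sprintf("between %s-%s seed %d", a, b, seed))
      }
    }
    # symmetry and range
    expect_equal(dm$means, t(dm$means))
    vals <- dm$means[!is.na(dm$means)]
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("p-distances agree with ape's raw pairwise-deletion distances", {
  set.seed(7)
  n <- 8; L <- 60
  residues <- replicate(n, paste(sample(c("A", "C", "G", "T"), L,
                                        replace = TRUE), collapse = ""))
  aln <- dna_alignment(paste0("s", 1:n), residues)
  bin <- ape::as.DNAbin(strsplit(tolower(residues), ""))
  names(bin) <- aln$ids
  want <- as.matrix(ape::dist.dna(bin, model = "raw",
                                  pairwise.deletion = TRUE))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    expect_equal(p_distance(residues[i], residues[j])$value,
                 unname(want[i, j]))
  }
})

test_that("distance matrix records pair counts and handles singletons", {
  aln <- dna_alignment(c("a1", "a2", "b1", "c1"),
                       c("AAAA", "AATA", "CCAA", "GGGG"))
  part <- species_partition(c("a1", "a2", "b1", "c1"), c("X", "X", "Y", "Z"))
  dm <- distance_matrix(aln, part)
  expect_s3_class(dm, "species_dist")
  expect_equal(dm$labels, c("X", "Y", "Z"))
  expect_true(is.na(dm$means["Y", "Y"]))     # one sequence: undefined within
  expect_equal(dm$n_pairs["X", "X"], 1L)
  expect_equal(dm$n_pairs["X", "Y"], 2L)
  expect_equal(dm$means["X", "X"], 0.25)

  # complete deletion drops every column with a gap/ambiguity anywhere
  aln2 <- dna_alignment(c("a", "b", "c", "d"),
                        c("A-CT", "AACT", "AAGT", "AAGA"))
  part2 <- species_partition(c("a", "b", "c", "d"), c("X", "X", "Y", "Y"))
  pw <- distance_matrix(aln2, part2, deletion = "complete")
  # columns 1,3,4 survive; a vs c differ at col 3 only
  expect_equal(pw$means["X", "Y"], mean(c(1/3, 2/3, 1/3, 2/3)))
})

test_that("nearest neighbour is the argmin with label-order tie-break", {
  m <- matrix(c(NA, 0.10, 0.20,
                0.10, 0.01, 0.10,
                0.20, 0.10, 0.02), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dm <- diagchar:::new_species_dist(c("A", "B", "C"), m,
                                    matrix(1L, 3, 3))
  nn <- nearest_neighbor(dm, "A")
  expect_equal(nn$species, "B")
  expect_equal(nn$value, 0.10)
  # tie between A and C from B: label order picks A
  expect_equal(nearest_neighbor(dm, "B")$species, "A")
  # two-species matrix: the only other species
  dm2 <- diagchar:::new_species_dist(c("A", "B"),
                                     matrix(c(NA, 0.3, 0.3, NA), 2, 2,
                                            dimnames = list(c("A", "B"),
                                                            c("A", "B"))),
                                     matrix(1L, 2, 2))
  expect_equal(nearest_neighbor(dm2, "A")$species, "B")
  expect_error(nearest_neighbor(dm, "Z"), "not in distance matrix")
})

test_that("prose-style percentages truncate rather than round", {
  expect_equal(floor_percent(c(0.0889, 0.0950, 0.0953, 0.1069, 0.1088)),
               c(8L, 9L, 9L, 10L, 10L))
  expect_equal(floor_percent(0.2674), 26L)
})
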