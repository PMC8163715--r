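---
title: "Diagnostic nucleotide characters: model, policies and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic nucleotide characters: model, policies and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagchar)
```

## The problem

Molecular species delimitation routinely reveals lineages that are
reproductively and evolutionarily distinct but morphologically
indistinguishable. Naming such cryptic species requires a diagnosis, and
when morphology offers none, the diagnosis must be molecular: a list of
alignment positions at which the new species differs from every congener
in the dataset. `diagchar` computes these character-based diagnoses — the
same idea implemented by character-based barcoding tools in the CAOS
tradition — together with the p-distance summaries that conventionally
accompany them.

The package is organised in the classic modelling idiom: `diagnose()` is
the fitting function, returning a `diagnosis` object with `print()`,
`summary()` and `predict()` methods (prediction = classification of new
sequences against the fitted diagnosis set).

## Character definitions

Work on one marker's alignment (columns are 1-based; positions reported in
a diagnosis are alignment coordinates, so they are only meaningful
together with the alignment they came from). Fix a query species $Q$ and a
reference group $R$ (by default, every other species in the partition).

**Single character.** Column $j$ with state $s \in \{A,C,G,T\}$ is
diagnostic for $Q$ iff every sequence of $Q$ carries exactly $s$ at $j$,
and no sequence of $R$ can carry $s$ at $j$.

**Combined character.** The adjacent duo $(j, j{+}1)$ with states $ss'$ is
diagnostic iff $Q$ is uniform and unambiguous at both columns, no single
reference sequence can realise the dinucleotide $ss'$ (the check is per
row, jointly over both columns — the column-wise unions of reference
states are not enough), and neither $j$ nor $j{+}1$ is single-diagnostic
on its own. Restricting duos to adjacent columns (a k-window of 2) keeps
diagnoses short and usable: unconstrained pairing can produce hundreds of
duos per species, which is unmanageable in a description, while an
adjacent duo is simply a two-base diagnostic motif.

## Gap and ambiguity policy

Published datasets contain gaps and IUPAC ambiguity codes, and the
treatment of these is the one genuinely open design choice in the
definition. Two policies are provided:

- **conservative** (default): a query column containing *any* gap or
  ambiguity is ineligible (we refuse to assert uniformity we cannot see);
  a reference ambiguity blocks a character whenever its expansion contains
  the query state ($Y$ blocks $C$ and $T$; $N$ blocks everything); a gap
  is the distinct symbol `-`, never equal to a base, so an otherwise
  absent state is still diagnostic against a gapped reference column. A
  character reported under this policy can never be falsified by
  resolving an ambiguity code into a concrete base.
- **strict**: every symbol is compared literally ($Y$ only blocks $Y$).

The conservative policy can only miss characters, never invent them, which
is the right default for published diagnoses; the strict mode exists
because the exact convention used by any given published analysis is
usually unstated, and comparing the two bounds the effect of that unknown.
The same pair of policies governs classification: an ambiguity in a query
sequence is a possible match under the conservative policy and a non-match
under strict; a gap makes a diagnostic inapplicable (it is dropped from
the denominator rather than scored).

## Ordering, determinism and a monotonicity subtlety

Diagnoses are emitted in a canonical order — singles ascending by
position, then duos ascending by first position — and identical inputs
give byte-identical output. Published diagnosis strings are not always
sorted; sorting is a presentation-layer decision made for testability, and
the renderer is a pure function of the canonical set.

Both finders are antitone in the data in the intuitive sense: adding query
sequences (more observed intraspecific variation) or reference sequences
(more species to be distinguished from) can only remove single characters.
One subtlety is worth knowing: because a duo is excluded when one of its
columns is single-diagnostic, a new reference sequence that blocks a
single at $j$ can *promote* the duo $(j, j{+}1)$ into the combined list —
the diagnostic information migrates between the two lists rather than
disappearing. The strictly monotone quantities are the single-character
set and the "raw" pair-level set (joint uniformity + joint absence,
ignoring the single-exclusion rule), and those are the forms the property
tests assert; the full reported set is monotone under query-group growth.

## Reference-group scope

There is a trade-off in choosing $R$: the larger the reference group, the
fewer characters survive, but the more reliable each survivor is; a small
$R$ yields many characters that may evaporate as more congeners are
sequenced. The default is the complete dataset supplied, and
`reference =` restricts $R$ to a subset of species for sensitivity
analysis. Diagnoses based on very few query sequences (the `based on n
sequences` clause is always emitted) should be read as provisional for the
same reason.

## Distances

The p-distance between two aligned sequences is the proportion of
differing sites over the sites compared. Compared sites are those where
*both* residues are unambiguous bases: gaps and ambiguity codes are
excluded per pair (pairwise deletion), matching literal base-difference
counting and the common default of barcoding practice. A
complete-deletion mode (drop every column containing any gap/ambiguity
anywhere) is available for sensitivity checks. Pairs with no comparable
sites are undefined and are excluded from group means rather than
propagating `NA` — short fragments should not poison a table. Species
means are arithmetic means over all (unordered within-species, or all
cross) pairs; a species with one sequence has an undefined within mean,
reported `NA` and deliberately distinct from a true 0.0000 over two or
more identical sequences. Tables print at 4 decimals; prose summaries
truncate to whole percentages (0.0889 → 8%), the convention of published
remarks, implemented in `floor_percent()`.

The species matrix is computed from one vectorised all-pairs pass
(indicator cross-products, so the cost is a few matrix multiplications),
and its cells are tested against a naive double loop over pairs and sites.

## The simulator

`generate_dataset()` emulates the structure of a single-marker barcode
dataset of a cryptic species complex, not its phylogeny. The scheme is a
star: a uniform random root; each species ancestor substitutes each site
with probability $\delta$ (uniformly to a different base); each individual
substitutes each ancestral site with probability $\varepsilon$. Two tips
of one species then differ per site with probability

$$ p_w(\varepsilon) = 2\varepsilon(1-\varepsilon) + \tfrac{2}{3}\varepsilon^2, $$

and two tips of different species with probability

$$ p_b(\varepsilon, \delta) = 1 - a^2 - \tfrac{(1-a)^2}{3}, \qquad
   a = (1-\delta)(1-\varepsilon) + \tfrac{\delta\varepsilon}{3}, $$

where $a$ is the probability that a root base survives the two-step
root→ancestor→tip channel (by symmetry the channel is "stay with
probability $a$, otherwise uniform over the other three bases", which is
what makes the closed form elementary). Setting $\delta = 0$ recovers
$p_w$. Both forms are verified against a Monte-Carlo simulation in the
tests, and realized group means are required to match them within three
binomial standard errors at 5000 sites.

**Planted characters.** Requested single characters are constructed
directly: the query species is fixed to a base and every reference
species' ancestor to some other base; combined duos give the first
reference species the query's first base and the second reference species
the query's second base (so neither column is single-diagnostic) while no
reference row carries the full dinucleotide. Planted columns are *locked*:
no subsequent substitution, gap or ambiguity ever touches them, for any
species. This makes recovery of planted characters an exact property
(recall is 1.0 by construction, and the generator re-verifies every plant
against the finders before returning) rather than a statistical one.
Locking slightly dilutes realized distances, so the convergence tests use
plant-free spectra.

**Defaults.** The defaults describe the dataset the package was designed
around: 13 species of 2–45 sequences over 650 columns,
$\varepsilon = 0.003$ (expected within-species mean $\approx 0.006$, the
middle of the observed 0.0008–0.011 range), $\delta = 0.11$ (expected
between-species mean $\approx 0.20$, the middle of the observed
0.09–0.28), 1% gaps, 0.2% ambiguity codes, two planted singles and one
planted duo per species. A star phylogeny makes all between-species
expectations equal, so the simulator reproduces the *levels* of a real
table but not its structure (no pairs of sister species closer to each
other than to the rest, no rate heterogeneity across sites, no indel
evolution — gaps are noise, not history). Passing tests on synthetic data
therefore demonstrate correctness of the definitions and machinery, not
robustness to every feature of real alignments.

## Degenerate inputs and numerical choices

Single-sequence species are valid queries (a diagnosis "based on 1
sequence" is permitted, flagged by validation) but have undefined within
distances. A dataset with one species has no reference group and is
refused. All-gap columns are warnings; they can never carry characters.
Unassigned sequences are dropped with a warning by default (outgroups are
common in real supplementary files) or refused in strict mode. `U` is
normalised to `T`, case is folded, and `.` is rejected — one canonical
alphabet keeps every downstream set comparison trivial. Nearest-neighbour
ties break by table order, and all character ordering is fixed, so every
output is deterministic.

## Validation strategy and problem sizes

The test suite checks the finders against brute-force re-statements of the
definitions on hundreds of randomized small instances (up to 10 sequences
× 50 columns, both policies), distance code against double loops (up to 20
sequences), recovery of planted characters across 50 seeds,
self-classification (every training sequence of a diagnosable species
classifies uniquely back to its own species), renderer/parser and
JSON/TSV round-trips, and the closed-form divergences at 5000 sites and
$10^5$ Monte-Carlo sites. These sizes keep the whole suite within a couple
of minutes on one core while leaving the statistical assertions
well-powered. The bundled published COI distance table is used to check
the reporting conventions (4-decimal cells, truncated percentages,
nearest-neighbour minima) against real published values; recomputing the
published *positions* additionally needs the original supplementary
alignments, which cannot be redistributed here.
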