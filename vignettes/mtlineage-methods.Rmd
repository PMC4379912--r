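---
title: "mtlineage: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mtlineage: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented by `mtlineage`, the tunable
parameters and their defaults, what the synthetic-data generators do and do
not emulate, and the design choices made where the methodology left the
design open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. Coordinate system and mutation notation

All positions are 1-based coordinates on the 16,569-bp revised Cambridge
reference sequence (rCRS), treated as circular; a sequenced range such as
16024–407 denotes 16024..16569 plus 1..407. Mutations use the phylotree
conventions: a bare position (`16172`) is a transition to the partner of
the reference base; a trailing base (`16183C`) is a substitution to that
base, classified transition/transversion by the purine–pyrimidine rule;
`pos.NX` is the N-th inserted base after `pos`; `posd` and `a-bd` are
deletions; `@pos` is a back mutation restoring the reference state. The
`+` insertion notation is normalised to the `.N` form on input.

Two notation decisions were open and are resolved as follows. A back
mutation's token does not encode the state it reverts, so parsed `@`
tokens record `kind = "transition"` by convention and always canonicalise
to `@pos`. Indels are placed at their 3'-most equivalent position after
alignment (gaps are slid rightwards while the flanking base repeats),
which is the convention the notation above assumes; the packaged test for
the 9-bp deletion in the 8272–8289 tandem repeat pins this behaviour.

**The packaged reference is synthetic.** The real rCRS base string cannot
be redistributed inside this repository, so `mt_reference()` loads a
deterministic stand-in (generated by `data-raw/make_extdata.R`, seeded)
with the real reference base pinned at every position the fixtures,
examples and tests touch: the control-region C stretches, the AC repeat,
the 8281–8289 repeat unit, the ND3 codon at 10398–10400, the AluI/HpaI
recognition sites at 5176/12406 and all motif positions in the bundled
haplogroup tree. Analyses of real data should pass the real rCRS FASTA to
`mt_reference(fasta = )`; every downstream function takes the reference as
an argument. The gene table (13 protein genes including light-strand ND6,
22 tRNAs, 2 rRNAs) is the standard public annotation; codons are
translated with the vertebrate mitochondrial code, light-strand genes via
the reverse complement, and the incomplete terminal codons of ND4/CO3-type
genes are polyadenylation-padded with `A`.

Ambiguity codes in sample sequences (N, R, Y, ...) are treated as
*uncovered* positions rather than calls — the conservative choice, since a
mis-scored ambiguity would otherwise create phantom variants.

The exclusion filter removes exactly the conventional set: indels in
303–315 and 515–522, `16182C`, `16183C`, C insertions after 16193 and any
variant at 16519. Position 16519 is excluded wherever the filter is
applied (dating always applies it); classification uses the unfiltered
profile unless the caller filters first, since defining motifs never use
the excluded sites.

## 2. Haplogroup classification

A haplogroup tree is a rooted set of named clades, each carrying the
defining mutations of the branch leading to it. The cumulative motif of a
clade is the concatenation of branch motifs from the root, with `@` tokens
cancelling earlier occurrences at the same position (an uncancelled `@` is
dropped as unobservable against the reference). The bundled fixture tree
carries the newly described clades with their published definitions —
M54a (12414, 16189), M55b (16172, 7972, 5564, 1719, 1047, 373 and a
recurrent 10398) and M84b (16311, 6260, 279, 152, 150) — plus placeholder
motifs, marked as synthetic in the file, for basal clades whose full
definitions exist only in unavailable supplementary material.

Assignment scores every clade as

    score = matched − w_miss × missing

where both counts run over the cumulative-motif tokens whose position lies
inside the profile's sequenced range; motif sites the sample never
sequenced neither help nor hurt. `w_miss = 1` by default (a missing
defining site cancels a matched one); the parameter is exposed because no
scoring rule is canonical. Ties are broken by more matches, fewer misses,
shallower depth, then name, and a best score ≤ 0 returns `Unassigned`.
Co-optimal clades are all reported and an `ambiguous` flag mirrors the
notion of an "unrecognized" sample. Ancestry labels (EastEurasian,
SouthAsian, WestEurasian, Other, Unassigned) are tree metadata, never
inferred.

One arithmetic note: in the published cohort the three reported classes
(532 East Eurasian, 36 South Asian, 269 unrecognized of 845) sum to
99.05%, leaving 8 samples implied but never broken out. The test cohort
realises them as West-Eurasian (HV-motif) profiles, HV being the one
West-Eurasian clade the source mentions; this only affects the
`WestEurasian` row of the summary, not the three asserted percentages.

## 3. Median-joining networks

`median_joining_network()` follows the Bandelt median-joining scheme:
build the ε-relaxed minimum-spanning connectivity (a link is feasible iff
its length is within ε of the distance level at which its endpoints'
components first join), propose median vectors, add those whose connection
cost is within ε of the iteration optimum, delete obsolete inferred nodes
(unobserved, degree ≤ 2), and repeat to a fixpoint. ε defaults to 0 and
characters are equally weighted by default, with a weight vector accepted.

Design choice: candidate medians are generated from **all node triplets**,
not only triplets sharing network links. The narrower candidate set can
miss a Steiner point at ε = 0 whose connection cost exceeds the iteration
optimum (we observed one-mutation-longer networks on random 5×6 binary
inputs); the wider set restored minimum-Steiner-length connectivity on
every case in the randomized oracle battery (exhaustive Dreyfus–Wagner
search in the test suite). For multistate sites with three distinct states
in a triplet the majority rule is undefined; the first node's state is
kept, which cannot occur on binary panels. Reduced-median preprocessing is
out of scope.

## 4. ρ-statistic dating

For a rooted genealogy with branch mutation counts `l_b` and `n_b` tips
below branch `b`:

    ρ = Σ_b l_b n_b / N      (equivalently the mean root-to-tip distance)
    σ = √(Σ_b l_b n_b²) / N  (Saillard standard error)

The three clocks are fixed constants: 2,585 years per complete-genome
substitution, 7,884 per coding-region synonymous substitution, 18,845 per
transition in 16090–16365. Clock filters run after the exclusion filter:
the complete clock keeps all substitutions (never indels), the synonymous
clock keeps class-`s` substitutions, the HVS clock keeps transitions in
the window. Ages are ρ × rate / 1000 kya.

When no genealogy is supplied, `date_haplogroup()` uses a **star
fallback**: every profile attaches to the clade root with the
clock-filtered symmetric-difference distance, since the genealogies behind
published tables are typically unstated. A supplied `genealogy_tree` (or
Newick file with mutation-count branch lengths) overrides it.
Heteroplasmic calls are ignored for dating. Profiles whose sequenced range
contains no clock-eligible sites are dropped with a warning count rather
than contributing spurious zeros.

Rounding: ages and reported ρ/σ round half-up to 2 decimals (the
convention of published tables; base R's half-to-even would print 0.865 as
0.86 or 0.87 inconsistently across values), while full precision is kept
internally — the three-tip example dates from ρ = 1/3, not from the
printed 0.33.

**Known discrepancy.** Converting the published per-clade ρ values back to
ages reproduces every printed complete-genome and synonymous age within
±0.05 kya (the slack the table's own 2-decimal ρ implies). The HVS-clock
column does not pass that band: at 18,845 yr/mutation a ±0.005 rounding of
ρ alone moves the age by up to ±0.094 kya, and two entries are
inconsistent with their printed ρ at any consistent rate (one ρ of 1.50
implies an age in [28.17, 28.36] against a printed 28.11; one σ of 0.45
implies [8.39, 8.57] against a printed 8.58). The corresponding acceptance
block asserts the stated band anyway and is expected red; nothing in the
estimator depends on it. Similarly, one published σ of 0.67 at ρ = 0.67
(N = 3) is unreachable from any single star configuration and is not
asserted.

## 5. Population statistics

*Frequency tables* are populations × haplogroups counts with per-row
normalisation; unassigned samples form an explicit `Unassigned` column.

*PCA* centres columns but does not scale them — haplogroup frequencies
share a unit, so correlation-mode rescaling would up-weight rare clades;
a `scale.` switch exists. Percent variance is `λ_i / Σλ` from the singular
values; the suite cross-checks against an independent eigendecomposition.

*Nei's d_A* is implemented in the single-locus Bhattacharyya form
`1 − Σ_h √(x_h y_h)` on the haplogroup panel. The source cites a distance
without printing its formula; among Nei's distances this is the one
computable from haplogroup profiles alone, and it is labelled as such.

*AMOVA* treats each individual as carrying one haplogroup and uses the 0/1
distance between distinct haplogroups by default (a haplogroup ×
haplogroup distance matrix overrides). Sums of squares follow the standard
hierarchical decomposition with unequal-size coefficients; Φ_CT permutes
populations across groups, Φ_SC individuals across populations within
groups, Φ_ST individuals across everything. Permutations default to 1,000
with a mandatory seed in the API (1234 in the CLI); p-values use the
add-one rule (b+1)/(m+1).

*WLS admixture* minimises `Σ_h w_h (f_h − Σ_p m_p f_ph)²` with `Σ m_p = 1`
enforced by substitution and `m_p ≥ 0` by active-set clipping with
renormalisation; weights default to 1. Rank-deficient parental matrices
are solved minimum-norm (SVD) and flagged `non_unique`.

## 6. Moran's I correlograms

Per distance class, binary weights `w_ij = 1` iff the haversine distance
(mean Earth radius 6,371 km) falls in the class; row standardisation is
off, matching the common correlogram convention. Classes default to
equal-width bins over (0, max pairwise distance]; an equal-pair-count mode
exists because the binning rule behind published correlograms is usually
unreported. Significance is two-sided around the null expectation
−1/(n−1), by permutation of values over locations (default 999, seed
required). Constant value vectors are rejected (I undefined); empty
classes are flagged rather than silently dropped.

## 7. What the generators emulate — and what a green test establishes

`simulate_star_genealogy()` draws Poisson(λ) private transitions per tip,
uniformly over clock-eligible sites minus the exclusion list — the model
under which ρ is unbiased and the Saillard formula is exact.
`simulate_tree_genealogy()` grows a Yule-style topology with
exponential branch durations and Poisson counts, storing branch
expectations so counts can be re-drawn on a fixed topology (the regime in
which σ is compared with the empirical SD of ρ).
`simulate_population_frequencies()` draws multinomial counts per
population, optionally tilting one haplogroup's expectation linearly along
longitude — enough to calibrate AMOVA's null and to produce the
positive-near/negative-far correlogram signature.
`fixture_sequences_for_haplogroup()` emits profiles carrying a clade's
cumulative motif plus private mutations that deliberately avoid every
defining site in the tree, so classification round-trips are unambiguous.

None of the generators model coalescent demography, migration, rate
heterogeneity across sites, sequencing error or recurrent mutation at
defining sites. A green suite therefore establishes correctness of the
estimators under their stated sampling models and exact agreement with
printed-table arithmetic — not robustness to the messiness of real
population data.

All generators take a mandatory seed and use one RNG stream per call;
every CLI run with fixed inputs and seed is byte-reproducible.

## 8. Numerical and degenerate-input conventions

Half-up rounding is applied only at reporting boundaries. Pairwise
alignment (for sequence input) uses Biostrings' global alignment with gap
opening 6 / extension 1, followed by the 3'-shift normalisation, so
substitution-only inputs are alignment-free. Zero-variance PCA inputs
return zero percent variance rather than NaN. AMOVA with a zero total
variance reports Φ = 0. The WLS active set drops the most negative
coordinate first and terminates after at most K−1 drops. Permutation
p-values are never 0 by construction. `round_half_up()` nudges by a
relative 1e-9 so that values stored just below a .5 boundary (e.g. 43.945
represented as 43.9449…) round as printed arithmetic expects.
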