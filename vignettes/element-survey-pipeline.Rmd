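---
title: "Surveying piggyBac-like element insertions across populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying piggyBac-like element insertions across populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pletools)
```

## The biological setting

piggyBac-like elements (PLEs) are class II DNA transposons that move by a
"cut-and-paste" mechanism and integrate almost exclusively at TTAA
tetranucleotides, duplicating the target so that TTAA flanks the element
on both sides. A full-length PLE carries short terminal inverted repeats
(ITRs, 13 bp in the element modeled here), longer subterminal inverted
repeats placed asymmetrically inside the ends, and a single transposase
ORF whose catalytic triad of aspartates (the "DDD" motif) must be intact
for activity.

Because an insertion at a given genomic site is either present or absent
in a population, insertion sites behave as dominant binary markers:
populations can be fingerprinted by transposon display, compared with a
similarity coefficient, and clustered. Within the element, sequence
variation among copies — substitutions and indels accumulated since the
element invaded the host — can be partitioned by region to ask where
mutations concentrate. This package implements that entire workflow, plus
a synthetic-data generator that produces inputs with known ground truth.

## Element annotation

`annotate_element()` defines a candidate element as an inverted pair of
`itr_length`-mers whose immediately flanking 4-mers both match the target
pattern within `tsd_max_mismatch` substitutions. Discovery is seeded by an
exact k-mer hash join between the sequence and its reverse complement,
split into `itr_max_mismatch + 1` fragments (pigeonhole principle), so a
qualifying pair always shares at least one exact fragment; this keeps the
scan near-linear in genome length rather than quadratic.

Two classes of spurious candidates arise and are resolved explicitly:

* **Shadows.** Because TTAA is its own reverse complement, the true
  boundary pair can be shifted a base into the duplication, and a
  subterminal repeat pair can masquerade as a short ITR pair whose
  flanking 4-mers happen to fall within the loose TSD tolerance.
  Candidates are ranked (canonical TSD first, then fewer ITR mismatches,
  then longer span) and overlapping lower-ranked spans are dropped.
* **Chimeras.** The left ITR of one copy can pair with the right ITR of a
  downstream copy, spanning both. A candidate that strictly contains two
  disjoint canonical candidates is discarded in favor of its parts.

Discovery defaults are strict: exact ITR pair, exact TTAA on both sides,
and identical left/right flanking 4-mers (`tsd_require_identical` —
integration duplicates *one* target, so a true element is flanked by two
copies of the same tetranucleotide). The strictness is a false-discovery
argument: in random sequence, inverted 13-mer pairs within one mismatch
arise about once per 1.7 Mb of (position × span) search volume, which in a
multi-kilobase genome with a ±2-mismatch TSD filter (admitting 26% of
random 4-mers on each side) yields several false elements per 30 kb.
Variant-bearing elements remain discoverable by raising
`itr_max_mismatch` to 1 and `tsd_max_mismatch` to 2 — the largest
deviations the field survey observed — on targeted sequence.
Characterization of *known* sites (variant-duplication and variant-ITR
tabulation, `find_target_sites()`) always uses the 2-mismatch tolerance
and is unaffected by the scanning defaults. Element span is constrained
to 100–5000 bp. All coordinates in the package are 0-based half-open (the
BED convention); the element span runs ITR-to-ITR and excludes both TSD
copies, which is how the 2406 bp length of the modeled element is defined.
ORFs are enumerated ATG-to-stop on both strands under the standard genetic
code, with the stop codon inside the reported interval (so a 505-residue
transposase occupies 3 × (505 + 1) = 1518 nt); equal-length ties are
broken toward the forward strand and leftmost start. `N` never matches any
motif.

## Transposon display in silico

The wet protocol digests genomic DNA with HindIII, ligates a linker, and
amplifies the fragment from the restriction site through the element's 5′
end; sequencing the product identifies the insertion site by its flank.
`extract_te_display_tags()` reproduces this: for each annotated element it
extracts the segment from the nearest upstream AAGCTT occurrence through
the 5′ TSD inclusive, flagging tags with no upstream site (truncated) or
with the site inside the TSD window (degenerate). `build_matrix()` then
identifies sites by **exact identity of the last 30 flank bases** before
the TSD — the field survey identified sites by sequencing flanks, and no
mismatch tolerance was reported, so none is applied — and records a population × site
presence matrix with site ids assigned in order of first observation.

## Similarity and clustering

`genetic_similarity()` computes the Dice coefficient
`GS(ij) = 2a/(2a + b + c)` from shared (`a`) and private (`b`, `c`)
sites. `upgma()` transforms similarities with `d = 1 − GS` — the source
analysis fed similarities to a clustering program without stating the
transform; the complement is the standard choice, order-preserving and
mapping GS = 1 to distance 0 — and agglomerates with classical
size-weighted UPGMA, merging at height `d/2`. Binary data produce many
exactly equal distances, so ties are broken deterministically by the
lexicographically smallest pair of cluster labels (each cluster labeled by
its smallest leaf); repeated runs and label permutations therefore give
reproducible, isomorphic trees. The tree is ultrametric by construction
and `cut_tree(tree, k)` undoes the last `k − 1` merges.

The three-group cut of the transcribed survey matrix is *compared* against
the published three clades but not asserted: with 0/1 data the topology
near equal-height merges depends on tie-breaking, and the original
analysis used a different program whose tie rule is unknown. The hard
guarantees are ultrametricity and exact agreement with an independent
naive implementation (tested over 100 random matrices, plus agreement
with `stats::hclust(method = "average")` cophenetic distances on tie-free
inputs).

## Variation rates

Aligned copy sets are partitioned into 5′-outside-ORF, ORF, and
3′-outside-ORF intervals in alignment coordinates. A column is one
variant position (`Nv`) when it holds at least two distinct symbols, with
the gap character counted as a symbol and `N` ignored; a multi-column
indel therefore contributes one variant position per column, while its
single-event character is captured separately by `detect_svps()`
(maximal runs of identical gap-pattern columns, default minimum 3 bp —
gapped minority reported as a deletion, gapped majority as an insertion
carried by the ungapped copies, ties as deletions). The region length `L`
is the mean ungapped length over copies, which is why published lengths
such as 613.2 are fractional. Leading and trailing gap runs are treated
as alignment padding and excluded from both `Nv` and `L`.

Two pooled rates are reported per region: the mean of per-group
`Rv = Nv/L` (matching the "average ± SEM" framing of the published table)
and the ratio of pooled means. For short regions these differ in the
third decimal — recomputing the published 3′ figures gives 3.1/278 =
0.0112 against a printed 0.0113 — so neither summary is forced to match
the printed third decimal and tests assert only the 5′ and ORF rates,
which reproduce at four decimals.

`compare_region_rates()` uses a paired sign-flip permutation test
(statistic: mean within-group rate difference; labels permuted within
groups) because the original analysis does not name its test; a
permutation test is assumption-free, seedable, and respects the grouped
design. Regions are summarized with a compact letter display at
`alpha = 0.01`.

`hotspot_profile()` pools the per-column variant indicator across copy
sets and smooths with a centered 11-column window (partial windows at the
edges; the first maximum is reported, so a flat profile yields column 0).
Copy sets from the simulator carry an alignment-to-template coordinate
map, letting independently aligned groups of different widths be pooled
on template coordinates.

## Insertion frequency

`classify_amplicons()` maps observed flanking-PCR band lengths to calls:
short only → absent, both → heterozygous, long only → homozygous-present,
neither → ambiguous, with a ±30 bp matching tolerance reflecting agarose
gel resolution. The occupied-site amplicon defaults to
`empty + element = 264 + 2406 = 2670` bp, the arithmetic used in the
source analysis; a convention counting the extra TSD copy (+4) is
available. "Carrier" includes homozygous-present individuals even though
the field data contained only heterozygotes — the generalization costs
nothing and contradicts no observation. `estimate_frequency()` averages
carrier frequencies over replicate groups and reports
`SEM = sd/sqrt(n_groups)` with the sample (n − 1) standard deviation,
the only replication structure the 3 × 15 design offers.
`rank_populations()` uses competition ranking, the convention of the
published frequency table (two populations share rank 3; rank 4 is
skipped).

## The synthetic-data generator

`build_element()` realizes a structural template: ITR at the 5′ end and
its reverse complement at the 3′ end, subterminal repeats at their
offsets, an ATG-to-stop ORF with aspartates planted at the DDD positions,
literal CAAT/TATA/AATAAA motifs, i.i.d. uniform bases elsewhere. An
in-frame stop guard immediately upstream of the ORF pins the annotated
ORF start to the planted ATG. Infeasible templates (overlapping parts)
raise an error naming the collision. The default template reproduces the
modeled element: 2406 bp, ITR `CCCAGATTAGCCT`, 505 codons at offset 613,
DDD at residues 268/346/447/450, signals at the published offsets.

`simulate_populations()` draws two alleles per individual per locus
(diploidy is modeled because the field survey genotyped heterozygotes)
and builds each individual's genome from a shared reference with TTAA
targets and an upstream HindIII site guaranteed at every catalog locus.
Host background is i.i.d. uniform sequence: flank content is irrelevant
to every statistic computed downstream, and a shared reference makes the
30-base flank keys identical across individuals, which is what makes
planted-truth recovery exact. One integer seed drives the scenario, with
fixed offsets deriving the element-construction, reference, and
genotype-drawing streams.

Mutation of element copies (`mutate_copy()`, `simulate_copy_set()`) draws
substitutions and indels per base at per-region rates; indel lengths
follow a geometric distribution truncated to 1–11 bases (mean ≈ 2.5),
covering the 2–11 bp events seen among field copies and ensuring ≥ 3 bp
SVP events occur. `simulate_copy_set()` constructs the gapped alignment
directly from the drawn events — deletions become gap columns,
insertions add columns — so the alignment is exactly consistent with the
event lists (verified in tests) and the true variant columns are known
without re-alignment.

**Rate calibration.** An alignment column is variant as soon as any one
of the `k` copies mutates there, so the expected variation rate is about
`k` times the per-copy rate. The default rates are therefore set to 1/4
of the field study's observed per-region variation rates (with the small
indel share concentrated in the 3′ region), so that default 4-copy sets
reproduce the observed magnitudes 0.0062 / 0.0053 / 0.0113.

## Test design choices

* **Frequency recovery** is asserted against the scenario's *theoretical*
  SEM, `sqrt(p(1 − p)/(G·n))` for `G` groups of `n` individuals. With
  only three replicate groups the empirical SEM follows a heavy-tailed
  distribution (a 3-SEM interval built from it has roughly t-with-2-df
  coverage, ~90%), so the theoretical SEM is the sound yardstick for a
  ≥95%-of-replicates criterion; its coverage is ~99.7%.
* **Rate-ordering recovery** uses configured rates with two-fold
  separations (0.003 ORF, 0.006 5′, 0.012 3′). A parameter-recovery check
  needs parameters distinguishable at the design's information content —
  21 groups × 4 copies; at the field study's own 5′/ORF gap
  (0.0062 vs 0.0053) the pooled estimates order correctly in only ~87% of
  replicates from binomial counting noise alone, regardless of
  implementation.
* **Problem sizes** in the test suite — 12 populations × 8 individuals ×
  21 loci for matrix recovery, 200 replicates for the statistical
  properties, 100 random matrices for the UPGMA oracle — mirror the field
  design where one exists and otherwise keep each property estimable with
  comfortable margins.

## What the simulations do and do not show

The generator emulates the *sampling structure* of a field survey:
diploid individuals, replicate groups, per-population insertion
probabilities, region-biased mutation. It does not simulate transposition
dynamics over generations, selection, horizontal transfer, PCR dropout,
or alignment error — insertion frequencies are parameters, not emergent
quantities, and alignments are exact by construction. Passing tests
therefore demonstrate that the estimators recover what the generative
model plants, not that real transposon-display gels or CLUSTAL alignments
are free of artifacts. Site identification by exact 30-base flank match
assumes flanks are locus-unique; paralogous flanks or sequencing errors
in real data would merge or split sites.

## Known limitations

* The annotation scan requires the flanking TSD tolerance to hold on both
  sides; an element that lost one TSD copy (e.g. by post-insertion
  deletion) is not found.
* Chimera resolution prefers canonical inner candidates; two adjacent
  copies both carrying variant TSDs could still be merged.
* `GS` for a population pair sharing no scored sites is defined as 0 with
  a warning; a valid presence matrix cannot produce it.
* The three-cluster reading of the survey tree is tie-sensitive and is
  reported rather than asserted.
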