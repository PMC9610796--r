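---
title: "Methods: annotating and comparing nucleopolyhedrovirus genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and comparing nucleopolyhedrovirus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npvanno)
```

npvanno implements the annotation and comparative workflow used for large
circular dsDNA insect-virus genomes (alphabaculoviruses and relatives): ORF
calling with the conventional filter rules, detection of homologous regions
(hrs), promoter-motif classification, intra-isolate variant classification,
Kimura 2-parameter distances with a species-demarcation verdict, gene-parity
synteny with inversion detection, and distance-based phylogeny with
bootstrap support. This vignette explains the models and procedures, the
parameters that matter, the synthetic-data generator used for validation,
and the numerical and design choices made where conventions are not fixed
by the field.

## Coordinates and genome topology

All coordinates are 1-based inclusive. Reverse-strand features keep
`start < end` on the forward strand with `strand = "-"`, matching the
left-arrow display convention of published annotation tables. On circular
genomes coordinate arithmetic wraps modulo the genome length, and features
spanning the origin are represented with `end` greater than the genome
length; the GFF3 writer splits such features into two segments that the
package's reader rejoins losslessly. `rotate_to_origin()` re-linearizes a
circular genome so the first base of a chosen ORF — conventionally
polyhedrin (*polh*) — becomes position 1, and returns a coordinate map for
transferring annotations.

## ORF calling and annotation filters

`find_orfs()` reports every maximal ATG-to-stop ORF in all six frames with
at least `min_codons` codons (start codon counted, stop excluded; default
50, the conventional annotation floor for baculovirus genomes). Only ATG
initiators are considered — the baculovirus convention — and nested in-frame
ORFs are suppressed: one ORF per stop codon and frame, anchored at the
first ATG after the previous in-frame stop. On circular genomes frames
continue across the junction; the scanner works on a doubled sequence and
canonicalizes by stop-codon position so each ORF is reported exactly once.

`annotate_orfs()` applies the filter rules used in practice. Any ORF with
an entry in the homology table (a stand-in for protein-similarity search
results) is annotated unconditionally, with `annotation_basis` reflecting
the table's source tag (core gene, genus-conserved, or other homolog). An
ORF without homology support is kept only if (a) it is not fully contained
in an hr, (b) it overlaps no hr by more than `max_overlap` bp (default 75),
(c) it overlaps no longer annotated ORF by more than `max_overlap` bp, and
(d) a coding predicate accepts it.

Three interpretation choices were genuinely open and are resolved as
follows. "Occurring within an hr" is read as full containment, which keeps
rules (a) and (b) from being redundant; partial overlap is governed by the
75-bp rule. Overlap is measured in bp on the forward-strand projection
regardless of strand, because the published rule does not distinguish
strands. "Larger ORF" means strictly more codons; an equal-length conflict
between two candidate ORFs is resolved toward the earlier start coordinate,
so exactly one of a heavily overlapping equal-length pair survives.

The coding predicate is pluggable because the original two ab initio gene
predictors are external services. The default,
`make_codon_usage_predicate()`, accepts an ORF when the cosine similarity
between its relative synonymous codon usage (RSCU) vector and the mean RSCU
of the homology-supported ORFs exceeds a threshold (default 0.5). For
planted-truth validation a constant-`FALSE` predicate models the case where
no ab initio support exists, making the annotated set exactly the
homology-supported set.

`translate_orf()` uses the standard genetic code; molecular weights are the
sum of average residue masses plus one water, reported in kDa to one
decimal as in published annotation tables.

## Homologous-region detection

hrs are clusters of 2–6 near-identical repeat units, typically around 59 bp
in alphabaculoviruses, containing an imperfect palindrome and occurring in
either orientation. `find_tandem_repeats()` detects them in four stages:

1. **Seeding.** All exact k-mer matches (default `k = 12`), in forward and
   reverse-complement orientation, at spacings between about 0.8 unit
   lengths and two unit lengths plus the cluster gap.
2. **Region formation.** Seed intervals closer than `gap` (default 250 bp)
   merge into candidate regions. A merged region can chain across several
   distinct arrays, so clusters are peeled off iteratively, with already
   claimed intervals blocked from re-tiling.
3. **Period and phase resolution.** Candidate unit lengths come from the
   modal seed spacings at unit scale, half the modal spacings at two-unit
   scale (regions whose units alternate orientation have no unit-scale
   same-orientation spacing), and a unit-length prior of 59 bp. The prior
   is essential for one structural corner case: an isolated
   forward+reverse unit pair produces only mirror-symmetric seed spacings
   which never equal the period. For every candidate anchor, period and
   tiling phase, the region is tiled greedily and the tiling maximizing
   *covered bases − 2 × accumulated edit distance* wins. This score
   resolves the tandem-rotation ambiguity — for interior tiles every
   rotation of the unit frame fits equally well, and only at the true unit
   boundaries do the edge tiles avoid paying for flanking non-repeat
   sequence. Residual boundary uncertainty is about a quarter unit in the
   worst case; validation uses a 15-bp tolerance on region boundaries while
   requiring the exact unit count.
4. **Final tiling and consensus.** Units are re-tiled with ±3 bp length
   jitter against the first unit, orientation-normalized, stacked into a
   consensus (position-wise majority, ties to the lexicographically
   smallest base), then re-oriented against that consensus in one
   refinement pass and the consensus rebuilt. Units whose
   orientation-normalized distance to the consensus exceeds
   `max_unit_divergence` × unit length (default 0.25) are dropped.
   Equal-length unit comparisons use Hamming distance — identical to edit
   distance for the substitution-dominated divergence the ceiling models —
   with full edit distance for off-length units.

`palindrome_score()` scans every center between adjacent positions and
returns the longest arm whose non-complementary pair count stays within the
mismatch ceiling; a position pairs with its mirror iff the bases are
reverse complements, so reverse-complement palindromes are always
even-length. `classify_hrs()` accepts a cluster as an hr iff the unit count
is within `[min_units, max_units]` (default 2–6), the consensus length is
within `[unit_min, unit_max]` (default 40–80 bp, a window deliberately
wider than the 59-bp prior so the method is not tied to one virus), and
the consensus contains a palindrome of arm ≥ `min_arm` (default 3, the
length of a 6-bp restriction-site core) at ≤ `max_mismatch` mismatches
(default 2, since the repeat palindromes are typically imperfect).

## Promoter motifs

`scan_promoters()` searches the `window` bp (default 200) strictly upstream
of the start codon, on the ORF's coding strand only: the early motif CAKT
(K = G or T, label `C`), the late motif TAAG (`L`), and the early TATA
motif TATAA (`T`). Occurrences may overlap (TATAAG scores both `T` and
`L`). Two readings of "within 200 bp of the start codon" were possible; the
window is taken as strictly 5′ of the ATG because both early and late
baculovirus promoter elements function upstream of the transcription start,
and the template strand is not scanned because the motifs are
strand-specific cis elements. Windows wrap on circular genomes and truncate
with a warning on linear ones.

## Intra-isolate variants

`filter_variants()` keeps variants with frequency strictly above `min_freq`
(default 0.10, matching the strict ">10%" reporting convention).
`classify_variants()` assigns five classes. Positions in an hr or outside
every annotated ORF are `hr_or_intergenic`; the hr takes precedence over an
overlapping ORF, consistent with reporting hr/intergenic positions as one
group before ORF-internal changes. SNPs inside ORFs are translated in codon
context, strand-aware, giving `synonymous` or `nonsynonymous`. Indels
(VCF-style anchored alleles, left-aligned, position at the anchor base) are
`inframe_indel` when the length difference is a multiple of 3, else
`frameshift_indel`. A position covered by two overlapping ORFs is
classified against the longer ORF with a warning — the count-once reading
of the published totals. Class counts always sum to the filtered variant
count.

## Nucleotide distances and species demarcation

`k2p_distance()` estimates substitutions/site from the transition
proportion *P* and transversion proportion *Q* over valid sites (pairwise
deletion of sites with a gap or ambiguous base in either sequence, the
default in the common distance software):

$$d = -\tfrac{1}{2}\ln(1-2P-Q) - \tfrac{1}{4}\ln(1-2Q)$$

With a gamma shape parameter $a$ each $-\ln(x)$ becomes $a(x^{-1/a}-1)$,
modeling gamma-distributed rate variation; as $a \to \infty$ the correction
vanishes. The shape is supplied, never estimated — the original analyses
delegated estimation to external software without documenting a procedure —
and defaults to none. Saturation ($1-2P-Q \le 0$ or $1-2Q \le 0$) is an
error, not a clamped value.

`demarcate()` applies the baculovirus species criterion: distances above
0.050 substitutions/site on marker genes indicate distinct species. The
boundary itself (`d == 0.050`) does not exceed the criterion, reading
"well above the criterion" as strict exceedance for distinctness.

## Gene parity and inversions

`gene_parity()` turns a partial injective homolog map into the point set of
a gene-parity plot: shared ORFs at their ordinal positions, genome-specific
ORFs on the axes (index 0 on the missing side). `detect_inversions()`
reports maximal runs of at least `min_run` consecutive shared points with
strictly decreasing partner index; plateaus (repeated partner indices)
break runs, and unshared points are skipped rather than breaking runs.
`plot_gene_parity()` draws the standard scatter with inversion blocks
boxed.

## Amino-acid distances, NJ, and bootstrap

`aa_distance()` is a maximum-likelihood pairwise distance under a
reversible empirical model: the likelihood of the observed site-pattern
counts is maximized over the branch length, using the model's
eigendecomposition for transition probabilities. The JTT exchangeabilities
and frequencies are taken from the phangorn distribution of that matrix;
the model interface is generic so other empirical matrices drop in, and a
Poisson model (uniform rates and frequencies) provides a closed-form
cross-check, $-\tfrac{19}{20}\ln(1 - \tfrac{20}{19}p)$ at observed
difference $p$. Rate heterogeneity uses k = 4 equal-probability discrete
gamma categories. The optimizer brackets on $[10^{-6}, 10]$ at tolerance
$10^{-8}$; hitting the upper bracket raises a saturation error. The gamma
shape (0.79 in the analyses this workflow reproduces) is accepted as
configuration only.

`nj_tree()` is a direct Saitou–Nei implementation. Exact ties in the
Q-criterion break lexicographically on taxon labels so the result is
invariant to input order. Negative branch estimates are clamped to zero
with the deficit moved to the sister branch. `bootstrap_support()`
resamples alignment columns with replacement under a seeded RNG, rebuilds
the NJ tree per replicate, and reports for each internal bipartition of the
full-data tree the percentage of replicates containing it; supports are
bit-identical under a fixed seed and invariant to taxon order because
bipartitions are keyed on sorted taxon names. NJ with bootstrap is a
desk-scale stand-in for the large concatenated-alignment ML/ME phylogenies
of the source analyses, which require external databases and days of
computation; it is validated by simulation recovery, not by matching any
specific published tree.

## The synthetic-data generator

`simulate_genome()` emulates the statistical structure of an AT-rich
circular alphabaculovirus genome: default length 100 kb at 34.2% GC, ORFs
of 50–400 codons on both strands (40% reverse), promoter label sets drawn
with early motifs more common than late ones, and hrs of 2–6 copies of the
published-style 58-bp unit at 3% per-base substitution divergence
(the units of real hrs are described as conserved, i.e. near-identical)
with one in four units reverse-oriented. The first ORF starts at position 1,
the polh-at-origin convention, so no rotation step is needed.

Construction guarantees make the truth exactly recoverable: guard cassettes
(`TTAATTAATTAA`, which contains stop codons in all six frames, no promoter
motif, and is its own reverse complement) bound every feature, so planted
ORFs are maximal ATG-to-stop spans at their exact coordinates and filler
never hosts an ORF of 50 codons. Promoter windows are composed, scrubbed of
unrequested motifs, planted with the requested ones, and verified against
the same motif definitions the scanner uses. Realized GC is nudged onto the
target by complementary base flips restricted to intergenic filler.
Determinism: one RNG sub-seed per feature class (layout, ORF contents, hr
contents, windows, filler/assembly), drawn from the user seed, so enabling
one feature class does not perturb another's draws.

`simulate_variants()` plants each class by construction — synonymous SNPs
at third positions of four-fold degenerate codons, nonsynonymous SNPs at
second codon positions (verified to change the amino acid), hr/intergenic
SNPs outside all ORFs, in-frame indels as 3-bp deletions and frameshifts as
1–2-bp deletions inside ORFs — with frequencies Uniform(0.10, 1.0) and an
optional sub-threshold fraction to exercise the filter. `evolve()`
simulates K2P (closed-form transition probabilities, transition/transversion
ratio `kappa`) or empirical-model amino-acid evolution along a branch or a
tree, without indels, so outputs are alignments by construction.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: overlapping genes and shared promoter
regions (real baculovirus genomes are compact; planted ORFs never overlap
and never overlap hrs, so the filter rules are exercised by explicitly
constructed overlap fixtures instead), realistic codon usage beyond a GC
bias, indel divergence within repeat units (substitutions only, so
detected unit lengths are homogeneous), repeat families unrelated to hrs,
sequencing error, and recombination. Detection performance on real genomes
with more divergent or indel-containing repeat units will be worse than the
planted-truth recovery rates; the thresholds exist to be tuned per dataset.

## Problem sizes

The validation suite runs at desk scale, chosen to exercise every code path
with comfortable margins: simulated genomes of 10–30 kb with 6–18 ORFs and
2–4 hrs for end-to-end recovery; 50 random 10-kb genomes for the ORF-caller
oracle equivalence; 1000 random sequences up to 100 nt for the palindrome
oracle; all permutations of up to 8 elements for inversion detection;
5000-site alignments over 50 seeds for distance-estimator recovery; and
100-replicate bootstraps on 4-taxon alignments. The full-scale defaults
(100-kb genomes, 80 ORFs, 6 hrs) run in well under a minute per genome for
annotation and a few seconds for detection per megabase.

## Known limitations

* hr boundary placement is ambiguous up to a rotation of the unit frame;
  the coverage-penalty score resolves it only where flanking sequence
  differs from the unit, so boundaries carry up to quarter-unit
  uncertainty.
* The ORF caller considers ATG initiators only; rare non-ATG starts would
  be missed.
* The coding predicate is a heuristic stand-in; on real genomes the
  published pipelines used two external ab initio predictors whose
  agreement it approximates, not reproduces.
* `aa_distance()` defines its own ML pairwise distance; it is validated by
  simulation recovery and against an independent implementation, not
  against the undocumented formulation of any specific GUI package.
* The demarcation criterion applies to marker-gene alignments supplied by
  the user; the package does not build those alignments.
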