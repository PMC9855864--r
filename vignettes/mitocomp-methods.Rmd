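---
title: "Methods and design of mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mitocomp is a toolkit for comparative mitogenomics of closely related
vertebrates — the motivating system is the three Nile tilapiine cichlids —
covering composition and strand asymmetry, codon usage, tandem repeats,
SNP/indel typing, diversity and neutrality statistics, synonymous/
nonsynonymous substitution counting, and distance-based phylogenies. This
vignette explains the statistical and algorithmic choices, the parameters
that matter, and what the simulation-based validation does and does not
demonstrate.

## Data model and conventions

A `mitogenome_record` holds one circular (or linear) genome with a feature
table (CDS, tRNA, rRNA, control region, pseudogene, spacer). Coordinates
are **1-based inclusive** throughout, the native R and Bioconductor
convention; GenBank I/O is 1-based inclusive as well, so no conversion
happens at the boundary. A feature whose end precedes its start wraps the
origin of a circular molecule; `extract_gene()` resolves the wrap and the
strand, so every downstream module works on linear, sense-strand
sequences. Light-strand features ("−") are reverse-complemented on
extraction.

N bases are allowed in sequences and are excluded from every counting
statistic; each module restates its own missing-data policy below. Spacer
(IGS) annotations are not required in input: `derive_igs()` reconstructs
maximal unannotated spans and names them "X-Y" after their flanking
features, which is how repeat locations such as "trnN-trnC" arise.

The genetic code is fixed to the vertebrate mitochondrial table
(AUA→Met, UGA→Trp, AGA/AGG→stop) and is configurable only by an explicit
argument, because the reassignments materially change both RSCU and the
synonymous/nonsynonymous split. Incomplete stop codons (a CDS ending in T
or TA, completed by polyadenylation) are a normal feature of these
genomes; codon-level operations trim the trailing partial codon, and the
GenBank reader flags only remainders that cannot be a stop prefix.

## Composition and skew

AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C); both are
undefined (reported as missing, never as 0) when the denominator is zero.
Per-gene skews are computed on each gene's **sense strand**. This is the
convention under which the single light-strand protein gene (ND6) shows a
positive GC skew against a genome-wide negative skew; the whole-genome row
and the control region (which has no sense strand) use the heavy strand.
Computation keeps full precision; TSV reports round to 2 decimals.

## Codon usage and RSCU

Codons are counted in frame from each CDS's `codon_start`, skipping codons
containing N or gaps and counting stop codons separately. RSCU for codon c
in a synonymous family of size k is k·x_c/Σx; an amino acid with zero
total usage has undefined RSCU (missing, not 0). The stop "family" is
excluded by default (`include_stops = FALSE`) since usage tables
conventionally cover the 20 amino acids. Bias classification uses a
tolerance of 0.005 around 1 so that values printing as 1.00 at two
decimals count as unbiased.

The high/middle/low usage grouping is obtained by ranking codons by their
cross-species mean RSCU and cutting a Ward-linkage (ward.D2) hierarchical
clustering of the one-dimensional means into seven subgroups, labelled
H1, H2, M1, M2, M3, L1, L2 in descending order. No published algorithm
accompanies this kind of grouping, so the method was chosen to be simple,
deterministic (ties broken by codon lexicographic order) and to expose the
per-subgroup RSCU ranges so users can compare groupings across datasets.
With all means equal the clustering is degenerate: one group plus a
warning.

## Tandem repeats

`find_tandem_repeats()` reports **perfect** tandem arrays only. For each
unit length u (2–15 bp), positions where the sequence equals itself at lag
u are found in one vectorised pass; maximal runs of matches of length r
correspond to arrays of length r + u. An array is kept when it reaches
`min_len` (default 8 bp, matching the shortest arrays worth reporting in
mitogenome surveys) and `min_copies` (default 2; the final copy may be
partial, so copy counts can be fractional). Units must be primitive (not
themselves a repetition), and overlapping detections collapse to the
representation with the shortest primitive unit (ties: longer array, then
leftmost). The reported unit is anchored at the array start; a canonical
(lexicographically smallest) rotation is carried for cross-sample
matching. Arrays never span an N.

Imperfect (mismatch-tolerant) repeat search is deliberately out of scope:
its scoring has too many unstated degrees of freedom to reproduce, whereas
the perfect-repeat definition admits a brute-force oracle against which
the detector is verified exactly. Consequently the package reproduces the
*arithmetic* of published repeat tables (class abundances → percentages)
rather than re-deriving their exact hit lists from raw genomes.

Cross-sample polymorphism matches homologous loci by projected alignment
columns when a whole-genome alignment is available, else by location label
and unit length. Scope is intra-specific (variation within at least one
species only), inter-specific (species internally uniform but different),
or shared.

## SNP/indel calling and scope typing

Every polymorphic alignment column emits exactly one call per kind: a
column with at least two distinct non-gap bases is a SNP; a column with at
least one gap among non-missing samples is an indel; a column with both
emits one of each (the SNP restricted to non-gap samples). N is missing
data for the samples carrying it.

The intra/inter classification must be **total and disjoint** to be
useful, and the prose definitions these types come from are ambiguous, so
the package fixes operational definitions:

- **intra** — exactly one species segregates; all other species are fixed
  for one common allele.
- **inter type i** — at least one species segregates and at least one is
  fixed (and the column is not intra).
- **inter type ii** — every species segregates.
- **inter type iii** — no species segregates; species are fixed for at
  least two distinct alleles.

A configuration with one segregating species and the remaining species
fixed for *different* alleles is type i under these rules (the narrower
reading "two or more species segregate" would leave it unclassified).
Multi-allelic columns follow the same rules on the full allele partition.
The classifier is verified by exhaustive enumeration of all two-allele,
three-species configurations against an independently coded decision
table. Pairwise counts in summaries are fixed-difference counts (columns
where the two species are each fixed, for different alleles).

## Diversity and neutrality

Haplotypes are distinct full-length sequences; Hd uses the small-sample
correction n(1 − Σp²)/(n − 1). π is the mean pairwise proportion of
differing sites over all C(n,2) pairs. The default missing-data policy is
pairwise deletion (sites with N or gap in either member of a pair are
dropped for that pair), the behaviour of standard polymorphism software at
default settings; complete deletion is available by flag since the choice
is not always documented in published analyses, and both are reported
where it matters. Tajima's D uses the standard constants with k̄ as the
mean pairwise difference **count** (not per site); it is undefined when
S = 0 or n < 4. Significance is not assessed: the beta-approximation
p-values some programs print are out of scope, and the report footer says
so rather than inventing a null.

## Substitution counting and ω

Counting is reference-anchored and site-independent: in a codon-aware
gene alignment, every position where the query differs from the reference
is classified by substituting the query base into the full reference codon
and comparing translations. This "number of substitutions" semantics (as
opposed to pathway-resolved counting) matches integer count tables and
reproduces their ω arithmetic exactly. Conventions: ω = nonsyn/syn when
syn > 0; ω = 0 whenever nonsyn = 0 (including 0/0); undefined when
syn = 0 with nonsyn > 0. Codons containing N or gaps in either row are
skipped. The classifier is validated exhaustively over all 64 × 3 × 3
single-base codon changes by double translation.

In the tilapiine substitution table shipped in `inst/extdata/`, the
per-species column pair is stored as (synonymous, nonsynonymous) — the
internally consistent reading under which every printed ratio equals
second/first (24/76 = 0.32, 3/9 = 0.33, 2/5 = 0.40, 3/3 = 1.00), even
though the source table's own column headers swap the two labels.

The amino-acid change spectrum is anchored on an outgroup: at each residue
column where ingroup samples differ from the outgroup residue o, changes
are tallied per species. Variants carried by **all** ingroup samples
(100% frequency) are excluded — they describe the reference, not the
ingroup. Direction uses the ingroup majority residue m: samples carrying
m ≠ o count as forward changes o→m; samples retaining o at such columns
count as reverse changes m→o. The anchor (outgroup vs reconstructed
ancestor) is a genuine design choice; the outgroup is used because it
requires no ancestral-state inference, and the choice is recorded in the
report metadata.

## Phylogeny

Distances: p (mismatch proportion), JC69 (−¾·log(1 − 4p/3), undefined at
saturation p ≥ ¾, reported missing) and K2P, all with pairwise deletion of
gap/N sites; they are cross-checked against an independent implementation
in the tests. Trees are neighbor joining (Saitou–Nei, via ape) with
negative branch lengths clamped to zero and the deficit moved to an
adjacent branch of the same node. Bootstrap support resamples columns with
replacement under a caller-supplied seed; support is the percentage of
replicate trees containing each internal bipartition of the full-data
tree. Full maximum-likelihood inference is deliberately not included: NJ
over corrected distances is self-contained, fast, exactly testable (it
provably recovers additive matrices), and for the shallow divergences this
package targets it recovers the same topologies; alignments can be
exported for external ML tools. Outgroup rooting is display-only; all
topology tests work on unrooted bipartitions.

## The simulator: what it emulates, and what it does not

`simulate_mitogenomes()` draws an ancestral genome on a standard
vertebrate mitochondrial template — 13 protein-coding genes, 22 tRNAs (one
annotated as the D-arm-less trnS2 pseudogene), 2 rRNAs and one control
region, ~16.5 kb in total, with ND6 and eight tRNAs on the light strand —
and evolves it along a species tree.

Default study conditions (chosen once, as the conditions the analyses
assume, and not revisited):

- **Base composition** A/C/G/T = 27.76/30.82/15.78/25.66% (the mean
  composition of the three tilapiine genomes; the printed percentages sum
  to 100.02 and are renormalised).
- **Tree** `((O. niloticus:0.03, S. galilaeus:0.03):0.015,
  C. zillii:0.045, O. keta:0.30)` substitutions/site, with
  within-species tip branches of 0.004: divergences of a few percent
  between congeneric cichlids, a deeply diverged salmonid outgroup, and
  sub-percent haplotype diversity, matching the depth at which the
  published comparisons operate. Three samples per ingroup species, one
  outgroup.
- **κ = 4**, a typical vertebrate mitochondrial transition bias.
- **Per-gene rates** high for the ND complex (ND6 highest), low for
  tRNAs, intermediate for rRNAs, control region fastest; **per-gene ω**
  from ~0.02 (COX3) to 0.45 (ND6), mirroring the strong purifying
  selection with ND6 as the fastest protein gene.
- **Repeat arrays**: TA (4–6 copies), TTA (4–5) and AATAC×5 in the
  control region — with AATGC as the *O. niloticus* unit variant — CCCG
  (4–6) in the trnN–trnC spacer and CAA (3–5) in the trnS2 pseudogene;
  copy numbers vary per sample in whole-unit steps.

Protein-coding genes are generated codon-aware (no internal stops; ATG
starts except GTG for COX1; several genes carry incomplete stops) and
evolved by acceptance-rejection: proposals from a frequency-weighted,
κ-biased kernel; stop-creating proposals rejected; synonymous proposals
accepted; nonsynonymous accepted with probability ω. This is simpler than
exponentiating a codon rate matrix and is adequate for the package's
validation goal, which is *rank* recovery of ω across genes, not unbiased
estimation of ω itself (the site-counting estimator is expected to
compress and inflate scales). The initiation codon is held fixed.

Indels occur only through repeat copy-number variation — never in CDS —
so CDS alignments are gap-free by construction, matching what is observed
in these genomes. The control-region and spacer backgrounds are screened
to be free of chance tandem arrays at the detector's thresholds, and the
bases adjacent to planted arrays are constrained so an array cannot extend
into its flanks. Because block-local screening cannot see arrays that
straddle block boundaries, a final deterministic pass scans each assembled
genome and point-mutates one base of any chance array overlapping those
compartments; planted arrays are therefore the *only* arrays there and
repeat recall/precision are well defined. SNP columns of
known scope/type are planted in the rRNAs by overwriting ingroup alleles
at distinct positions after evolution.

What the simulator does **not** emulate: recombination and heteroplasmy
(absent by assumption in mitogenomes), sequencing error, alignment error
(alignments are emitted with known homology; real pipelines inherit MAFFT's
choices), imperfect repeats, and selection regimes beyond a constant
per-gene ω. Passing recovery tests therefore demonstrates that the
analysis chain is correct on data satisfying its assumptions — not that
those assumptions hold for any particular real dataset.

## Validation strategy and problem sizes

Each algorithm is checked against an independent oracle: the repeat
detector against brute-force enumeration on random sequences up to 200 bp;
Tajima's D against a step-by-step evaluation of the constants (to 1e-9) on
random alignments (n ≤ 8, L ≤ 50); the syn/nonsyn classifier exhaustively
over all single-base codon changes; NJ against the generating tree of
random additive matrices (≤ 12 taxa); the scope/type classifier
exhaustively over all two-allele three-species configurations. Recovery
experiments use a full-scale (~16.5 kb) simulation for SNP typing, repeat
recovery and tree splits, and a dedicated 10-gene × 2,000-codon experiment
for ω rank correlation; bootstrap support uses 100 replicates. Unit tests
run the same machinery on a ×0.1 miniature genome, which preserves the
structure (all 37 genes, arrays, planted SNPs) at a fraction of the cost;
these sizes are the package's chosen validation design.

## Known limitations

- Repeat detection is perfect-match only; abundance tables from
  mismatch-tolerant searches are comparable only at the arithmetic level.
- ω from site counting is a rank statistic here, not an estimate of the
  dN/dS parameter (no per-site opportunity normalisation).
- Tajima's D comes without significance; D-loop alignments with heavy
  indel content reduce usable sites under pairwise deletion.
- The NJ trees stand in for likelihood methods; at deep divergences or
  strong rate heterogeneity they may differ.
- The forward/reverse direction of amino-acid changes depends on the
  outgroup anchor; with a poorly chosen outgroup the labels (not the
  counts) change meaning.
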