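# mitocomp

Comparative analysis of annotated mitochondrial genomes in closely related
species, built around the Nile tilapiine cichlids (*Coptodon zillii*,
*Oreochromis niloticus*, *Sarotherodon galilaeus*) as the motivating system.
The package takes annotated mitogenomes (GenBank flat files) and multiple
sequence alignments (aligned FASTA plus a sample-to-species table) and
computes, per gene and per genome:

- **Composition and strand asymmetry** — base content, AT/GC content, and the
  skew statistics AT skew = (A − T)/(A + T), GC skew = (G − C)/(G + C),
  evaluated on each gene's sense strand (so a light-strand gene such as ND6
  can show positive GC skew against a negative genome-wide skew).
- **Codon usage** — codon counts over the 13 protein-coding genes under the
  vertebrate mitochondrial code (AUA→Met, UGA→Trp, AGA/AGG→stop), relative
  synonymous codon usage RSCU_c = k·x_c / Σ x (k = family size), bias
  classes (RSCU >1 preferred, =1 unbiased, <1 avoided), and 1-D Ward
  clustering of codons into usage subgroups H1–L2.
- **Tandem repeats** — perfect tandem arrays with primitive units of 2–15 bp
  (default minimum array 8 bp, ≥2 copies), localised against the annotation
  (gene, D-loop, pseudogene, or the derived intergenic spacer "X-Y"), with
  class-abundance summaries and cross-sample unit/copy-number polymorphism.
- **SNPs and indels** — deterministic alignment-column calls, split into
  intra-specific variation and three inter-specific types (i: segregating in
  some species, fixed in others; ii: the polymorphism segregates in every
  species; iii: fixed differences between species groups), plus a minimal
  VCF export against a named reference row.
- **Diversity and neutrality** — segregating sites S, haplotypes h,
  haplotype diversity Hd = n(1 − Σp²)/(n − 1), nucleotide diversity π
  (mean pairwise difference proportion), and Tajima's D from the standard
  constants (a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂).
- **Selection** — reference-anchored counts of synonymous and nonsynonymous
  substitutions (every mismatching site classified against the full
  reference codon), ω = nonsyn/syn with the bookkeeping conventions of
  count tables (ω = 0 whenever nonsyn = 0), cross-species averages, and an
  outgroup-anchored amino-acid change spectrum with forward/reverse
  direction and pair imbalance.
- **Phylogeny** — p/JC69/K2P distances, neighbor-joining trees with
  column-resampling bootstrap, newick and PHYLIP output, over whole-genome,
  concatenated-CDS, control-region and spacer partitions.

A codon-aware simulator (`simulate_mitogenomes()`) generates annotated
~16.5 kb circular mitogenomes with the standard vertebrate gene order
(13 PCGs, 22 tRNAs, 2 rRNAs, control region; ND6 and eight tRNAs on the
light strand), realistic AT-rich composition, per-gene rates and dN/dS,
planted repeat arrays and SNP columns with known labels — so the entire
pipeline is testable end to end without downloading anything.

## Worked example

```r
library(mitocomp)

# simulate a three-species set (plus outgroup), miniature genome for speed
sim <- simulate_mitogenomes(simulation_config(seed = 7, scale = 0.1))
sim
#> <mito_sim> 10 samples, 4 species, genome 2143 bp (aligned 2164)

# per-gene dN/dS against a reference sample
aln <- sim$gene_alns[["ND6"]]
count_gene_substitutions(aln, "Sgal_01", "Czil_01")
#>   gene         species syn_count nonsyn_count omega reference_id
#> 1  ND6 Coptodon_zillii         2            2     1      Sgal_01

# how well does the analysis chain recover what the generator planted?
rr <- recovery_report(sim)
rr$snp$accuracy      #> 1       (planted SNP scope/type labels recovered)
rr$repeats$recall    #> 1       (planted repeat arrays, unit + copy number)
rr$tree$recall       #> 1       (species clades and the true tree's splits)
```

(Numbers above are from this exact seed; `Czil_01`'s counts vary with the
seed, the recovery metrics are stably 1 at these settings.)

The full workflow — composition, codon usage, repeats, variants, diversity,
selection, trees, one JSON summary — runs as one call:

```r
cfg <- pipeline_config(sim, reference_id = "Sgal_01", outgroup_id = "Oket_01",
                       out_dir = "report")
run_pipeline(cfg)
```

or from the shell over a directory of GenBank + FASTA inputs:

```sh
Rscript inst/scripts/mitocomp.R simulate --seed 7 --scale 0.1 --out simdir
Rscript inst/scripts/mitocomp.R run --in simdir --reference Sgal_01 \
    --outgroup Oket_01 --out report
```

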