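# teloci

Comparative transposable-element (TE) annotation and allelic inheritance
analysis for two related genome assemblies.

## The problem

Two closely related haploid yeast strains can differ strikingly in
transposable-element content even when one strain is a parent of the
other (via a cross with a second parent). Three histories can explain an
element present in one strain but not the other:

1. **Degenerated relic** — the element decayed beyond recognition in one
   lineage;
2. **Differential segregation** — the element was inherited from the
   second parent of the cross *together with its flanking sequence*;
3. **Post-cross transposition** — a new insertion after the cross, at a
   position unrelated to parental origin.

`teloci` implements the analysis that separates these: structural
annotation of LTR retrotransposons, solo LTRs and LINE fragments from
raw sequence; partition of each annotated genome into interval loci
(iLoci); reciprocal-best allelic mapping with per-kb variant densities
(M = mismatches/kb, I = inserted bases/kb, D = deleted bases/kb);
reconstruction of naive (pre-insertion) sites and search for the empty
junction in the partner strain (tests history 1); and a permutation
contrast of mean flanking density between allelic and non-allelic
elements (separates histories 2 and 3). A synthetic hybrid-strain
generator produces the full data structure with known truth, so every
stage is testable without downloads. In-silico nickase digest utilities
(Nt.BspQI by default) with tandem-period detection support optical-map
style localization of large tandem repeats such as rDNA arrays.

The core statistic: for each TE, variant densities are averaged over the
four iLoci surrounding the insertion (two per flank), and the allelic
group is compared with the non-allelic group by a two-sided
label-permutation test on the difference of group means
(`(count + 1)/(n_perm + 1)`, 10,000 permutations by default, rank-sum
p reported alongside). Elements inherited from the second parent sit in
measurably denser flanking variation; post-cross insertions do not.

## Worked example

Simulate a hybrid strain pair at 1-Mb scale and run the comparison with
the derived strain as focal:

```r
library(teloci)

cfg <- simulation_config(seed = 42,
                         chrom_lengths = c(chrA = 500000L, chrB = 500000L))
anc <- generate_ancestor(cfg)
sim <- simulate_hybrid_strains(anc, cfg)
res <- compare_strains(sim$strain_b, sim$strain_a,
                       sim$features_b, sim$features_a, seed = 42)
rep <- res$report
rep$pooled$allelic_means
#>    M    I    D
#> 1.94 0.54 0.67
rep$pooled$non_allelic_means
#>    M    I    D
#> 4.10 1.01 2.22
rep$pooled$comparisons$M$p_value
#> [1] 9.999e-05
rep$fraction_empty_sites
#> [1] 0.9
rep$verdict
#> $H1
#> [1] "excluded"
#> $H2_vs_H3
#> [1] "H2-supported"
```

Reading the output: the 20 non-allelic elements (planted inside
second-parent mosaic blocks carrying 3x divergence) sit in flanking
sequence with mean mismatch density 4.10/kb versus 1.94/kb for the 16
allelic elements, and the permutation test rejects equal means
(p &asymp; 1e-4). Nine of ten reconstructed naive sites are found as
intact empty junctions in the partner strain, excluding the
degenerated-relic history; the report labels the data as supporting
differential segregation (H2) over post-cross transposition (H3) —
which is exactly how the pair was simulated.

Structural anatomy of a single element:

```r
el <- cfg$templates$gypA$element_seq
annotate_element_anatomy(el, trna_ends = c(tMet_i = cfg$trna_end),
                         params = list(min_orf_aa = 300))
#> ElementAnatomy: full-length (5973 bp)
#>   TIR 6 bp (TG...CA)
#>   LTR pair 244 bp, identity 1
#>   PBS14nt at +2 (tMet_i)
#>   PPT 13 purines, end offset 0
#>   ORFs: 2 ; spacers: 324
```

File-based runs (`run_simulate`, `run_annotate`, `run_compare`,
`run_digest`) write FASTA/GFF3/TSV/JSON/BED outputs plus a run manifest;
a thin command-line wrapper ships in `inst/cli/teloci.R`.

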