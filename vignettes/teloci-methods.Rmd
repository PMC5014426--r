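---
title: "Methods: comparative transposable-element annotation and allelic inheritance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative transposable-element annotation and allelic inheritance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Two closely related haploid yeast strains — one of which is a parent of
the other via a cross with a second, more distant parent — can differ
strikingly in transposable-element (TE) content. Three histories can
produce such differences:

* **H1 — degenerated relics.** The elements were once present in both
  lineages but have decayed beyond recognition in one of them.
* **H2 — differential segregation.** The elements existed in one parent
  of the cross and were inherited *together with their flanking
  sequence*; where the derived strain carries a chromosomal block from
  the second parent, it carries that parent's elements too.
* **H3 — post-cross transposition.** A wave of new insertions occurred
  after the cross, landing at positions unrelated to parental origin.

These histories make distinct, testable predictions. H1 is tested by
reconstructing the pre-insertion ("naive") site — element excised, one
copy of the target-site duplication retained — and searching the other
strain for the intact empty junction: if the empty site exists, there is
no decayed relic there. H2 and H3 are separated by the divergence of the
sequence *around* each insertion: under H2, elements present in only one
strain (non-allelic) sit in chromosomal blocks inherited from the
second parent and are therefore embedded in locally divergent sequence,
while shared (allelic) elements sit in low-divergence sequence; under H3
the flanking divergence of non-allelic elements matches the genome-wide
average. `teloci` implements this complete analysis, plus the structural
TE annotation it depends on and a synthetic data generator that creates
the H2 structure with known truth.

# Structural annotation

Elements are recognized from sequence alone by their replication and
integration signatures. Each detector is a small exact algorithm; every
one of them is property-tested against an independent brute-force
enumeration on short inputs.

* **Terminal inverted repeat (TIR)** — the longest prefix of the element
  equal to the reverse complement of its suffix, with a configurable
  mismatch budget; flagged as conforming when it obeys the near-universal
  `TG...CA` rule. An `N` opposite anything counts as a mismatch.
* **Target-site duplication (TSD)** — the longest word ending the
  upstream flank and beginning the downstream flank, with a bounded
  length band (default 4–12 bp), an upstream offset tolerance (default
  1 bp — the worked example in the source strain has a 5-bp TSD whose
  upstream copy is offset by one base), and exact matching by default.
  Ties break to the longer length, then the smaller offset.
* **LTR pair** — local affine-gap alignment of the first and last
  `max_ltr` bp (windows kept disjoint by construction); a pair is
  reported when both aligned repeats are at least `min_ltr` long, within
  2 bp of each other, and at `min_identity` (default 0.90). Scoring is
  match +2 / mismatch −3, so a terminal substitution trims at most two
  bases — the origin of the ±2 bp recovery tolerance.
* **PBS** — the minus-strand primer site: best reverse-complement match
  between the region just downstream of the 5' LTR and the 3' terminus of
  any supplied tRNA (longest, then closest to the LTR). G:U-equivalent
  wobble pairing is off by default and available as a flag, since the
  pairing rule for imperfect primers is not standardized.
* **PPT** — the longest purine run ending within a few bp of the 3' LTR.
* **ORF layout** — maximal stop-free codon runs in the three forward
  frames (elements are oriented by LTR/TIR polarity first); an ORF's
  interval includes its terminating stop codon, so the spacer between
  consecutive ORFs starts after the upstream stop, and the spacer's
  in-frame stop count excludes that stop. This convention makes a
  two-ORF element with a 324-bp spacer containing four stops read out as
  exactly `spacer_lengths = 324`, `spacer_stop_counts = 4`.
* **RNAP3 association** — an insertion boundary 15–17 bp upstream of a
  mature tDNA/5S start (on that gene's strand) is start-targeted; inside
  the gene, internal; within 100 bp, adjacent. The window is the
  combined effect of the ~10-nt pre-tRNA leader and a 5-bp TSD.
  Classification is strand-symmetric under coordinate mirroring.
* **Solo-LTR families** — single-linkage clustering at coverage-weighted
  identity (matches over the longer sequence, default threshold 0.80)
  with a per-family majority-rule consensus against the longest member.
* **Census** — homology hits of one reference per family (search
  delegated to `blastn`), merged per family, then length-classified:
  full-length at ≥ 0.92 of the reference length, partial above 1 kb,
  fragment from 30 bp to 1 kb, shorter hits discarded. The full-length
  threshold is a fraction so one rule serves a 6.5-kb LINE and a 9.5-kb
  LTR element. Because the two LTRs of a full element cross-match, short
  HSPs mostly covered by a longer kept HSP are dropped before merging;
  otherwise a coincidental 1-bp extension of a cross-LTR HSP can nudge a
  merged boundary.

# iLoci and allelic mapping

Each annotated genome is partitioned into **iLoci**: merged feature
intervals and the intergenic gaps between them. Overlapping and
book-ended features merge (member ids preserved), zero-length gaps are
omitted, and the partition is exact — iLocus lengths sum to the
chromosome length, which the tests assert on random annotations. A TE's
**flank set** is the nearest `k` (default 2) iLoci strictly on each side;
iLoci overlapping the TE interval are never used, so the element's own
locus and any locus containing it are excluded. Whether a *neighboring*
TE's iLocus may serve as a flank is left permissive.

Allelic pairs are found by a two-layered reciprocal mapping: each locus
set is queried against the other, and a pair is emitted only when the two
loci are one another's best hits. Candidates are pre-screened with exact
24-mer probes located in the partner genome, so only the top two vote
winners are aligned. Alignment is global affine-gap (match +1, mismatch
−2, gap open 6, gap extend 1); pairs longer than the length cap are split
recursively at a shared unique anchor k-mer. Identity is matches over
aligned base pairs with N columns excluded, so assembly gaps never
inflate variant counts.

Coverage is **glocal**: the pairing requirement is that the *shorter*
sequence be nearly fully aligned (`max(coverage_a, coverage_b) >= 0.80`).
This is deliberate: when an element is annotated in one strain only, the
intergenic locus at that position is split into two pieces in the
element-bearing strain, and each piece must still be able to pair with
the single intact locus of the other strain, exactly as a glocal
cDNA-style aligner would map it. Terminal gap runs of such pairs are
locus structure, not sequence variation, and are trimmed before variant
counting. Spurious pairings of small loci into large ones are prevented
by the exact-probe prescreen and the reciprocal-best requirement.

Variant counts follow the convention that bases present in the focal
strain and absent in the partner are insertions, and vice versa
deletions; densities (`M`, `I`, `D` per kb) are anchored on the focal
(strain-A) locus length so they are comparable across pairs. Whether the
source analysis counted indel events or indel bases is not stated; we
count bases (matching the "nucleotides ... classified as an insertion"
convention) and report event counts as auxiliary output.

# Inheritance analysis

A focal-strain TE is **allelic** when the partner-strain region delimited
by the partners of its nearest partnered flanking iLoci contains a
same-family TE of any class (a solo LTR at the position of a full element
still counts); otherwise, or when no flank has a partner, it is
non-allelic. Per TE, the mean M/I/D over its partnered flank iLoci is
recorded (flanks without partners reduce `n_flanks`).

The allelic versus non-allelic contrast is tested per metric with a
two-sided label-permutation test on the difference of group means,
`(count + 1)/(n_perm + 1)` convention, default 10,000 permutations and a
recorded seed; a Wilcoxon rank-sum p-value is reported alongside as a
cross-check. The source analysis reports p-values without naming the
test; a permutation test was chosen because it is distribution-free and
honest for small, unequal groups. The three metrics are tested
separately, mirroring the three separate published p-values. The pooled
(all families together) grouping is the default, matching the phrasing
"comparing all allelic TE to non-allelic TE"; per-family means are
reported in the same structure.

The report's verdicts are: H1 `excluded` when any reconstructed naive
site is found empty in the partner genome (contiguous junction, ≥ 0.90
identity over ≥ 90% of the naive sequence, no element-sized gap);
H2 `supported` when non-allelic mean mismatch density exceeds allelic
with permutation p below 0.05; otherwise `H3-consistent`.

# The synthetic generator

The generator creates the study's data structure with known truth:

* An **ancestor** genome (random sequence at GC 0.49) annotated with
  genes (0.35/kb, mean 1,350 bp — fungal-genome-like density where about
  half the genome is genic) and tDNAs (0.025/kb), placed slot-wise so the
  density is met without overlap.
* **Second-parent blocks** drawn by an alternating renewal process
  (fraction 0.5, mean block 50 kb) emulating one meiosis worth of
  mosaic inheritance; no block statistics are published, so both numbers
  are config-exposed.
* **Divergence** realized on the strain-B lineage: substitutions at
  2.4/kb intergenic and 1.2/kb genic (the published genome-wide iLocus
  densities), multiplied by 3 inside second-parent blocks; intergenic
  indel events (geometric lengths, mean 2 bp, capped at 50 bp) at rates
  giving roughly 1–2 inserted/deleted bases per kb. Indel events are kept
  60 bp clear of feature boundaries so every annotation coordinate remaps
  exactly through the event list. Putting all pairwise divergence on one
  lineage is equivalent for every statistic computed, all of which are
  pairwise.
* **Elements** built from anatomy templates — 244-bp LTRs with the
  TG...CA hexamer termini, a 14-nt PBS two nt downstream of the 5' LTR,
  a 324-bp four-stop inter-ORF spacer, a 13-purine PPT, total 5,973 bp —
  and planted with a 5-bp TSD. Ancestral elements are confined to
  shared-parent territory and inherited by both strains; lineage-B
  elements are confined to second-parent blocks with their flanking
  region inside the block (that is what "embedded in second-parent
  sequence" means, and it is the H2 structure); lineage-A elements are
  placed uniformly in intergenic space. The default plan (6 full + 10
  solo ancestral, 8 full + 12 solo lineage-B, 3 lineage-A solos) is
  scaled to the published census, where both groups number in the tens.
* **Guard bases.** The generator's truth labels must be unambiguous by
  construction: template construction pins the TIR at exactly 6 bp and
  the PBS at exactly 14 nt, and planting re-detects the TSD and edits up
  to two neighbouring bases (or resamples the site) if ambient sequence
  would extend the duplication. Without the guards a truth label would
  occasionally be wrong by construction rather than by detector fault.

What the generator does **not** emulate: real base composition and
repeat landscape (random sequence has no microsatellites, no biased
codon usage), sequencing or assembly error, segmental duplications and
inversions as random events (available only as explicit constructions),
tRNA gene sequences with real secondary structure, and selection.
Passing tests therefore demonstrate algorithmic correctness and
end-to-end recovery of the planted structure, not performance on real
assemblies.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere inside the package; GFF3
  and BED conversion happens only at the I/O boundary.
* The nick-site tandem-period detector chains sites `s, s+p, s+2p, ...`
  over candidate periods taken from pairwise spacings (tolerance 0.2% of
  the period, capped at 25 bp) and accepts a period only when some chain
  spans three sites, total support is at least three links, and the
  period explains at least half the sites in the window — random site
  patterns contain short arithmetic progressions but never explain most
  sites. Nick sites are reported per strand (a nickase cuts one strand);
  period detection uses the strand-merged list, as labels appear on a
  molecule. A minimum inter-site distance (default 0) is exposed because
  near-adjacent opposite-strand sites merge on real optical maps.
* `compare_groups` saves and restores the global RNG state, so a fixed
  analysis seed cannot perturb surrounding simulations.
* Best-hit ties break by longer alignment, then lexicographic id —
  output is deterministic.
* The end-to-end comparison maps only the TE flank iLoci by default
  (`full_map = FALSE`); the statistic needs densities only for paired
  flank loci, and the restriction makes a 2-Mb, 20-seed study run in
  minutes on one CPU. `full_map = TRUE` maps everything and adds
  genome-wide genic/intergenic baselines.
* Problem sizes used by the test suite: detector oracles run 500 draws
  on inputs up to 2 kb; alignment is checked against a quadratic affine
  DP oracle on pairs up to 300 bp; density calibration uses 200
  simulated 1.5-kb loci at 5 substitutions/kb; the end-to-end
  hypothesis-2 recovery uses 20 seeds at the default 2-Mb genome.
* The element census length (5,973 bp) is reported LTR-start to LTR-end;
  whether the published length spans TSD-to-TSD instead is not stated,
  and the TSD copies are not part of the element interval here.

# Known limitations

* The reciprocal mapper assumes mostly co-linear strains; it has no
  inversion awareness, and a locus inside a large inversion pairs only
  if its own sequence still matches (the probes are strand-specific).
* `census_elements` requires the BLAST+ executables on the PATH.
* Naive-site search localizes by exact 21-mers; at divergences far above
  a few percent the probe hit rate, and with it sensitivity, drops.
* The permutation test treats TEs as exchangeable units; flanks shared
  between two nearby TEs are counted in both profiles.
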