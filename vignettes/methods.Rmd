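---
title: "Methods: small RNA profiling and microRNA discovery in mirseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling and microRNA discovery in mirseek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseek)
```

## The analysis problem

`mirseek` implements a complete two-library small RNA sequencing analysis
for species without their own sequenced genome, the situation of many
non-model fishes profiled against the zebrafish genome as a surrogate
reference. The pipeline takes two deep small RNA libraries (here called
`A` and `B`), cleans and collapses them to unique tags, maps tags to the
surrogate genome with a one-mismatch tolerance, triages away other
non-coding RNA and repeat-associated material, quantifies conserved
miRNAs against a mature reference set, and searches for novel miRNAs by
two complementary routes:

* **genome-anchored discovery** — candidate precursor windows are excised
  around unannotated mapped read clusters, folded, and filtered by the
  stem-loop criteria below;
* **genome-free discovery** — unmapped tags are paired into putative
  miRNA/miRNA\* duplexes, joined with a hairpin-forming linker
  (`GCGGGGACGC`), folded, and filtered by free energy. This route finds
  species-specific miRNAs that the surrogate genome cannot anchor.

Finally the conserved profile is compared between the libraries on the
TPM scale with log2 fold classes, a ≥10-fold "maximum difference" table,
a top-family share table and an average-linkage clustering.

## Decision thresholds

All constants live in `pipeline_config()` and are overridable. The
defaults are the study-scale values:

| parameter | default | role |
|---|---|---|
| `min_read_len` | 18 nt | insert length floor after trimming |
| `map_mismatch_max` | 1 | genome mapping Hamming tolerance |
| `rasirna_len` | 24–27 nt | repeat-associated siRNA length window |
| `s1_mature_len` | 20–24 nt | mature length, genome-anchored route |
| `s1_min_reads` | 5 | read floor for a genome-anchored candidate |
| `s1_dg_max` | −18 kcal/mol | precursor fold energy ceiling |
| `s1_bulge_max` | 4 nt | largest bulge in the miR/miR\* duplex |
| `s1_lendiff_max` | 4 nt | miR vs miR\* length difference |
| `s1_loop` | 5–35 nt | space between the duplex arms |
| `s1_asym_max` | 5 nt | duplex asymmetry |
| `s2_min_reads` | 10 | dominant-strand read floor, genome-free route |
| `s2_len` | 18–24 nt | duplex strand lengths |
| `s2_mismatch_max` | 4 | duplex mismatches (G:U counts as a pair) |
| `s2_bulge_max` | 4 nt | largest bulge (gap run) in the duplex |
| `s2_dg_max` | −21 kcal/mol | joined stem-loop energy ceiling |
| `linker` | `GCGGGGACGC` | hairpin-forming joint for the two strands |
| `tpm_pseudo` | 0.01 | substitution for a zero TPM in ratios |
| `tpm_discard` | 1 | records under this TPM in both libraries drop |
| `fold_class_bounds` | 1, 2 | \|log2\| bin edges (2-fold, 4-fold) |

Free-energy cutoffs are **inclusive**: a candidate at exactly
−18 (or −21) kcal/mol passes. Published descriptions of such filters say
"below −18" without stating how boundary equality is treated; we fix the
inclusive convention and document it here. Likewise the 2-fold class
boundary is inclusive ("equal or less than 2-fold").

## Folding engine

Both discovery routes need minimum-free-energy secondary structure. The
engine (`fold_hairpin()`, C++ core) searches the *single-hairpin* class:
one nested chain of pairs closed by one terminal loop — no multiloops or
pseudoknots, which is the class a pre-miRNA stem-loop occupies. The
energy model is a Turner-style nearest-neighbour table
(`fold_params()`): Watson–Crick and G:U stacking energies, hairpin,
bulge and internal-loop initiation penalties with Jacobson–Stockmayer
extrapolation, an asymmetry penalty of 0.6 kcal/mol per nt capped at
3.0, a 3-nt minimum hairpin loop, and a 30-nt interior-loop cap.
Single-nucleotide bulges retain the flanking stack. Dangling ends and
terminal mismatches are omitted; this biases energies towards zero by
roughly 1–2 kcal/mol and is accepted because the −18/−21 cutoffs
presuppose energies on the classic mfold scale, which these tables
reproduce. Tie-breaking is deterministic (more pairs, then 5′-most
pairing).

On sequences of ≤30 nt the engine is checked against exhaustive
enumeration of every legal structure scored by an independent energy
evaluator; on the synthetic precursor set its energies are on the same
scale as an external thermodynamic folding engine.

The fold used when screening linker-joined duplexes caps interior loops
at 12 nt (`s2_fold_max_interior`): a structure needing a larger interior
loop could not satisfy the 4-nt bulge criterion anyway, and the cap
makes the screening fold several-fold faster.

### Stem geometry

`hairpin_geometry()` measures the quantities the criteria need. The
star arm is the largest contiguous block of positions paired to the
mature (blocks split at gaps >6 nt), extended by the canonical 2-nt
3′ overhang. A window fold can extend a stem opportunistically into
flanking sequence; mature bases pairing outside the chosen block are
treated as unpaired within the duplex, so bulges and asymmetry are
measured on the miR/miR\* duplex rather than on the whole opportunistic
helix. A mature arm with under half of its bases paired is reported "off
stem" (a verdict, not an error).

## Mapping and annotation

Mapping reports **all** genomic loci at Hamming distance ≤1 over the
full tag length, on both strands, via an exact k-mer seed index. The
seed length is capped at ⌈(L−1)/2⌉ (9 for 18-nt tags) so a tag with one
mismatch always retains an intact seed — the index only prunes and the
result equals a brute-force scan, which the tests assert.

Annotation assigns exactly one category per tag with fixed priority:
other ncRNA (substring of an rRNA/tRNA/snRNA/snoRNA reference at ≤1
mismatch) > rasiRNA (24–27 nt with a hit in a repeat interval) >
conserved miRNA (tolerance rule below) > mapped candidate; unmapped tags
feed the genome-free route. When a known-precursor set is supplied the
pipeline additionally sets aside mapped candidates that fall inside a
known hairpin outside its mature (star arms, loop fragments) so
discovery only sees new loci.

The **tolerance rule** for matching a tag to a known mature allows: an
exact match; or ≤2 mismatches confined to the last 2 nt of the 3′ end;
or ≤1 internal mismatch — with ≤2 nt total length difference and a 5′
offset of at most 2 nt (isomiR end variation). A tag is assigned to at
most one miRNA (fewest mismatches, smallest length difference,
lexicographically smallest reference id).

IsomiR clustering merges tags whose primary hits on one strand lie
within `shift_max` (3 nt, transitive closure); the representative is the
member with the dominant read count, ties broken towards the
lexicographically smallest sequence. The 3-nt value is our choice — the
processing-offset scale of Drosha/Dicer variants — and is configurable.

## Genome-anchored discovery

For each unannotated cluster two windows are excised to test the
representative read as the 5′ or 3′ arm: `[start−70, end+15)` and
`[start−15, end+70)` (window extents are tool internals in the
literature and are configurable here; the recovery tests pin the
defaults). Minus-strand anchors use the reverse complement. Each window
is folded and the seven criteria in the table above are evaluated; when
both windows pass, the lower-energy window wins. Accepted candidates
whose windows overlap on the same strand are deduplicated (lowest
energy kept); a near-palindromic hairpin can additionally be reported on
the antisense strand of the same locus, which we keep as-is since it
identifies the same physical hairpin. Accepted candidates are then
cross-checked: a mature that is a substring (≤1 mismatch) of a
transcriptome contig is re-labelled an mRNA degradation fragment; one
matching a known mature under the tolerance rule is re-labelled a
conserved-family homolog; the remainder are novel. Star-strand read
support is reported but not required — the structural criteria constrain
the star arm without demanding star reads; `s1_require_star` turns the
stricter behaviour on.

## Genome-free discovery

Unmapped tags of 18–24 nt are searched for duplex partners. A tag needs
≥10 reads to launch a search (the dominant strand); partners need ≥1
read (the literature states no floor for the partner; configurable).
The pairing alignment is a small constrained dynamic program: global
alignment of the dominant against the reversed partner under a pairing
alphabet (A–U, C–G, G–U wobble = paired), gap runs are bulges of ≤4 nt,
total gap columns ≤8 (`s2_gap_total`, our choice: two maximal bulges
plus Dicer-style end overhangs), mismatches ≤4. The search is exact; a
banded upper bound on achievable paired columns only prunes pairs that
cannot reach feasibility, and the tests compare the output against a
brute-force recursive aligner.

Each retained pair is joined with the linker in both orders; the
lower-energy order is kept. Acceptance requires the joined fold at or
below −21 kcal/mol **and** at least 60% of dominant bases paired to
partner bases in the MFE structure (`s2_pair_frac`; the energy rule
is the stated filter in the literature; the pairing check makes "the two tags
form the duplex" explicit). Only the most duplex-like pairings of each
dominant are folded (`s2_fold_per_dominant`, 25, ranked by paired
columns then mismatches); the final report keeps one partner per
dominant (lowest energy among accepted), so this cap does not change
the reported calls in practice while bounding the fold work. Candidates
whose dominant is a substring (≤1 mismatch) of a transcript contig are
removed as mRNA degradation products.

A property worth stating plainly: the four duplex criteria alone are
weakly selective — with G:U wobble and bulges, a substantial fraction of
*random* 18–24-nt tag pairs admits an alignment with ≤4 mismatches, and
many of those fold below −21 kcal/mol once joined by the GC-rich linker
(an external thermodynamic folding engine scores such decoys in the
same range, so this is not a quirk of our energy tables). The method's
real specificity comes from the read-count floor, the transcriptome
subtraction and the restriction to the unmapped fraction; in the
synthetic studies every surviving accepted dominant traces back to a
planted genome-free locus, and the tests assert exactly that.

## Expression profiling

Raw counts per conserved miRNA are normalised as TPM with the
per-library **conserved-miRNA total** as denominator — the base under
which the published per-miRNA normalised values are recovered — and
this is configurable to any totals (e.g. clean-read totals). Zero
values are replaced by 0.01 only when forming ratios; records below 1
TPM in both libraries are excluded from comparison; display values are
rounded half-up. The log2 ratio (B over A) is binned into fold classes
(≤2-fold inclusive, 2–4-fold, >4-fold); the maximum-difference table
collects records changed ≥10-fold in either direction. Star reads are
tags aligning (≤1 mismatch) to the arm opposite the annotated mature of
a reference hairpin, covering the fold-predicted star region by at
least half the tag. Hierarchical clustering uses average linkage on
euclidean distance over log2(TPM+1) (linkage and metric are rarely reported
for such profiles; both are configurable), serialised as Newick.

## The synthetic study generator

`build_mock_references()` and `simulate_library()` generate the ground
truth the tests and the acceptance script measure against. Defaults:
20 conserved genomic miRNA loci, 6 novel genomic loci, 5 genome-free
loci, 3 loci per contaminating ncRNA class, 4 repeat copies, 5
transcript contigs (the first also inserted into the genome so that
degradation fragments exercise the mapped mRNA cross-check), a 100-kb
genome, 10⁶ reads per library, log-normal locus abundances (sdlog 1.2),
a 5% star fraction, geometric isomiR end offsets (p = 0.6), 0.1%
per-base substitution error, and 5 conserved loci planted at a 16-fold
between-library difference.

Precursors are built stem-first: a 20–24-nt mature arm (modal length
22), a star arm that is its reverse complement with 1–3 substitutions
and at most one ≤2-nt bulge, a 6–20-nt loop and 5-nt pads. Construction
guarantees the structural criteria are satisfiable, which rejection
sampling of random sequence would not. Two further guarantees matter in
genomic context: mature arms avoid homopolymer runs ≥5 nt (register
slippage under folding would make the planted ground truth ambiguous),
and each novel locus is validated *in its genomic window context* — the
flanking genome is redrawn until the ±70/15-nt excision windows fold to
a criteria-passing hairpin, since flanking sequence can reroute or
extend a stem. Loci are spaced ≥160 nt apart so excision windows and
flank redraws never touch a neighbouring locus.

The planted fold differences are applied symmetrically (×√16 in one
library, ÷√16 in the other) to below-median-abundance loci: large
between-species changes in such studies occur in low-to-mid abundance
miRNAs, and planting a 16× factor on a dominant locus would distort the
whole library composition rather than emulate a per-locus change. Four
of five planted changes are up in library B, one up in A, mirroring the
direction asymmetry such comparisons report. Degradation of ncRNA,
repeat and transcript material is modelled as recurrent fragment
species (log-normal abundances over fixed cut sites) rather than
uniform shredding — real degradation is hotspot-like — which also keeps
the unique-tag count realistic.

What the generator does **not** emulate: indel sequencing errors,
adapter-dimer artifacts, realistic quality-score models, per-organ
structure (the emulated studies pool organs before sequencing), RNA
editing, and cross-mapping between paralogous loci. Passing recovery
tests therefore demonstrate correctness of the decision logic under the
stated statistical structure, not performance on any real library.

## Problem sizes and determinism

Every simulation is a deterministic function of one integer seed.
Recovery tests and the acceptance script run the full pipeline at the
default scale (10⁶ reads per library, 100-kb genome, seeds 1–10 in the
test suite); oracle-equivalence tests use 20-kb genomes, tag sets of a
few dozen and ≤30-nt folds, sizes at which the independent oracles are
exact and fast. Unit tests use a scaled-down configuration (40-kb
genome, 10 conserved loci, 2–6 × 10⁴ reads) that keeps the same
statistical structure.

## Known limitations

* The energy model omits dangling ends, terminal mismatches and
  sequence-dependent loop bonuses; absolute energies carry a 1–2
  kcal/mol bias relative to full Turner 2004 tables.
* Multi-mapping tags contribute each best hit to mapping output but only
  their first best hit (deterministic chromosomal order) to clustering;
  no genome-specific placement heuristic is attempted.
* The genome-free route reports isomiR variants of one locus as separate
  dominants (deduplication is per dominant tag, not per locus); the
  ground-truth join in the tests aggregates them.
* Strict zero false-positive behaviour of the duplex route is a property
  of the whole pipeline (mapping triage + transcriptome subtraction),
  not of the duplex criteria in isolation — see the genome-free section.
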