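---
title: "Models and methods behind clonekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonekin)
```

`clonekin` quantifies how individual CD8+ CAR-T cell clones behave after
adoptive transfer, using three orthogonal clone marks: the TCRβ CDR3
sequence (bulk repertoire sequencing), the lentiviral vector integration
site (a heritable genomic mark), and paired V(D)J clonotypes in
single-cell RNA-seq data. This vignette explains the statistical models,
the tunable parameters and their defaults, the synthetic-data generators
that stand in for patient data, and the numerical and design choices
made where the methodology left room.

## Repertoire diversity and overlap

A repertoire sample is a map from clonotype to a non-negative template
count; the relative frequency of clonotype $i$ is $p_i = n_i/N$.

**Shannon entropy** is $H = -\sum_{p_i>0} p_i \log p_i$. The logarithm
base is natural by default (`base` argument; use 2 for bits): entropy in
nats is the common convention for repertoire work and the choice only
rescales comparisons. Entropy estimates are depth-biased, so
cross-sample comparisons use `median_downsampled_entropy()`: each sample
is subsampled *without replacement* (templates are physical molecules,
so a hypergeometric rather than multinomial subsample is the honest
model) to the minimum per-patient total, 1000 times by default, and the
median entropy across replicates is reported. The replicate stream is
seeded per sample so results are reproducible.

**Morisita–Horn overlap.** Repertoire similarity uses the Morisita–Horn
estimator on relative abundances,
$C = 2\sum_i p_i q_i \big/ (\sum_i p_i^2 + \sum_i q_i^2)$. Among the
Morisita family this is the variant bounded in $[0,1]$ with 0 for
disjoint and 1 for identical composition — the scale on which CAR-T
repertoire overlap is conventionally reported — and it is invariant to
multiplying either sample's counts by a constant. The classic
count-based Morisita index differs only in small-sample correction
terms; the choice is documented here because the two can disagree at
very shallow depth.

**Ranking.** Clonotypes are ranked by descending count with competition
ranking (ties share the minimum rank of the tied block); ranks beyond a
cap (default 100) are reported as cap+1, and clonotypes absent from a
sample are reported at cap+1 with frequency 0, so rank trajectories can
be plotted on a bounded axis. Ties at a top-$n$ boundary are broken
lexicographically by clonotype identifier so the selection is
deterministic.

## Absolute clone counts and kinetic patterns

Relative frequencies describe clones only relative to each other. To
decide whether a clone is actually accumulating or disappearing from the
blood, frequencies are converted to absolute concentrations:

* estimated blood volume: $V = w \times 65$ ml (women) or
  $w \times 75$ ml (men), with $w$ the body weight in kg;
* modeled day-0 concentration of a clone: the infused CD8+ CAR-T cell
  dose times the clone's IP frequency, divided by $V$ in µl
  ($\times 1000$);
* at a later day, the clone's frequency times the measured absolute
  CD8+ CAR-T count (cells/µl) on that day.

Summed over all clones these conversions conserve the total count
exactly when frequencies sum to 1.

`classify_kinetics()` reduces each clone's (day-0, early, late) triple
to one of three patterns with a fold threshold $f$ (default 2, exposed
as an argument): *increasing* when early $> f\cdot$day0 and late
$\geq$ early; *transient* when early $> f\cdot$day0 and late
$<$ early$/f$; *decreasing* when early $\leq$ day0$/f$; otherwise
*indeterminate*. The visual separation of published clone-track plots
does not come with a numeric rule, so this explicit rule was adopted;
it is scale-invariant, which also defines the clean recovery
experiment: with a constant absolute CAR-T count across the three days
the conversion is a uniform scaling, and the classifier is tested
purely against each clone's planted frequency dynamics. That is the
design used in the recovery checks; under strongly peaked bulk
kinetics, frequency-decreasing clones can legitimately classify as
transient in absolute terms, which is a feature of the absolute view,
not a classifier error. Tracked clones default to the union of the
top 30 of the IP, early, and late samples, covering clones that are
prominent at any of the three draws.

## Integration-site clone calling

The ISA arm reconstructs clones from stitched LTR-junction reads of the
form LTR suffix + genomic fragment + linker. Stages, with thresholds as
arguments throughout:

1. **LTR filter** (`min_ltr_identity = 0.90`): the LTR is aligned
   semi-globally (LTR in full, read locally); identity is matches /
   aligned columns, gaps counting as mismatches — the single identity
   definition used everywhere in the package. Reads below 0.90 are
   discarded; the matched span is trimmed.
2. **Linker trimming**: the linker is a known ligated adapter, so when
   it aligns within an insert at ≥0.80 identity the insert is cut at
   the alignment start. Trimming before the vector comparison matters:
   a short vector fragment plus a 30 bp linker would otherwise dilute
   below the vector threshold and contaminant reads would leak through.
3. **Vector filter** (`max_vector_identity = 0.80`): the insert is
   aligned in full against the best-matching vector region; identity
   ≥0.80 means vector carry-over, not a genomic junction. A
   score-optimal *local* alignment is deliberately not used for this
   statistic: optimal local alignments of unrelated sequences are short
   and near-perfect, which would reject every read; aligning the
   constrained side in full makes the threshold a whole-insert match
   fraction.
4. **Alignment** (`genome_index()`, `align_inserts()`): a k-mer
   seed-and-extend local aligner (seed length 11, genome tiling step 5,
   both strands; match +1, mismatch −1, gap open 2, extend 1) replaces
   an external genome aligner at desk scale. Over-represented k-mers
   are masked by a simple frequency cap (default 24 genome positions),
   the toy-genome analogue of repeat masking. Per read, the top-scoring
   alignment and all alignments within 95% of its score are kept. The
   reported locus is the genomic position of the *first insert base*
   (the LTR junction), extrapolated across soft-trimmed leading bases
   so that reads whose first bases carry substitutions still group at
   the same locus; minus-strand loci follow the same convention on the
   reverse complement. Reads whose best alignment is shorter than 30
   aligned columns or starts more than 10 bases into the insert are
   discarded.
5. **Grouping and consensus**: reads sharing an identical alignment set
   are grouped (multi-mapping reads are grouped, not discarded),
   processed in descending read-count order with lexicographic
   tie-breaks so output is invariant to input read order. Each group's
   consensus is built by center-star multiple alignment around the most
   frequent member sequence with per-column majority vote, ties
   resolved to the center base — a deterministic, desk-scale stand-in
   for a full progressive multiple alignment that is exact for the
   substitution-dominated error profile the generator produces. Reads
   the aligner could not place are rescued into the best-matching group
   at ≥0.90 global consensus identity.
6. **Merging** (`merge_clones()`): within a sample, groups with ≥0.90
   consensus identity merge; across samples of one subject, groups
   merge on exact alignment-set match, exact consensus match, or — for
   non-uniquely aligned groups, multi-align-ratio ≥0.9 — ≥0.90
   consensus identity. The multi-align-ratio is second-best/best
   alignment score (0 for unique mappers), taken from the group's
   center read. The published procedure merges sequentially
   (highest-count against lowest-count); `clonekin` applies the same
   rules as a transitive closure via union–find, which is
   order-independent and therefore reproducible by construction; with
   well-separated sites the two differ only in pathological chains of
   borderline similarities. Consensus similarity uses *global*
   alignment identity: clones at the same locus already merge via the
   locus rules, so the sequence-similarity rule only needs to capture
   near-identical sequences of comparable length, and a global
   definition avoids the trivial-local-alignment problem above.
7. **Frequencies and summaries**: clone frequency is the clone's reads
   over all clone-assigned reads in the sample (summing to 1 by
   construction); clones at ≥1% get individual ribbon flags. Site
   annotation is exon / intron / intergenic by point overlap against a
   gene model (BED12 blocks or GFF3 gene/exon features), strand
   ignored. Expanded/contracted site lists use a ≥5-fold frequency
   ratio between IP and a post-infusion sample; a clone undetected on
   one side receives a pseudo-frequency of half the reciprocal of that
   sample's read total, which keeps the ratio defined while remaining
   conservative about single-read appearances.

Coordinates are 1-based in all outputs (`chr1_8020175_+` style);
internal interval work uses the standard Bioconductor containers.

## Single-cell clonotype fate

Cells are filtered on three QC gates — at least 200 detected genes,
mitochondrial fraction at most 20%, at most 40,000 UMIs — applied as a
single idempotent conjunction. For each clonotype observed in the IP,
a 2×2 table (clonotype cells vs all other cells, IP vs early) is tested
with a two-sided Fisher exact test; two-sided is the conservative
default when no direction is pre-specified, with direction assigned
post hoc from the proportion difference. Benjamini–Hochberg correction
is applied across the tested clonotypes within a patient (patients are
analyzed separately), and labels IRF/DRF are assigned at FDR 5%. Cell
counts, not UMI-weighted counts, enter the tables: a cell is the
sampling unit of the assay. "Detected" at a later timepoint means at
least one post-QC cell carries the clonotype; persistence percentages
are rounded to whole percent, and empty label classes report `NA`
rather than 0. Cluster attribution reports, among IP cells of each
label's clonotypes, the fraction per transcriptional cluster (summing
to 1 per label); cluster labels are consumed as precomputed input —
normalization, clustering and embedding are upstream concerns.

## The synthetic-data generators

The generators define the study conditions under which the package's
guarantees are tested; they are first-class, tested code.

**Repertoire timeline.** Baseline clone frequencies follow a power law
in rank, $p_r \propto r^{-\alpha}$ with $\alpha = 1$ by default,
reproducing the heavy-tailed shape of real TCRB repertoires without
fitting any dataset. Planted clones multiply their true frequency by
`fold_per_step` each step (*increasing*), divide by it (*decreasing*),
or rise through the second timepoint and decay symmetrically
(*transient*); frequencies are renormalized and counts drawn
multinomially at the per-timepoint depth, so totals are conserved
exactly and observed counts carry sampling noise. The demo design
(`sim_demo_repertoire()`) uses 1000 clonotypes, depths
25,000/18,000/12,000/8,000 (deepest in the IP, shallower blood draws),
and twenty 4-fold planted clones (ten increasing, five transient, five
decreasing) seeded at mid-rank abundances — enough planted mass that
diversity visibly declines after infusion, the regime the diversity
analyses target.

**ISA reads.** A uniform random toy genome (default 100 kb; real
genomes' repeat structure is deliberately absent, see Limitations) is
planted with integration sites on both strands; per-site read counts
are `min + Poisson(mean − min)` (defaults 5 and 10), fragment lengths
uniform on 40–150 bp, and each read is LTR + fragment + linker with
i.i.d. substitutions (default 1%; indels optional and off by default —
substitutions dominate stitched Illumina consensus reads, and the
default keeps the identity thresholds the stressed quantity). A
configurable fraction of contaminant reads carries internal vector
sequence instead of a genomic fragment.

**Cell table.** Cells are drawn per timepoint from the timeline's true
clonotype frequencies (2000 cells/timepoint by default). IP cells of
planted *increasing* clonotypes land in designated clusters (defaults 2
and 4, mirroring cytotoxicity- and proliferation-high clusters) with
probability `irf_cluster_bias` (default 0.85); other cells follow the
baseline cluster mixture. QC scalars are drawn in-range (genes ≈ 2500,
mitochondrial fraction ≈ 5%, UMIs ≈ 8000), and a `qc_outlier_rate`
fraction of cells violates exactly one QC gate.

All three generators split one integer seed into independent
per-generator streams and are byte-identical under a fixed seed.

## Problem sizes used in the checks

The automated checks run the full pipelines at desk scale: repertoire
depths of $10^4$–$10^5$ templates over 500–1000 clonotypes; the ISA
recovery at a 100 kb genome with 50 sites, ≥5 reads/site and 1%
substitutions; fate calibration and sensitivity at 2000 cells/timepoint
over 500 clonotypes with twenty 8-fold planted expansions; the
diversity-decline check over 40 (tests) or 20 (acceptance script)
simulation seeds with 25 downsampling replicates. These sizes keep each
suite comfortably fast while leaving every statistical property
non-trivially exercised (hundreds of clonotypes tested per Fisher/BH
run, hundreds of reads per ISA run).

## What passing tests do and do not show

The generators produce exactly the structure the analyses assume:
power-law abundances, multinomial sampling, substitution-only errors on
a repeat-free genome, binomially assigned cluster labels. Passing
recovery checks therefore demonstrates correctness of the algorithms
under their stated models, not robustness to everything real data adds:
PCR amplification bias and template resampling, V(D)J sharing between
biological clones, genome repeats and mappability artifacts,
cross-sample index hopping, doublets and ambient RNA in single-cell
data. The QC and identity thresholds are honored at their boundaries,
but their field values are conventions inherited from the assays, not
quantities the simulations can validate.

## Known limitations

* The k-mer aligner is exact-seed based: inserts whose every seed-length
  window is mutated (improbable at 1% substitutions but possible) join
  the unaligned pool and must be rescued by consensus identity.
* Consensus building is center-star, not a full progressive MSA;
  indel-rich data would erode its accuracy (indels are off by default
  in the generator and rare in stitched reads).
* Transitive-closure merging can, in principle, chain borderline-similar
  groups that sequential merging would keep apart.
* The Fisher/BH fate test treats cells as independent draws; within-cell
  UMI structure and doublets are outside the model.
* Patient metadata enters only through the blood-volume and dose
  arithmetic; no pharmacokinetic model is fitted to expansion curves.
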