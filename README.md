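# clonekin

Tools for tracking the clonal behavior of CD8+ chimeric antigen receptor
(CAR) T cells after adoptive transfer. After a CAR-T infusion product (IP)
is administered, individual T-cell clones — identifiable by their TCRβ
CDR3 sequence, by their lentiviral vector integration site, or by paired
V(D)J sequences in single-cell data — expand, contract, or disappear from
the blood. `clonekin` implements the four analysis arms needed to
quantify that behavior, plus a synthetic-data module that generates all
three input types with planted ground truth so every stage is testable
without patient data.

## What it computes

**Repertoire diversity and overlap** on clonotype count tables
(`clonotype_id`, `count`), where a clonotype's relative frequency is
`p_i = n_i / N`:

- Shannon entropy `H = -Σ p_i ln p_i`, compared across samples of
  different depths via `median_downsampled_entropy()`: subsample without
  replacement to a common depth (the minimum per-patient total), 1000
  times, and take the median entropy.
- Morisita–Horn overlap `C = 2 Σ p_i q_i / (Σ p_i² + Σ q_i²)`, 0 for
  disjoint repertoires and 1 for identical composition.
- Top-clonotype fractions (`top_n_fraction()`) and competition-rank
  trajectories with a rank cap (`rank_clonotypes()`,
  `track_clonotype_ranks()`; absent clonotypes report rank cap+1).

**Absolute clone kinetics** (`clone_kinetics()`): blood volume is
`weight × 65 ml/kg` (women) or `× 75 ml/kg` (men); the modeled day-0
concentration of a clone is `dose × p_i / (blood volume in µl)`; later
concentrations are `p_i ×` the measured absolute CD8+ CAR-T count.
`classify_kinetics()` labels each clone `increasing`, `transient`, or
`decreasing` from its (day 0, early, late) counts with a 2-fold
threshold rule.

**Integration-site clone calling** (`call_integration_sites()`): reads
with <90% identity to the LTR are discarded and the LTR trimmed; the
known linker is trimmed; inserts with ≥80% identity to internal vector
sequence are discarded; the rest are aligned to the genome with a
k-mer-seeded local aligner (seed 11, step 5), keeping the best alignment
and all within 95% of its score; reads with best alignment length <30 or
alignment start >10 are dropped; reads sharing an alignment set are
grouped, given a center-star majority-vote consensus, unaligned reads
are rescued at ≥90% consensus identity, and groups are merged by locus,
consensus identity, and multi-align-ratio rules. Outputs are per-sample
clone frequencies (with ≥1% ribbon flags), exon/intron/intergenic
annotation against a gene model, and ≥5-fold expanded/contracted site
lists.

**Single-cell clonotype fate** (`clonotype_fate_test()`): cells failing
QC (genes <200, mitochondrial fraction >20%, or >40,000 UMIs) are
removed; each IP clonotype's cell counts at IP vs the early timepoint
form a 2×2 table tested with a two-sided Fisher exact test and
Benjamini–Hochberg correction; significant clonotypes at FDR 5% are IRF
(increased relative frequency) or DRF (decreased). Persistence at later
timepoints, IP-cluster attribution of IRF/DRF cells, and
detected-vs-not cluster composition summaries follow.

## Worked example

```r
library(clonekin)

# four-timepoint repertoire with planted oligoclonal expansion
sim <- sim_demo_repertoire(seed = 42)
repertoire_metrics(sim$samples, n_reps = 200, seed = 42)
#>   patient_id timepoint total richness entropy median_downsampled_entropy top10_fraction
#> 1         P1        IP 25000      993   5.177                      5.130         0.3892
#> 2         P1     early 18000      966   5.131                      5.090         0.3456
#> 3         P1      late 12000      844   4.616                      4.593         0.4552
#> 4         P1 very_late  8000      541   3.603                      3.603         0.7201
```

Diversity is highest in the infusion product and falls as the planted
clones take over (entropy 5.13 → 3.60 nats), while the top-10 clonotype
share rises from 39% to 72%. Repertoire overlap with the IP decays the
same way (`morisita_matrix()`: IP–early 0.97, IP–late 0.72, IP–very-late
0.28).

```r
# clonotype fate: 20 clones planted to expand 8-fold by the early draw
planted <- data.frame(clone_index = 11:30, pattern = "increasing",
                      fold_per_step = 8)
sim2 <- sim_repertoire_timeline(500, depth = 1e5, n_timepoints = 4,
                                planted = planted, seed = 5)
cells <- qc_filter(sim_cell_table(sim2, n_cells_per_timepoint = 2000,
                                  qc_outlier_rate = 0.03, seed = 5))
fate <- clonotype_fate_test(cells)
fate
#> Clonotype fate test (IP vs early): 363 clonotypes tested, 20 IRF, 8 DRF (FDR 0.05)

ca <- cluster_attribution(fate, cells[cells$timepoint == "IP", ])
sum(ca$fraction[ca$label == "IRF" & ca$cluster %in% c(2, 4)])
#> [1] 0.846
```

All 20 planted expanders are recovered as IRF, and 84.6% of their IP
cells sit in the two designated clusters (the generator's bias is 0.85).
`tidy(fate)` returns the per-clonotype table (counts, Fisher p, BH q,
label); `autoplot(fate)` draws the volcano view.

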