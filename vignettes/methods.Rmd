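---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`neuriteMPRA` implements, as one coherent and fully simulated pipeline,
the computational workflow used to dissect how the RNA-binding protein
TDP-43 controls mRNA accumulation in neurites: subcellular fractionation
statistics, tiling reporter-pool (MPRA) design and quantification, in
vitro binding enrichment (RNA Bind-n-Seq style R values), metabolic
labeling (SLAM-seq style T>C conversion) stability estimates, RNA
secondary-structure context profiling, and the integrative comparisons
that connect them. Every raw input -- UTR sequences, paired-end reads,
count matrices, CLIP-style intervals -- comes from the package's own
seeded generator, so every claim the pipeline makes can be checked
against planted ground truth.

This vignette records the quantitative models, the tunable parameters
with their defaults and units, the numerical choices, and the places
where a design decision was genuinely open.

# The localization model

For a feature (gene or reporter oligo) with relative abundance $n$ in
the neurite fraction and $s$ in the cell-body (soma) fraction, the
localization ratio is

$$\mathrm{LR} = \log_2 \frac{n}{s},$$

computed per replicate after total-count normalisation with a
pseudocount of 0.5 (finite LR for zero counts without dominating
moderate ones). The genotype effect is
$\Delta\mathrm{LR} = \overline{\mathrm{LR}}_{KO} -
\overline{\mathrm{LR}}_{WT}$, tested per feature with a two-sided Welch
t-test across replicates and Benjamini-Hochberg FDR across features.

Relative abundances are compositional: if a sizeable set of features
genuinely gains neurite abundance in the knockout, every other feature's
relative abundance must fall, and all LRs shift together. Before
testing, `delta_lr_test()` therefore centres each replicate's LR vector
on its median across features. This is the same
"most-features-unchanged" assumption that size-factor normalisation
makes in standard count-based differential tools, stated explicitly. It
fails by design when the affected fraction is large; the package's
parameter-recovery experiments use a sparse design (10 affected genes
out of 100) for exactly that reason, while the default study set (30
target / 60 background UTRs) trades a small residual compression for
well-populated downstream contrast groups.

A practical note on power: with three replicates per genotype and
negative-binomial dispersion 0.1, the Welch test has roughly four
degrees of freedom and per-feature raw p-values of order $10^{-3}$ to
$10^{-2}$ for a planted $\Delta\mathrm{LR}=4$; after BH adjustment
individual features sit near, not always under, FDR 0.05 when true
positives are rare. The estimate itself recovers well (bias about
$-0.15\ \log_2$ units). A variance-moderated test would sharpen this,
but the package deliberately keeps the self-contained Welch formulation.

# Pool design

The designer follows the standard tiling scheme of such reporter pools: transcripts
with ill-defined 3' ends (`cds_end_NF`/`mRNA_end_NF` tags) are dropped,
UTRs longer than 10 kb are excluded (the bound is inclusive at exactly
10,000 nt), and the polyA site must be flagged conserved. Filter-passing
isoform UTRs of a gene are merged into a meta-UTR by interval union;
disjoint segments are concatenated in coordinate order before tiling, so
tiles may span junctions -- the simplest reading of "merged", chosen
deliberately. Tiles are 260 nt with a 6-nt step, starting 260 nt into
the upstream flank and ending 260 nt into the downstream flank so the
UTR ends are covered by full-length tiles. Coordinates are 0-based
half-open throughout, with flank tiles at negative offsets.

Canonical motifs (GTGTG, TGTGT, GTATG in the synthesis alphabet) are
scanned allowing overlaps. A motif-containing tile gets one companion
oligo in which every motif-covered position is base-complemented
(G$\leftrightarrow$C, A$\leftrightarrow$T), reproducing the canonical
per-motif substitutions (GUGUG$\to$CACAC, UGUGU$\to$ACACA,
GUAUG$\to$CAUAC) and extending them uniquely and consistently over
overlapping occurrences. The 20-nt PCR handles are configurable
constants; the defaults are arbitrary motif-free 20-mers, since only
their constancy matters.

# Read processing

Amplicon reads are processed against the pool as a closed dictionary:
5' adapters (the fixed 45-nt forward and 35-nt reverse amplicon
prefixes) are trimmed within a per-mate Hamming budget (default 2,
N counts as a mismatch); the UMI is the first 8 nt of the trimmed
reverse read, kept verbatim (no error correction -- the count is
literally the number of distinct UMI strings); the forward remainder is
matched to the 5' end of a variable region and the reverse remainder to
the reverse-complemented 3' end. Matching is seeded (two 20-nt seeds per
mate, hash lookup, Hamming verification, no indels); the unique best
candidate wins and ties are unassigned. The tie rule matters for
wild-type/mutant companion pairs: with 2x150 reads the mates cover
105 + 107 nt of the 260-mer, so a pair whose only distinguishing motif
lies in the central 48-nt blind zone is genuinely ambiguous and is
dropped for both pool members. Simulated reads are 2x150 by default for
this reason.

For metabolic-labeling samples the matcher runs in conversion-aware mode
(`tc_aware`): a T read as C on the forward mate (A read as G on the
reverse mate) is not a mismatch, and seeds are hashed in a
conversion-collapsed alphabet. Without this, heavily labeled molecules
would be rejected preferentially and stability ratios would be biased
toward stability -- the same reason dedicated SLAM aligners exist. The
labeling stage also raises the per-mate mismatch budget to 10.

# Binding enrichment

$R$ for an oligo is its relative frequency in a protein-bound sample
divided by its relative frequency in the matched input sample. Oligos
with fewer than 10 input reads (configurable) are NA: the ratio variance
explodes at small denominators. The assay runs in duplicate at 500, 50
and 5 nM; how the six bound samples combine into one number per oligo is
not prescribed anywhere, so the package reports per-sample R plus an
unweighted mean, and checks concordance by pairwise Spearman correlation
of log R (NA-pairwise) with average-linkage clustering on
$1 - \rho$.

# Stability from conversion counting

Per oligo and sample, the conversion rate is pooled:
$\hat c = n_{T\to C} / n_T$ over all covered reference-T positions
(base quality $\ge$ Q20 where qualities exist; non-T mismatches are kept
as diagnostics only). The stability ratio is
$\hat c(t{=}12\,\mathrm{h}) / \hat c(t{=}0)$ per genotype -- 1 for an
infinitely stable RNA, $2^{-12/t_{1/2}}$ under exponential decay of the
pulse-labeled pool -- and the genotype effect is
$\log_2(\mathrm{ratio}_{KO}/\mathrm{ratio}_{WT})$. Coverage below 200
reference-T observations at either timepoint gives NA. Optional
background subtraction (a no-label control rate) is off by default.
Per-read mixture modelling of new/old RNA fractions is deliberately out
of scope; at reporter-pool depths the pooled estimator is tight.

# Structure profiling

Each 260-mer is folded in 80-nt windows sliding by 10 nt (19 windows; a
trailing window is added when geometry would otherwise leave positions
uncovered). Within a window, a position's pairing probability is the row
sum $\sum_j P_{ij}$ of the Boltzmann pair-probability matrix; positions
covered by several windows take the arithmetic mean -- the combination
rule across windows is not prescribed anywhere, and the mean is simple
and count-independent. A motif's score is the mean (not sum) over its
five positions, keeping scores comparable between oligos with different
motif counts.

The default energy model is intentionally minimal so an exact oracle
exists: nested structures only, pair energies (kT) GC $-3$, AU $-2$, GU
$-1$, minimum hairpin loop 3, no stacking or dangle terms, plus a
helix-initiation penalty of $+8$ kT paid once per maximal helix. The
initiation term is essential, not cosmetic: without any cooperativity an
isolated A-U pair costs $-2$ kT against dozens of candidate partners, so
every U in an accessible context ends up "paired" with probability near
one and accessible and stem-buried motifs become inseparable. The $+8$
value is on the scale of nearest-neighbour duplex initiation
($\approx 4.1$ kcal/mol $\approx 6.6$ kT at 37°C), rounded up for a
desk model without stacking rewards. The partition function and exact
outside recursion (including the stacked-pair correction for directly
nested pairs, which pay no initiation) are verified against exhaustive
enumeration of all structures for sequences up to 12 nt at $10^{-9}$.
An `RNAfold -p` backend is available as a drop-in and is tested for
ordering agreement, not numerical equality.

Classification of motifs into paired vs single-stranded uses
1-dimensional 2-means on the scores -- threshold-free, so it transfers
across backends with different absolute probability scales. The
top/bottom 20% split used in the localization analysis is a stable rank
on (score, id) with sets of size $\lceil qN \rceil$.

# The synthetic-data generator

The generator is the package's definition of the study conditions.

* **UTR set**: 30 target and 60 background UTRs of 300 nt (desk-scale
  stand-ins for mammalian 3' UTRs), single isoform each plus two decoy
  isoforms exercising the design filters. Each target carries three
  planted motifs (one of each canonical 5-mer) in well-separated slots
  so no 80-nt window sees two constructs. Each planted motif is
  "occupied" with probability 0.5.
* **Structural contexts**: occupied motifs stay accessible -- their
  $\pm$85-nt neighbourhood is scrubbed of any 2-5-bp antiparallel stack
  against the motif with summed pair energy $\ge 5$ kT, each offender
  getting one base replaced by a random non-pairing letter. Unoccupied
  motifs sit in the 5' arm of a designed 12-bp hairpin (GC-rich arm
  extensions, 4-nt loop) whose partner arm is wobble-randomised (each G
  paired by C or U, each U by A or G) rather than an exact complement.
  Both choices exist to keep the sequence composition honest: a fixed
  accessible flank (e.g. poly-A) or a deterministic complement string
  would itself become a top-ranked "enriched" k-mer in the discovery
  analysis, confounding the motif signal. The scrubbing leaves a mild
  pyrimidine shift near accessible motifs, visible as weakly enriched
  C/T-rich 5-mers well below the canonical three.
* **Effects**: target genes get a gene-level planted
  $\Delta\mathrm{LR}$ of 4 (the fractionation experiments report
  10-30-fold neurite increases, i.e. 3.3-4.9 log2 units). At the oligo
  level, each intact occupied motif contributes 1.5 log2 units of
  localization effect, one 2-fold step of binding affinity, and switches
  the oligo to the destabilised half-life class (6 h wild-type vs 12 h
  knockout, others 24 h in both); stem-buried planted motifs contribute
  a small 0.2-unit localization effect and half an affinity step.
  Mutant companions inherit nothing, since their motifs are
  complemented.
* **Reads**: fractionation counts are negative binomial (dispersion
  0.1, library size $10^6 \times$ log-normal jitter) with soma means
  genotype-invariant and knockout neurite means scaled by
  $2^{\Delta\mathrm{LR}}$. MPRA samples draw 120,000 read pairs
  multinomially per library (2 compartments x 2 genotypes x 3
  replicates); binding samples 80,000 (duplicate, one input plus three
  concentrations per replicate); labeling samples exactly 100 pairs per
  oligo per genotype/timepoint, conversions binomial per T at 5%
  (labeled) and 0.1% (background), labeled fraction $2^{-t/t_{1/2}}$.
  Per-base substitution errors at 0.2% everywhere.
* **CLIP intervals**: one peak per occupied motif ($\pm$20 nt) and
  Poisson-placed reads at 10 reads/kb background with 13-fold local
  elevation inside peaks, which puts the expected UTR-level density
  contrast for target UTRs (about 22% of their length inside peaks)
  near the 3.5-fold figure reported for real CLIP data.

What the generator does **not** emulate: realistic quality-score
profiles, PCR duplicate families, indels, splice structure, isoform
diversity beyond the decoys, or transcriptome-scale gene numbers.
Passing tests therefore demonstrate the correctness and calibration of
the statistical machinery under the planted model, not performance on
real libraries.

# Problem sizes

Default end-to-end scale, chosen to keep a laptop run in minutes: 90
simulated UTRs; a 15-gene pool (9 target, 6 background) of roughly
2,400 oligos including companions; about 1.4M MPRA, 0.6M binding and
1M labeling read pairs; and roughly 8,000 unique folded windows
(memoised across overlapping tiles). Parameter-recovery experiments are
smaller and seeded: 10 seeds for affinity rank order and stability
signs, 5 for localization recovery, 100 random sequences for the
folding oracle.

# Known limitations

* Welch testing at three replicates is conservative after FDR
  adjustment (see above); discovery-phase recall at default scale is
  roughly 60-90% of planted targets, which the downstream k-mer and
  CLIP analyses tolerate.
* The tie rule discards both members of a companion pair whose motif
  falls in the central blind zone of the 2x150 design (~18% of
  motif positions); those oligos are NA downstream.
* The folding model ranks accessibility correctly but its absolute
  probabilities are not thermodynamic predictions; cross-backend
  comparisons should use orderings, as the tests do.
* R values at low input counts are NA rather than shrunk; a
  concentration-aware binding-curve fit is out of scope.
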