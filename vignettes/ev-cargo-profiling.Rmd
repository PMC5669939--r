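---
title: "Profiling the small-RNA cargo of extracellular vesicles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the small-RNA cargo of extracellular vesicles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EVcargo)
```

# The problem

Cultured cell lines release small extracellular vesicles (EVs, roughly
30-240 nm) whose RNA cargo -- miRNAs, their sequence variants (isomiRs),
snoRNAs and longer transcripts -- is selectively loaded and differs between
cell lines. EVcargo implements the computational half of such a profiling
study: it takes small-RNA reads (or simulates them), resolves each read
against a canonical mature miRNA reference with explicit end offsets,
substitutions and non-templated tails, and derives the descriptive summaries
such studies report: percent-of-total abundance profiles with an expression
floor, top-N shared/unique cargo lists, sample dendrograms with
replicate-coherence checks, per-miRNA isomiR variant-type histograms,
dual-library snoRNA box-class compositions, and two EV biophysics readouts
(nanoplasmonic aggregation index, weighted mean particle diameter).

# Read assignment model

## Placement and scoring

Reads are assigned directly in miRNA space, not genome-first. Each mature
miRNA is stored with its position on its hairpin (pre-miRNA), because the
hairpin decides whether an end variation is *templated* (copied from the
precursor, as alternative Drosha/Dicer cleavage produces) or
*non-templated* (enzymatic 3' A/U tailing). For a read of length $L$ placed
on a hairpin at the mature start plus a 5' offset $o_5$, the 3' offset is
determined, $o_3 = o_5 + L - L_{mature}$, so candidate placements are
enumerated over (mature, $o_5$) only. The alignment is ungapped: isomiRs are
defined by end addition/trimming and internal substitutions, not indels.

Within a placement:

* mismatches over the canonical body (including a templated 5' extension)
  are **substitutions**, recorded at canonical-relative 0-based positions;
* in the 3'-extension region beyond the mature end, the minimal read suffix
  covering every mismatch (plus any overhang past the hairpin end) is the
  **non-templated tail** -- never counted as substitutions;
* 5' extensions must be templated ($o_5 \ge -$ hairpin flank), because 5'
  ends change by alternative cleavage, not tailing.

Placements violating the bounds (defaults: $|o_5| \le 3$, $|o_3| \le 5$ nt,
tail $\le 3$ nt, substitutions $\le 2$, read length $\ge 16$ nt) are
discarded; among the survivors the assignment minimizes the score triple
(substitutions, tail length, $|o_5| + |o_3|$) lexicographically. Ties break
by ascending miRNA id, then ascending $o_5$, so results are deterministic
and independent of reference file order. Each read is counted once (no
fractional multi-mapping); a read with no qualifying placement is
UNASSIGNED, never an error. The bounds themselves are artifact choices: the
upstream colorspace small-RNA pipelines of the studies this emulates do not
publish theirs, so numerical concordance with any particular study's counts
is not a goal.

The inner loop is compiled (Rcpp); the test suite checks it read-for-read
against a pure-R brute-force enumeration of every (mature, offset,
tail-split) placement, and checks that the recorded offsets, substitutions
and tail reconstruct each read byte-for-byte from the hairpin.

## IsomiR identity, classes and names

An isomiR key is the tuple (miRNA, $o_5$, $o_3$, substitutions, tail);
distinct keys are distinct isomiRs. Six classes partition key space:
`CANONICAL`, `FIVE_PRIME_ONLY`, `THREE_PRIME_ONLY` (offset and/or tail --
tailing is end modification, not substitution), `BOTH_ENDS`,
`SUBSTITUTION_ONLY`, `SUBSTITUTION_AND_END`. Names use an invertible
grammar, e.g. `mir-1-5p|5e+1|3e+2|s:10C>T|t:AA`, with the bare id reserved
for the canonical key; `parseIsomirName()` is its exact inverse. Variant
histograms are computed, by default, among isomiR reads only (the five
variant classes sum to 100% per miRNA); since published figure legends
rarely state the denominator, `denominator = "all"` is provided as well.
No seed-region-specific substitution rule is implemented.

# Quantification, thresholding and clustering

Counts are normalized to **percent of total** per sample (columns sum
to 100). Group-level profiles are arithmetic means over biological
replicates. The expression floor retains a feature iff its *group-mean*
percentage reaches the threshold (default 0.05%, inclusive "at least") in
at least one group; per-replicate maxima are available via applying
`thresholdFilter()` to the sample-level matrix instead. Top-N lists rank by
descending percentage with ties broken by feature id; a feature is "shared"
when it reaches the top-N of two or more groups (top-N co-membership -- an
alternative reading, above-threshold presence in several groups, is not
implemented). Percent normalization deliberately replaces count-model
normalizations (TMM and relatives): every downstream statistic here is
defined on percentages, and no differential-expression inference is done.

Clustering uses distance $1 - r$ (Pearson, over features) and average
linkage -- common choices for expression heatmaps, exposed as options since
the emulated analyses name neither. Percentages are $\log_2(x + 0.01)$
transformed; the 0.01% pseudocount sits well below the 0.05% floor so it
only regularizes zeros. Samples are sorted by id before clustering, making
the dendrogram invariant to input order; constant (zero-variance) profiles
are an error naming the offending sample, since their correlation is
undefined. Trees serialize as Newick; a group is *replicate-coherent* when
its replicates form a clade with no foreign leaf.

# snoRNA dual-library profile

snoRNAs (60-300 nt) appear in EVs both as full-length molecules, visible to
whole-transcriptome (WTA) libraries, and as short fragments, visible to
size-selected small-RNA libraries. Fragments are attributed to their parent
snoRNA id -- the analysis counts species, not fragment isoforms -- and the
library type is a given label, not inferred from read lengths (the
full-length/fragment length boundary is not defined in this setting). Per
library type the profile takes the union of per-group top-20 lists,
summarizes it by box class (C/D methylation guides, H/ACA
pseudouridylation guides, Cajal-body scaRNAs), and reports the
intersection/Jaccard between the two library types' unions.

# Biophysics

The aggregation index of a gold-nanoparticle/EV colorimetric assay is
$AI = A_{519}/A_{650}$ from a UV-Vis spectrum (1 nm steps over 400-900 nm
expected; off-grid wavelengths are linearly interpolated, a negligible
approximation at that resolution; $A_{650} = 0$ is an error). The weighted
mean EV diameter is $\sum d_i n_i / \sum n_i$ over AFM size-histogram bins
with $d_i \ge 30$ nm -- the sub-30 nm exclusion drops tip artifacts and
non-vesicular debris, and the threshold is inclusive because the excluded
objects are those *below* 30 nm. Count-weighting and bin-fraction weighting
coincide under this formula. Concentration calibration against a liposome
standard curve is out of scope (no curve data to calibrate against).

# The synthetic-data generator

Because no sequencing accession accompanies the emulated study, the
generator *is* the study conditions, and its defaults are fixed
accordingly:

* **Design**: 4 groups (cell lines) x 2 biological replicates, 50,000
  reads per sample.
* **Reference**: 100 miRNAs (mature 20-23 nt embedded in hairpins with
  5-30 nt flanks), 60 snoRNAs of 60-300 nt with classes drawn
  C/D : H/ACA : scaRNA = 0.5 : 0.4 : 0.1.
* **Abundances**: lognormal with $\sigma = 1$ on the log scale, composed of
  a shared-across-lines component plus a line-specific one (EV profiles
  share a similar background). A shared core of 14 miRNAs is boosted into
  the upper tail in every group and 3 miRNAs per group are boosted only in
  their own group (zero elsewhere). Boosted features have a $+3\sigma$
  log-offset over a background truncated at $+2.5\sigma$, so core/specific
  membership of each group's top list is guaranteed, not probabilistic.
  Under these settings the top-10 miRNAs carry roughly 60-80% of a group's
  cargo and nearly all of the 100 features clear the 0.05% floor -- the
  long tail of barely-detected species in real libraries is not modelled
  at this reference size, so the floor's semantics are exercised by
  dedicated hand-count and monotonicity tests rather than by the
  end-to-end run.
* **IsomiR process**: 5' offsets of $\pm 1$ (templated, clipped to the
  hairpin) with probability 0.06; 3' offsets from
  $\{-2{:}0.035,\ -1{:}0.08,\ 0{:}0.845,\ +1{:}0.028,\ +2{:}0.012\}$
  (templated when extending); substitutions at 0.005/nt over the covered
  canonical body; with probability 0.10 a 3'-extended read carries a
  non-templated A/T tail of 1-2 nt replacing the outermost templated
  bases. The closed-form expected isomiR fraction
  (`expectedIsomirFraction()`) is then ~0.29 with about a third of isomiRs
  carrying a substitution and a clear 3' predominance -- the regime the
  emulated libraries report. Substitutions are never placed on templated
  extensions or tails: a substituted templated-extension terminal base
  would be representationally indistinguishable from a shorter extension
  plus tail, and keeping the truth unambiguous is what lets the suite
  demand *exact* (100%) truth/label agreement downstream.
* **snoRNA populations**: full-length abundance profiles for the WTA-type
  pool (H/ACA-weighted 2.5:1:1) and a fragment pool for the small-RNA-type
  libraries (C/D-weighted 3:0.5:1); 5% of small-RNA reads are snoRNA
  fragments of 18-40 nt. These reads fall outside the assignment bounds of
  any mature and surface as unassigned background, as real non-miRNA reads
  do.
* **Mechanics**: one master seed drives every stage through a single
  generator stream; constant quality `I` (quality is unused downstream);
  reads are never shorter than 16 nt; no adapter, quality-error or
  colorspace simulation, and no ligation bias.

Per-read ground truth (source, offsets, substitutions, tail, class) is
emitted alongside the reads, so every downstream stage is tested as a
recovery problem. What passing those tests shows is that the pipeline
inverts its own generative process exactly and estimates its parameters
within sampling error; it does not certify behaviour on real libraries,
whose variation process (editing, quality-dependent errors, cross-mapping
between paralogous miRNA families) is richer than the simulator's.

# Problem sizes and numerical conventions

The shipped test suite runs the brute-force assignment oracle on over 8,000
enumerated and random reads against a 10-miRNA reference, truth-recovery
and isomiR-fraction checks on 50,000-read samples, coherence and
determinism checks on a 4x2-sample design at 1,500-4,000 reads per sample,
and 1,000-matrix normalization sweeps; the acceptance script re-runs the
full default design (8 samples x 50,000 reads). Exact comparisons are used
wherever the quantity is discrete (class labels, names, retained sets);
stochastic recoveries use 3-binomial-SD bands; column-sum and percentage
identities use 1e-9 tolerances. Counts are integers end to end --
fractional values in a count table are rejected, not rounded. miRBase-style
U-containing references are converted to DNA (T) on read so references and
reads share one alphabet; the miRBase release to use is the caller's
choice, as releases differ between sections of published methods.

# Known limitations

* Assignment is ungapped and single-best; paralogous matures with near-identical
  sequences resolve by the deterministic tie rule, not by fractional
  allocation.
* The 0.05% floor, 1 - Pearson/average-linkage clustering and top-N
  co-membership "shared" definition are one reasonable reading of common
  figure legends; alternatives are exposed as parameters where they exist.
* The generator's isomiR knobs are exploratory, not estimates of any real
  library's process.
* Heatmap rendering is out of scope; the clustering surface is the tree
  and the coherence report.
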