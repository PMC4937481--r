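---
title: "Screening yeast introns for conserved RNA structures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening yeast introns for conserved RNA structures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`intronscreen` is a pipeline for asking whether spliceosomal introns
carry functional RNA secondary structures: hairpins conserved across
related genomes, supported by compensatory substitutions, expressed at
elevated levels after splicing, and preferentially associated with the
RNA-degradation machinery. This vignette explains the models behind
each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices that were genuinely open.

## Ortholog mapping

The comparative substrate of the screen is, for every focal intron, the
set of orthologous intron sequences found in a panel of comparison
genomes. Orthologous genes are located by a translated local search:
BLOSUM62-scored 3-mer seeds (with full score-neighbourhood expansion at
threshold 11), a two-hit rule per diagonal, ungapped X-drop extension
(drop-off 20), and colinear chaining of extended segments across frames
and strands with a maximum coordinate gap of 1000 nt. Chaining across
frames matters: an intron in the target gene shifts the downstream exon
into a different reading frame whenever its length is not a multiple of
three, so a gene-level hit must assemble segments from several frame
translations. Segments scoring below 40 never enter chaining — with
3-mer seeds the extension stage otherwise produces a dense carpet of
short random segments. Gene hits require at least 65% query coverage
and an e-value below 1e-6 under a Karlin-Altschul-style approximation
`E = K * m * n * exp(-lambda * S)` with fixed constants
(lambda = 0.267, K = 0.041 for protein; 0.625 and 0.41 for nucleotide
scores). These constants order hits consistently but are not calibrated
against any external search engine; the acceptance checks therefore
compare hit *locations* against an exhaustive local-alignment oracle
rather than e-values.

Retained gene hits are widened by 1000 nt of 5' and 300 nt of 3' flank
in transcript orientation (swapped on the minus strand, clipped at
contig ends) and searched at the nucleotide level for the focal intron:
exact 3-mer seeds, diagonal bands whose seed count exceeds the
word-size background expectation `m * band_width / 64` by five standard
deviations (word size 3 means the background is dense, so an absolute
threshold would either drown in noise or miss diverged copies), then
affine-gap local alignment (match +2, mismatch -3, gap open 5,
extend 2) of the intron against each candidate region. Hits above
e-value 0.1 are discarded; among survivors the lowest e-value wins,
with ties broken by higher score and then leftmost coordinate — a
deterministic stand-in for the manual inspection a human curator would
apply.

## The conserved-structure screen

Ortholog sets are aligned by reference-anchored merging: each ortholog
is aligned globally to the focal sequence with affine gaps and the
pairwise alignments are merged on focal coordinates, with insertion
columns allocated so that degapping any row reproduces its input
exactly. This is deterministic and dependency-free; its quality
differences from a simultaneous multiple aligner are absorbed by the
window filters. Windows of 120 columns every 40 columns (the
conventional defaults of comparative screens at this scale; alignments
shorter than one window yield a single full-length window) are dropped
when their gap fraction exceeds 0.25 or mean pairwise identity falls
below 30%; when more than 6 rows are present a greedy subset spreading
pairwise identity is kept, the focal row always first.

Three independent evidence channels score each window, mirroring the
decision logic of a three-tool consensus without reimplementing any
published classifier:

* **Thermodynamic z-score.** The focal row is folded by a
  Nussinov-style dynamic program whose score is a linearised energy:
  pair weights 3 (G:C), 2 (A:U), 0.5 (G:U wobble), +1 per helically
  stacked pair, and -9 for opening a new helix. The opening penalty is
  the crucial term: a plain maximum-pairing DP saturates on random
  sequence (any 120-nt window pairs ~40 bases) and has essentially no
  discriminative power; charging helix initiation, as the
  nearest-neighbour model's loop costs do, concentrates score in long
  contiguous stems. The z-score compares the focal pseudo-energy
  E = -score with 100 dinucleotide-preserving shuffles
  (Altschul-Erickson Euler-path shuffle, exact doublet preservation);
  a degenerate null (sd < 1e-9, e.g. homopolymers) returns z = 0 by
  convention. The channel passes at z <= -2 together with a minimum
  focal folding score (default 5), the analog of requiring a stable
  minimum free energy.
* **Structure conservation index.** The consensus fold maximises the
  summed consensus pair score over window columns: a column pair may
  pair when at least 75% of rows are complementary (Watson-Crick or
  wobble; gaps count against support), scoring support plus
  kappa = 0.5 per distinct complementary residue combination beyond the
  most frequent (the covariation bonus), minus a helix-opening penalty
  of 2 in support units, with hairpin loops of at least 3 columns and a
  deterministic traceback (prefer pairing, then leaving the right end
  unpaired, then the leftmost bifurcation). SCI divides the consensus
  DP objective by the mean single-sequence folding score of the rows
  under the same helix penalty; with that symmetry an alignment of
  identical rows has SCI exactly 1, which the tests assert. The channel
  passes at SCI >= 0.5.
* **Covariation.** For each predicted pair and each non-focal row, a
  substitution pattern is *compensatory* when both positions differ
  from the focal row and the row restores a Watson-Crick pair, and
  *consistent* when one position differs and complementarity (including
  wobble) holds. Restricting the compensatory count to restored
  Watson-Crick pairing follows the field's usage — a single
  G:C -> G:U change is the canonical example of a consistent, not
  compensatory, substitution — and avoids crediting chance double
  substitutions that happen to land on a wobble pair. The channel
  passes at >= 1 compensatory substitution.

A window is called when at least `min_scorers` channels pass
(default 3, the strict intersection; 2 admits loci with strong support
in two channels, as a more inclusive screen would). Overlapping called
windows of one intron merge into one candidate (union of focal
coordinates, best score per channel). Each candidate's conservation
extent is the smallest named clade of the species tree containing the
focal species and every species whose row retains at least 75% of the
predicted pairs.

### What the screen can and cannot control

The intersection rule is only as specific as its channels. Neutral
intron-sized sequences contain thermodynamically genuine hairpins at an
appreciable rate — raising the shuffle count tenfold identifies the
same windows, so these are not estimator noise — and at realistic
divergences the SCI and covariation channels pass often enough on such
windows that the intersection cannot always veto them. Published
screens control this with trained classifiers (an SVM over z and SCI, a
phylogenetic SCFG log-odds, a covariance-model composite score), which
this package deliberately does not reimplement; with the transparent
thresholds used here the per-intron false-positive rate sits above what
a trained classifier would achieve, and the acceptance script reports
the measured operating point rather than hiding it. Users wanting a
stricter screen should raise `cov_min` or tighten `z_max` via
`screen_thresholds()` — the candidate set shrinks monotonically under
any tightening, which the tests verify.

## Expression, exosome association, phenotype

Read counting is unstranded any-overlap: a read is assigned to every
feature its reference span overlaps by at least one nucleotide, so a
read straddling an exon-intron boundary counts for both the CDS and the
intron, matching the default of the standard feature-summarisation
tool. RPKM is `count / (length/1000) / (total_mapped/1e6)`; intron
expression is additionally normalised by the host CDS RPKM (undefined
and excluded when the host RPKM is 0); the expression-evidence rule is
`count > 150 | RPKM >= 20`. Group comparisons (ribosomal-protein
introns with vs without predictions, raw and host-normalised) use an
in-package Mann-Whitney U test: exact two-sided p by a rank-sum
counting recursion when both groups are small (min n <= 8, total <= 25)
and tie-free, otherwise the normal approximation with tie and
continuity corrections.

CRAC counts are normalised per experiment by ORF RPKM (the ambiguity
between raw ORF reads and ORF RPKM as the denominator is resolved in
favour of RPKM, with the raw-count alternative one line of code away),
genes with zero ORF signal being unscorable for that experiment rather
than imputed. Percentile ranks use the mean-rank convention
`100 * (r - 0.5) / N` — symmetric (mean exactly 50 without missing
data), tie-robust, and invariant under any monotone per-experiment
transformation, which makes the cross-experiment average meaningful.
The top-decile flag marks genes at or above the 90th percentile of the
average.

Growth curves are analysed on two tracks, as plate-reader studies
usually are: AUC by trapezoid on the full 5-minute grid of
baseline-normalised absorbance (hours on the x-axis), and parametric
fits on a 30-minute resample. Both logistic and Gompertz sigmoids are
fitted by Levenberg-Marquardt least squares, each parameterised
directly in (A, mu, lambda) — asymptote, slope at inflection, lag as
the tangent x-intercept — and the model with the lower residual is
reported. Because the data are baseline-normalised, the model is fitted
minus its own value at the first time point; in the noise-free limit
this recovers the generating parameters to numerical precision
(asserted at 1e-6). Non-convergence of both models falls back to
data-derived parameters with a flag. Competition assays count
generations as the summed log2 expansion over transfers relative to the
2e5 cells/ml bottleneck (densities below the bottleneck clamp to zero
with a warning) and test replicate mutant fractions against the neutral
0.5 by a one-sample two-sided t-test; a zero-variance replicate set
returns p = 1 at the null and a degenerate flag otherwise. qPCR folds
follow the delta-delta-Ct model with a reference gene,
`fold = 2^-ddCt`, summarised as mean and standard error over
replicates.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
tested. One focal chromosome carries 40 genes by default (80% with one
intron; 45% of intron genes named as ribosomal-protein genes), each
with two exons of 150-300 nt (CDS padded to whole codons), introns of
150-350 nt, random strand, and 200-400 nt spacers. A planted hairpin —
stem 8-15 bp, loop 4-8 nt, drawn uniformly and placed uniformly inside
the intron — marks 30% of introns as structured; these scales match the
40-200 nt structured regions the screen is designed to find while
keeping a desk-scale problem. Comparison species fall into three clades
with per-site intronic substitution probabilities 0.10/0.15/0.20,
0.22/0.25/0.25 and 0.25/0.25: noncoding identity between the focal
yeast and its closest sensu-stricto-like relatives of 80-90%, falling
to ~75% further out, which is where comparative yeast genomics actually
operates; exons evolve at 0.4 times the intronic rate (purifying
selection on coding sites). Gene- and intron-retention probabilities
fall off by clade (0.95/0.8/0.6 and 0.9/0.5/0.25), reproducing the
skewed ortholog-count histogram of real intron panels where most
introns are recoverable only from close relatives. Stems co-evolve by a
joint per-pair model: when either side substitutes, the partner is
substituted to restore Watson-Crick pairing with probability
`compensatory_rate` (default 0.9), and loop and flanking positions
evolve neutrally — so `compensatory_rate = 1` provably preserves
complementarity, and `compensatory_rate = 0` reduces to independent
evolution with a closed-form disrupted-pair probability that the tests
check by enumeration.

Expression is log-normal per gene (meanlog 3, sdlog 1); exonic read
counts are Poisson in expression x length, intronic counts additionally
carry a post-splicing maintenance factor — 0.3 for unstructured
introns, doubled for structured ones, the two-fold default matching the
roughly two-fold median expression difference the screen is expected to
recover. Reads are error-free, fixed-length 50 nt, placed uniformly
within their feature and emitted pre-aligned as SAM: read mapping,
sequencing error, fragment-length effects, splice-junction reads and
PCR duplicates are all out of scope, so passing tests say nothing about
mapping artefacts in real data. CRAC pseudo-experiments (16 by default)
are Poisson with a per-experiment log-normal library scale and a
configurable enrichment multiplier (default 10) for structured-intron
genes. Growth curves are logistic (A = 1, mu = 0.4/h, lambda = 2 h)
sampled every 5 minutes over 24 h with Gaussian noise sd 0.02;
competition runs transfer cycles of ~3 doublings to a target of 37
generations with binomial plating of 200 colonies and selection
coefficient -0.05, for a closed-form expected final fraction
`1/(1 + 0.95^-37) ~ 0.13`.

All stage seeds derive from one global seed by fixed offsets, so stages
are independently reproducible and the whole pipeline is byte-stable
under a fixed configuration (asserted by the determinism tests). A
counts-level twin of the read simulator
(`simulate_expression_study()`) draws the same gene-level quantities
without materialising sequences, so the calibration studies (null
p-value uniformity over 200 replicates, top-decile fraction over 60,
recapitulation over 50) run in seconds.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; GFF3 and SAM
  retain their native 1-based conventions at the boundary, and the
  conversion is an exact bijection (property-tested on 10,000 random
  intervals).
* Minus-strand sequences are always reported in host-transcript sense;
  the screen folds transcript-sense RNA.
* The exact Mann-Whitney tail doubles the smaller tail and caps at 1;
  ties force the approximate path exactly as the reference
  implementation does.
* Folding DP tracebacks are fully deterministic; equal-scoring
  structures resolve toward pairing, then the smaller right endpoint,
  then the leftmost bifurcation.
* Empty intron sequences, missing header lines, unknown chromosomes,
  overlapping exons, out-of-bounds features and non-monotone time
  vectors raise immediate, named errors; unmapped and multi-mapping
  reads are excluded silently but counted.
* Singleton ortholog sets (focal only) are skipped by the screen with a
  zero-row result rather than an error.

## Problem sizes

The test suite and the acceptance script use panels of 20 genes by 8
species for screen recovery (20 replicate panels), 10-gene panels for
end-to-end mapping, 80-100 gene count-level studies for calibration,
30 growth fits and 100 competition replicates. These sizes put every
Monte-Carlo assertion's standard error well inside its tolerance while
keeping a full run to minutes on a single core.

## Known limitations

* The ortholog search is tuned for desk-scale synthetic panels;
  e-values are approximations and the seed thresholds have not been
  calibrated against genome-scale backgrounds.
* The screen's specificity is bounded by chance structure in neutral
  sequence (discussed above); no trained classifier is included by
  design.
* Reference-anchored alignment degrades below ~50% identity, where a
  simultaneous aligner would do better; such windows are largely
  removed by the identity filter rather than rescued.
* Stranded RNA-seq protocols, paired-end data, BAM input and
  splice-junction-aware counting are not supported.
* The package's command-line surface is its R API plus
  `scripts/acceptance.R`; there is no standalone shell tool.
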