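---
title: "Calling and characterising nucleotide excision repair super hotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterising nucleotide excision repair super hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairspot)
library(dplyr)
```

## The problem

XR-seq sequences the ~21–31-nt oligonucleotides that nucleotide excision
repair cuts out of UV-damaged DNA, so each read marks an ongoing repair
event at near-nucleotide resolution. Performed as a time course (minutes to
hours after irradiation), it asks: which genomic sites does the cell repair
*first*, and which does it leave until the genome is almost clean?
`repairspot` implements the corresponding analysis pipeline: post-alignment
read QC, equal-depth downsampling, fixed-width binning, a replicate-wise
threshold caller for repair *super hotspots* (earliest repair) and *super
coldspots* (latest repair), a Poisson log-linear null model for per-bin
enrichment testing, and downstream characterisation against damage maps,
regulatory/3D-genome annotations, gene-level strand-resolved repair, and
local sequence context.

Everything is exercised end to end on synthetic data with planted
structure; the generator is first-class, tested code.

## Spot calling

Reads are deduplicated on identical 5'/3' end coordinates (strand included
in the key — the two strands have different 5' ends for the same interval;
`use_strand = FALSE` is available), then filtered to mapping quality
strictly above 20 and lengths 21–31 nt inclusive. Samples are downsampled
without replacement to a common depth (default 7.7 million reads; the
synthetic fixture uses 80,000) so that per-bin read-count thresholds are
comparable across libraries.

The genome is tiled with consecutive 50-bp bins; plus- and minus-strand
reads are counted separately. A read increments exactly one bin — the bin
holding its strand-aware 5' end by default (`assign = "midpoint"` is the
alternative). Because an excision product's 5' end lies 14–26 nt upstream
of the lesion, a call can sit up to one bin 5' of the lesion cluster;
planted-truth scoring therefore uses one-bin (50 bp) slack, and users
comparing calls with single-nucleotide annotations should allow the same.

A 50-bp bin is a **super hotspot** when it holds at least `min_early`
reads (default 15) in *every* early replicate (the two 1-min libraries)
and at most `max_late` reads (default 5) in *every* late replicate (the
two 4-h libraries). A **super coldspot** is the mirror image with relaxed
thresholds, at most 2 early and at least 10 late by default; the exact
relaxation is exposed in `coldspot_rule()` and recorded in the output.
Boundaries are inclusive on both sides. For CPD data only hotspots are
called — transcription-coupled repair dominates late CPD time points and
would confound a coldspot definition — and `call_spots()` refuses CPD
coldspots unless forced. Bins overlapping a blacklist (assembly gaps,
segmental duplications, repeats) by one or more bp are masked from
calling, fitting, and bootstrap sampling. Adjacent qualifying bins are
reported as separate 50-bp spots; `merge = TRUE` collapses runs.

## The Poisson log-linear null model

Counts for strand *s* are modelled as

$$Y_{ij} \sim \mathrm{Poisson}(\lambda_{ij}), \qquad
  \lambda_{ij} = N_j\,\beta_i\,f_j(\mathrm{TC}_i),$$

with $N_j$ the fixed (downsampled) per-strand library size, $\beta_i$ a
bin propensity capturing library-preparation and sequencing bias
(normalised to sum to 1 over unmasked bins), and $f_j$ a sample-specific
smooth function of the bin's T+C (pyrimidine) fraction — the substrate
availability for UV lesions — normalised to $\beta$-weighted mean 1. We
read "TC content" as the pyrimidine fraction of the strand-specific bin
sequence; on the minus strand it is computed on the reverse complement.

**Estimation.** `fit_null_model()` alternates two exact conditional
maximisation steps: $\beta_i \leftarrow \sum_j Y_{ij} / \sum_j N_j
f_j(\mathrm{TC}_i)$, and, on TC-content quantile strata (20 by default),
$f_j(\text{stratum}) \leftarrow \sum_{i \in s} Y_{ij} / (N_j \sum_{i\in s}
\beta_i)$. Because each step is the exact stratum-level MLE, every sweep
ascends the Poisson log-likelihood; the fit asserts this and records the
trace. $\hat f_j$ is piecewise-constant on the strata. We chose the
stratum ratio over a median of per-bin ratios (available as
`f_method = "median"`) because with per-bin means around 5 the median of
$Y/(N\beta)$ is quantised by count discreteness and biased by up to ~10%,
while the ratio estimator is unbiased and keeps the ascent exact;
piecewise-linear evaluation between stratum midpoints is available in
`predict_f()` for display.

**Robustness.** After a first converged pass, bins are trimmed from the
update steps when (i) any sample's standardised Pearson residual exceeds
`resid_cut = 3` — catches bins whose time pattern deviates from the null,
e.g. genuine repair hotspots — or (ii) the bin's log-propensity is more
than `beta_cut = 5` robust (median/MAD) z-units above the centre — catches
collapsed-repeat-like bins that are uniformly over-represented in every
sample and therefore invisible to the residual rule. Trimmed bins keep a
null propensity equal to the median $\hat\beta$ of their TC stratum, so
the expected counts used to test them are not inflated by their own
signal; the model is then refit on the kept bins (freezing the trim set
keeps the likelihood ascent monotone).

**Identifiability.** $\sum_i \beta_i = 1$ and weighted-mean-1 $f_j$ force
$\sum_i \lambda_{ij} = N_j$. Multiplying all library sizes by a constant
leaves $\hat\beta$ and $\hat f$ unchanged.

**Testing.** `test_enrichment()` sums counts and expectations over a
replicate group (Poisson additivity rather than combining p-values) and
uses the Poisson upper tail for hotspots, the lower tail for early
depletion at coldspots, with Benjamini–Hochberg correction across tested
bins. Two caveats are deliberate: exact tail p-values of a discrete count
are conservative (mid-p and randomised variants are provided; calibration
checks use the randomised version, which is exactly uniform under a
correct null), and p-values computed against a *refitted* null are
additionally conservative because the tested counts also feed
$\hat\beta$ — with 6 samples and a 2-sample test group the fraction of
null bins below 0.01 drops to roughly a quarter of nominal. The test
suite verifies calibration against the generating expectations and
verifies that the refit-and-test route errs on the conservative side.
For discovery this conservatism only strengthens reported spots.

## Gene-level repair and the trajectory

Reads overlapping a gene are split by strand: antisense reads are
transcribed-strand (TS) repair, sense reads nontranscribed-strand (NTS) —
the orientation excision products inherit from the template; a
`ts_convention = "sense"` flag flips the convention, and reads spanning
two genes count for both. Genes pass QC when they carry at least 10 TT or
TC dinucleotides on either strand, are shorter than 300 kb (strict), and
collect at least 10 reads across all samples. Within-sample normalisation
is RPKM; the ratio TS/(TS+NTS), bounded in [0, 1], cancels library size
and gene-specific biases and quantifies the transcription-coupled
contribution (0.5 = no strand preference). The repair trajectory ranks
genes by variance of log2(RPKM+1) (a variance rank; the pseudocount is
our choice), keeps the top 2,000, and runs SVD-based PCA on centred
values; PC1's sign is fixed to increase with time-point rank so plots are
reproducible.

## Damage analysis

Damage-seq chemistry stalls a high-fidelity polymerase immediately before
the lesion, so a plus-strand read starting at $s$ implies a lesion
dinucleotide at $[s-2, s)$ and a minus-strand read ending at $e$ one at
$[e, e+2)$; pileups are keyed by the leftmost genomic base of that
dinucleotide on both strands (the synthetic generator uses the same
convention, making the round trip exact; the offset is configurable).
Single-nucleotide damage hotspots are positions with at least 10
supporting reads, per strand. Regional damage at repair spots is
quantified by summing pileup counts within spots extended by 0, 20, and
500 bp at both ends — the extensions compensate for the sparse coverage
of damage sequencing — and compared across hotspot/coldspot/random
categories by Kruskal–Wallis.

## Overlap enrichment

`bootstrap_enrichment()` compares the observed fraction of spots
overlapping an annotation (any-overlap, ≥ 1 bp) with a null built by
re-placing the spot set uniformly over eligible (non-blacklisted,
non-excluded) space, widths matched exactly and per-chromosome counts
matched by default. Empirical p-values use the add-one formula
$(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$ — never zero — with B =
1,000 by default; the null mean doubles as the genome-average overlap
estimate and is reported alongside the annotation's raw coverage
fraction, since the two differ by an edge term of (spot width − 1) per
interval. Interaction counting maps spots and BEDPE anchors to 40-kb bins
(typical Hi-C resolution) and compares per-spot interaction counts
against matched random spots by rank-sum; signal tracks are averaged
per-base with missing bases as zero; chromatin-state composition assigns
each spot to its largest-overlap label with alphabetical tie-break.

## Sequence context

Each spot-mapped read is anchored at its damage dinucleotide, located by
scanning 9 down to 4 nt from the 3' end — the window implied by
dual-incision geometry — for TT/TC (CPD) or TC with a preferred CTCA
context ((6-4)PP), preferring candidates near 6 nt from the 3' end with
ties resolved 3'-ward and a flagged fallback at exactly 6 nt. A 15-position
window (−7..+7, the dinucleotide at 0/+1) is tallied per strand;
positions beyond the read are filled from the genome when available,
otherwise dropped from that position's denominator.
`compare_c_enrichment()` contrasts per-position cytosine frequencies
against a reference (e.g. genome-wide composition) with two-proportion
z-tests and BH correction, excluding the dinucleotide positions.

## The synthetic-data generator

`sim_config()` + `simulate_*()` generate a miniature study whose
statistical structure matches the model above: i.i.d. background
sequence; per-bin counts Poisson with mean
$N_j\,\beta_i\,f_j(\mathrm{TC}_i)\,e_{ij}$, where $\beta$ is log-normal
(σ = 0.6 by default — a strong but realistic library-prep bias spread,
chosen so that bin propensities vary several-fold as bin-level coverage
does in short-read libraries) normalised per strand, $f_j = \exp(b_j
(\mathrm{TC}_i - \overline{\mathrm{TC}}))$ with per-sample slopes
$b_j \sim N(0, 1)$, and $e_{ij}$ the planted enrichment fold,
interpolated geometrically between a spot's early and late fold across
the time course. Planted spots carry canonical damage motifs (CTCA for
(6-4)PP, TT for CPD) in cytosine-weighted flanks.

Three generator choices deserve comment:

* **Multiple lesions and incision jitter.** Each planted 50-bp spot holds
  5 evenly spaced damage motifs, and the lesion's distance from the read
  3' end varies by ±2 nt around 6 nt. Real UV hotspots contain several
  dipyrimidine sites and dual-incision positions vary by a few
  nucleotides; without this variability, coordinate deduplication would
  cap a single lesion at ~11 distinct reads and the ≥ 15-read hotspot
  threshold could never be met — duplicate-collapsed data would
  contradict the observable the caller relies on.
* **Planted bins sit on the clean baseline.** At planted bins the
  propensity is set to the strand mean and the TC-bias modulation is
  switched off, so "early fold 50" means exactly 50 × (N / bins per
  strand) expected reads. Otherwise the planted contract would be
  confounded by the bias draws (a low-propensity draw could silently
  halve a planted signal), making recovery tests uninterpretable.
* **Library size is per strand.** $N_j$ enters the per-strand count
  model directly (per-bin mean $N_j$/bins-per-strand at folds 1), so a
  sample emits about $2N_j$ reads.

The generator emulates per-sample library sizes, bin-level biases,
TS/NTS asymmetry on genes, uniform large-scale damage, annotation sets
with controllable spot co-location, and interaction lists with planted
anchor excess. It does **not** emulate alignment artefacts, mappability
structure, fragment-level sequencing errors, overdispersion beyond the
Poisson, or correlated biological replicates — so passing tests show the
pipeline's statistical machinery is correct under its stated model, not
that the model captures every feature of real XR-seq libraries.

## The canonical fixture and study sizes

`fixture_config()` defines the study used by the end-to-end tests and
`scripts/acceptance.R`: two 1-Mb chromosomes; eight samples (1-min ×2,
5-min, 20-min, 1-h, 2-h, 4-h ×2) with unequal library sizes (42–50k per
strand) downsampled to 80,000 reads per sample, which makes the
post-downsampling baseline exactly one read per bin per strand; twenty
planted hotspots (fold 50 → 0.1) and ten coldspots (0.1 → 40), 50 bp
each, alternating strands, clear of a fixture blacklist. Null-model
studies use 10,000 bins × 6 samples at mean depth 5; bootstrap
calibration uses 200 spot-set replicates at B = 200. These sizes were
chosen so each property has clear statistical resolution while a full
run stays interactive on a laptop; `make_fixture()` writes the same
study to disk as FASTA/BED/BEDPE/chrom.sizes for external tools.

## Numerical and edge-case conventions

Coordinates are 0-based half-open throughout; strands are `+`/`-`.
Partial terminal bins are kept and flagged. `N` bases leave both the
numerator and denominator of TC content; all-N bins are masked. The
final bin-count matrix keeps masked bins as rows (excluded from calling
and fitting) and counts library size as the per-sample, per-strand
in-bounds read total. Downsampling pools a sample's strands. TC strata
can collapse below 20 when bin-level TC values tie; stratum counts adapt.
Random-region sampling is uniform over eligible *start* positions, which
the tests verify by chi-square against the exact eligible-start measure.
All generator randomness derives from one master seed with
per-operation offsets; identical configurations reproduce byte-identical
output.

## Limitations

The null model is Poisson by design; overdispersed real libraries would
need a negative-binomial extension. Threshold calling answers "earliest
/ latest repaired", not "most repaired overall", and its counts depend
on the downsampling depth — thresholds travel with the 7.7 M design and
must be recalibrated for other depths. Multi-mapper handling is
delegated to the upstream aligner (MAPQ filtering approximates it).
Enrichment p-values against a refitted null are conservative, as
discussed above. The synthetic genome's base composition is uniform
outside planted flanks, so sequence-context baselines are cleaner than
in real genomes.
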