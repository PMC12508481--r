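---
title: "Promoter secondary structure and transcription-replication conflict analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter secondary structure and transcription-replication conflict analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trcatlas)
```

## Scope and scientific background

R-loops are three-stranded structures in which a nascent RNA hybridises
back to its template DNA, displacing the non-template strand. Promoters
whose non-template strand is G-rich (positive GC skew) or can fold into
G-quadruplexes (G4) form R-loops readily, and loci where R-loops meet an
oncoming replication fork are hotspots of transcription-replication
conflict (TRC). `trcatlas` implements the two genomic analyses that connect
a sequence-specific DNA-binding factor to this biology:

1. **Promoter structure profiling** — given a binding-peak set and a TSS
   universe, select the peak-bound TSSs, draw GC-matched unbound control
   TSS sets, and compare sliding-window GC-skew profiles, G4-propensity
   profiles, and (optionally) an external signal metaprofile such as DRIP
   across the sets.
2. **TRC-site discovery and factor enrichment** — compute replication fork
   directionality (RFD) from stranded Okazaki-fragment (OK-seq) counts,
   retain regions of near-deterministic fork direction (|RFD| > 0.75),
   keep genes contained in them, intersect with R-loop (DRIPc) peaks to
   define TRC sites, and score factor ChIP tracks by their signal ratio at
   the TRC window versus two distal control windows.

Everything runs on plain-text standard formats (FASTA, BED, bedGraph,
minimal GTF, TSV) through Bioconductor's GRanges/Biostrings/rtracklayer
stack, and every input can be generated by the seeded synthetic-data
module, so the full pipeline is testable without any external download.

## Coordinate model

Internally the package uses `GRanges` (1-based, closed intervals), the
Bioconductor convention; BED and bedGraph input/output converts at the
rtracklayer boundary, which is the only place a conversion happens. The one
exception is the TRC site table, a BED-like TSV whose coordinate columns
are 0-based half-open so it can be consumed directly by bedtools-style
tooling. The TSS anchor of a gene is its 5' base in reading direction
(start for `+` genes, end for `-` genes), stored as a width-1 range.

## Sequence statistics

**GC skew** of a window is $(G - C)/(G + C)$, undefined (`NA`) when the
window has no G or C; ambiguous bases are excluded throughout. Profiles
(`skew_profile()`) slide a 200 bp window in 1 bp steps across ±5 kb of each
TSS, always reading the coding (non-template) strand, so a positive profile
downstream of the TSS means the displaced strand of a co-transcriptional
R-loop would be G-rich. Minus-strand windows are chosen so the TSS base
occupies the same reading-direction position as for plus-strand genes,
making the operation exactly mirror-symmetric.

**G4 propensity** (`g4_base_scores()`, `g4_profile()`) uses the
G4Hunter-style rule: every base in a maximal run of $k$ consecutive Gs
scores $+\min(k, 4)$, in a run of Cs $-\min(k, 4)$, 0 otherwise; a window's
score is the mean of its base scores (25 bp windows over ±1 kb by default).
Because a quadruplex can form on either strand, the cross-TSS aggregate
uses the absolute window score by default; a `signed` mode is available
since the choice of aggregate is a genuine design freedom. Scores are
bounded by ±4 by construction.

## Peak annotation and bound-TSS selection

Peaks are classified by their midpoint with the fixed priority
promoter > exon > intron > downstream > intergenic, so the categories
partition the peak set (a pie-chart-compatible contract). The promoter
window (default ±1 kb) and the downstream window (3 kb past the 3' end)
are explicit, logged parameters, since annotation tools differ in their
internal defaults. "Bound" TSSs are those whose distance to the nearest
peak *edge* is strictly below 3 kb, matching the `< 3 kb` selection rule;
distances are counted as intervening bases, so a TSS abutting a peak is at
distance 0.

## GC-matched control sets

Control TSSs emulate the "randomly selected TSSs with comparable GC
percentage" design. Matching is stratified: GC% over ±1 kb of the TSS is
binned at width 0.01, and each control set reproduces the bound set's bin
counts exactly, sampling without replacement among TSSs that are at least
3 kb from every peak (mirroring the bound definition) and not bound
themselves. The requested number of sets (default 2) is drawn disjointly.
Stratification was chosen over nearest-neighbour pairing because it makes
the central invariant checkable: identical histograms force the binned GC%
CDFs of bound and control sets to coincide, bounding their KS distance by
one bin width. If any bin lacks candidates the function fails loudly,
naming the bin and shortfall — degrading the match silently would
invalidate the downstream comparison. All draws are seeded and
byte-reproducible.

## Signal metaprofiles

`signal_matrix()` is a reference-point analogue of deepTools'
computeMatrix: one row per anchor, covering ±3 kb resampled to 50 bp
columns by averaging the covered fine bins, with minus-strand rows
reversed so columns read upstream to downstream. Missing bins (`NA`)
propagate only when every covered fine bin is missing, and column means in
`summary_profile()` ignore missing cells while reporting the per-offset
`n`. Anchors without full flank room are dropped and counted rather than
clipped, which keeps every column's sample size interpretable.

## Replication fork directionality and TRC sites

RFD per bin is $(C - W)/(C + W)$ from Crick/Watson Okazaki counts, after a
centred moving average of both strands (half-width 2 bins by default);
bins whose smoothed coverage falls below `min_total = 10` are undefined.
Positive RFD means rightward-moving forks predominate, the OK-seq
literature convention. The published analysis delegates RFD to an HMM
caller and then keeps only |RFD| > 0.75 regions; since everything
downstream depends only on that threshold, the package calls
thresholded runs directly: maximal same-sign runs with strict inequality,
tolerating one interior sub-threshold or undefined bin (`merge_gap_bins`),
never bridging opposite-sign bins, and requiring at least 5 qualifying
bins. OK-seq bins default to 1 kb; bin size, smoothing and the gap/length
parameters are explicit because the upstream tools do not document theirs.

Genes whose body is fully contained in one region inherit its fork sign
(an `overlap` mode exists behind a flag; containment is the stricter, more
literal reading). For each such gene overlapping at least one DRIPc peak,
the overlap span runs from the leftmost to the rightmost overlapped base
across all peaks — the deterministic reading of "closest beginning and end
positions of the overlap" for multi-peak genes. The TRC window is the span
centre ±10 kb; control windows are 20 kb long, centred 1 Mb up- and
downstream. Sites whose window or controls leave the chromosome are
dropped (and counted), not clipped, so control means stay comparable
across sites. Head-on orientation means transcription opposes the
predominant fork direction: a `+` gene in a leftward (`-`) region or a `-`
gene in a rightward (`+`) region.

## Enrichment scoring

Factor tracks are normalized to RPKM
($c / (\mathrm{bin}/10^3 \cdot N/10^6)$) or CPM at 100 bp bins, replicate
tracks are averaged bin-wise, and each site is scored as

$$\mathrm{ratio} = \frac{\overline{x}_{\mathrm{TRC}} + pc}
{\tfrac12(\overline{x}_{\mathrm{up}} + \overline{x}_{\mathrm{down}}) + pc}$$

with pseudocount $pc = 0.01$ guarding sparse controls. The per-factor
summary is $\log_2$ of the across-site mean ratio; the source analysis
does not fix the order of averaging and log, so the alternative (mean of
per-site $\log_2$) is available behind a flag. The ratio is
scale-invariant as $pc \to 0$, so the summary does not depend on
sequencing depth.

## What the synthetic data emulate — and what they do not

The generators (`sim_config()` and friends) produce every pipeline input
with the statistical structure the analyses assume:

- genomes with i.i.d. background at a configurable GC fraction, an
  optional per-promoter GC spectrum (each promoter ±1 kb resampled at its
  own GC drawn from a range, giving the TSS universe the broad GC spread
  that stratified matching needs), planted downstream GC skew, and planted
  short `(CGG)n` promoter tracts;
- OK-seq counts whose true RFD is a step function of planted origins
  (+1 from an origin to the next termination midpoint, -1 elsewhere), with
  Poisson totals and binomial strand assignment;
- ChIP tracks with Poisson noise and planted fold enrichment at chosen
  sites; DRIPc peaks over a seeded gene subset; peak sets at designated
  promoters.

Skew is planted by reassigning existing G/C positions (G with probability
$(1+a)/2$ on the coding strand), which changes skew without moving a
single base in or out of the G+C pool — planted skew therefore cannot leak
into GC-based matching, mirroring the real-data situation where bound and
control sets are GC-comparable yet skew-distinct. Every generator is a
pure function of its configuration: same seed, byte-identical output.

The simulations do **not** model read-level artefacts (mappability, PCR
duplication, fragment-length effects), overdispersed ChIP noise,
replication-timing gradients between origins, or correlated placement of
genes, origins and R-loops. Passing tests therefore demonstrate that the
estimators are correct under their stated model, not that the biological
signal in real data is as clean.

## Study conditions used by tests and the acceptance script

Problem sizes were chosen as the smallest at which each estimator's
sampling error is far from its tolerance:

- **RFD recovery**: one 5 Mb chromosome, origins at 1.5 and 3.5 Mb,
  200 reads per 1 kb bin. At |true RFD| = 1 the binomial noise vanishes,
  so the residual error is confined to transition bins.
- **TRC recovery**: the same chromosome with 30 genes of 5–20 kb placed
  clear of fork-direction transitions (5 kb margin) and of chromosome ends
  (1.02 Mb margin, so 1 Mb-distant controls always fit); DRIPc peaks over
  half the genes. Called sites are compared with the planted truth subset.
- **Enrichment recovery**: 50 sites on 25 chromosomes of 3 Mb, one origin
  each, background 50 reads per 100 bp bin, planted folds {1, 2, 4, 8}.
  Genes sit in a central 0.96 Mb band, which is narrower than
  1 Mb − 20 kb; distal controls therefore can never touch another site's
  planted window, keeping the control estimate clean by construction.
- **Promoter structure**: one 3.5 Mb chromosome with 300 short
  (2–4 kb) genes spaced ≥ 3.5 kb apart (so no two TSSs fall within the
  3 kb bound cutoff of the same peak), promoter GC drawn from
  [0.35, 0.65], skew amplitude 0.3 at the 20 bound promoters. Bound
  promoters are drawn by `choose_bound_genes()`, which respects the
  stratified-matching feasibility cap (bound count per GC bin at most a
  third of the bin's TSS count for two disjoint control sets) — the same
  property a real promoter universe provides by sheer size.

## Numerical and degenerate-input choices

- Windows with no G/C give `NA` skew and are excluded from profile means;
  a TSS without full flank room is skipped and counted.
- RFD at insufficient coverage is `NA`; `NA` bins neither qualify for nor
  (singly) break high-RFD runs.
- Thresholds are strict (`> 0.75`, `< 3 kb`) as printed in the source
  analysis; ties in nearest-TSS lookup go to the smaller absolute
  distance, then the leftmost TSS.
- `bedGraph` records must align to the track's bin grid on read; writing
  collapses equal-valued runs and omits `NA` bins.
- An empty TRC site table is a legitimate result (`status = "no_sites"`),
  not an error; a site whose window has no defined signal is dropped with
  a count.

## Known limitations

- RFD region calling is threshold-run based and has no notion of the
  HMM state uncertainty a dedicated OK-seq segmenter would provide; it is
  faithful to the |RFD| > 0.75 retention rule but not a general origin
  caller.
- Peak classification intentionally collapses UTRs into exon and decides
  by midpoint; it will not reproduce another annotator's category
  boundaries exactly.
- The G4 score is sequence-rule based; it does not model loop
  thermodynamics or RNA G4s.
- DRIPc intersection is strand-agnostic, as the strand-matching policy of
  the source analysis is unstated.
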