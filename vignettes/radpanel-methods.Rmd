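---
title: "Methods: dosage genomics for an irradiated allopolyploid panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage genomics for an irradiated allopolyploid panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Ionizing radiation (gamma rays, fast neutrons) applied to seeds of an
allotetraploid crop such as oilseed rape (*Brassica napus*, AACC, 2n = 38)
induces lesions across a wide size spectrum: single-base variants, small
insertions/deletions, multi-megabase segmental deletions and duplications,
and occasional whole-chromosome losses or gains. A re-sequenced M2 panel
built from such material supports reverse genetics: find a line carrying a
lesion in the gene you care about, then confirm the predicted phenotype.

`radpanel` implements the computational layer of that workflow:

1. **Homoeologue dosage.** Gene-level read counts (genome or transcriptome
   re-sequencing) are RPKM-normalized and converted to per-gene copy-number
   estimates against the median of the untreated controls.
2. **Tile-plot visualization.** One CMYK tile per homoeologue A/C gene
   pair, plotted in A-genome order — cyan carries A dosage, magenta C
   dosage, so a lost A segment renders magenta and a duplicated one renders
   darker blue.
3. **CNV calling.** A running-median segmentation of the dosage series
   automates the visual read-out of the tile plots: segmental deletions and
   duplications, whole-chromosome events, homoeologous exchanges, sibling
   reciprocal pairs, single-gene candidates, dose–response tables and
   saturation estimates.
4. **Small-variant filtering.** A control-subtraction and recurrence filter
   chain over VCF calls, tiers by variant-allele read depth, and a
   simplified coding-consequence classifier.
5. **IHP genotyping.** Quantitative copy-number genotyping from capillary
   peak intensities at inter-homoeologue polymorphism positions.
6. **Trait modelling.** Welch *t* comparisons of seed fatty-acid
   composition between genotype groups, with Benjamini–Hochberg adjustment.
7. **A synthetic panel generator** that exercises all of the above with
   known truth, so every stage is testable without external data.

# The dosage model

For gene $g$ in sample $s$,

$$\mathrm{RPKM}_{gs} = \frac{c_{gs}}{(\ell_g/10^3)\,(N_s/10^6)}, \qquad
\hat k_{gs} = 2\,\frac{\mathrm{RPKM}_{gs}}{m_g},$$

where $c_{gs}$ is the raw count, $\ell_g$ the gene length in bp, $N_s$ the
sample's total mapped reads and $m_g$ the median control RPKM. The balanced
euploid state is $\hat k = 2$; a heterozygous deletion sits at 1, a
homozygous duplication at 4. Copy estimates are deliberately not clipped —
the colour map saturates at $k = 4$ instead (`C = min(k_A/4, 1)`,
`M = min(k_C/4, 1)`, Y = K = 0), because no copy class beyond two extra
copies is distinguished downstream.

Genes whose control median falls below $\tau_{\min} = 0.5$ RPKM are masked:
below that level the ratio estimator is dominated by shot noise. The value
is a conservative floor, not a tuned constant; it only removes genes that
could never support a ±0.5-copy decision at realistic depth.

# The segment caller

Per sample, subgenome and chromosome, the gene-order dosage series is
smoothed with a **truncated-window running median** (window `w = 9` genes;
ends use shorter windows rather than padding, so output length equals input
length). States are *deletion* below 1.5, *duplication* above 2.5 —
midpoints between integer copy numbers, the maximal-margin choice under
symmetric noise. Maximal same-state runs separated by fewer than `w/2`
baseline genes are bridged (a human reading a tile plot bridges such gaps),
then runs shorter than `min_run = 10` genes are dropped: this is the
package's operationalization of a "visible" lesion.

Because adjacent running medians share most of their window, a handful of
outlier genes can drag a whole window-length run across a threshold. Each
run is therefore confirmed on the **raw** series: its raw median must lie
beyond the threshold *and* deviate from 2 by at least
$z \cdot 1.2533\,\hat\sigma/\sqrt{n}$, where $\hat\sigma$ is the MAD of the
chromosome's raw dosage around 2, $1.2533\sqrt{n}$ scales a median's
standard error, and $z = 4$. For tight genome-sequencing noise the rule is
inactive (the threshold margin dominates); for noisier transcriptome dosage
it suppresses short marginal runs while leaving segments of 30+ genes
untouched. This is what makes genome-mode and transcriptome-mode call sets
agree on large lesions.

Mean smoothed dosage over a run maps to integer copies via cut points
{0.5, 1.5, 2.5, 3.5}; copies 0/4 are homozygous, 1/3 heterozygous. Runs
covering ≥ 95% of a chromosome's genes are reclassified whole-chromosome
loss/gain.

**Homoeologous exchanges.** A duplication whose homoeologue pairs coincide
with deletions on the other subgenome (reciprocal overlap ≥ 0.7 in pair
space) merges into one exchange call. Because a contiguous A-genome
interval maps to C-genome synteny blocks that may span a chromosome
boundary, the detector aggregates *all* partner-side deletions the
duplication explains before testing coverage, rather than requiring a
single matching deletion.

**Sibling reciprocal pairs.** Within an M1 family, a deletion in one M2
sibling and a duplication in another on the same chromosome pair when their
gene-index intervals have Jaccard ≥ 0.6.

**Single-gene scan.** Population-normalized dosage ratios
$r = \hat k_{gs} / \mathrm{median}_s(\hat k_g)$ flag per-gene candidates at
$r \ge 1.75$ (duplication) or $r \le 0.25$ (homozygous deletion), excluding
genes inside already-called segments, ranked by $|\log_2 r|$.

**Dose–response and saturation.** Event counts per dose group are divided
by the number of plants and rounded *half-up* to 2 decimals; the summary
column is the half-up-rounded mean of the four visible deletion/duplication
rates. Half-up rounding is used because the published calibration tables
round that way (a row mean of 1.205 prints as 1.21; round-half-even would
give 1.20). The saturation estimator is the fixed-point expectation
$N = \lceil T/(\lambda \bar f)\rceil$ for target multiplicity $T$, mean
events per plant $\lambda$ and mean genome fraction per event $\bar f$; its
inputs are exposed rather than hard-coded because published population-size
figures of this kind are experience-based, with no stated formula.

# The variant filter chain

Order matters and is fixed: **quality → control subtraction → recurrence →
region restriction → consequence**.

- *Quality*: records with QUAL ≤ 20 are removed; SNVs within 3 bp of a
  retained InDel on the same chromosome (and sample) are removed, InDels
  themselves never are — the documented semantics of the standard
  SNV-gap filter.
- *Control subtraction*: any mutant position present in the merged,
  quality-filtered control master set is removed **by position, not by
  allele** — pre-existing variation and systematic artifacts are
  position-level phenomena.
- *Recurrence*: a variant called in more than 8 samples is removed from all
  samples. Independent radiation events are line-specific; recurrent calls
  are artifacts. (The filter direction is configurable; this reading is the
  package's choice.)
- Every record ends in survivors or rejects exactly once, with the removing
  filter named in an append-only history — so the chain is auditable and
  idempotent.

Calls are tiered by variant-allele read depth: `low` (VAD = 2, validation
rate a few percent), `standard` (VAD > 2, validation rate around forty
percent), `reject` (VAD < 2). Validation percentages are reported both
integer-rounded and to one decimal, since both renderings occur in
practice.

The consequence classifier is deliberately minimal: codon-table translation
(standard nuclear code, strand-aware) for SNVs (synonymous / missense /
stop_gained / stop_lost); indel length mod 3 decides in-frame (with
aa_change = length/3) versus frameshift; intronic positions within 2 nt of
a CDS boundary are splice_site; everything else is non_coding. It is not a
replacement for a full effect predictor — it covers the decisions this
pipeline actually takes.

# IHP copy-number genotyping

At an inter-homoeologue polymorphism the A- and C-diagnostic bases
co-amplify; the A-signal proportion $p_A = I_A/(I_A + I_C)$ estimates
$a/(a+c)$ for copy state $(a, c)$. Classification is nearest-expectation
with a no-call margin of 0.08. The default class set
$\{(0,2),(1,2),(2,2),(4,2),(2,0)\}$ keeps adjacent expectations at least
1/6 apart, so the margin can never produce an ambiguous call. Two states
are excluded by default, with reasons the assay itself imposes:
heterozygous C loss (2,1) has expectation 2/3, *identical* to homozygous A
duplication (4,2); heterozygous A duplication (3,2) sits at 3/5, only 1/15
from (4,2) — unresolvable at realistic chromatogram noise (σ ≈ 0.03). Both
can be requested explicitly when the experimental context disambiguates
them. Consensus over multiple markers is by majority vote; ties are
no-calls with per-marker detail retained.

# The trait model

Group comparisons use Welch's unequal-variance *t* test (the conventional
default when "t tests" are unqualified) with Benjamini–Hochberg adjustment
across the comparisons of one analysis, labelled `**` below 0.005 and
`****` below 0.00005 (tiers configurable). The gene-dosage phenotype model
is linear: erucic acid rises ~5 mol% per functional elongase (FAE1) copy
and oleic falls correspondingly; losing the A5 desaturase (FAD2) moves the
oil from 15% to 8% linoleic, 15% to 19% oleic and 46% to 50% erucic at
complete loss, with Gaussian residuals (default SD 1.5 mol%). The anchors
are the published trait values; the per-copy elongase slope is a package
choice consistent with the additive genetics of the locus.

# What the synthetic panel emulates — and what it does not

The generator reproduces the statistical structure the analysis relies on:

- ~20k homoeologue pairs over 10 A + 9 C chromosomes (default 2000
  pairs per A chromosome), with the C genome ~10% larger and pairs
  distributed over C chromosomes in contiguous synteny blocks;
- per-M1-family lesion counts Poisson with mean linear through the origin
  in dose; default per-Gray coefficients are the published per-plant rates
  divided by their dose (gamma: 2000 Gy row; fast neutron: 100 Gy row,
  since FNT is ~20× more damaging per Gray);
- 1:2:1 selfed segregation of M1-heterozygous lesions into M2 plants. M1
  rates are inflated by the carrier fraction so that **per-M2-plant**
  detectable event means equal rate × dose — the scale on which per-plant
  rates are reported;
- sibling reciprocal inheritance: with probability `recip_prob` (default
  0.25) a deletion is transmitted as a het deletion in one sibling and a
  het duplication of the same segment in another. The independent
  duplication rate is reduced by the expected reciprocal contribution so
  total duplication means stay calibrated; when the reciprocal contribution
  alone exceeds the nominal duplication rate (the C genome, where
  deletions are frequent), the independent rate floors at zero and
  realized duplications modestly exceed the nominal rate — mirroring the
  observation that duplications are largely captures of sibling deletions;
- log-uniform segment lengths (min 5 genes to the chromosome length),
  dose-independent, since lesion size spectra differ little across doses.
  Lesions of one family are placed without overlap (whole-chromosome
  events first, then segments, re-drawing position or chromosome on
  collision): physical collisions are rare at the observed per-plant
  rates, and disjoint placement keeps every truth interval individually
  detectable when scoring the caller;
- homoeologous exchanges (A replacing C) in a fraction of all lines
  (default 0.1), reflecting pre-existing seed-lot heterogeneity;
- negative-binomial counts at ~12× depth (80 reads per kb at balanced
  dosage). Genome mode uses dispersion 0.005 — near-Poisson with mild
  mapping overdispersion, appropriate for DNA coverage. Transcriptome mode
  uses dispersion 0.05 plus a per-gene, per-sample lognormal factor with
  CV 0.2 for between-plant expression variability, and a fixed lognormal
  per-gene expression level (sdlog 0.8);
- small-variant calls whose probability of being real is stratified by
  variant-allele read depth (0.38 above depth 2, 0.035 at depth 2), plus
  shared artifact positions recurring across lines and controls.

It does **not** model: read-level data (FASTQ/BAM), GC or mappability bias,
recombination or selection, dosage compensation of expression, partial
(mosaic) lesions, or correlated noise along chromosomes. Passing tests
therefore demonstrate the pipeline's correctness under the stated
statistical assumptions, not robustness to every artifact of real
sequencing data.

# Numerical choices and degenerate inputs

- Rounding of reported rates is half-up (see above); all internal
  computation is full precision.
- The running median truncates windows at chromosome ends; series with
  missing (masked) genes fall back to a dense implementation.
- Zygosity cut points {0.5, 1.5, 2.5, 3.5} are midpoints; a run's state
  (deletion/duplication) clamps the copy assignment to its own side, so a
  mean dosage of 2.4 inside a duplication run still reports 3 copies.
- Degenerate cases error early and name the offender: zero-length genes,
  zero-total samples, events on unknown chromosomes, singleton phenotype
  groups, empty IHP class sets.
- Determinism: every simulator entry point draws inside a seeded scope
  derived from the panel seed plus a fixed per-stage offset, so identical
  configurations give byte-identical outputs and the stages can be re-run
  independently.

# Problem sizes used in validation

The packaged validation runs at sizes chosen to give tight Monte-Carlo
error while staying comfortably interactive: calibration of per-plant
event means at 10 000 simulated plants (±3 SE bands), caller recovery and
transcriptome concordance on a 200-plant panel of 2000 pairs (sensitivity
and precision ≥ 0.95 for segments of ≥ 30 genes), sibling-reciprocity
recovery over ~400 simulated reciprocal events, IHP accuracy over 10 000
noisy draws, and filter-chain checks on panels of ~6000 simulated variant
calls. The full-size defaults (20k pairs, 1000+ lines) run the same code
paths unchanged.

# Known limitations

- The caller reports gene-index intervals, not base-pair breakpoints.
- Exchange direction is inferred from which side gained; balanced (copy
  neutral) exchanges between more than two intervals are not modelled or
  called.
- The consequence classifier ignores splice-site creation inside exons,
  stop-loss read-through length, and compound heterozygosity.
- The trait model is strictly additive across loci; epistasis between the
  elongase loci and the desaturase is not represented.
- Transcriptome mode inherits the expression-variability floor: lesions
  shorter than ~10 genes are intentionally not callable there.
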