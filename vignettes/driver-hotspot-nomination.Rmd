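---
title: "Tumor-only driver-hotspot nomination: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only driver-hotspot nomination: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caahotspot)
```

# The nomination model

`caahotspot` nominates somatic driver mutations from tumor-only exome variant
calls. Without a matched normal, a called SNV may be (i) a clonal somatic
driver, (ii) a personal germline variant, or (iii) a sequencing or fixation
artifact. The package separates these with three complementary pieces of
information:

* **Allele fraction.** For a clonal heterozygous mutation in a diploid tumor
  admixed with normal stroma, the variant allele fraction is
  $\mathrm{VAF} \approx \rho/2$ where $\rho$ is tumor purity. Germline
  heterozygotes sit near 0.5 regardless of purity, homozygotes near 1, and
  FFPE cytosine-deamination artifacts well below 0.1. A two-sided evidence
  band (default 20–50%, depth ≥ 20) therefore removes most homozygous
  germline calls and low-level noise while retaining clonal somatic events in
  specimens of ~40–100% purity.
* **Population SNP exclusion.** Known germline sites are removed by exact
  (chrom, pos, alt) match against a supplied VCF of population variants.
* **Hotspot priors.** Remaining calls are restricted to a cancer-gene list
  and, finally, to residues orthologous to recurrently mutated positions in
  human cancer genes. This is the strongest somatic/germline discriminator
  available without a normal: recurrent activating substitutions at RAS
  codon 61 or RAF codon 600 are vanishingly unlikely as private germline
  polymorphisms.

The cascade runs in that narrative order (gene list → SNP exclusion →
evidence → consequence → hotspot). The stages are conjunctive, so the
survivor *set* is order-independent; the per-stage rejection counts reported
in the trace are not, which is why the order is fixed and documented.

## The low-VAF rescue

A hard 20% VAF floor misses true drivers in low-purity specimens
($\rho/2 < 0.2$ whenever $\rho < 0.4$ — common in FFPE blocks with abundant
stroma). The rescue step re-examines only variants that (a) failed the
evidence stage alone, (b) failed it *low* (depth or below-band VAF, never
above-band), and (c) lie at a genomic position of a mapped hotspot codon. It
promotes those with VAF ≥ `rescue_vaf_floor` (default 0.05) and alt reads ≥
`rescue_min_alt_reads` (default 4). The defaults admit an 11% VAF call at
~100× with a comfortable margin while staying above the mass of deamination
artifacts (see the artifact model below); both are configurable. Above-band
failures are never rescued because a >50% VAF with adequate depth indicates a
germline homozygote, not a diluted somatic event. Rescue is monotone: it only
moves records from rejected to rescued, never demotes a nominated record.

# Consequence classification

One transcript model per gene (exons, CDS bounds including the stop codon,
strand). For a coding SNV the affected codon is looked up in the spliced CDS;
minus-strand transcripts reverse-complement the alt allele before lookup. The
classes are deliberately the closed set the cascade needs: the *High
consequence* group is exactly {missense, stop-gain, splice donor,
splice acceptor}. Splice sites are the two intronic bases flanking each exon
boundary — the canonical GT/AG dinucleotide positions — labelled
donor/acceptor in transcription direction. Two boundary decisions:

* any substitution in the initiation codon is `start_loss` and **not** High
  consequence (the retained set is closed; a start-loss is a loss-of-function
  mechanism the hotspot catalogs used here do not describe);
* a substitution in the stop codon is `synonymous` if the mutant codon still
  terminates, else `stop_loss` (also not High consequence).

The classifier is validated against a brute-force oracle that rebuilds and
translates the entire mutant CDS for every possible SNV of a transcript, on
dozens of randomly generated models on both strands, and a strand-symmetry
property (a reverse-complemented mirror gene yields identical calls).

# Hotspot orthology transfer

Human hotspot residue numbers are transferred to the canine protein through a
global pairwise alignment: BLOSUM62 substitution scores, affine gap penalty
`gap_open + gap_extend * L` with defaults 10 and 0.5 — standard protein
alignment parameters; orthologous RAS/RAF proteins are >90% identical, so the
mapping is insensitive to reasonable variations. The aligned-pair list keeps
every column with residues in both sequences (matches and mismatches);
hotspots falling in gapped columns report "no orthologous position" rather
than guessing. When the canine residue differs from the catalog's human
reference residue, the transfer is flagged (`residue_mismatch`) but not
discarded, because genuine inter-species reference differences exist. The
packaged demonstration catalog covers RAS codons 12/13/61, BRAF 600, and SMO
412/535; it is a TSV of `gene, human_pos, ref_aa, alt_aas` and can be swapped
for a full COSMIC-derived file of the same shape.

The packaged toy "BRAF" pair encodes the canonical 5-residue human insertion
upstream of position 600, so the alignment maps human 600 to canine 595 —
the relationship between the human V600E and canine V595E driver mutations.

# Copy-number profiling

The cohort is tumor-only, so each sample's per-target depths are normalized
against the *other* cohort samples: the bin value is
$\log_2(d_i/\tilde d) - \log_2(m_i)$, where $\tilde d$ is the sample's median
depth and $m_i$ the panel median of the same median-scaled quantity. Shared
capture efficiency cancels; the result is scale-invariant per sample. Bins
with zero sample depth or zero panel median are masked.

Segmentation is recursive binary splitting: at each step the contiguous
window whose mean most differs from its complement (two-sample t statistic,
maximized over all windows of at least `min_seg_size = 5` bins) is split out
if its t exceeds `t_threshold = 5`, and the three resulting parts are
processed recursively; adjacent segments closer than `merge_delta = 0.1` are
re-merged. Ties resolve to the first maximal window, making the procedure
deterministic. For breakpoint *detection* the ratios are first run through
running-median outlier smoothing (a bin deviating > 3 robust SDs from its
local median is pulled in), which stops single noisy low-coverage targets
from dragging a boundary; reported segment means are always computed from the
raw ratios, so segment means equal the mean of their member bins exactly.

A profile's **flatness** is the fraction of bins whose segment mean satisfies
$|\log_2| < 0.3$ (about a single-copy change at 40% purity); a profile is
called flat when flatness ≥ 0.95. Both thresholds are configurable; they are
the package's own operating point, chosen so that a 10%-of-genome single-copy
event flips the call while panel noise does not. There is no GC correction in
this version — the synthetic data carry no GC bias — but the normalization
step is the natural hook for one.

# The synthetic cohort generator

The generator emulates the study conditions of a tumor-only FFPE exome
cohort:

| Quantity | Model | Default |
|---|---|---|
| cases | — | 24 |
| driver assignment | mutually exclusive per case | HRAS 0.63, BRAF 0.08 |
| purity | Uniform | (0.2, 0.9) |
| site depth | NegBin(mean, size) | mean 116, size 8 |
| driver VAF | Binomial(depth, purity/2)/depth | — |
| germline het / hom VAF | Binomial(depth, p)/depth | p = 0.5 / 0.98 |
| germline sites per case | drawn from a shared population pool | 30 het + 15 hom |
| known-SNP resource | fraction of the pool | 0.9 |
| artifacts per case | C>T (G>A) with VAF ~ Beta(1.5, 40) | 12 |
| coverage noise | Poisson at the target's expected depth | — |
| CNA event | one contiguous 2× or 0.5× span | prob 1/16 |

Choices worth explaining:

* **Single-clone diploid tumors** (driver VAF = ρ/2) — exactly the
  stromal-admixture reading of the observed 11–46% driver VAFs. Subclonality
  would need a cellular-fraction factor; the VAF model is the single place to
  add it.
* **Beta(1.5, 40) artifact VAFs** (mean ≈ 3.6%, ~80% of mass below 5%) — a
  declared assumption standing in for the unreported FFPE deamination
  spectrum; with the hotspot restriction, artifact records cannot be
  nominated regardless, which the end-to-end tests confirm empirically.
* **Population SNP pool** — per-case germline sites are drawn from a shared
  pool (as real personal variants are), so the known-SNP resource covers a
  *fraction of sites* (default 0.9), not a fraction per case. Pool sites
  exclude hotspot codons: a private germline variant exactly at a RAS/RAF
  hotspot is not a realistic confounder.
* **Coverage counting noise** — per-target coverage is Poisson around the
  expected depth (shared lognormal capture efficiency × copy-number
  multiplier), the sampling-noise regime in which read-depth CNA calling at
  ~116× operates; a finite negative-binomial size is available for
  overdispersion experiments.
* **Per-case RNG streams** are derived from the master seed plus the case
  index, so case k's files are byte-identical whether the cohort has 2 or
  200 cases, and identical seed + config reproduce every output byte.

What the generator does **not** model: read-level errors (no FASTQ/BAM),
mapping artifacts, GC bias, subclonal structure, indels, and the real
genome's gene density (ten synthetic genes on two contigs). Passing the
end-to-end tests therefore demonstrates the *logic* of the cascade — its
selectivity and the rescue's sensitivity under the stated VAF/depth models —
not performance on real FFPE libraries.

# Validation scale and determinism

The shipped validation uses problem sizes chosen to exercise every code path
at comfortable statistical resolution: exhaustive SNV enumeration over ≥50
random transcripts for the classifier oracle; alignment-score agreement with
an independent dynamic-programming oracle on random pairs up to 60 residues
plus all packaged pairs; a 1,000+-variant cascade-vs-reimplementation
comparison; a 200-case end-to-end recovery run (estimated driver frequency
inside the 95% binomial CI of the realized truth, zero artifacts nominated);
and 16-sample coverage cohorts for flatness calling and ±2-bin breakpoint
recovery at |log2| ≥ 0.58. All stochastic steps run under fixed seeds, and
every reported number in the README is produced by the code shown there.

# Known limitations

* SNVs only; indel consequence calling is out of scope.
* One transcript per gene — no multi-isoform severity arbitration.
* The evidence band's endpoints are treated as inclusive; sources that print
  a "20–50%" band rarely state strictness, and the boundary behavior is
  pinned by tests so a different convention is a one-line, test-visible
  change.
* The hotspot catalog shipped is a small demonstration set, not a complete
  COSMIC extract.
* Real-cohort quantities that depend on archive-scale raw data (total
  SNV yields across a sequenced cohort, real CNA profiles) are outside what
  a desk reproduction can compute; the package validates those analysis
  classes on synthetic truth instead.
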