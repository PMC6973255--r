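---
title: "MSI classification from smMIP sequencing of short mononucleotide repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSI classification from smMIP sequencing of short mononucleotide repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnrmsi)
```

## The assay and its model

Microsatellite instability (MSI) is the accumulation of length mutations in
short tandem repeats and the sequencing-visible hallmark of mismatch-repair
deficiency. The assay modelled here amplifies a panel of short (7--12 bp)
monomorphic mononucleotide repeats (MNRs) with single-molecule molecular
inversion probes (smMIPs), sequences the captured inserts in both
orientations on a short-read instrument, and classifies each tumor sample as
MSI-high (MSI-H) or microsatellite stable (MSS). Short MNRs are deliberately
chosen: polymerase slippage ("stutter") grows rapidly with repeat length, so
short tracts keep the artifact floor low enough that true somatic deletions
dominate the signal. Each repeat is paired with a nearby common SNP inside
the same captured insert, and each captured molecule carries a random
6-base molecular barcode (UMI) adjacent to the probe's extension arm.

Two per-marker statistics feed the classifier:

* **Deletion frequency** $d_m$ — the proportion of a marker's reads whose
  measured repeat-tract length is below the reference length. Reads longer
  than the reference (insertions) are not deletions but stay in the
  denominator.
* **Allelic bias** — for samples heterozygous at the linked SNP, the
  two-sided Fisher exact p-value of the SNP-allele × deleted/not-deleted
  2×2 table. Somatic deletions arise on one haplotype and therefore ride
  one SNP allele; stutter is haplotype-blind. Allelic bias is thus evidence
  that observed deletions are real mutations rather than noise.

Both statistics are dichotomized into binary traits: $D_m = 1$ when $d_m$
strictly exceeds the 95th percentile of the MSS training samples' deletion
frequencies at that marker, and $B_m = 1$ when the p-value is strictly
below .05. A naive Bayes model combines the traits across markers. With
Laplace-smoothed per-class trait probabilities
$\hat P(t \mid \text{class}) = (k + \kappa)/(n + 2\kappa)$, $\kappa = 1$,
the score of a new sample is the decadic log-odds

$$ S \;=\; \log_{10}\frac{1 - \pi}{\pi}
   \;+\; \sum_m \log_{10}
     \frac{P(D_m \mid \text{MSI-H})}{P(D_m \mid \text{MSS})}
   \;+\; \sum_{m:\,B_m \text{ observed}} \log_{10}
     \frac{P(B_m \mid \text{MSI-H})}{P(B_m \mid \text{MSS})}, $$

with prior MSS probability $\pi = 0.85$ (roughly one tumor in six is
mismatch-repair deficient). $S > 0$ calls MSI-H, $S < 0$ calls MSS; the
measure-zero case $S = 0$ is reported as *indeterminate* rather than
silently resolved. Missing traits (no measurable reads; SNP not
heterozygous) contribute nothing — markers are skipped, never imputed — and
the number of markers actually used is recorded. Because the model weighs
every marker by its own sensitivity and specificity, it needs far fewer
markers than classifiers that count the proportion of mutated loci.

## Reference-free extraction

Alignment to a reference genome is unnecessary for this assay: the captured
inserts are fully determined by the panel, so reads are assigned by matching
both probe arms (at most one substitution per arm, no indels — arms are
primer-like and an indel would corrupt the barcode frame; ties between
markers are counted as ambiguous and dropped). The two mates of a pair read
the same molecule in opposite orientations; after orientation they are
superimposed and only base calls supported by both mates are kept, the rest
masked. The repeat-tract length is the run of repeat-unit bases between
exact, unmasked flank anchors (>= 4 nt each, chosen so that neither flank
continues the repeat); any masked or foreign base inside the tract, a
missing anchor, or a tract more than 10 bp above the reference length
(chimera guard) voids the measurement and the read is excluded from the
histogram — exclusions are counted, never silently lost. The linked SNP is
read at its insert offset; the panel schema places it 5' of the repeat so a
deletion cannot shift it.

Two deliberate asymmetries are worth stating. First, barcodes are read from
the extension-side mate only and are **not** error-corrected or clustered:
they serve as a quality-control estimate of the number of template
molecules sequenced, and distinct-barcode counting is bias-free on
error-free data while sequencing errors inflate it only mildly (documented
below for the generator's operating point). Second, BRAF c.1799 variant
calling keeps the two orientations as *separate* base calls: its raw
variant-allele frequency (VAF) is meant to sit at the per-read base-calling
error floor (~0.62%/3 for the specific substitution) so that
barcode-consensus calling (majority base per barcode, >= 2 calls, ties
dropped) can be seen to suppress it. Applying the pair-agreement mask there
would hide exactly the error floor the consensus mode is designed to
remove. The MSI repeat path, by contrast, uses the pair-consensus rule
throughout, and deletion frequencies use raw (not barcode-collapsed) reads:
barcode collapsing is available (`umi_collapse = TRUE`) but does not
improve class separation for this trait pair, at the cost of discarding
most of the depth.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `prior_mss` | 0.85 | prior probability a sample is MSS |
| `kappa` | 1 | Laplace pseudocount for trait probabilities |
| `p_cut` | 0.05 | allelic-bias dichotomization cut (strict `<`) |
| threshold $t_m$ | trained | MSS 95th percentile of $d_m$ (strict `>`) |
| `het_min_frac` / `het_min_reads` | 0.2 / 5 | SNP heterozygosity rule (minor-allele read fraction and per-allele depth) |
| `qc_threshold` | 75 | mean barcodes/marker for QC pass |
| advisory minima | 10 / 15 | barcodes/marker for reliable scoring (24- / 6-marker panel) |
| arm tolerance | 1 | substitutions allowed per probe arm |
| `vaf_threshold` | 0.05 | BRAF positivity cut (strict `>`) |

The percentile uses the type-7 (linear interpolation) convention of
`stats::quantile`, i.e. fractional rank $0.95(n-1)+1$; the convention is
fixed and tested, since with ~47 training values neighbouring conventions
shift the threshold by a visible amount. The heterozygosity rule is chosen
to be robust both to the ~0.6% per-base error (which puts a few reads on
the wrong allele) and to allelic dropout at low template counts. All
boundary comparisons are strict, so a deletion frequency exactly at its
threshold, or p exactly .05, does not fire the trait.

## What the synthetic generator emulates

The generator (`make_fixture_panel()`, `cohort_config()`,
`generate_cohort()`) produces paired FASTQ cohorts with the statistical
structure the assay relies on, plus full ground truth. Per marker and
sample, it draws ~150 template molecules, each with a distinct barcode
(sampled without replacement, so barcode counts measure template counts
exactly in the error-free limit); under MSI-H, templates acquire 1--3 bp
deletions (geometric sizes) at rate *mutant fraction × tumor content*, with
mutant fractions drawn per marker from 0.3--0.7 and placed on one SNP
haplotype with probability 0.9 in heterozygous samples (the source of the
allelic-bias signal; SNP heterozygosity probability 0.3). Every read pair —
a pair sequences one PCR amplicon — is subject to stutter deletions at
0.5--3% rising with repeat length, and each mate independently to 0.62%
per-base substitution errors. Stutter lives at the pair level deliberately:
a slippage event happens during amplification and is shared by both mates,
whereas per-mate stutter would be annihilated by the consensus rule and the
MSS deletion frequency would no longer converge to the configured stutter
rate. Tumor content of MSI-H samples is uniform on 0.5--1; reads per
template are Poisson with mean 3; an optional BRAF locus draws
alternate-allele templates at a configurable fraction.

What the generator does **not** emulate: FFPE damage (deamination
artifacts), indel sequencing errors outside the repeat, quality-score
structure (qualities are flat and ignored beyond the both-mates-agree
rule), barcode cross-contamination, and the marker-to-marker sensitivity
spread of the real panel (real per-marker operating points would need the
original sequencing data, which is not shipped; the fixture panel is
synthetic and labelled as such). Passing tests therefore demonstrate the
method's internal correctness and its behavior under the modelled noise
processes — not clinical performance on real tumors.

## Numerical and design choices

* **Fisher exact test** — implemented by summation of hypergeometric point
  probabilities with the point-probability two-sided convention and a
  `1e-7` relative guard against floating ties (the same convention as
  `stats::fisher.test`, against which — and against a direct
  binomial-coefficient enumeration — it is tested exhaustively for all
  tables with total up to 40). Tables with an empty margin return p = 1.
  One-sided variants exist for sensitivity analyses only.
* **Clopper–Pearson** intervals by beta tail inversion; at $x = n$ the
  lower bound is $(\alpha/2)^{1/n}$.
* **Model files** are versioned JSON written with 17 significant digits,
  which round-trips IEEE doubles exactly; loading refuses unknown format
  tags or versions rather than guessing.
* **Stepwise marker selection** (backward–forward) had to be pinned down
  beyond the usual sketch, because the obvious greedy rule — remove only
  while the objective does not drop — provably stalls: with small cohorts,
  leave-one-out (LOO) noise lets subsets of uninformative markers overfit
  so that every single removal loses a sample even when a far smaller
  subset is strictly better. The implemented search walks from the full
  panel by single-marker moves, accepts the best removal as long as
  accuracy stays at or above the *full panel's* accuracy (the floor the
  selected subset must meet), re-adds removed markers only on strict
  accuracy gains, never revisits a subset (guaranteeing termination), and
  returns the best subset visited — ranked by accuracy, then parsimony,
  then mean |score| margin. Candidate moves are tie-broken by margin, then
  by the least informative deletion trait
  ($|\log_{10} P(D{=}1 \mid \text{MSI-H}) / P(D{=}1 \mid \text{MSS})|$),
  then by name, so the search is fully deterministic. The default
  objective is LOO accuracy (each held-out sample is scored by a model
  retrained without it, thresholds included); a training-reclassification
  objective is available. Because the naive Bayes score is additive over
  markers, per-sample per-marker LOO contributions are precomputed once and
  any subset's objective is a row sum — the same machinery that lets tests
  compare the search against exhaustive enumeration of all subsets.
* **Read mixing** operates on whole read records (length, SNP allele and
  barcode move together), since allelic bias depends on their joint
  distribution; total depth is matched to the shallower source per marker
  and the fraction drawn from the MSI-H source is binomial. At the
  degenerate fractions 0 and 1 the source sample is taken verbatim.
  Detection limits are reported on the evaluated grid only — no
  interpolation.
* **Barcode resampling** subsamples distinct barcodes per marker
  (keeping all reads of a kept barcode) down to a target mean, mimicking
  lower template input at constant library quality.
* **Degenerate inputs** — empty FASTQs yield valid zero-count profiles that
  fail QC rather than erroring; a sample with no measurable marker at all
  is refused as unscorable; QC failure flags but never suppresses a call
  (low-template samples are reported, as they would be in a diagnostic
  setting, with the flag carrying the caveat).

## Problem sizes used in the validation suite

The packaged experiments run at deliberately chosen sizes: training and
validation cohorts of 51 MSI-H / 47 MSS and 50 MSI-H / 49 MSS samples at
the generator's defaults for the headline reclassification experiment
(which achieves 100% sensitivity and specificity, with exact binomial CI
lower bounds of 93.0% / 92.5% and 92.9% / 92.7% — quantities the acceptance
script recomputes end-to-end); a 24-marker, 10+10-sample cohort for the
panel-size comparison of detection limits; 25+25-sample cohorts for the
selection oracle (at smaller cohorts LOO noise makes even exhaustive search
unstable, which is a property of the objective, not of the search); and
tens of templates per marker where only structural round-trips are being
checked.

## Known limitations

* The fixture panel is synthetic; nothing here calibrates per-marker
  thresholds or trait probabilities for a real assay. Training on real
  FASTQs with a real panel definition is supported but unvalidated.
* Distinct-barcode counting saturates as read depth approaches the barcode
  space and inflates slightly under sequencing error (a few percent of
  pairs carry an error inside the 6-base barcode); both effects are
  irrelevant at the QC thresholds used but would matter for absolute
  template quantification.
* The B-trait probabilities are conditioned on heterozygosity being
  observed; whether to condition or estimate marginally is a genuine
  modelling fork, and conditioning was chosen because the trait is
  undefined — not zero — for homozygous samples.
* MSI-low biology is not modelled: samples with a single mutant reference
  marker are labelled MSS upstream, following the reference-standard
  convention, and no multi-class extension is attempted.
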