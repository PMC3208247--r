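---
title: "Detecting tumor-specific alternative TSS usage from exon-level expression"
author: "alttss package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tumor-specific alternative TSS usage from exon-level expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alttss)
```

## The problem

A large fraction of human genes can initiate transcription from more than
one promoter, producing isoforms that differ in their first exons and,
often, in their protein products. In colorectal and other cancers, tumors
sometimes activate a transcription start site (TSS) that is barely used in
the matched normal tissue — a shift invisible to gene-level differential
expression, because total transcript output may hardly change while the
isoform composition does.

Exon-resolution expression data (classically exon arrays, with one
*probe set* per exonic region) can reveal such shifts: probe sets unique to
one isoform's first exons gain or lose signal relative to the gene as a
whole. `alttss` implements that screen end to end: cataloging multi-TSS
genes, normalizing and filtering the expression matrix, testing each gene
for isoform-composition changes, classifying candidates as
alternative-TSS versus alternative-splicing events, confirming them in
independent cohorts, and asking which transcription factors might drive the
shift via promoter motif enrichment. A fully seeded synthetic-data
generator provides datasets with known ground truth, so the operating
characteristics of every stage are measurable.

## The model

### Preprocessing

Probe-set intensities are quantile-normalized across samples and
transformed as

$$y = \log_2(x + 16),$$

an offset-log transform that stabilizes the variance of low intensities and
gives the data a floor of exactly $\log_2 16 = 4$. Genes are kept only when
expressed above background: strictly more than 50% of a gene's probe sets
must exceed a log2 threshold (default 5.0, configurable; a
detection-above-background p-value matrix may be used instead when
available) in at least half of the normal samples *and* at least half of
the tumor samples (adenomas and carcinomas pooled). Gene-level expression
is the mean (optionally median) of the gene's *core*-tier probe sets —
the constitutive, well-annotated exons — on the log2 scale.

### The splicing index and the splicing ANOVA

For probe set $p$ of gene $g$ in sample $s$, the log2 splicing index is

$$\mathrm{SI}_{ps} = y_{ps} - \bar{y}_{g(p),s},$$

the probe set's log2 value minus the gene's summarized log2 value. Sample
scaling effects and gene-level expression changes cancel, so SI contrasts
isolate isoform-composition changes.

Each gene is tested for a group-by-probe-set interaction in the two-way
fixed-effects model

$$\mathrm{SI} \sim \text{group} + \text{probeset} +
  \text{group:probeset},$$

with group = normal versus pooled tumor. Because every sample measures
every probe set, the design has proportional cell counts and the orthogonal
sums-of-squares decomposition is exact; the partial $F$ statistic for the
interaction has $(P-1,\; NP-2P)$ degrees of freedom for $P$ probe sets and
$N$ samples. P-values are Benjamini–Hochberg corrected across genes.

Two degenerate cases arise in synthetic data and are handled explicitly:
a gene with essentially zero interaction sum of squares reports $F = 0$,
$p = 1$ (no interaction, whatever the residual); a gene with interaction
signal but zero residual variance (possible only in noise-free simulation)
reports $p = 0$ with a degeneracy flag rather than NaN, so edge cases
cannot silently vanish.

The model is fixed-effects only; no per-sample or per-patient random effect
is fitted. Consequently $F$ is *not* invariant to adding arbitrary
per-sample constants to the SI values of one gene — but such constants
never reach the ANOVA, because SI construction itself removes per-sample
shifts, and group-level constants are absorbed by the group main effect.

### Filter cascade and positional classification

Candidates pass two tiers: *discovery* at BH $q < 0.05$, and *stringent*
at $q < 10^{-6}$ together with an effect gate
$\max_p |\Delta\mathrm{SI}_p| > 0.5$, where
$\Delta\mathrm{SI}_p = \overline{\mathrm{SI}}_p(\text{tumor}) -
\overline{\mathrm{SI}}_p(\text{normal})$. The SI gate is applied to the
group-mean difference per probe set, the standard reading for exon-array
effect sizes.

Stringent candidates are then classified by an explicit positional rule
that replaces manual genome-browser curation. Probe sets are first
annotated against the gene models: a probe set supported (≥ 1 bp exonic
overlap) by *all* of a gene's transcripts is `shared`; one supported by the
transcripts of exactly one TSS group *and* lying strictly 5' of the exonic
region common to all TSS groups is `tss_unique`; other partial support is
`internal_unique` (cassette-like); probe sets overlapping no exon are
`unmapped` and excluded. A candidate is called `ALT_TSS` when every probe
set beyond the SI gate is TSS-unique, no shared probe set exceeds the gate,
and at least one TSS group's mean $\Delta$SI exceeds $+0.5$ — that group
becomes the *tumor-preferred TSS*. Differential signal confined to internal
cassette probe sets yields `ALT_SPLICING`; any mixture is `AMBIGUOUS`.

Validation in independent cohorts requires, in at least one cohort,
splicing-ANOVA $q < 0.05$ (BH across the candidates tested there), the SI
gate, and a positive mean $\Delta$SI on the tumor-preferred group (same
direction as discovery).

### Isoform-level statistics

Isoform expression is the mean log2 value of a TSS group's unique probe
sets; the *isoform ratio* is the long-isoform value minus the
short-isoform value, in log2 units (the long isoform is the one from the
most 5' TSS). Group comparisons use the equal-variance Student t-test
(Welch by flag), paired designs a two-sided paired t-test with the
increase count reported as "n of N pairs", and agreement with orthogonal
measurements Spearman rank correlation with average ranks for ties.
Comparisons of constant vectors return $p = 1$ with a degeneracy flag so
batch runs survive pathological genes.

### Promoter motifs

For each TSS the promoter window spans 300 bp upstream to 100 bp
downstream, strand-aware (the promoter string always reads 5'→3' with the
TSS at position 300). PWMs (JASPAR or MEME minimal format) are scanned on
both strands with log2-odds scores against a background base composition;
a window is a hit at a threshold defaulting to 80% of the motif's maximum
attainable score. Enrichment of tumor-preferred-TSS promoters
(foreground) against normal-preferred promoters plus any user-supplied
background set is a one-sided Fisher exact test on promoters-with-≥1-hit
(per-site counting by flag), BH-corrected across motifs. Enriched motifs
are finally crossed with their transcription factors' own differential
expression (BH-corrected t-test, $q < 0.05$) and tagged up or down in
tumor.

## The synthetic-data generator

The generator emulates the structure of a colorectal exon-array study so
every stage is testable without external data. Defaults, fixed as the
package's study conditions:

* **Cohort**: 24 normal mucosa, 49 adenomas, 35 carcinomas (30
  microsatellite-stable, 5 unstable); 23 patients contribute both a normal
  and a tumor sample. Paired samples share half of their sample-effect
  variance.
* **Genes**: 500 per replicate, each with a long isoform (2 unique
  upstream first exons) and a short isoform (1 unique first exon from a
  downstream TSS) sharing 3 constitutive exons; one probe set per exon.
  Shared exons are tier `core`, TSS-unique exons `extended`, mirroring how
  array annotation treats alternative first exons.
* **Abundances**: per-gene baselines draw from
  $\mathcal N(10, 1.5^2)$ log2 units, spreading genes over the broad
  intensity range real arrays show — quantile normalization presupposes
  such smooth, comparable distributions, and an early homogeneous-baseline
  draft of the generator demonstrated how badly QN misbehaves without it.
  The short isoform sits `minor_offset` = 2.5 log2 units below the long
  one in normal tissue: the tumor-preferred TSS is the one barely used in
  normal mucosa, the pattern of interest.
* **Events**: 10% of genes are true alternative-TSS events (the short
  isoform gains `effect_delta_si` = 1.0 log2 units in every tumor sample),
  10% are alternative-splicing-like (the shift lands on one internal
  shared exon instead), 5% are "dark" (all probe sets at the background
  level of 3, exercising the background filter), the rest null.
* **Noise**: probe affinities, sample effects and measurement noise are
  each $\mathcal N(0, 0.25^2)$ on the log2 scale; shared probe sets read
  $\log_2(2^{\text{long}} + 2^{\text{short}})$, so shared-exon responses
  to an isoform switch are attenuated by the mixing exactly as on a real
  array — a derivable property, not an assumption.

All randomness flows from a single integer seed; identical configurations
produce bit-identical matrices.

What the generator does *not* emulate: probe-level (within-probe-set)
effects, cross-hybridization, batch structure, stromal contamination, or
correlated noise between neighboring probe sets. Passing tests therefore
show that the statistics behave as designed under a clean isoform-mixing
noise model, not that the pipeline is robust to every artifact of real
arrays.

## Design choices and numerical notes

* **Probe-set-level input.** The classical probe-level RMA summarization
  with the +16 offset variant operates on raw array files; this package
  accepts probe-set-level linear intensities and applies quantile
  normalization, the offset-log2 transform and gene summarization itself,
  preserving every downstream formula while keeping inputs simulable.
* **Core-only gene summary.** Summarizing genes from core (shared-exon)
  probe sets keeps the gene estimate on the constitutive part of the gene.
  It also gives the screen its calibration: with the default architecture
  the SI noise contributions balance so that the residual mean square is
  an unbiased noise estimate, and null genes reject at the nominal rate
  (verified by the null-calibration test). Summarizing over all probe sets
  would center each sample's SI exactly and bias the residual downward.
* **Mean summarizer default.** With mean summarization, the SI of a
  gene's summarized probe sets averages to exactly zero per sample — a
  cheap, exact invariant the tests exploit.
* **"Different TSSs"** means distinct genomic 5' coordinates; any nonzero
  difference counts by default (`min_tss_sep = 1`), configurable when
  annotation jitter should be tolerated.
* **Ties in BH** are handled by the standard step-up with stable ordering;
  adjusted values are monotone via the running minimum from the largest p.
* **Quantile normalization and degenerate input.** QN equalizes the
  per-rank means across samples (ties broken by position). On noise-free
  synthetic data whole columns are exactly tied, rank order within a tie
  block is arbitrary, and QN scrambles part of a planted signal; since
  such data are already perfectly normalized, `run_detect(normalize =
  FALSE)` is the appropriate setting there, and the noise-free
  identifiability check runs that way. Real (noisy) data are unaffected.
* **Effect attenuation near the gate.** Because shared exons mix both
  isoforms, the observable $\Delta$SI of a planted shift $\delta$ is
  $\delta$ minus a log-sum attenuation term; for effects only marginally
  above the 0.5 gate, attenuation (and, at low intensities, compression by
  the +16 offset) can pull the observed effect below it. Recovery
  guarantees are therefore stated at the default effect size 1.0, where
  the observed effect stays well clear of the gate.
* **Problem sizes in the tests.** The acceptance suite measures FDR and
  power over 20 seeded replicates of the default 500-gene, 108-sample
  study, null calibration over 20 zero-event replicates, and paired-count
  calibration over 200 replicates of the 23-pair design — sizes chosen to
  put three Monte-Carlo standard errors well inside the asserted bounds.

## Known limitations

* The splicing ANOVA tests *any* interaction; the positional classifier,
  not the test, distinguishes TSS shifts from splicing. Genes whose
  differential signal touches shared exons are deliberately left
  `AMBIGUOUS` rather than guessed.
* Gene matching between models and probe-set catalogs is by gene symbol.
* Patient pairing is ignored by the screen itself (fixed-effects ANOVA);
  pairing is used only in the dedicated paired analyses.
* No liftover, no trans-spliced or multi-chromosome genes, no de novo
  motif discovery, and no probe-level modeling.

## A minimal run

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 42)
gm  <- simulate_gene_models(cfg)
sim <- simulate_expression(gm$models, gm$probesets, cfg)
det <- run_detect(gm$models, gm$probesets, sim$expr, sim$sheet)
evaluate_calls(det$calls, sim$truth)
```

`run_detect()` logs the funnel (multi-TSS genes → with data → above
background → discovery → stringent → ALT_TSS), writes TSV reports and a
reproducibility manifest when `out_dir` is given, and returns the test
table, calls and splicing-index matrix for downstream isoform and motif
analyses.
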