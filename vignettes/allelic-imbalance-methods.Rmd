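---
title: "Quantifying allelic expression imbalance: models, decisions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allelic expression imbalance: models, decisions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeiquant)
```

## The problem

A disease-associated SNP that falls outside any coding change often acts as
a *cis*-regulatory variant: it changes how much mRNA one chromosome
produces relative to the other. Total-expression comparisons across
genotype groups are a blunt instrument for detecting this, because
between-individual variation in expression dwarfs the typical regulatory
effect. Allelic expression analysis sidesteps that variation: in an
individual heterozygous for a *transcript SNP* (a SNP inside the mRNA), the
two alleles' transcripts can be distinguished and quantified within the
same RNA sample, so each individual is their own control. A departure from
the 1:1 allelic ratio — allelic expression imbalance (AEI) — is direct
evidence of *cis*-regulation acting on that gene in that tissue.

`aeiquant` implements this analysis end to end for the study design it was
built around: joint-tissue samples from joint-replacement patients, assayed
at eight transcript SNPs across three genes (*BCL2L13*, *BID*, *MICAL3*)
in a region where an intronic marker SNP (rs2277831) shows association
with osteoarthritis. The package ships the published 33-patient
allelic-ratio table as a fixture ([`load_table2()`]) and reproduces its
summary statistics exactly ([`reproduce_table2()`]); the same functions run
on user-supplied replicate tables and on synthetic cohorts.

## The measurement model

Two platforms produce the raw allele-signal pairs:

* **Dual-probe qPCR (TaqMan)**: each allele has its own fluorescent probe
  (FAM/VIC); the readout is a pair of threshold cycles. The per-replicate
  allelic ratio is $2^{-\mathrm{Ct}_1} / 2^{-\mathrm{Ct}_2} =
  2^{\mathrm{Ct}_2 - \mathrm{Ct}_1}$, i.e. perfect doubling per cycle. The
  amplification efficiency is fixed at 2 and is a per-assay configuration
  (`efficiency` argument), never inferred from data.
* **Single-base primer extension (mass spectrometry)**: each allele
  produces a peak whose intensity is proportional to template amount; the
  per-replicate ratio is the direct intensity quotient.

The allele *orientation* — which allele is the numerator — is a property of
the assay, declared in the SNP panel (`snp_panel()`), and matches the
orientation in which the fixture's ratios are printed. It is never guessed
from the data.

Because probes and extension chemistry are not perfectly allele-balanced,
the raw cDNA ratio is biased even at true 1:1 expression. Genomic DNA from
the same heterozygous individual carries the two alleles at exactly 1:1
and therefore measures that assay bias. The headline statistic is the
**normalised allelic ratio**

$$\mathrm{NAR} = \frac{\overline{r}_{\mathrm{cDNA}}}{\overline{r}_{\mathrm{gDNA}}},$$

the mean of the cDNA per-replicate ratios over the mean of the gDNA
per-replicate ratios (four replicates per template in the emulated
design). The averaging rule is the arithmetic mean of raw ratios, the
plain reading of the formula above; because ratio averaging is asymmetric
around 1, a geometric (log-domain) mean is available via
`normalize_allelic_ratio(..., average = "geometric")`. The default stays
arithmetic for parity with the reproduced study.

## Calling imbalance

A measurement is called imbalanced when the fold difference between the
alleles reaches 20%: $\mathrm{NAR} \ge 1.20$ or $\mathrm{NAR} \le 0.80$,
**both bounds inclusive, on the raw ratio scale**. Two deliberate choices
sit here:

* *Inclusive bounds*: the reproduced table marks 0.80 and 1.22 as
  imbalanced but not 0.81–0.83 or 1.19, which pins the rule to closed
  intervals applied to the 2-decimal printed values.
* *Asymmetry*: the lower cutoff is 0.80, not $1/1.2 \approx 0.833$. This
  is what the reproduced calls imply. A symmetric alternative,
  $|\log_2 \mathrm{NAR}| \ge \log_2 1.2$, is available via
  `scale = "log"`; the two rules differ exactly on $[0.80, 1/1.2)$.

Patient-level aggregation is *any SNP, any tissue*: a patient is
AEI-positive for a gene if any of their measurements at any of the gene's
transcript SNPs, in any tissue, is imbalanced, and patients contributing
two tissues are counted once. This matches how the reproduced study counts
patients (heterozygote denominators 28/11/27, AEI numerators 12/3/19).

## Statistical tests

**Exact Mann–Whitney.** Each measurement's cDNA replicate ratios are
compared against the gDNA replicate ratios with a two-sided exact
Mann–Whitney test (`mann_whitney_exact()`). For pooled sizes up to 20 the
null distribution of U is enumerated over all $\binom{n+m}{n}$ assignments
of the observed pooled values; midranks make tie handling exact. The
two-sided p doubles the smaller one-sided tail and caps at 1 — conventions
differ here, so this is stated explicitly. Beyond 20 the normal
approximation with tie and continuity correction takes over.

A consequence worth stating: with four replicates per template the
smallest achievable two-sided exact p is $2/70 \approx 0.029$. Published
per-measurement values such as 0.004 or 0.001 cannot arise from a 4-vs-4
exact test; whatever comparison produced them (pooled references, a
different test) is not recoverable from the printed record, so the package
implements the test as specified and does not chase those values.

**Kruskal–Wallis stratification.** To ask whether AEI tracks the marker
SNP, each patient's measurements at a transcript SNP are reduced to one
value — the mean of $\log_2 \mathrm{NAR}$ across their tissues — grouped
by marker genotype (AA/GA/GG), and tested per SNP with the tie-corrected
Kruskal–Wallis statistic (`kruskal_wallis()`, chi-square p on $k-1$ df; an
exact/Monte-Carlo permutation option exists for small groups). Signed
ratios in the assay's declared orientation are used; no multiple-testing
adjustment is applied, matching the reproduced analysis. The chi-square
approximation at very small pooled sizes (n ≈ 9) is coarse — enumeration
shows typical deviations under 0.05 but excursions toward 0.1 — which is
why the permutation option exists.

**Total expression.** `delta_ct()` computes
$\Delta\mathrm{Ct} = \mathrm{Ct}_{\mathrm{test}} -
\overline{\mathrm{Ct}}_{\mathrm{controls}}$ (lower = more expression; the
value is analysed on the cycle scale, not $2^{-\Delta\mathrm{Ct}}$), and
`expression_vs_genotype()` regresses it on the additive dosage of the
marker's G allele with a two-sided t-test on the slope. The reproduced
study plots three genotype columns without naming a coding; additive
dosage is the standard eQTL convention and is the documented choice here.
Degenerate designs (one genotype group, n < 3) are rejected; a perfectly
flat zero-residual fit returns p = 1 rather than NaN.

## The synthetic cohort generator

No raw replicate signals are published for the real cohort, so
replicate-level behaviour is exercised on synthetic data whose parameters
are fixed once, as study conditions, not tuned:

* **Haplotype model** (`hap_model()`): three loci — a causal regulatory
  variant (`up`/`down`), the marker, and the transcript SNP — with the
  marker and transcript SNP each coupled to the causal variant by a
  requested $D'$ and conditionally independent given the causal allele.
  Cohorts are assembled under random mating (HWE); the emulated cohort is
  far too small to inform departures from it. The default emulates the
  strongest published LD scenario: transcript-allele frequency 0.32 (the
  panel's rs5992854 frequency), $D' = 1$ to the causal variant, and the
  marker placed on the causal variant at frequency 0.2504, which makes the
  marker–transcript $r^2 \approx 0.71$ — the printed $D'/r^2$ pair for
  that SNP. Those printed LD values derive from external reference panels
  and are treated as configuration inputs, not as quantities to estimate.
* **Effect model**: a haplotype carrying the causal `up` allele expresses
  at `fold_change` $F$ relative to 1; cDNA allele copy numbers follow the
  expression of the haplotype carrying each allele, gDNA is 1:1. With zero
  noise the normalised ratio is exactly the haplotype expression ratio.
* **Noise model**: additive Gaussian noise on the Ct scale
  (`ct_noise_sd`, default 0.25 cycles) — the standard qPCR error model —
  and multiplicative lognormal noise on peaks (`peak_cv`, default 0.15).
  No noise magnitudes are published; these defaults were chosen once so
  that the null-consistent spread of the reproduced table's ratios
  (roughly 0.83–1.19) is plausible, and they are assumptions, not
  estimates. The baseline Ct at unit copy number (`c0 = 30`) cancels in
  every ratio and exists only so emitted tables look like plate data.

All stochastic operations take explicit seeds and are bit-for-bit
reproducible; `run_power_study()` derives per-cell seeds from a master
seed by a documented linear-hash scheme so grid cells are independently
reproducible.

What the generator does *not* emulate: genotyping error, assay dropout,
between-tissue heterogeneity within a patient, isoform-specific
expression (the reproduced data show the same patient discordant across
transcript SNPs of one gene, plausibly because the SNPs sit in different
isoform subsets), and coalescent-scale haplotype diversity. Passing tests
on synthetic data therefore demonstrate correctness of the computations
and calibration of the tests under the stated model — not robustness to
those real-data features.

## Numerical and design notes

* Enumeration sizes: exact MW enumerates up to $\binom{20}{10} = 184756$
  assignments (well under a second); KW permutation enumerates fully up to
  a pooled size of 10, then switches to seeded Monte-Carlo.
* Tail comparisons in the exact tests use an absolute fuzz of $10^{-9}$ on
  the rank-sum scale so that midrank ties are not split by floating-point
  noise.
* All-tied inputs are handled explicitly: Kruskal–Wallis returns
  $H = 0, p = 1$ (the tie-corrected formula is 0/0 there), Mann–Whitney
  returns 1.
* Missing genotype cells are missing (`NA`), never zero; genotypes are
  stored unordered (`AG` ≡ `GA`).
* Calibration problem sizes: the null calibration runs 2,000 simulated
  4-vs-4 measurements and 2,000 null regressions; fold-change recovery
  averages 1,000 measurements per effect size; LD recovery samples 10,000
  haplotypes. These sizes give binomial/Monte-Carlo standard errors
  comfortably below the tolerances being checked.

## Known limitations

* The exact test with 4 replicates has very low resolution (p-floor 2/70);
  significance claims for single measurements in this design rest mostly
  on the threshold rule, and the power study quantifies exactly that.
* The Kruskal–Wallis stratification inherits the sign ambiguity of allelic
  ratios: the analysis uses signed $\log_2$ ratios in assay orientation,
  and a cis-effect whose phase is not consistently oriented relative to
  the marker can cancel within a genotype group.
* The fixture stores ratios exactly as printed (2 decimals); raw
  replicate-level signals for the real cohort were never published, so
  replicate-level claims are only testable synthetically.
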