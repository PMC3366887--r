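# aeiquant

Allelic expression imbalance (AEI) analysis for candidate *cis*-eQTL loci.

## What this is for

When a disease-associated SNP sits in non-coding sequence, the usual
hypothesis is that it regulates a nearby gene in *cis*. Comparing total
expression across genotype groups is noisy; a sharper instrument is
**allelic expression analysis**: in an individual heterozygous for a SNP
inside the mRNA, the two alleles' transcripts can be quantified within the
same sample, so each person is their own control. `aeiquant` implements
that analysis for replicate-level dual-probe qPCR (FAM/VIC Ct pairs) and
single-base primer-extension (peak intensity) data, for the analysts and
genetic epidemiologists who run such assays.

The core statistic is the **normalised allelic ratio** for one sample at
one transcript SNP,

```
NAR = mean(cDNA per-replicate allelic ratios) / mean(gDNA per-replicate allelic ratios)
```

where per-replicate ratios are `2^(Ct2 - Ct1)` for TaqMan and `peak1/peak2`
for extension assays, and the genomic DNA — physically 1:1 in a
heterozygote — cancels the assay's allele bias. A sample shows AEI when the
fold difference reaches 20% (`NAR >= 1.20` or `NAR <= 0.80`, inclusive).
Around this sit: an exact, tie-aware two-sided Mann-Whitney test of cDNA vs
gDNA replicate ratios; per-gene patient-level AEI summaries; Kruskal-Wallis
association of per-patient mean log2 ratios with a marker genotype; delta-Ct
total-expression regression on additive genotype dosage; and a synthetic
cohort generator (haplotype/LD model, per-haplotype fold change,
replicate-level Ct/peak noise) for calibration and power studies.

The package ships a transcription of the published 33-patient allelic
expression table from an osteoarthritis candidate-locus study of
*BCL2L13*, *BID* and *MICAL3* (marker SNP rs2277831) and reproduces its
summary values exactly — see `reproduce_table2()`.

## Worked example

```r
library(aeiquant)

## the packaged 35-row patient table (33 patients, 8 transcript SNPs)
t2 <- load_table2()
summarize_gene(t2$ratios, t2$samples, "MICAL3")
#> <gene_aei_summary> MICAL3: 19/27 patients AEI-positive/heterozygous, max ratio 5.47 (rs5992854, patient 38)
```

Nineteen of the 27 patients heterozygous for a *MICAL3* transcript SNP show
AEI at the 20% threshold; the largest imbalance is a 5.47-fold excess of
one allele, at rs5992854 in patient 38.

```r
strat <- stratify_by_marker(t2$ratios, t2$samples)
strat[strat$snp_id == "rs5992854", ]
#>     snp_id n_AA n_GA n_GG          h   p_value
#>  rs5992854    5   10    0 0.01502683 0.9024365
```

Despite widespread AEI, per-patient mean log2 ratios at rs5992854 show no
association with the marker genotype (Kruskal-Wallis p = 0.90): the
imbalance is real but not tagged by rs2277831.

Replicate-level quantification from raw signals:

```r
gdna <- replicate_set("pt38", "rs5992854", "gDNA", "taqman",
                      signal_1 = c(26.1, 26.0, 26.2, 25.9),
                      signal_2 = c(26.0, 26.1, 26.0, 26.1))
cdna <- replicate_set("pt38", "rs5992854", "cDNA", "taqman",
                      signal_1 = c(23.6, 23.5, 23.7, 23.4),
                      signal_2 = c(26.0, 26.1, 25.9, 26.2))
nar <- normalize_allelic_ratio(cdna, gdna)
nar
#> <normalized_allelic_ratio> pt38 rs5992854: 5.691 (4 cDNA / 4 gDNA replicates)
call_aei(nar$value)
#> [1] TRUE
mann_whitney_exact(nar$cdna_ratios, nar$gdna_ratios)
#> [1] 0.02857143
```

The p-value is 2/70 — the smallest value a 4-vs-4 exact test can produce,
a design limit the methods vignette discusses.

A command-line wrapper is provided at `inst/cli/aei.R`
(`Rscript aei.R reproduce-table2`, `quantify`, `call`, `deltact`,
`associate`, `simulate`); it exits 0 iff the packaged reproduction passes,
so it can serve as a CI gate.

## Documentation

The methods vignette (`vignettes/allelic-imbalance-methods.Rmd`) describes
the measurement model, the inclusive asymmetric threshold rule, the exact
tests and their small-sample limits, the synthetic-data model and its
assumptions, and known limitations.
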