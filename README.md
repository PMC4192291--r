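# ldpanel

Design and evaluation of low-density SNP panels for genotype imputation in
pedigreed livestock populations.

## What problem this solves

Genomic selection needs dense SNP genotypes, but dense chips are too
expensive to run on every animal. The standard compromise is to genotype
most animals on a low-density (LD) chip and impute the missing high-density
(HD) genotypes from a reference population — which is only safe if the
imputation is accurate for the chip, method and population at hand. The
canonical way to measure that is a masking experiment: hide every off-chip
genotype of animals whose HD genotypes are actually known, impute them
back, and score the result. This package implements that evaluation
framework end-to-end for cattle-style populations (it was built with
indicine populations such as Nelore in mind, where short-range linkage
disequilibrium is comparatively weak):

* **Quality control** of HD genotypes: non-autosomal and
  duplicate-position markers, Hardy-Weinberg z-test (p ≤ 1e-5), MAF < 0.02,
  SNP call rate < 0.98 with GenCall-score masking at 0.70, individual call
  rate ≤ 0.90 — with exact per-filter exclusion accounting.
* **Chip design** by windowed selection over the post-QC map: one SNP per
  window of *k* consecutive markers, chosen by even spacing, maximum MAF,
  maximum average window r², or the MAF × r² product; plus add-on designs
  that extend a commercial base chip.
* **Masking scenarios** with strict truth/masked separation, plus baseline
  imputers (reference mode; nearest reference animal per genomic window)
  and exchange IO for external imputation tools.
* **Accuracy metrics**: PERC (percent concordance) and CORR (dosage
  correlation), per individual and per SNP, over imputed SNPs only;
  genome-window scans flagging regions with mean CORR < 0.60.
* **Relatedness**: the VanRaden genomic relationship matrix
  G = MM′ / Σ2pᵢ(1−pᵢ), per-animal Maxr / Mean10 summaries against the
  reference set, and regression of accuracy on Mean10.
* **A synthetic study generator**: multi-generation pedigree, blockwise-LD
  founder haplotypes, gene dropping with recombination, call noise — so the
  entire pipeline is testable with no external data.

Formats: PLINK PED/MAP and BED/BIM/FAM, VCF (GT), plain-text chip
manifests, 5-column pedigrees, and a TSV sidecar for per-call quality
scores.

## Worked example

Simulate a study population, run QC, design a ~15K-style chip, mask the
validation dams down to it, impute with the nearest-neighbour baseline and
score:

```r
library(ldpanel)

cfg <- sim_config(seed = 1)
fx  <- make_study_fixture(cfg)
fx
#> synthetic study fixture: 15000 SNPs on 10 chromosomes; 200 reference sires,
#>   50 young sires, 100 dams (pedigree of 562)

qc <- run_qc(fx$geno, fx$map, qc_thresholds(), reference_ids = fx$reference_ids)
qc$report
#> SNP quality control
#>   input SNPs: 15000
#>   excluded (non_autosomal): 0
#>   excluded (duplicate_position): 0
#>   excluded (hwe): 0
#>   excluded (maf): 66
#>   excluded (snp_call_rate): 17
#>   surviving SNPs: 14917
#>   excluded individuals: 0
#>   surviving individuals: 350

chip <- design_chip(qc$geno, qc$map, k = 29, "max_maf_times_r2",
                    reference_ids = fx$reference_ids)
chip
#> chip_def 'custom_k29_max_maf_times_r2': 519 SNPs

sc  <- mask_to_chip(qc$geno, qc$map, chip, fx$reference_ids, fx$dam_ids)
res <- score_scenario(sc, impute_nn_window(sc, window_snps = 50))
res
#> imputation accuracy, chip 'custom_k29_max_maf_times_r2': 14398 SNPs to impute (96.5%)
#>   by individual, PERC: 77.4116 (1.5819)
#>   by individual, CORR: 0.7576 (0.0231)
#>   by snp, PERC: 77.4129 (19.0483)
#>   by snp, CORR: 0.6978 (0.3075)
#>   undefined CORR excluded: 0 individual(s), 613 SNP(s)
```

(Exact accuracy values vary with the seed; the baseline imputer is a test
instrument, far below production imputation software.) The per-individual
accuracies rise with each animal's genomic relatedness to the reference
set:

```r
g   <- vanraden_grm(qc$geno)
rel <- relatedness_summary(g, fx$reference_ids, fx$dam_ids)
regress_accuracy_on_relatedness(res, rel, degree = 1)
#> CORR ~ Mean10 polynomial fit (degree 1)
#>   coefficients: 0.7314, 0.1617
#>   R-squared: 0.2070 on 100 individuals
```

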