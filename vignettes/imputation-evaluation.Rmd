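---
title: "Evaluating genotype imputation with masked low-density panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genotype imputation with masked low-density panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dense SNP chips are too expensive to run on every animal in a beef cattle
breeding program, so most animals are genotyped on a low-density (LD) chip
and their remaining high-density (HD) genotypes are imputed from a reference
population genotyped at full density. Whether that is safe depends on the
imputation accuracy achievable with a given LD chip, imputation method and
population structure — a question usually answered by a masking experiment:
take animals with complete HD genotypes, hide every genotype not on the
candidate LD chip, impute the hidden ones back, and compare.

`ldpanel` implements that whole evaluation loop for indicine-style cattle
populations (the motivating case is the Nelore breed, where linkage
disequilibrium at short distances is weaker than in taurine cattle):

1. quality control of HD genotypes,
2. design of customized LD chips by windowed SNP selection,
3. construction of masked validation scenarios,
4. accuracy metrics per individual and per SNP,
5. genomic relatedness statistics and their link to accuracy,
6. genome-window scans for poorly imputed regions, and
7. a pedigree gene-dropping simulator so that every stage is testable
   without access to proprietary genotypes.

## Quality control

`run_qc()` applies five SNP filters in a fixed order, attributing each
excluded SNP to the first filter it violates:

1. non-autosomal SNPs (chromosomes outside `1..n_autosomes`; 29 for cattle);
2. duplicate genomic coordinates — only the replicates are removed, the
   first record at each (chromosome, position) is kept;
3. Hardy-Weinberg equilibrium z-test p-value at or below `1e-5`;
4. minor allele frequency below 0.02;
5. per-SNP call rate below 0.98, where calls with a quality (GenCall-type)
   score below 0.70 count as missing.

Afterwards individuals with a call rate at or below 0.90 over the surviving
SNPs are dropped. SNP statistics are computed on the reference individuals
only and the exclusion list is applied to everyone, which harmonizes the
validation matrices automatically.

Two choices here were genuinely open:

* **Form of the HWE test.** The test is the normal approximation on the
  heterozygote proportion, `z = (h_obs - h_exp) / sqrt(h_exp (1 - h_exp) / n)`
  with `h_exp = 2p(1-p)`, two-sided. It is the simplest statistic that is a
  z-test; an exact test would change borderline calls only.
* **Quality masking in the individual filter.** Quality-score masking is
  specified for the per-SNP call rate; we apply the same masking in the
  per-individual call rate for consistency, since a call unreliable for one
  statistic is unreliable for the other.

A subtlety worth documenting: exclusion *counts* depend on filter order
(first attribution), but the surviving set must not. `run_qc()` therefore
evaluates every filter's violation set on the full input — including the
keep-first duplicate rule — and a SNP survives only if it violates nothing.
Applying filters sequentially instead would let a kept duplicate that fails
a later filter resurrect its replicate, making survivors order-dependent.

## Designing low-density chips

`partition_windows()` cuts the post-QC map into consecutive windows of `k`
markers per chromosome; windows never span chromosomes and the remainder
(fewer than `k` markers) forms a final short window. The designed chip takes
exactly one SNP per window, so its size is the sum of `ceiling(m_c / k)`
over chromosomes — with 439,595 post-QC markers and `k = 29` that is the
~15 K regime of commercial practice.

Four selection criteria are implemented (`design_chip()`): the last marker
of each window (`even_last`, pure even spacing), the highest minor allele
frequency (`max_maf`), the highest average linkage disequilibrium r² with
the other window members (`max_avg_r2`), and the highest MAF × average-r²
product (`max_maf_times_r2`). Criterion statistics are computed on the
reference individuals, mirroring QC. Ties break to the lowest bp position,
and a window where a criterion is undefined for every member (for example
all pairwise r² undefined) falls back to even spacing — both rules exist
purely to make designs deterministic and reproducible.

`design_addon_chip()` implements the add-on concept: a commercial base chip
(such as a 7 K panel) is kept whole and one SNP per window is added, with
the windows partitioned over the map *excluding* base-chip SNPs. That
exclusion is a design decision: it guarantees the exact size arithmetic
`|result| = |base| + number of windows` and never wastes an added SNP on a
marker the base chip already carries. Window sizes of 39, 25, 16 and 9
markers span the ~18 K to ~55 K add-on range.

## Masking scenarios and baseline imputers

`mask_to_chip()` hides every off-chip genotype of the validation animals
while reference animals stay complete; the true matrix is retained only for
scoring. Production imputation engines (family/population haplotype
methods) are exchanged with via `export_for_tool()` / `import_imputed()`
and are deliberately out of the package's algorithmic scope.

Two built-in baselines exist so the evaluation stack can be exercised
end-to-end and respond to the factors the evaluation is about:

* `impute_mode()` fills with the most frequent reference genotype per SNP
  (ties to the lower dosage) — a floor that ignores both LD and pedigree;
* `impute_nn_window()` finds, per validation animal and per window of
  `window_snps` markers, the reference animal with the smallest Hamming
  distance on the window's chip SNPs and copies its genotypes into the
  masked cells (ties to the first reference animal in id order; windows
  with no chip SNP fall back to the modal fill, and any residual gap — for
  example when the donor itself has a missing call — is modal-filled so no
  missing genotype remains). Because matching improves with chip density
  and with the presence of close relatives in the reference, this baseline
  reproduces the qualitative phenomena of interest without re-implementing
  any production algorithm.

These baselines are the package's own test instruments; they are not
re-implementations of any published imputation method, and absolute
accuracies obtained with them are not comparable to production tools.

## Accuracy metrics

For imputed (masked) cells only, `score_scenario()` computes

* **PERC** — the percentage of imputed genotypes identical to the hidden
  truth, and
* **CORR** — the Pearson correlation between imputed and true dosages
  (0/1/2 copies of the B allele),

each both per individual (all of that animal's masked cells genome-wide)
and per SNP (across validation animals). CORR penalizes a single-allele
error less than PERC and is undefined when either vector is constant; such
cases are recorded as `NA`, excluded from summaries, and counted. Cells
whose *true* genotype is missing are never scored. Summary tables report
means and sample (n−1) standard deviations.

`regress_accuracy_on_relatedness()` quantifies the relatedness effect by
OLS regression of per-individual CORR on Mean10 (below), at degree 1 or 2 —
both degrees are exposed because the curvature of the relationship is an
empirical question that differs between sparse and dense chips.

## Genomic relatedness

`vanraden_grm()` builds `G = M M' / sum(2 p_i (1 - p_i))` with M the
column-centered dosage matrix (`dosage - 2 p_i`). Allele frequencies are
computed from all genotyped individuals (reference plus validation) unless
supplied: a single consistent frequency set keeps the centering identical
across animals. Residual missing dosages are mean-imputed (`2 p_i`), which
contributes exactly zero after centering. `relatedness_summary()` reports,
per validation animal, `maxr` (largest relationship with any reference
animal) and `mean10` (mean of the 10 largest, or all of them when the
reference holds fewer than 10) — the two statistics that predict
imputation accuracy in practice.

## Window scans

`window_accuracy_scan()` averages per-SNP CORR in windows of about 50
consecutive markers and flags windows whose mean falls below 0.60 — the
operational definition of a poorly imputed region. Each window also reports
its mean MAF and mean pairwise r², because the diagnostic signature of such
regions is locally erratic LD (often indicating mapping or assembly
problems); the flagged list is the region report a GWAS analyst would use
as an exclusion mask.

## The synthetic study generator

The generator (`sim_config()`, `make_study_fixture()`) emulates the
statistical structure the evaluation assumes, at desk scale:

* **Pedigree.** Three generations from a closed founder nucleus: the
  pre-validation generations supply 200 reference sires, the last
  generation supplies 50 young sires (sire drawn from the most recent
  reference sires, dam from the most recent breeding females) and 100
  validation dams (sire drawn from the oldest reference generation, or
  recorded unknown for 38% of them; maternal parent outside the recorded
  pedigree). Birth years follow generation index, so the "sires born before
  the cutoff year" split rule operates naturally. This produces the
  relatedness gradient the study design needs — young sires closer to the
  reference than dams — with default Mean10 values near 0.20 versus 0.14.
* **Genome.** 15,000 SNPs on 10 chromosomes of 3 Morgans. The genome size
  matters more than it may appear: realized relationships scatter around
  pedigree expectations with a variance inversely proportional to total map
  length (Mendelian sampling), and a toy genome of a few Morgans makes the
  genomic-vs-pedigree comparison irrecoverably noisy no matter how many
  markers are typed. Thirty Morgans is the smallest genome at which the
  GRM recovers pedigree ranking cleanly while staying cheap to simulate.
* **LD.** Founder haplotypes follow a blockwise first-order Markov model:
  blocks of geometric mean length 50 markers; within a block each adjacent
  allele state is copied with probability 0.985, otherwise resampled from
  the SNP's frequency (drawn uniformly on [0.05, 0.95]). Copying produces
  few distinct haplotypes per block — the low local haplotype diversity
  that makes population imputation work at all — while block boundaries
  and the resampling events make LD decay with marker distance. An
  optional `low_ld_region` forces the copy probability to zero over a
  marker range, planting the erratic-LD signature that the window scan is
  designed to detect.
* **Gene dropping.** Non-founders inherit one recombined gamete per parent
  (Poisson crossovers, uniform positions); an unknown parent contributes a
  gamete drawn fresh from the founder distribution, so "unknown sire"
  means genuinely unrelated, not merely unrecorded.
* **Noise.** 0.2% of calls are set missing and 0.2% receive a quality
  score below 0.70 (the rest uniform on [0.70, 1]), enough to exercise the
  call-rate and quality-masking filters without dominating the data.

What the generator does **not** emulate: real allele-frequency spectra
(no rare-variant tail), coalescent LD (block boundaries are sharp rather
than smoothly decaying), selection, assortative mating, genotyping-batch
artifacts, and real chip ascertainment. Passing tests on this fixture
therefore demonstrate that the *pipeline machinery* behaves correctly and
that the *qualitative* phenomena — accuracy rising with density, accuracy
rising with relatedness and more steeply for sparse chips, low-LD regions
surfacing in the window scan — emerge as they do in real data; they say
nothing about the absolute accuracy any real chip would achieve.

### Scope of the pedigree-vs-GRM check

The package's recovery check correlates GRM off-diagonals with
pedigree-expected additive relationships over the animals whose recorded
pedigree is complete (reference and young sires). Validation dams are
excluded on purpose: 38% have an unknown sire and all have an unrecorded
maternal side, so their pedigree expectation understates their true
relatedness by construction, and a rank correlation over all pairs mostly
measures that recording gap (it plateaus near 0.6 even for a noise-free
genomic matrix). Restricting to complete pedigrees makes the check a true
calibration of the GRM rather than of the pedigree's completeness.

## Numerical conventions

* Missing genotype calls are `NA` throughout; dosage 0 is never conflated
  with missing. PLINK text encodes missing as `0 0`, VCF as `./.`.
* Coordinates are 1-based bp; all window logic runs on post-QC marker
  order per chromosome, not bp distance.
* Allele B (the counted allele) is the second allele of the map — BIM's
  A2, VCF's ALT. PED/MAP carries no allele columns, so on reading, the two
  observed labels are ordered lexicographically to keep round trips
  deterministic.
* Undefined r² or CORR (constant vectors, too few complete pairs) is `NA`,
  excluded from averages, and counted where it matters.
* Every simulation entry point reseeds deterministically from
  `config$seed`, so fixtures are bit-reproducible and distinct stages can
  be re-run standalone.

## Problem sizes

The shipped tests run the full pipeline on a 15,000-SNP, 350-animal
fixture (the default configuration above) plus many hand-sized fixtures;
the whole suite completes in a few minutes on one core. The acceptance
script (`scripts/acceptance.R`) regenerates the fixture from a
command-line seed and recomputes every headline quantity from scratch in
roughly two minutes.

## Known limitations

* The baseline imputers cap well below production engines (no haplotype
  phasing, no iterative refinement); they are measurement instruments, not
  methods.
* The HWE filter uses a normal approximation; at very small reference
  sizes an exact test would be preferable.
* Chip-count arithmetic for published commercial chips is reproduced from
  their published post-QC counts; the proprietary genotypes behind those
  counts are not available, so the published accuracy values themselves
  are outside what can be recomputed.
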