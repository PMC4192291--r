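test_that("generators are deterministic in the seed and sensitive to it", {
  a <- make_study_fixture(small_sim_config(seed = 5))
  b <- make_study_fixture(small_sim_config(seed = 5))
  c <- make_study_fixture(small_sim_config(seed = 6))
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$geno$quality, b$geno$quality)
  expect_identical(a$map, b$map)
  expect_identical(as.data.frame(a$pedigree), as.data.frame(b$pedigree))
  expect_false(identical(a$geno$dosage, c$geno$dosage))
})

test_that("founder haplotypes realize the requested LD structure", {
  cfg0 <- small_sim_config(within_block_corr = 0)
  pool0 <- simulate_founder_haplotypes(cfg0)
  cfg9 <- small_sim_config(within_block_corr = 0.95)
  pool9 <- simulate_founder_haplotypes(cfg9)
  adj_r2 <- function(pool, pairs) {
    vapply(pairs, function(j) {
      r <- ld_r2(pool$hap[, j], pool$hap[, j + 1])
      if (is.na(r)) NA_real_ else r
    }, numeric(1))
  }
  within <- which(!pool9$block_start[-1])          # j, j+1 in same block
  across <- which(pool9$block_start[-1])           # block boundary pairs
  r_within <- mean(adj_r2(pool9, within), na.rm = TRUE)
  r_across <- mean(adj_r2(pool9, across), na.rm = TRUE)
  expect_gt(r_within, r_across)
  # no-LD limit: adjacent r2 indistinguishable from the independence null,
  # whose mean for n haplotypes is about 1/(n-1)
  r_null <- mean(adj_r2(pool0, seq_len(cfg0$n_snps - 1)), na.rm = TRUE)
  n_hap <- nrow(pool0$hap)
  expect_lt(abs(r_null - 1 / (n_hap - 1)), 0.05)
})

test_that("LD decays with marker distance inside the simulated genome", {
  fx <- small_fixture()
  d <- fx$geno$dosage[fx$reference_ids, ]
  lag_r2 <- function(l) {
    js <- seq(1, ncol(d) - l, by = 3)
    mean(vapply(js, function(j) ld_r2(d[, j], d[, j + l]), numeric(1)),
         na.rm = TRUE)
  }
  expect_gt(lag_r2(1), lag_r2(5))
  expect_gt(lag_r2(5), lag_r2(20))
})

test_that("pedigree structure carries the designed relatedness gradient", {
  ped <- simulate_pedigree(small_sim_config())
  roles <- attr(ped, "roles")
  expect_equal(length(roles$reference_ids), 30)
  expect_equal(length(roles$young_sire_ids), 8)
  expect_equal(length(roles$dam_ids), 12)
  # construction is generation-ordered, so pedigree() accepted it (acyclic);
  # parents precede offspring in the returned order
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  parent_first <- !is.na(ped$sire) & idx[ped$sire] < seq_len(nrow(ped))
  expect_true(all(parent_first | is.na(ped$sire)))
  # pedigree-expected relatedness: young sires above validation dams
  a <- pedigree_additive_matrix(ped)
  mean_rel <- function(v) mean(a[v, roles$reference_ids])
  expect_gt(mean_rel(roles$young_sire_ids), mean_rel(roles$dam_ids))
  # a minimal two-generation pedigree has correct links
  tiny <- simulate_pedigree(small_sim_config(n_founders = 1, n_ref_sires = 1,
                                             n_females_per_gen = 1,
                                             n_young_sires = 1, n_dams = 1))
  ys <- tiny[tiny$id == attr(tiny, "roles")$young_sire_ids, ]
  expect_equal(ys$sire, attr(tiny, "roles")$reference_ids)
})

test_that("gene dropping is exact in the no-recombination homozygous limit", {
  cfg <- small_sim_config(chrom_length_morgans = 0, n_snps = 50)
  pool <- simulate_founder_haplotypes(cfg)
  # make every founder homozygous: offspring dosages become fully predictable
  odd <- seq(1, nrow(pool$hap), by = 2)
  pool$hap[odd + 1, ] <- pool$hap[odd, ]
  ped <- pedigree(c("f1", "f2", "kid"), c(NA, NA, "f1"), c(NA, NA, "f2"),
                  c(2000, 2000, 2003), c("M", "F", "M"))
  out <- gene_drop(ped, pool, cfg)
  expected <- pool$hap[1, ] + pool$hap[3, ]   # one haplotype per parent
  expect_equal(unname(out$geno$dosage["kid", ]), expected)
  expect_false(anyNA(out$geno$dosage))
})

test_that("realized genomic relationships track pedigree expectations", {
  # a broad founder base keeps sample allele frequencies close to the base
  # population's, avoiding the centering bias a structured sample induces
  cfg <- small_sim_config(seed = 9, n_founders = 40, n_ref_sires = 60,
                          n_females_per_gen = 40, n_young_sires = 25,
                          n_dams = 25, n_snps = 2000, n_chromosomes = 5,
                          chrom_length_morgans = 3, offspring_per_mating = 2)
  fx <- make_study_fixture(cfg)
  g <- vanraden_grm(fx$geno)
  ped <- fx$pedigree
  a <- pedigree_additive_matrix(ped, ids = g$ids)
  # parent-offspring pairs among genotyped animals average near 0.5
  po <- which(a == 0.5 & upper.tri(a), arr.ind = TRUE)
  expect_gt(nrow(po), 5)
  expect_lt(abs(mean(g$values[po]) - 0.5), 0.05)
  # full sibs (expected 0.5 with both parents shared) vs half sibs (0.25)
  ids <- rownames(a)
  sires <- ped$sire[match(ids, ped$id)]
  dams <- ped$dam[match(ids, ped$id)]
  pairs <- which(upper.tri(a), arr.ind = TRUE)
  same_s <- !is.na(sires[pairs[, 1]]) & !is.na(sires[pairs[, 2]]) &
    sires[pairs[, 1]] == sires[pairs[, 2]]
  same_d <- !is.na(dams[pairs[, 1]]) & !is.na(dams[pairs[, 2]]) &
    dams[pairs[, 1]] == dams[pairs[, 2]]
  full_sib <- same_s & same_d
  half_sib <- xor(same_s, same_d)
  expect_gt(sum(full_sib), 2)
  expect_gt(mean(g$values[pairs[full_sib, , drop = FALSE]]),
            mean(g$values[pairs[half_sib, , drop = FALSE]]))
})

test_that("noise layer produces the configured missingness and quality mix", {
  fx0 <- make_study_fixture(small_sim_config(missing_rate = 0,
                                             low_quality_rate = 0))
  expect_false(anyNA(fx0$geno$dosage))
  expect_true(all(fx0$geno$quality >= 0.70))
  cfg <- small_sim_config(missing_rate = 0.05, low_quality_rate = 0.1)
  fx <- make_study_fixture(cfg)
  ncell <- length(fx$geno$dosage)
  frac_missing <- sum(is.na(fx$geno$dosage)) / ncell
  expect_lt(abs(frac_missing - 0.05), 3 * sqrt(0.05 * 0.95 / ncell))
  frac_lowq <- sum(fx$geno$quality < 0.70) / ncell
  expect_lt(abs(frac_lowq - 0.1), 3 * sqrt(0.1 * 0.9 / ncell))
  # a planted half-missing SNP is removed by default QC
  d <- fx0$geno$dosage
  d[seq(1, nrow(d), by = 2), 10] <- NA
  out <- run_qc(geno_matrix(d), fx0$map, qc_thresholds())
  expect_false(colnames(fx0$geno$dosage)[10] %in%
                 out$report$surviving_snp_ids)
})

test_that("the realized MAF spectrum respects the configured floor", {
  fx <- small_fixture()
  mafs <- apply(fx$geno$dosage, 2, snp_maf)
  expect_lt(mean(mafs < 0.02), 0.05)
})

test_that("study fixtures round trip through the exchange formats", {
  dir <- withr::local_tempdir()
  cfg <- small_sim_config(n_snps = 60)
  fx <- make_study_fixture(cfg, dir = dir)
  back <- read_genotypes(file.path(dir, "geno"), "ped",
                         quality_file = file.path(dir, "quality.tsv"))
  expect_identical(unname(back$geno$dosage), unname(fx$geno$dosage))
  expect_equal(unname(back$geno$quality), unname(fx$geno$quality),
               tolerance = 1e-12)
  ped <- read_pedigree_file(file.path(dir, "pedigree.txt"))
  expect_setequal(ped$id, fx$pedigree$id)
  expect_equal(readLines(file.path(dir, "reference_ids.txt")),
               fx$reference_ids)
})
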