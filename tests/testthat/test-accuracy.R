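test_that("PERC and CORR match independent hand computations", {
  expect_equal(imputation_perc(c(0, 1, 2, 1), c(0, 1, 2, 1)), 100)
  expect_equal(imputation_perc(c(0, 1, 2, 1), c(0, 1, 2, 2)), 75)
  expect_equal(imputation_perc(c(1, 2, 0), c(0, 1, 2)), 0)
  expect_error(imputation_perc(c(0, 1), c(NA, NA)), "no scored")
  expect_equal(imputation_corr(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  # cov 2, sums of squares 2 and 2.75: r = 2 / sqrt(5.5)
  expect_equal(imputation_corr(c(0, 1, 2, 1), c(0, 1, 2, 2)), 2 / sqrt(5.5),
               tolerance = 1e-12)
  expect_equal(round(imputation_corr(c(0, 1, 2, 1), c(0, 1, 2, 2)), 4),
               0.8528)
  expect_true(is.na(imputation_corr(c(1, 1, 1, 1), c(0, 1, 2, 0))))
})

test_that("PERC 100 implies CORR 1, but not conversely", {
  set.seed(41)
  for (rep in 1:10) {
    obs <- sample(0:2, 20, TRUE)
    if (sd(obs) == 0) next
    expect_equal(imputation_perc(obs, obs), 100)
    expect_equal(imputation_corr(obs, obs), 1)
  }
  # a shifted dosage vector: perfect correlation, zero concordance
  obs <- c(0, 1, 0, 1, 0, 1)
  imp <- c(1, 2, 1, 2, 1, 2)
  expect_equal(imputation_corr(imp, obs), 1)
  expect_equal(imputation_perc(imp, obs), 0)
})

test_that("perfect imputation scores 100 / 1 with zero dispersion", {
  set.seed(42)
  tg <- toy_geno(setNames(lapply(1:6, function(i) sample(0:2, 20, TRUE)),
                          c("r1", "r2", "r3", "v1", "v2", "v3")))
  chip <- chip_def("c", tg$map$snp_id[seq(5, 20, by = 5)])
  sc <- mask_to_chip(tg$geno, tg$map, chip, paste0("r", 1:3),
                     paste0("v", 1:3))
  res <- score_scenario(sc, tg$geno)   # impute with the truth itself
  expect_true(all(res$per_individual$perc == 100))
  corr <- res$per_individual$corr
  expect_true(all(abs(corr - 1) < 1e-12 | is.na(corr)))
  s <- res$summary
  expect_equal(s$mean[s$level == "individual" & s$metric == "perc"], 100)
  expect_equal(s$sd[s$level == "individual" & s$metric == "perc"], 0)
  expect_equal(res$n_imputed_snps, 16)
  expect_equal(res$frac_imputed_snps, 16 / 20)
})

test_that("a 3-animal toy scenario matches cell-by-cell hand scoring", {
  truth <- rbind(r1 = c(0, 1, 2, 1, 0, 2),
                 v1 = c(0, 1, 2, 2, 1, 0),
                 v2 = c(2, 1, 0, 0, 1, 2))
  colnames(truth) <- paste0("s", 1:6)
  map <- marker_map(colnames(truth), 1, 1:6 * 10)
  chip <- chip_def("c", c("s1", "s4"))       # imputed SNPs: s2 s3 s5 s6
  sc <- mask_to_chip(geno_matrix(truth), map, chip, "r1", c("v1", "v2"))
  imputed <- truth
  imputed["v1", c("s2", "s3", "s5", "s6")] <- c(1, 0, 1, 1)  # 2 of 4 right
  imputed["v2", c("s2", "s3", "s5", "s6")] <- c(1, 0, 1, 2)  # all 4 right
  res <- score_scenario(sc, geno_matrix(imputed))
  expect_equal(res$per_individual$perc, c(50, 100))
  expect_equal(res$per_individual$corr[1],
               cor(c(1, 0, 1, 1), c(1, 2, 1, 0)))
  expect_equal(res$per_individual$corr[2], 1)
  # per-SNP scores across the two validation animals
  ps <- res$per_snp
  expect_setequal(ps$snp_id, c("s2", "s3", "s5", "s6"))
  expect_equal(ps$perc[ps$snp_id == "s2"], 100)
  expect_equal(ps$perc[ps$snp_id == "s3"], 50)
  # s2 imputed (1,1) vs observed (1,1): constant -> CORR undefined
  expect_true(is.na(ps$corr[ps$snp_id == "s2"]))
  expect_equal(res$n_undefined_corr[["snp"]],
               sum(is.na(ps$corr)))
})

test_that("per-individual results are permutation-equivariant", {
  set.seed(43)
  tg <- toy_geno(setNames(lapply(1:8, function(i) sample(0:2, 30, TRUE)),
                          c(paste0("r", 1:4), paste0("v", 1:4))))
  chip <- chip_def("c", tg$map$snp_id[seq(3, 30, 3)])
  refs <- paste0("r", 1:4)
  sc1 <- mask_to_chip(tg$geno, tg$map, chip, refs, c("v1", "v2", "v3", "v4"))
  sc2 <- mask_to_chip(tg$geno, tg$map, chip, refs, c("v3", "v1", "v4", "v2"))
  imp <- impute_mode(sc1)
  r1 <- score_scenario(sc1, imp)
  r2 <- score_scenario(sc2, imp)
  ord <- match(r1$per_individual$id, r2$per_individual$id)
  expect_equal(r2$per_individual$perc[ord], r1$per_individual$perc)
  expect_equal(r2$per_individual$corr[ord], r1$per_individual$corr)
  expect_equal(r2$summary, r1$summary)
})

test_that("regression on relatedness recovers exact fits and errors", {
  res <- structure(list(per_individual = data.frame(
    id = sprintf("v%02d", 1:12),
    perc = 90, corr = 0.5 + 0.8 * seq(0.05, 0.3, length.out = 12),
    stringsAsFactors = FALSE
  )), class = "accuracy_result")
  rel <- data.frame(id = sprintf("v%02d", 1:12),
                    maxr = 0.5, mean10 = seq(0.05, 0.3, length.out = 12))
  class(rel) <- c("relatedness_summary", "data.frame")
  fit <- regress_accuracy_on_relatedness(res, rel, 1)
  expect_equal(fit$coefficients, c(0.5, 0.8), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # constant accuracy: zero slope
  res$per_individual$corr <- 0.9
  flat <- regress_accuracy_on_relatedness(res, rel, 1)
  expect_equal(flat$coefficients[2], 0, tolerance = 1e-10)
  # quadratic recovery at degree 2
  res$per_individual$corr <- 0.2 + 1.5 * rel$mean10 - 2 * rel$mean10^2
  quad <- regress_accuracy_on_relatedness(res, rel, 2)
  expect_equal(quad$coefficients, c(0.2, 1.5, -2), tolerance = 1e-8)
  # insufficient points
  res$per_individual <- res$per_individual[1:2, ]
  expect_error(regress_accuracy_on_relatedness(res, rel, 1), "at least")
})

test_that("window scan flags low-accuracy windows and only those", {
  set.seed(44)
  tg <- toy_geno(setNames(lapply(1:10, function(i) sample(0:2, 60, TRUE)),
                          paste0("i", 1:10)))
  per_snp <- data.frame(snp_id = tg$map$snp_id, corr = 1)
  scan <- window_accuracy_scan(per_snp, tg$map, tg$geno, window_snps = 20)
  expect_equal(nrow(scan), 3)
  expect_false(any(scan$flagged))
  # plant a poor window: mean CORR 0.39 < 0.60
  per_snp$corr[21:40] <- 0.39
  scan2 <- window_accuracy_scan(per_snp, tg$map, tg$geno, window_snps = 20)
  expect_equal(scan2$flagged, c(FALSE, TRUE, FALSE))
  expect_equal(scan2$mean_corr[2], 0.39)
  expect_equal(scan2$n_snps, c(20, 20, 20))
  # report carries window MAF and r2 summaries
  expect_true(all(is.finite(scan2$mean_maf)))
  expect_true(all(scan2$mean_r2 >= 0 & scan2$mean_r2 <= 1, na.rm = TRUE))
})
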