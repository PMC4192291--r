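make_ped <- function(n_old, n_young, n_dams) {
  n <- n_old + n_young + n_dams
  pedigree(
    id = c(sprintf("o%02d", seq_len(n_old)), sprintf("y%02d", seq_len(n_young)),
           sprintf("d%02d", seq_len(n_dams))),
    sire = NA, dam = NA,
    birth_year = c(rep(2000, n_old), rep(2006, n_young), rep(2006, n_dams)),
    sex = c(rep("M", n_old + n_young), rep("F", n_dams))
  )
}

test_that("reference/validation splits follow the birth-year and sex rules", {
  ped <- make_ped(20, 5, 10)
  sires <- split_by_rule(ped, "sires_before_year", 2005)
  expect_equal(length(sires$reference_ids), 20)
  expect_equal(length(sires$validation_ids), 5)
  dams <- split_by_rule(ped, "dams", 2005)
  expect_equal(length(dams$reference_ids), 20)
  expect_equal(length(dams$validation_ids), 10)
  # cutoff splits a run of birth years as expected
  ped5 <- pedigree(paste0("s", 1:5), NA, NA, 2000 + 2 * (0:4), "M")
  got <- split_by_rule(ped5, "sires_before_year", 2005)
  expect_setequal(got$reference_ids, c("s1", "s2", "s3"))  # 2000, 2002, 2004
  # degenerate: no males at all
  allf <- pedigree(paste0("f", 1:3), NA, NA, 2000, "F")
  expect_error(split_by_rule(allf, "sires_before_year"), "empty reference")
})

test_that("masking hides exactly the off-chip validation cells", {
  set.seed(31)
  tg <- toy_geno(setNames(lapply(1:5, function(i) sample(0:2, 10, TRUE)),
                          c("r1", "r2", "r3", "v1", "v2")))
  chip <- chip_def("c2", tg$map$snp_id[c(2, 7)])
  sc <- mask_to_chip(tg$geno, tg$map, chip, c("r1", "r2", "r3"),
                     c("v1", "v2"))
  # masked-cell count = |validation| x (m - |chip|)
  expect_equal(sum(is.na(sc$masked$dosage)) - sum(is.na(tg$geno$dosage)),
               2 * (10 - 2))
  # chip cells keep the truth; reference rows untouched
  expect_equal(sc$masked$dosage[c("v1", "v2"), c(2, 7)],
               sc$truth$dosage[c("v1", "v2"), c(2, 7)])
  expect_equal(sc$masked$dosage[c("r1", "r2", "r3"), ],
               sc$truth$dosage[c("r1", "r2", "r3"), ])
  # unmasking with truth restores the original
  restored <- sc$masked$dosage
  restored[is.na(restored)] <- sc$truth$dosage[is.na(restored)]
  expect_equal(restored, tg$geno$dosage)
  # full-map chip leaves nothing to impute
  sc_full <- mask_to_chip(tg$geno, tg$map, chip_def("all", tg$map$snp_id),
                          c("r1", "r2"), c("v1", "v2"))
  expect_equal(sc_full$masked$dosage, tg$geno$dosage)
  expect_error(mask_to_chip(tg$geno, tg$map, chip_def("none", "zz"),
                            "r1", "v1"), "empty chip")
  expect_error(mask_to_chip(tg$geno, tg$map, chip, "r1", "r1"), "overlap")
})

test_that("modal imputation fills with the most frequent reference genotype", {
  d <- rbind(r1 = c(0, 0), r2 = c(0, 0), r3 = c(1, 2), r4 = c(2, 2),
             v1 = c(0, 1))
  colnames(d) <- c("s1", "s2")
  map <- marker_map(colnames(d), 1, c(10, 20))
  sc <- mask_to_chip(geno_matrix(d), map, chip_def("s1only", "s1"),
                     paste0("r", 1:4), "v1")
  imp <- impute_mode(sc)
  expect_equal(imp$dosage["v1", "s2"], 0)   # tie 0/2 resolves to lower dosage
  expect_equal(imp$dosage["v1", "s1"], 0)   # chip cell untouched
  expect_false(anyNA(imp$dosage["v1", ]))
})

test_that("nn-window imputation copies a matching reference animal", {
  set.seed(32)
  base <- sample(0:2, 40, TRUE)
  d <- rbind(rA = base, rB = sample(0:2, 40, TRUE), v = base)
  colnames(d) <- sprintf("s%02d", 1:40)
  map <- marker_map(colnames(d), 1, 1:40 * 100)
  chip <- chip_def("sparse", colnames(d)[seq(4, 40, by = 4)])
  sc <- mask_to_chip(geno_matrix(d), map, chip, c("rA", "rB"), "v")
  imp <- impute_nn_window(sc, window_snps = 40)
  # v is identical to rA on the chip, so it receives rA's full genotypes
  expect_equal(unname(imp$dosage["v", ]), unname(d["rA", ]))
  # single reference animal: copied everywhere
  sc1 <- mask_to_chip(geno_matrix(d[c("rA", "v"), ]), map, chip, "rA", "v")
  imp1 <- impute_nn_window(sc1, window_snps = 10)
  expect_equal(unname(imp1$dosage["v", ]), unname(d["rA", ]))
  expect_false(anyNA(imp1$dosage))
})

test_that("imputers never read masked truth cells", {
  set.seed(33)
  tg <- toy_geno(setNames(lapply(1:6, function(i) sample(0:2, 30, TRUE)),
                          c("r1", "r2", "r3", "r4", "v1", "v2")))
  chip <- chip_def("c", tg$map$snp_id[seq(3, 30, by = 3)])
  refs <- paste0("r", 1:4)
  sc <- mask_to_chip(tg$geno, tg$map, chip, refs, c("v1", "v2"))
  # perturb an off-chip truth cell of a validation animal
  sc2 <- sc
  j <- which(!(colnames(sc2$truth$dosage) %in% chip$snp_ids))[1]
  sc2$truth$dosage["v1", j] <- (sc2$truth$dosage["v1", j] + 1) %% 3
  for (f in list(impute_mode, function(s) impute_nn_window(s, 10))) {
    expect_identical(f(sc)$dosage, f(sc2)$dosage)
  }
})

test_that("export/import round trips and validates identity of the data", {
  set.seed(34)
  tg <- toy_geno(setNames(lapply(1:5, function(i) sample(0:2, 12, TRUE)),
                          c("r1", "r2", "r3", "v1", "v2")))
  chip <- chip_def("c", tg$map$snp_id[c(3, 6, 9, 12)])
  sc <- mask_to_chip(tg$geno, tg$map, chip, paste0("r", 1:3),
                     c("v1", "v2"))
  dir <- withr::local_tempdir()
  for (fmt in c("vcf", "ped")) {
    path <- file.path(dir, paste0("x_", fmt))
    export_for_tool(sc, path, fmt)
    back <- import_imputed(path, fmt, sc)
    expect_identical(unname(back$dosage), unname(sc$masked$dosage),
                     info = fmt)
  }
  # a file missing one validation animal is rejected by name
  crop <- sc$masked[rownames(sc$masked$dosage) != "v2", ]
  write_genotypes(crop, tg$map, file.path(dir, "crop"), "ped")
  expect_error(import_imputed(file.path(dir, "crop"), "ped", sc), "v2")
  # an extra SNP is rejected by name
  d_ext <- cbind(sc$masked$dosage, zz9 = rep(1, 5))
  map_ext <- marker_map(c(tg$map$snp_id, "zz9"), 1,
                        c(tg$map$pos, max(tg$map$pos) + 10))
  write_genotypes(geno_matrix(d_ext), map_ext, file.path(dir, "ext"), "ped")
  expect_error(import_imputed(file.path(dir, "ext"), "ped", sc), "zz9")
})
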