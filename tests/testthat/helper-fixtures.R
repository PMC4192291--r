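# shared fixtures, built in code at test time

# a small, fast simulation used by most unit tests
small_sim_config <- function(seed = 42, ...) {
  defaults <- list(n_founders = 4, n_generations = 2, n_ref_sires = 30,
                   n_females_per_gen = 15, n_young_sires = 8, n_dams = 12,
                   n_snps = 400, n_chromosomes = 2, chrom_length_morgans = 1,
                   ld_block_mean_snps = 10, within_block_corr = 0.9,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- make_study_fixture(small_sim_config())
  }
  .fixture_cache$small
}

# the full-scale study fixture (default generator conditions, planted low-LD
# region); built once and shared by the acceptance tests
study_config <- function(seed = 1) {
  sim_config(seed = seed, low_ld_region = list(chrom = 1, from = 301, to = 400))
}

study_fixture_qc <- function() {
  if (is.null(.fixture_cache$study)) {
    fx <- make_study_fixture(study_config())
    qc <- run_qc(fx$geno, fx$map, qc_thresholds(),
                 reference_ids = fx$reference_ids)
    .fixture_cache$study <- list(fx = fx, geno = qc$geno, map = qc$map)
  }
  .fixture_cache$study
}

# a deterministic hand-sized genotype matrix + map (no simulation)
toy_geno <- function(dosage_rows, snp_ids = NULL, chrom = 1, pos = NULL) {
  d <- do.call(rbind, dosage_rows)
  if (is.null(snp_ids)) snp_ids <- sprintf("s%d", seq_len(ncol(d)))
  if (is.null(pos)) pos <- seq_len(ncol(d)) * 1000L
  rownames(d) <- names(dosage_rows)
  colnames(d) <- snp_ids
  list(geno = geno_matrix(d),
       map = marker_map(snp_ids, rep_len(chrom, ncol(d)), pos))
}

# builds a 20-SNP matrix with exactly 2 non-autosomal, 2 duplicate-position,
# 3 HWE-violating, 3 low-MAF and 2 low-call-rate SNPs planted among 8 clean
# ones; each planted SNP violates exactly one filter
planted_qc_fixture <- function() {
  n <- 30L
  good <- function() rep(c(0, 1, 1, 2, 0, 1), length.out = n)  # h_obs = 0.5
  all_het <- rep(1, n)                                         # HWE violator
  low_maf <- c(1, rep(0, n - 1))                               # MAF = 1/60
  low_cr <- function() c(rep(NA, 2), good()[-(1:2)])           # rate 28/30
  cols <- list(
    g1 = good(), g2 = good(), hwe1 = all_het, g3 = good(),
    maf1 = low_maf, dup1 = good(), g4 = good(), cr1 = low_cr(),
    maf2 = low_maf, g5 = good(), hwe2 = all_het, dup2 = good(),
    g6 = good(), cr2 = low_cr(), x1 = good(), g7 = good(),
    maf3 = low_maf, hwe3 = all_het, x2 = good(), g8 = good()
  )
  d <- do.call(cbind, cols)
  rownames(d) <- sprintf("i%02d", seq_len(n))
  chrom <- rep(1, 20)
  chrom[names(cols) == "x1"] <- "X"
  chrom[names(cols) == "x2"] <- 30       # beyond the 29 cattle autosomes
  pos <- seq_len(20) * 1000L
  pos[names(cols) == "dup1"] <- pos[1]   # replicate of g1's coordinates
  pos[names(cols) == "dup2"] <- pos[2]   # replicate of g2's coordinates
  map <- marker_map(names(cols), chrom, pos)
  d <- d[, map$snp_id]
  list(geno = geno_matrix(d), map = map)
}

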