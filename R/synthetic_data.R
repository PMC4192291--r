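#' Simulation configuration
#'
#' Parameters of the synthetic pedigreed-genotype generator. The defaults
#' describe the desk-scale study design the rest of the package is exercised
#' on: a three-generation sire-line pedigree from a small founder base,
#' giving 200 reference sires, a validation set of 50 young sires (sired by
#' recent reference sires, hence closely related to the reference) and a
#' validation set of 100 dams (38% with unknown sires and out-of-pedigree
#' dams, hence less related), genotyped at 15,000 SNPs on 10 chromosomes of
#' 3 Morgans with strong blockwise linkage disequilibrium. See the methods
#' vignette for the reasoning behind each default.
#'
#' @param n_founders founder males (an equal number of founder females is
#'   created).
#' @param n_generations pedigree depth; generations `1..n_generations - 1`
#'   supply the reference sires, the last generation is the validation one.
#' @param offspring_per_mating full-sib family size within a generation.
#' @param n_ref_sires reference sires, split evenly over the pre-validation
#'   generations.
#' @param n_females_per_gen breeding females per pre-validation generation.
#' @param n_young_sires,n_dams validation-set sizes.
#' @param unknown_sire_frac fraction of validation dams whose sire is
#'   recorded unknown (their paternal gamete is drawn from the founder
#'   haplotype distribution).
#' @param n_snps,n_chromosomes marker panel size and chromosome count.
#' @param chrom_length_morgans genetic length per chromosome (mean crossover
#'   count in gene dropping).
#' @param ld_block_mean_snps mean LD-block length in markers (geometric).
#' @param within_block_corr probability that an adjacent marker within a
#'   block copies the previous marker's allele state (first-order Markov);
#'   controls LD strength.
#' @param maf_floor founder allele frequencies are drawn uniformly on
#'   `[maf_floor, 1 - maf_floor]`.
#' @param missing_rate,low_quality_rate per-call rates of missing calls and
#'   of low (quality < 0.70) call scores.
#' @param low_ld_region optional `list(chrom =, from =, to =)` marker-index
#'   range (within the chromosome) where the copy probability is forced to 0,
#'   planting a region of negligible LD.
#' @param base_year,gen_gap birth years: founders are born in `base_year`,
#'   generation g in `base_year + g * gen_gap`; the reference/validation
#'   cutoff year is `base_year + n_generations * gen_gap`.
#' @param seed integer seed; every generator is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 6, n_generations = 3,
                       offspring_per_mating = 1, n_ref_sires = 200,
                       n_females_per_gen = 100, n_young_sires = 50,
                       n_dams = 100, unknown_sire_frac = 0.38,
                       n_snps = 15000, n_chromosomes = 10,
                       chrom_length_morgans = 3.0, ld_block_mean_snps = 50,
                       within_block_corr = 0.985, maf_floor = 0.05,
                       missing_rate = 0.002, low_quality_rate = 0.002,
                       low_ld_region = NULL, base_year = 1996, gen_gap = 3,
                       seed = 1) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_ref_sires = as.integer(n_ref_sires),
              n_females_per_gen = as.integer(n_females_per_gen),
              n_young_sires = as.integer(n_young_sires),
              n_dams = as.integer(n_dams),
              unknown_sire_frac = unknown_sire_frac,
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_morgans = chrom_length_morgans,
              ld_block_mean_snps = as.integer(ld_block_mean_snps),
              within_block_corr = within_block_corr,
              maf_floor = maf_floor, missing_rate = missing_rate,
              low_quality_rate = low_quality_rate,
              low_ld_region = low_ld_region,
              base_year = as.integer(base_year),
              gen_gap = as.integer(gen_gap), seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_founders >= 1, n_generations >= 2, offspring_per_mating >= 1,
              n_ref_sires >= 1, n_females_per_gen >= 1, n_young_sires >= 1,
              n_dams >= 1, n_snps >= 1, n_chromosomes >= 1,
              chrom_length_morgans >= 0, ld_block_mean_snps >= 1)
    stopifnot(unknown_sire_frac >= 0, unknown_sire_frac <= 1,
              within_block_corr >= 0, within_block_corr < 1,
              maf_floor >= 0, maf_floor <= 0.5,
              missing_rate >= 0, missing_rate <= 1,
              low_quality_rate >= 0, low_quality_rate <= 1)
  })
  if (!is.null(cfg$low_ld_region)) {
    stopifnot(all(c("chrom", "from", "to") %in% names(cfg$low_ld_region)))
  }
  structure(cfg, class = "sim_config")
}

cutoff_year <- function(config) {
  config$base_year + config$n_generations * config$gen_gap
}

#' Simulate a founder haplotype pool
#'
#' Builds the marker map (markers spread over chromosomes at random sorted
#' positions), draws per-SNP B-allele frequencies uniformly on
#' `[maf_floor, 1 - maf_floor]`, partitions each chromosome into LD blocks of
#' geometric mean length `ld_block_mean_snps`, and samples founder
#' haplotypes with a first-order Markov copy process inside blocks (adjacent
#' allele states are copied with probability `within_block_corr`, resampled
#' from the allele frequency otherwise; blocks are independent). Inside a
#' configured `low_ld_region` the copy probability is 0.
#'
#' @param config a [sim_config()].
#' @return An object of class `founder_pool`: list with `map`
#'   ([marker_map()]), `freqs`, `block_start` (logical per SNP), `copy_prob`
#'   (per SNP), and `hap`, a `(4 * n_founders) x n_snps` 0/1 matrix (two
#'   haplotypes for each founder male and female).
#' @export
simulate_founder_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m_per_chr <- rep(config$n_snps %/% config$n_chromosomes,
                   config$n_chromosomes)
  extra <- config$n_snps %% config$n_chromosomes
  if (extra > 0) m_per_chr[seq_len(extra)] <- m_per_chr[seq_len(extra)] + 1L
  chrom <- rep(seq_len(config$n_chromosomes), m_per_chr)
  pos <- unlist(lapply(m_per_chr, function(m) {
    sort(sample.int(1e8L, m))
  }))
  map <- marker_map(sprintf("snp%05d", seq_len(config$n_snps)), chrom, pos)

  freqs <- stats::runif(config$n_snps, config$maf_floor, 1 - config$maf_floor)
  block_start <- logical(config$n_snps)
  offset <- 0L
  for (m in m_per_chr) {
    block_start[offset + 1L] <- TRUE
    j <- 1L
    while (j < m) {
      len <- stats::rgeom(1, 1 / config$ld_block_mean_snps) + 1L
      j <- j + len
      if (j <= m) block_start[offset + j] <- TRUE
    }
    offset <- offset + m
  }
  copy_prob <- ifelse(block_start, 0, config$within_block_corr)
  reg <- config$low_ld_region
  if (!is.null(reg)) {
    in_reg <- which(chrom == reg$chrom)
    in_reg <- in_reg[seq(reg$from, min(reg$to, length(in_reg)))]
    copy_prob[in_reg] <- 0
  }
  pool <- structure(list(map = map, freqs = freqs, block_start = block_start,
                         copy_prob = copy_prob, chrom = chrom),
                    class = "founder_pool")
  pool$hap <- sample_pool_haplotypes(pool, 4L * config$n_founders)
  pool
}

# draw n haplotypes from the pool's Markov-block model (uses the current RNG)
sample_pool_haplotypes <- function(pool, n) {
  m <- length(pool$freqs)
  h <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    fresh <- stats::rbinom(n, 1L, pool$freqs[j])
    if (pool$copy_prob[j] == 0) {
      h[, j] <- fresh
    } else {
      copy <- stats::runif(n) < pool$copy_prob[j]
      h[, j] <- ifelse(copy, h[, j - 1L], fresh)
    }
  }
  h
}

#' Simulate a multi-generation sire-line pedigree
#'
#' Generation 0 holds the founders. Each pre-validation generation adds
#' reference sires and breeding females (parents drawn from the previous
#' generation). The final generation holds the validation animals: young
#' sires (sire drawn from the most recent reference sires, dam from the most
#' recent breeding females) and validation dams (sire drawn from the oldest
#' reference sires, or recorded unknown for a configurable fraction; dam a
#' founder female). This makes young sires more related to the reference set
#' than the dams, the relatedness gradient the evaluation is designed
#' around.
#'
#' @param config a [sim_config()].
#' @return A [pedigree()] with attribute `roles`: list of `reference_ids`,
#'   `young_sire_ids`, `dam_ids`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  nf <- config$n_founders
  id <- c(sprintf("FM%03d", seq_len(nf)), sprintf("FF%03d", seq_len(nf)))
  sire <- rep(NA_character_, 2L * nf)
  dam <- rep(NA_character_, 2L * nf)
  year <- rep(config$base_year, 2L * nf)
  sex <- rep(c("M", "F"), each = nf)

  n_pre <- max(1L, config$n_generations - 1L)
  males_per_gen <- rep(config$n_ref_sires %/% n_pre, n_pre)
  rem <- config$n_ref_sires %% n_pre
  if (rem > 0) males_per_gen[seq_len(rem)] <- males_per_gen[seq_len(rem)] + 1L

  add_generation <- function(n_m, n_f, g, sires_avail, dams_avail) {
    n_off <- n_m + n_f
    opm <- config$offspring_per_mating
    n_matings <- ceiling(n_off / opm)
    mat_sire <- sample(sires_avail, n_matings, replace = TRUE)
    mat_dam <- sample(dams_avail, n_matings, replace = TRUE)
    fam <- rep(seq_len(n_matings), each = opm)[seq_len(n_off)]
    new_sex <- sample(rep(c("M", "F"), c(n_m, n_f)))
    new_ids <- character(n_off)
    new_ids[new_sex == "M"] <- sprintf("G%d_M%03d", g, seq_len(n_m))
    new_ids[new_sex == "F"] <- sprintf("G%d_F%03d", g, seq_len(n_f))
    list(id = new_ids, sire = mat_sire[fam], dam = mat_dam[fam],
         sex = new_sex)
  }

  prev_males <- id[sex == "M"]
  prev_females <- id[sex == "F"]
  reference_ids <- character(0)
  for (g in seq_len(n_pre)) {
    n_m <- males_per_gen[g]
    n_f <- config$n_females_per_gen
    gen <- add_generation(n_m, n_f, g, prev_males, prev_females)
    ids_m <- sprintf("G%d_M%03d", g, seq_len(n_m))
    ids_f <- sprintf("G%d_F%03d", g, seq_len(n_f))
    id <- c(id, gen$id)
    sire <- c(sire, gen$sire)
    dam <- c(dam, gen$dam)
    year <- c(year, rep(config$base_year + g * config$gen_gap, n_m + n_f))
    sex <- c(sex, gen$sex)
    reference_ids <- c(reference_ids, ids_m)
    prev_males <- ids_m
    prev_females <- ids_f
  }

  g_val <- config$n_generations
  val_year <- config$base_year + g_val * config$gen_gap
  # young sires: closely tied to the most recent reference generation
  ys_ids <- sprintf("G%d_M%03d", g_val, seq_len(config$n_young_sires))
  ys_sire <- sample(prev_males, config$n_young_sires, replace = TRUE)
  ys_dam <- sample(prev_females, config$n_young_sires, replace = TRUE)
  # validation dams: founder dams; sire old or unknown
  oldest_ref <- reference_ids[seq_len(males_per_gen[1])]
  dam_ids <- sprintf("G%d_F%03d", g_val, seq_len(config$n_dams))
  dam_sire <- sample(oldest_ref, config$n_dams, replace = TRUE)
  unknown <- stats::runif(config$n_dams) < config$unknown_sire_frac
  dam_sire[unknown] <- NA
  # commercial-herd dams: maternal side outside the recorded pedigree, so the
  # maternal gamete is drawn fresh from the founder distribution
  dam_dam <- rep(NA_character_, config$n_dams)

  id <- c(id, ys_ids, dam_ids)
  sire <- c(sire, ys_sire, dam_sire)
  dam <- c(dam, ys_dam, dam_dam)
  year <- c(year, rep(val_year, config$n_young_sires + config$n_dams))
  sex <- c(sex, rep(c("M", "F"), c(config$n_young_sires, config$n_dams)))

  ped <- pedigree(id, sire, dam, year, sex)
  attr(ped, "roles") <- list(reference_ids = reference_ids,
                             young_sire_ids = ys_ids, dam_ids = dam_ids)
  ped
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders receive haplotype pairs from the pool; every other individual
#' inherits one recombined gamete per parent (crossover count per chromosome
#' Poisson with mean `chrom_length_morgans`, crossover positions uniform in
#' bp). A recorded-unknown parent contributes a gamete drawn fresh from the
#' founder haplotype distribution. Dosage is the sum of the two haplotypes.
#'
#' @param ped a [pedigree()] (parents precede offspring).
#' @param pool a [simulate_founder_haplotypes()] pool.
#' @param config the [sim_config()] used to build the pool.
#' @return A list with `geno` (a [geno_matrix()] over all pedigree
#'   individuals, no missing calls) and `map` (the pool's [marker_map()]).
#' @export
gene_drop <- function(ped, pool, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(pool, "founder_pool"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- nrow(ped)
  m <- length(pool$freqs)
  chrom_ids <- unique(pool$chrom)
  chrom_idx <- lapply(chrom_ids, function(ch) which(pool$chrom == ch))
  pos <- pool$map$pos

  founder <- is.na(ped$sire) & is.na(ped$dam)
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)

  gamete <- function(i_parent) {
    g <- integer(m)
    for (c_i in seq_along(chrom_idx)) {
      idx <- chrom_idx[[c_i]]
      ncross <- stats::rpois(1, config$chrom_length_morgans)
      start <- sample.int(2L, 1L)
      if (ncross == 0) {
        g[idx] <- if (start == 1L) h1[i_parent, idx] else h2[i_parent, idx]
      } else {
        xpos <- sort(stats::runif(ncross, min(pos[idx]), max(pos[idx])))
        phase <- (start + findInterval(pos[idx], xpos)) %% 2L
        g[idx] <- ifelse(phase == 1L, h1[i_parent, idx], h2[i_parent, idx])
      }
    }
    g
  }

  f_next <- 0L
  for (i in seq_len(n)) {
    if (founder[i]) {
      # parentless individuals take pool haplotypes while they last (the
      # topological sort places the generation-0 founders first); any excess
      # parentless individuals draw fresh from the founder distribution
      if (f_next + 2L <= nrow(pool$hap)) {
        h1[i, ] <- pool$hap[f_next + 1L, ]
        h2[i, ] <- pool$hap[f_next + 2L, ]
        f_next <- f_next + 2L
      } else {
        fresh <- sample_pool_haplotypes(pool, 2L)
        h1[i, ] <- fresh[1L, ]
        h2[i, ] <- fresh[2L, ]
      }
    } else {
      h1[i, ] <- if (is.na(si[i])) {
        sample_pool_haplotypes(pool, 1L)[1L, ]
      } else {
        gamete(si[i])
      }
      h2[i, ] <- if (is.na(di[i])) {
        sample_pool_haplotypes(pool, 1L)[1L, ]
      } else {
        gamete(di[i])
      }
    }
  }
  dosage <- h1 + h2
  storage.mode(dosage) <- "double"
  rownames(dosage) <- ped$id
  colnames(dosage) <- pool$map$snp_id
  list(geno = geno_matrix(dosage), map = pool$map)
}

#' Add missingness and per-call quality scores
#'
#' Sets a `missing_rate` fraction of calls missing, assigns a
#' `low_quality_rate` fraction of the calls a quality score uniform on
#' `[0, 0.70)` and the remainder uniform on `[0.70, 1]`, emulating the
#' GenCall-score structure the QC filters operate on.
#'
#' @param geno a [geno_matrix()].
#' @param config a [sim_config()].
#' @return A [geno_matrix()] with missing calls and a quality matrix.
#' @export
add_noise <- function(geno, config) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  d <- geno$dosage
  ncell <- length(d)
  d[stats::runif(ncell) < config$missing_rate] <- NA
  q <- matrix(stats::runif(ncell, 0.70, 1), nrow(d), ncol(d),
              dimnames = dimnames(d))
  low <- stats::runif(ncell) < config$low_quality_rate
  q[low] <- stats::runif(sum(low), 0, 0.70)
  geno_matrix(d, q)
}

#' Build a complete synthetic study fixture
#'
#' One call that produces everything the pipeline consumes: founder
#' haplotypes, pedigree, gene-dropped genotypes for the genotyped animals
#' (reference sires, young sires, validation dams), call noise and quality
#' scores, and the role id lists. Optionally writes the bundle to disk in
#' the package's exchange formats.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes `geno.ped/.map`,
#'   `quality.tsv`, `pedigree.txt` and one id-list file per role.
#' @return An object of class `study_fixture`: list with `geno`, `map`,
#'   `pedigree`, `reference_ids`, `young_sire_ids`, `dam_ids`, `config`.
#' @export
make_study_fixture <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pool <- simulate_founder_haplotypes(config)
  ped <- simulate_pedigree(config)
  gd <- gene_drop(ped, pool, config)
  roles <- attr(ped, "roles")
  genotyped <- c(roles$reference_ids, roles$young_sire_ids, roles$dam_ids)
  geno <- gd$geno[match(genotyped, rownames(gd$geno$dosage)), ]
  geno <- add_noise(geno, config)
  out <- structure(list(geno = geno, map = gd$map, pedigree = ped,
                        reference_ids = roles$reference_ids,
                        young_sire_ids = roles$young_sire_ids,
                        dam_ids = roles$dam_ids, config = config),
                   class = "study_fixture")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genotypes(geno, gd$map, file.path(dir, "geno"), "ped")
    write_quality_sidecar(geno, file.path(dir, "quality.tsv"))
    write_pedigree_file(ped, file.path(dir, "pedigree.txt"))
    writeLines(roles$reference_ids, file.path(dir, "reference_ids.txt"))
    writeLines(roles$young_sire_ids, file.path(dir, "young_sire_ids.txt"))
    writeLines(roles$dam_ids, file.path(dir, "dam_ids.txt"))
  }
  out
}

#' @export
print.study_fixture <- function(x, ...) {
  cat(sprintf(paste0("synthetic study fixture: %d SNPs on %d chromosomes; ",
                     "%d reference sires, %d young sires, %d dams ",
                     "(pedigree of %d)\n"),
              ncol(x$geno$dosage), x$config$n_chromosomes,
              length(x$reference_ids), length(x$young_sire_ids),
              length(x$dam_ids), nrow(x$pedigree)))
  invisible(x)
}
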