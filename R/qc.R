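#' Quality-control thresholds
#'
#' Bundles the SNP and individual filters applied by [run_qc()], with the
#' defaults used throughout: Hardy-Weinberg z-test p-value <= 1e-5, minor
#' allele frequency < 0.02, per-SNP call rate < 0.98 (calls with quality
#' below 0.70 count as missing for this statistic), per-individual call rate
#' <= 0.90, and 29 autosomes (cattle).
#'
#' @param hwe_p_max SNPs with HWE p-value `<=` this are excluded.
#' @param maf_min SNPs with MAF `<` this are excluded.
#' @param snp_call_rate_min SNPs with call rate `<` this are excluded.
#' @param gencall_min calls with quality score `<` this count as missing in
#'   call-rate statistics.
#' @param ind_call_rate_min individuals with call rate `<=` this (over
#'   surviving SNPs) are excluded.
#' @param n_autosomes chromosomes `1..n_autosomes` are autosomal; everything
#'   else is excluded by the non-autosomal filter.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_max = 1e-5, maf_min = 0.02,
                          snp_call_rate_min = 0.98, gencall_min = 0.70,
                          ind_call_rate_min = 0.90, n_autosomes = 29L) {
  stopifnot(hwe_p_max >= 0, hwe_p_max <= 1, maf_min >= 0, maf_min <= 0.5,
            snp_call_rate_min >= 0, snp_call_rate_min <= 1,
            gencall_min >= 0, gencall_min <= 1,
            ind_call_rate_min >= 0, ind_call_rate_min <= 1, n_autosomes >= 1)
  structure(list(hwe_p_max = hwe_p_max, maf_min = maf_min,
                 snp_call_rate_min = snp_call_rate_min,
                 gencall_min = gencall_min,
                 ind_call_rate_min = ind_call_rate_min,
                 n_autosomes = as.integer(n_autosomes)),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium z-test
#'
#' Normal-approximation test on the heterozygote proportion:
#' `z = (h_obs - h_exp) / sqrt(h_exp (1 - h_exp) / n)` with
#' `h_obs = n_AB / n`, `h_exp = 2 p (1 - p)` and
#' `p = (2 n_BB + n_AB) / (2 n)`. A monomorphic sample (expected
#' heterozygosity 0 with none observed) gives z = 0, p = 1. The returned
#' p-value is two-sided.
#'
#' @param n_aa,n_ab,n_bb genotype counts (AA, AB, BB).
#' @return The two-sided p-value in \[0, 1\].
#' @examples
#' hwe_z_test(25, 50, 25)  # exact HWE proportions -> p = 1
#' hwe_z_test(30, 40, 30)  # z = -2, p ~ 0.0455
#' @export
hwe_z_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (any(n < 1)) stop("no genotyped individuals: cannot test HWE")
  p <- (2 * n_bb + n_ab) / (2 * n)
  h_obs <- n_ab / n
  h_exp <- 2 * p * (1 - p)
  z <- ifelse(h_exp == 0 & h_obs == 0, 0,
              (h_obs - h_exp) / sqrt(h_exp * (1 - h_exp) / n))
  2 * stats::pnorm(-abs(z))
}

#' Minor allele frequency of a dosage vector
#'
#' @param dosages dosages in `{0, 1, 2, NA}`; missing calls are ignored.
#' @return `min(p, 1 - p)` where p is the B-allele frequency over non-missing
#'   calls.
#' @examples
#' snp_maf(c(0, 1, 1, 2))  # 0.5
#' @export
snp_maf <- function(dosages) {
  x <- dosages[!is.na(dosages)]
  if (!length(x)) stop("all calls missing: MAF undefined")
  p <- mean(x) / 2
  min(p, 1 - p)
}

#' Per-SNP call rate with quality masking
#'
#' Proportion of individuals whose call is present and has quality score at
#' least `gencall_min` (calls below that score are treated as missing,
#' mirroring GenCall-score masking).
#'
#' @param dosages dosages in `{0, 1, 2, NA}`.
#' @param quality per-call quality scores (same length); `NULL` means all 1.
#' @param gencall_min quality threshold below which a call counts as missing.
#' @return Call rate in \[0, 1\].
#' @export
snp_call_rate <- function(dosages, quality = NULL, gencall_min = 0.70) {
  if (!length(dosages)) stop("empty dosage vector")
  if (is.null(quality)) quality <- rep(1, length(dosages))
  stopifnot(length(quality) == length(dosages))
  mean(!is.na(dosages) & quality >= gencall_min)
}

# vectorised internals used by run_qc (NA where undefined)
col_maf <- function(d) {
  p <- colMeans(d, na.rm = TRUE) / 2  # NaN if all missing
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- NA
  maf
}

col_hwe_p <- function(d) {
  n_aa <- colSums(d == 0, na.rm = TRUE)
  n_ab <- colSums(d == 1, na.rm = TRUE)
  n_bb <- colSums(d == 2, na.rm = TRUE)
  n <- n_aa + n_ab + n_bb
  p <- ifelse(n > 0, (2 * n_bb + n_ab) / (2 * n), NA)
  h_obs <- ifelse(n > 0, n_ab / n, NA)
  h_exp <- 2 * p * (1 - p)
  z <- ifelse(h_exp == 0,
              ifelse(h_obs == 0, 0, Inf),
              (h_obs - h_exp) / sqrt(h_exp * (1 - h_exp) / n))
  ifelse(is.na(z), NA, 2 * stats::pnorm(-abs(z)))
}

col_call_rate <- function(d, q, gencall_min) {
  if (is.null(q)) return(colMeans(!is.na(d)))
  colMeans(!is.na(d) & q >= gencall_min)
}

#' Run SNP and individual quality control
#'
#' Applies, in order, the five SNP exclusion filters — (1) non-autosomal,
#' (2) duplicate genomic position (only the replicates are removed; the first
#' record at each position is kept), (3) Hardy-Weinberg z-test p <= threshold,
#' (4) MAF below threshold, (5) per-SNP call rate below threshold (with
#' quality-score masking) — followed by the per-individual call-rate filter
#' computed over the surviving SNPs. SNP statistics are computed on the
#' designated reference individuals only; the resulting exclusion list is
#' applied to every individual, so validation genotypes are harmonized
#' automatically.
#'
#' Each filter's violation set is evaluated on the full input, and every
#' excluded SNP is attributed to the first filter (in the order above) that
#' it violates; the surviving set is therefore invariant to filter order.
#'
#' @param geno a [geno_matrix()].
#' @param map the matching [marker_map()].
#' @param thresholds a [qc_thresholds()].
#' @param reference_ids individuals on which SNP statistics are computed;
#'   default all individuals.
#' @return A list with elements `report` (a `qc_report`), `geno` (filtered
#'   genotypes) and `map` (filtered map).
#' @export
run_qc <- function(geno, map, thresholds = qc_thresholds(),
                   reference_ids = NULL) {
  check_geno_map(geno, map)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (is.null(reference_ids)) reference_ids <- rownames(geno$dosage)
  missing_ref <- setdiff(reference_ids, rownames(geno$dosage))
  if (length(missing_ref)) {
    stop("reference ids absent from genotype matrix: ",
         paste(utils::head(missing_ref, 5), collapse = ", "))
  }
  d_ref <- geno$dosage[reference_ids, , drop = FALSE]
  q_ref <- if (!is.null(geno$quality)) {
    geno$quality[reference_ids, , drop = FALSE]
  }

  v_nonauto <- !is_autosome(map$chrom, thresholds$n_autosomes)
  v_dup <- duplicated(paste(map$chrom, map$pos))
  hwe_p <- col_hwe_p(d_ref)
  v_hwe <- !is.na(hwe_p) & hwe_p <= thresholds$hwe_p_max
  maf <- col_maf(d_ref)
  v_maf <- !is.na(maf) & maf < thresholds$maf_min
  cr <- col_call_rate(d_ref, q_ref, thresholds$gencall_min)
  v_cr <- cr < thresholds$snp_call_rate_min

  viol <- cbind(non_autosomal = v_nonauto, duplicate_position = v_dup,
                hwe = v_hwe, maf = v_maf, snp_call_rate = v_cr)
  first <- apply(viol, 1, function(v) if (any(v)) which(v)[1] else 0L)
  counts <- vapply(seq_len(ncol(viol)),
                   function(k) sum(first == k), integer(1))
  names(counts) <- colnames(viol)
  survivors <- map$snp_id[first == 0L]
  if (!length(survivors)) {
    stop("no SNPs survive QC; largest exclusion from filter '",
         names(counts)[which.max(counts)], "'")
  }

  geno_f <- geno[, match(survivors, colnames(geno$dosage))]
  map_f <- map[map$snp_id %in% survivors, , drop = FALSE]
  class(map_f) <- c("marker_map", "data.frame")

  # individual call rate over surviving SNPs (quality-masked)
  q_f <- geno_f$quality
  ind_cr <- if (is.null(q_f)) {
    rowMeans(!is.na(geno_f$dosage))
  } else {
    rowMeans(!is.na(geno_f$dosage) & q_f >= thresholds$gencall_min)
  }
  excluded_ind <- rownames(geno_f$dosage)[ind_cr <= thresholds$ind_call_rate_min]
  keep_ind <- setdiff(rownames(geno_f$dosage), excluded_ind)
  if (!length(keep_ind)) {
    stop("no individuals survive the individual call-rate filter")
  }
  geno_f <- geno_f[match(keep_ind, rownames(geno_f$dosage)), ]

  report <- structure(list(
    n_input_snps = nrow(map),
    exclusions = counts,
    surviving_snp_ids = survivors,
    excluded_individual_ids = excluded_ind,
    n_surviving_individuals = length(keep_ind),
    thresholds = thresholds
  ), class = "qc_report")
  list(report = report, geno = geno_f, map = map_f)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control\n")
  cat(sprintf("  input SNPs: %d\n", x$n_input_snps))
  for (nm in names(x$exclusions)) {
    cat(sprintf("  excluded (%s): %d\n", nm, x$exclusions[[nm]]))
  }
  cat(sprintf("  surviving SNPs: %d\n", length(x$surviving_snp_ids)))
  cat(sprintf("  excluded individuals: %d\n",
              length(x$excluded_individual_ids)))
  cat(sprintf("  surviving individuals: %d\n", x$n_surviving_individuals))
  invisible(x)
}

#' Imputation load implied by a chip
#'
#' The number and percentage of HD SNPs that must be imputed for animals
#' genotyped on a lower-density chip: `n_total - n_chip` SNPs, as a
#' percentage of `n_total`.
#'
#' @param n_total number of post-QC HD SNPs.
#' @param n_chip number of post-QC SNPs on the lower-density chip.
#' @return A list with `n_to_impute` and `pct_to_impute` (percent).
#' @examples
#' snps_to_impute(439595, 4086)
#' @export
snps_to_impute <- function(n_total, n_chip) {
  stopifnot(n_chip <= n_total, n_total > 0)
  list(n_to_impute = n_total - n_chip,
       pct_to_impute = 100 * (n_total - n_chip) / n_total)
}
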