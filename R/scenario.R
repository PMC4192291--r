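#' Split genotyped animals into reference and validation sets
#'
#' The reference set is the older sires: males born before the cutoff year.
#' The validation set is either the remaining (young) sires or the dams
#' (all females), depending on the rule.
#'
#' @param ped a [pedigree()].
#' @param rule `"sires_before_year"` (validation = males born in or after the
#'   cutoff year) or `"dams"` (validation = all females).
#' @param cutoff_year reference sires are males with `birth_year < cutoff_year`.
#' @param ids optional restriction to the genotyped individuals.
#' @return A list with `reference_ids` and `validation_ids`.
#' @export
split_by_rule <- function(ped, rule = c("sires_before_year", "dams"),
                          cutoff_year = 2005, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  rule <- match.arg(rule)
  p <- ped
  if (!is.null(ids)) p <- p[p$id %in% ids, , drop = FALSE]
  males <- p$sex == "M" & !is.na(p$sex)
  reference <- p$id[males & !is.na(p$birth_year) & p$birth_year < cutoff_year]
  validation <- switch(rule,
    sires_before_year = p$id[males & !is.na(p$birth_year) &
                               p$birth_year >= cutoff_year],
    dams = p$id[p$sex == "F" & !is.na(p$sex)]
  )
  if (!length(reference)) stop("empty reference set under the split rule")
  if (!length(validation)) stop("empty validation set under the split rule")
  list(reference_ids = reference, validation_ids = validation)
}

#' Build a masking-based imputation scenario
#'
#' Validation animals keep their genotypes only at the chip's SNPs; every
#' off-chip call of a validation animal is set missing, mimicking genotyping
#' on the lower-density chip. Reference rows stay complete. The full (truth)
#' matrix is retained privately for scoring.
#'
#' @param truth a [geno_matrix()] holding the complete genotypes.
#' @param map the matching [marker_map()].
#' @param chip a [chip_def()]; markers not on the map are dropped.
#' @param reference_ids,validation_ids disjoint id sets present in `truth`.
#' @return An object of class `imputation_scenario`: list with
#'   `reference_ids`, `validation_ids`, `chip`, `map`, `masked` and `truth`.
#' @export
mask_to_chip <- function(truth, map, chip, reference_ids, validation_ids) {
  check_geno_map(truth, map)
  stopifnot(inherits(chip, "chip_def"))
  if (length(intersect(reference_ids, validation_ids))) {
    stop("reference and validation sets overlap")
  }
  missing <- setdiff(c(reference_ids, validation_ids), rownames(truth$dosage))
  if (length(missing)) {
    stop("ids absent from genotype matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  chip <- intersect_chip(chip, map)
  masked <- truth
  off_chip <- !(colnames(masked$dosage) %in% chip$snp_ids)
  vi <- match(validation_ids, rownames(masked$dosage))
  masked$dosage[vi, off_chip] <- NA
  structure(list(reference_ids = reference_ids,
                 validation_ids = validation_ids,
                 chip = chip, map = map,
                 masked = masked, truth = truth),
            class = "imputation_scenario")
}

#' @export
print.imputation_scenario <- function(x, ...) {
  m <- ncol(x$truth$dosage)
  cat(sprintf(paste0("imputation scenario: chip '%s' (%d SNPs of %d; ",
                     "%d to impute), %d reference, %d validation animals\n"),
              x$chip$name, length(x$chip$snp_ids), m,
              m - length(x$chip$snp_ids),
              length(x$reference_ids), length(x$validation_ids)))
  invisible(x)
}

# per-SNP modal reference genotype; tie -> lower dosage
ref_mode <- function(d_ref) {
  counts <- rbind(colSums(d_ref == 0, na.rm = TRUE),
                  colSums(d_ref == 1, na.rm = TRUE),
                  colSums(d_ref == 2, na.rm = TRUE))
  apply(counts, 2, which.max) - 1  # which.max: first maximum = lower dosage
}

#' Baseline imputer: reference modal genotype
#'
#' Fills every missing call of the validation rows with the most frequent
#' reference genotype at that SNP (ties resolve to the lower dosage). A
#' deliberately naive baseline used to exercise the evaluation stack.
#'
#' @param scenario an [mask_to_chip()] scenario.
#' @return A [geno_matrix()] with no missing calls on validation rows.
#' @export
impute_mode <- function(scenario) {
  stopifnot(inherits(scenario, "imputation_scenario"))
  out <- scenario$masked
  d_ref <- out$dosage[scenario$reference_ids, , drop = FALSE]
  modes <- ref_mode(d_ref)
  vi <- match(scenario$validation_ids, rownames(out$dosage))
  for (i in vi) {
    miss <- is.na(out$dosage[i, ])
    out$dosage[i, miss] <- modes[miss]
  }
  out
}

#' Baseline imputer: nearest reference animal per genomic window
#'
#' For each validation animal and each window of `window_snps` consecutive
#' markers, finds the reference animal with the smallest Hamming distance on
#' the chip SNPs inside the window (ties resolve to the first reference
#' animal in id order) and copies that animal's genotypes into the masked
#' cells of the window. Windows containing no chip SNPs fall back to the
#' modal-genotype imputer. Because matching uses only observed chip
#' genotypes, accuracy responds to both chip density and relatedness, which
#' is what the evaluation pipeline is designed to measure.
#'
#' @param scenario an [mask_to_chip()] scenario.
#' @param window_snps window length in markers.
#' @return A [geno_matrix()] with no missing calls on validation rows.
#' @export
impute_nn_window <- function(scenario, window_snps = 50) {
  stopifnot(inherits(scenario, "imputation_scenario"))
  out <- scenario$masked
  d <- out$dosage
  ref_i <- match(scenario$reference_ids, rownames(d))
  val_i <- match(scenario$validation_ids, rownames(d))
  on_chip <- colnames(d) %in% scenario$chip$snp_ids
  modes <- ref_mode(d[ref_i, , drop = FALSE])
  plan <- partition_windows(scenario$map, window_snps)
  for (w in plan$windows) {
    chip_w <- w[on_chip[w]]
    mask_w <- w[!on_chip[w]]
    if (!length(mask_w)) next
    if (!length(chip_w)) {
      for (i in val_i) {
        miss <- mask_w[is.na(d[i, mask_w])]
        d[i, miss] <- modes[miss]
      }
      next
    }
    rc <- d[ref_i, chip_w, drop = FALSE]
    vc <- d[val_i, chip_w, drop = FALSE]
    # Hamming distance counting only the validation animal's observed calls
    mism <- matrix(0L, length(val_i), length(ref_i))
    for (g in 0:2) {
      vg <- vc == g
      vg[is.na(vg)] <- FALSE
      rg <- rc != g
      rg[is.na(rg)] <- TRUE
      mism <- mism + vg %*% t(rg)
    }
    best <- apply(mism, 1, which.min)  # tie -> first reference in id order
    for (v in seq_along(val_i)) {
      i <- val_i[v]
      miss <- mask_w[is.na(d[i, mask_w])]
      d[i, miss] <- d[ref_i[best[v]], miss]
    }
  }
  # residual gaps (donor itself missing, or missing truth calls at chip SNPs)
  # fall back to the reference modal genotype so no missing call remains
  for (i in val_i) {
    miss <- is.na(d[i, ])
    d[i, miss] <- modes[miss]
  }
  geno_matrix(d, out$quality)
}

#' Export a scenario's masked genotypes for an external imputation tool
#'
#' Writes the masked matrix (reference rows complete, validation rows
#' restricted to the chip) in PLINK or VCF format so that external software
#' can impute it; [import_imputed()] validates and reads the result back.
#'
#' @param scenario an [mask_to_chip()] scenario.
#' @param path file prefix (PED/BED) or path (VCF).
#' @param format `"ped"`, `"bed"` or `"vcf"`.
#' @return Invisibly, the files written.
#' @export
export_for_tool <- function(scenario, path, format = c("ped", "bed", "vcf")) {
  stopifnot(inherits(scenario, "imputation_scenario"))
  write_genotypes(scenario$masked, scenario$map, path, format)
}

#' Import genotypes imputed by an external tool
#'
#' @param path file prefix or path, as written by the external tool.
#' @param format `"ped"`, `"bed"` or `"vcf"`.
#' @param scenario the scenario the file must match: every scenario
#'   individual must be present and the markers must be exactly the
#'   scenario's map (errors name the offending id or SNP).
#' @return A [geno_matrix()] with rows in scenario order.
#' @export
import_imputed <- function(path, format = c("ped", "bed", "vcf"), scenario) {
  stopifnot(inherits(scenario, "imputation_scenario"))
  got <- read_genotypes(path, format)
  want_ids <- rownames(scenario$truth$dosage)
  missing_ids <- setdiff(want_ids, rownames(got$geno$dosage))
  if (length(missing_ids)) {
    stop("imported file is missing individual(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  extra_snps <- setdiff(got$map$snp_id, scenario$map$snp_id)
  if (length(extra_snps)) {
    stop("imported file contains SNP(s) not in the scenario map: ",
         paste(utils::head(extra_snps, 5), collapse = ", "))
  }
  missing_snps <- setdiff(scenario$map$snp_id, got$map$snp_id)
  if (length(missing_snps)) {
    stop("imported file is missing SNP(s): ",
         paste(utils::head(missing_snps, 5), collapse = ", "))
  }
  got$geno[match(want_ids, rownames(got$geno$dosage)),
           match(scenario$map$snp_id, colnames(got$geno$dosage))]
}
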