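#' Percentage of correctly imputed genotypes (PERC)
#'
#' `100 * matches / scored`, scored over positions where the observed (true)
#' genotype is non-missing.
#'
#' @param imputed,observed dosage vectors of equal length.
#' @return Percentage in \[0, 100\].
#' @examples
#' imputation_perc(c(0, 1, 2, 1), c(0, 1, 2, 2))  # 75
#' @export
imputation_perc <- function(imputed, observed) {
  stopifnot(length(imputed) == length(observed))
  ok <- !is.na(observed)
  if (!any(ok)) stop("no scored positions: all observed genotypes missing")
  100 * mean(imputed[ok] == observed[ok])
}

#' Dosage correlation between imputed and observed genotypes (CORR)
#'
#' Pearson correlation of the imputed and observed dosage vectors (0/1/2
#' copies of allele B). Undefined when either vector is constant over the
#' scored positions; that case returns `NA` (it is excluded from summaries,
#' never raised as an error).
#'
#' @inheritParams imputation_perc
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @examples
#' imputation_corr(c(0, 1, 2, 1), c(0, 1, 2, 2))  # 0.8528
#' @export
imputation_corr <- function(imputed, observed) {
  stopifnot(length(imputed) == length(observed))
  ok <- !is.na(observed) & !is.na(imputed)
  if (sum(ok) < 2) return(NA_real_)
  x <- imputed[ok]
  y <- observed[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Score an imputed matrix against a scenario's truth
#'
#' Computes PERC and CORR per individual (over that individual's masked
#' cells, genome-wide) and per SNP (over the validation individuals at each
#' masked SNP), for imputed SNPs only. Cells whose true genotype is missing
#' are not scored. Summaries are means and sample (n-1) standard deviations
#' over individuals and over SNPs; undefined CORR values are excluded, with
#' their counts reported.
#'
#' @param scenario an [mask_to_chip()] scenario.
#' @param imputed a [geno_matrix()] covering the scenario's individuals and
#'   map, complete on validation rows.
#' @return An object of class `accuracy_result`: list with `per_individual`,
#'   `per_snp` (data.frames with `perc` and `corr`), `summary` (data.frame),
#'   `n_imputed_snps`, `frac_imputed_snps` and `n_undefined_corr`.
#' @export
score_scenario <- function(scenario, imputed) {
  stopifnot(inherits(scenario, "imputation_scenario"),
            inherits(imputed, "geno_matrix"))
  truth <- scenario$truth$dosage
  imp <- imputed$dosage[rownames(truth), colnames(truth), drop = FALSE]
  vi <- match(scenario$validation_ids, rownames(truth))
  masked <- is.na(scenario$masked$dosage[rownames(truth), , drop = FALSE]) &
    !is.na(truth)
  masked[-vi, ] <- FALSE
  if (!any(masked)) stop("scenario has no masked cells to score")

  per_ind <- data.frame(
    id = scenario$validation_ids,
    perc = NA_real_, corr = NA_real_, n_scored = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (r in seq_along(vi)) {
    i <- vi[r]
    cells <- masked[i, ]
    per_ind$n_scored[r] <- sum(cells)
    if (!any(cells)) next
    per_ind$perc[r] <- imputation_perc(imp[i, cells], truth[i, cells])
    per_ind$corr[r] <- imputation_corr(imp[i, cells], truth[i, cells])
  }

  snp_any <- colSums(masked) > 0
  snp_ids <- colnames(truth)[snp_any]
  per_snp <- data.frame(
    snp_id = snp_ids, perc = NA_real_, corr = NA_real_,
    n_scored = NA_integer_, stringsAsFactors = FALSE
  )
  for (s in seq_along(snp_ids)) {
    j <- which(colnames(truth) == snp_ids[s])
    rows <- which(masked[, j])
    per_snp$n_scored[s] <- length(rows)
    per_snp$perc[s] <- imputation_perc(imp[rows, j], truth[rows, j])
    per_snp$corr[s] <- imputation_corr(imp[rows, j], truth[rows, j])
  }

  summarize <- function(x) c(mean = mean(x, na.rm = TRUE),
                             sd = stats::sd(x[!is.na(x)]))
  summary <- data.frame(
    level = c("individual", "individual", "snp", "snp"),
    metric = c("perc", "corr", "perc", "corr"),
    mean = c(summarize(per_ind$perc)[1], summarize(per_ind$corr)[1],
             summarize(per_snp$perc)[1], summarize(per_snp$corr)[1]),
    sd = c(summarize(per_ind$perc)[2], summarize(per_ind$corr)[2],
           summarize(per_snp$perc)[2], summarize(per_snp$corr)[2]),
    stringsAsFactors = FALSE
  )
  m <- ncol(truth)
  n_imputed <- m - length(scenario$chip$snp_ids)
  structure(list(
    per_individual = per_ind, per_snp = per_snp, summary = summary,
    n_imputed_snps = n_imputed, frac_imputed_snps = n_imputed / m,
    n_undefined_corr = c(individual = sum(is.na(per_ind$corr)),
                         snp = sum(is.na(per_snp$corr))),
    chip_name = scenario$chip$name
  ), class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("imputation accuracy, chip '%s': %d SNPs to impute (%.1f%%)\n",
              x$chip_name, x$n_imputed_snps, 100 * x$frac_imputed_snps))
  s <- x$summary
  for (r in seq_len(nrow(s))) {
    cat(sprintf("  by %s, %s: %.4f (%.4f)\n", s$level[r], toupper(s$metric[r]),
                s$mean[r], s$sd[r]))
  }
  if (any(x$n_undefined_corr > 0)) {
    cat(sprintf("  undefined CORR excluded: %d individual(s), %d SNP(s)\n",
                x$n_undefined_corr[["individual"]],
                x$n_undefined_corr[["snp"]]))
  }
  invisible(x)
}

#' Regress per-individual accuracy on relatedness to the reference set
#'
#' Ordinary least-squares polynomial regression of per-individual CORR on
#' Mean10 (the mean of each validation animal's 10 largest genomic
#' relationships with reference animals), at degree 1 (linear) or 2.
#'
#' @param result an [score_scenario()] result.
#' @param rel a [relatedness_summary()] covering the validation individuals.
#' @param degree polynomial degree, 1 or 2.
#' @return An object of class `accuracy_regression`: list with
#'   `coefficients` (intercept first), `r_squared`, `fitted` (data.frame id,
#'   mean10, corr, fitted), `degree` and the underlying `lm` fit.
#' @export
regress_accuracy_on_relatedness <- function(result, rel, degree = 1) {
  stopifnot(inherits(result, "accuracy_result"),
            inherits(rel, "relatedness_summary"), degree %in% c(1, 2))
  dat <- merge(result$per_individual[, c("id", "corr")],
               rel[, c("id", "mean10")], by = "id")
  dat <- dat[!is.na(dat$corr) & !is.na(dat$mean10), , drop = FALSE]
  if (nrow(dat) < degree + 2) {
    stop("need at least ", degree + 2,
         " individuals with defined CORR and Mean10")
  }
  fit <- stats::lm(corr ~ poly(mean10, degree, raw = TRUE), data = dat)
  # summary.lm warns on exact fits (zero residual); that case is legitimate
  # here (e.g. accuracy exactly linear in relatedness on constructed data)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    coefficients = unname(stats::coef(fit)),
    r_squared = r2,
    fitted = data.frame(id = dat$id, mean10 = dat$mean10, corr = dat$corr,
                        fitted = unname(stats::fitted(fit))),
    degree = degree, fit = fit
  ), class = "accuracy_regression")
}

#' @export
print.accuracy_regression <- function(x, ...) {
  cat(sprintf("CORR ~ Mean10 polynomial fit (degree %d)\n", x$degree))
  cat("  coefficients:", paste(sprintf("%.4g", x$coefficients),
                               collapse = ", "), "\n")
  cat(sprintf("  R-squared: %.4f on %d individuals\n", x$r_squared,
              nrow(x$fitted)))
  invisible(x)
}

#' Genome-window scan of SNP-wise imputation accuracy
#'
#' Splits the map into consecutive windows of `window_snps` markers per
#' chromosome (remainder windows allowed) and reports, per window, the mean
#' per-SNP CORR (defined values only), the mean MAF and the mean pairwise r²
#' among the window's markers. Windows whose mean CORR falls below
#' `flag_threshold` are flagged as poorly imputed regions.
#'
#' @param per_snp data.frame with columns `snp_id` and `corr` (e.g. the
#'   `per_snp` element of an [score_scenario()] result); SNPs of the map
#'   absent from it (the chip SNPs, which are not imputed) are ignored in the
#'   window means.
#' @param map the post-QC [marker_map()].
#' @param geno the [geno_matrix()] from which window MAF and r² are computed.
#' @param window_snps markers per window.
#' @param flag_threshold windows with mean CORR below this are flagged.
#' @return A data.frame of class `window_accuracy_report` with columns
#'   `chrom`, `start_bp`, `end_bp`, `n_snps`, `n_scored`, `mean_corr`,
#'   `mean_maf`, `mean_r2`, `flagged`.
#' @export
window_accuracy_scan <- function(per_snp, map, geno, window_snps = 50,
                                 flag_threshold = 0.60) {
  stopifnot(inherits(map, "marker_map"), inherits(geno, "geno_matrix"))
  check_geno_map(geno, map)
  if (nrow(map) == 0) stop("empty marker map")
  corr <- per_snp$corr[match(map$snp_id, per_snp$snp_id)]
  plan <- partition_windows(map, window_snps)
  rows <- lapply(seq_along(plan$windows), function(w) {
    idx <- plan$windows[[w]]
    cw <- corr[idx]
    mc <- if (all(is.na(cw))) NA_real_ else mean(cw, na.rm = TRUE)
    d <- geno$dosage[, idx, drop = FALSE]
    r2 <- r2_matrix(d)
    mean_r2 <- if (all(is.na(r2))) NA_real_ else
      mean(r2[upper.tri(r2)], na.rm = TRUE)
    data.frame(
      chrom = plan$chrom[w],
      start_bp = map$pos[idx[1]],
      end_bp = map$pos[idx[length(idx)]],
      n_snps = length(idx),
      n_scored = sum(!is.na(cw)),
      mean_corr = mc,
      mean_maf = mean(col_maf(d), na.rm = TRUE),
      mean_r2 = mean_r2,
      flagged = !is.na(mc) && mc < flag_threshold,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_accuracy_report", "data.frame")
  out
}
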