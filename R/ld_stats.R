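#' Pairwise linkage disequilibrium r-squared
#'
#' Composite (genotype-based) LD: the squared Pearson correlation of the two
#' dosage vectors over pairwise-complete individuals. Undefined (fewer than
#' two complete pairs, or either vector constant on the complete subset) is
#' returned as `NA` and excluded from any averaging downstream.
#'
#' @param x,y dosage vectors in `{0, 1, 2, NA}` of equal length.
#' @return r² in \[0, 1\], or `NA` when undefined.
#' @examples
#' ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 2))  # 0.7273
#' @export
ld_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Pairwise r-squared matrix for a set of SNPs
#'
#' @param d dosage matrix (individuals x SNPs).
#' @return Symmetric matrix of pairwise r² values with `NA` where undefined
#'   and `NA` on the diagonal.
#' @export
r2_matrix <- function(d) {
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  # pairs with < 2 complete observations: cor() may return values computed
  # from a single pair as NA already (sd = 0); square what remains
  r2 <- r^2
  diag(r2) <- NA
  r2
}

#' Per-SNP mean r-squared within a window
#'
#' For each SNP of a window, the mean of its defined pairwise r² values with
#' the other window members ("average linkage disequilibrium with other SNPs
#' from the same window"). A SNP whose pairs are all undefined — including
#' every SNP of a size-1 window — gets `NA`.
#'
#' @param d dosage matrix restricted to the window's SNPs.
#' @return Numeric vector of per-SNP mean r² (NA where undefined).
#' @export
window_avg_r2 <- function(d) {
  d <- as.matrix(d)
  if (ncol(d) < 2) return(rep(NA_real_, ncol(d)))
  r2 <- r2_matrix(d)
  out <- colMeans(r2, na.rm = TRUE)
  out[is.nan(out)] <- NA
  out
}

#' VanRaden genomic relationship matrix
#'
#' `G = M M' / sum(2 p_i (1 - p_i))`, where the i-th column of M holds the
#' centered dosages `0 - 2 p_i`, `1 - 2 p_i`, `2 - 2 p_i` for genotypes AA,
#' AB and BB, and `p_i` is the frequency of allele B at marker i. Residual
#' missing dosages are mean-imputed to `2 p_i` before centering (so they
#' contribute 0).
#'
#' @param geno a [geno_matrix()] of post-QC genotypes.
#' @param freqs optional per-SNP B-allele frequencies used for centering;
#'   default: computed from all individuals in `geno`.
#' @return An object of class `grm`: list with `ids`, `values` (symmetric
#'   n x n matrix) and `allele_freqs`.
#' @export
vanraden_grm <- function(geno, freqs = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- geno$dosage
  if (is.null(freqs)) {
    freqs <- colMeans(d, na.rm = TRUE) / 2
  }
  stopifnot(length(freqs) == ncol(d))
  denom <- sum(2 * freqs * (1 - freqs))
  if (denom <= 0) {
    stop("all allele frequencies are 0 or 1: zero GRM denominator")
  }
  m <- sweep(d, 2, 2 * freqs)
  m[is.na(m)] <- 0  # mean-imputed dosage centers to zero
  g <- tcrossprod(m) / denom
  structure(list(ids = rownames(d), values = g, allele_freqs = freqs),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("genomic relationship matrix: %d individuals, mean diagonal %.3f\n",
              length(x$ids), mean(diag(x$values))))
  invisible(x)
}

#' Maxr / Mean10 relatedness summary
#'
#' For each validation individual: `maxr`, the maximum genomic relationship
#' with any reference individual, and `mean10`, the mean of the 10 largest
#' such relationships (of all of them if the reference holds fewer than 10).
#'
#' @param grm a [vanraden_grm()] result.
#' @param reference_ids,validation_ids disjoint, non-empty id sets present in
#'   the GRM.
#' @return A data.frame of class `relatedness_summary` with columns `id`,
#'   `maxr`, `mean10`.
#' @export
relatedness_summary <- function(grm, reference_ids, validation_ids) {
  stopifnot(inherits(grm, "grm"))
  if (!length(reference_ids) || !length(validation_ids)) {
    stop("reference and validation sets must be non-empty")
  }
  if (length(intersect(reference_ids, validation_ids))) {
    stop("reference and validation sets overlap")
  }
  missing <- setdiff(c(reference_ids, validation_ids), grm$ids)
  if (length(missing)) {
    stop("ids absent from GRM: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  g <- grm$values[validation_ids, reference_ids, drop = FALSE]
  top <- min(10L, length(reference_ids))
  out <- data.frame(
    id = validation_ids,
    maxr = apply(g, 1, max),
    mean10 = apply(g, 1, function(r) mean(sort(r, decreasing = TRUE)[seq_len(top)])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("relatedness_summary", "data.frame")
  out
}

#' Pedigree additive (numerator) relationship matrix
#'
#' Expected additive relationships from the pedigree via the tabular method;
#' unknown parents contribute nothing. Used as the pedigree-side oracle
#' against which the genomic relationship matrix is checked.
#'
#' @param ped a [pedigree()].
#' @param ids optional subset of ids for the returned matrix.
#' @return Symmetric matrix of additive relationships with ids as dimnames.
#' @export
pedigree_additive_matrix <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  a <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    a[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * a[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1)
      rel <- 0.5 * ((if (!is.na(s)) a[j, s] else 0) +
                    (if (!is.na(d)) a[j, d] else 0))
      a[i, j] <- rel
      a[j, i] <- rel
    }
  }
  if (!is.null(ids)) {
    missing <- setdiff(ids, ped$id)
    if (length(missing)) stop("ids not in pedigree: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    a <- a[ids, ids, drop = FALSE]
  }
  a
}
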