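#' Marker map constructor
#'
#' A marker map is the coordinate system of the pipeline: one row per SNP with
#' its chromosome, 1-based physical position and the two alleles. Allele B is
#' the counted allele of the 0/1/2 dosage coding. Rows are sorted by
#' chromosome (autosomes first, in numeric order) and ascending position.
#'
#' @param snp_id character vector of unique marker names.
#' @param chrom chromosome labels; autosomes are the integers `1..n`,
#'   non-autosomal chromosomes keep their labels (e.g. `"X"`, `"MT"`).
#' @param pos integer vector of 1-based bp positions.
#' @param allele_a,allele_b allele labels; B is the counted allele.
#' @return A `data.frame` of class `marker_map` with columns `snp_id`,
#'   `chrom`, `pos`, `allele_a`, `allele_b`.
#' @examples
#' marker_map(c("s1", "s2"), c(1, 1), c(100, 200))
#' @export
marker_map <- function(snp_id, chrom, pos, allele_a = "A", allele_b = "B") {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) {
    stop("duplicate snp_id in marker map: ",
         paste(utils::head(snp_id[duplicated(snp_id)], 5), collapse = ", "))
  }
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) stop("positions must be integers >= 1")
  map <- data.frame(
    snp_id = snp_id,
    chrom = as.character(chrom),
    pos = pos,
    allele_a = rep_len(as.character(allele_a), length(snp_id)),
    allele_b = rep_len(as.character(allele_b), length(snp_id)),
    stringsAsFactors = FALSE
  )
  map <- map[order_chrom(map$chrom, map$pos), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  map
}

# chromosome ordering: numeric chromosomes first in numeric order, then others
order_chrom <- function(chrom, pos) {
  num <- suppressWarnings(as.integer(chrom))
  key <- ifelse(is.na(num), .Machine$integer.max, num)
  order(key, chrom, pos)
}

is_autosome <- function(chrom, n_autosomes) {
  num <- suppressWarnings(as.integer(chrom))
  !is.na(num) & num >= 1L & num <= n_autosomes
}

#' Genotype matrix constructor
#'
#' Holds an individuals x SNPs dosage matrix counting copies of allele B
#' (0, 1, 2), with `NA` as the missing-call sentinel, plus an optional
#' same-shape matrix of per-call quality scores in \[0, 1\] (GenCall-like).
#'
#' @param dosage numeric matrix with rownames = individual ids and colnames =
#'   snp ids; entries in `{0, 1, 2, NA}`.
#' @param quality optional numeric matrix of the same shape with per-call
#'   quality scores; `NULL` means every call has quality 1.
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   and `quality`.
#' @examples
#' g <- geno_matrix(matrix(c(0, 1, 2, NA), 2, 2,
#'   dimnames = list(c("a", "b"), c("s1", "s2"))))
#' dim(g)
#' @export
geno_matrix <- function(dosage, quality = NULL) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) > 0 && is.null(rownames(dosage))) {
    stop("dosage matrix needs individual rownames")
  }
  if (is.null(rownames(dosage))) rownames(dosage) <- character(0)
  if (ncol(dosage) > 0 && is.null(colnames(dosage))) {
    stop("dosage matrix needs snp colnames")
  }
  if (anyDuplicated(rownames(dosage))) stop("duplicate individual ids")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "double"
  if (!is.null(quality)) {
    quality <- as.matrix(quality)
    if (!identical(dim(quality), dim(dosage))) {
      stop("quality matrix must match dosage dimensions")
    }
    if (any(quality < 0 | quality > 1, na.rm = TRUE)) {
      stop("quality scores must lie in [0, 1]")
    }
    dimnames(quality) <- dimnames(dosage)
  }
  structure(list(dosage = dosage, quality = quality), class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' @export
dimnames.geno_matrix <- function(x) dimnames(x$dosage)

#' Subset a genotype matrix
#'
#' Row/column subsetting that keeps dosage and quality aligned.
#'
#' @param x a [geno_matrix()].
#' @param i,j row (individual) and column (SNP) indices.
#' @param ... ignored.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  geno_matrix(
    x$dosage[i, j, drop = FALSE],
    if (!is.null(x$quality)) x$quality[i, j, drop = FALSE]
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  d <- dim(x$dosage)
  nmiss <- sum(is.na(x$dosage))
  cat(sprintf("geno_matrix: %d individuals x %d SNPs (%.2f%% missing)%s\n",
              d[1], d[2], 100 * nmiss / max(1, prod(d)),
              if (is.null(x$quality)) "" else ", with quality scores"))
  invisible(x)
}

#' Pedigree constructor
#'
#' @param id individual ids (unique).
#' @param sire,dam parent ids; `NA` for unknown. Every known parent must
#'   itself be an entry (founders have both parents unknown).
#' @param birth_year integer birth years, `NA` allowed.
#' @param sex `"M"` or `"F"` (or `NA`).
#' @return A `data.frame` of class `pedigree`, ordered so that parents precede
#'   offspring.
#' @export
pedigree <- function(id, sire = NA, dam = NA, birth_year = NA, sex = NA) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  ped <- data.frame(
    id = id,
    sire = as.character(rep_len(sire, length(id))),
    dam = as.character(rep_len(dam, length(id))),
    birth_year = as.integer(rep_len(birth_year, length(id))),
    sex = as.character(rep_len(sex, length(id))),
    stringsAsFactors = FALSE
  )
  known <- c(ped$sire, ped$dam)
  known <- known[!is.na(known)]
  missing_parents <- setdiff(known, ped$id)
  if (length(missing_parents)) {
    stop("parents not present as pedigree entries: ",
         paste(utils::head(missing_parents, 5), collapse = ", "))
  }
  ped <- sort_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# topological sort; errors on a cycle (an individual being its own ancestor)
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- match(ped$id, ped$id)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(ped$id[!placed], 5), collapse = ", "))
  }
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chip definition constructor
#'
#' A named set of marker ids describing a (commercial or customized)
#' genotyping chip.
#'
#' @param name chip label.
#' @param snp_ids character vector of marker ids (deduplicated, order kept).
#' @return An object of class `chip_def`.
#' @export
chip_def <- function(name, snp_ids) {
  snp_ids <- as.character(snp_ids)
  snp_ids <- snp_ids[!duplicated(snp_ids)]
  structure(list(name = as.character(name)[1], snp_ids = snp_ids),
            class = "chip_def")
}

#' @export
print.chip_def <- function(x, ...) {
  cat(sprintf("chip_def '%s': %d SNPs\n", x$name, length(x$snp_ids)))
  invisible(x)
}

#' @export
length.chip_def <- function(x) length(x$snp_ids)
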