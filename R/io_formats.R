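#' Read genotypes, marker map (and dosages) from standard formats
#'
#' Supports PLINK text (PED/MAP), PLINK binary (BED/BIM/FAM, PLINK 1.9
#' SNP-major) and VCF v4.2 (GT field only; parsed via the vcfR package).
#' Dosage counts copies of allele B; when a format does not fix which allele
#' is counted, the second allele listed in the map (BIM A2, VCF ALT) is B.
#' Missing calls become `NA`.
#'
#' @param path for `"ped"` and `"bed"`, the file prefix (without extension);
#'   for `"vcf"`, the VCF file path.
#' @param format one of `"ped"`, `"bed"`, `"vcf"`.
#' @param quality_file optional path to a per-call quality sidecar (TSV with
#'   columns individual, snp, score); calls not listed get score 1.
#' @return A list with elements `geno` ([geno_matrix()]) and `map`
#'   ([marker_map()]).
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("ped", "bed", "vcf"),
                           quality_file = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    ped = read_ped(path),
    bed = read_bed(path),
    vcf = read_vcf(path)
  )
  if (!is.null(quality_file)) {
    out$geno <- attach_quality(out$geno, read_quality_sidecar(quality_file))
  }
  out
}

#' Write genotypes and marker map to standard formats
#'
#' Inverse of [read_genotypes()]: round-trips dosage (including missing
#' calls), marker order and alleles through PED/MAP, BED/BIM/FAM or VCF.
#'
#' @param geno a [geno_matrix()].
#' @param map the matching [marker_map()] (column order of `geno` must equal
#'   `map$snp_id`).
#' @param path file prefix (PED/BED) or file path (VCF).
#' @inheritParams read_genotypes
#' @return Invisibly, the paths written.
#' @export
write_genotypes <- function(geno, map, path, format = c("ped", "bed", "vcf")) {
  format <- match.arg(format)
  check_geno_map(geno, map)
  if (nrow(geno$dosage) == 0L) stop("refusing to write zero individuals")
  switch(format,
    ped = write_ped(geno, map, path),
    bed = write_bed(geno, map, path),
    vcf = write_vcf(geno, map, path)
  )
}

check_geno_map <- function(geno, map) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(map, "marker_map"))
  if (!identical(colnames(geno$dosage), map$snp_id)) {
    stop("genotype columns do not match the marker map order")
  }
  invisible(TRUE)
}

# ---- PLINK text (PED/MAP) ----------------------------------------------

read_map_file <- function(file) {
  tab <- utils::read.table(file, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  list(chrom = as.character(tab$chrom), snp_id = as.character(tab$snp_id),
       pos = as.integer(tab$pos))
}

read_ped <- function(prefix) {
  ped_file <- paste0(prefix, ".ped")
  map_file <- paste0(prefix, ".map")
  if (!file.exists(ped_file) || !file.exists(map_file)) {
    stop("missing ", ped_file, " or ", map_file)
  }
  m <- read_map_file(map_file)
  lines <- readLines(ped_file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PED file: ", ped_file)
  n_snps <- length(m$snp_id)
  alleles_a <- alleles_b <- character(n_snps)
  dosage <- matrix(NA_real_, length(lines), n_snps)
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * n_snps) {
      stop(sprintf("PED line %d: expected %d fields, found %d",
                   i, 6L + 2L * n_snps, length(f)))
    }
    ids[i] <- f[2]
    a1 <- f[seq(7L, by = 2L, length.out = n_snps)]
    a2 <- f[seq(8L, by = 2L, length.out = n_snps)]
    present <- a1 != "0" & a2 != "0"
    for (j in which(present)) {
      for (al in c(a1[j], a2[j])) {
        if (alleles_a[j] == "") {
          alleles_a[j] <- al
        } else if (alleles_a[j] != al && alleles_b[j] == "") {
          alleles_b[j] <- al
        } else if (al != alleles_a[j] && al != alleles_b[j]) {
          stop(sprintf("PED line %d, SNP %s: more than two alleles", i,
                       m$snp_id[j]))
        }
      }
    }
  }
  # PED/MAP does not name the counted allele; order the two observed labels
  # lexicographically so that allele B (the counted one) is deterministic
  swap <- alleles_b != "" & alleles_b < alleles_a
  tmp <- alleles_a[swap]
  alleles_a[swap] <- alleles_b[swap]
  alleles_b[swap] <- tmp
  alleles_a[alleles_a == ""] <- "A"
  alleles_b[alleles_b == ""] <- "B"
  # second pass: dosage = copies of allele B
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    a1 <- f[seq(7L, by = 2L, length.out = n_snps)]
    a2 <- f[seq(8L, by = 2L, length.out = n_snps)]
    present <- a1 != "0" & a2 != "0"
    dosage[i, present] <- (a1 == alleles_b)[present] + (a2 == alleles_b)[present]
  }
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", ped_file)
  rownames(dosage) <- ids
  colnames(dosage) <- m$snp_id
  map <- marker_map(m$snp_id, m$chrom, m$pos, alleles_a, alleles_b)
  dosage <- dosage[, map$snp_id, drop = FALSE]
  list(geno = geno_matrix(dosage), map = map)
}

write_ped <- function(geno, map, prefix) {
  ped_file <- paste0(prefix, ".ped")
  map_file <- paste0(prefix, ".map")
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0L, map$pos),
    map_file, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  d <- geno$dosage
  n <- nrow(d)
  ids <- rownames(d)
  lines <- character(n)
  a <- map$allele_a
  b <- map$allele_b
  for (i in seq_len(n)) {
    x <- d[i, ]
    a1 <- ifelse(is.na(x), "0", ifelse(x >= 1, b, a))
    a2 <- ifelse(is.na(x), "0", ifelse(x == 2, b, a))
    gt <- character(2L * length(x))
    gt[c(TRUE, FALSE)] <- a1
    gt[c(FALSE, TRUE)] <- a2
    lines[i] <- paste(c(ids[i], ids[i], "0", "0", "0", "-9", gt),
                      collapse = " ")
  }
  writeLines(lines, ped_file)
  invisible(c(ped_file, map_file))
}

# ---- PLINK binary (BED/BIM/FAM) ----------------------------------------

read_bed <- function(prefix) {
  bed_file <- paste0(prefix, ".bed")
  bim_file <- paste0(prefix, ".bim")
  fam_file <- paste0(prefix, ".fam")
  for (f in c(bed_file, bim_file, fam_file)) {
    if (!file.exists(f)) stop("missing ", f)
  }
  bim <- utils::read.table(bim_file, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "a1", "a2"))
  fam <- utils::read.table(fam_file, header = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(fam[[2]])
  n <- length(ids)
  m <- nrow(bim)
  raw <- readBin(bed_file, "raw", n = file.info(bed_file)$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK BED file (bad magic bytes): ", bed_file)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major BED files are supported")
  bpS <- ceiling(n / 4)
  if (length(raw) - 3L != bpS * m) {
    stop(sprintf("BED size mismatch: expected %d data bytes, found %d",
                 bpS * m, length(raw) - 3L))
  }
  body <- raw[-(1:3)]
  # decode 2-bit codes, individual 1 in the lowest bits of each byte
  codes <- matrix(0L, 4L * bpS, m)
  ints <- as.integer(body)
  dim(ints) <- c(bpS, m)
  for (k in 0:3) {
    codes[seq(k + 1L, by = 4L, length.out = bpS), ] <-
      (ints %/% 4L^k) %% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(0, NA, 1, 2)  # 00 homA1, 01 missing, 10 het, 11 homA2
  dosage <- matrix(lookup[codes + 1L], n, m)
  rownames(dosage) <- ids
  colnames(dosage) <- bim$snp_id
  map <- marker_map(bim$snp_id, bim$chrom, bim$pos, bim$a1, bim$a2)
  dosage <- dosage[, map$snp_id, drop = FALSE]
  list(geno = geno_matrix(dosage), map = map)
}

write_bed <- function(geno, map, prefix) {
  bed_file <- paste0(prefix, ".bed")
  bim_file <- paste0(prefix, ".bim")
  fam_file <- paste0(prefix, ".fam")
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0L, map$pos, map$allele_a, map$allele_b),
    bim_file, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  ids <- rownames(geno$dosage)
  utils::write.table(
    data.frame(ids, ids, 0L, 0L, 0L, -9L),
    fam_file, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " "
  )
  d <- geno$dosage
  n <- nrow(d)
  m <- ncol(d)
  bpS <- ceiling(n / 4)
  code <- matrix(1L, 4L * bpS, m)  # pad with "missing"
  enc <- c(0L, 2L, 3L)             # dosage 0/1/2 -> 2-bit code
  code[seq_len(n), ] <- ifelse(is.na(d), 1L, enc[d + 1L])
  weights <- 4L^(0:3)
  bytes <- integer(bpS * m)
  dim(bytes) <- c(bpS, m)
  for (k in 0:3) {
    bytes <- bytes + weights[k + 1L] *
      code[seq(k + 1L, by = 4L, length.out = bpS), , drop = FALSE]
  }
  con <- file(bed_file, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(c(bed_file, bim_file, fam_file))
}

# ---- VCF ----------------------------------------------------------------

read_vcf <- function(path) {
  if (!file.exists(path)) stop("missing VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  # dosage = number of ALT (allele B) alleles in the GT string
  gt_clean <- gsub("\\|", "/", gt)
  count_alt <- function(s) {
    if (is.na(s) || s %in% c("./.", ".")) return(NA_real_)
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (any(parts == ".")) return(NA_real_)
    sum(parts == "1")
  }
  dosage <- t(apply(gt_clean, c(1, 2), count_alt))
  rownames(dosage) <- colnames(gt)
  colnames(dosage) <- fix[, "ID"]
  map <- marker_map(fix[, "ID"], fix[, "CHROM"], as.integer(fix[, "POS"]),
                    fix[, "REF"], fix[, "ALT"])
  dosage <- dosage[, map$snp_id, drop = FALSE]
  list(geno = geno_matrix(dosage), map = map)
}

write_vcf <- function(geno, map, path) {
  d <- geno$dosage
  ids <- rownames(d)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ldpanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    gt <- ifelse(is.na(x), "./.", gt_code[x + 1L])
    paste(c(map$chrom[j], map$pos[j], map$snp_id[j], map$allele_a[j],
            map$allele_b[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- quality sidecar ----------------------------------------------------

#' Read / write a per-call quality sidecar
#'
#' PED/BED cannot carry per-call quality scores, so they travel in a TSV
#' sidecar with columns `individual`, `snp`, `score`. Calls absent from the
#' sidecar get score 1.0.
#'
#' @param path sidecar file path.
#' @return `read_quality_sidecar`: a data.frame with columns `individual`,
#'   `snp`, `score`.
#' @export
read_quality_sidecar <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "snp", "score") %in% names(tab)))
  tab
}

#' @rdname read_quality_sidecar
#' @param geno a [geno_matrix()] whose quality the sidecar describes.
#' @export
write_quality_sidecar <- function(geno, path) {
  q <- geno$quality
  if (is.null(q)) stop("genotype matrix carries no quality scores")
  idx <- which(q < 1, arr.ind = TRUE)
  tab <- data.frame(individual = rownames(q)[idx[, 1]],
                    snp = colnames(q)[idx[, 2]],
                    score = q[idx])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

attach_quality <- function(geno, sidecar) {
  q <- matrix(1, nrow(geno$dosage), ncol(geno$dosage),
              dimnames = dimnames(geno$dosage))
  ri <- match(sidecar$individual, rownames(q))
  ci <- match(sidecar$snp, colnames(q))
  keep <- !is.na(ri) & !is.na(ci)
  q[cbind(ri[keep], ci[keep])] <- sidecar$score[keep]
  geno_matrix(geno$dosage, q)
}

# ---- pedigree file ------------------------------------------------------

#' Read / write a pedigree file
#'
#' Plain 5-column whitespace-separated text: id, sire, dam, birth_year, sex,
#' with `0` denoting an unknown parent or year.
#'
#' @param path file path.
#' @return `read_pedigree_file`: a [pedigree()].
#' @export
read_pedigree_file <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "sire", "dam", "birth_year",
                                         "sex"))
  unknown <- function(x) ifelse(x %in% c("0", "NA"), NA, x)
  pedigree(as.character(tab$id), unknown(as.character(tab$sire)),
           unknown(as.character(tab$dam)),
           ifelse(tab$birth_year == 0, NA, tab$birth_year),
           as.character(tab$sex))
}

#' @rdname read_pedigree_file
#' @param ped a [pedigree()].
#' @export
write_pedigree_file <- function(ped, path) {
  unk <- function(x) ifelse(is.na(x), "0", as.character(x))
  utils::write.table(
    data.frame(ped$id, unk(ped$sire), unk(ped$dam), unk(ped$birth_year),
               ped$sex),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " "
  )
  invisible(path)
}

# ---- chip manifests -----------------------------------------------------

#' Read a chip manifest
#'
#' One marker id per line; blank lines and `#` comments are ignored.
#'
#' @param path manifest file.
#' @param name chip name; defaults to the file name without extension.
#' @return A [chip_def()].
#' @export
read_chip_manifest <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty chip manifest: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  chip_def(name, lines)
}

#' Write a chip manifest
#'
#' @param chip a [chip_def()].
#' @param path output file.
#' @export
write_chip_manifest <- function(chip, path) {
  writeLines(c(paste0("# chip: ", chip$name), chip$snp_ids), path)
  invisible(path)
}

#' Intersect a chip with a marker map
#'
#' Restricts a chip to markers present in the map (e.g. the post-QC map),
#' reporting how many ids were dropped. This is the "number of SNPs shared
#' with the HD chip after QC" operation.
#'
#' @param chip a [chip_def()].
#' @param map a [marker_map()].
#' @return A [chip_def()] whose ids all occur in `map`, with attribute
#'   `n_dropped` (count of manifest ids absent from the map).
#' @export
intersect_chip <- function(chip, map) {
  keep <- chip$snp_ids %in% map$snp_id
  if (!any(keep)) stop("empty chip after intersection with the map")
  out <- chip_def(chip$name, chip$snp_ids[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}
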