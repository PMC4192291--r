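#' Partition a marker map into consecutive windows
#'
#' Per chromosome, consecutive blocks of `k` markers in map order; a trailing
#' remainder (< k markers) forms a final short window. Windows never span
#' chromosomes.
#'
#' @param map a [marker_map()] (typically post-QC).
#' @param k window size in markers (>= 1).
#' @return An object of class `windowing_plan`: list with `windows` (list of
#'   integer row-index vectors into `map`), `chrom` (per-window chromosome)
#'   and `k`.
#' @examples
#' m <- marker_map(paste0("s", 1:10), rep(1, 10), 1:10 * 100)
#' lengths(partition_windows(m, 3)$windows)  # 3 3 3 1
#' @export
partition_windows <- function(map, k) {
  stopifnot(inherits(map, "marker_map"))
  if (nrow(map) == 0) stop("empty marker map")
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("window size k must be >= 1")
  windows <- list()
  chroms <- character(0)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    starts <- seq(1L, length(idx), by = k)
    for (s in starts) {
      windows[[length(windows) + 1L]] <- idx[s:min(s + k - 1L, length(idx))]
      chroms <- c(chroms, ch)
    }
  }
  structure(list(windows = windows, chrom = chroms, k = k),
            class = "windowing_plan")
}

normalize_criterion <- function(criterion) {
  aliases <- c(e = "even_last", em = "max_maf", el = "max_avg_r2",
               eml = "max_maf_times_r2",
               even_last = "even_last", max_maf = "max_maf",
               max_avg_r2 = "max_avg_r2",
               max_maf_times_r2 = "max_maf_times_r2")
  out <- aliases[criterion]
  if (is.na(out)) stop("unknown selection criterion: ", criterion)
  unname(out)
}

# pick one map row index from a window by criterion; ties and the even_last
# fallback resolve to a deterministic choice (map order = ascending bp)
select_in_window <- function(idx, d_ref, criterion) {
  if (criterion == "even_last") return(idx[length(idx)])
  score <- switch(criterion,
    max_maf = col_maf(d_ref[, idx, drop = FALSE]),
    max_avg_r2 = window_avg_r2(d_ref[, idx, drop = FALSE]),
    max_maf_times_r2 = col_maf(d_ref[, idx, drop = FALSE]) *
      window_avg_r2(d_ref[, idx, drop = FALSE])
  )
  if (all(is.na(score))) return(idx[length(idx)])  # fall back to even_last
  idx[which.max(score)]  # which.max: first maximum = lowest bp position
}

#' Design a customized chip by windowed SNP selection
#'
#' Selects exactly one SNP from each window of `k` subsequent markers of the
#' post-QC map, by one of four criteria: `even_last` (the last marker of each
#' window, giving even spacing), `max_maf` (highest minor allele frequency),
#' `max_avg_r2` (highest average linkage disequilibrium r² with the other
#' window members) or `max_maf_times_r2` (highest MAF x average r² product).
#' Ties break to the lowest bp position; windows where a criterion is
#' undefined for every member fall back to `even_last`.
#'
#' @param geno a post-QC [geno_matrix()].
#' @param map the matching post-QC [marker_map()].
#' @param k window size in markers.
#' @param criterion `"even_last"`, `"max_maf"`, `"max_avg_r2"`,
#'   `"max_maf_times_r2"` (short aliases `"e"`, `"em"`, `"el"`, `"eml"`).
#' @param reference_ids individuals on which MAF/r² are computed; default all.
#' @param name chip name; default derived from k and criterion.
#' @return A [chip_def()] with one SNP per window.
#' @export
design_chip <- function(geno, map, k, criterion = "even_last",
                        reference_ids = NULL, name = NULL) {
  check_geno_map(geno, map)
  criterion <- normalize_criterion(criterion)
  if (is.null(reference_ids)) reference_ids <- rownames(geno$dosage)
  d_ref <- geno$dosage[reference_ids, , drop = FALSE]
  plan <- partition_windows(map, k)
  picked <- vapply(plan$windows, select_in_window, integer(1),
                   d_ref = d_ref, criterion = criterion)
  if (is.null(name)) name <- sprintf("custom_k%d_%s", as.integer(k), criterion)
  chip_def(name, map$snp_id[picked])
}

#' Design an add-on chip over a commercial base chip
#'
#' Augments a base chip (e.g. a commercial 7K panel) with one SNP per window
#' of `k` subsequent markers, where the windows are partitioned over the
#' post-QC map *excluding* the base-chip SNPs. The result is the union of the
#' base chip and the selected SNPs, so its size is `|base| + number of
#' windows` exactly.
#'
#' @inheritParams design_chip
#' @param base a [chip_def()] already intersected with `map`. An empty base
#'   degenerates to [design_chip()] (with a warning).
#' @export
design_addon_chip <- function(geno, map, base, k,
                              criterion = "max_maf_times_r2",
                              reference_ids = NULL, name = NULL) {
  check_geno_map(geno, map)
  criterion <- normalize_criterion(criterion)
  if (is.null(name)) {
    name <- sprintf("addon_k%d_%s_on_%s", as.integer(k), criterion, base$name)
  }
  base_ids <- intersect(base$snp_ids, map$snp_id)
  if (!length(base_ids)) {
    warning("empty base chip: degenerating to design_chip()")
    return(design_chip(geno, map, k, criterion, reference_ids, name))
  }
  rest <- !(map$snp_id %in% base_ids)
  if (!any(rest)) return(chip_def(name, base_ids))  # base saturates the map
  map_rest <- map[rest, , drop = FALSE]
  class(map_rest) <- c("marker_map", "data.frame")
  geno_rest <- geno[, which(rest)]
  added <- design_chip(geno_rest, map_rest, k, criterion, reference_ids,
                       name = "tmp")
  chip_def(name, c(base_ids, added$snp_ids))
}

#' Restrict a commercial chip manifest to the post-QC map
#'
#' The "number of SNPs shared with the HD chip after QC" operation: markers
#' of the manifest that survive on the post-QC map define the chip actually
#' available to validation animals.
#'
#' @param map the post-QC [marker_map()].
#' @param manifest a [chip_def()] read from a manifest file.
#' @return A [chip_def()] (see [intersect_chip()]); errors if the
#'   intersection is empty.
#' @export
mimic_commercial_chip <- function(map, manifest) {
  intersect_chip(manifest, map)
}
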