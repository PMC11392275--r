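# Pseudo-bulk ATAC accessibility: tiling the genome into 500-kb
# compartment-labelled windows, counting fragment midpoints per window,
# the per-group median-log2 autosomal adjustment (so -1 reads as a
# two-fold drop in accessibility), zone-split pseudo-bulks, per-cell
# counts in peaks, and the window-level rank test.

#' Tile the genome into fixed-size windows labelled by compartment
#'
#' Half-open tiling `[0, w), [w, 2w), ...` of every chromosome; the
#' trailing partial window is retained. Each window takes the
#' compartment of the region-map span covering its midpoint
#' (`AUTOSOME` when no span covers it).
#'
#' @param region_map `RegionMap` of compartment spans.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param window_size window width in bp (default 500,000).
#' @param min_fraction drop terminal windows shorter than this fraction
#'   of `window_size` (default 0: keep all).
#' @return data.frame of class `WindowGrid`: `chromosome`, `start`,
#'   `end`, `compartment`; `window_size` stored as an attribute.
#' @export
tile_genome <- function(region_map, chrom_sizes, window_size = 5e5,
                        min_fraction = 0) {
  stopifnot(inherits(region_map, "RegionMap"))
  if (window_size <= 0) stop("window_size must be positive")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  out <- lapply(names(chrom_sizes), function(chr) {
    size <- chrom_sizes[[chr]]
    start <- seq(0, size - 1, by = window_size)
    data.frame(chromosome = chr, start = start,
               end = pmin(start + window_size, size),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, out)
  if (min_fraction > 0)
    grid <- grid[(grid$end - grid$start) >= min_fraction * window_size, ,
                 drop = FALSE]
  mid <- (grid$start + grid$end) / 2
  grid$compartment <- "AUTOSOME"
  for (i in seq_len(nrow(region_map))) {
    hit <- grid$chromosome == region_map$chromosome[i] &
      mid >= region_map$start[i] & mid < region_map$end[i]
    grid$compartment[hit] <- region_map$compartment[i]
  }
  rownames(grid) <- NULL
  structure(grid, window_size = window_size,
            class = c("WindowGrid", "data.frame"))
}

#' Count ATAC fragments per genomic window (pseudo-bulk)
#'
#' Each fragment is assigned to the single window containing its
#' midpoint and contributes its support count. Fragments on chromosomes
#' absent from the grid are skipped and tallied in
#' `attr(, "skipped_support")`.
#'
#' @param fragments `FragmentSet`.
#' @param grid `WindowGrid` from [tile_genome()].
#' @param cell_subset optional barcodes to pool; `NULL` pools all.
#' @param group label stored in `attr(, "group")`.
#' @return data.frame of class `PseudoBulkCounts`: the grid plus a
#'   `count` column.
#' @export
count_fragments <- function(fragments, grid, cell_subset = NULL,
                            group = "all") {
  stopifnot(inherits(fragments, "FragmentSet"),
            inherits(grid, "WindowGrid"))
  fr <- fragments
  if (!is.null(cell_subset))
    fr <- fr[fr$barcode %in% cell_subset, , drop = FALSE]
  counts <- numeric(nrow(grid))
  skipped <- 0
  mid <- (fr$start + fr$end) %/% 2
  for (chr in unique(fr$chromosome)) {
    g <- which(grid$chromosome == chr)
    sel <- fr$chromosome == chr
    if (!length(g)) {
      skipped <- skipped + sum(fr$support[sel])
      next
    }
    # windows per chromosome are ordered, contiguous from 0
    idx <- findInterval(mid[sel], grid$start[g])
    ok <- idx >= 1 & mid[sel] < grid$end[g][pmax(idx, 1)]
    skipped <- skipped + sum(fr$support[sel][!ok])
    if (any(ok)) {
      add <- tapply(fr$support[sel][ok], idx[ok], sum)
      counts[g[as.integer(names(add))]] <-
        counts[g[as.integer(names(add))]] + as.numeric(add)
    }
  }
  out <- as.data.frame(grid)
  out$count <- counts
  structure(out, group = group, skipped_support = skipped,
            window_size = attr(grid, "window_size"),
            class = c("PseudoBulkCounts", "data.frame"))
}

#' Median-log2 autosomal adjustment of window counts
#'
#' For one pseudo-bulk, `adjusted_log2 = log2(count) - median(log2(count)
#' over autosomal windows)`. Zero-count windows are excluded from both
#' the median and the output, so the adjusted autosomal median is
#' exactly 0 and a value of -1 corresponds to a two-fold decrease in
#' fragment counts.
#'
#' @param counts `PseudoBulkCounts` from [count_fragments()].
#' @return `PseudoBulkCounts` restricted to nonzero windows, with an
#'   `adjusted_log2` column.
#' @export
adjust_log2 <- function(counts) {
  stopifnot(inherits(counts, "PseudoBulkCounts"))
  nz <- counts$count > 0
  auto <- nz & counts$compartment == "AUTOSOME"
  if (!any(auto))
    stop("no autosomal windows with nonzero counts in group ",
         attr(counts, "group"))
  med <- median(log2(counts$count[auto]))
  out <- counts[nz, , drop = FALSE]
  out$adjusted_log2 <- log2(out$count) - med
  rownames(out) <- NULL
  structure(out, group = attr(counts, "group"),
            skipped_support = attr(counts, "skipped_support"),
            window_size = attr(counts, "window_size"),
            class = c("PseudoBulkCounts", "data.frame"))
}

#' Zone-split pseudo-bulk window counts within a cluster
#'
#' Splits a cluster's cells by their dosage zone, pools the ATAC
#' fragments of each zone into its own pseudo-bulk, and applies the
#' autosomal median-log2 adjustment per zone. Zones without cells are
#' omitted with a warning.
#'
#' @param fragments `FragmentSet`.
#' @param grid `WindowGrid`.
#' @param cells `CellTable`.
#' @param zones `ZoneClassification`.
#' @param cluster cluster to split.
#' @return named list of adjusted `PseudoBulkCounts` (one per zone).
#' @export
zone_pseudobulks <- function(fragments, grid, cells, zones, cluster) {
  stopifnot(inherits(zones, "ZoneClassification"))
  cl <- cells$cluster[match(zones$barcode, cells$barcode)]
  out <- list()
  for (z in c("DC", "LACK", "REPRESSED")) {
    bc <- zones$barcode[cl == cluster & zones$zone == z]
    if (!length(bc)) {
      warning("no ", z, " cells in cluster ", cluster)
      next
    }
    pb <- count_fragments(fragments, grid, cell_subset = bc,
                          group = paste(cluster, z, sep = "."))
    out[[z]] <- adjust_log2(pb)
  }
  out
}

#' Per-cell fragment counts in peaks
#'
#' Overlapping peak intervals are merged (unioned) first; a fragment
#' contributes its support once if it overlaps any merged peak by at
#' least 1 bp.
#'
#' @param fragments `FragmentSet`.
#' @param peaks data.frame with `chromosome`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @param cells optional `CellTable`; if given, all its barcodes appear
#'   in the output (zero counts included).
#' @return data.frame: `barcode`, `peak_counts`.
#' @export
counts_in_peaks <- function(fragments, peaks, cells = NULL) {
  stopifnot(inherits(fragments, "FragmentSet"))
  hit_support <- setNames(numeric(0), character(0))
  acc <- list()
  for (chr in unique(peaks$chromosome)) {
    pk <- peaks[peaks$chromosome == chr, , drop = FALSE]
    ir_pk <- IRanges::reduce(IRanges::IRanges(pk$start + 1, pk$end))
    fr <- fragments[fragments$chromosome == chr, , drop = FALSE]
    if (!nrow(fr)) next
    ir_fr <- IRanges::IRanges(fr$start + 1, fr$end)
    ov <- IRanges::overlapsAny(ir_fr, ir_pk)
    if (any(ov))
      acc[[chr]] <- data.frame(barcode = fr$barcode[ov],
                               support = fr$support[ov],
                               stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, acc)
  bc_all <- if (is.null(cells)) unique(fragments$barcode) else cells$barcode
  counts <- setNames(numeric(length(bc_all)), bc_all)
  if (!is.null(hits)) {
    s <- tapply(hits$support, hits$barcode, sum)
    s <- s[names(s) %in% bc_all]
    counts[names(s)] <- as.numeric(s)
  }
  data.frame(barcode = bc_all, peak_counts = unname(counts),
             stringsAsFactors = FALSE)
}

#' Rank-sum test between two compartments' adjusted window values
#'
#' Two-sided Wilcoxon rank-sum test on the `adjusted_log2` values of the
#' windows of two compartments within one adjusted pseudo-bulk.
#'
#' @param adjusted adjusted `PseudoBulkCounts` (see [adjust_log2()]).
#' @param compartment_a,compartment_b compartments to compare (defaults
#'   `"S0"` vs `"AUTOSOME"`).
#' @param mode passed to [wilcoxon_test()].
#' @return list: `statistic`, `p.value`, `mode`, plus window counts
#'   `n_a`, `n_b`.
#' @export
window_rank_test <- function(adjusted, compartment_a = "S0",
                             compartment_b = "AUTOSOME", mode = "AUTO") {
  stopifnot(inherits(adjusted, "PseudoBulkCounts"))
  if (is.null(adjusted$adjusted_log2))
    stop("run adjust_log2() first")
  a <- adjusted$adjusted_log2[adjusted$compartment == compartment_a]
  b <- adjusted$adjusted_log2[adjusted$compartment == compartment_b]
  if (!length(a) || !length(b)) stop("empty window set")
  res <- wilcoxon_test(a, b, mode = mode)
  res$n_a <- length(a)
  res$n_b <- length(b)
  res
}
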