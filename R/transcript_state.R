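# Per-cluster transcriptional-activity metrics: total RNA counts per
# cell and the spliced/unspliced composition of each cluster's pooled
# transcripts. A high spliced fraction flags reduced nascent
# transcription (transcriptional shutdown) in late germ cells.

#' Per-cell total UMI counts with cluster labels
#'
#' @param mat RAW `ExpressionMatrix`.
#' @param cells `CellTable`.
#' @return data.frame: `barcode`, `cluster`, `lineage`, `total_counts`.
#' @export
per_cell_totals <- function(mat, cells) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$norm_state != "RAW")
    stop("totals are computed on raw counts")
  m <- match(rownames(mat$counts), cells$barcode)
  data.frame(barcode = rownames(mat$counts),
             cluster = cells$cluster[m], lineage = cells$lineage[m],
             total_counts = Matrix::rowSums(mat$counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pooled spliced/unspliced composition per cluster
#'
#' Sums the spliced and unspliced layers over the cells of each cluster
#' and reports the spliced percentage. Clusters with zero pooled UMIs
#' get `NA` with a warning.
#'
#' @param mat RAW `ExpressionMatrix` with `spliced` and `unspliced`
#'   layers.
#' @param cells `CellTable`.
#' @return data.frame of class `SpliceSummary`: `cluster`,
#'   `spliced_total`, `unspliced_total`, `spliced_percent`.
#' @export
splice_summary <- function(mat, cells) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!all(c("spliced", "unspliced") %in% names(mat$layers)))
    stop("spliced and unspliced layers required")
  cl <- cells$cluster[match(rownames(mat$counts), cells$barcode)]
  sp <- tapply(Matrix::rowSums(mat$layers$spliced), cl, sum)
  un <- tapply(Matrix::rowSums(mat$layers$unspliced), cl, sum)
  tot <- sp + un
  if (any(tot == 0))
    warning("cluster(s) with zero pooled UMIs: ",
            paste(names(tot)[tot == 0], collapse = ", "))
  out <- data.frame(cluster = names(sp),
                    spliced_total = as.numeric(sp),
                    unspliced_total = as.numeric(un),
                    spliced_percent = ifelse(tot > 0, 100 * sp / tot,
                                             NA_real_),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("SpliceSummary", "data.frame")
  out
}

#' Chi-square test of splice composition: one cluster vs the rest
#'
#' 2x2 contingency table of pooled (spliced, unspliced) transcript
#' counts in the target cluster vs all other clusters pooled, tested
#' with the Pearson chi-square test.
#'
#' @param summary `SpliceSummary` from [splice_summary()].
#' @param target_cluster the cluster of interest.
#' @param yates apply the continuity correction (default off).
#' @return list: `statistic`, `df`, `p.value`, `table`, `stars`.
#' @export
splice_enrichment_test <- function(summary, target_cluster, yates = FALSE) {
  stopifnot(inherits(summary, "SpliceSummary"))
  if (nrow(summary) < 2) stop("need at least two clusters")
  it <- summary$cluster == target_cluster
  if (!any(it)) stop("unknown cluster ", target_cluster)
  tab <- rbind(target = c(sum(summary$spliced_total[it]),
                          sum(summary$unspliced_total[it])),
               rest = c(sum(summary$spliced_total[!it]),
                        sum(summary$unspliced_total[!it])))
  colnames(tab) <- c("spliced", "unspliced")
  res <- chi_square_test(tab, yates = yates)
  res$table <- tab
  res$stars <- p_stars(res$p.value)
  res
}
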