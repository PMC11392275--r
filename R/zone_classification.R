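# Classification of adjusted per-cell dosage ratios into regulatory
# zones (dosage compensated / lack of compensation / repressed), zone
# proportions per cluster, and chi-square enrichment tests against the
# pooled somatic reference.

classify_cutoffs <- function(adjusted, upper_cut, lower_cut, scheme) {
  if (!(lower_cut > 0 && lower_cut < upper_cut))
    stop("need 0 < lower_cut < upper_cut")
  if (is.null(adjusted$adjusted_ratio))
    stop("ratios are unadjusted; run somatic_adjust() first")
  r <- adjusted$adjusted_ratio
  zone <- ifelse(is.na(r), "UNDEFINED",
                 ifelse(r > upper_cut, "DC",
                        ifelse(r > lower_cut, "LACK", "REPRESSED")))
  out <- data.frame(barcode = adjusted$barcode,
                    zone = factor(zone, levels = ZONES),
                    stringsAsFactors = FALSE)
  structure(out, scheme = scheme, upper_cut = upper_cut,
            lower_cut = lower_cut,
            class = c("ZoneClassification", "data.frame"))
}

#' Classify cells under the fixed cutoff scheme
#'
#' Tripartition of the adjusted compartment:autosome ratio:
#' dosage compensated (`DC`) if ratio > 0.66, lack of compensation
#' (`LACK`) if 0.33 < ratio <= 0.66, repressed (`REPRESSED`) if
#' ratio <= 0.33. Boundaries are inclusive downward (0.66 is `LACK`,
#' 0.33 is `REPRESSED`). Cells with undefined ratios are `UNDEFINED`.
#'
#' @param adjusted `RatioTable` with `adjusted_ratio` (see
#'   [somatic_adjust()]).
#' @param upper_cut,lower_cut the zone boundaries (defaults 0.66, 0.33).
#' @return data.frame of class `ZoneClassification` (`barcode`, `zone`)
#'   with the scheme and cutoffs in attributes.
#' @export
classify_fixed <- function(adjusted, upper_cut = 0.66, lower_cut = 0.33) {
  classify_cutoffs(adjusted, upper_cut, lower_cut, scheme = "FIXED")
}

#' Classify cells under the percentile-based cutoff scheme
#'
#' A noise-aware alternative: the upper cutoff is the `q`-th percentile
#' (linear interpolation between order statistics) of the adjusted
#' ratios of somatic cells, imposing a `q`% false-positive rate on the
#' dosage-compensated call among somatic cells; the repression cutoff is
#' half of it. The computed cutoffs are reported at full precision.
#'
#' @param adjusted `RatioTable` with `adjusted_ratio`.
#' @param cells `CellTable`.
#' @param q percentile (percent, default 5).
#' @return `ZoneClassification` with attributes `upper_cut`, `lower_cut`.
#' @export
classify_percentile <- function(adjusted, cells, q = 5) {
  stopifnot(inherits(cells, "CellTable"))
  lin <- cells$lineage[match(adjusted$barcode, cells$barcode)]
  som <- lin == "SOMATIC" & adjusted$defined
  if (!any(som)) stop("no somatic cells with defined ratios")
  upper <- unname(quantile(adjusted$adjusted_ratio[som], q / 100,
                           type = 7, names = FALSE))
  classify_cutoffs(adjusted, upper, upper / 2, scheme = "PERCENTILE")
}

#' Per-cluster zone percentages
#'
#' Percentage of `DC`, `LACK` and `REPRESSED` cells per cluster among
#' cells with defined ratios; rows sum to 100. Clusters with zero
#' defined cells are omitted with a warning.
#'
#' @param zones `ZoneClassification`.
#' @param cells `CellTable`.
#' @return data.frame: `cluster`, `n_defined`, `DC`, `LACK`,
#'   `REPRESSED` (percent).
#' @export
zone_proportions <- function(zones, cells) {
  stopifnot(inherits(zones, "ZoneClassification"))
  cl <- cells$cluster[match(zones$barcode, cells$barcode)]
  keep <- zones$zone != "UNDEFINED"
  empty <- setdiff(unique(cl), unique(cl[keep]))
  if (length(empty))
    warning("cluster(s) without defined-ratio cells omitted: ",
            paste(empty, collapse = ", "))
  tab <- table(cluster = cl[keep],
               zone = factor(as.character(zones$zone[keep]),
                             levels = c("DC", "LACK", "REPRESSED")))
  n <- rowSums(tab)
  out <- data.frame(cluster = rownames(tab), n_defined = as.integer(n),
                    stringsAsFactors = FALSE)
  for (z in c("DC", "LACK", "REPRESSED"))
    out[[z]] <- 100 * tab[, z] / n
  rownames(out) <- NULL
  out
}

#' Chi-square enrichment of a zone in one cluster vs the somatic pool
#'
#' Builds the 2x2 contingency table (cells in `zone_of_interest` vs all
#' other zones) x (`target_cluster` vs pooled somatic clusters) over
#' defined-ratio cells and applies the Pearson chi-square test.
#'
#' @param zones `ZoneClassification`.
#' @param cells `CellTable`.
#' @param target_cluster cluster whose enrichment is tested.
#' @param zone_of_interest `"LACK"`, `"REPRESSED"` or `"DC"`.
#' @param yates apply the continuity correction (default off).
#' @return list: `statistic`, `df`, `p.value`, `table`, `stars`.
#' @export
enrichment_test <- function(zones, cells, target_cluster, zone_of_interest,
                            yates = FALSE) {
  stopifnot(inherits(zones, "ZoneClassification"))
  zone_of_interest <- match.arg(zone_of_interest, c("DC", "LACK",
                                                    "REPRESSED"))
  m <- match(zones$barcode, cells$barcode)
  cl <- cells$cluster[m]
  lin <- cells$lineage[m]
  keep <- zones$zone != "UNDEFINED"
  in_target <- keep & cl == target_cluster
  in_ref <- keep & lin == "SOMATIC" & cl != target_cluster
  if (!any(in_target) || !any(in_ref))
    stop("target cluster or somatic reference is empty")
  in_zone <- zones$zone == zone_of_interest
  tab <- rbind(target = c(sum(in_target & in_zone),
                          sum(in_target & !in_zone)),
               somatic = c(sum(in_ref & in_zone), sum(in_ref & !in_zone)))
  colnames(tab) <- c(zone_of_interest, "other")
  res <- chi_square_test(tab, yates = yates)
  res$table <- tab
  res$stars <- p_stars(res$p.value)
  res
}

#' Significance stars at the conventional thresholds
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05,
#' `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns")))
}
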