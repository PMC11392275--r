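# Per-cell compartment:autosome expression ratios, the somatic-median
# adjustment that anchors them, and the equal-gene-count window control
# against sparsity artifacts.

compartment_genes <- function(mat, annotation, compartment) {
  g <- annotation$gene_id[annotation$compartment %in% compartment]
  if (!length(g))
    stop("no genes annotated in compartment ", paste(compartment,
                                                     collapse = ","))
  g <- intersect(g, colnames(mat$counts))
  if (!length(g))
    stop("no ", paste(compartment, collapse = ","),
         " genes present in the matrix")
  g
}

cell_mean <- function(mat, genes) {
  Matrix::rowSums(mat$counts[, genes, drop = FALSE]) / length(genes)
}

#' Per-cell compartment-to-autosome expression ratio
#'
#' For each cell, the mean normalized expression over all genes of the
#' numerator compartment (zero counts included, so the mean is over the
#' fixed gene inventory) divided by the same mean over the denominator
#' compartment. Cells whose denominator mean is zero are flagged
#' undefined and excluded from downstream medians and classification.
#'
#' @param mat normalized `ExpressionMatrix` (see [normalize_counts()]).
#' @param annotation `GeneAnnotation`.
#' @param numerator compartment of the numerator gene set (default
#'   `"S0"`), or a character vector of gene_ids when `genes = TRUE`.
#' @param denominator compartment of the denominator gene set (default
#'   `"AUTOSOME"`), or gene_ids when `genes = TRUE`.
#' @param genes if `TRUE`, `numerator`/`denominator` are interpreted as
#'   explicit gene_id vectors rather than compartment labels.
#' @return data.frame of class `RatioTable`: `barcode`, `raw_ratio`,
#'   `defined`.
#' @export
compartment_ratio <- function(mat, annotation, numerator = "S0",
                              denominator = "AUTOSOME", genes = FALSE) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$norm_state == "RAW")
    stop("ratios are computed on normalized values; run normalize_counts()")
  if (genes) {
    num_g <- intersect(numerator, colnames(mat$counts))
    den_g <- intersect(denominator, colnames(mat$counts))
    if (!length(num_g) || !length(den_g)) stop("empty gene set")
  } else {
    num_g <- compartment_genes(mat, annotation, numerator)
    den_g <- compartment_genes(mat, annotation, denominator)
  }
  num <- cell_mean(mat, num_g)
  den <- cell_mean(mat, den_g)
  defined <- den > 0
  out <- data.frame(barcode = rownames(mat$counts),
                    raw_ratio = ifelse(defined, num / den, NA_real_),
                    defined = defined, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("RatioTable", "data.frame")
  out
}

#' Anchor ratios so the somatic median equals 1
#'
#' Adds the constant offset `1 - median(raw_ratio over somatic cells)`
#' to every cell's raw ratio. After adjustment the somatic median is
#' exactly 1, so a germline value of 0.5 reads directly as a two-fold
#' expression reduction relative to the somatic baseline.
#'
#' @param ratios `RatioTable` from [compartment_ratio()].
#' @param cells `CellTable` assigning barcodes to clusters/lineages.
#' @return `RatioTable` with `cluster`, `lineage` and `adjusted_ratio`
#'   columns; the offset is stored in `attr(, "offset")`.
#' @export
somatic_adjust <- function(ratios, cells) {
  stopifnot(inherits(ratios, "RatioTable"), inherits(cells, "CellTable"))
  m <- match(ratios$barcode, cells$barcode)
  if (anyNA(m)) stop("ratio barcodes missing from the cell table")
  ratios$cluster <- cells$cluster[m]
  ratios$lineage <- cells$lineage[m]
  som <- ratios$lineage == "SOMATIC" & ratios$defined
  if (!any(som)) stop("no somatic cells with defined ratios")
  offset <- 1 - median(ratios$raw_ratio[som])
  ratios$adjusted_ratio <- ratios$raw_ratio + offset
  n_undef <- sum(!ratios$defined)
  if (n_undef > 0)
    message(n_undef, " cell(s) with undefined ratios excluded downstream")
  attr(ratios, "offset") <- offset
  class(ratios) <- c("RatioTable", "data.frame")
  ratios
}

#' Chunk autosomal genes into windows of fixed gene count
#'
#' Autosomal genes are ordered by genomic position (chromosomes in the
#' order they appear in the annotation) and chunked into consecutive
#' non-overlapping blocks of `w` genes, the same gene count as the
#' numerator compartment; a trailing block of fewer than `w` genes is
#' dropped, so the window count is `floor(N_autosomal / w)`.
#'
#' @param annotation `GeneAnnotation`.
#' @param w genes per window (default 446, the S0 gene count).
#' @return list of class `GeneWindowSet`; each element is a character
#'   vector of `w` autosomal gene_ids.
#' @export
build_gene_windows <- function(annotation, w = 446L) {
  auto <- annotation[annotation$compartment == "AUTOSOME", , drop = FALSE]
  if (nrow(auto) < w)
    stop("fewer than ", w, " autosomal genes")
  chr_order <- unique(annotation$chromosome)
  auto <- auto[order(match(auto$chromosome, chr_order), auto$start), ,
               drop = FALSE]
  n_win <- nrow(auto) %/% w
  windows <- lapply(seq_len(n_win), function(i)
    auto$gene_id[((i - 1) * w + 1):(i * w)])
  names(windows) <- sprintf("window_%02d", seq_len(n_win))
  structure(windows, w = w, class = "GeneWindowSet")
}

#' Per-cluster medians of the compartment:window ratio for every window
#'
#' The sparsity control: for each autosomal gene window, the per-cell
#' ratio mean(numerator)/mean(window) is computed and its median taken
#' per cluster. Windows hold the same number of genes as the numerator
#' compartment, so they are equally exposed to dropout and
#' non-biological zeros.
#'
#' @param mat normalized `ExpressionMatrix`.
#' @param annotation `GeneAnnotation`.
#' @param windows `GeneWindowSet` from [build_gene_windows()].
#' @param cells `CellTable`.
#' @param numerator numerator compartment (default `"S0"`).
#' @return data.frame `cluster` x `window` (long): `cluster`, `window`,
#'   `median_ratio`, `n_cells`.
#' @export
window_control_medians <- function(mat, annotation, windows, cells,
                                   numerator = "S0") {
  stopifnot(inherits(windows, "GeneWindowSet"))
  num_g <- compartment_genes(mat, annotation, numerator)
  num <- cell_mean(mat, num_g)
  cl <- cells$cluster[match(rownames(mat$counts), cells$barcode)]
  out <- list()
  for (wn in names(windows)) {
    den <- cell_mean(mat, intersect(windows[[wn]], colnames(mat$counts)))
    ok <- den > 0
    r <- num[ok] / den[ok]
    med <- tapply(r, cl[ok], median)
    out[[wn]] <- data.frame(cluster = names(med), window = wn,
                            median_ratio = as.numeric(med),
                            n_cells = as.integer(table(cl[ok])[names(med)]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
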