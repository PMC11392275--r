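# Data model and readers/writers for the external formats the analysis
# consumes: Matrix-Market triplet counts with barcode/feature tables,
# BED-like ATAC fragments, BED region maps and peaks, and TSV metadata.
# Coordinates are 0-based half-open (BED convention) throughout.

#' Construct an expression matrix container
#'
#' Bundles a sparse cells x genes UMI count matrix with optional named
#' layers (e.g. `spliced`, `unspliced`) of identical shape and a
#' normalization-state flag.
#'
#' @param counts sparse (or coercible) numeric matrix, cells in rows,
#'   genes in columns, with barcode rownames and gene_id colnames.
#' @param layers named list of matrices with the same shape and dimnames.
#' @param norm_state one of `"RAW"`, `"SIZE_NORMALIZED"`,
#'   `"LOG_NORMALIZED"`. `RAW` entries must be non-negative integers.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `counts`, `layers`, `norm_state`.
#' @export
expression_matrix <- function(counts, layers = list(),
                              norm_state = c("RAW", "SIZE_NORMALIZED",
                                             "LOG_NORMALIZED")) {
  norm_state <- match.arg(norm_state)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry barcode rownames and gene_id colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated cell barcodes")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated gene identifiers")
  if (any(counts@x < 0))
    stop("negative count entries")
  if (norm_state == "RAW" && any(counts@x != round(counts@x)))
    stop("RAW counts must be integral")
  if (length(layers)) {
    if (is.null(names(layers)) || any(!nzchar(names(layers))))
      stop("layers must be named")
    layers <- lapply(layers, function(l) {
      l <- as(as(l, "CsparseMatrix"), "generalMatrix")
      if (!identical(dim(l), dim(counts)))
        stop("layer shape differs from counts")
      dimnames(l) <- dimnames(counts)
      l
    })
  }
  structure(list(counts = counts, layers = layers, norm_state = norm_state),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              nrow(x$counts), ncol(x$counts), x$norm_state))
  if (length(x$layers))
    cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Construct a validated gene annotation table
#'
#' Maps each gene to a chromosome, a 0-based half-open coordinate span
#' and a compartment: `AUTOSOME`, the Z strata (`PAR`, the differentiated
#' `S0`, the younger `S1`/`S2`), `W`, or `OTHER`.
#'
#' @param gene_id,chromosome character vectors.
#' @param start,end integer coordinates (bp), `end > start`.
#' @param compartment character vector over the compartment vocabulary.
#' @return data.frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(gene_id, chromosome, start, end, compartment) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   compartment = as.character(compartment),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("gene_ids must be unique")
  if (any(df$start < 0)) stop("negative start coordinate")
  if (any(df$end <= df$start)) stop("end must exceed start")
  bad <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Construct a region map of compartment spans
#'
#' Coordinate-level compartment definitions (e.g. the PAR/S0/S1/S2
#' strata on the Z scaffold) used to label ATAC windows. Spans on one
#' chromosome must not overlap.
#'
#' @param chromosome,start,end,compartment parallel vectors; 0-based
#'   half-open spans.
#' @return data.frame of class `RegionMap`.
#' @export
region_map <- function(chromosome, start, end, compartment) {
  df <- data.frame(chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   compartment = as.character(compartment),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("end must exceed start")
  bad <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  for (chr in unique(df$chromosome)) {
    sp <- df[df$chromosome == chr, , drop = FALSE]
    sp <- sp[order(sp$start), , drop = FALSE]
    if (nrow(sp) > 1 && any(sp$start[-1] < sp$end[-nrow(sp)]))
      stop("overlapping spans on ", chr)
  }
  class(df) <- c("RegionMap", "data.frame")
  df
}

#' Construct a cell metadata table
#'
#' @param barcode unique cell barcodes.
#' @param cluster cluster label per barcode.
#' @param lineage `"GERMLINE"`, `"SOMATIC"` or `"EXCLUDED"`; must be
#'   constant within a cluster.
#' @param replicate replicate label (recycled).
#' @return data.frame of class `CellTable`.
#' @export
cell_table <- function(barcode, cluster, lineage, replicate = "rep1") {
  df <- data.frame(barcode = as.character(barcode),
                   cluster = as.character(cluster),
                   lineage = as.character(lineage),
                   replicate = as.character(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$barcode)) stop("barcodes must be unique")
  bad <- setdiff(unique(df$lineage), LINEAGES)
  if (length(bad)) stop("unknown lineage(s): ", paste(bad, collapse = ", "))
  n_lin <- tapply(df$lineage, df$cluster, function(l) length(unique(l)))
  if (any(n_lin > 1))
    stop("cluster(s) mapped to more than one lineage: ",
         paste(names(n_lin)[n_lin > 1], collapse = ", "))
  class(df) <- c("CellTable", "data.frame")
  df
}

#' Construct an ATAC fragment set
#'
#' @param chromosome,start,end fragment spans, 0-based half-open,
#'   `start < end`, `start >= 0`.
#' @param barcode cell barcode per fragment.
#' @param support duplicate-support count per fragment (>= 1).
#' @return data.frame of class `FragmentSet`.
#' @export
fragment_set <- function(chromosome, start, end, barcode, support = 1L) {
  df <- data.frame(chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   barcode = as.character(barcode),
                   support = as.integer(support),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0)) stop("negative fragment coordinates")
  if (any(df$start >= df$end)) stop("fragment start must be < end")
  if (any(df$support < 1)) stop("support must be >= 1")
  class(df) <- c("FragmentSet", "data.frame")
  df
}

#' Read a 10x-style Matrix-Market count matrix
#'
#' Reads a Matrix-Market triplet file (features x barcodes, the 10x
#' layout) plus its feature and barcode TSVs and returns a RAW
#' cells x genes [expression_matrix()].
#'
#' @param matrix_path path to the `.mtx` file.
#' @param features_path TSV whose first column is the gene_id.
#' @param barcodes_path one barcode per line.
#' @return `ExpressionMatrix` with `norm_state = "RAW"`.
#' @export
read_matrix <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  feats <- read.table(features_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
  bcs <- read.table(barcodes_path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m))
    stop(sprintf("feature table has %d rows but matrix declares %d features",
                 nrow(feats), nrow(m)))
  if (nrow(bcs) != ncol(m))
    stop(sprintf("barcode table has %d rows but matrix declares %d cells",
                 nrow(bcs), ncol(m)))
  m <- Matrix::t(m)
  dimnames(m) <- list(bcs[[1]], feats[[1]])
  expression_matrix(m, norm_state = "RAW")
}

#' Write an expression matrix in the 10x triplet layout
#'
#' Inverse of [read_matrix()]: writes `matrix.mtx` (features x
#' barcodes), `features.tsv` and `barcodes.tsv` into `dir`. Layers, if
#' present, are written as `<layer>.mtx` over the same axes.
#'
#' @param mat `ExpressionMatrix`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_matrix <- function(mat, dir) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             features = file.path(dir, "features.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"))
  Matrix::writeMM(Matrix::t(mat$counts), paths["matrix"])
  writeLines(colnames(mat$counts), paths["features"])
  writeLines(rownames(mat$counts), paths["barcodes"])
  for (nm in names(mat$layers)) {
    p <- file.path(dir, paste0(nm, ".mtx"))
    Matrix::writeMM(Matrix::t(mat$layers[[nm]]), p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read ATAC fragments from a 5-column BED-like file
#'
#' Tab-separated `chrom start end barcode support` records with optional
#' `#` comment lines; gzip input is handled transparently.
#'
#' @param path fragment file path.
#' @return `FragmentSet`.
#' @export
read_fragments <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("chromosome", "start", "end",
                                 "barcode", "support"))
  fragment_set(df$chromosome, df$start, df$end, df$barcode, df$support)
}

#' Write ATAC fragments as 5-column BED-like TSV
#'
#' @param fragments `FragmentSet`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fragments <- function(fragments, path) {
  stopifnot(inherits(fragments, "FragmentSet"))
  write.table(fragments, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED intervals (e.g. ATAC peaks)
#'
#' @param path BED file; first three columns used, an optional fourth is
#'   kept as `name`.
#' @return data.frame with `chromosome`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least 3 columns")
  out <- data.frame(chromosome = as.character(df[[1]]),
                    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  if (any(out$end <= out$start)) stop("end must exceed start")
  out
}

#' Read a compartment region map from BED
#'
#' The BED name column carries the compartment label.
#'
#' @param path 4-column BED (`chrom start end compartment`).
#' @return `RegionMap`.
#' @export
read_region_map <- function(path) {
  df <- read_bed(path)
  if (is.null(df$name)) stop("region map BED needs a compartment column")
  region_map(df$chromosome, df$start, df$end, df$name)
}

#' Read a gene annotation TSV
#'
#' Expects named columns `gene_id`, `chromosome`, `start`, `end`,
#' `compartment` (0-based half-open coordinates).
#'
#' @param path TSV with header.
#' @return `GeneAnnotation`.
#' @export
read_gene_annotation <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  gene_annotation(df$gene_id, df$chromosome, df$start, df$end, df$compartment)
}

#' Read a cell metadata TSV
#'
#' Expects named columns `barcode`, `cluster`, `lineage` and optionally
#' `replicate`.
#'
#' @param path TSV with header.
#' @return `CellTable`.
#' @export
read_cell_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  rep <- if (is.null(df$replicate)) "rep1" else df$replicate
  cell_table(df$barcode, df$cluster, df$lineage, rep)
}

#' Size-normalize a raw count matrix
#'
#' `SIZE` divides each cell by its total UMI count and multiplies by
#' `scale`; `LOG_SIZE` additionally applies `log(1 + x)`, the standard
#' log-normalization of single-cell toolchains. Dosage ratios are taken
#' on the linear `SIZE` scale by default, where a ratio of 0.5 literally
#' means a two-fold expression reduction.
#'
#' @param mat RAW `ExpressionMatrix`.
#' @param mode `"SIZE"` or `"LOG_SIZE"`.
#' @param scale positive scale factor (default 10,000).
#' @param strict if `TRUE`, a cell with zero total counts is an error;
#'   otherwise such cells are dropped with a warning.
#' @return Normalized `ExpressionMatrix` (layers are dropped: splice
#'   proportions are computed on raw counts).
#' @export
normalize_counts <- function(mat, mode = c("SIZE", "LOG_SIZE"),
                             scale = 1e4, strict = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$norm_state != "RAW") stop("matrix is already normalized")
  if (scale <= 0) stop("scale must be positive")
  tot <- Matrix::rowSums(mat$counts)
  zero <- tot == 0
  if (any(zero)) {
    if (strict)
      stop(sum(zero), " cell(s) with zero total counts")
    warning("dropping ", sum(zero), " cell(s) with zero total counts")
  }
  counts <- mat$counts[!zero, , drop = FALSE]
  norm <- Matrix::Diagonal(x = scale / tot[!zero]) %*% counts
  norm <- as(norm, "CsparseMatrix")
  dimnames(norm) <- dimnames(counts)
  state <- "SIZE_NORMALIZED"
  if (mode == "LOG_SIZE") {
    norm@x <- log1p(norm@x)
    state <- "LOG_NORMALIZED"
  }
  expression_matrix(norm, norm_state = state)
}
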