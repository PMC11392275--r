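# Paired snRNA/snATAC simulator with known per-cell dosage regimes.
#
# The generator emulates the statistical structure the downstream
# analysis assumes: gamma-distributed gene rates, log-normal per-cell
# depth, Poisson counts, cluster-specific depth collapse and low
# unspliced fraction in late germ cells, pooled-profile ambient
# contamination, and reduced ATAC fragment density on the Z in
# non-compensated cells. Every cell carries a ground-truth dosage zone.

#' Describe one simulated cluster
#'
#' @param name cluster label.
#' @param lineage `"GERMLINE"` or `"SOMATIC"`.
#' @param n_cells number of cells.
#' @param mean_depth mean UMIs per cell (log-normal across cells).
#' @param depth_dispersion sdlog of the per-cell depth distribution.
#' @param unspliced_fraction probability that a UMI is unspliced.
#' @param atac_mean_fragments mean ATAC fragments per cell.
#' @param p_dc,p_lack,p_repressed per-cell dosage-zone probabilities
#'   (must sum to 1; somatic clusters must have `p_dc = 1`).
#' @return one-row data.frame usable in [simulation_config()].
#' @export
sim_cluster <- function(name, lineage, n_cells, mean_depth,
                        depth_dispersion = 0.35, unspliced_fraction = 0.30,
                        atac_mean_fragments = 5000,
                        p_dc = 1, p_lack = 0, p_repressed = 0) {
  data.frame(name = name, lineage = lineage, n_cells = as.integer(n_cells),
             mean_depth = mean_depth, depth_dispersion = depth_dispersion,
             unspliced_fraction = unspliced_fraction,
             atac_mean_fragments = atac_mean_fragments,
             p_dc = p_dc, p_lack = p_lack, p_repressed = p_repressed,
             stringsAsFactors = FALSE)
}

#' Default simulated ovary atlas clusters
#'
#' Three somatic control clusters (follicle, tracheal, ovarian muscle),
#' an early germline cluster with a moderate lack-of-compensation
#' fraction, and a late germline cluster with collapsed sequencing
#' depth, a high spliced fraction, few ATAC fragments, and a majority of
#' non-compensated plus a minority of repressed cells.
#'
#' @return data.frame of cluster descriptions.
#' @export
default_clusters <- function() {
  rbind(
    sim_cluster("Follicle", "SOMATIC", 800, 8000, unspliced_fraction = 0.30,
                atac_mean_fragments = 8000),
    sim_cluster("Tracheal", "SOMATIC", 400, 8000, unspliced_fraction = 0.30,
                atac_mean_fragments = 8000),
    sim_cluster("OvarianMuscle", "SOMATIC", 300, 9000,
                unspliced_fraction = 0.30, atac_mean_fragments = 9000),
    sim_cluster("GermA", "GERMLINE", 600, 6000, unspliced_fraction = 0.25,
                atac_mean_fragments = 6000,
                p_dc = 0.70, p_lack = 0.28, p_repressed = 0.02),
    sim_cluster("GermB", "GERMLINE", 700, 1200, unspliced_fraction = 0.05,
                atac_mean_fragments = 800,
                p_dc = 0.28, p_lack = 0.55, p_repressed = 0.17)
  )
}

#' Default chromosome sizes for the simulated genome
#'
#' Five 30-Mb autosomes, a 40-Mb Z and a 5-Mb W.
#'
#' @return named numeric vector of chromosome lengths (bp).
#' @export
default_chrom_sizes <- function() {
  c(chr1 = 30e6, chr2 = 30e6, chr3 = 30e6, chr4 = 30e6, chr5 = 30e6,
    chrZ = 40e6, chrW = 5e6)
}

#' Default Z/W compartment layout
#'
#' The Z carries a 20-Mb pseudoautosomal region, the ~13-Mb
#' differentiated stratum S0, and two younger strata S1 and S2; the W is
#' one W compartment. Autosomes need no spans (windows default to
#' `AUTOSOME`).
#'
#' @return `RegionMap`.
#' @export
default_region_map <- function() {
  region_map(chromosome = c("chrZ", "chrZ", "chrZ", "chrZ", "chrW"),
             start = c(0, 20e6, 33e6, 37e6, 0),
             end = c(20e6, 33e6, 37e6, 40e6, 5e6),
             compartment = c("PAR", "S0", "S1", "S2", "W"))
}

#' Build a simulation configuration
#'
#' Defaults encode the study conditions the analysis targets: 446 S0
#' genes against thousands of autosomal genes; dosage factors 1.0
#' (compensated), 0.5 (single-copy, uncompensated) and 0.15 (repressed,
#' comfortably below the 0.33 classification boundary) on S0; ATAC zone
#' factors 1.0/0.5/0.5 on the Z strata so non-compensated chromatin
#' shows the two-fold accessibility drop; 5% ambient contamination.
#'
#' @param seed integer seed; all generator randomness flows from it
#'   (expression uses `seed`, layers `seed + 1`, fragments `seed + 2`).
#' @param clusters data.frame as returned by [default_clusters()] /
#'   [sim_cluster()].
#' @param gene_counts named integer vector: genes per compartment.
#' @param dosage_factors named multipliers on the S0 gene rate per zone.
#' @param atac_zone_factors named multipliers on Z fragment rate per zone.
#' @param ambient_fraction fraction of UMIs replaced by draws from the
#'   pooled mean profile, in `[0, 1)`.
#' @param rate_shape gamma shape of the per-gene baseline rates.
#' @param fragment_length fixed ATAC fragment length (bp).
#' @param rna_affected compartments whose RNA rate the dosage factor
#'   multiplies (default S0 only: PAR/S1/S2 retain W homologs).
#' @param atac_affected compartments whose ATAC rate the zone factor
#'   multiplies (default all Z strata).
#' @param chromosome_layout `RegionMap` with the Z/W strata spans.
#' @param chrom_sizes named chromosome lengths (bp).
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              clusters = default_clusters(),
                              gene_counts = c(AUTOSOME = 5000L, S0 = 446L,
                                              PAR = 300L, S1 = 100L,
                                              S2 = 100L, W = 20L),
                              dosage_factors = c(DC = 1.0, LACK = 0.5,
                                                 REPRESSED = 0.15),
                              atac_zone_factors = c(DC = 1.0, LACK = 0.5,
                                                    REPRESSED = 0.5),
                              ambient_fraction = 0.05,
                              rate_shape = 2,
                              fragment_length = 200,
                              rna_affected = "S0",
                              atac_affected = c("PAR", "S0", "S1", "S2"),
                              chromosome_layout = default_region_map(),
                              chrom_sizes = default_chrom_sizes()) {
  stopifnot(is.data.frame(clusters), nrow(clusters) >= 1)
  psum <- clusters$p_dc + clusters$p_lack + clusters$p_repressed
  if (any(abs(psum - 1) > 1e-8))
    stop("zone probabilities must sum to 1 per cluster")
  som <- clusters$lineage == "SOMATIC"
  if (any(som & clusters$p_dc != 1))
    stop("somatic clusters must have p_dc = 1")
  if (any(clusters$mean_depth <= 0) || any(clusters$n_cells < 0))
    stop("non-positive depths or negative cell counts")
  if (any(dosage_factors <= 0) || any(atac_zone_factors <= 0))
    stop("factors must be positive")
  if (ambient_fraction < 0 || ambient_fraction >= 1)
    stop("ambient_fraction must be in [0, 1)")
  stopifnot(inherits(chromosome_layout, "RegionMap"))
  structure(list(seed = as.integer(seed), clusters = clusters,
                 gene_counts = gene_counts, dosage_factors = dosage_factors,
                 atac_zone_factors = atac_zone_factors,
                 ambient_fraction = ambient_fraction,
                 rate_shape = rate_shape,
                 fragment_length = fragment_length,
                 rna_affected = rna_affected, atac_affected = atac_affected,
                 chromosome_layout = chromosome_layout,
                 chrom_sizes = chrom_sizes),
            class = "SimulationConfig")
}

# compartment spans including implicit full-chromosome AUTOSOME spans for
# chromosomes absent from the region map
compartment_spans <- function(config) {
  rm <- as.data.frame(config$chromosome_layout)
  auto_chr <- setdiff(names(config$chrom_sizes), unique(rm$chromosome))
  if (length(auto_chr)) {
    rm <- rbind(rm, data.frame(chromosome = auto_chr, start = 0,
                               end = unname(config$chrom_sizes[auto_chr]),
                               compartment = "AUTOSOME",
                               stringsAsFactors = FALSE))
  }
  rm
}

# place n genes per compartment uniformly within that compartment's spans
make_gene_annotation <- function(config) {
  spans <- compartment_spans(config)
  out <- list()
  for (comp in names(config$gene_counts)) {
    n <- config$gene_counts[[comp]]
    if (n == 0) next
    sp <- spans[spans$compartment == comp, , drop = FALSE]
    if (!nrow(sp))
      stop("no spans for compartment ", comp)
    len <- sp$end - sp$start
    idx <- sample.int(nrow(sp), n, replace = TRUE, prob = len)
    pos <- floor(sp$start[idx] + runif(n) * (len[idx] - 1000))
    pos <- pmax(pos, sp$start[idx])
    df <- data.frame(gene_id = sprintf("%s_g%04d", comp, seq_len(n)),
                     chromosome = sp$chromosome[idx],
                     start = pos, end = pos + 1000,
                     compartment = comp, stringsAsFactors = FALSE)
    df <- df[order(df$chromosome, df$start), , drop = FALSE]
    df$gene_id <- sort(df$gene_id)
    out[[comp]] <- df
  }
  df <- do.call(rbind, out)
  gene_annotation(df$gene_id, df$chromosome, df$start, df$end,
                  df$compartment)
}

# per-gene sampling profile for a zone: gamma rates (unit mean per
# compartment) times the zone's dosage factor on the affected
# compartments; W genes at single-copy (0.5x) rate in all cells
zone_profile <- function(rates, annotation, config, zone) {
  w <- rates
  aff <- annotation$compartment %in% config$rna_affected
  w[aff] <- w[aff] * config$dosage_factors[[zone]]
  w[annotation$compartment == "W"] <- w[annotation$compartment == "W"] * 0.5
  w / sum(w)
}

#' Simulate a cells x genes UMI count matrix with known dosage regimes
#'
#' Per-gene baseline rates are gamma-distributed and rescaled to unit
#' mean within each compartment, so a configured dosage factor is
#' exactly the generative compartment:autosome expression ratio. Each
#' cell draws a zone from its cluster's zone probabilities and a depth
#' from a log-normal around the cluster mean; counts are Poisson with
#' expected value `depth * profile`, where the profile mixes the cell's
#' zone profile with the pooled population profile at
#' `ambient_fraction` (per-UMI ambient replacement).
#'
#' @param config `SimulationConfig`.
#' @return list of class `ZDosageSim` with elements `matrix`
#'   (RAW `ExpressionMatrix`), `cells` (`CellTable`), `annotation`
#'   (`GeneAnnotation`), `truth` (barcode, cluster, zone, depth,
#'   per-gene `rates` as an attribute) and `config`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  annotation <- make_gene_annotation(config)
  n_genes <- nrow(annotation)
  rates <- rgamma(n_genes, shape = config$rate_shape,
                  rate = config$rate_shape)
  rates <- pmax(rates, 1e-8)
  for (comp in unique(annotation$compartment)) {
    i <- annotation$compartment == comp
    rates[i] <- rates[i] / mean(rates[i])
  }

  zones <- c("DC", "LACK", "REPRESSED")
  profiles <- vapply(zones, function(z)
    zone_profile(rates, annotation, config, z), numeric(n_genes))

  cl <- config$clusters
  # pooled (ambient) profile: zone profiles weighted by expected UMI mass
  zmass <- colSums(cl$n_cells * cl$mean_depth *
                     as.matrix(cl[, c("p_dc", "p_lack", "p_repressed")]))
  pool <- as.numeric(profiles %*% (zmass / sum(zmass)))

  blocks <- list()
  meta <- list()
  for (k in seq_len(nrow(cl))) {
    n <- cl$n_cells[k]
    if (n == 0) next
    bc <- sprintf("%s_BC%05d", cl$name[k], seq_len(n))
    zone <- sample(zones, n, replace = TRUE,
                   prob = c(cl$p_dc[k], cl$p_lack[k], cl$p_repressed[k]))
    sdlog <- cl$depth_dispersion[k]
    depth <- rlnorm(n, meanlog = log(cl$mean_depth[k]) - sdlog^2 / 2,
                    sdlog = sdlog)
    for (z in zones) {
      i <- which(zone == z)
      if (!length(i)) next
      p <- (1 - config$ambient_fraction) * profiles[, z] +
        config$ambient_fraction * pool
      lambda <- outer(depth[i], p)
      x <- matrix(rpois(length(lambda), lambda), nrow = length(i))
      dimnames(x) <- list(bc[i], annotation$gene_id)
      blocks[[length(blocks) + 1]] <- as(Matrix::Matrix(x, sparse = TRUE),
                                         "generalMatrix")
    }
    meta[[k]] <- data.frame(barcode = bc, cluster = cl$name[k],
                            lineage = cl$lineage[k], zone = zone,
                            depth = depth, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  counts <- do.call(rbind, blocks)
  counts <- counts[meta$barcode, , drop = FALSE]

  truth <- meta[, c("barcode", "cluster", "zone", "depth")]
  attr(truth, "rates") <- setNames(rates, annotation$gene_id)
  structure(list(matrix = expression_matrix(counts),
                 cells = cell_table(meta$barcode, meta$cluster,
                                    meta$lineage),
                 annotation = annotation, truth = truth, config = config),
            class = "ZDosageSim")
}

#' Split simulated counts into spliced and unspliced layers
#'
#' Each UMI is unspliced with its cluster's `unspliced_fraction`
#' (binomial thinning per matrix entry); the two layers sum to the
#' counts exactly.
#'
#' @param mat RAW `ExpressionMatrix` from [simulate_expression()].
#' @param cells matching `CellTable`.
#' @param config `SimulationConfig` (seed `config$seed + 1` is used).
#' @return `ExpressionMatrix` with `spliced` and `unspliced` layers.
#' @export
simulate_layers <- function(mat, cells, config) {
  stopifnot(inherits(mat, "ExpressionMatrix"), mat$norm_state == "RAW")
  if (any(config$clusters$unspliced_fraction < 0 |
            config$clusters$unspliced_fraction > 1))
    stop("unspliced_fraction outside [0, 1]")
  set.seed(config$seed + 1L)
  frac <- setNames(config$clusters$unspliced_fraction, config$clusters$name)
  cell_frac <- frac[cells$cluster[match(rownames(mat$counts),
                                        cells$barcode)]]
  tm <- as(mat$counts, "TsparseMatrix")
  p <- cell_frac[tm@i + 1L]
  uns_x <- rbinom(length(tm@x), size = tm@x, prob = p)
  unspliced <- Matrix::sparseMatrix(i = tm@i + 1L, j = tm@j + 1L,
                                    x = uns_x, dims = dim(tm),
                                    dimnames = dimnames(mat$counts))
  spliced <- mat$counts - unspliced
  expression_matrix(mat$counts,
                    layers = list(spliced = Matrix::drop0(spliced),
                                  unspliced = Matrix::drop0(unspliced)))
}

#' Simulate ATAC fragments with zone-dependent Z accessibility
#'
#' Per cell, the fragment count is Poisson around the cluster's
#' `atac_mean_fragments`; each fragment's midpoint is uniform within a
#' compartment span chosen proportionally to span length times the
#' cell-zone's `atac_zone_factors` on the affected Z compartments (the
#' single-copy W at half rate). Fragment length is fixed.
#'
#' @param config `SimulationConfig` (seed `config$seed + 2` is used).
#' @param truth ground-truth table from [simulate_expression()]
#'   (`barcode`, `cluster`, `zone`).
#' @return `FragmentSet`.
#' @export
simulate_fragments <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  spans <- compartment_spans(config)
  if (!nrow(spans)) stop("empty chromosome layout")
  if (nrow(truth) == 0)
    return(fragment_set(character(), numeric(), numeric(), character(),
                        integer()))
  len <- spans$end - spans$start
  csize <- config$chrom_sizes
  mean_fr <- setNames(config$clusters$atac_mean_fragments,
                      config$clusters$name)
  half <- floor(config$fragment_length / 2)

  out <- list()
  for (z in c("DC", "LACK", "REPRESSED")) {
    rows <- which(truth$zone == z)
    if (!length(rows)) next
    w <- len * ifelse(spans$compartment %in% config$atac_affected,
                      config$atac_zone_factors[[z]], 1)
    w[spans$compartment == "W"] <- w[spans$compartment == "W"] * 0.5
    nfrag <- rpois(length(rows), mean_fr[truth$cluster[rows]])
    total <- sum(nfrag)
    if (total == 0) next
    sp <- sample.int(nrow(spans), total, replace = TRUE, prob = w)
    mid <- floor(spans$start[sp] + runif(total) * len[sp])
    start <- pmax(mid - half, 0)
    end <- pmin(start + config$fragment_length,
                csize[spans$chromosome[sp]])
    start <- pmin(start, end - 1)
    out[[z]] <- data.frame(chromosome = spans$chromosome[sp],
                           start = start, end = unname(end),
                           barcode = rep(truth$barcode[rows], nfrag),
                           support = 1L + rgeom(total, 0.7),
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  fragment_set(df$chromosome, df$start, df$end, df$barcode, df$support)
}

#' Write a simulation to disk in the formats the readers consume
#'
#' Writes the 10x-style matrix triplet (plus layer matrices), cell and
#' gene annotation TSVs, the region-map BED, chromosome sizes, ATAC
#' fragments, the ground-truth table, and the configuration as JSON.
#'
#' @param sim `ZDosageSim` from [simulate_expression()]; pass a matrix
#'   with layers via `matrix_override` to include spliced/unspliced.
#' @param dir output directory.
#' @param fragments optional `FragmentSet` to write alongside.
#' @param matrix_override optional `ExpressionMatrix` replacing
#'   `sim$matrix` (e.g. the output of [simulate_layers()]).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir, fragments = NULL,
                             matrix_override = NULL) {
  stopifnot(inherits(sim, "ZDosageSim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- if (is.null(matrix_override)) sim$matrix else matrix_override
  write_matrix(mat, file.path(dir, "matrix"))
  write.table(sim$cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rm <- sim$config$chromosome_layout
  write.table(data.frame(rm$chromosome, rm$start, rm$end, rm$compartment),
              file.path(dir, "region_map.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(chromosome = names(sim$config$chrom_sizes),
                         size = unname(sim$config$chrom_sizes)),
              file.path(dir, "chrom_sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(fragments))
    write_fragments(fragments, file.path(dir, "fragments.tsv"))
  cfg <- unclass(sim$config)
  cfg$chromosome_layout <- as.data.frame(cfg$chromosome_layout)
  cfg$chrom_sizes <- as.list(cfg$chrom_sizes)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
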