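# End-to-end orchestration: simulate (or read) paired snRNA/snATAC
# inputs, normalize, compute adjusted dosage ratios, classify zones,
# test enrichments, run the gene-window sparsity control, the ATAC
# window analysis, and the splice summaries, writing every result table
# as TSV plus a machine-readable run manifest.

#' Assemble a pipeline run configuration
#'
#' Exactly one of `simulate` or `input_dir` must be given. `input_dir`
#' expects the layout written by [write_simulation()]: `matrix/`
#' (triplet files plus optional `spliced.mtx`/`unspliced.mtx`),
#' `cells.tsv`, `annotation.tsv`, `region_map.bed`, `chrom_sizes.tsv`
#' and optionally `fragments.tsv`.
#'
#' @param outdir directory for result tables.
#' @param simulate optional [simulation_config()].
#' @param input_dir optional directory of input files.
#' @param normalization `"SIZE"` (linear, the default: a ratio of 0.5 is
#'   literally a two-fold reduction) or `"LOG_SIZE"`.
#' @param scale normalization scale factor.
#' @param schemes classification schemes to run (`"FIXED"`,
#'   `"PERCENTILE"`).
#' @param numerator numerator compartment for dosage ratios.
#' @param gene_window_size genes per control window (default 446).
#' @param bp_window_size ATAC window width in bp (default 500,000).
#' @param percentile_q percentile for the percentile scheme.
#' @param write_inputs also write the simulated inputs under
#'   `outdir/inputs` (simulation runs only).
#' @return list of class `RunConfig`.
#' @export
pipeline_config <- function(outdir, simulate = NULL, input_dir = NULL,
                            normalization = c("SIZE", "LOG_SIZE"),
                            scale = 1e4,
                            schemes = c("FIXED", "PERCENTILE"),
                            numerator = "S0",
                            gene_window_size = 446L,
                            bp_window_size = 5e5,
                            percentile_q = 5,
                            write_inputs = FALSE) {
  normalization <- match.arg(normalization)
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (is.null(simulate) == is.null(input_dir))
    stop("give exactly one of `simulate` or `input_dir`")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "SimulationConfig"))
  structure(list(outdir = outdir, simulate = simulate,
                 input_dir = input_dir, normalization = normalization,
                 scale = scale, schemes = schemes, numerator = numerator,
                 gene_window_size = as.integer(gene_window_size),
                 bp_window_size = bp_window_size,
                 percentile_q = percentile_q,
                 write_inputs = write_inputs),
            class = "RunConfig")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

load_pipeline_inputs <- function(dir) {
  mdir <- file.path(dir, "matrix")
  mat <- read_matrix(file.path(mdir, "matrix.mtx"),
                     file.path(mdir, "features.tsv"),
                     file.path(mdir, "barcodes.tsv"))
  for (layer in c("spliced", "unspliced")) {
    p <- file.path(mdir, paste0(layer, ".mtx"))
    if (file.exists(p)) {
      l <- Matrix::t(Matrix::readMM(p))
      dimnames(l) <- dimnames(mat$counts)
      mat$layers[[layer]] <- as(as(l, "CsparseMatrix"), "generalMatrix")
    }
  }
  cs <- read.table(file.path(dir, "chrom_sizes.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  fp <- file.path(dir, "fragments.tsv")
  list(matrix = mat,
       cells = read_cell_table(file.path(dir, "cells.tsv")),
       annotation = read_gene_annotation(file.path(dir, "annotation.tsv")),
       region_map = read_region_map(file.path(dir, "region_map.bed")),
       chrom_sizes = setNames(cs$size, cs$chromosome),
       fragments = if (file.exists(fp)) read_fragments(fp) else NULL)
}

#' Run the full dosage analysis pipeline
#'
#' Executes the stages in dependency order — simulate/read, normalize,
#' dosage ratios and somatic adjustment, zone classification and
#' enrichment tests, gene-window sparsity control, ATAC window
#' accessibility (cluster and zone-split pseudo-bulks with rank tests),
#' and splice summaries — and writes each result as a TSV under
#' `config$outdir` plus a `manifest.json`. All randomness flows from the
#' simulation seed; a fixed seed reproduces every table byte for byte.
#'
#' @param config `RunConfig` from [pipeline_config()].
#' @return Invisibly, a list with every intermediate and result object.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  inputs <- with_stage("input", {
    if (!is.null(config$simulate)) {
      sim <- simulate_expression(config$simulate)
      mat <- simulate_layers(sim$matrix, sim$cells, config$simulate)
      frags <- simulate_fragments(config$simulate, sim$truth)
      if (config$write_inputs)
        write_simulation(sim, file.path(config$outdir, "inputs"),
                         fragments = frags, matrix_override = mat)
      list(matrix = mat, cells = sim$cells, annotation = sim$annotation,
           region_map = config$simulate$chromosome_layout,
           chrom_sizes = config$simulate$chrom_sizes,
           fragments = frags, truth = sim$truth)
    } else {
      load_pipeline_inputs(config$input_dir)
    }
  })

  with_stage("validate", {
    som <- unique(inputs$cells$cluster[inputs$cells$lineage == "SOMATIC"])
    if (!length(som)) stop("no somatic clusters in the cell table")
  })
  germ <- unique(inputs$cells$cluster[inputs$cells$lineage == "GERMLINE"])

  norm <- with_stage("normalize",
                     normalize_counts(inputs$matrix,
                                      mode = config$normalization,
                                      scale = config$scale))

  adjusted <- with_stage("dosage", {
    raw <- compartment_ratio(norm, inputs$annotation,
                             numerator = config$numerator)
    somatic_adjust(raw, inputs$cells)
  })
  write_tsv(adjusted, config$outdir, "ratios.tsv")

  results <- list(inputs = inputs, adjusted = adjusted)

  with_stage("classify", {
    props <- list()
    enr <- list()
    for (scheme in config$schemes) {
      zones <- if (scheme == "FIXED") classify_fixed(adjusted)
               else classify_percentile(adjusted, inputs$cells,
                                        q = config$percentile_q)
      results[[paste0("zones_", tolower(scheme))]] <- zones
      write_tsv(cbind(zones,
                      scheme = scheme,
                      upper_cut = attr(zones, "upper_cut"),
                      lower_cut = attr(zones, "lower_cut")),
                config$outdir, paste0("zones_", tolower(scheme), ".tsv"))
      pr <- zone_proportions(zones, inputs$cells)
      pr$scheme <- scheme
      props[[scheme]] <- pr
      for (g in germ) {
        for (z in c("LACK", "REPRESSED")) {
          t <- enrichment_test(zones, inputs$cells, g, z)
          enr[[paste(scheme, g, z)]] <-
            data.frame(scheme = scheme, cluster = g, zone = z,
                       statistic = t$statistic, p.value = t$p.value,
                       stars = t$stars, stringsAsFactors = FALSE)
        }
      }
    }
    results$proportions <- do.call(rbind, c(props,
                                             make.row.names = FALSE))
    results$enrichment <- do.call(rbind, c(enr, make.row.names = FALSE))
    write_tsv(results$proportions, config$outdir, "zone_proportions.tsv")
    write_tsv(results$enrichment, config$outdir, "zone_enrichment.tsv")
  })

  with_stage("window_control", {
    wins <- build_gene_windows(inputs$annotation,
                               w = config$gene_window_size)
    results$window_medians <-
      window_control_medians(norm, inputs$annotation, wins, inputs$cells,
                             numerator = config$numerator)
    write_tsv(results$window_medians, config$outdir,
              "window_control_medians.tsv")
  })

  if (!is.null(inputs$fragments)) with_stage("atac", {
    grid <- tile_genome(inputs$region_map, inputs$chrom_sizes,
                        window_size = config$bp_window_size)
    clusters <- unique(inputs$cells$cluster)
    pb <- list()
    tests <- list()
    for (cl in clusters) {
      bc <- inputs$cells$barcode[inputs$cells$cluster == cl]
      adj <- adjust_log2(count_fragments(inputs$fragments, grid,
                                         cell_subset = bc, group = cl))
      adj$group <- cl
      pb[[cl]] <- adj
      for (comp in intersect(c("S0", "PAR"), adj$compartment)) {
        t <- window_rank_test(adj, compartment_a = comp)
        tests[[paste(cl, comp)]] <-
          data.frame(group = cl, compartment = comp,
                     statistic = t$statistic, p.value = t$p.value,
                     stars = p_stars(t$p.value), stringsAsFactors = FALSE)
      }
    }
    results$atac_cluster_windows <- do.call(rbind,
                                             c(pb, make.row.names = FALSE))
    write_tsv(results$atac_cluster_windows, config$outdir,
              "atac_cluster_windows.tsv")

    zones <- results$zones_fixed
    if (!is.null(zones)) {
      zpb <- list()
      for (g in germ) {
        lst <- withCallingHandlers(
          zone_pseudobulks(inputs$fragments, grid, inputs$cells, zones, g),
          warning = function(w) invokeRestart("muffleWarning"))
        for (z in names(lst)) {
          d <- lst[[z]]
          d$group <- paste(g, z, sep = ".")
          zpb[[paste(g, z)]] <- d
          for (comp in intersect(c("S0", "PAR"), d$compartment)) {
            t <- window_rank_test(d, compartment_a = comp)
            tests[[paste(g, z, comp)]] <-
              data.frame(group = paste(g, z, sep = "."),
                         compartment = comp, statistic = t$statistic,
                         p.value = t$p.value, stars = p_stars(t$p.value),
                         stringsAsFactors = FALSE)
          }
        }
      }
      results$atac_zone_windows <- do.call(rbind,
                                            c(zpb, make.row.names = FALSE))
      write_tsv(results$atac_zone_windows, config$outdir,
                "atac_zone_windows.tsv")
    }
    results$atac_tests <- do.call(rbind, c(tests, make.row.names = FALSE))
    write_tsv(results$atac_tests, config$outdir, "atac_window_tests.tsv")
  })

  with_stage("splice", {
    results$totals <- per_cell_totals(inputs$matrix, inputs$cells)
    write_tsv(results$totals, config$outdir, "per_cell_totals.tsv")
    if (all(c("spliced", "unspliced") %in% names(inputs$matrix$layers))) {
      ss <- splice_summary(inputs$matrix, inputs$cells)
      results$splice_summary <- ss
      write_tsv(ss, config$outdir, "splice_summary.tsv")
      st <- lapply(germ, function(g) {
        t <- splice_enrichment_test(ss, g)
        data.frame(cluster = g, statistic = t$statistic,
                   p.value = t$p.value, stars = t$stars,
                   stringsAsFactors = FALSE)
      })
      results$splice_tests <- do.call(rbind, st)
      write_tsv(results$splice_tests, config$outdir, "splice_tests.tsv")
    }
  })

  with_stage("manifest", {
    manifest <- list(
      package = "zdosage",
      version = as.character(utils::packageVersion("zdosage")),
      seed = if (!is.null(config$simulate)) config$simulate$seed else NA,
      normalization = config$normalization,
      schemes = config$schemes,
      numerator = config$numerator,
      gene_window_size = config$gene_window_size,
      bp_window_size = config$bp_window_size,
      n_cells = nrow(inputs$cells),
      n_genes = ncol(inputs$matrix$counts),
      offset = attr(adjusted, "offset"))
    jsonlite::write_json(manifest, file.path(config$outdir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(results)
}
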