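# Shared fixture builders: everything is generated in code at test time.

# a tiny normalized matrix with explicit values (cells x genes)
norm_matrix <- function(values, barcodes, genes) {
  m <- matrix(values, nrow = length(barcodes),
              dimnames = list(barcodes, genes))
  expression_matrix(Matrix::Matrix(m, sparse = TRUE),
                    norm_state = "SIZE_NORMALIZED")
}

# annotation placing the first n_num genes in `numerator` and the rest
# on an autosome, in input order
two_compartment_annotation <- function(genes, n_num, numerator = "S0") {
  n <- length(genes)
  gene_annotation(gene_id = genes,
                  chromosome = c(rep("chrZ", n_num),
                                 rep("chr1", n - n_num)),
                  start = c(seq_len(n_num), seq_len(n - n_num)) * 1000,
                  end = c(seq_len(n_num), seq_len(n - n_num)) * 1000 + 500,
                  compartment = c(rep(numerator, n_num),
                                  rep("AUTOSOME", n - n_num)))
}

# RatioTable constructed directly (documented class: barcode, raw_ratio,
# defined)
ratio_table <- function(barcode, raw_ratio) {
  out <- data.frame(barcode = barcode, raw_ratio = raw_ratio,
                    defined = !is.na(raw_ratio), stringsAsFactors = FALSE)
  class(out) <- c("RatioTable", "data.frame")
  out
}

# small two-cluster simulation config (one somatic, one germline)
small_sim_config <- function(seed = 11, n_som = 150, n_germ = 150,
                             depth = 5000,
                             p_dc = 0.3, p_lack = 0.55, p_repressed = 0.15,
                             ambient = 0.05, n_auto = 2000L, ...) {
  simulation_config(
    seed = seed,
    clusters = rbind(
      sim_cluster("Som", "SOMATIC", n_som, depth,
                  atac_mean_fragments = 3000, unspliced_fraction = 0.40),
      sim_cluster("Germ", "GERMLINE", n_germ, depth,
                  atac_mean_fragments = 3000, unspliced_fraction = 0.10,
                  p_dc = p_dc, p_lack = p_lack,
                  p_repressed = p_repressed)),
    gene_counts = c(AUTOSOME = n_auto, S0 = 446L, PAR = 100L,
                    S1 = 50L, S2 = 50L, W = 10L),
    ambient_fraction = ambient, ...)
}

# adjusted ratios straight from a simulation
sim_adjusted <- function(sim) {
  norm <- normalize_counts(sim$matrix)
  somatic_adjust(compartment_ratio(norm, sim$annotation), sim$cells)
}
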