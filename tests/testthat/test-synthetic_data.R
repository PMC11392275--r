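test_that("all three generators are deterministic given the seed", {
  cfg <- small_sim_config(seed = 21, n_som = 40, n_germ = 40,
                          n_auto = 300L)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$truth$zone, b$truth$zone)

  la <- simulate_layers(a$matrix, a$cells, cfg)
  lb <- simulate_layers(b$matrix, b$cells, cfg)
  expect_identical(as.matrix(la$layers$unspliced),
                   as.matrix(lb$layers$unspliced))

  fa <- simulate_fragments(cfg, a$truth)
  fb <- simulate_fragments(cfg, b$truth)
  expect_identical(fa, fb)
})

test_that("mean per-gene counts match the analytic depth x rate-share expectation", {
  # fully compensated cells, no ambient: E[count_cg] = depth_c * p_g
  cfg <- simulation_config(
    seed = 31,
    clusters = sim_cluster("Som", "SOMATIC", 150, 50000,
                           depth_dispersion = 0.2),
    gene_counts = c(AUTOSOME = 800L, S0 = 200L, PAR = 50L,
                    S1 = 20L, S2 = 20L, W = 10L),
    ambient_fraction = 0)
  sim <- simulate_expression(cfg)
  rates <- attr(sim$truth, "rates")
  w <- rates
  w[sim$annotation$compartment == "W"] <- w[sim$annotation$compartment ==
                                              "W"] * 0.5
  p <- w / sum(w)
  expected <- mean(sim$truth$depth) * p[colnames(sim$matrix$counts)]
  obs <- Matrix::colMeans(sim$matrix$counts)
  se <- apply(sim$matrix$counts, 2, stats::sd) / sqrt(nrow(sim$matrix$counts))
  z <- (obs - expected) / pmax(se, 1e-9)
  expect_gt(mean(abs(z) <= 3), 0.985)
})

test_that("LACK cells realize the configured S0:autosome generative ratio", {
  cfg <- small_sim_config(seed = 32, n_som = 0, n_germ = 200,
                          depth = 5000, p_dc = 0, p_lack = 1,
                          p_repressed = 0, ambient = 0)
  sim <- simulate_expression(cfg)
  norm <- normalize_counts(sim$matrix)
  r <- compartment_ratio(norm, sim$annotation)
  expect_equal(mean(r$raw_ratio), 0.5, tolerance = 0.05)
})

test_that("spliced and unspliced layers conserve counts and hit the target fraction", {
  cfg <- small_sim_config(seed = 33, n_som = 80, n_germ = 80,
                          depth = 4000, n_auto = 500L)
  sim <- simulate_expression(cfg)
  mat <- simulate_layers(sim$matrix, sim$cells, cfg)
  # conservation holds entrywise
  expect_equal(max(abs((mat$layers$spliced + mat$layers$unspliced) -
                         mat$counts)), 0)
  # pooled unspliced share per cluster within 2 points of the target
  # (Som 0.40, Germ 0.10; >= 1e5 UMIs per cluster)
  cl <- sim$cells$cluster[match(rownames(mat$counts), sim$cells$barcode)]
  tot <- Matrix::rowSums(mat$counts)
  expect_true(all(tapply(tot, cl, sum) >= 1e5))
  uns <- Matrix::rowSums(mat$layers$unspliced)
  share <- tapply(uns, cl, sum) / tapply(tot, cl, sum)
  expect_lt(max(abs(share[c("Som", "Germ")] - c(0.40, 0.10))), 0.02)

  # zero unspliced fraction: spliced layer equals the counts
  cfg0 <- simulation_config(
    seed = 34, clusters = sim_cluster("Som", "SOMATIC", 20, 2000,
                                      unspliced_fraction = 0),
    gene_counts = c(AUTOSOME = 200L, S0 = 50L))
  sim0 <- simulate_expression(cfg0)
  mat0 <- simulate_layers(sim0$matrix, sim0$cells, cfg0)
  expect_equal(sum(mat0$layers$unspliced), 0)
  expect_equal(max(abs(mat0$layers$spliced - mat0$counts)), 0)
})

test_that("fragment placement follows the length x zone-factor law", {
  # neutral factors: Z fragment share matches the Z length share
  cfg <- small_sim_config(seed = 35, n_som = 120, n_germ = 0,
                          n_auto = 100L,
                          atac_zone_factors = c(DC = 1, LACK = 1,
                                                REPRESSED = 1))
  sim <- simulate_expression(cfg)
  fr <- simulate_fragments(cfg, sim$truth)
  # W is at half rate by design; compare Z share against non-W total
  zs <- sum(fr$support[fr$chromosome == "chrZ"])
  notw <- sum(fr$support[fr$chromosome != "chrW"])
  z_len <- 40e6
  nonw_len <- sum(cfg$chrom_sizes) - 5e6
  p <- z_len / nonw_len
  se <- sqrt(p * (1 - p) / notw)
  expect_lt(abs(zs / notw - p), 3 * se * 2)  # support inflates variance

  # zero cells: empty fragment set
  cfg0 <- small_sim_config(seed = 36, n_som = 0, n_germ = 0)
  empty <- simulate_fragments(cfg0, data.frame(barcode = character(),
                                               cluster = character(),
                                               zone = character()))
  expect_s3_class(empty, "FragmentSet")
  expect_equal(nrow(empty), 0)
})

test_that("configuration invariants are enforced", {
  expect_error(small_sim_config(p_dc = 0.5, p_lack = 0.2,
                                p_repressed = 0.2), "sum to 1")
  expect_error(simulation_config(clusters = sim_cluster(
    "S", "SOMATIC", 10, 1000, p_dc = 0.9, p_lack = 0.1)), "p_dc = 1")
  expect_error(small_sim_config(ambient = 1.2), "ambient_fraction")
  expect_error(small_sim_config(dosage_factors = c(DC = 1, LACK = 0,
                                                   REPRESSED = 0.1)),
               "positive")
})

test_that("written simulations are re-readable and identical", {
  cfg <- small_sim_config(seed = 37, n_som = 30, n_germ = 30,
                          n_auto = 200L)
  sim <- simulate_expression(cfg)
  mat <- simulate_layers(sim$matrix, sim$cells, cfg)
  fr <- simulate_fragments(cfg, sim$truth)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, fragments = fr, matrix_override = mat)

  back <- read_matrix(file.path(dir, "matrix", "matrix.mtx"),
                      file.path(dir, "matrix", "features.tsv"),
                      file.path(dir, "matrix", "barcodes.tsv"))
  expect_equal(as.matrix(back$counts), as.matrix(mat$counts))
  cells <- read_cell_table(file.path(dir, "cells.tsv"))
  expect_identical(cells$barcode, sim$cells$barcode)
  ann <- read_gene_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(as.data.frame(ann), as.data.frame(sim$annotation))
  frb <- read_fragments(file.path(dir, "fragments.tsv"))
  expect_equal(as.data.frame(frb), as.data.frame(fr))
})
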