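grid_fixture <- function() {
  rmap <- region_map(c("chrZ", "chrZ"), c(0, 1e6), c(1e6, 2e6),
                     c("PAR", "S0"))
  tile_genome(rmap, c(chr1 = 1250000, chrZ = 2e6), window_size = 5e5)
}

test_that("genome tiling is exact, half-open, and labelled by window midpoint", {
  grid <- grid_fixture()
  chr1 <- grid[grid$chromosome == "chr1", ]
  expect_equal(chr1$start, c(0, 5e5, 1e6))
  expect_equal(chr1$end, c(5e5, 1e6, 1.25e6))
  expect_identical(chr1$compartment, rep("AUTOSOME", 3))
  # tiling covers every chromosome exactly once
  covered <- tapply(grid$end - grid$start, grid$chromosome, sum)
  expect_equal(as.numeric(covered[c("chr1", "chrZ")]), c(1250000, 2e6))
  # midpoint rule for compartments
  expect_identical(grid$compartment[grid$chromosome == "chrZ"],
                   c("PAR", "PAR", "S0", "S0"))

  # chromosome shorter than the window: a single window
  g2 <- tile_genome(region_map("chrZ", 0, 100, "S0"), c(tiny = 2e5),
                    window_size = 5e5)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$end, 2e5)

  # terminal window filter
  g3 <- tile_genome(default_region_map(), c(chr1 = 1.1e6),
                    window_size = 5e5, min_fraction = 0.5)
  expect_equal(nrow(g3), 2)

  expect_error(tile_genome(default_region_map(), c(chr1 = 1e6),
                           window_size = 0), "positive")
})

test_that("fragments are counted once, by midpoint, weighted by support", {
  grid <- grid_fixture()
  fr <- fragment_set(
    chromosome = c("chr1", "chr1", "chrZ", "chrMissing", "chr1"),
    start = c(100, 499900, 1.2e6, 10, 1240000),
    end = c(300, 500100, 1.2e6 + 200, 200, 1249000),
    barcode = c("A", "A", "B", "A", "C"),
    support = c(2L, 1L, 3L, 5L, 1L))
  pb <- count_fragments(fr, grid)
  # midpoint 200 -> window 1; straddling fragment midpoint 5e5 -> window 2
  expect_equal(pb$count[pb$chromosome == "chr1"], c(2, 1, 1))
  expect_equal(pb$count[pb$chromosome == "chrZ" & pb$start == 1e6], 3)
  # unknown chromosome support is tallied, and conservation holds
  expect_equal(attr(pb, "skipped_support"), 5)
  expect_equal(sum(pb$count) + attr(pb, "skipped_support"),
               sum(fr$support))

  # barcode filtering; empty subset gives all-zero counts
  pbA <- count_fragments(fr, grid, cell_subset = "A")
  expect_equal(sum(pbA$count), 3)
  pb0 <- count_fragments(fr, grid, cell_subset = character(0))
  expect_equal(sum(pb0$count), 0)
})

test_that("median-log2 adjustment self-normalizes autosomes and encodes two-fold drops as -1", {
  grid <- grid_fixture()
  pb <- count_fragments(fragment_set("chr1", 1, 201, "A"), grid)
  # construct counts directly: all autosomal windows at 512, S0 at 256
  pb$count <- ifelse(pb$compartment == "S0", 256,
                     ifelse(pb$compartment == "AUTOSOME", 512, 0))
  adj <- adjust_log2(pb)
  expect_equal(adj$adjusted_log2[adj$compartment == "AUTOSOME"],
               rep(0, 3))
  expect_identical(adj$adjusted_log2[adj$compartment == "S0"], c(-1, -1))
  # zero-count windows (PAR here) are excluded from the output
  expect_false("PAR" %in% adj$compartment)
  # median of adjusted autosomal windows is 0 by construction
  expect_identical(median(adj$adjusted_log2[adj$compartment ==
                                              "AUTOSOME"]), 0)

  # two-fold law: halving one window set shifts it by exactly -1
  pb2 <- pb
  pb2$count <- ifelse(pb2$compartment == "S0", 512, 64)
  pb2$count[pb2$chromosome == "chrZ" &
              pb2$compartment == "PAR"] <- c(32, 16)
  a1 <- adjust_log2(pb2)
  pb3 <- pb2
  halve <- pb3$compartment == "S0"
  pb3$count[halve] <- pb3$count[halve] / 2
  a2 <- adjust_log2(pb3)
  expect_equal(a2$adjusted_log2[a2$compartment == "S0"],
               a1$adjusted_log2[a1$compartment == "S0"] - 1)

  # a group without nonzero autosomal windows is an error
  pb4 <- pb
  pb4$count[pb4$compartment == "AUTOSOME"] <- 0
  expect_error(adjust_log2(pb4), "no autosomal windows")
})

test_that("zone pseudo-bulks recover the simulated accessibility drop", {
  cfg <- small_sim_config(seed = 61, n_som = 200, n_germ = 300,
                          depth = 5000, n_auto = 200L)
  sim <- simulate_expression(cfg)
  fr <- simulate_fragments(cfg, sim$truth)
  grid <- tile_genome(cfg$chromosome_layout, cfg$chrom_sizes)

  # all cells in one zone: identical to the whole-cluster pseudo-bulk
  zall <- structure(
    data.frame(barcode = sim$cells$barcode,
               zone = factor("DC", levels = c("DC", "LACK", "REPRESSED",
                                              "UNDEFINED"))),
    scheme = "FIXED", upper_cut = 0.66, lower_cut = 0.33,
    class = c("ZoneClassification", "data.frame"))
  full <- suppressWarnings(
    zone_pseudobulks(fr, grid, sim$cells, zall, "Som"))
  ref <- adjust_log2(count_fragments(
    fr, grid, sim$cells$barcode[sim$cells$cluster == "Som"]))
  expect_equal(full$DC$adjusted_log2, ref$adjusted_log2)
  expect_length(full, 1)

  # true zones: repressed/lack S0 near -1, compensated near 0
  zones <- structure(
    data.frame(barcode = sim$truth$barcode,
               zone = factor(sim$truth$zone,
                             levels = c("DC", "LACK", "REPRESSED",
                                        "UNDEFINED"))),
    scheme = "FIXED", upper_cut = 0.66, lower_cut = 0.33,
    class = c("ZoneClassification", "data.frame"))
  zp <- zone_pseudobulks(fr, grid, sim$cells, zones, "Germ")
  s0_med <- vapply(zp, function(d)
    median(d$adjusted_log2[d$compartment == "S0"]), numeric(1))
  expect_equal(unname(s0_med["DC"]), 0, tolerance = 0.2)
  expect_equal(unname(s0_med["REPRESSED"]), -1, tolerance = 0.2)
  expect_equal(unname(s0_med["LACK"]), -1, tolerance = 0.2)
})

test_that("peak counting merges overlapping peaks and counts any-overlap support", {
  peaks <- data.frame(chromosome = c("chr1", "chr1", "chr1", "chrZ"),
                      start = c(100, 200, 500, 0),
                      end = c(200, 300, 600, 50))
  fr <- fragment_set(
    chromosome = c("chr1", "chr1", "chr1", "chr1"),
    start = c(120, 180, 350, 90),
    end = c(180, 320, 450, 101),
    barcode = c("A", "B", "B", "C"),
    support = c(2L, 1L, 4L, 1L))
  res <- counts_in_peaks(fr, peaks)
  got <- setNames(res$peak_counts, res$barcode)
  expect_equal(got[["A"]], 2)    # fully inside a peak
  expect_equal(got[["B"]], 1)    # straddles two abutting peaks: counted once
  expect_equal(got[["C"]], 1)    # 1-bp overlap counts

  # cells argument pads zero-count barcodes
  cells <- cell_table(c("A", "B", "C", "D"), "X", "SOMATIC")
  res2 <- counts_in_peaks(fr, peaks, cells)
  expect_equal(res2$peak_counts[res2$barcode == "D"], 0)
})

test_that("window rank test flags shifted compartments and matches the reference", {
  grid <- grid_fixture()
  pb <- count_fragments(fragment_set("chr1", 1, 201, "A"), grid)
  # identical distributions: p near 1
  pb$count <- 100
  adj <- adjust_log2(pb)
  expect_gt(window_rank_test(adj, "S0", "AUTOSOME")$p.value, 0.5)

  # a clear shift on >= 20 windows per side
  rmap <- region_map("chrZ", 0, 20e6, "S0")
  big <- tile_genome(rmap, c(chr1 = 20e6, chrZ = 20e6), window_size = 5e5)
  pb2 <- count_fragments(fragment_set("chr1", 1, 201, "A"), big)
  set.seed(3)
  pb2$count <- round(ifelse(pb2$compartment == "S0", 50, 100) *
                       exp(rnorm(nrow(pb2), 0, 0.1)))
  adj2 <- adjust_log2(pb2)
  res <- window_rank_test(adj2, "S0", "AUTOSOME")
  expect_lt(res$p.value, 1e-6)
  ref <- stats::wilcox.test(
    adj2$adjusted_log2[adj2$compartment == "S0"],
    adj2$adjusted_log2[adj2$compartment == "AUTOSOME"],
    exact = FALSE, correct = TRUE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-9)

  expect_error(window_rank_test(adj2, "S0", "W"), "empty window set")
})
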