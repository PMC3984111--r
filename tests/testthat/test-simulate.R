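test_that("point-mass spectra give all-reference or all-homozygous truth", {
  design <- build_design(paste0("s", 1:12), 3, 4, 1)
  t0 <- draw_genotypes(sim_config(n_sites = 20, maf = maf_point(0), seed = 3),
                       design)
  expect_true(all(t0$genotypes == 0L))
  t2 <- draw_genotypes(sim_config(n_sites = 20, maf = maf_point(1), seed = 3),
                       design)
  expect_true(all(t2$genotypes == 2L))
})

test_that("carrier counts match the binomial closed form", {
  design <- build_design(sprintf("S%03d", 1:144), 12, 12, 1)
  cfg <- sim_config(n_sites = 1000, maf = maf_point(0.01), seed = 5)
  truth <- draw_genotypes(cfg, design)
  carriers_per_site <- colSums(truth$genotypes > 0)
  # per sample P(>=1 alt copy) = 1 - 0.99^2; expectation 144 * that = 2.8656
  expected <- 144 * (1 - 0.99^2)
  se <- sqrt(144 * (1 - 0.99^2) * (0.99^2) / 1000)
  expect_lt(abs(mean(carriers_per_site) - expected), 3 * se)
})

test_that("identical seed and config reproduce the draw bit-for-bit", {
  design <- build_design(paste0("s", 1:12), 3, 4, 1)
  cfg <- sim_config(n_sites = 30, maf = maf_uniform(0, 0.1), seed = 99,
                    error_rate = 0.001)
  a <- draw_genotypes(cfg, design)
  b <- draw_genotypes(cfg, design)
  expect_identical(a, b)
  ca <- simulate_pool_counts(a, design[[1]], cfg)
  cb <- simulate_pool_counts(b, design[[1]], cfg)
  expect_identical(ca, cb)
})

test_that("pool counts conserve depth and start-point totals", {
  design <- build_design(paste0("s", 1:12), 3, 4, 1)
  cfg <- sim_config(n_sites = 50, maf = maf_point(0.1), mean_depth = 500,
                    error_rate = 0.01, seed = 7)
  truth <- draw_genotypes(cfg, design)
  counts <- simulate_pool_counts(truth, design[[1]], cfg)
  for (pc in counts) {
    expect_equal(unname(rowSums(pc$base_counts)), as.numeric(pc$depth))
    expect_equal(vapply(pc$start_points, sum, 0), as.numeric(pc$depth))
  }
})

test_that("mean simulated depth tracks the configured per-pool scale", {
  design <- build_design(paste0("s", 1:12), 3, 4, 1)
  cfg <- sim_config(n_sites = 2000, maf = maf_point(0), mean_depth = 4320,
                    seed = 21)
  truth <- draw_genotypes(cfg, design)
  pc <- simulate_pool_counts(truth, design[[1]], cfg)[[1]]
  expect_lt(abs(mean(pc$depth) - 4320) / 4320, 0.02)
})

test_that("one heterozygous carrier yields the expected 1/24 pool fraction", {
  l <- build_design(sprintf("S%03d", 1:144), 12, 12, 1)[[1]]
  sites <- manual_sites(200)
  carrier <- l$grid[4, 9]
  truth <- manual_truth(layout_samples(l), sites,
                        data.frame(sample = carrier, site = seq_len(200),
                                   copies = 1))
  cfg <- noiseless_config(200, seed = 13)
  counts <- simulate_pool_counts(truth, l, cfg)
  row_pool <- counts[[4]]          # row 4
  col_pool <- counts[[12 + 9]]     # column 9
  frac <- function(pc) {
    alt <- sites$alt
    pc$base_counts[cbind(seq_len(nrow(sites)), match(alt, c("A","C","G","T")))] /
      pc$depth
  }
  expect_lt(abs(mean(frac(row_pool)) - 1 / 24), 3 * sqrt((1/24) * (23/24) / (4000 * 200)))
  expect_lt(abs(mean(frac(col_pool)) - 1 / 24), 3 * sqrt((1/24) * (23/24) / (4000 * 200)))
  # a carrier-free pool shows zero alternate reads without error
  expect_true(all(frac(counts[[1]]) == 0))
})

test_that("dropout injection erases the variant but conserves depth", {
  l <- toy_layout_3x3()
  sites <- manual_sites(3)
  truth <- manual_truth(layout_samples(l), sites,
                        data.frame(sample = "s5", site = 1:3, copies = 1))
  cfg <- sim_config(n_sites = 3, maf = maf_point(0), mean_depth = 2000,
                    error_rate = 0, seed = 1)
  pc <- simulate_pool_counts(truth, l, cfg)[[2]]  # row 2 holds s4..s6
  expect_gt(pc$base_counts[1, sites$alt[1]], 0)
  dropped <- inject_dropout(pc, 1, sites$alt[1])
  expect_equal(dropped$base_counts[1, sites$alt[1]], c(G = 0L),
               ignore_attr = TRUE)
  expect_equal(rowSums(dropped$base_counts), rowSums(pc$base_counts),
               ignore_attr = TRUE)
})

test_that("uneven pooling weights shift the expected fraction", {
  l <- toy_layout_3x3()
  sites <- manual_sites(400)
  truth <- manual_truth(layout_samples(l), sites,
                        data.frame(sample = "s1", site = seq_len(400),
                                   copies = 1))
  cfg <- noiseless_config(400, seed = 31, mean_depth = 3000)
  w <- stats::setNames(rep(1, 9), paste0("s", 1:9))
  w["s1"] <- 2  # carrier over-represented in its pools
  counts <- simulate_pool_counts(truth, l, cfg, weights = w)
  pc <- counts[[1]]  # row 1 = s1..s3, weights 2,1,1
  frac <- pc$base_counts[cbind(seq_len(400), match(sites$alt, c("A","C","G","T")))] /
    pc$depth
  expect_lt(abs(mean(frac) - 0.25), 0.01)  # (2/4 samples' worth) * 1/2 copies
})

test_that("fixture files round-trip counts and start points", {
  l <- build_design(paste0("s", 1:12), 3, 4, 1)[[1]]
  cfg <- sim_config(n_sites = 40, maf = maf_point(0.1), mean_depth = 300,
                    depth_dispersion = 50, error_rate = 0.005,
                    start_points = 10, seed = 17)
  truth <- draw_genotypes(cfg, list(l))
  counts <- simulate_pool_counts(truth, l, cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(counts, truth, dir)
  expect_length(list.files(dir, pattern = "\\.pileup$"), 7L)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(all(vapply(list.files(dir, "\\.pileup$", full.names = TRUE),
                         function(f) length(readLines(f)) == 40L, TRUE)))
  back <- read_fixture_dir(dir)
  key <- function(pcs) vapply(pcs, function(p) format_pool_id(p$pool), "")
  back <- back[match(key(counts), key(back))]
  for (i in seq_along(counts)) {
    expect_identical(back[[i]]$base_counts, counts[[i]]$base_counts)
    expect_identical(back[[i]]$depth, counts[[i]]$depth)
    expect_identical(back[[i]]$start_points, counts[[i]]$start_points)
    expect_identical(back[[i]]$sites, counts[[i]]$sites)
  }
})
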