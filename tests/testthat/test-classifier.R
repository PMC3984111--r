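states_12x12 <- function(rows_obs = integer(0), cols_obs = integer(0),
                         insufficient = character(0),
                         obs_state = "confident_variant") {
  st <- stats::setNames(rep("confident_ref", 24),
                        c(paste0("row_", 1:12), paste0("column_", 1:12)))
  if (length(rows_obs)) st[paste0("row_", rows_obs)] <- obs_state
  if (length(cols_obs)) st[paste0("column_", cols_obs)] <- obs_state
  if (length(insufficient)) st[insufficient] <- "insufficient"
  st
}

test_that("classification patterns match the class definitions", {
  l <- build_design(sprintf("S%03d", 1:144), 12, 12, 1)[[1]]
  # one row + one column: pinnable, pinned to the single intersection
  cv <- classify_variant(states_12x12(3, 7), l)
  expect_equal(cv$variant_class, "pinnable")
  expect_equal(cv$pinned_samples[[1]], l$grid[3, 7])
  # one row + two columns: pinnable with two pinned carriers
  cv <- classify_variant(states_12x12(1, c(2, 6)), l)
  expect_equal(cv$variant_class, "pinnable")
  expect_setequal(cv$pinned_samples[[1]], c(l$grid[1, 2], l$grid[1, 6]))
  # a potential observation still counts towards the pattern
  st <- states_12x12(3, integer(0))
  st["column_7"] <- "potential_variant"
  cv <- classify_variant(st, l)
  expect_equal(cv$variant_class, "pinnable")
  expect_equal(cv$pinned_samples[[1]], l$grid[3, 7])
  # >1 row and >1 column: multiple with the 4-sample candidate intersection
  cv <- classify_variant(states_12x12(c(2, 5), c(1, 9)), l)
  expect_equal(cv$variant_class, "multiple")
  expect_setequal(cv$candidate_samples[[1]],
                  c(l$grid[2, 1], l$grid[2, 9], l$grid[5, 1], l$grid[5, 9]))
  # row-only observation: singleton
  cv <- classify_variant(states_12x12(4, integer(0)), l)
  expect_equal(cv$variant_class, "singleton")
  expect_equal(cv$observed_cols[[1]], integer(0))
  # three insufficient pools block classification
  cv <- classify_variant(states_12x12(3, 7, insufficient =
                                        paste0("row_", 8:10)), l)
  expect_equal(cv$variant_class, "missing_coverage")
  expect_equal(cv$insufficient_pools, 3L)
  # two insufficient pools do not
  cv <- classify_variant(states_12x12(3, 7, insufficient =
                                        paste0("row_", 8:9)), l)
  expect_equal(cv$variant_class, "pinnable")
  # potential-only variants are discarded
  expect_null(classify_variant(states_12x12(3, 7,
                                            obs_state = "potential_variant"), l))
})

test_that("the insufficient-pool tolerance is configurable", {
  l <- build_design(sprintf("S%03d", 1:144), 12, 12, 1)[[1]]
  st <- states_12x12(3, 7, insufficient = paste0("row_", 8:10))
  expect_equal(classify_variant(st, l, max_insufficient_pools = 3L)$variant_class,
               "pinnable")
  expect_equal(classify_variant(st, l, max_insufficient_pools = 2L)$variant_class,
               "missing_coverage")
})

test_that("classifier agrees with the brute-force oracle on random patterns", {
  l <- build_design(sprintf("S%03d", 1:144), 12, 12, 1)[[1]]
  set.seed(202)
  five <- c("confident_variant", "potential_variant", "potential_ref",
            "confident_ref", "insufficient")
  for (i in 1:300) {
    st <- sample(five, 24, replace = TRUE)
    expect_equal(classify_class_of(st, l),
                 oracle_classify(st, 12, 12),
                 info = paste(st, collapse = ","))
  }
})

test_that("second-pass collection resolves absent pools to ref or insufficient", {
  l <- toy_layout_3x3()
  sites <- manual_sites(2)
  truth <- manual_truth(layout_samples(l), sites,
                        data.frame(sample = "s5", site = 1:2, copies = 1))
  cfg <- noiseless_config(2, seed = 8, mean_depth = 2000)
  counts <- simulate_pool_counts(truth, l, cfg)
  collected <- call_matrix(counts, l)
  expect_equal(nrow(collected$keys), 2L)
  expect_equal(colnames(collected$states),
               c(paste0("row_", 1:3), paste0("column_", 1:3)))
  # s5 sits at (2,2): its pools carry the variant, all others confident_ref
  expect_equal(unname(collected$states[1, ]),
               c("confident_ref", "confident_variant", "confident_ref",
                 "confident_ref", "confident_variant", "confident_ref"))
  # a pool with no coverage at the position resolves to insufficient
  counts2 <- counts
  keep <- c(TRUE, FALSE)
  counts2[[1]]$sites <- counts2[[1]]$sites[keep, , drop = FALSE]
  counts2[[1]]$depth <- counts2[[1]]$depth[keep]
  counts2[[1]]$base_counts <- counts2[[1]]$base_counts[keep, , drop = FALSE]
  counts2[[1]]$start_points <- counts2[[1]]$start_points[keep]
  collected2 <- call_matrix(counts2, l)
  expect_equal(unname(collected2$states[2, "row_1"]), "insufficient")
})

test_that("mixed-matrix pools are rejected", {
  l <- toy_layout_3x3()
  sites <- manual_sites(1)
  truth <- manual_truth(layout_samples(l), sites,
                        data.frame(sample = "s1", site = 1, copies = 1))
  cfg <- noiseless_config(1, seed = 9, mean_depth = 2000)
  counts <- simulate_pool_counts(truth, l, cfg)
  counts[[2]]$pool$matrix_id <- "OTHER"
  expect_error(call_matrix(counts, l), "matrix")
})

test_that("aggregation uses set semantics over variant keys", {
  base <- function(matrix_id, cls, pos) {
    out <- data.frame(chrom = "chr5", pos = pos, ref = "A", alt = "G",
                      matrix_id = matrix_id, variant_class = cls,
                      insufficient_pools = 0L, has_confident = TRUE,
                      stringsAsFactors = FALSE)
    out$observed_rows <- I(list(1L)); out$observed_cols <- I(list(1L))
    out$pinned_samples <- I(list("s")); out$candidate_samples <- I(list(character(0)))
    out
  }
  cl <- rbind(base("M1", "pinnable", 100L), base("M2", "pinnable", 100L),
              base("M1", "multiple", 200L), base("M3", "singleton", 300L),
              base("M4", "pinnable", 400L))
  agg <- aggregate_matrices(cl)
  # same pinnable key in two matrices: unique count 1, matrices-observed 2
  expect_equal(unname(agg$unique_by_class["pinnable"]), 2L)
  expect_equal(unname(agg$matrices_observed[["chr5:100:A:G"]]), 2L)
  expect_equal(unname(agg$unique_by_class["multiple"]), 1L)
  expect_equal(unname(agg$unique_by_class["singleton"]), 1L)
  expect_equal(unname(agg$crosstab["pinnable", "2"]), 1L)
  expect_equal(unname(agg$crosstab["pinnable", "1"]), 1L)
  # per-matrix table is additive over disjoint keys
  expect_equal(unname(rowSums(agg$by_matrix)), c(2L, 1L, 1L, 1L),
               ignore_attr = TRUE)
})

test_that("known-site percentages are computed per class", {
  base <- function(pos, cls) {
    out <- data.frame(chrom = "chr5", pos = pos, ref = "A", alt = "G",
                      matrix_id = "M1", variant_class = cls,
                      insufficient_pools = 0L, has_confident = TRUE,
                      stringsAsFactors = FALSE)
    out$observed_rows <- I(list(1L)); out$observed_cols <- I(list(1L))
    out$pinned_samples <- I(list("s")); out$candidate_samples <- I(list(character(0)))
    out
  }
  cl <- do.call(rbind, c(lapply(c(100L, 200L, 300L, 400L), base, cls = "pinnable"),
                         list(base(500L, "multiple"))))
  agg <- aggregate_matrices(cl)
  expect_equal(unname(annotate_known(agg, character(0))$pct_known_by_class),
               c(0, 0, 0, 0))
  all_keys <- paste("chr5", c(100, 200, 300, 400, 500), "A", "G", sep = ":")
  expect_equal(unname(annotate_known(agg, all_keys)$pct_known_by_class[c("pinnable", "multiple")]),
               c(100, 100))
  expect_equal(unname(annotate_known(agg, "chr5:100:A:G")$pct_known_by_class[["pinnable"]]),
               25)
})

test_that("common variants are classified multiple in every matrix", {
  design <- build_design(sprintf("S%03d", 1:576), 12, 12, 4)
  cfg <- noiseless_config(40, seed = 77, maf = maf_point(0.3))
  truth <- draw_genotypes(cfg, design)
  cl <- do.call(rbind, lapply(seq_along(design), function(m)
    classify_matrix(call_matrix(simulate_pool_counts(truth, design[[m]], cfg),
                                design[[m]]))))
  agg <- aggregate_matrices(cl)
  expect_true(all(cl$variant_class == "multiple"))
  expect_true(all(agg$matrices_observed == 4L))
  # candidate supersets contain every true carrier
  for (m in seq_along(design)) {
    l <- design[[m]]
    sub <- cl[cl$matrix_id == l$matrix_id, ]
    g <- truth$genotypes[layout_samples(l), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      site <- match(sub$pos[i], truth$sites$pos)
      carriers <- rownames(g)[g[, site] > 0]
      expect_true(all(carriers %in% sub$candidate_samples[[i]]))
    }
  }
})
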