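#' Per-pool and per-sample coverage from a pool-set total
#'
#' For a set of `n_pools` pools of `pool_size` samples each (the canonical
#' design has 12 pools of 12 on each axis of a matrix), the average depth
#' per pool is the set total divided by `n_pools`, and the average depth per
#' sample is the total divided by `n_pools * pool_size` — each sample's
#' share of its pool under even pooling.
#'
#' @param total_coverage summed coverage over the pool set (reads x fold).
#' @param n_pools number of pools in the set.
#' @param pool_size samples per pool.
#' @return list with `per_pool` and `per_sample` averages.
#' @export
coverage_summary <- function(total_coverage, n_pools = 12L, pool_size = 12L) {
  stopifnot(n_pools > 0, pool_size > 0)
  list(per_pool = total_coverage / n_pools,
       per_sample = total_coverage / (n_pools * pool_size))
}

#' Minimum reads per individual at the depth cutoff
#'
#' Under even pooling, a pool-level depth floor of `min_depth` reads
#' guarantees each of the `pool_size` individuals at least
#' `floor(min_depth / pool_size)` reads — 16 for the default 200-read
#' cutoff and 12-sample pools.
#'
#' @param min_depth pool-level depth cutoff (reads).
#' @param pool_size samples per pool.
#' @return integer floor of reads per individual.
#' @export
min_reads_per_sample <- function(min_depth = 200L, pool_size = 12L) {
  stopifnot(min_depth > 0, pool_size > 0)
  as.integer(floor(min_depth / pool_size))
}

#' Bundled sequencing-yield table
#'
#' Per-pool-set sequencing yield and enrichment efficiency of a sequenced
#' four-matrix study (row and column pool sets of each 12x12 matrix), with
#' the region total coverage and the derived per-pool and per-sample
#' averages.
#'
#' @return data.frame with columns pool_set, raw_yield_gb, pct_mapped,
#'   pct_on_target, total_coverage, avg_coverage_per_pool,
#'   avg_coverage_per_sample.
#' @export
sequencing_yield <- function() {
  utils::read.table(system.file("extdata", "sequencing_yield.tsv",
                                package = "poolpin"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
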