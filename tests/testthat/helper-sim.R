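# Shared in-code fixtures for the simulator and classifier tests.

toy_layout_3x3 <- function() {
  matrix_layout("T1", matrix(paste0("s", 1:9), 3, 3, byrow = TRUE))
}

# A truth object with hand-placed carriers: `carriers` is a data.frame with
# columns sample, site (index), copies.
manual_truth <- function(samples, sites, carriers = NULL) {
  geno <- matrix(0L, length(samples), nrow(sites),
                 dimnames = list(samples, NULL))
  if (!is.null(carriers))
    for (i in seq_len(nrow(carriers)))
      geno[carriers$sample[i], carriers$site[i]] <- as.integer(carriers$copies[i])
  structure(list(sites = sites, genotypes = geno), class = "sim_truth")
}

manual_sites <- function(n, chrom = "chr5", start = 1300000L) {
  data.frame(chrom = chrom, pos = start + seq_len(n) * 10L,
             ref = rep_len(c("A", "C", "G", "T"), n),
             alt = rep_len(c("G", "T", "A", "C"), n),
             stringsAsFactors = FALSE)
}

noiseless_config <- function(n_sites, seed = 42L, mean_depth = 4000,
                             maf = maf_point(0.005)) {
  sim_config(n_sites = n_sites, maf = maf, mean_depth = mean_depth,
             error_rate = 0, fn_dropout_rate = 0, fp_rate = 0, seed = seed)
}

# Grid position of a sample in a layout.
grid_pos <- function(layout, sample) {
  w <- which(layout$grid == sample, arr.ind = TRUE)
  c(row = unname(w[1, 1]), col = unname(w[1, 2]))
}
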