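#' Allele-frequency spectra for the simulator
#'
#' A spectrum describes how the population alternate-allele frequency of each
#' simulated site is drawn: a point mass (every site at the same frequency),
#' a uniform range, or a beta distribution (a standard skewed spectrum for
#' rare variation).
#'
#' @param f,min,max,shape1,shape2 distribution parameters; all frequencies
#'   must lie in `[0, 1]`.
#' @return a `maf_spectrum` object.
#' @export
maf_point <- function(f) {
  stopifnot(f >= 0, f <= 1)
  structure(list(kind = "point", f = f), class = "maf_spectrum")
}

#' @rdname maf_point
#' @export
maf_uniform <- function(min, max) {
  stopifnot(min >= 0, max <= 1, min <= max)
  structure(list(kind = "uniform", min = min, max = max),
            class = "maf_spectrum")
}

#' @rdname maf_point
#' @export
maf_beta <- function(shape1, shape2) {
  stopifnot(shape1 > 0, shape2 > 0)
  structure(list(kind = "beta", shape1 = shape1, shape2 = shape2),
            class = "maf_spectrum")
}

draw_maf <- function(spectrum, n) {
  if (!inherits(spectrum, "maf_spectrum")) stop("not a maf_spectrum")
  switch(spectrum$kind,
         point = rep(spectrum$f, n),
         uniform = stats::runif(n, spectrum$min, spectrum$max),
         beta = stats::rbeta(n, spectrum$shape1, spectrum$shape2),
         stop("unknown spectrum kind: ", spectrum$kind))
}

#' Simulator configuration
#'
#' Defaults emulate the canonical deep-pooled-resequencing setting: 12-sample
#' pools at a mean per-pool depth of 4,320 reads (the per-pool average of a
#' sequenced 12x12 matrix), quality-passing bases only, and tens of distinct
#' read start points per position so the start-point-bias filter passes at
#' ordinary sites. A heterozygous carrier in a 12-sample pool contributes an
#' expected alternate-allele fraction of 1/24.
#'
#' @param n_sites number of simulated variant sites.
#' @param maf a `maf_spectrum`; default a point mass at 0.5%, a rare-variant
#'   regime where most matrices hold 0-3 carriers of a site.
#' @param mean_depth expected per-pool per-site read depth.
#' @param depth_dispersion negative-binomial size parameter for depth; larger
#'   values approach Poisson. Default 20 gives a coefficient of variation of
#'   about 22% at depth 4,320.
#' @param error_rate per-base miscall probability; an erroneous read is
#'   assigned uniformly to the three other bases.
#' @param start_points expected number of distinct read start points per
#'   site (Poisson mean, floored at 2); set `single_start = TRUE` to force
#'   the degenerate one-start-point mode that the bias filter must reject.
#' @param single_start logical; all reads from one start point.
#' @param fn_dropout_rate per (pool, site) probability that a truly present
#'   variant is erased from that pool's counts (false-negative injection).
#' @param fp_rate per (pool, site) probability of injecting a spurious
#'   above-threshold alternate count (false-positive injection).
#' @param seed master integer seed; per-pool substreams are derived from it
#'   deterministically.
#' @param region_chrom,region_start,region_end genomic region the simulated
#'   sites are placed in (defaults: a 250 kb window of chromosome 5).
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_sites = 1000L,
                       maf = maf_point(0.005),
                       mean_depth = 4320,
                       depth_dispersion = 20,
                       error_rate = 0,
                       start_points = 50,
                       single_start = FALSE,
                       fn_dropout_rate = 0,
                       fp_rate = 0,
                       seed = 1L,
                       region_chrom = "chr5",
                       region_start = 1250000L,
                       region_end = 1500000L) {
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites > 0, mean_depth > 0, depth_dispersion > 0,
            error_rate >= 0, error_rate <= 1,
            fn_dropout_rate >= 0, fn_dropout_rate <= 1,
            fp_rate >= 0, fp_rate <= 1,
            start_points >= 1,
            region_end - region_start >= n_sites)
  if (!inherits(maf, "maf_spectrum")) stop("maf must be a maf_spectrum")
  structure(list(n_sites = n_sites, maf = maf, mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion, error_rate = error_rate,
                 start_points = start_points, single_start = single_start,
                 fn_dropout_rate = fn_dropout_rate, fp_rate = fp_rate,
                 seed = as.integer(seed), region_chrom = region_chrom,
                 region_start = as.integer(region_start),
                 region_end = as.integer(region_end)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# Deterministic substream seed from the master seed and a label; kept within
# the 32-bit integer range.
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h) %% .Machine$integer.max)
}

#' Draw per-sample genotypes with known truth
#'
#' For each site an alternate-allele frequency is drawn from the configured
#' spectrum; each sample's alternate-copy count is then binomial(2, f),
#' independently across samples (Hardy-Weinberg sampling). Deterministic
#' given the config seed.
#'
#' @param config a `sim_config`.
#' @param layouts list of `matrix_layout` objects whose samples are genotyped.
#' @return a `sim_truth` object: `$sites` (data.frame chrom, pos, ref, alt,
#'   maf) and `$genotypes` (integer matrix samples x sites, entries 0/1/2).
#' @export
draw_genotypes <- function(config, layouts) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(layouts, "matrix_layout")) layouts <- list(layouts)
  samples <- unlist(lapply(layouts, layout_samples), use.names = FALSE)
  if (anyDuplicated(samples)) stop("layouts share sample identifiers")
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- config$n_sites
  pos <- sort(sample.int(config$region_end - config$region_start,
                         n, replace = FALSE)) + config$region_start
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
  f <- draw_maf(config$maf, n)
  geno <- matrix(stats::rbinom(length(samples) * n, 2L, rep(f, each = length(samples))),
                 nrow = length(samples), ncol = n,
                 dimnames = list(samples, NULL))
  structure(list(
    sites = data.frame(chrom = config$region_chrom, pos = pos,
                       ref = ref, alt = unname(alt), maf = f,
                       stringsAsFactors = FALSE),
    genotypes = geno), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d samples x %d sites, %d carrier genotypes\n",
              nrow(x$genotypes), ncol(x$genotypes), sum(x$genotypes > 0)))
  invisible(x)
}

# Split n reads carrying true base `b` into observed base counts under a
# uniform substitution error model. Vectorised over sites.
scatter_errors <- function(n, true_base_idx, error_rate) {
  counts <- matrix(0L, nrow = length(n), ncol = 4L)
  if (error_rate == 0) {
    counts[cbind(seq_along(n), true_base_idx)] <- n
    return(counts)
  }
  err <- stats::rbinom(length(n), n, error_rate)
  counts[cbind(seq_along(n), true_base_idx)] <- n - err
  # distribute errors over the three other bases sequentially
  rem <- err
  others <- matrix(0L, length(n), 3L)
  others[, 1] <- stats::rbinom(length(n), rem, 1 / 3)
  rem <- rem - others[, 1]
  others[, 2] <- stats::rbinom(length(n), rem, 1 / 2)
  others[, 3] <- rem - others[, 2]
  for (b in 1:4) {
    sel <- true_base_idx != b
    # for each site, which of its three "other" slots is base b
    slot <- integer(length(n))
    for (i in which(sel)) {
      ob <- setdiff(1:4, true_base_idx[i])
      slot[i] <- match(b, ob)
    }
    counts[sel, b] <- counts[sel, b] + others[cbind(which(sel), slot[sel])]
  }
  counts
}

#' Simulate pooled base counts for one matrix
#'
#' Each pool mixes its 12 (generally `pool size`) samples' alleles equally:
#' at a site where the pool's samples carry `k` alternate copies, the expected
#' alternate fraction is `k / (2 * pool size)`. Reads are drawn at a
#' negative-binomially dispersed depth, alternate reads binomially at that
#' fraction, and sequencing errors scatter reads uniformly onto the other
#' three bases. Read start-point multiplicities are drawn multinomially over
#' a Poisson number of distinct start points. Optional per-sample weights
#' model uneven pooling. False-negative dropout and false-positive injection
#' are applied per the config, creating the singleton-class events a
#' two-dimensional design is built to expose.
#'
#' @param truth a `sim_truth` covering all samples of `layout`.
#' @param layout a `matrix_layout`.
#' @param config a `sim_config`.
#' @param weights optional positive per-sample weight vector (named by sample
#'   id) for uneven pooling; default equal.
#' @return list of `pool_counts` objects, one per pool of the layout (rows
#'   first, then columns).
#' @export
simulate_pool_counts <- function(truth, layout, config, weights = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(layout, "matrix_layout"),
            inherits(config, "sim_config"))
  missing <- setdiff(layout_samples(layout), rownames(truth$genotypes))
  if (length(missing))
    stop("samples absent from truth: ", paste(missing, collapse = ", "))
  lapply(pools(layout), function(p)
    simulate_one_pool(truth, layout, p, config, weights))
}

simulate_one_pool <- function(truth, layout, pool, config, weights = NULL) {
  members <- samples_in_pool(layout, pool)
  geno <- truth$genotypes[members, , drop = FALSE]
  if (is.null(weights)) {
    w <- rep(1, length(members))
  } else {
    w <- weights[members]
    if (anyNA(w) || any(w <= 0)) stop("weights must be positive for all pool members")
  }
  w <- w / sum(w)
  # expected alt fraction: weighted carrier copies over 2 copies per sample
  f <- as.vector(crossprod(geno, w)) / 2
  set.seed(derive_seed(config$seed, paste0("pool:", format_pool_id(pool))))
  n <- nrow(truth$sites)
  depth <- stats::rnbinom(n, mu = config$mean_depth,
                          size = config$depth_dispersion)
  depth <- pmax(depth, 1L)
  ref_idx <- match(truth$sites$ref, BASES)
  alt_idx <- match(truth$sites$alt, BASES)
  alt_true <- stats::rbinom(n, depth, f)

  # dropout: erase the variant from this pool's counts
  if (config$fn_dropout_rate > 0) {
    drop <- stats::runif(n) < config$fn_dropout_rate & alt_true > 0
    alt_true[drop] <- 0L
  }
  counts <- scatter_errors(depth - alt_true, ref_idx, config$error_rate) +
    scatter_errors(alt_true, alt_idx, config$error_rate)

  # false positives: move an above-threshold slug of reads onto the alt base
  if (config$fp_rate > 0) {
    fp <- stats::runif(n) < config$fp_rate
    for (i in which(fp)) {
      s <- min(ceiling(depth[i] * 0.02), counts[i, ref_idx[i]])
      counts[i, ref_idx[i]] <- counts[i, ref_idx[i]] - s
      counts[i, alt_idx[i]] <- counts[i, alt_idx[i]] + s
    }
  }
  colnames(counts) <- BASES

  start_points <- lapply(seq_len(n), function(i) {
    if (config$single_start) return(depth[i])
    n_sp <- max(2L, stats::rpois(1L, config$start_points))
    n_sp <- min(n_sp, depth[i])
    as.integer(stats::rmultinom(1L, depth[i], rep(1 / n_sp, n_sp)))
  })

  pool_counts(pool, truth$sites[, c("chrom", "pos", "ref")], depth,
              counts, start_points)
}

#' Per-pool base-count table
#'
#' The internal count container shared by the simulator and the pileup
#' reader: one row per site with the (quality-passing) read count of each
#' base, the total depth, and the read-start-point multiplicities `d_i`
#' used by the bias filter.
#'
#' @param pool a `pool_id`.
#' @param sites data.frame with columns chrom, pos, ref.
#' @param depth integer vector of per-site depths.
#' @param base_counts integer matrix sites x 4 with columns A, C, G, T;
#'   rows must sum to `depth`.
#' @param start_points list of integer vectors (`d_i` per site), each summing
#'   to the site depth, or `NULL` entries where start information is absent.
#' @param indel_counts optional list of named integer vectors of indel-allele
#'   read counts (names like `"+A"`, `"-AT"`).
#' @return a `pool_counts` object.
#' @export
pool_counts <- function(pool, sites, depth, base_counts, start_points = NULL,
                        indel_counts = NULL) {
  stopifnot(inherits(pool, "pool_id"),
            all(c("chrom", "pos", "ref") %in% names(sites)),
            nrow(sites) == length(depth),
            nrow(base_counts) == nrow(sites),
            identical(colnames(base_counts), BASES))
  if (any(depth < 0) || any(base_counts < 0)) stop("counts must be >= 0")
  if (any(rowSums(base_counts) != depth))
    stop("base counts must sum to depth at every site")
  storage.mode(base_counts) <- "integer"
  if (!is.null(start_points)) {
    stopifnot(length(start_points) == nrow(sites))
    ok <- vapply(seq_along(start_points), function(i)
      is.null(start_points[[i]]) || sum(start_points[[i]]) == depth[i], TRUE)
    if (!all(ok)) stop("start-point multiplicities must sum to depth")
  }
  structure(list(pool = pool,
                 sites = data.frame(chrom = as.character(sites$chrom),
                                    pos = as.integer(sites$pos),
                                    ref = as.character(sites$ref),
                                    stringsAsFactors = FALSE),
                 depth = as.integer(depth),
                 base_counts = base_counts,
                 start_points = start_points,
                 indel_counts = indel_counts),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("<pool_counts> pool %s: %d sites, mean depth %.0f\n",
              format_pool_id(x$pool), nrow(x$sites), mean(x$depth)))
  invisible(x)
}

#' Erase a variant from one pool's counts
#'
#' Moves all reads of the given alternate base back onto the reference base
#' at one site, emulating a pool-level false negative. Used to study the
#' singleton class: dropping one of a pinnable variant's two observation
#' pools turns it into a singleton.
#'
#' @param counts a `pool_counts`.
#' @param site_index 1-based site row.
#' @param alt alternate base to erase.
#' @return the modified `pool_counts`.
#' @export
inject_dropout <- function(counts, site_index, alt) {
  stopifnot(inherits(counts, "pool_counts"))
  ref <- counts$sites$ref[site_index]
  k <- counts$base_counts[site_index, alt]
  counts$base_counts[site_index, alt] <- 0L
  counts$base_counts[site_index, ref] <-
    counts$base_counts[site_index, ref] + k
  counts
}

#' Write simulated pools as pileup fixtures
#'
#' Emits one pileup-dialect file per pool (`<matrix>_<row|col><index>.pileup`)
#' plus `truth.tsv` (sample, chrom, pos, ref, alt, copies). The base column
#' encodes start-point groups with `^` markers (the first read of each start
#' point carries one), so `read_pileup()` recovers identical counts and
#' multiplicities; all base qualities are written as q40.
#'
#' @param counts_list list of `pool_counts`.
#' @param truth a `sim_truth` (or `NULL` to skip the truth file).
#' @param dir output directory, created if needed.
#' @return character vector of written paths, invisibly.
#' @export
write_fixture <- function(counts_list, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(counts_list, function(pc) {
    p <- pc$pool
    fn <- file.path(dir, sprintf("%s_%s%d.pileup", p$matrix_id,
                                 if (p$axis == "row") "row" else "col",
                                 p$index))
    write_pileup(pc, fn)
    fn
  }, "")
  if (!is.null(truth)) {
    tf <- file.path(dir, "truth.tsv")
    carriers <- which(truth$genotypes > 0, arr.ind = TRUE)
    df <- data.frame(
      sample = rownames(truth$genotypes)[carriers[, 1]],
      chrom = truth$sites$chrom[carriers[, 2]],
      pos = truth$sites$pos[carriers[, 2]],
      ref = truth$sites$ref[carriers[, 2]],
      alt = truth$sites$alt[carriers[, 2]],
      copies = truth$genotypes[carriers],
      stringsAsFactors = FALSE)
    df <- df[order(df$pos, df$sample), ]
    utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tf)
  }
  invisible(paths)
}
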