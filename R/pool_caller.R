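#' Calling thresholds
#'
#' The per-pool caller partitions every covered (position, alternate allele)
#' pair into one of five states from three quantities: the quality-filtered
#' depth, the start-point-bias score, and the alternate-allele fraction
#' `f = alt reads / filtered depth`.
#'
#' * depth < `min_depth` or score < `min_start_point_score` -> `insufficient`
#' * `f > confident_variant_frac`                   -> `confident_variant`
#' * `potential_variant_frac < f <= confident_variant_frac` -> `potential_variant`
#' * `confident_ref_frac <= f <= potential_variant_frac`    -> `potential_ref`
#' * `f < confident_ref_frac`                       -> `confident_ref`
#'
#' Defaults: 200 reads, score 1.25, and fractions 1%, 0.5% and 0.1%. With
#' 12-sample pools the 200-read floor guarantees at least
#' `floor(200 / 12) = 16` reads per individual under even pooling, and a
#' single heterozygous carrier's expected fraction 1/24 (about 4.2%) sits
#' well above the 1% confident threshold.
#'
#' @param min_depth minimum quality-filtered depth (reads).
#' @param min_start_point_score minimum start-point-bias score.
#' @param confident_variant_frac,potential_variant_frac,confident_ref_frac
#'   fraction tier boundaries; must satisfy
#'   `confident_ref_frac < potential_variant_frac < confident_variant_frac`.
#' @return a `call_thresholds` object.
#' @export
call_thresholds <- function(min_depth = 200L,
                            min_start_point_score = 1.25,
                            confident_variant_frac = 0.01,
                            potential_variant_frac = 0.005,
                            confident_ref_frac = 0.001) {
  stopifnot(min_depth > 0, min_start_point_score >= 1,
            confident_ref_frac < potential_variant_frac,
            potential_variant_frac < confident_variant_frac)
  structure(list(min_depth = as.integer(min_depth),
                 min_start_point_score = min_start_point_score,
                 confident_variant_frac = confident_variant_frac,
                 potential_variant_frac = potential_variant_frac,
                 confident_ref_frac = confident_ref_frac),
            class = "call_thresholds")
}

CALL_STATES <- c("confident_variant", "potential_variant", "potential_ref",
                 "confident_ref", "insufficient")

#' Start-point-bias score
#'
#' The effective number of distinct read start points,
#' `(sum(d))^2 / sum(d^2)` (an inverse Simpson index), where `d_i` is the
#' number of reads beginning at the i-th start point. The score is 1 when
#' all reads share one start point — the PCR-duplication signature the
#' filter exists to catch — and rises with both the number of start points
#' and the evenness of their coverage, reaching `n` for an even split over
#' `n` starts. Positions scoring below the threshold (default 1.25) are
#' treated as having insufficient coverage.
#'
#' @param d integer vector of reads per start point; all entries >= 1.
#' @return the score (>= 1).
#' @export
start_point_score <- function(d) {
  if (length(d) == 0L) stop("start-point multiplicities must be non-empty")
  if (any(d < 1)) stop("start-point multiplicities must be >= 1")
  sum(d)^2 / sum(d^2)
}

#' Five-state call from depth, score and alternate count
#'
#' Vectorised core of the caller; see [call_thresholds()] for the partition.
#' A score of `NA` means start-point information was absent in the source
#' data: the bias filter is then not evaluable and treated as passing.
#'
#' @param depth quality-filtered depth (reads).
#' @param alt_count alternate-supporting reads.
#' @param score start-point-bias score, or `NA` when not evaluable.
#' @param thresholds a `call_thresholds`.
#' @return character vector of states.
#' @export
call_allele <- function(depth, alt_count, score = NA_real_,
                        thresholds = call_thresholds()) {
  stopifnot(inherits(thresholds, "call_thresholds"))
  n <- max(length(depth), length(alt_count))
  depth <- rep_len(depth, n)
  alt_count <- rep_len(alt_count, n)
  score <- rep_len(score, n)
  f <- ifelse(depth > 0, alt_count / depth, 0)
  state <- rep("insufficient", n)
  ok <- depth >= thresholds$min_depth &
    (is.na(score) | score >= thresholds$min_start_point_score)
  state[ok & f > thresholds$confident_variant_frac] <- "confident_variant"
  state[ok & f > thresholds$potential_variant_frac &
          f <= thresholds$confident_variant_frac] <- "potential_variant"
  state[ok & f >= thresholds$confident_ref_frac &
          f <= thresholds$potential_variant_frac] <- "potential_ref"
  state[ok & f < thresholds$confident_ref_frac] <- "confident_ref"
  state
}

pool_scores <- function(counts) {
  if (is.null(counts$start_points)) return(rep(NA_real_, nrow(counts$sites)))
  vapply(counts$start_points, function(d)
    if (is.null(d)) NA_real_ else start_point_score(d), 0)
}

#' Call variants in one pool
#'
#' Emits one call per (position, alternate allele observed with at least one
#' read), plus — when `candidate_keys` is supplied — a call for every
#' candidate key covered by this pool even when its alternate count is zero.
#' Ref-state calls matter: knowing a variant is *absent* from a pool is what
#' lets the classifier trace it to an individual. Masked positions are
#' skipped entirely. Indel alleles, when present in the counts, flow through
#' identically via their count fractions.
#'
#' @param counts a `pool_counts` (sites must be sorted by chrom, pos).
#' @param thresholds a `call_thresholds`.
#' @param mask optional `GRanges` exclusion mask.
#' @param candidate_keys optional character vector of `chrom:pos:ref:alt`
#'   keys that must receive a call if covered.
#' @return data.frame with columns matrix_id, axis, pool_index, chrom, pos,
#'   ref, alt, depth, alt_count, fraction, score, state.
#' @export
call_pool <- function(counts, thresholds = call_thresholds(), mask = NULL,
                      candidate_keys = NULL) {
  stopifnot(inherits(counts, "pool_counts"))
  s <- counts$sites
  if (any(vapply(split(s$pos, s$chrom), is.unsorted, TRUE)))
    stop("pileup columns must be sorted by (chrom, pos)")
  keep <- !in_mask(mask, s$chrom, s$pos)
  scores <- pool_scores(counts)

  # SNV alleles: all three non-reference bases per unmasked site, long form
  alt_by_ref <- lapply(stats::setNames(BASES, BASES),
                       function(b) setdiff(BASES, b))
  keep_idx <- which(keep)
  site_idx <- rep(keep_idx, each = 3L)
  alt <- unlist(alt_by_ref[s$ref[keep_idx]], use.names = FALSE)
  cnt <- counts$base_counts[cbind(site_idx, match(alt, BASES))]
  want <- cnt > 0L
  if (!is.null(candidate_keys)) {
    k <- variant_key(s$chrom[site_idx], s$pos[site_idx], s$ref[site_idx], alt)
    want <- want | k %in% candidate_keys
  }
  out <- data.frame(chrom = s$chrom[site_idx[want]],
                    pos = s$pos[site_idx[want]],
                    ref = s$ref[site_idx[want]], alt = alt[want],
                    depth = counts$depth[site_idx[want]],
                    alt_count = as.integer(cnt[want]),
                    score = scores[site_idx[want]],
                    stringsAsFactors = FALSE)
  # indel alleles flow through identically via their count fractions
  if (!is.null(counts$indel_counts)) {
    for (i in intersect(keep_idx, which(!vapply(counts$indel_counts,
                                                is.null, TRUE)))) {
      icnt <- counts$indel_counts[[i]]
      out <- rbind(out, data.frame(
        chrom = s$chrom[i], pos = s$pos[i], ref = s$ref[i],
        alt = names(icnt), depth = counts$depth[i],
        alt_count = as.integer(icnt), score = scores[i],
        stringsAsFactors = FALSE))
    }
    out <- out[order(match(out$chrom, unique(s$chrom)), out$pos, out$alt), ]
    row.names(out) <- NULL
  }
  out$fraction <- ifelse(out$depth > 0, out$alt_count / out$depth, 0)
  out$state <- call_allele(out$depth, out$alt_count, out$score, thresholds)
  p <- counts$pool
  cbind(data.frame(matrix_id = rep(p$matrix_id, nrow(out)),
                   axis = rep(p$axis, nrow(out)),
                   pool_index = rep(p$index, nrow(out)),
                   stringsAsFactors = FALSE),
        out)[, c("matrix_id", "axis", "pool_index", "chrom", "pos", "ref",
                 "alt", "depth", "alt_count", "fraction", "score", "state")]
}
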