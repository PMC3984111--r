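VARIANT_STATES <- c("confident_variant", "potential_variant")

pool_label <- function(axis, index) paste0(axis, "_", index)

#' Assemble per-variant call vectors across the pools of a matrix
#'
#' For every variant key observed (confidently or potentially) in at least
#' one pool, assembles the full vector of call states over all pools of the
#' matrix. Pools whose first-pass call table carries no record at a key are
#' resolved by a second-pass query of their base counts — yielding a
#' ref-state call or `insufficient` — because knowing a variant is absent
#' from a pool is as informative as seeing it.
#'
#' @param call_tables list of per-pool call tables from [call_pool()], in
#'   the order of `pools(layout)` (rows first, then columns).
#' @param pool_counts_list list of `pool_counts` parallel to `call_tables`,
#'   used for the second pass.
#' @param layout the `matrix_layout` the pools belong to.
#' @param thresholds a `call_thresholds`.
#' @param mask optional exclusion mask.
#' @return a `matrix_calls` object: `$keys` (data.frame chrom, pos, ref,
#'   alt) and `$states` (character matrix keys x pools, columns labelled
#'   `row_1 ... column_n`).
#' @export
collect_matrix_calls <- function(call_tables, pool_counts_list, layout,
                                 thresholds = call_thresholds(),
                                 mask = NULL) {
  stopifnot(inherits(layout, "matrix_layout"))
  pl <- pools(layout)
  if (length(call_tables) != length(pl) ||
      length(pool_counts_list) != length(pl))
    stop(sprintf("matrix %s has %d pools; got %d call tables and %d count sets",
                 layout$matrix_id, length(pl), length(call_tables),
                 length(pool_counts_list)))
  for (j in seq_along(pl)) {
    tbl <- call_tables[[j]]
    if (nrow(tbl) &&
        (any(tbl$matrix_id != pl[[j]]$matrix_id) ||
         any(tbl$axis != pl[[j]]$axis) ||
         any(tbl$pool_index != pl[[j]]$index)))
      stop("call table ", j, " does not match pool ",
           format_pool_id(pl[[j]]), " of matrix ", layout$matrix_id)
    pc <- pool_counts_list[[j]]
    if (pc$pool$matrix_id != layout$matrix_id)
      stop("pool counts from matrix ", pc$pool$matrix_id,
           " mixed into matrix ", layout$matrix_id)
  }

  seen <- do.call(rbind, lapply(call_tables, function(t)
    t[t$state %in% VARIANT_STATES,
      c("chrom", "pos", "ref", "alt"), drop = FALSE]))
  if (is.null(seen) || !nrow(seen)) {
    return(structure(list(
      keys = data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0)),
      states = matrix(character(0), 0, length(pl),
                      dimnames = list(NULL, vapply(pl, function(p)
                        pool_label(p$axis, p$index), ""))),
      layout = layout), class = "matrix_calls"))
  }
  keydf <- unique(seen)
  keydf <- keydf[order(keydf$chrom, keydf$pos, keydf$alt), , drop = FALSE]
  row.names(keydf) <- NULL
  keys <- variant_key(keydf$chrom, keydf$pos, keydf$ref, keydf$alt)

  states <- matrix(NA_character_, nrow(keydf), length(pl),
                   dimnames = list(keys, vapply(pl, function(p)
                     pool_label(p$axis, p$index), "")))
  for (j in seq_along(pl)) {
    tbl <- call_tables[[j]]
    tkeys <- variant_key(tbl$chrom, tbl$pos, tbl$ref, tbl$alt)
    m <- match(keys, tkeys)
    st <- tbl$state[m]
    miss <- which(is.na(m))
    if (length(miss)) {
      second <- call_pool(pool_counts_list[[j]], thresholds, mask,
                          candidate_keys = keys[miss])
      skeys <- variant_key(second$chrom, second$pos, second$ref, second$alt)
      m2 <- match(keys[miss], skeys)
      st[miss] <- second$state[m2]
      st[miss[is.na(m2)]] <- "insufficient"  # position not covered in pool
    }
    states[, j] <- st
  }
  structure(list(keys = keydf, states = states, layout = layout),
            class = "matrix_calls")
}

#' Classify one variant from its 24-pool call vector
#'
#' Rule order: (1) a variant with no *confident* call in any pool is
#' discarded (`NULL`); (2) if the number of pools with insufficient coverage
#' exceeds `max_insufficient_pools`, the evidence cannot distinguish the
#' classes and the variant is `missing_coverage`; (3) otherwise the observed
#' rows/columns are the pools in a variant state (confident or potential):
#' exactly one row or exactly one column (both non-empty) is `pinnable`,
#' with carriers pinned at the grid intersections; more than one of each is
#' `multiple`, with the intersections as the candidate superset; observation
#' on one axis only is a `singleton` — inconsistent with a design in which
#' every sample is sequenced twice, so a false positive or a dropout.
#'
#' @param states named character vector of call states over the pools of a
#'   matrix (names `row_i` / `column_j`).
#' @param layout the `matrix_layout`.
#' @param max_insufficient_pools most insufficient pools tolerated before
#'   declaring `missing_coverage` (default 2, i.e. 3 or more blocks
#'   classification).
#' @return a one-row data.frame (list-columns for index and sample sets), or
#'   `NULL` for a discarded potential-only variant.
#' @export
classify_variant <- function(states, layout, max_insufficient_pools = 2L) {
  stopifnot(inherits(layout, "matrix_layout"))
  expect <- vapply(pools(layout), function(p) pool_label(p$axis, p$index), "")
  if (!setequal(names(states), expect) || length(states) != length(expect))
    stop("states must cover every pool of the matrix exactly once")
  states <- states[expect]
  if (!any(states == "confident_variant")) return(NULL)

  is_row <- grepl("^row_", names(states))
  idx <- as.integer(sub("^(row|column)_", "", names(states)))
  observed <- states %in% VARIANT_STATES
  obs_rows <- idx[is_row & observed]
  obs_cols <- idx[!is_row & observed]
  n_insuf <- sum(states == "insufficient")

  if (n_insuf > max_insufficient_pools) {
    cls <- "missing_coverage"
    pinned <- character(0); cand <- character(0)
  } else if (length(obs_rows) && length(obs_cols)) {
    if (length(obs_rows) == 1L || length(obs_cols) == 1L) {
      cls <- "pinnable"
      pinned <- intersect_samples(layout, obs_rows, obs_cols)
      cand <- character(0)
    } else {
      cls <- "multiple"
      pinned <- character(0)
      cand <- intersect_samples(layout, obs_rows, obs_cols)
    }
  } else if (length(obs_rows) || length(obs_cols)) {
    cls <- "singleton"
    pinned <- character(0); cand <- character(0)
  } else {
    stop("internal inconsistency: confident call but no observed pool")
  }
  out <- data.frame(matrix_id = layout$matrix_id, variant_class = cls,
                    insufficient_pools = n_insuf,
                    has_confident = TRUE, stringsAsFactors = FALSE)
  out$observed_rows <- I(list(sort(obs_rows)))
  out$observed_cols <- I(list(sort(obs_cols)))
  out$pinned_samples <- I(list(pinned))
  out$candidate_samples <- I(list(cand))
  out
}

#' Classify all variants of a matrix
#'
#' @param collected a `matrix_calls` from [collect_matrix_calls()].
#' @param max_insufficient_pools see [classify_variant()].
#' @return data.frame with one row per emitted variant: chrom, pos, ref,
#'   alt, matrix_id, variant_class, insufficient_pools, and list-columns
#'   observed_rows, observed_cols, pinned_samples, candidate_samples. The
#'   number of discarded potential-only variants is attached as attribute
#'   `"discarded_potential_only"`.
#' @export
classify_matrix <- function(collected, max_insufficient_pools = 2L) {
  stopifnot(inherits(collected, "matrix_calls"))
  layout <- collected$layout
  rows <- vector("list", nrow(collected$keys))
  discarded <- 0L
  for (i in seq_len(nrow(collected$keys))) {
    cv <- classify_variant(collected$states[i, ], layout,
                           max_insufficient_pools)
    if (is.null(cv)) { discarded <- discarded + 1L; next }
    rows[[i]] <- cbind(collected$keys[i, , drop = FALSE], cv)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    empty_classified()
  row.names(out) <- NULL
  attr(out, "discarded_potential_only") <- discarded
  out
}

empty_classified <- function() {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    matrix_id = character(0), variant_class = character(0),
                    insufficient_pools = integer(0),
                    has_confident = logical(0), stringsAsFactors = FALSE)
  out$observed_rows <- I(list())
  out$observed_cols <- I(list())
  out$pinned_samples <- I(list())
  out$candidate_samples <- I(list())
  out
}

VARIANT_CLASSES <- c("pinnable", "multiple", "singleton", "missing_coverage")

is_snv_key <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L & ref %in% BASES & alt %in% BASES
}

#' Aggregate classified variants across matrices
#'
#' Cross-matrix identity is by variant key (chrom, pos, ref, alt); the class
#' is a per-matrix attribute. A key classified differently in different
#' matrices contributes to each class's unique tally; its matrices-observed
#' count uses all matrices where it was emitted.
#'
#' @param classified data.frame of classified variants, rbind-ed over
#'   matrices ([classify_matrix()] output).
#' @param snv_only drop indel-shaped alleles before summarising (default
#'   FALSE; indels are tallied separately by [report()]).
#' @return a `pool_study_summary`: `$by_matrix` (class counts per matrix),
#'   `$unique_by_class` (unique keys per class across matrices),
#'   `$matrices_observed` (per key), `$crosstab` (class x number of matrices
#'   observed, over unique (key, class) pairs), `$n_matrices`.
#' @export
aggregate_matrices <- function(classified, snv_only = FALSE) {
  if (snv_only) classified <- classified[is_snv_key(classified$ref,
                                                    classified$alt), ]
  if (is.null(classified) || !nrow(classified)) {
    zeros <- stats::setNames(rep(0L, length(VARIANT_CLASSES)), VARIANT_CLASSES)
    return(structure(list(
      by_matrix = as.data.frame(matrix(integer(0), 0, 4,
                                       dimnames = list(NULL, VARIANT_CLASSES))),
      unique_by_class = zeros,
      matrices_observed = stats::setNames(integer(0), character(0)),
      crosstab = matrix(0L, 4, 1, dimnames = list(VARIANT_CLASSES, "1")),
      n_matrices = 0L,
      keys_by_class = list()), class = "pool_study_summary"))
  }
  key <- variant_key(classified$chrom, classified$pos, classified$ref,
                     classified$alt)
  mats <- sort(unique(classified$matrix_id))
  by_matrix <- as.data.frame.matrix(
    table(factor(classified$matrix_id, levels = mats),
          factor(classified$variant_class, levels = VARIANT_CLASSES)))
  m_obs <- tapply(classified$matrix_id, key,
                  function(x) length(unique(x)))
  uniq_pairs <- unique(data.frame(key = key,
                                  variant_class = classified$variant_class,
                                  stringsAsFactors = FALSE))
  unique_by_class <- table(factor(uniq_pairs$variant_class,
                                  levels = VARIANT_CLASSES))
  crosstab <- table(factor(uniq_pairs$variant_class, levels = VARIANT_CLASSES),
                    factor(m_obs[uniq_pairs$key],
                           levels = seq_len(max(1L, length(mats)))))
  structure(list(by_matrix = by_matrix,
                 unique_by_class = c(unique_by_class),
                 matrices_observed = c(m_obs),
                 crosstab = unclass(crosstab),
                 n_matrices = length(mats),
                 keys_by_class = split(uniq_pairs$key, uniq_pairs$variant_class)),
            class = "pool_study_summary")
}

#' @export
print.pool_study_summary <- function(x, ...) {
  cat("<pool_study_summary>", x$n_matrices, "matrices\n")
  print(x$by_matrix)
  cat("unique keys by class:\n")
  print(x$unique_by_class)
  invisible(x)
}

#' Annotate a study summary with known-site percentages
#'
#' For each class, the percentage of its unique variant keys present in the
#' supplied known-sites set (e.g. a dbSNP extract read with
#' [read_known_sites()]). A low known-site rate for a class is evidence that
#' its calls are enriched for artefacts or genuinely novel rare variation.
#'
#' @param summary a `pool_study_summary`.
#' @param known_keys character vector of known `chrom:pos:ref:alt` keys.
#' @return the summary with `$pct_known_by_class` added (percent, 0-100).
#' @export
annotate_known <- function(summary, known_keys) {
  stopifnot(inherits(summary, "pool_study_summary"))
  pct <- vapply(VARIANT_CLASSES, function(cl) {
    k <- summary$keys_by_class[[cl]]
    if (is.null(k) || !length(k)) return(0)
    100 * mean(k %in% known_keys)
  }, 0)
  summary$pct_known_by_class <- pct
  summary
}
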