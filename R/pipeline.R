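#' Call all pools of one matrix and assemble per-variant vectors
#'
#' Convenience wrapper: first-pass [call_pool()] over the matrix's pools,
#' then [collect_matrix_calls()] with second-pass absence resolution.
#'
#' @param pool_counts_list list of `pool_counts` in `pools(layout)` order.
#' @param layout the `matrix_layout`.
#' @param thresholds a `call_thresholds`.
#' @param mask optional exclusion mask.
#' @return a `matrix_calls` object.
#' @export
call_matrix <- function(pool_counts_list, layout,
                        thresholds = call_thresholds(), mask = NULL) {
  tables <- lapply(pool_counts_list, call_pool, thresholds = thresholds,
                   mask = mask)
  collect_matrix_calls(tables, pool_counts_list, layout, thresholds, mask)
}

#' Run the full two-dimensional pooling pipeline
#'
#' Orchestrates design -> (simulate | ingest) -> per-pool calling ->
#' classification -> aggregation, writing all artifacts under `out_dir`:
#' `manifest.tsv`, `classified.vcf`, `summary.tsv` (class counts per matrix
#' plus the total-unique row, with known-site percentages when a known-sites
#' file is given), `crosstab.tsv` (class x matrices-observed), `report.txt`,
#' and `run_manifest.json` (package version, seed, configuration). Given
#' identical inputs the run is deterministic and idempotent.
#'
#' @param out_dir output directory (created).
#' @param layouts list of `matrix_layout`s; defaults to the canonical four
#'   12x12 matrices over 576 samples when simulating.
#' @param sim a `sim_config` to generate data, or `NULL` to ingest pileups.
#' @param input_dir directory of `write_fixture()`-style pileup files
#'   (ingest mode; requires `layouts` or `manifest`).
#' @param manifest optional manifest TSV path to read layouts from.
#' @param thresholds a `call_thresholds`.
#' @param mask_path optional BED exclusion mask.
#' @param known_sites_path optional known-sites VCF for membership
#'   annotation.
#' @param max_insufficient_pools see [classify_variant()].
#' @return invisibly, a list: `layouts`, `truth` (sim mode), `classified`,
#'   `summary`, `paths`.
#' @export
run_pipeline <- function(out_dir,
                         layouts = NULL,
                         sim = NULL,
                         input_dir = NULL,
                         manifest = NULL,
                         thresholds = call_thresholds(),
                         mask_path = NULL,
                         known_sites_path = NULL,
                         max_insufficient_pools = 2L) {
  if (is.null(sim) && is.null(input_dir))
    stop("pipeline needs either a sim config or an input_dir of pileups")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(manifest)) layouts <- read_manifest(manifest)
  if (is.null(layouts))
    layouts <- build_design(sprintf("S%03d", 1:576), 12, 12, 4)
  if (inherits(layouts, "matrix_layout")) layouts <- list(layouts)
  mask <- if (!is.null(mask_path)) read_mask(mask_path) else NULL

  truth <- NULL
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    truth <- draw_genotypes(sim, layouts)
    counts_by_matrix <- lapply(layouts, function(l)
      simulate_pool_counts(truth, l, sim))
  } else {
    all_counts <- read_fixture_dir(input_dir)
    counts_by_matrix <- lapply(layouts, function(l) {
      wanted <- vapply(pools(l), format_pool_id, "")
      got <- vapply(all_counts, function(pc) format_pool_id(pc$pool), "")
      idx <- match(wanted, got)
      if (anyNA(idx))
        stop("stage ingest: missing pileup for pool(s): ",
             paste(wanted[is.na(idx)], collapse = ", "))
      all_counts[idx]
    })
  }

  classified <- do.call(rbind, lapply(seq_along(layouts), function(m) {
    collected <- call_matrix(counts_by_matrix[[m]], layouts[[m]],
                             thresholds, mask)
    classify_matrix(collected, max_insufficient_pools)
  }))
  if (is.null(classified)) classified <- empty_classified()

  known <- if (!is.null(known_sites_path)) read_known_sites(known_sites_path)
           else NULL
  if (!is.null(known)) {
    classified$known_site <- variant_key(classified$chrom, classified$pos,
                                         classified$ref,
                                         classified$alt) %in% known
  }
  summary <- aggregate_matrices(classified)
  if (!is.null(known)) summary <- annotate_known(summary, known)

  paths <- list(
    manifest = file.path(out_dir, "manifest.tsv"),
    vcf = file.path(out_dir, "classified.vcf"),
    summary = file.path(out_dir, "summary.tsv"),
    crosstab = file.path(out_dir, "crosstab.tsv"),
    report = file.path(out_dir, "report.txt"),
    run_manifest = file.path(out_dir, "run_manifest.json"))
  write_manifest(layouts, paths$manifest)
  write_vcf(classified, paths$vcf)
  write_summary_tsv(summary, paths$summary)
  utils::write.table(data.frame(variant_class = rownames(summary$crosstab),
                                summary$crosstab, check.names = FALSE),
                     paths$crosstab, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(report(summary), paths$report)
  jsonlite::write_json(
    list(package = "poolpin",
         version = as.character(utils::packageVersion("poolpin")),
         mode = if (is.null(sim)) "ingest" else "simulate",
         seed = if (is.null(sim)) NA else sim$seed,
         n_matrices = length(layouts),
         thresholds = unclass(thresholds),
         max_insufficient_pools = max_insufficient_pools),
    paths$run_manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(layouts = layouts, truth = truth, classified = classified,
                 summary = summary, paths = paths))
}

write_summary_tsv <- function(summary, path) {
  df <- data.frame(matrix_id = rownames(summary$by_matrix),
                   summary$by_matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  total <- data.frame(matrix_id = "total_unique",
                      t(as.matrix(summary$unique_by_class)),
                      check.names = FALSE, stringsAsFactors = FALSE)
  names(total) <- names(df)
  df <- rbind(df, total)
  if (!is.null(summary$pct_known_by_class)) {
    pk <- data.frame(matrix_id = "pct_known",
                     t(round(summary$pct_known_by_class, 2)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(pk) <- names(df)
    df <- rbind(df, pk)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Human-readable study report
#'
#' Per-matrix class counts, the total-unique row, known-site percentages
#' when available, and (for multi-matrix studies) the class-by-number-of-
#' matrices-observed cross-tabulation. Counts equal those in the machine
#' summary by construction.
#'
#' @param summary a `pool_study_summary`.
#' @return character vector of report lines.
#' @export
report <- function(summary) {
  stopifnot(inherits(summary, "pool_study_summary"))
  lines <- c("Two-dimensional pooling study summary",
             "=====================================", "")
  hdr <- sprintf("%-14s %9s %9s %10s %17s", "matrix", "pinnable",
                 "multiple", "singleton", "missing_coverage")
  lines <- c(lines, hdr)
  for (m in rownames(summary$by_matrix)) {
    r <- summary$by_matrix[m, ]
    lines <- c(lines, sprintf("%-14s %9d %9d %10d %17d", m,
                              r$pinnable, r$multiple, r$singleton,
                              r$missing_coverage))
  }
  u <- summary$unique_by_class
  lines <- c(lines, sprintf("%-14s %9d %9d %10d %17d", "total_unique",
                            u[["pinnable"]], u[["multiple"]],
                            u[["singleton"]], u[["missing_coverage"]]))
  if (!is.null(summary$pct_known_by_class)) {
    p <- summary$pct_known_by_class
    lines <- c(lines, sprintf("%-14s %8.2f%% %8.2f%% %9.2f%% %16.2f%%",
                              "pct_known", p[["pinnable"]], p[["multiple"]],
                              p[["singleton"]], p[["missing_coverage"]]))
  }
  if (summary$n_matrices > 1L) {
    lines <- c(lines, "", "Unique variants by number of matrices observed in:")
    ct <- summary$crosstab
    lines <- c(lines, paste0(sprintf("%-17s", "class"),
                             paste(sprintf("%6s", colnames(ct)),
                                   collapse = " ")))
    for (cl in rownames(ct))
      lines <- c(lines, paste0(sprintf("%-17s", cl),
                               paste(sprintf("%6d", ct[cl, ]),
                                     collapse = " ")))
  }
  lines
}
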