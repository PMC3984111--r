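variant_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Write classified variants as VCF
#'
#' One record per (variant, matrix). INFO keys: `MATRIX` (matrix id),
#' `CLASS` (pinnable / multiple / singleton / missing_coverage), `ROWS` and
#' `COLS` (observed pool indices), `NINSUF` (pools with insufficient
#' coverage), `PINNED` (sample ids, pinnable only), `NCAND` (candidate-sample
#' count, multiple only), and `KNOWN` (flag, only when a known-sites set was
#' supplied). The output is valid VCF 4.2; with zero variants a header-only
#' file is written.
#'
#' @param classified data.frame from [classify_matrix()] (possibly rbind-ed
#'   across matrices).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(classified, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolpin",
    '##INFO=<ID=MATRIX,Number=1,Type=String,Description="Matrix the classification applies to">',
    '##INFO=<ID=CLASS,Number=1,Type=String,Description="Variant class: pinnable, multiple, singleton or missing_coverage">',
    '##INFO=<ID=ROWS,Number=.,Type=Integer,Description="Row pools where the variant was observed">',
    '##INFO=<ID=COLS,Number=.,Type=Integer,Description="Column pools where the variant was observed">',
    '##INFO=<ID=NINSUF,Number=1,Type=Integer,Description="Pools with insufficient coverage at this site">',
    '##INFO=<ID=PINNED,Number=.,Type=String,Description="Samples the variant is pinned to (pinnable class)">',
    '##INFO=<ID=NCAND,Number=1,Type=Integer,Description="Candidate samples at observed intersections (multiple class)">',
    '##INFO=<ID=KNOWN,Number=0,Type=Flag,Description="Variant present in the supplied known-sites set">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  recs <- character(0)
  if (!is.null(classified) && nrow(classified)) {
    cl <- classified[order(classified$chrom, classified$pos,
                           classified$alt, classified$matrix_id), ]
    recs <- vapply(seq_len(nrow(cl)), function(i) {
      v <- cl[i, ]
      info <- c(paste0("MATRIX=", v$matrix_id),
                paste0("CLASS=", v$variant_class))
      if (length(v$observed_rows[[1]]))
        info <- c(info, paste0("ROWS=", paste(v$observed_rows[[1]], collapse = ",")))
      if (length(v$observed_cols[[1]]))
        info <- c(info, paste0("COLS=", paste(v$observed_cols[[1]], collapse = ",")))
      info <- c(info, paste0("NINSUF=", v$insufficient_pools))
      if (v$variant_class == "pinnable" && length(v$pinned_samples[[1]]))
        info <- c(info, paste0("PINNED=", paste(v$pinned_samples[[1]], collapse = ",")))
      if (v$variant_class == "multiple")
        info <- c(info, paste0("NCAND=", length(v$candidate_samples[[1]])))
      if (!is.null(v$known_site) && isTRUE(v$known_site))
        info <- c(info, "KNOWN")
      paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
            paste(info, collapse = ";"), sep = "\t")
    }, "")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a known-sites VCF into a set of variant keys
#'
#' Returns `chrom:pos:ref:alt` keys for membership annotation (e.g. a dbSNP
#' extract). Multi-allelic records are expanded into one key per ALT allele.
#'
#' @param path VCF file (plain text).
#' @return character vector of unique variant keys.
#' @export
read_known_sites <- function(path) {
  body <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  body <- body[nzchar(body)]
  if (!length(body)) return(character(0))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  keys <- unlist(lapply(seq_len(nrow(fx)), function(i) {
    alts <- strsplit(fx[i, "ALT"], ",", fixed = TRUE)[[1]]
    variant_key(fx[i, "CHROM"], fx[i, "POS"], fx[i, "REF"], alts)
  }))
  unique(keys)
}

#' Read back a VCF written by `write_vcf`
#'
#' Round-trip reader used for auditing pipeline output: recovers the class,
#' observed pools and pinned samples of every record.
#'
#' @param path VCF file written by [write_vcf()].
#' @return data.frame with columns chrom, pos, ref, alt, matrix_id,
#'   variant_class and list-columns observed_rows, observed_cols,
#'   pinned_samples.
#' @export
read_classified_vcf <- function(path) {
  body <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  body <- body[nzchar(body)]
  if (!length(body))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      matrix_id = character(0), variant_class = character(0)))
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  parse_ints <- function(x) if (is.na(x)) integer(0) else as.integer(strsplit(x, ",")[[1]])
  parse_chr <- function(x) if (is.na(x)) character(0) else strsplit(x, ",")[[1]]
  out <- data.frame(chrom = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4],
                    alt = f[, 5],
                    matrix_id = vapply(f[, 8], info_get, "", key = "MATRIX"),
                    variant_class = vapply(f[, 8], info_get, "", key = "CLASS"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$observed_rows <- lapply(f[, 8], function(s) parse_ints(info_get(s, "ROWS")))
  out$observed_cols <- lapply(f[, 8], function(s) parse_ints(info_get(s, "COLS")))
  out$pinned_samples <- lapply(f[, 8], function(s) parse_chr(info_get(s, "PINNED")))
  out
}
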