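#' Write a pool's counts as a pileup-dialect file
#'
#' Classic 6-column samtools pileup text: chrom, 1-based position, reference
#' base, depth, read bases, base qualities. Reference-matching reads are
#' written as `.`, mismatches as their base letter. Start-point structure is
#' encoded by prefixing the first read of each start-point group with `^I`
#' (a start marker plus a mapping-quality character), so the multiplicities
#' `d_i` are the gaps between successive `^` markers. All base qualities are
#' written as `I` (Phred 40), above the default q30 filter.
#'
#' @param counts a `pool_counts`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(counts, path) {
  stopifnot(inherits(counts, "pool_counts"))
  n <- nrow(counts$sites)
  lines <- character(n)
  for (i in seq_len(n)) {
    ref <- counts$sites$ref[i]
    bc <- counts$base_counts[i, ]
    # reference reads first (as '.'), then alternates in base order
    read_chars <- c(rep(".", bc[[ref]]),
                    unlist(lapply(setdiff(BASES, ref), function(b)
                      rep(b, bc[[b]]))))
    depth <- counts$depth[i]
    stopifnot(length(read_chars) == depth)
    sp <- if (is.null(counts$start_points)) NULL else counts$start_points[[i]]
    marks <- rep("", depth)
    if (!is.null(sp)) {  # NULL = start info absent: write no markers
      first_of_group <- cumsum(c(1L, sp[-length(sp)]))
      marks[first_of_group] <- "^I"
    }
    lines[i] <- paste(counts$sites$chrom[i], counts$sites$pos[i], ref, depth,
                      paste0(marks, read_chars, collapse = ""),
                      paste(rep("I", depth), collapse = ""),
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# Tokenise one pileup base string. Returns per-read base characters
# (upper-case; "." resolved to ref; "*" kept for deletion placeholders),
# a logical start-marker flag per read, and indel strings ("+SEQ"/"-SEQ")
# attached to the preceding read.
parse_base_string <- function(bases, ref) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(chars)
  read_base <- character(0)
  is_start <- logical(0)
  indels <- character(0)
  i <- 1L
  pending_start <- FALSE
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      pending_start <- TRUE
      i <- i + 2L  # skip mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      seq <- paste(chars[j:(j + len - 1L)], collapse = "")
      indels <- c(indels, paste0(ch, toupper(seq)))
      i <- j + len
    } else if (ch %in% c(".", ",")) {
      read_base <- c(read_base, ref)
      is_start <- c(is_start, pending_start)
      pending_start <- FALSE
      i <- i + 1L
    } else if (toupper(ch) %in% c(BASES, "N", "*", "#")) {
      b <- if (ch %in% c("*", "#")) "*" else toupper(ch)
      read_base <- c(read_base, b)
      is_start <- c(is_start, pending_start)
      pending_start <- FALSE
      i <- i + 1L
    } else {
      stop("unexpected pileup character '", ch, "'")
    }
  }
  list(read_base = read_base, is_start = is_start, indels = indels)
}

#' Read a pileup-dialect file into per-pool counts
#'
#' Parses classic 6-column samtools pileup text. Bases with quality below
#' `min_base_quality` are excluded from the counts (the quality-filtered
#' depth is what downstream fraction thresholds divide by). `^` read-start
#' markers, when present at the first read of the column, are interpreted as
#' start-point group boundaries and populate the `d_i` multiplicities; when
#' a column carries no markers the bias filter is reported as not evaluable
#' (`NULL` entry) and treated as passing downstream. Deletion placeholders
#' (`*`) consume a quality character but are never counted as alleles;
#' `+n`/`-n` indel strings are tallied separately per indel allele.
#'
#' @param path pileup file.
#' @param pool `pool_id` to attach to the result.
#' @param min_base_quality Phred threshold; default 30.
#' @return a `pool_counts` whose `depth` is the quality-filtered depth.
#' @export
read_pileup <- function(path, pool, min_base_quality = 30L) {
  lines <- readLines(path)
  n <- length(lines)
  chrom <- character(n); pos <- integer(n); ref <- character(n)
  depth <- integer(n)
  bc <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  sp <- vector("list", n)
  ind <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L)
      stop(sprintf("malformed pileup line %d: expected 6 fields, got %d",
                   i, length(f)))
    chrom[i] <- f[1]
    pos[i] <- as.integer(f[2])
    if (is.na(pos[i])) stop(sprintf("malformed pileup line %d: bad position", i))
    ref[i] <- toupper(f[3])
    raw_depth <- as.integer(f[4])
    tok <- tryCatch(parse_base_string(f[5], ref[i]),
                    error = function(e)
                      stop(sprintf("malformed pileup line %d: %s",
                                   i, conditionMessage(e))))
    quals <- utf8ToInt(f[6]) - 33L
    if (length(tok$read_base) != length(quals))
      stop(sprintf("malformed pileup line %d: %d read bases but %d qualities",
                   i, length(tok$read_base), length(quals)))
    if (!is.na(raw_depth) && length(tok$read_base) != raw_depth)
      stop(sprintf("malformed pileup line %d: depth field %d but %d reads",
                   i, raw_depth, length(tok$read_base)))
    pass <- quals >= min_base_quality & tok$read_base %in% BASES
    tab <- table(factor(tok$read_base[pass], levels = BASES))
    bc[i, ] <- as.integer(tab)
    depth[i] <- sum(bc[i, ])
    if (any(tok$is_start) && tok$is_start[1]) {
      starts <- which(tok$is_start)
      d_all <- diff(c(starts, length(tok$read_base) + 1L))
      # restrict multiplicities to quality-passing base reads
      grp <- rep(seq_along(starts), d_all)
      d_pass <- as.integer(table(factor(grp[pass], levels = seq_along(starts))))
      sp[[i]] <- d_pass[d_pass > 0L]
      if (!length(sp[[i]])) sp[[i]] <- NULL
    }
    if (length(tok$indels)) {
      t2 <- table(tok$indels)
      ind[[i]] <- stats::setNames(as.integer(t2), names(t2))
    }
  }
  pool_counts(pool, data.frame(chrom = chrom, pos = pos, ref = ref,
                               stringsAsFactors = FALSE),
              depth, bc, sp, ind)
}

#' Read pool files written by `write_fixture`
#'
#' Scans a directory for `<matrix>_<row|col><index>.pileup` files and parses
#' each into a `pool_counts` with its `pool_id` reconstructed from the file
#' name.
#'
#' @param dir directory of pileup files.
#' @param min_base_quality Phred threshold passed to `read_pileup()`.
#' @return list of `pool_counts`.
#' @export
read_fixture_dir <- function(dir, min_base_quality = 30L) {
  files <- list.files(dir, pattern = "\\.pileup$", full.names = TRUE)
  if (!length(files)) stop("no .pileup files under ", dir)
  lapply(files, function(fn) {
    base <- sub("\\.pileup$", "", basename(fn))
    m <- regmatches(base, regexec("^(.+)_(row|col)([0-9]+)$", base))[[1]]
    if (length(m) != 4L) stop("unrecognised pool file name: ", basename(fn))
    p <- pool_id(m[2], if (m[3] == "row") "row" else "column",
                 as.integer(m[4]))
    read_pileup(fn, p, min_base_quality)
  })
}
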