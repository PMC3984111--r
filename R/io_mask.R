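#' Exclusion masks from BED intervals
#'
#' Positions inside a mask (e.g. repeat-masked or self-chained regions) are
#' skipped entirely by the caller: no call of any state is emitted there.
#' BED coordinates are 0-based half-open; pileup/VCF positions are 1-based.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). Intervals may overlap.
#' @return a `GRanges` mask (1-based closed internally).
#' @export
mask_set <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stop("mask intervals must satisfy start < end")
  GenomicRanges::GRanges(
    seqnames = as.character(intervals$chrom),
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
}

#' @rdname mask_set
#' @param path BED file (chrom, start, end in the first three columns; no
#'   header).
#' @export
read_mask <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(mask_set(data.frame(chrom = character(0), start = integer(0),
                               end = integer(0))))
  df <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                          stringsAsFactors = FALSE)
  mask_set(data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]]))
}

#' Mask membership for 1-based positions
#'
#' @param mask a `GRanges` mask from [mask_set()] / [read_mask()], or `NULL`
#'   (nothing masked).
#' @param chrom,pos equal-length vectors of sequence names and 1-based
#'   positions.
#' @return logical vector: `TRUE` where the position falls inside the mask.
#' @export
in_mask <- function(mask, chrom, pos) {
  if (is.null(mask) || length(mask) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(as.character(chrom),
                              IRanges::IRanges(pos, pos))
  suppressWarnings(GenomicRanges::countOverlaps(q, mask) > 0L)
}
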