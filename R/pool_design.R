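#' Construct a two-dimensional pooling design
#'
#' Arranges samples into one or more row-by-column matrices. Each matrix of
#' `n_rows * n_cols` samples yields `n_rows + n_cols` pools: every grid row is
#' one pool and every grid column is another, so each sample is sequenced in
#' exactly one row pool and exactly one column pool. Samples are filled
#' row-major into successive matrices; any bijection would do, row-major is
#' fixed for reproducibility.
#'
#' @param samples character vector of distinct sample identifiers, of length
#'   `n_rows * n_cols * n_matrices`.
#' @param n_rows,n_cols grid dimensions (the canonical design is 12 x 12).
#' @param n_matrices number of matrices.
#' @param matrix_ids optional character vector of matrix identifiers; defaults
#'   to `"M1"`, `"M2"`, ...
#' @return a list of `matrix_layout` objects, one per matrix.
#' @examples
#' design <- build_design(sprintf("S%03d", 1:576), 12, 12, 4)
#' length(design)                    # 4 matrices
#' sum(vapply(design, n_pools, 0L))  # 96 pools
#' @export
build_design <- function(samples, n_rows = 12L, n_cols = 12L, n_matrices = 1L,
                         matrix_ids = NULL) {
  samples <- as.character(samples)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  n_matrices <- as.integer(n_matrices)
  if (n_rows < 1L || n_cols < 1L || n_matrices < 1L)
    stop("n_rows, n_cols and n_matrices must all be >= 1")
  expected <- n_rows * n_cols * n_matrices
  if (length(samples) != expected)
    stop(sprintf("expected %d samples (%d x %d x %d matrices), got %d",
                 expected, n_rows, n_cols, n_matrices, length(samples)))
  if (anyDuplicated(samples))
    stop("sample identifiers must be distinct; duplicated: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (is.null(matrix_ids)) matrix_ids <- paste0("M", seq_len(n_matrices))
  if (length(matrix_ids) != n_matrices || anyDuplicated(matrix_ids))
    stop("matrix_ids must be ", n_matrices, " distinct identifiers")
  per_matrix <- n_rows * n_cols
  lapply(seq_len(n_matrices), function(m) {
    block <- samples[((m - 1L) * per_matrix + 1L):(m * per_matrix)]
    grid <- matrix(block, nrow = n_rows, ncol = n_cols, byrow = TRUE)
    matrix_layout(matrix_ids[m], grid)
  })
}

#' Create a matrix layout from an explicit grid
#'
#' @param matrix_id matrix identifier.
#' @param grid character matrix of sample identifiers; `grid[r, c]` is the
#'   sample at row `r`, column `c` (1-based).
#' @return a `matrix_layout` object.
#' @export
matrix_layout <- function(matrix_id, grid) {
  if (!is.matrix(grid) || !is.character(grid))
    stop("grid must be a character matrix of sample identifiers")
  if (anyNA(grid) || anyDuplicated(as.vector(grid)))
    stop("grid cells must hold distinct, non-missing sample identifiers")
  structure(
    list(matrix_id = as.character(matrix_id),
         n_rows = nrow(grid), n_cols = ncol(grid), grid = grid),
    class = "matrix_layout")
}

#' @export
print.matrix_layout <- function(x, ...) {
  cat(sprintf("<matrix_layout> %s: %d x %d grid, %d samples, %d pools\n",
              x$matrix_id, x$n_rows, x$n_cols,
              x$n_rows * x$n_cols, x$n_rows + x$n_cols))
  invisible(x)
}

#' Identify a single pool within a matrix
#'
#' @param matrix_id matrix the pool belongs to.
#' @param axis `"row"` or `"column"`.
#' @param index 1-based row or column index.
#' @return a `pool_id` object.
#' @export
pool_id <- function(matrix_id, axis = c("row", "column"), index) {
  axis <- match.arg(axis)
  index <- as.integer(index)
  if (is.na(index) || index < 1L) stop("pool index must be a positive integer")
  structure(list(matrix_id = as.character(matrix_id), axis = axis,
                 index = index),
            class = "pool_id")
}

#' @export
print.pool_id <- function(x, ...) {
  cat(sprintf("<pool_id> %s\n", format_pool_id(x)))
  invisible(x)
}

#' @rdname pool_id
#' @param x a `pool_id`.
#' @export
format_pool_id <- function(x) sprintf("%s:%s:%d", x$matrix_id, x$axis, x$index)

#' All pools of a layout
#'
#' @param layout a `matrix_layout`.
#' @return list of `pool_id` objects: the row pools (in row order) followed by
#'   the column pools.
#' @export
pools <- function(layout) {
  stopifnot(inherits(layout, "matrix_layout"))
  c(lapply(seq_len(layout$n_rows),
           function(r) pool_id(layout$matrix_id, "row", r)),
    lapply(seq_len(layout$n_cols),
           function(c) pool_id(layout$matrix_id, "column", c)))
}

#' Number of pools in a layout
#' @param layout a `matrix_layout`.
#' @export
n_pools <- function(layout) layout$n_rows + layout$n_cols

check_pool <- function(layout, pool) {
  if (!inherits(pool, "pool_id")) stop("pool must be a pool_id")
  if (pool$matrix_id != layout$matrix_id)
    stop(sprintf("pool %s does not belong to matrix %s",
                 format_pool_id(pool), layout$matrix_id))
  lim <- if (pool$axis == "row") layout$n_rows else layout$n_cols
  if (pool$index > lim)
    stop(sprintf("pool index %d out of range for axis %s (max %d)",
                 pool$index, pool$axis, lim))
  invisible(pool)
}

#' Samples contained in one pool
#'
#' A row pool holds the full grid row (`n_cols` samples); a column pool holds
#' the full grid column (`n_rows` samples).
#'
#' @param layout a `matrix_layout`.
#' @param pool a `pool_id` belonging to `layout`.
#' @return character vector of sample identifiers.
#' @export
samples_in_pool <- function(layout, pool) {
  stopifnot(inherits(layout, "matrix_layout"))
  check_pool(layout, pool)
  if (pool$axis == "row") layout$grid[pool$index, ] else layout$grid[, pool$index]
}

#' Samples at the intersection of rows and columns
#'
#' Deconvolution primitive: the samples compatible with a variant observed in
#' the given row pools and column pools are exactly those at the grid
#' positions `(r, c)` with `r` in `row_indices` and `c` in `col_indices`.
#'
#' @param layout a `matrix_layout`.
#' @param row_indices,col_indices integer vectors of 1-based indices (either
#'   may be empty, giving an empty intersection).
#' @return character vector of `length(row_indices) * length(col_indices)`
#'   sample identifiers.
#' @export
intersect_samples <- function(layout, row_indices, col_indices) {
  stopifnot(inherits(layout, "matrix_layout"))
  row_indices <- as.integer(row_indices)
  col_indices <- as.integer(col_indices)
  if (length(row_indices) && (min(row_indices) < 1L || max(row_indices) > layout$n_rows))
    stop("row index out of range")
  if (length(col_indices) && (min(col_indices) < 1L || max(col_indices) > layout$n_cols))
    stop("column index out of range")
  if (!length(row_indices) || !length(col_indices)) return(character(0))
  as.vector(t(layout$grid[row_indices, col_indices, drop = FALSE]))
}

#' All samples of a layout (row-major order)
#' @param layout a `matrix_layout`.
#' @export
layout_samples <- function(layout) as.vector(t(layout$grid))

#' Write / read a sample manifest
#'
#' The manifest is a TSV with header `sample_id  matrix_id  row  col`, one
#' line per sample. Writing then reading reproduces the layouts exactly.
#'
#' @param layouts list of `matrix_layout` objects.
#' @param path file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   a list of `matrix_layout` objects.
#' @export
write_manifest <- function(layouts, path) {
  if (inherits(layouts, "matrix_layout")) layouts <- list(layouts)
  rows <- lapply(layouts, function(l) {
    idx <- expand.grid(row = seq_len(l$n_rows), col = seq_len(l$n_cols))
    idx <- idx[order(idx$row, idx$col), ]
    data.frame(sample_id = l$grid[cbind(idx$row, idx$col)],
               matrix_id = l$matrix_id, row = idx$row, col = idx$col,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "integer"))
  need <- c("sample_id", "matrix_id", "row", "col")
  if (!identical(names(df), need))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, factor(df$matrix_id, levels = unique(df$matrix_id))),
         function(block) {
           nr <- max(block$row); nc <- max(block$col)
           if (nrow(block) != nr * nc)
             stop("incomplete grid for matrix ", block$matrix_id[1])
           grid <- matrix(NA_character_, nr, nc)
           grid[cbind(block$row, block$col)] <- block$sample_id
           matrix_layout(block$matrix_id[1], grid)
         })
}
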