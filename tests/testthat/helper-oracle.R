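# Independent brute-force interpreter of the classification rules, written
# as plain nested conditionals over pool assignments. Used to cross-check
# classify_variant() on exhaustively enumerated small matrices.
#
# states: character vector over the pools of a matrix, rows first then
# columns. Accepts the five call states plus the reduced labels "observed"
# (a confident observation) and "absent" (a confident reference call).
oracle_classify <- function(states, n_rows, n_cols, max_insufficient = 2L) {
  observed <- states %in% c("observed", "confident_variant",
                            "potential_variant")
  confident <- any(states %in% c("observed", "confident_variant"))
  if (!confident) return("discarded")
  if (sum(states == "insufficient") > max_insufficient)
    return("missing_coverage")
  r <- sum(observed[seq_len(n_rows)])
  k <- sum(observed[n_rows + seq_len(n_cols)])
  if (r == 0 && k == 0) return("discarded")
  if (r == 0 || k == 0) return("singleton")
  if (r == 1 || k == 1) return("pinnable")
  "multiple"
}

# Convert a states vector (rows first, then columns) into the named vector
# classify_variant() expects.
named_states <- function(states, n_rows, n_cols) {
  stats::setNames(states, c(paste0("row_", seq_len(n_rows)),
                            paste0("column_", seq_len(n_cols))))
}

classify_class_of <- function(states, layout, max_insufficient = 2L) {
  cv <- classify_variant(named_states(states, layout$n_rows, layout$n_cols),
                         layout, max_insufficient)
  if (is.null(cv)) "discarded" else cv$variant_class
}
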