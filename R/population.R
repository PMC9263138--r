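#' Summarize silencing outcomes across a transgenic population
#'
#' Converts per-construct line counts in the three silencing categories
#' (strong, weak, almost none) into percentages of the population total,
#' reported to one decimal. Accepts a data frame with one row per construct,
#' so summaries chain directly from count tables.
#'
#' @param counts A data frame with columns `strong`, `weak`, `none`
#'   (non-negative integer line counts) and optionally a construct identifier
#'   column, which is carried through.
#' @return A tibble with the input counts plus `total`, `pct_strong`,
#'   `pct_weak`, `pct_none`.
#' @examples
#' summarize_population(data.frame(
#'   construct = "hp[WT]", strong = 35, weak = 9, none = 15
#' ))
#' @export
summarize_population <- function(counts) {
  counts <- tibble::as_tibble(counts)
  needed <- c("strong", "weak", "none")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols) > 0) {
    abort_parameter(sprintf(
      "`counts` must have columns %s (missing: %s).",
      paste(needed, collapse = ", "), paste(missing_cols, collapse = ", ")
    ))
  }
  vals <- as.matrix(counts[needed])
  if (any(is.na(vals)) || any(vals < 0) || any(vals != floor(vals))) {
    abort_parameter("Category counts must be non-negative integers.")
  }
  total <- rowSums(vals)
  if (any(total == 0)) {
    hp_abort(
      "Population total is zero for at least one row; percentages undefined.",
      class = "hairpinr_empty_population_error"
    )
  }
  dplyr::mutate(
    counts,
    total = as.integer(total),
    pct_strong = round(100 * .data$strong / total, 1),
    pct_weak = round(100 * .data$weak / total, 1),
    pct_none = round(100 * .data$none / total, 1)
  )
}
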