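# Methylation read-outs: in-silico bisulfite conversion, Sanger-trace
# peak-height methylation calling with CG/CHG/CHH context assignment, and
# McrBC digestion-ratio estimation.

#' In-silico bisulfite conversion
#'
#' Bisulfite treatment converts unmethylated cytosine to uracil (read as
#' thymine after PCR) and leaves methylated cytosine intact. This function
#' applies that conversion to one strand of a DNA sequence.
#'
#' @param sequence DNA string (the top strand as written).
#' @param methylated_positions Integer vector of 1-based positions, on the
#'   analyzed strand, that are methylated. Must all be C on that strand.
#' @param strand `"top"` (analyze the sequence as given) or `"bottom"`
#'   (reverse-complement first, convert, and report in bottom-strand 5'->3'
#'   orientation).
#' @return The converted sequence (character scalar).
#' @examples
#' bisulfite_convert("ACGCT") # "ATGTT"
#' bisulfite_convert("ACGCT", methylated_positions = c(2, 4)) # "ACGCT"
#' @export
bisulfite_convert <- function(sequence, methylated_positions = integer(),
                              strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  sequence <- chartr("Uu", "Tt", toupper(sequence))
  check_dna_alphabet(sequence)
  if (strand == "bottom") sequence <- dna_revcomp(sequence)
  chars <- seq_chars(sequence)
  mpos <- as.integer(methylated_positions)
  if (length(mpos) > 0) {
    bad <- mpos < 1L | mpos > length(chars) | chars[pmax(pmin(mpos, length(chars)), 1L)] != "C"
    if (any(bad)) {
      hp_abort(
        sprintf("Methylated position(s) %s are not cytosines on the analyzed strand.",
                paste(mpos[bad], collapse = ", ")),
        class = "hairpinr_position_error"
      )
    }
  }
  convert <- chars == "C" & !(seq_along(chars) %in% mpos)
  chars[convert] <- "T"
  chars_to_seq(chars)
}

#' Cytosine context classification (CG / CHG / CHH)
#'
#' Plant cytosine methylation contexts are read from the two bases downstream
#' on the same strand: `CG` if the next base is G, otherwise `CHG` if the base
#' after that is G, otherwise `CHH` (H = A, C or T). Cytosines too close to
#' the 3' end for a full context are classed `CHH` (terminal convention).
#'
#' @param sequence DNA string.
#' @param positions 1-based positions to classify (must be C); default all C
#'   positions in `sequence`.
#' @return A tibble with `position` and `context`.
#' @examples
#' classify_context("CGA")$context # "CG"
#' @export
classify_context <- function(sequence, positions = NULL) {
  sequence <- chartr("Uu", "Tt", toupper(sequence))
  check_dna_alphabet(sequence)
  chars <- seq_chars(sequence)
  if (is.null(positions)) positions <- which(chars == "C")
  positions <- as.integer(positions)
  if (any(chars[positions] != "C")) {
    hp_abort("All classified positions must be cytosines.",
             class = "hairpinr_position_error")
  }
  L <- length(chars)
  nxt <- ifelse(positions + 1L <= L, chars[positions + 1L], NA)
  nxt2 <- ifelse(positions + 2L <= L, chars[positions + 2L], NA)
  context <- dplyr::case_when(
    !is.na(nxt) & nxt == "G" ~ "CG",
    !is.na(nxt2) & nxt2 == "G" ~ "CHG",
    .default = "CHH"
  )
  tibble::tibble(position = positions, context = context)
}

#' Call per-cytosine methylation from Sanger trace peak heights
#'
#' In a bisulfite-PCR Sanger trace, an unmethylated cytosine reads as T and a
#' methylated one as C; the relative C vs T peak height at each reference-C
#' position estimates the methylated fraction:
#' `fraction = height_C / (height_C + height_T)`. Positions whose summed
#' height falls below a noise floor are reported as missing (`NA`), not zero.
#'
#' @param trace A data frame with columns `position` (1-based on the analyzed
#'   strand), `ref_base`, `height_C`, `height_T` (see [read_trace_table()]).
#'   Only reference-C rows are used.
#' @param reference Optional reference DNA string; when supplied, its length
#'   must match the trace span and its sequence is used for context
#'   classification. Otherwise contexts come from the `ref_base` column.
#' @param noise_floor Fraction of the per-trace median total height below
#'   which a position is reported missing. Default 0.1.
#' @return A `methylation_profile` tibble: `position`, `context`,
#'   `height_C`, `height_T`, `fraction_methylated`.
#' @export
call_methylation <- function(trace, reference = NULL, noise_floor = 0.1) {
  trace <- tibble::as_tibble(trace)
  needed <- c("position", "ref_base", "height_C", "height_T")
  if (!all(needed %in% names(trace))) {
    abort_parameter(sprintf("`trace` must have columns %s.",
                            paste(needed, collapse = ", ")))
  }
  if (nrow(trace) == 0) {
    hp_abort("Trace table is empty.", class = "hairpinr_empty_trace_error")
  }
  if (any(trace$height_C < 0 | trace$height_T < 0, na.rm = TRUE)) {
    abort_parameter("Peak heights must be non-negative.")
  }
  trace <- dplyr::arrange(trace, .data$position)
  ref_seq <- chars_to_seq(toupper(trace$ref_base))
  if (!is.null(reference)) {
    reference <- chartr("Uu", "Tt", toupper(reference))
    if (nchar(reference) != nrow(trace)) {
      hp_abort(
        sprintf("Reference length %d does not match trace rows %d.",
                nchar(reference), nrow(trace)),
        class = "hairpinr_alignment_length_error"
      )
    }
    ref_seq <- reference
  }
  c_rows <- which(seq_chars(ref_seq) == "C")
  ctx <- classify_context(ref_seq, positions = c_rows)
  sub <- trace[c_rows, ]
  total <- sub$height_C + sub$height_T
  floor_abs <- noise_floor * stats::median(total)
  frac <- ifelse(total > 0 & total >= floor_abs,
                 sub$height_C / total, NA_real_)
  out <- tibble::tibble(
    position = sub$position,
    context = ctx$context,
    height_C = sub$height_C,
    height_T = sub$height_T,
    fraction_methylated = frac
  )
  class(out) <- c("methylation_profile", class(out))
  out
}

#' Per-context methylation summary
#'
#' Mean methylated fraction in each of the CG, CHG and CHH contexts,
#' excluding positions reported missing by the noise floor.
#'
#' @param profile A `methylation_profile` from [call_methylation()].
#' @return A tibble with `context`, `n_sites`, `n_called`, `mean_fraction`.
#' @export
summarize_contexts <- function(profile) {
  profile |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_called = sum(!is.na(.data$fraction_methylated)),
      mean_fraction = mean(.data$fraction_methylated, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @export
glance.methylation_profile <- function(x, ...) {
  tibble::tibble(
    n_cytosines = nrow(x),
    n_called = sum(!is.na(x$fraction_methylated)),
    mean_fraction = mean(x$fraction_methylated, na.rm = TRUE)
  )
}

#' Estimate methylation from McrBC digestion
#'
#' McrBC cleaves DNA containing methylated cytosines, so template surviving
#' digestion is the unmethylated fraction. Comparing amplification of
#' digested vs undigested aliquots estimates the methylated fraction. In
#' `qpcr` mode the inputs are cycle thresholds and the retained fraction is
#' `efficiency^(ct_undigested - ct_digested)`; in `band` mode the inputs are
#' band intensities and the retained fraction is their ratio.
#'
#' @param digested,undigested Ct values (`qpcr`) or band intensities
#'   (`band`); vectorized.
#' @param mode `"qpcr"` or `"band"`.
#' @param efficiency Per-cycle amplification factor for `qpcr` mode
#'   (default 2, i.e. 100% efficiency).
#' @return A tibble with `retained_fraction` and `methylated_fraction`
#'   (clamped to `[0, 1]`).
#' @examples
#' mcrbc_fraction(50, 100, mode = "band")$methylated_fraction # 0.5
#' @export
mcrbc_fraction <- function(digested, undigested, mode = c("qpcr", "band"),
                           efficiency = 2) {
  mode <- match.arg(mode)
  if (any(!is.finite(digested)) || any(!is.finite(undigested))) {
    abort_parameter("Inputs must be finite.")
  }
  retained <- if (mode == "qpcr") {
    efficiency^(undigested - digested)
  } else {
    if (any(undigested == 0)) {
      hp_abort("Undigested intensity is zero; ratio undefined.",
               class = "hairpinr_division_error")
    }
    digested / undigested
  }
  tibble::tibble(
    mode = mode,
    retained_fraction = retained,
    methylated_fraction = pmin(pmax(1 - retained, 0), 1)
  )
}

#' Read a trace peak-height table
#'
#' Accepts the package's documented dialect (columns `position`, `ref_base`,
#' `height_C`, `height_T`; comma- or tab-delimited, sniffed from the header
#' line) as well as exported four-channel tables with per-base height columns
#' `A`, `C`, `G`, `T` (as produced by trace-viewer "export trace values"
#' features), from which `height_C`/`height_T` are taken.
#'
#' @param path Path to the delimited file.
#' @return A tibble with columns `position`, `ref_base`, `height_C`,
#'   `height_T`.
#' @export
read_trace_table <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (all(c("A", "C", "G", "T") %in% names(tbl)) &&
      !all(c("height_C", "height_T") %in% names(tbl))) {
    tbl <- dplyr::mutate(tbl, height_C = .data$C, height_T = .data$T)
  }
  if (!"position" %in% names(tbl)) {
    tbl <- dplyr::mutate(tbl, position = dplyr::row_number(), .before = 1)
  }
  needed <- c("position", "ref_base", "height_C", "height_T")
  if (!all(needed %in% names(tbl))) {
    abort_parameter(sprintf(
      "Trace file must provide columns %s (or A/C/G/T height columns).",
      paste(needed, collapse = ", ")
    ))
  }
  dplyr::select(tbl, dplyr::all_of(needed))
}
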