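# Small-RNA read classification against a hairpin reference panel.
#
# Mapping is exact substring matching (the reference arms are 200-450 nt, so
# exhaustive exact scanning is equivalent to no-mismatch short-read mapping).
# Sense reads are sub-classified by whether they match the modified sense arm
# only (primary: Dicer product of the hairpin transcript itself), the
# wild-type sense sequence only (secondary: RDR-copied target RNA), or both
# (ambiguous: the read spans no substituted position).

#' Build the reference panel for read classification
#'
#' @param design A `hairpin_design`.
#' @param loop Loop (intron spacer) DNA string, or `""` for none.
#' @return A `reference_panel`: list with `sense_modified`, `sense_wt`,
#'   `antisense`, `loop`.
#' @export
reference_panel <- function(design, loop = "") {
  stopifnot(inherits(design, "hairpin_design"))
  loop <- toupper(chartr("Uu", "Tt", loop))
  if (nchar(loop) > 0) check_dna_alphabet(loop)
  structure(
    list(
      sense_modified = design$sense_arm,
      sense_wt = design$target$sequence,
      antisense = design$antisense_arm,
      loop = loop
    ),
    class = "reference_panel"
  )
}

normalize_reads <- function(reads) {
  reads <- tibble::as_tibble(reads)
  if (!"sequence" %in% names(reads)) {
    abort_parameter("`reads` must have a `sequence` column.")
  }
  if (!"id" %in% names(reads)) {
    reads <- dplyr::mutate(reads,
                           id = paste0("read", dplyr::row_number()),
                           .before = 1)
  }
  if (!"count" %in% names(reads)) reads$count <- 1L
  reads$count[is.na(reads$count)] <- 1L
  if (any(reads$count < 1)) abort_parameter("Read counts must be >= 1.")
  dplyr::mutate(
    reads,
    sequence = toupper(chartr("Uu", "Tt", .data$sequence)),
    length = nchar(.data$sequence)
  )
}

#' Length-filter a small-RNA read set
#'
#' Retains reads of 18-35 nt inclusive (sequences shorter than 18 nt or
#' longer than 35 nt are filtered out) and records how many were removed.
#'
#' @param reads A data frame with columns `sequence` and optionally `id`,
#'   `count`.
#' @param min_len,max_len Inclusive length bounds (default 18 and 35 nt).
#' @return The filtered tibble, with attributes `n_input`, `n_removed`
#'   (summed read counts) and `total_input` (input count total, used as the
#'   default normalization denominator downstream).
#' @export
length_filter <- function(reads, min_len = 18L, max_len = 35L) {
  reads <- normalize_reads(reads)
  keep <- reads$length >= min_len & reads$length <= max_len
  out <- reads[keep, ]
  attr(out, "n_input") <- sum(reads$count)
  attr(out, "n_removed") <- sum(reads$count[!keep])
  attr(out, "total_input") <- sum(reads$count)
  out
}

classify_one <- function(seq, panel) {
  in_mod <- grepl(seq, panel$sense_modified, fixed = TRUE)
  in_wt <- grepl(seq, panel$sense_wt, fixed = TRUE)
  in_as <- grepl(seq, panel$antisense, fixed = TRUE)
  in_loop <- nchar(panel$loop) > 0 && grepl(seq, panel$loop, fixed = TRUE)
  # stem-first, then sense-first priority
  if (in_mod || in_wt) {
    if (in_mod && in_wt) "ambiguous_sense"
    else if (in_mod) "primary_sense"
    else "secondary_sense"
  } else if (in_as) {
    "antisense"
  } else if (in_loop) {
    "loop"
  } else {
    "unmapped"
  }
}

#' Classify small-RNA reads against a hairpin reference panel
#'
#' Each read is assigned exactly one class by exact substring matching:
#' `primary_sense` (matches the modified sense arm only), `secondary_sense`
#' (matches the wild-type sense sequence only), `ambiguous_sense` (matches
#' both, i.e. spans no substituted position), `antisense`, `loop`, or
#' `unmapped`. Matching is stem-first and sense-first: a read matching both a
#' sense reference and the antisense arm is classed sense and flagged in
#' `both_strands`.
#'
#' @param reads A data frame of reads (see [length_filter()]); reads should
#'   already be length-filtered.
#' @param panel A `reference_panel`.
#' @return A `read_classification` tibble: the reads plus `class` and
#'   `both_strands` columns. The `total_input` attribute of `reads` (if any)
#'   is carried through.
#' @export
classify_reads <- function(reads, panel) {
  stopifnot(inherits(panel, "reference_panel"))
  reads <- normalize_reads(reads)
  uniq <- unique(reads$sequence)
  cls <- vapply(uniq, classify_one, character(1), panel = panel)
  both <- vapply(uniq, function(s) {
    (grepl(s, panel$sense_modified, fixed = TRUE) ||
       grepl(s, panel$sense_wt, fixed = TRUE)) &&
      grepl(s, panel$antisense, fixed = TRUE)
  }, logical(1))
  out <- dplyr::mutate(
    reads,
    class = unname(cls[match(.data$sequence, uniq)]),
    both_strands = unname(both[match(.data$sequence, uniq)])
  )
  attr(out, "total_input") <- attr(reads, "total_input")
  class(out) <- c("read_classification", class(out))
  out
}

#' Size profile of classified stem siRNAs
#'
#' Counts reads by length (18-35 nt) and strand. Sense includes
#' `primary_sense`, `secondary_sense` and `ambiguous_sense`; antisense is the
#' `antisense` class; `loop` and `unmapped` reads are excluded.
#'
#' @param classified A `read_classification` tibble.
#' @param total_input Denominator for RPM normalization; defaults to the
#'   `total_input` attribute carried from [length_filter()], falling back to
#'   the summed counts.
#' @return A `size_profile` tibble: `length`, `strand`, `count`, `rpm`, with
#'   all 18-35 x {sense, antisense} cells present (zero-filled).
#' @export
size_profile <- function(classified, total_input = NULL) {
  total_input <- total_input %||% attr(classified, "total_input") %||%
    sum(classified$count)
  strand_of <- c(
    primary_sense = "sense", secondary_sense = "sense",
    ambiguous_sense = "sense", antisense = "antisense"
  )
  kept <- classified |>
    dplyr::filter(.data$class %in% names(strand_of)) |>
    dplyr::mutate(strand = unname(strand_of[.data$class]))
  grid <- tidyr::expand_grid(length = 18:35,
                             strand = c("sense", "antisense"))
  prof <- kept |>
    dplyr::group_by(.data$length, .data$strand) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  out <- grid |>
    dplyr::left_join(prof, by = c("length", "strand")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      rpm = normalize_rpm(.data$count, total_input)
    )
  class(out) <- c("size_profile", class(out))
  attr(out, "total_input") <- total_input
  out
}

#' Reads-per-million normalization
#'
#' @param counts Non-negative read counts.
#' @param total_input Total input reads (the denominator).
#' @return `1e6 * counts / total_input`.
#' @export
normalize_rpm <- function(counts, total_input) {
  if (length(total_input) != 1 || total_input == 0) {
    hp_abort("`total_input` must be a single non-zero total.",
             class = "hairpinr_division_error")
  }
  1e6 * counts / total_input
}

#' Fraction of sense siRNAs that are secondary
#'
#' Among unambiguous sense reads, the fraction matching the wild-type sense
#' sequence only (RDR-synthesized secondary siRNAs) rather than the modified
#' hairpin sense arm (primary siRNAs). Ambiguous reads (substitution-free
#' windows) are excluded from numerator and denominator and reported
#' separately.
#'
#' @param classified A `read_classification` tibble.
#' @return A one-row tibble: `n_primary`, `n_secondary`, `n_ambiguous`,
#'   `secondary_fraction`.
#' @export
secondary_fraction <- function(classified) {
  n_p <- sum(classified$count[classified$class == "primary_sense"])
  n_s <- sum(classified$count[classified$class == "secondary_sense"])
  n_a <- sum(classified$count[classified$class == "ambiguous_sense"])
  if (n_p + n_s == 0) {
    hp_abort("No unambiguous sense reads; secondary fraction undefined.",
             class = "hairpinr_no_sense_reads_error")
  }
  tibble::tibble(
    n_primary = n_p, n_secondary = n_s, n_ambiguous = n_a,
    secondary_fraction = n_s / (n_p + n_s)
  )
}

#' Per-class count summary
#'
#' @param classified A `read_classification` tibble.
#' @param total_input RPM denominator (see [size_profile()]).
#' @return A tibble with `class`, `count`, `rpm` for every class level.
#' @export
class_summary <- function(classified, total_input = NULL) {
  total_input <- total_input %||% attr(classified, "total_input") %||%
    sum(classified$count)
  levels <- c("primary_sense", "secondary_sense", "ambiguous_sense",
              "antisense", "loop", "unmapped")
  tibble::tibble(class = levels) |>
    dplyr::left_join(
      classified |>
        dplyr::group_by(.data$class) |>
        dplyr::summarise(count = sum(.data$count), .groups = "drop"),
      by = "class"
    ) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      rpm = normalize_rpm(.data$count, total_input)
    )
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Quality strings are ignored. Collapsed-read FASTA headers of the form
#' `id_count` (e.g. `read7_42`) set the `count` column; otherwise each record
#' counts once.
#'
#' @param path Path to a FASTA or FASTQ file (format sniffed from the first
#'   character).
#' @return A tibble with `id`, `sequence`, `count`.
#' @export
read_sirna_reads <- function(path) {
  first <- readLines(path, n = 1)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  counts <- rep(1L, length(ids))
  collapsed <- grepl("^.+_\\d+$", ids)
  counts[collapsed] <- as.integer(sub("^.+_(\\d+)$", "\\1", ids[collapsed]))
  tibble::tibble(id = ids, sequence = unname(as.character(set)),
                 count = counts)
}
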