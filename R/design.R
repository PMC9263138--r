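# Hairpin sense-arm design schemes.
#
# All schemes keep the antisense arm as the exact reverse complement of the
# wild-type target, so antisense siRNAs remain perfectly complementary to the
# target mRNA. Only the sense arm is modified:
#   * wt     — unmodified (perfect inverted repeat)
#   * gu     — every C -> T, turning C:G stem pairs into G:U wobbles
#   * m1in4  — 1 complement substitution per 4-nt window
#   * m2in10 — 2 consecutive complement substitutions per 10-nt window
# Complement substitution follows C->G, G->C, A->T, T->A (a self-pairing
# mismatch in the stem at that position).

COMPLEMENT_MAP <- c(A = "T", C = "G", G = "C", T = "A")

new_hairpin_design <- function(scheme, target, sense_arm, substitutions) {
  antisense <- dna_revcomp(target$sequence)
  metrics <- design_metrics_tbl(scheme, target$length, substitutions)
  structure(
    list(
      scheme = scheme,
      target = target,
      sense_arm = sense_arm,
      antisense_arm = antisense,
      substitutions = substitutions,
      metrics = metrics
    ),
    class = "hairpin_design"
  )
}

empty_substitutions <- function() {
  tibble::tibble(
    position = integer(), from_base = character(),
    to_base = character(), kind = character()
  )
}

design_metrics_tbl <- function(scheme, length, substitutions) {
  n_sub <- nrow(substitutions)
  n_gu <- sum(substitutions$kind == "GU_WOBBLE")
  n_mm <- sum(substitutions$kind == "SELF_MISMATCH")
  tibble::tibble(
    scheme = scheme,
    stem_length = length,
    n_substitutions = n_sub,
    pct_substituted = round(100 * n_sub / length, 1),
    n_gu_pairs = n_gu,
    pct_gu_pairs = round(100 * n_gu / length, 1),
    n_mismatch_pairs = n_mm,
    pct_mismatch = round(100 * n_mm / length, 1)
  )
}

#' Design a hairpin construct from a target region
#'
#' Dispatches to the individual scheme constructors. Every design carries the
#' unmodified reverse complement of the target as its antisense arm; the
#' scheme decides how the sense arm is modified.
#'
#' @param target A `target_region` from [validate_target()].
#' @param scheme One of `"wt"`, `"gu"`, `"m1in4"`, `"m2in10"`, `"custom"`.
#' @param window,block,offset Mismatch-pattern parameters, used by the
#'   mismatch schemes and `"custom"`; see [design_mismatch()].
#' @return A `hairpin_design` object.
#' @seealso [design_gu()], [design_mismatch()], [design_wt()]
#' @export
design_hairpin <- function(target,
                           scheme = c("wt", "gu", "m1in4", "m2in10", "custom"),
                           window = NULL, block = NULL, offset = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
    wt = design_wt(target),
    gu = design_gu(target),
    m1in4 = design_mismatch(target, window = 4L, block = 1L,
                            offset = offset %||% 3L, scheme = "m1in4"),
    m2in10 = design_mismatch(target, window = 10L, block = 2L,
                             offset = offset %||% 8L, scheme = "m2in10"),
    custom = design_mismatch(target, window = window, block = block,
                             offset = offset, scheme = "custom")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Wild-type (perfect inverted repeat) design
#'
#' @inheritParams design_hairpin
#' @return A `hairpin_design` with an unmodified sense arm.
#' @export
design_wt <- function(target) {
  stopifnot(inherits(target, "target_region"))
  new_hairpin_design("wt", target, target$sequence, empty_substitutions())
}

#' G:U wobble design: convert every sense-arm cytosine to thymine
#'
#' Replaces all C in the sense arm with T. In the transcribed hairpin each
#' former C:G stem pair becomes a U:G (G:U) wobble, which still base-pairs in
#' RNA, while the inverted-repeat DNA structure is disrupted. A C-free target
#' yields a design identical to wild type.
#'
#' @inheritParams design_hairpin
#' @return A `hairpin_design` whose substitutions are all `GU_WOBBLE`.
#' @examples
#' tr <- validate_target("GCGCAT")
#' design_gu(tr)$sense_arm # "GTGTAT"
#' @export
design_gu <- function(target) {
  stopifnot(inherits(target, "target_region"))
  chars <- seq_chars(target$sequence)
  pos <- which(chars == "C")
  sense <- chars
  sense[pos] <- "T"
  subs <- tibble::tibble(
    position = as.integer(pos),
    from_base = rep("C", length(pos)),
    to_base = rep("T", length(pos)),
    kind = rep("GU_WOBBLE", length(pos))
  )
  new_hairpin_design("gu", target, chars_to_seq(sense), subs)
}

#' Patterned-mismatch design: complement-substitute positions in each window
#'
#' Tiles the sense arm with non-overlapping windows of `window` nt. Within
#' every complete window the `block` consecutive positions starting at
#' `offset` (0-based offset within the window) are replaced by their
#' complements (C<->G, A<->T), creating a self-pairing mismatch in the stem at
#' each substituted position. A trailing partial window too short to contain
#' the full block receives no substitutions.
#'
#' The published patterns are 1-in-4 (`window = 4, block = 1`) and
#' 2-in-10 (`window = 10, block = 2`). The position of the block within the
#' window is not fixed by the pattern description; the default places it at
#' the end of the window (`offset = window - block`).
#'
#' @inheritParams design_hairpin
#' @param window Window length in nt (tiling period).
#' @param block Number of consecutive substituted positions per window.
#' @param offset 0-based start of the block within each window,
#'   `0 <= offset <= window - block`. Default `window - block`.
#' @param scheme Label stored on the design (`"custom"` by default).
#' @return A `hairpin_design` whose substitutions are all `SELF_MISMATCH`.
#' @examples
#' tr <- validate_target("ACGT")
#' design_mismatch(tr, window = 4, block = 1, offset = 3)$sense_arm # "ACGA"
#' @export
design_mismatch <- function(target, window, block, offset = NULL,
                            scheme = "custom") {
  stopifnot(inherits(target, "target_region"))
  if (is.null(window) || is.null(block)) {
    abort_parameter("`window` and `block` are required for mismatch designs.")
  }
  window <- as.integer(window)
  block <- as.integer(block)
  offset <- as.integer(offset %||% (window - block))
  if (block < 1L || block >= window) {
    abort_parameter("`block` must satisfy 1 <= block < window.")
  }
  if (window > target$length) {
    abort_parameter("`window` must not exceed the target length.")
  }
  if (offset < 0L || offset > window - block) {
    abort_parameter("`offset` must satisfy 0 <= offset <= window - block.")
  }
  chars <- seq_chars(target$sequence)
  n_windows <- target$length %/% window
  # 1-based positions of substituted bases: window starts + offset .. +block-1
  starts <- (seq_len(n_windows) - 1L) * window + offset + 1L
  pos <- sort(as.integer(outer(starts, 0L:(block - 1L), `+`)))
  # trailing partial window: substitute only if the full block fits
  tail_start <- n_windows * window + offset + 1L
  if (tail_start + block - 1L <= target$length) {
    pos <- c(pos, tail_start:(tail_start + block - 1L))
  }
  from <- chars[pos]
  to <- unname(COMPLEMENT_MAP[from])
  sense <- chars
  sense[pos] <- to
  subs <- tibble::tibble(
    position = as.integer(pos), from_base = from, to_base = to,
    kind = rep("SELF_MISMATCH", length(pos))
  )
  new_hairpin_design(scheme, target, chars_to_seq(sense), subs)
}

#' @export
print.hairpin_design <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<hairpin_design> scheme %s on %s (%d nt)\n  %d substitution(s): %d G:U, %d mismatch (%.1f%% of stem)\n",
    x$scheme, x$target$id, x$target$length,
    m$n_substitutions, m$n_gu_pairs, m$n_mismatch_pairs, m$pct_substituted
  ))
  invisible(x)
}

#' Tidy a hairpin design into its substitution records
#'
#' @param x A `hairpin_design`.
#' @param ... Unused.
#' @return A tibble with one row per substitution: `position` (1-based on the
#'   sense arm), `from_base`, `to_base`, `kind`.
#' @export
tidy.hairpin_design <- function(x, ...) {
  dplyr::mutate(x$substitutions, scheme = x$scheme, .before = 1)
}

#' One-row design metrics summary
#'
#' @param x A `hairpin_design`.
#' @param ... Unused.
#' @return A one-row tibble of design metrics (substitution counts and
#'   percentages of stem positions that are G:U or mismatched).
#' @export
glance.hairpin_design <- function(x, ...) {
  dplyr::mutate(x$metrics, target_id = x$target$id, .before = 1)
}

#' Design-metrics table for a set of schemes on one target
#'
#' Convenience wrapper running several schemes on the same target and binding
#' their [glance()] rows, ready to write as TSV.
#'
#' @param target A `target_region`.
#' @param schemes Character vector of scheme names (see [design_hairpin()]).
#' @return A tibble with one row per scheme.
#' @export
design_metrics <- function(target, schemes = c("wt", "gu", "m1in4", "m2in10")) {
  purrr::map(schemes, function(s) glance(design_hairpin(target, s))) |>
    dplyr::bind_rows()
}
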