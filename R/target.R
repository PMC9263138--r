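#' Validate and normalize a target region sequence
#'
#' Normalizes a raw nucleotide string (mixed case, RNA `U` allowed) into a
#' strict DNA target region over `{A,C,G,T}`. Ambiguity codes and any other
#' non-nucleotide characters are rejected with their positions. The target
#' region is the wild-type subsequence of the gene to be silenced; its reverse
#' complement becomes the invariant antisense arm of every hairpin design.
#'
#' @param raw_sequence A single character string of nucleotides. `U` is
#'   converted to `T`; case is ignored.
#' @param id Identifier for the region.
#' @param parent_id,start,end Optional provenance: the parent sequence the
#'   region was cut from and its 1-based inclusive coordinates there. When
#'   given, `end - start + 1` must equal the sequence length.
#' @return A `target_region` object: a list with elements `id`, `sequence`,
#'   `length`, and (optionally) `parent_id`, `start`, `end`.
#' @examples
#' validate_target("acgu")$sequence # "ACGT"
#' @export
validate_target <- function(raw_sequence, id = "target",
                            parent_id = NULL, start = NULL, end = NULL) {
  if (!is.character(raw_sequence) || length(raw_sequence) != 1L) {
    abort_parameter("`raw_sequence` must be a single character string.")
  }
  seq <- chartr("u", "t", toupper(raw_sequence))
  seq <- chartr("U", "T", seq)
  if (nchar(seq) == 0L) {
    abort_parameter("Target sequence must be non-empty.")
  }
  check_dna_alphabet(seq)
  len <- nchar(seq)
  if (!is.null(start) && !is.null(end)) {
    if (end - start + 1L != len) {
      abort_parameter(sprintf(
        "Coordinate span %d-%d (length %d) does not match sequence length %d.",
        start, end, end - start + 1L, len
      ))
    }
  }
  structure(
    list(id = id, sequence = seq, length = len,
         parent_id = parent_id, start = start, end = end),
    class = "target_region"
  )
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("<target_region> %s: %d nt", x$id, x$length))
  if (!is.null(x$parent_id)) {
    cat(sprintf(" (%s:%d-%d)", x$parent_id, x$start, x$end))
  }
  cat("\n")
  shown <- if (x$length > 60) paste0(substr(x$sequence, 1, 57), "...") else x$sequence
  cat(" ", shown, "\n")
  invisible(x)
}

#' Read target regions from a FASTA file
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A list of [validate_target()] regions, one per record.
#' @export
read_target_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  purrr::map2(
    as.character(set), names(set),
    function(s, nm) validate_target(s, id = strsplit(nm, "\\s+")[[1]][1])
  )
}

count_base <- function(x, base) {
  sum(seq_chars(x) == base)
}
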