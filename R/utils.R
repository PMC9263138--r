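# Shared low-level helpers: condition constructors and sequence primitives.
# All user-facing positions in this package are 1-based inclusive
# (Biostrings/GFF3 convention).

hp_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "hairpinr_error"), ...)
}

abort_alphabet <- function(offending, positions) {
  hp_abort(
    c("Sequence contains non-nucleotide characters.",
      x = sprintf(
        "Offending character(s) %s at position(s) %s.",
        paste0("'", offending, "'", collapse = ", "),
        paste(positions, collapse = ", ")
      )),
    class = "hairpinr_alphabet_error",
    offending = offending, positions = positions
  )
}

abort_parameter <- function(message) {
  hp_abort(message, class = "hairpinr_parameter_error")
}

# DNA complement / reverse complement on plain character scalars.
# Thin wrappers over Biostrings so all revcomp logic has one provenance.
dna_complement <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAString(x)))
}

dna_revcomp <- function(x) {
  if (nchar(x) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

dna_to_rna <- function(x) chartr("T", "U", x)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste(x, collapse = "")

# Validate a plain DNA string (already normalized); returns invisibly or aborts.
check_dna_alphabet <- function(x, what = "sequence") {
  chars <- seq_chars(x)
  bad <- !chars %in% c("A", "C", "G", "T")
  if (any(bad)) {
    abort_alphabet(unique(chars[bad]), which(bad))
  }
  invisible(x)
}

# Derive a deterministic 31-bit sub-seed for a named random substream, so each
# generator draws from its own stream and adding one does not shift another.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483629)
}
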