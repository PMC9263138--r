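# Cassette assembly: promoter :: sense arm :: loop (intron) :: antisense arm
# :: terminator, in that fixed order. Part spans are 1-based inclusive and
# tile the full sequence without gaps.

#' Assemble a hairpin expression cassette
#'
#' Concatenates promoter, the design's (possibly modified) sense arm, the loop
#' spacer (typically an intron), the invariant antisense arm, and terminator,
#' and annotates each part with its role and span. Any part may be empty
#' (its span then has zero width).
#'
#' @param design A `hairpin_design`.
#' @param promoter,loop,terminator DNA strings (validated; `U` normalized to
#'   `T`, case-insensitive). May be `""`.
#' @param id Cassette identifier; default derived from target and scheme.
#' @return A `cassette_record`: list with `id`, `parts` (tibble: `name`,
#'   `role`, `sequence`, `start`, `end`) and `full_sequence`.
#' @examples
#' d <- design_wt(validate_target("ACG"))
#' assemble_cassette(d, "AA", "TT", "GG")$full_sequence # "AAACGTTCGTGG"
#' @export
assemble_cassette <- function(design, promoter, loop, terminator,
                              id = NULL) {
  stopifnot(inherits(design, "hairpin_design"))
  norm_part <- function(x, what) {
    if (!is.character(x) || length(x) != 1L) {
      abort_parameter(sprintf("`%s` must be a single character string.", what))
    }
    x <- chartr("Uu", "Tt", x)
    x <- toupper(x)
    if (nchar(x) > 0) check_dna_alphabet(x, what)
    x
  }
  promoter <- norm_part(promoter, "promoter")
  loop <- norm_part(loop, "loop")
  terminator <- norm_part(terminator, "terminator")
  id <- id %||% sprintf("hp%s[%s]", design$target$id, design$scheme)

  seqs <- c(promoter, design$sense_arm, loop, design$antisense_arm, terminator)
  roles <- c("promoter", "sense", "loop", "antisense", "terminator")
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  parts <- tibble::tibble(
    name = roles, role = roles, sequence = seqs,
    start = as.integer(starts), end = as.integer(ends)
  )
  structure(
    list(id = id, parts = parts, full_sequence = paste(seqs, collapse = "")),
    class = "cassette_record"
  )
}

#' @export
print.cassette_record <- function(x, ...) {
  cat(sprintf("<cassette_record> %s: %d nt\n", x$id, nchar(x$full_sequence)))
  print(dplyr::select(x$parts, "role", "start", "end"))
  invisible(x)
}

#' @export
tidy.cassette_record <- function(x, ...) x$parts

#' Write a cassette to FASTA and GFF3
#'
#' The FASTA holds the full cassette sequence; the GFF3 feature table records
#' each part's role as the feature type with 1-based inclusive coordinates.
#'
#' @param cassette A `cassette_record`.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the cassette.
#' @export
write_cassette <- function(cassette, fasta_path, gff3_path) {
  stopifnot(inherits(cassette, "cassette_record"))
  seqs <- Biostrings::DNAStringSet(cassette$full_sequence)
  names(seqs) <- cassette$id
  Biostrings::writeXStringSet(seqs, fasta_path)

  parts <- dplyr::filter(cassette$parts, .data$end >= .data$start)
  gr <- GenomicRanges::GRanges(
    seqnames = cassette$id,
    ranges = IRanges::IRanges(start = parts$start, end = parts$end),
    strand = ifelse(parts$role == "antisense", "-", "+")
  )
  S4Vectors::mcols(gr)$type <- parts$role
  S4Vectors::mcols(gr)$source <- "hairpinr"
  S4Vectors::mcols(gr)$ID <- paste0(cassette$id, ":", parts$role)
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(cassette)
}

#' Read a cassette back from FASTA + GFF3
#'
#' Reconstructs a `cassette_record` from files written by [write_cassette()].
#' Zero-width parts (e.g. an empty loop) are not representable in GFF3 and are
#' restored as empty sequences.
#'
#' @param fasta_path,gff3_path Paths written by [write_cassette()].
#' @return A `cassette_record`.
#' @export
read_cassette <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  full <- as.character(seqs[[1]])
  id <- strsplit(names(seqs)[1], "\\s+")[[1]][1]
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  roles_order <- c("promoter", "sense", "loop", "antisense", "terminator")
  got <- tibble::tibble(
    role = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  parts <- tibble::tibble(role = roles_order) |>
    dplyr::left_join(got, by = "role")
  # restore zero-width parts from neighbours
  prev_end <- 0L
  starts <- ends <- integer(5)
  for (i in seq_len(5)) {
    if (is.na(parts$start[i])) {
      starts[i] <- prev_end + 1L
      ends[i] <- prev_end
    } else {
      starts[i] <- parts$start[i]
      ends[i] <- parts$end[i]
      prev_end <- parts$end[i]
    }
  }
  parts <- tibble::tibble(
    name = roles_order, role = roles_order,
    sequence = purrr::map2_chr(starts, ends, function(s, e) {
      if (e < s) "" else substr(full, s, e)
    }),
    start = starts, end = ends
  )
  structure(
    list(id = id, parts = parts, full_sequence = full),
    class = "cassette_record"
  )
}

#' Placeholder regulatory part library
#'
#' Short synthetic stand-ins for promoter, intron loop, and terminator parts,
#' for examples and tests. These are arbitrary sequences, not the real 35S
#' promoter, PDK intron, or OCS terminator (which are vector-specific).
#'
#' @return A named list of DNA strings: `promoter`, `loop`, `terminator`.
#' @export
default_parts <- function() {
  list(
    promoter = "TATAGCTAGCCAATTGGCTTAAGGCTAGCTATA",
    loop = "GTAAGTTTCTGCTTCTACCTTTGATATATATATAATAATTATCACTAATTAGTAGTAATATAGTATTTCAAGTATTTTTTTCAAAATAAAAGAATGTAGTATATAGCAATTGCTTTTCTGTAGTTTATAAGTGTGTATATTTTAATTTATAACTTTTCTAATATATGACCAAAACATGGTGATGTGCAG",
    terminator = "GCTTGAGCTTGACTCTAGCTAGAGGATCCCCGG"
  )
}
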