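# Seeded generators for every input the analysis modules need: random
# targets with a fixed cytosine count, Dicer-like small-RNA read sets drawn
# from a hairpin design, and noisy Sanger-trace peak tables. Each generator
# draws from its own deterministic substream of the user seed, so adding one
# generator to a pipeline does not shift the draws of another.

#' Default siRNA size distribution
#'
#' Dominant 21-nt class followed by 24 nt, the two sizes hairpin transgenes
#' mainly produce, with minor 22/23-nt classes.
#'
#' @return A named probability vector over read lengths (names are lengths).
#' @export
default_size_distribution <- function() {
  c(`21` = 0.55, `22` = 0.08, `23` = 0.07, `24` = 0.30)
}

#' Random target region with an exact cytosine count
#'
#' Draws a uniformly random sequence conditioned on containing exactly
#' `c_count` cytosines: C positions are a uniform random subset and the
#' remaining positions are uniform over `{A,G,T}`.
#'
#' @param length Target length in nt.
#' @param c_count Exact number of C positions, `0 <= c_count <= length`.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param id Identifier for the region.
#' @return A `target_region`.
#' @export
random_target <- function(length, c_count, seed, id = "synthetic_target") {
  length <- as.integer(length)
  c_count <- as.integer(c_count)
  if (length < 1L) abort_parameter("`length` must be >= 1.")
  if (c_count < 0L || c_count > length) {
    abort_parameter("`c_count` must satisfy 0 <= c_count <= length.")
  }
  seq <- withr::with_seed(substream_seed(seed, "random_target"), {
    chars <- sample(c("A", "G", "T"), length, replace = TRUE)
    cpos <- sample.int(length, c_count)
    chars[cpos] <- "C"
    chars
  })
  validate_target(chars_to_seq(seq), id = id)
}

#' Simulate a Dicer-like small-RNA read set from a hairpin design
#'
#' Reads are windows of sampled length drawn uniformly over valid start
#' positions of the hairpin arms: sense reads come from the modified sense
#' arm (primary) or, with probability `secondary_rate`, from the wild-type
#' sense sequence (emulating RDR-synthesized secondary siRNAs); antisense
#' reads come from the antisense arm. Truth labels are emitted alongside the
#' sequences for parameter-recovery tests.
#'
#' @param design A `hairpin_design`.
#' @param n_reads Number of reads to draw.
#' @param size_distribution Named probability vector over read lengths
#'   (default [default_size_distribution()]). Lengths must not exceed the
#'   stem length.
#' @param strand_ratio Probability a read is sense (default 0.6; sense
#'   siRNAs are the more abundant class in G:U hairpin lines).
#' @param secondary_rate Probability a sense read is drawn from the
#'   wild-type sense sequence instead of the modified arm (default 0).
#' @param seed Integer seed.
#' @return A tibble with `id`, `sequence`, `count` (all 1), plus truth
#'   columns `truth_class` (`"primary"`, `"secondary"`, `"antisense"`),
#'   `truth_start`, `length`.
#' @export
simulate_reads <- function(design, n_reads,
                           size_distribution = default_size_distribution(),
                           strand_ratio = 0.6,
                           secondary_rate = 0,
                           seed = 1L) {
  stopifnot(inherits(design, "hairpin_design"))
  if (n_reads < 0) abort_parameter("`n_reads` must be non-negative.")
  if (strand_ratio < 0 || strand_ratio > 1 ||
      secondary_rate < 0 || secondary_rate > 1) {
    abort_parameter("`strand_ratio` and `secondary_rate` must lie in [0, 1].")
  }
  p <- size_distribution
  if (abs(sum(p) - 1) > 1e-9) {
    abort_parameter("`size_distribution` probabilities must sum to 1.")
  }
  lens <- as.integer(names(p))
  if (anyNA(lens) || any(lens > design$target$length)) {
    abort_parameter("Read lengths must be named integers <= the stem length.")
  }
  L <- design$target$length
  withr::with_seed(substream_seed(seed, "simulate_reads"), {
    read_len <- sample(lens, n_reads, replace = TRUE, prob = p)
    is_sense <- stats::runif(n_reads) < strand_ratio
    is_secondary <- is_sense & stats::runif(n_reads) < secondary_rate
    start <- vapply(read_len, function(l) sample.int(L - l + 1L, 1L),
                    integer(1))
    src <- ifelse(!is_sense, design$antisense_arm,
                  ifelse(is_secondary, design$target$sequence,
                         design$sense_arm))
    tibble::tibble(
      id = paste0("simread", seq_len(n_reads)),
      sequence = substr(src, start, start + read_len - 1L),
      count = rep(1L, n_reads),
      truth_class = ifelse(!is_sense, "antisense",
                           ifelse(is_secondary, "secondary", "primary")),
      truth_start = as.integer(start),
      length = as.integer(read_len)
    )
  })
}

#' Simulate a bisulfite Sanger trace peak table
#'
#' Generates per-position C and T peak heights for a bisulfite-PCR product of
#' `reference`: at each reference C, `height_C` is proportional to the
#' programmed methylated fraction and `height_T` to its complement, each
#' perturbed by independent multiplicative lognormal noise. Non-C positions
#' receive their full base height on the T channel convention used by
#' [call_methylation()] only at C rows, so they carry zero C/T heights.
#'
#' @param reference DNA string of the analyzed (top) strand.
#' @param methylation_truth Programmed methylated fraction(s) in `[0, 1]`:
#'   either a scalar applied to every C, or a vector named by C position.
#' @param noise_sigma Standard deviation of the lognormal multiplicative
#'   noise (0 for noiseless traces).
#' @param seed Integer seed.
#' @param base_height Mean total peak height (arbitrary units).
#' @return A trace tibble: `position`, `ref_base`, `height_C`, `height_T`.
#' @export
simulate_trace <- function(reference, methylation_truth, noise_sigma = 0.05,
                           seed = 1L, base_height = 1000) {
  reference <- chartr("Uu", "Tt", toupper(reference))
  check_dna_alphabet(reference)
  chars <- seq_chars(reference)
  cpos <- which(chars == "C")
  truth <- rep(NA_real_, length(chars))
  if (length(methylation_truth) == 1 && is.null(names(methylation_truth))) {
    truth[cpos] <- methylation_truth
  } else {
    idx <- as.integer(names(methylation_truth))
    if (anyNA(idx) || !all(idx %in% cpos)) {
      abort_parameter("Named truth fractions must address C positions.")
    }
    truth[idx] <- unname(methylation_truth)
    truth[setdiff(cpos, idx)] <- 0
  }
  if (any(truth[cpos] < 0 | truth[cpos] > 1)) {
    abort_parameter("Truth fractions must lie in [0, 1].")
  }
  if (noise_sigma < 0) abort_parameter("`noise_sigma` must be >= 0.")
  withr::with_seed(substream_seed(seed, "simulate_trace"), {
    noise <- function(n) exp(stats::rnorm(n, mean = 0, sd = noise_sigma))
    n_c <- length(cpos)
    height_C <- height_T <- numeric(length(chars))
    height_C[cpos] <- truth[cpos] * base_height * noise(n_c)
    height_T[cpos] <- (1 - truth[cpos]) * base_height * noise(n_c)
    tibble::tibble(
      position = seq_along(chars),
      ref_base = chars,
      height_C = height_C,
      height_T = height_T
    )
  })
}
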