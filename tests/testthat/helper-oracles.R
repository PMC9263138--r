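# Independent oracles and brute-force references used across the suite.

# Uniform random DNA string (unconditioned composition).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force enumeration of substituted positions for the windowed mismatch
# pattern: walk windows explicitly, one position at a time.
brute_window_positions <- function(len, window, block, offset) {
  pos <- integer()
  w_start <- 1L
  while (w_start <= len) {
    first <- w_start + offset
    last <- first + block - 1L
    # a window (complete or trailing partial) substitutes only if the whole
    # block fits inside the sequence
    if (last <= len) pos <- c(pos, first:last)
    w_start <- w_start + window
  }
  pos
}

# Brute-force read classifier: compare the read against every window of every
# reference, no substring search.
brute_classify_read <- function(seq, panel) {
  hits <- function(ref) {
    L <- nchar(ref); l <- nchar(seq)
    if (l > L || l == 0) return(FALSE)
    any(vapply(1:(L - l + 1), function(i) {
      substr(ref, i, i + l - 1) == seq
    }, logical(1)))
  }
  in_mod <- hits(panel$sense_modified)
  in_wt <- hits(panel$sense_wt)
  if (in_mod && in_wt) return("ambiguous_sense")
  if (in_mod) return("primary_sense")
  if (in_wt) return("secondary_sense")
  if (hits(panel$antisense)) return("antisense")
  if (nchar(panel$loop) > 0 && hits(panel$loop)) return("loop")
  "unmapped"
}

# Independent duplex-energy oracle: ViennaRNA's RNAduplex on the two arms.
rnaduplex_available <- function() nzchar(Sys.which("RNAduplex"))

rnaduplex_energy <- function(sense_dna, antisense_dna) {
  input <- paste0(chartr("T", "U", sense_dna), "\n",
                  chartr("T", "U", antisense_dna), "\n")
  out <- system2("RNAduplex", stdout = TRUE, stderr = FALSE, input = input)
  m <- regmatches(out[1], regexpr("\\(\\s*-?[0-9.]+\\)$", out[1]))
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

# Brute-force pairing walk: base i of the sense arm against base L+1-i of the
# antisense arm, classified from first principles.
brute_pair_walk <- function(design) {
  s <- strsplit(chartr("T", "U", design$sense_arm), "")[[1]]
  a <- strsplit(chartr("T", "U", design$antisense_arm), "")[[1]]
  L <- length(s)
  vapply(seq_len(L), function(i) {
    p <- paste0(s[i], a[L + 1 - i])
    if (p %in% c("AU", "UA", "GC", "CG")) "WC"
    else if (p %in% c("GU", "UG")) "GU"
    else "MISMATCH"
  }, character(1))
}
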