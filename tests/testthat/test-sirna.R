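make_panel <- function(len = 200, c_count = 52, seed = 1, loop = "") {
  d <- design_gu(random_target(len, c_count, seed = seed))
  list(design = d, panel = reference_panel(d, loop = loop))
}

test_that("length filter keeps 18-35 nt inclusive and reports removals", {
  reads <- tibble::tibble(sequence = vapply(c(17, 18, 35, 36), function(n) {
    strrep("A", n)
  }, character(1)))
  kept <- length_filter(reads)
  expect_equal(kept$length, c(18L, 35L))
  expect_equal(attr(kept, "n_removed"), 2L)
  expect_equal(attr(kept, "total_input"), 4L)

  empty <- length_filter(tibble::tibble(sequence = character()))
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_input"), 0L)

  all21 <- length_filter(tibble::tibble(sequence = rep(strrep("A", 21), 1000)))
  expect_equal(sum(all21$count), 1000L)
})

test_that("constructed reads classify as primary, secondary or ambiguous", {
  mp <- make_panel(c_count = 8, seed = 5)
  subs <- mp$design$substitutions$position
  # a window spanning a substitution distinguishes modified from WT origin
  p <- subs[5]
  win_mod <- substr(mp$design$sense_arm, p - 10, p + 10)
  win_wt <- substr(mp$design$target$sequence, p - 10, p + 10)
  # a substitution-free window cannot be told apart: find a 21-nt stretch
  # with no substituted position
  is_free <- !(1:200 %in% subs)
  runs <- rle(is_free)
  stopifnot(any(runs$lengths[runs$values] >= 21))
  ends <- cumsum(runs$lengths)
  i <- which(runs$values & runs$lengths >= 21)[1]
  g <- ends[i] - runs$lengths[i] + 1L
  win_amb <- substr(mp$design$sense_arm, g, g + 20)
  cls <- classify_reads(
    tibble::tibble(sequence = c(win_mod, win_wt, win_amb)), mp$panel
  )
  expect_equal(cls$class,
               c("primary_sense", "secondary_sense", "ambiguous_sense"))
})

test_that("ambiguous windows are exactly the substitution-free windows", {
  mp <- make_panel(len = 120, c_count = 30, seed = 9)
  subs <- mp$design$substitutions$position
  k <- 21L
  starts <- 1:(120 - k + 1)
  wins <- substring(mp$design$sense_arm, starts, starts + k - 1L)
  cls <- classify_reads(tibble::tibble(sequence = wins), mp$panel)
  has_sub <- vapply(starts, function(s) {
    any(subs >= s & subs <= s + k - 1L)
  }, logical(1))
  # windows over a substitution are primary; others can still be ambiguous
  expect_true(all(cls$class[!has_sub] == "ambiguous_sense"))
  expect_true(all(cls$class[has_sub] %in% c("primary_sense", "ambiguous_sense")))
  # a window spanning a substitution is ambiguous only if the same string
  # happens to occur elsewhere in the WT sequence; with a 21-nt window this
  # is vanishingly rare, so essentially all should be primary
  expect_gt(mean(cls$class[has_sub] == "primary_sense"), 0.95)
})

test_that("classification agrees with a brute-force all-window scan", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      mp <- make_panel(len = 80, c_count = 20, seed = 200 + rep,
                       loop = random_dna(40))
      reads <- dplyr::bind_rows(
        simulate_reads(mp$design, 30, seed = 300 + rep,
                       secondary_rate = 0.3, strand_ratio = 0.5),
        tibble::tibble(id = "rnd", sequence = random_dna(21), count = 1L,
                       truth_class = NA, truth_start = NA, length = 21L),
        tibble::tibble(id = "loopread",
                       sequence = substr(mp$panel$loop, 3, 24),
                       count = 1L, truth_class = NA, truth_start = NA,
                       length = 22L)
      )
      cls <- classify_reads(reads, mp$panel)
      brute <- vapply(cls$sequence, brute_classify_read, character(1),
                      panel = mp$panel)
      expect_equal(cls$class, unname(brute))
    }
  })
})

test_that("classification is a partition conserving read counts", {
  mp <- make_panel(seed = 15)
  reads <- simulate_reads(mp$design, 500, seed = 4, secondary_rate = 0.2,
                          strand_ratio = 0.6)
  filtered <- length_filter(reads)
  cls <- classify_reads(filtered, mp$panel)
  expect_equal(sum(cls$count), sum(filtered$count))
  summary <- class_summary(cls)
  expect_equal(sum(summary$count), sum(filtered$count))
  expect_true(all(cls$class %in% summary$class))
})

test_that("no read containing a converted position can be secondary sense", {
  mp <- make_panel(seed = 25)
  reads <- simulate_reads(mp$design, 2000, seed = 8, secondary_rate = 0.5,
                          strand_ratio = 1)
  cls <- classify_reads(reads, mp$panel)
  secondary <- cls[cls$class == "secondary_sense", ]
  # every secondary read must match WT only; none may contain a C->T site
  # read back from the modified arm
  expect_true(all(!vapply(secondary$sequence, grepl, logical(1),
                          x = mp$design$sense_arm, fixed = TRUE)))
})

test_that("size profiles follow the simulated length distribution", {
  mp <- make_panel(seed = 35)
  reads <- simulate_reads(
    mp$design, 2000, size_distribution = c(`21` = 0.7, `24` = 0.3),
    strand_ratio = 0.5, seed = 12
  )
  cls <- classify_reads(length_filter(reads), mp$panel)
  prof <- size_profile(cls)
  totals <- prof |>
    dplyr::group_by(length) |>
    dplyr::summarise(count = sum(count))
  expect_equal(totals$length[which.max(totals$count)], 21L)
  expect_equal(sum(totals$count[!totals$length %in% c(21, 24)]), 0L)
  # multinomial agreement within 3 sigma
  p21 <- sum(totals$count[totals$length == 21]) / 2000
  expect_lt(abs(p21 - 0.7), 3 * sqrt(0.7 * 0.3 / 2000))
})

test_that("degenerate profiles have the right zeros", {
  mp <- make_panel(seed = 45)
  anti <- simulate_reads(mp$design, 100, strand_ratio = 0, seed = 3)
  prof <- size_profile(classify_reads(anti, mp$panel))
  expect_equal(sum(prof$count[prof$strand == "sense"]), 0L)
  empty <- size_profile(classify_reads(tibble::tibble(sequence = character()),
                                       mp$panel),
                        total_input = 1)
  expect_equal(nrow(empty), 36L)
  expect_true(all(empty$count == 0))
})

test_that("RPM normalization is linear and conserves totals", {
  expect_equal(normalize_rpm(500, 1e6), 500)
  expect_equal(normalize_rpm(0, 1e6), 0)
  expect_error(normalize_rpm(1, 0), class = "hairpinr_division_error")
  counts <- c(10, 20, 30)
  expect_equal(normalize_rpm(2 * counts, 1000), 2 * normalize_rpm(counts, 1000))
  expect_equal(sum(normalize_rpm(counts, 1000)), 1e6 * sum(counts) / 1000)
})

test_that("secondary fraction counts unambiguous sense reads only", {
  mp <- make_panel(seed = 55)
  pure <- classify_reads(
    simulate_reads(mp$design, 500, secondary_rate = 0, strand_ratio = 1,
                   seed = 6),
    mp$panel
  )
  expect_equal(secondary_fraction(pure)$secondary_fraction, 0)
  sf <- secondary_fraction(pure)
  expect_equal(sf$n_secondary, 0L)

  amb_only <- tibble::tibble(
    sequence = substr(mp$design$sense_arm, 1, 20), class = "ambiguous_sense",
    count = 5L
  )
  expect_error(secondary_fraction(amb_only),
               class = "hairpinr_no_sense_reads_error")
})

test_that("injected secondary reads are recovered at their simulated rate", {
  mp <- make_panel(seed = 65)
  reads <- simulate_reads(mp$design, 10000, secondary_rate = 0.1,
                          strand_ratio = 1, seed = 31)
  cls <- classify_reads(reads, mp$panel)
  sf <- secondary_fraction(cls)
  sigma <- sqrt(0.1 * 0.9 / (sf$n_primary + sf$n_secondary))
  expect_lt(abs(sf$secondary_fraction - 0.1), 3 * sigma)
})

test_that("FASTA/FASTQ readers handle plain and collapsed headers", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1_42", "ACGTACGTACGTACGTACGTA",
               ">plain", "TGCATGCATGCATGCATGCAT"), fa)
  reads <- read_sirna_reads(fa)
  expect_equal(reads$count, c(42L, 1L))
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGTACGTACGTACGTACGTA", "+",
               strrep("I", 21)), fq)
  reads2 <- read_sirna_reads(fq)
  expect_equal(reads2$sequence, "ACGTACGTACGTACGTACGTA")
})
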