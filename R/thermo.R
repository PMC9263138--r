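# Nearest-neighbor free-energy model for the hairpin dsRNA stem.
#
# The stem is the sense arm paired position-by-position against the antisense
# arm (position i of the sense arm pairs position L+1-i of the antisense arm,
# both read 5'->3'). Pair states are WC ({A:U, U:A, G:C, C:G}), GU
# ({G:U, U:G}) or MISMATCH. Free energy at 37 degrees C is the sum of helix
# stacking terms over adjacent paired dinucleotides (Watson-Crick and G:U
# wobble stacks from the bundled Turner 2004 table), plus duplex initiation,
# terminal A:U/G:U end penalties, and an internal-loop penalty per run of
# mismatched positions. The loop (intron) spacer contributes nothing: only
# the stem is scored.

the_params_cache <- new.env(parent = emptyenv())

#' Load a nearest-neighbor duplex parameter set
#'
#' Reads the bundled plain-text parameter tables (stacking free energies and
#' duplex-level constants) and verifies the stack table against its embedded
#' checksum.
#'
#' @param parameter_set_id Name of the parameter set. Only `"turner2004"` is
#'   bundled.
#' @return A `duplex_params` object: list with `id`, `stacks` (named numeric
#'   lookup of stacking energies), `misc` (named numeric constants), and
#'   `checksum`.
#' @export
duplex_params <- function(parameter_set_id = "turner2004") {
  if (!identical(parameter_set_id, "turner2004")) {
    abort_parameter(sprintf("Unknown parameter set '%s'.", parameter_set_id))
  }
  if (!is.null(the_params_cache[[parameter_set_id]])) {
    return(the_params_cache[[parameter_set_id]])
  }
  stacks_path <- system.file("extdata", "turner2004_stacks.tsv",
                             package = "hairpinr", mustWork = TRUE)
  misc_path <- system.file("extdata", "turner2004_misc.tsv",
                           package = "hairpinr", mustWork = TRUE)
  stacks_tbl <- readr::read_tsv(stacks_path, comment = "#",
                                show_col_types = FALSE)
  misc_tbl <- readr::read_tsv(misc_path, comment = "#",
                              show_col_types = FALSE)
  expected <- readLines(stacks_path, n = 20)
  expected <- expected[grepl("^# checksum_x100:", expected)]
  expected <- as.integer(sub("^# checksum_x100:\\s*", "", expected))
  got <- as.integer(round(sum(stacks_tbl$dg_kcal) * 100))
  if (!identical(got, expected)) {
    abort_parameter("Stack parameter table failed its checksum; file corrupted?")
  }
  stacks <- stats::setNames(
    stacks_tbl$dg_kcal,
    paste(stacks_tbl$pair5p, stacks_tbl$pair3p, sep = "/")
  )
  misc <- stats::setNames(misc_tbl$value, misc_tbl$name)
  obj <- structure(
    list(id = parameter_set_id, stacks = stacks, misc = misc, checksum = got),
    class = "duplex_params"
  )
  the_params_cache[[parameter_set_id]] <- obj
  obj
}

WC_PAIRS <- c("AU", "UA", "GC", "CG")
GU_PAIRS <- c("GU", "UG")

#' Walk the stem of a design and assign a pairing state per position
#'
#' @param design A `hairpin_design`.
#' @return A `pair_states` tibble: `index` (1-based stem position),
#'   `sense_base`, `antisense_base` (RNA alphabet), `state`
#'   (`"WC"`, `"GU"`, `"MISMATCH"`). The design identifier and target id are
#'   carried as attributes.
#' @export
pair_states <- function(design) {
  stopifnot(inherits(design, "hairpin_design"))
  if (nchar(design$sense_arm) != nchar(design$antisense_arm)) {
    hp_abort("Sense and antisense arms differ in length.",
             class = "hairpinr_length_mismatch_error")
  }
  s <- seq_chars(dna_to_rna(design$sense_arm))
  a <- seq_chars(dna_to_rna(design$antisense_arm))
  L <- length(s)
  partner <- rev(a) # antisense position L+1-i pairs sense position i
  pair <- paste0(s, partner)
  state <- ifelse(pair %in% WC_PAIRS, "WC",
                  ifelse(pair %in% GU_PAIRS, "GU", "MISMATCH"))
  out <- tibble::tibble(
    index = seq_len(L), sense_base = s, antisense_base = partner,
    state = state
  )
  attr(out, "design_id") <- sprintf("%s[%s]", design$target$id, design$scheme)
  attr(out, "target_id") <- design$target$id
  class(out) <- c("pair_states", class(out))
  out
}

stack_key <- function(s1, b1, b2, s2) {
  paste0(s1, b1, "/", b2, s2)
}

# Sum of stacking energies over adjacent paired (non-mismatch) dinucleotides.
# Internal helper, also used by the additivity property test.
stack_sum <- function(states, params) {
  paired <- states$state != "MISMATCH"
  i <- which(paired[-nrow(states)] & paired[-1])
  if (length(i) == 0) return(0)
  keys <- stack_key(
    states$sense_base[i], states$antisense_base[i],
    states$antisense_base[i + 1], states$sense_base[i + 1]
  )
  vals <- params$stacks[keys]
  if (anyNA(vals)) {
    abort_parameter("Stack lookup failed for an adjacent paired dinucleotide.")
  }
  sum(vals)
}

# Penalty for a run of k consecutive mismatched stem positions.
mismatch_run_penalty <- function(k, misc) {
  if (k == 1) {
    misc[["mismatch_1x1"]]
  } else {
    misc[["mismatch_2x2"]] + (k - 2) * misc[["mismatch_ext"]]
  }
}

#' Nearest-neighbor free energy of a hairpin stem
#'
#' @param states A `pair_states` tibble from [pair_states()].
#' @param params A `duplex_params` object (default the bundled Turner 2004
#'   set).
#' @return Free energy in kcal/mol at 37 degrees C (more negative = more
#'   stable).
#' @export
duplex_free_energy <- function(states, params = duplex_params()) {
  stopifnot(inherits(params, "duplex_params"))
  if (nrow(states) < 2) {
    abort_parameter("At least 2 stem positions are required.")
  }
  misc <- params$misc
  dg <- misc[["duplex_init"]] + stack_sum(states, params)
  # terminal penalties at the outermost paired positions
  paired_idx <- which(states$state != "MISMATCH")
  if (length(paired_idx) > 0) {
    for (i in c(paired_idx[1], paired_idx[length(paired_idx)])) {
      pr <- paste0(states$sense_base[i], states$antisense_base[i])
      if (pr %in% c("AU", "UA")) dg <- dg + misc[["terminal_au"]]
      if (pr %in% GU_PAIRS) dg <- dg + misc[["terminal_gu"]]
    }
  }
  # internal-loop penalties per mismatch run
  runs <- rle(states$state == "MISMATCH")
  mm_runs <- runs$lengths[runs$values]
  dg <- dg + sum(vapply(mm_runs, mismatch_run_penalty, numeric(1),
                        misc = misc))
  unname(dg)
}

#' Score a design: pairing table plus free energy
#'
#' @param design A `hairpin_design`.
#' @param params A `duplex_params` object.
#' @return A `duplex_report`: list with `design_id`, `target_id`,
#'   `pair_states`, `delta_g`, counts `n_wc`/`n_gu`/`n_mm`, and
#'   `parameter_set_id`.
#' @export
duplex_report <- function(design, params = duplex_params()) {
  st <- pair_states(design)
  structure(
    list(
      design_id = attr(st, "design_id"),
      target_id = attr(st, "target_id"),
      scheme = design$scheme,
      pair_states = st,
      delta_g = duplex_free_energy(st, params),
      n_wc = sum(st$state == "WC"),
      n_gu = sum(st$state == "GU"),
      n_mm = sum(st$state == "MISMATCH"),
      parameter_set_id = params$id
    ),
    class = "duplex_report"
  )
}

#' @export
print.duplex_report <- function(x, ...) {
  cat(sprintf(
    "<duplex_report> %s: dG = %.2f kcal/mol (%d WC, %d G:U, %d mismatch; %s)\n",
    x$design_id, x$delta_g, x$n_wc, x$n_gu, x$n_mm, x$parameter_set_id
  ))
  invisible(x)
}

#' @export
tidy.duplex_report <- function(x, ...) x$pair_states

#' @export
glance.duplex_report <- function(x, ...) {
  stem <- x$n_wc + x$n_gu + x$n_mm
  tibble::tibble(
    design_id = x$design_id, scheme = x$scheme, target_id = x$target_id,
    delta_g = x$delta_g, n_wc = x$n_wc, n_gu = x$n_gu, n_mm = x$n_mm,
    pct_gu = round(100 * x$n_gu / stem, 1),
    parameter_set_id = x$parameter_set_id
  )
}

#' Rank designs by predicted stem stability
#'
#' Orders duplex reports most stable first (ascending free energy; ties
#' broken by design id). All reports must concern the same target.
#'
#' @param reports A list of `duplex_report` objects.
#' @return A tibble (one row per report, in rank order) with a `rank` column.
#' @export
rank_designs <- function(reports) {
  if (inherits(reports, "duplex_report")) reports <- list(reports)
  stopifnot(all(purrr::map_lgl(reports, inherits, "duplex_report")))
  targets <- unique(purrr::map_chr(reports, "target_id"))
  if (length(targets) > 1) {
    hp_abort(
      sprintf("Reports span different targets: %s.",
              paste(targets, collapse = ", ")),
      class = "hairpinr_mixed_target_error"
    )
  }
  purrr::map(reports, glance) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$delta_g, .data$design_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Score a set of schemes on one target
#'
#' @param target A `target_region`.
#' @param schemes Character vector of scheme names.
#' @param params A `duplex_params` object.
#' @return A ranked tibble from [rank_designs()].
#' @export
score_schemes <- function(target, schemes = c("wt", "gu", "m1in4", "m2in10"),
                          params = duplex_params()) {
  purrr::map(schemes, function(s) {
    duplex_report(design_hairpin(target, s), params)
  }) |>
    rank_designs()
}
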