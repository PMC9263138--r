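---
title: "Designing and analysing G:U wobble and mismatched hairpin RNAi constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing G:U wobble and mismatched hairpin RNAi constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinr)
```

## The problem

A hairpin RNA (hpRNA) transgene expresses a target-gene fragment followed by
its reverse complement, separated by an intron spacer; the transcript folds
into a double-stranded stem that Dicer-like enzymes process into siRNAs. The
inverted-repeat (IR) DNA encoding that stem is itself a strong attractor of
cytosine methylation in plants, and the methylation spreads into the
adjacent promoter, transcriptionally silencing the very transgene that is
supposed to do the silencing. The outcome is a familiar one to anyone who
has screened hpRNA transformants: a minority of lines silence strongly and
many barely at all.

The remedy implemented here is to modify the *sense* arm only, so that the
DNA is no longer a palindrome while the antisense siRNAs — the strand that
actually guides cleavage of the target mRNA — remain perfectly
complementary to it. Three modification schemes are provided alongside the
unmodified control:

| scheme   | sense-arm modification                     | stem consequence |
|----------|--------------------------------------------|------------------|
| `wt`     | none                                       | perfect duplex   |
| `gu`     | every C → T                                | former C:G pairs become G:U wobbles |
| `m1in4`  | 1 complement substitution per 4 nt         | 25% self-pairing mismatches |
| `m2in10` | 2 consecutive substitutions per 10 nt      | 20% mismatches in 2-nt loops |

The `gu` scheme is the interesting one: U still pairs with G in RNA (the
G:U wobble), so the transcript folds into an essentially perfect hairpin
even though the DNA repeat is broken at every former cytosine. Across
typical plant coding sequence, cytosines are roughly 18–26% of positions,
so the scheme modifies about a fifth to a quarter of the arm.

## Design rules and their invariants

`design_gu()` replaces every sense-arm C with T and records each change as a
`GU_WOBBLE` substitution. `design_mismatch()` tiles the arm with
non-overlapping windows of `window` nt and complement-substitutes
(`C↔G`, `A↔T`) the `block` consecutive positions starting at a fixed
`offset` within each window; each such position then faces its own
complement's complement in the stem — i.e. itself — and cannot pair. Both
constructors enforce, and the test suite property-checks, the central
contract: **the antisense arm is always the exact reverse complement of the
wild-type target**, whatever happens to the sense arm.

Two conventions needed a decision:

* **Block placement within the window.** The 1-in-4 and 2-in-10 patterns fix
  the substitution density but not where the block sits inside each window.
  The default `offset = window - block` places it at the window end; the
  offset is an explicit argument, so any literal reading of the pattern can
  be reproduced exactly.
* **Trailing partial windows** receive substitutions only when the whole
  block fits inside the sequence — the conservative reading of "every N
  nucleotides".
* **Coordinates** are 1-based inclusive everywhere (the Biostrings/GFF3
  convention an R user expects); substitution positions index the sense arm.

`assemble_cassette()` concatenates promoter :: sense :: loop :: antisense ::
terminator and annotates the spans; `write_cassette()`/`read_cassette()`
round-trip the construct through FASTA + GFF3. The bundled
`default_parts()` are clearly synthetic placeholders — real constructs use
vector-specific promoter/intron/terminator parts that the user supplies as
FASTA.

## The stem free-energy model

Silencing strength tracks the predicted thermodynamic stability of the
dsRNA stem, so the package scores each design with a nearest-neighbor
model:

$$\Delta G^\circ_{37}(\text{stem}) = \Delta G_{\text{init}}
  + \sum_i \Delta G_{\text{stack}}(p_i, p_{i+1})
  + \Delta G_{\text{ends}} + \sum_{\text{runs}} \Delta G_{\text{loop}}(k)$$

* **Stacks.** Adjacent paired dinucleotides contribute the Turner 2004
  stacking free energies (37 °C, kcal/mol), including the G:U wobble
  stacks. The table ships as a plain-text TSV under `inst/extdata/` with an
  embedded checksum that `duplex_params()` verifies at load time.
* **Initiation and ends.** Duplex initiation +4.09 kcal/mol; terminal A:U
  (and, by the same logic, terminal G:U) ends +0.45 kcal/mol.
* **Mismatches.** A run of *k* consecutive mismatched positions interrupts
  the stack sum and adds a generic internal-loop penalty: +1.70 kcal/mol for
  an isolated mismatch (1×1 loop), +2.80 for a 2×2 loop, +0.50 per further
  mismatch. These are deliberately generic constants — no loop model is
  implied by the biology being emulated — and they are configurable through
  the parameter table. Only the relative ranking of designs is interpreted,
  never absolute stem energies.
* **Scope.** Only the stem is scored; the intron loop contributes nothing.
  No suboptimal folds, no partition function, no salt correction.

On any realistic target the scheme ranking is `wt` (most stable) → `gu` →
`m2in10` → `m1in4`, because a WC→GU stack change costs roughly 1–2 kcal/mol
per flanking stack while each mismatch additionally forfeits two stacks and
pays a loop penalty. The test suite checks this ranking across seeded random
200-nt targets with 20–30% C content, and checks the energies of pure
Watson–Crick duplexes (≤ 20 bp) against an independent duplex-folding
oracle when one is available on the `PATH`. One asymmetry worth knowing
about: in the Turner table the A:U→G:U replacement can be mildly
*stabilizing* in some contexts; the monotone "wobbles destabilize" property
holds for the C:G→U:G changes the `gu` design actually makes, and that is
what the tests assert.

## Methylation read-outs

`bisulfite_convert()` models the chemistry: unmethylated C → T, methylated
C retained, on an explicitly chosen strand (`"bottom"` reverse-complements
first and reports in bottom-strand orientation; the strand is never
inferred). A pleasing corollary checked in the tests: the `gu` sense arm is
C-free on the top strand, so its bisulfite conversion is the identity
regardless of methylation state — any residual C signal in a real trace of
such an amplicon is background noise.

`call_methylation()` consumes a per-position table of Sanger trace peak
heights and estimates, at each reference cytosine,
`fraction = height_C / (height_C + height_T)`. Rows whose total height
falls below `noise_floor` (default 10%) of the per-trace median total are
reported as `NA` — missing, never zero, since an absent peak is not
evidence of zero methylation. Contexts are assigned from the two downstream
bases on the same strand (next base G → CG; else next-next G → CHG; else
CHH), with cytosines truncated at the 3′ end classed CHH by convention;
`summarize_contexts()` aggregates per context. `mcrbc_fraction()` covers the
coarser enzyme assay: McrBC cleaves methylated DNA, so the template fraction
surviving digestion estimates the *un*methylated fraction — from band
intensities as a direct ratio, or from qPCR Ct values as
`efficiency^(Ct_undigested − Ct_digested)` with 100% efficiency (factor 2)
as the default.

## siRNA classification

Reads are length-filtered to 18–35 nt and classified by **exact substring
matching** against the hairpin references. At reference lengths of a few
hundred nucleotides, exhaustive exact scanning is equivalent to no-mismatch
short-read mapping and needs no external aligner; a brute-force all-window
scan serves as the oracle in the tests. Classes are mutually exclusive,
with stem-first and sense-first priority for the rare read matching several
references (palindromic windows are additionally flagged):

* `primary_sense` — matches the modified sense arm only: it carries at
  least one converted position, so it can only be a Dicer product of the
  hairpin transcript itself;
* `secondary_sense` — matches the wild-type sense sequence only: it must
  derive from RDR-copied target mRNA;
* `ambiguous_sense` — spans no substituted position, so both origins fit;
  excluded from the `secondary_fraction()` numerator and denominator and
  reported separately;
* `antisense`, `loop`, `unmapped`.

`size_profile()` tabulates 18–35 nt × strand (ambiguous counted as sense,
loop/unmapped excluded) and `normalize_rpm()` scales to reads per million of
total filtered input reads. That denominator is a deliberate, documented
deviation from practice on real libraries, where totals include reads
mapping to the host genome: without a genome in scope, total filtered input
is the reproducible choice.

## What the simulators emulate — and what they do not

`random_target(length, c_count, seed)` draws a uniform sequence conditioned
on an exact cytosine count, matching how the real target regions are
characterised (200 nt / 43 C, 450 nt / 82 C, 200 nt / 52 C).
`simulate_reads()` draws read lengths from a configurable distribution
(default peaked at 21 nt with a 24-nt shoulder, the two dominant Dicer
classes), strand by a `strand_ratio` coin (default 0.6 sense), windows
uniformly over valid starts, and injects wild-type-sense reads at
`secondary_rate`; truth labels ride along for recovery tests.
`simulate_trace()` produces C/T peak heights proportional to the programmed
methylated fraction under multiplicative lognormal noise (σ = 0.05 by
default).

Each generator draws from its own deterministic substream of the user seed,
so inserting one generator into a pipeline never shifts another's output.

Deliberately **not** modelled: sequencing error, positional Dicer hot-spots,
RDR transitivity beyond the secondary-rate mixture, and chromatogram
base-calling (the trace importer consumes exported height tables, not
binary trace files). Passing tests therefore demonstrate correctness of the
algorithms under idealised inputs — exact matching, clean traces plus
lognormal noise — not robustness to real library artefacts.

## Problem sizes and numerical checks

The shipped tests and the acceptance script run at desk scale, chosen to
make the statistics decisive while staying quick: 100 random 200-nt targets
for the ranking property, 10,000 reads for rate recovery (3 binomial σ
bounds), 50 replicate traces for methylation recovery (±0.03 at σ = 0.05),
50 random panels for classifier–oracle equivalence, and exhaustive
enumeration wherever the space is finite (all 3-mers for context rules, all
stack-table entries for the wobble-destabilization property). Determinism
is pinned by seeding every stochastic draw; floating-point energies are
compared exactly where the computation is a fixed sum and with explicit
tolerances where an external oracle with its own rounding is involved.

## Known limitations

* Absolute stem free energies depend on the generic mismatch-loop constants
  and should only be read comparatively; rankings are the supported output.
* The qPCR McrBC estimator assumes a shared amplification efficiency
  between digested and undigested templates.
* Exact matching means a single sequencing error unmaps a read; on real
  libraries the class counts are therefore conservative.
* The trace caller assumes the table rows are aligned 1:1 with the
  reference; indels in the Sanger read are the user's problem upstream.
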