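---
title: "Calling transcript errors from rolling-circle consensus reads"
author: "circlecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transcript errors from rolling-circle consensus reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlecall)
```

## The measurement problem

A transcript error is a base difference between an RNA molecule and its
genomic template. Per-site error rates in bacteria are on the order of
10^-6^ to 10^-5^ per nucleotide — far below the raw error rates of reverse
transcription (~10^-4^/nt) and of sequencing (10^-4^ to 10^-3^ per call), so
naive RNA-seq cannot see them. Rolling-circle (CirSeq-style) sequencing
solves this by circularizing short RNA fragments and reverse-transcribing
them by rolling circle, so that each read carries several tandem repeats of
the same template molecule. A true template change is present in *every*
repeat; a reverse-transcription error is confined to one repeat; a
sequencing error to one cycle. `circlecall` implements the full inference
chain from raw reads to error calls and the downstream statistics, plus a
seeded simulator that reproduces the three-tier causal structure so that
every stage can be validated end to end without external data.

## Pipeline model

**Period detection.** The repeat length `P` of a read is found by
autocorrelation: for each candidate period, `f(P)` is the fraction of
position pairs `(i, i+P)` with identical non-N base calls, and the maximizing
`P` is accepted when `f(P) >= min_identity` (default 0.85; random sequence
scores near 0.25, true repeats near 1). Ties are broken toward the smallest
period, the fundamental one, since multiples of the true period score equally
on clean reads. The candidate range is `[25, floor(L/2)]` nt: 25 nt is the
smallest circularizable fragment, and `L/2` guarantees at least two repeats.
On reads carrying a stray technical error, the doubled period can
occasionally outscore the fundamental one (the error may break fewer
comparison pairs at `2P`); such fragments later fail the longest-block
acceptance in mapping and are discarded — a few percent of yield, with no
bias against true transcript errors, which are repeat-consistent and do not
perturb `f(P)` at all.

**Bayesian consensus.** Column `j` of the consensus collects the calls at
read positions `j, j+P, j+2P, ...` with their Phred-decoded error
probabilities; the trailing partial repeat contributes its calls too, so the
first `L mod P` columns have depth `r+1`. With a uniform prior over the four
bases (the neutral choice; the genome composition is close to uniform and the
posterior is dominated by the likelihood at any depth ≥ 2), the posterior of
base `a` is proportional to the product of `1-ε` over agreeing calls and
`ε/3` over disagreeing ones. The consensus call is the posterior maximizer
and its recomputed error probability is `q = 1 - posterior`. Exact posterior
ties (e.g. two equal-quality disagreeing calls at depth 2) emit `N`, which is
excluded from all assayed counts, rather than an arbitrary pick. Input `ε`
is clamped to `[1e-6, 0.75]`: the floor (Q60) prevents a single overconfident
call from dominating, the ceiling keeps degenerate quality strings finite.
The computation runs in log space and is verified against a direct-product
enumeration oracle in the test suite.

**Junction recovery.** The original fragment is a rotation of the consensus
(the ligation junction can fall anywhere), so a tandem duplicate of the
consensus contains exactly one contiguous copy of the original fragment. The
built-in mapper seeds the duplicate with exact 15-mers against the reference,
votes on (replicon, strand, diagonal), and then *places a window of exactly
one period length* on each candidate diagonal where the exact-match count is
maximal, using a prefix-sum scan over all placements. We deliberately avoid
free local extension: with unit match/mismatch costs, random flank matches
extend an alignment block a few bases past the true junction about 10% of
the time, which mis-rotates the fragment and pairs real consensus bases with
the wrong reference positions just beyond the 4-nt end trim — a false-call
channel at the 10^-4^ level that would swamp the signal. Window placement is
immune: shifting the window by one position swaps a near-certain interior
match for a 1/4-probability flank match, so the placement is sharply peaked
at the true junction. Single indels up to 3 nt are recovered by a paired
diagonal search (head on diagonal `D`, tail on `D±g`), attempted only when no
candidate explains the fragment ungapped (best score < `P-2`), since
substitutions never break the single-diagonal window. A fragment is accepted
when the placed window reaches `min_block_identity` (default 0.9) of exact
matches; the window start fixes the rotation and the reference anchor. The
4 nt at both ends of the reorganized consensus are excluded from the assayed
mask because mapping is intrinsically ambiguous at fragment ends. Fragments
scoring within one match of the best at a second locus are non-unique and
are retained only at ncRNA loci, where identical gene copies make unique
mapping impossible. Externally produced alignments (e.g. BWA on the
duplicated consensus FASTA) can be imported from SAM; the import path applies
identical block, rotation, trimming and uniqueness logic and is tested for
agreement with the built-in mapper.

**Error calling.** Assayed counts require `q <= 1e-7` — two orders of
magnitude below the smallest transcript-error rates of interest, so that the
residual contribution of consensus miscalls is negligible; at least two
repeats, so that a single reverse-transcription error can never masquerade as
a template change. Calls and coverage are accumulated in transcript-sense
orientation (the alignment strand of the fragment, which for transcribed
regions is the sense strand). An alternative base supported by at least one
molecule but **less than 1%** of the site's coverage is a transcript error;
the boundary is strict, and an alternative at or above 1% marks the site as a
putative genetic variant. Variant sites are removed from the denominators as
well as from the calls — they are not assayable for transcription errors, and
keeping their coverage would bias rates downward at polymorphic loci (the
converse choice changes desk-scale rates by well under a percent). For ncRNA
genes, paralogous copies are clustered at ≥ 90% global identity and an
alternative equal to the aligned base of another copy is excluded as
cross-mapping. Site coverage must exceed 100 for any call to survive the 1%
rule, so meaningful runs need per-site coverage in the hundreds.

**Rates and spectra.** The error rate of a region is the number of erroneous
molecules divided by the nucleotides assayed there (each supporting call is
one molecule; a site with `k = 2` contributes two errors). Conditional
substitution rates `e(X→Y)` divide the X→Y molecule count by the coverage of
assayed X sites, on the RNA sense strand. Reference bases with zero assayed
coverage give missing rates, never zero. Indel events pass the same strict
1% site filter and share the assayed-nucleotide denominator, so the
indel-to-substitution ratio is directly comparable.

## Downstream statistics

**Effect classification** compares reference and error codons under the
genome's NCBI translation table, which is a required parameter: bacterial
table 11 is *not* safe universally (Mollicutes such as *M. florum* use
table 4, where UGA encodes tryptophan, turning many would-be nonsense calls
synonymous). Start-codon changes that destroy the initiator are
`start_loss`; stop-codon changes are `stop_loss`; both are tallied as
"other" outside the three printed classes.

**Expected effect percentages** under random error generation weight the 9
single-base changes of each codon by `μ_j = e_j / Σe_j` from the measured
spectrum, take the effect-indicator expectation per codon, and average over
codons by usage `P_i` (computed over all valid CDS, sense strand, stops
included). A reference stop codon mutating to a coding codon counts as
"other" (stop loss); a stop mutating to another stop is synonymous.
Start loss is positional and therefore not representable in a per-codon
expectation. The implementation is checked exactly against an exhaustive
64 × 9 enumeration oracle.

**Per-gene enrichment** uses the expected count `λ = rate × coverage` and the
upper-tail Poisson probability `P(X ≥ k)`, Bonferroni-corrected over the
number of genes with at least one detected error. That denominator matches
deep-coverage data, where nearly every expressed gene carries some error; at
sparse coverage it under-counts the hypothesis family and the procedure
becomes anti-conservative (family-wise error up to `α × n/m`). The
calibration test therefore runs in the deep-coverage regime (mean `λ ≈ 2.5`);
the limitation is inherent to the correction choice, not to this
implementation.

**Nonsense-error positional analysis.** Each assayed CDS site strictly
upstream of the original stop contributes its distance to the stop (nt from
the stop codon's first base, counting upstream along the mRNA), coverage and
nonsense-molecule count; frequencies are pooled across genes per distance.
A 100-nt sliding window (step 1 nt) serves visualization only. Two
normalizations address composition confounders: dividing by the all-error
frequency, and dividing by the coverage-weighted abundance of one-off codons
(non-stop codons one substitution from a stop under the applicable table).
The trend test is a weighted least-squares regression of the unbinned
per-distance frequencies on distance, with weights `1/variance` and the
binomial variance estimated as `p(1-p)/n`. At `p = 0` the variance is
estimated with the continuity-corrected `p̃ = (k + 0.5)/(n + 1)` so weights
stay finite. The weights are informative when per-point expected counts
reach the tens; far below that, estimated inverse-variance weights are noisy
and nominal CI coverage degrades for any implementation — the calibration
test uses ~50-100 counts per point.

**Contamination bound.** Low-frequency genetic mutations arising over `g`
generations of culture growth inflate the apparent transcript-error rate by
`μ·g` per site (transcribed size and expression cancel); the reported
fraction is `μ·g / rate`, typically 0.1-1% for bacterial mutation rates and
~30 generations.

## The simulator

`sim_config()` defaults encode the study conditions: 300-nt single-end
reads; fragment lengths lognormal with median ~60 nt, clamped to
[25, 150] nt; reverse-transcription errors at 10^-4^ per nt per repeat;
per-cycle mean quality declining linearly Q38→Q28 with Gaussian jitter
(σ = 3, clamped to [2, 40]) — a generic Illumina-like profile, as no
empirical profile is prescribed; transcript errors at 10^-5^ per site with a
C→U-biased spectrum (weight 10 for C→U, 2 for the other transitions, 1 for
transversions); indel errors off by default. Transcript errors are planted
per molecule (shared by all repeats), RT errors per repeat position, and
sequencing errors per cycle; every event is recorded in a truth table from
which each read can be reconstructed byte-exactly (a test does exactly
that). The simulated genome — 20 CDS of 600 nt, a duplicated rRNA-like pair
at 98% identity to exercise the paralog filter, two tRNA-like genes,
lognormal expression (σ~log~ = 0.6) — is desk-scale: with 10^5^ reads it
yields ~5 × 10^6^ assayed nucleotides at per-site coverage of several
hundred, enough for the 1% frequency filter to behave as in deep real data.

What the simulator does **not** model: GC- or position-dependent coverage,
ligation bias, rRNA-depletion chemistry, RNA secondary structure effects,
antisense transcription, and (by default) damage-induced deamination.
Passing the end-to-end tests therefore demonstrates correctness of the
inference chain under the stated causal model, not robustness to every
artifact of real libraries.

## Numerical and design choices

- Coordinates are 1-based inclusive throughout, the R/Bioconductor
  convention, in code and in output.
- Posterior ties and all-N columns yield `N` (excluded), never an arbitrary
  base.
- `f(P)` ties prefer the smallest period; window-placement ties prefer the
  smallest offset.
- The strict `< 1%` frequency rule means a site needs coverage above 100
  before any call can survive; windows with under 10^4^ assayed nt are
  blanked in the sliding-window track (threshold exposed as a flag).
- Zero-error rates report a one-sided 95% upper bound of `3/assayed`
  (rule of three) instead of pretending precision.
- Problem sizes in the tests (10^5^ reads for the end-to-end checks, 1000
  replicates for the calibration checks, depth ≤ 5 for exact posterior
  enumeration) keep the full suite under a few minutes while leaving the
  statistical assertions well-powered.

## Known limitations

- Reads whose doubled period outscores the fundamental one (a few percent,
  caused by mid-read technical errors) are discarded at the mapping stage
  rather than rescued.
- Indel events within four nucleotides of the fragment ends fall in the
  trimmed region and are not counted, biasing the indel rate slightly
  downward (the same trim protects substitution calls from junction
  ambiguity).
- The Bonferroni family of the enrichment test is the set of genes with
  detected errors; see above for its behavior at sparse coverage.
- One fragment is assumed to produce one read; molecule-level deduplication
  of optical/PCR duplicates is upstream of this package.
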