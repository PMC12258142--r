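---
title: "Consensus SV and copy-number calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SV and copy-number calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svconsensus)
```

## The problem

Somatic structural variants (SVs) and copy-number variants (CNVs) in tumor
genomes are called by many algorithms with notoriously low agreement:
split-read, discordant-pair and assembly-based callers each miss different
events and produce different false positives. A standard remedy is to run
several callers and keep the calls they agree on, since consensus calls
carry far fewer false positives. `svconsensus` implements that consensus
step in a caller-agnostic way: it standardizes heterogeneous SV call files
to oriented breakend pairs, merges related calls into consensus SVs with a
caller-support confidence, derives a genome-wide consensus copy-number
profile from per-caller segment tables, and scores each caller's
concordance with the consensus. A seeded simulator of multi-caller output
supports recovery testing without any external data.

## The SV data model

Every SV is a pair of *breakends*: (chromosome, 1-based position,
orientation). Orientation `"+"` means the sequence 5' of the breakpoint
(to its left) is retained in the derivative chromosome; `"-"` means the 3'
side is retained. This matches the common BEDPE strand convention, so a
deletion-type junction is `(+,-)`, a tandem-duplication-type junction
`(-,+)`, an inversion `(+,+)` or `(-,-)`, and any interchromosomal pair a
translocation (TRA). The type is *recomputed from this geometry* rather
than voted from caller labels, because labels disagree across callers
while the standardized geometry does not. Insertions are the exception: a
single-locus insertion has no second-breakend geometry, so a
caller-declared `INS` label is carried through standardization untouched
and insertions only ever merge with other insertions.

VCF breakend (BND) records encode the same orientations in bracket
notation; the four shapes map as `t[p[` → `(+,-)`, `t]p]` → `(+,+)`,
`]p]t` → `(-,+)`, `[p[t` → `(-,-)`. Mated BND records are collapsed to
one pair by reciprocal coordinate matching (so MATEID-less dialects still
parse); unmated breakends — as emitted by some assembly-based callers —
are dropped and counted in the parse report. Symbolic records
(`<DEL>`, `<DUP>`, `<INV>`, `<INS>`, `<TRA>`) are converted using the
orientation table; symbolic `<INV>` records carry no bracket geometry, so
their orientation defaults to `(+,+)` (configurable via
`sv_dialect(inv_orient=)`), and a Delly-style `CT=3to5` connection-type
INFO field is honoured when present (`3` → `"+"`, `5` → `"-"`).

Breakend pairs are kept in canonical order — breakends sorted by
(chromosome rank, position), orientations travelling with their breakends
— which makes merging order-independent.

## Consensus SV merging

Two canonical calls are *related* when they agree in both chromosomes and
both orientations and each breakend's positions differ by at most the
window `w` (default **150 bp**, compared inclusively: a 150 bp offset is
related, 151 bp is not). Relatedness is grouped into clusters by
**single-linkage connected components**: a chain of related calls forms
one cluster even if its extremes are farther apart than `w`. Single
linkage is the simplest aggregation consistent with a symmetric pairwise
relation; its behaviour is pinned by an independent brute-force
all-pairs graph oracle in the test suite, so the transitivity semantics
are explicit rather than incidental.

Each cluster collapses to one consensus SV:

* **position** — per breakend, the statistical mode of the member
  positions; among tied modes the smallest position wins. When no
  position repeats at all the sample is amodal and the mode degenerates;
  taking the "smallest tie" there would systematically pick the minimum
  and bias every consensus breakend left by roughly 1.2 jitter standard
  deviations, so the collapse falls back to the lower median, which is
  central, deterministic, and identical to the smallest-tie answer for
  two members.
* **confidence** — the number of *distinct* callers contributing;
  duplicate calls from one caller count once (confidence reflects
  independent sources) but remain members.
* **type** — re-derived from the shared chromosomes and orientations
  (or `INS` if the cluster is insertions).

Consensus SVs supported by fewer than `min_support` callers (default
**3**) are dropped. The result is sorted by (chromosome rank, position)
and is invariant — byte-for-byte in the writers — to the order of callers
and of calls within callers.

## Consensus copy number

Per-caller CN segment tables (chrom, start, end, CN; 1-based inclusive
after import) are combined in five steps:

1. **Expansion.** Every segment grows `pad` bp (default **5000**) on each
   side, absorbing small boundary disagreements between callers.
2. **Equal division.** Where the expansions of two neighbouring segments
   of one caller overlap, the overlap is divided equally at its integer
   midpoint (left side keeps `floor((ov_start+ov_end)/2)`). Division is
   performed before clamping to the chromosome, which makes it equivalent
   to assigning every base to the side of its nearer raw segment, with
   ties going left — a formulation the per-base oracle tests verify
   literally.
3. **Partition.** Per chromosome, the union of all callers' segment
   starts and `end + 1` values defines boundaries; consecutive boundaries
   delimit consensus alteration sites on which every covering caller's CN
   is constant. Uncovered genome is emitted too, with no contributions.
4. **Weighting.** The consensus CN of an interval is the arithmetic mean
   of the contributing callers' values. Because every caller is constant
   per interval, this equals proportion-weighting the CN states of any
   coarser region, and — the normative contract — equals the per-base
   mean over covering callers at every single base. Intervals covered by
   no caller get `default_cn` (default **2**, the diploid state).
5. **Smoothing.** Adjacent intervals whose consensus CN differs by at
   most `smooth_tol` (default **0.1** CN units) merge into one interval
   carrying their length-weighted mean, repeated to a fixed point. Each
   merge conserves total length × CN exactly. The tolerance-merge is this
   package's concretization of profile smoothing; it is deliberately
   conservative (mass-preserving, no re-segmentation).

**Caller concordance** is computed *before* smoothing (smoothing discards
per-caller contributions). For caller *t* over the intervals it covers,
with deviation `d_i = cn_t,i − consensus_i` and interval lengths as
weights: *bias* is the weighted mean of `d_i` (signed — does the caller
call high or low?) and *volatility* the weighted standard deviation of
`d_i` around the bias (how consistently?). For cross-caller comparison,
`|bias|` and volatility are min-max scaled to [0, 1]; when all callers
tie the scaled value is 0.

## Purity and ploidy

When several tools provide a tumor purity/ploidy solution, the Sequenza
estimate is preferred, then PURPLE's, then whatever is available —
a fixed, deterministic preference order rather than any averaging.

## The simulator

`sim_config()` defines the study conditions the recovery tests run under:
one 10 Mb chromosome, 100 truth SVs (mix DEL 0.4 / DUP 0.3 / INV 0.3;
translocations require configuring a second chromosome, so the
single-chromosome default carries no TRA mass), a piecewise-constant
truth CN profile of ~20 segments over states {0,1,2,3,4,6}, and six
callers each with breakend jitter sd 20 bp, false-negative rate 0.1,
private false-positive rate 0.2 per truth SV, CN boundary jitter sd
1000 bp and CN value noise sd 0.1. The SV noise parameters are the
conditions the recovery properties are stated at; the CN noise defaults
are chosen once as realistic magnitudes for segmentation disagreement
(boundaries of real callers disagree by hundreds of bases to kilobases;
ratio-derived CN values wobble by about a tenth of a copy).

Truth breakends are placed uniformly but with pairwise separation greater
than twice the merge window, so cluster membership is unambiguous and
recovery failures cannot be blamed on the truth set. Private false
positives are placed more than twice the window away from every truth
breakend and are caller-exclusive by construction, which makes the
min-support filter's effect provable: a private call can never reach
support 3, so consensus precision is exactly 1 under these conditions.
All randomness flows from one root seed through named substreams (truth,
caller *i* SV, caller *i* CN), so adding a caller to the panel never
perturbs another caller's draws.

What the simulator does *not* emulate: realistic SV size and type
spectra, correlated errors between callers sharing an algorithmic family,
coverage- and mappability-dependent error rates, subclonal CN states, or
read-level evidence. Passing recovery tests therefore demonstrates the
correctness of the merging machinery under controlled noise, not the
field performance of any particular caller panel.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally (VCF-style); BEDPE and
  0-based segment input are converted exactly at the boundary, and the
  conversions are involutive.
* The window comparison is inclusive (`<= 150`), the midpoint split uses
  integer floor division, and mode/median tie-breaks always prefer the
  smaller position — every tie in the pipeline resolves deterministically.
* Empty inputs are first-class: an empty VCF yields an empty call set
  with a zeroed parse report; an empty segment table yields a
  whole-genome default-CN profile (chromosome lengths required, since
  nothing else defines the genome); an empty consensus set writes a
  header-only file.
* Overlapping raw segments within one caller are rejected as an input
  invariant violation, not silently resolved.
* A caller covering zero intervals is excluded from concordance with a
  message rather than producing NaNs.

## Problem sizes in the tests

The property tests run at deliberately small scale — clustering oracles
on up to 200 calls per instance, per-base CN oracles on genomes up to
100 kb with up to 5 callers, recovery at 100 truth SVs × 6 callers × 20
replicates — sizes at which the independent brute-force oracles
(all-pairs graph components; per-base averaging) are exact and cheap.
The merging code paths are size-independent, so these scales exercise
every branch the genome-scale inputs would.

## Known limitations

* Single-linkage chaining means a dense run of calls can merge into one
  consensus spanning more than the window; this is inherent to the
  aggregation semantics, is covered by the oracle tests, and matters
  mainly at window values far above the default.
* The smoothing step summarizes `n_callers` of merged intervals as a
  floored length-weighted mean; per-caller attribution is not preserved
  through smoothing (use the pre-smoothing profile for attribution).
* Breakend-level refinement against the consensus CN profile, genotype
  merging, per-caller weighting schemes and allele-specific CN are out of
  scope.

## A worked example

```{r example}
cfg <- sim_config(seed = 42)
sim <- simulate_callers(cfg)
cons <- merge_svs(lapply(sim$callers, `[[`, "sv"),
                  merge_params(window = 150, min_support = 3),
                  rank = names(cfg$chrom_lengths))
evaluate_consensus(cons, sim$truth$sv)[c("precision", "recall")]

segs <- do.call(rbind, lapply(sim$callers, `[[`, "cn"))
res <- consensus_cn(segs, cn_params(chrom_lengths = cfg$chrom_lengths))
head(res$concordance)
```
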