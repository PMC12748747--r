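---
title: "Strand-resolved duplex analysis of double-strand break repair: models and methods"
author: "duplexrepair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved duplex analysis of double-strand break repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexrepair)
```

## The problem

A chromosomal double-strand break (DSB) is really two single-strand breaks,
one per strand. When nonhomologous end joining (NHEJ) repairs a DSB, there
are a priori only two ways to finish the job:

* **Model 1 — parallel, symmetric.** Each strand break is ligated
  independently and near-simultaneously. Each strand keeps its own terminal
  bases, so designed terminal mispairs survive into the product, one per
  strand.
* **Model 2 — ordered, semi-conservative.** One strand break is repaired
  first; the sealed strand then serves as template for synthesis-dependent
  repair of the second. The second strand's junction is the complement of
  the first strand's product, not an independent outcome.

Distinguishing the two requires *single-molecule, strand-resolved* readout:
bulk qPCR cannot tell a population of fully repaired duplexes from a
mixture of top-only and bottom-only molecules. This package implements that
readout for designed extrachromosomal DSB substrates:

1. a 5-nt fully mismatched **strand-ID** region identifies which physical
   strand each read came from;
2. a double-stranded sequencing adapter carries a **10-nt UMI** shared by
   both strands of one duplex molecule, so top and bottom reads with the
   same UMI came from the same molecule, and the *absence* of an
   opposite-strand read under a UMI is evidence that only one strand was
   joined;
3. a closed set of **reference junctions** — direct ligation, templated
   +C/+TC/+CTC insertions, and semi-conservative copies of each opposite
   product — makes junction classification an exact matching problem rather
   than free alignment.

## Substrate model and product enumeration

A substrate is two strand sequences plus two end structures (5'/3' overhang
or blunt, symmetric polarity required for head-to-tail joining) and the
strand-ID region. All coordinates are 0-based half-open on the top strand;
bottom-strand features are stored in bottom 5'→3' orientation with a
deterministic pairing map between the two frames.

Every repaired strand is represented as one fixed linearisation of the
repaired circle: the strand is cut at an interior "rotation cut" so the
head-to-tail junction sits mid-sequence. The bottom cut is the phosphate
conjugate to the top cut under the pairing map, which makes a model-2
product *literally* the reverse complement of its template strand's
rendering, up to the strand-ID substitution. The cut is chosen as close to
the middle of the strand as possible subject to (i) junction-window margins
on both strands and (ii) not splitting the strand-ID locus or its 8-nt
anchor flank on either strand.

**Junction windows.** Each reference junction comprises J/2 fixed bases on
either side of the inserted bases (J = 40 by default), so windows are
`J + insertion length` nt. We deliberately did not use a literally-J-nt
window centered on an integer coordinate: with an odd `J - insertion
length` no integer-aligned window is mirror-symmetric, whereas the
flank-anchored definition makes the model-2 invariant — every model-2
window equals the reverse complement of the opposite-strand product window
— exact for every insertion length and overhang offset. J = 40 comfortably
spans the longest designed insertion (+CTC) plus overhangs (≤ 10 nt) with
margin.

Label pairs whose rendered products are identical are recorded as
**degenerate pairs**. Because products of one strand differ only within
their junction windows, full-sequence identity is exactly
read-indistinguishability — and it also catches windows that are equal up
to the nick-offset shift. Two cases arise in the bundled substrates: on a
blunt, fully complementary substrate, direct ligation and its model-2 copy
are the same molecule; and on the GAG-3' overhang substrate the +CTC
insertion completes a self-complementary junction (GAGCTC), so the model-1
+CTC product and the model-2 copy of the opposite strand's +CTC are
identical, with only the (unobservable) ligation scar at a different
phosphate. The classifier reports the canonical joint label for such reads
rather than guessing, and molecules whose labels are degenerate between
the two paths are classed path-indeterminate.

## Synthetic data: the stated world

The simulator draws per-strand join times from exponential hazards
(continuous time, no discrete steps — the data it emulates report only
saturation behaviour):

* parallel mode: `t_top ~ Exp(k_top)`, `t_bottom ~ Exp(k_bottom)`,
  independent; each joined strand draws its product label independently.
* ordered mode: the first strand (fixed, or the winner of competing
  hazards) joins at `t1 ~ Exp(k_first)`; the second strand's clock starts
  at `t1` with hazard `k_second` and its product is forced to be the
  model-2 copy of the first strand's label.

Defaults were chosen once to match the regimes the assays report and are
not tuned to test outcomes: `k_top = k_bottom = 0.3/min` saturates direct
ligation by 10 simulated minutes (1 − e⁻³ ≈ 0.95); `k_second = 0.15/min`
saturates second-strand repair by 30 minutes; `p_ribo = 0.95` reproduces
the ~95% initial alkali sensitivity of templated +C additions; and
`k_rer = 0.018/min` lets ribonucleotide excision repair reduce that
fraction to ~61% between 5 and 30 minutes (e^(−0.018·25) ≈ 0.64). Only
inserted nucleotides can be ribonucleotides; second strands synthesised on
a repaired template are pure DNA.

Reads are emitted pre-merged (the original data were merged in external
software before custom analysis) with layout
`phasing (0–5 random nt) | barcode (6 nt) | UMI (10 nt) | constant adapter
flank | insert`, where the insert is the full rendered repaired strand.
One UMI is drawn uniformly per molecule and shared by both strands — the
double-stranded-adapter property the duplex inference depends on. Read
counts per joined strand are Poisson(`oversampling_mean`) (the per-UMI
count distribution of the real protocol is unknown; negative-binomial
overdispersion is available as an option, not the default), and errors are
i.i.d. substitutions (indel-free by default so the classification oracle
stays exact). Unjoined strands produce no reads: a junction PCR cannot
span a break.

What a green test on this world does **not** establish: robustness to PCR
jackpots and chimeras, instrument-specific quality profiles, adapter
artefacts, or indel-rich error processes — none of which are simulated.

## Read annotation

* **Demultiplexing** scans the first `barcode + 5` positions for each
  barcode within 1 substitution; tables whose minimum pairwise Hamming
  distance is ≤ 2×max_mismatch are rejected up front as ambiguous.
* **UMI extraction** locates the constant adapter flank with ≤ 1
  substitution; the 10 bases before it are the UMI, everything after is
  the insert. Failures are counted, never silently dropped.
* **Strand assignment** compares the 5 observed strand-ID bases against
  each variant (located via that strand's 8-nt anchor flank) and assigns
  only if the best variant has ≤ 1 mismatch and the margin is ≥ 2 — with
  fully mismatched 5-nt variants a single sequencing error can never flip
  the call. The data source is silent on how its original script handled
  errors here; these thresholds are our explicit stand-ins.
* **Junction calling** takes the best bounded edit-distance match
  (`max_edit = 1` by default; the source is silent) among the strand's
  reference windows; unique best wins, ties within a degenerate pair give
  the joint label, any other tie is `unclassified`. The pipeline's batch
  path deduplicates identical inserts and checks an exact match at the
  expected offset before banded DP; `call_junction()`'s default remains
  the exhaustive whole-insert infix search, and the test suite proves both
  agree with an independent DP oracle.

## Duplex reconstruction

UMI grouping is exact-match — the original analysis describes no
clustering. UMI sequencing errors therefore create spurious low-count
families, which the oversampling filter is expected to remove at realistic
coverage. Two filters, both with *strict* inequalities exactly as the
protocol states them:

1. **2% rule:** a family is excluded if its read count is less than 2% of
   the mean oversampling ratio (total reads / input template molecules).
   The input template count is an explicit parameter — measured by digital
   PCR for real libraries, taken from truth for simulations — because the
   rule is undefined without it.
2. **20% rule:** within a family, a strand is excluded if it holds less
   than 20% of the family's reads. The majority strand always holds ≥ 50%,
   so both strands can never be dropped.

Per strand the consensus is the plurality junction label (ties →
ambiguous); each surviving UMI becomes one molecule call: both-joined /
top-only / bottom-only / ambiguous, and for both-joined molecules the path
is model 1 (two autonomous products), model 2 (one label is the
semi-conservative copy of the other), or indeterminate (degenerate or
unclassified labels). Preference ratios (model 1 : model 2) exclude
indeterminate molecules from both numerator and denominator and flag —
rather than raise on — zero denominators.

**Estimating P(both strands joined).** Molecules with neither strand
joined yield no junction-spanning reads and are invisible to sequencing,
so the both-joined *fraction of detected families* overestimates the
per-molecule probability. Where the analytic recovery tests compare
against `(1 − e^(−kt))²` they divide the both-joined call count by the
known number of input templates instead. One-strand-joined classes are
reported raw, uncorrected for the (negligible at default coverage)
probability that a joined strand drew zero reads.

## Quantification formulas

* Spike-in normalised abundance: `2^-((Ct − Ct_spike) − (Ct_ref −
  Ct_spike,ref))`, with the per-cycle efficiency configurable (default 2,
  as implied by the 2^ΔCt arithmetic).
* Alkali fraction RNA: `1 − 2^(Ct_mock − Ct_alkali)`; negative values
  (noise) clamp to 0 with a warning, because the formula permits them but
  no physical fraction does.
* Droplet digital PCR: `λ = −ln(1 − positives/total)` copies per droplet;
  all strand ratios use λ ratios directly so the droplet volume (default
  0.85 nL, configurable) cancels. Saturated wells (all droplets positive)
  are flagged, not estimated.
* The bottom:top ratio reports second-strand completion: bottom strands
  complementary to the top product divided by top product copies.
* Time courses scale every value to a named reference condition (e.g. the
  most abundant product at 30 min); the cross-calibration between qPCR and
  digital-PCR scales is explicit configuration, never inferred.

## Numerical and design choices

* Strict `<` at both filter thresholds (quoted wording); boundary families
  with exactly the threshold count are retained.
* Exponential join times use R's RNG exclusively; every public entry point
  takes an optional seed and `run_pipeline()` reruns are byte-identical.
* Degenerate-label ties never silently coerce to one path; molecules whose
  labels are mutually inconsistent are classed indeterminate/ambiguous.
* The 5 strand-ID positions are required fully mismatched for
  package-designed substrates, relaxed to ≥ 1 mismatch when loading user
  substrates (the original oligo set is not reproduced here, so the
  all-different property is our constraint on synthetic designs only).
* `emulate_alkali_qpcr()` anchors the mock Ct at `40 − log2(templates)` —
  an arbitrary but fixed scale; only Ct *differences* carry information.

## Known limitations

* No base-level duplex consensus: the unit of consensus is the junction
  label, so the package does not error-correct arbitrary variants.
* No UMI clustering by default; a heavily error-degraded UMI space (error
  rates ≫ 0.5%) would fragment families faster than the 2% rule removes
  them.
* Detection dropout of joined-but-unsequenced strands is not corrected in
  reported class frequencies.
* The kinetics simulator is memoryless by construction; real repair with
  multi-step processing shows delay distributions an exponential cannot
  reproduce, which is why recovery tests compare saturation-regime
  functionals rather than full time courses.
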