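---
title: "Methods: two-library small RNA-seq miRNA profiling with goosemir"
author: "goosemir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA-seq miRNA profiling with goosemir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goosemir)
```

# The experimental design this package models

`goosemir` analyses the replicate-free two-library design that dominated
early small-RNA sequencing of non-model birds: total RNA from several
animals per physiological state (here: laying vs broody goose ovary) is
pooled into one library per state, size-selected to the 18–30 nt fraction,
ligated to 3′/5′ adapters and sequenced deeply. All inference is therefore
between two single libraries of counts — there is no within-group variance
to estimate, which drives most of the methodological choices below.

# Read cleaning

A read survives cleaning when it has a detectable 3′ adapter, no 5′
adapter contamination, and an insert of 18–30 nt that is not a poly(A)
artefact. Each discarded read is counted once under the first violated
filter in the fixed order *no 3′ adapter → 5′ contaminant → no insert →
poly(A) → too short → length out of range*, so the discard tally plus the
clean count always equals the raw count exactly.

The filters themselves are named, but not parameterised, by the upstream
literature (they were internal to the sequencing provider's pipeline), so
the package documents concrete, configurable semantics:

* **3′ adapter**: the leftmost read position where the *full* overlap with
  the adapter — `min(adapter length, bases remaining)` — matches with at
  most 1 mismatch for overlaps of ≥8 nt, exactly for 5–7 nt, never for <5.
  Requiring the whole overlap to match (not merely an 8-mer seed) makes
  accidental matches inside real inserts vanishingly rare, which is what
  lets the simulator's per-class ledger be recovered exactly.
* **5′ contaminant**: the read starts with the first 8 nt of the 5′
  adapter, exactly.
* **no insert**: trimmed insert length 0 (adapter dimer).
* **poly(A)**: insert with ≥80 % adenine.
* **length**: inserts <18 nt are `too_short`; because the sequenced size
  range was 18–30 nt, inserts >30 nt are discarded under the sibling key
  `length_out_of_range`.

# Annotation and known-miRNA quantification

Every unique tag receives exactly one category by the priority rule
*rRNA etc. (GenBank > Rfam) > known miRNA > repeat > exon > intron*, with
`unannotated` for no match. Contaminant matching is a plain substring
match against the contaminant reference, split by a `source=` tag in the
FASTA headers; covariance-model scanning and genome mapping are out of
scope (no goose genome existed for the original analysis, which borrowed
the chicken genome only for distribution summaries; this package matches
directly against the supplied references instead).

A tag is attributed to a mature miRNA when it aligns without gaps to the
precursor at a start within ±2 nt of the mature 5′ end, ends within ±2 nt
of the mature 3′ end, and has at most `tolerance` mismatches (default 1,
mirroring the one-mismatch mapping tolerance of such pipelines; with
`tolerance = 0` the simulator's planted counts are recovered exactly).
A tag equidistant from several matures goes to the lexicographically
smallest ID and is flagged ambiguous — deterministic and auditable.
miRNA *families* are defined by an identical seed (mature positions 2–8);
the upstream literature reports families without defining them, so the
seed — the region that drives targeting — is the natural grouping.

# Hairpin folding and the seven criteria

Novel-miRNA discovery folds candidate precursor windows around
transcriptome-anchored tags. The folding engine is a single-hairpin
dynamic programme over chains of nested pairs (A:U, G:C, G:U): one
terminal loop, bulges and internal gaps allowed, no multiloops or
pseudoknots — every accepted candidate in this literature is a plain
stem-loop. The energy model is a deliberately small constant table
(kcal/mol, all configurable via `hairpin_energy_params()`):

| term | value |
|---|---|
| stack of two G:C pairs | −3.0 |
| stack of G:C with A:U | −2.4 |
| stack of two A:U pairs | −1.8 |
| any stack involving G:U | −1.2 |
| terminal-loop closure | +4.0 |
| per bulged side between pairs | +3.0 |

with a minimum terminal loop of 3 nt and interior gaps capped at 30 nt per
side. The loop-closure penalty is charged once for any folded structure,
so a structure is only reported when its stacks pay for the loop — the
returned energy is always ≤0, and a lone G:U helix can never beat the open
chain. Ties are broken toward more base pairs, then toward the 5′-most
loop, making the fold fully deterministic. The DP is verified against
explicit enumeration of *every* single-hairpin structure for all sequences
up to 12 nt (≈22 million sequences) plus random longer sequences; both
implementations live in `src/` and share only the energy table. An
external thermodynamic engine (e.g. a ViennaRNA-style folder) can be
substituted by scoring structures with a different parameter set; the
−20 kcal/mol acceptance threshold then applies to whichever engine is
configured.

The seven acceptance criteria, with inclusive bounds except where noted:
stem pairs ≥18; largest one-sided bulge ≤18 nt (as printed in the source
criteria — anomalously permissive, likely a typo there, but implemented
as stated and configurable); energy strictly < −20 kcal/mol (an equality
at −20.0 fails; a 1e-6 kcal/mol guard keeps floating-point sums from
leaking across the strict boundary); ≥80 % of the mature inside the stem
region (positions covered by the pair chain on either arm); hairpin span
(outermost pair, i.e. both stems plus loop) ≥53 nt; terminal loop ≤22 nt;
mature A+U fraction in [30 %, 70 %].

Discovery considers, for each supported tag occurrence (pooled support ≥5
reads), two windows — tag on the 5′ arm extending 120 nt downstream, and
tag on the 3′ arm extending 120 nt upstream, clipped at transcript ends —
folds both, and keeps the lowest-energy window passing all seven criteria.
The reported precursor is trimmed to the folded hairpin (outer pair span,
extended to cover the mature), so identical precursors planted in
different transcripts merge into a single candidate listing every locus.
Tags already claimed by the contaminant or known-miRNA categories are
excluded; transcriptome-matching ("exon") tags are exactly the discovery
substrate, matching the original workflow in which novel prediction ran on
the remaining sequences aligned to the transcriptome.

# Differential expression

Normalised expression is reads per million clean reads,
`NE = count / N × 1e6`. A zero NE is floored to 0.01 so fold changes stay
finite; features with NE < 1 in both libraries are excluded from testing.
The fold change is `log2(NE_broody / NE_laying)`.

The test statistic is the Audic–Claverie posterior-predictive probability
for two libraries of unequal depth. Three numerical/definitional choices:

* **Counts, not floored NE.** The statistic's legend in this literature is
  phrased in terms of "normalized expression", but the formula is defined
  on counts, and a floored pseudo-value of 0.01 is not a valid count; the
  package feeds raw counts `x, y` with the library totals carrying the
  depth correction.
* **Two-sided by tail doubling.** Both up- and down-regulation are called
  at one threshold, so the observed-direction tail (`y′ ≥ y` when `y`
  exceeds its depth-scaled expectation `x·N2/N1`, `y′ ≤ y` otherwise) is
  doubled and capped at 1.
* **Canonical orientation.** The predictive tail is not exactly symmetric
  under exchanging `(x, N1) ↔ (y, N2)` when `N1 ≠ N2` (the swapped pmf
  differs pointwise by the constant `N1/N2`). Users rightly expect the
  answer not to depend on which library is "first", so the implementation
  canonicalises the orientation — smaller library first, ties broken by
  the smaller count — before computing the tail. The statistic is thereby
  exactly exchange-symmetric by definition.

Evaluation is in log space with `lgamma`; the upper tail terminates when a
term falls 40 nats below the running maximum (a relative truncation below
4e-18, far inside the 1e-10 oracle tolerance). Calls: `up` if `P ≤ 0.01`
and fold change >0, `down` if <0; the boundary is inclusive. No
multiple-testing correction is applied to the calls, matching the original
single-threshold practice; a Benjamini–Hochberg q-value column is emitted
for information. The `2^-ΔΔCt` helper implements the standard relative
quantification arithmetic for qPCR validation; the wet-lab assay itself
and replicate t-tests are out of scope.

# Target prediction

Sites are sought by scanning every window of every transcript against each
differentially expressed miRNA — exhaustive and heuristic-free, chosen for
correctness at desk scale; the compiled scanner prefilters windows by
mismatch score before the full rule report is built in R. Duplexes are
ungapped (the governing rules never mention target bulges). Per position,
the state is Watson–Crick match, G:U wobble (0.5 mismatches) or mismatch
(1). The elliptical positional phrases of the plant-miRNA criteria are
interpreted as ranges, following the Allen/Schwab conventions they cite:
"positions 2, 12" means the span 2–12, "positions 1, 12" the span 1–12,
and "positions 10, 11" exactly those two positions (which must be perfect
Watson–Crick matches — a wobble is half a mismatch, hence not "no
mismatch"). For adjacency rules a G:U counts as a non-match state while
still scoring 0.5. The strict criterion (total score ≤2) is applied on top
of rules 1–5 — the source text is ambiguous about whether it replaced
them, so all are evaluated and each is independently switchable via
`target_rules()`.

Duplex energies reuse the hairpin stacking table in intermolecular form:
stacks form only between adjacent Watson–Crick matches (mismatches and
wobbles break the helix), and no initiation term is included because it
cancels in the ratio. A site passes when
`MFE(duplex) / MFE(perfect complement) ≥ 0.75`, boundary inclusive.
Overlapping accepted windows of one miRNA on one transcript are merged to
the best score, ties to the lowest start.

# Enrichment

For each term: `N` = genes with at least one annotation in the supplied
map (the annotated universe, not the whole transcriptome), `n` = distinct
target transcripts within it, `M` = genes annotated to the term, `m` =
targets among them; the raw p-value is the upper-tail hypergeometric
probability `P(X ≥ m)` (enrichment, not depletion), computed with R's
exact distribution function. GO terms are used flat, as given — no DAG
propagation. Corrections: Bonferroni `min(1, k·p)` for GO and
Benjamini–Hochberg FDR for pathways, each flagged at the historically used
— and unusually lenient — threshold of ≤0.5, inclusive and configurable.

# The synthetic experiment

The generator produces the study conditions end to end: two libraries
(default 100,000 reads each — the lower end of the emulated depth range,
sized so a full run plus its reruns stay interactive on one core), 50-nt
reads of insert + 3′ adapter, inserts of 19–24 nt with mode 22, ~15 %
contaminant small RNAs (rRNA/tRNA/snRNA/snoRNA fragments tagged
GenBank/Rfam), ~12 % junk split evenly across the six filter classes, 60
known miRNAs of which 16 carry planted log2 fold changes of ±2, three
novel hairpin precursors embedded mid-transcript, and one perfect
antisense target site per regulated miRNA in the final 150 nt of a
transcript (a 3′UTR-like region). Everything derives from one seed.

Three design rules make the ground truth exact rather than approximate:

* **Self-validation by the downstream predicates.** Planted hairpins must
  pass all seven criteria under the package's own fold (including the
  windowed fold used by discovery); planted target sites must pass the
  package's own rule report and MFE filter; junk reads are rejection-
  sampled until the package's own classifier assigns exactly the intended
  filter class. No private copies of any acceptance rule exist in the
  generator.
* **Exact conservation.** Per-feature counts are gamma-Poisson weights
  (`count_noise` is the squared coefficient of variation; 0 gives
  deterministic weights, i.e. Poisson-like allocation) turned into counts
  by a single multinomial draw conditioned on the configured library
  total, so provenance counts always sum exactly to the library size.
* **A diffable ledger.** Feature-level truth (per-miRNA counts and true
  fold changes, hairpin loci, target sites, per-class read counts) is one
  plain TSV; the bundle manifest carries an MD5 per file.

What the generator does *not* emulate: per-cycle sequencing error and
quality scores (all qualities are "I"; low quality exists only as junk
classes), ligation and PCR biases, isomiR 5′/3′ heterogeneity, genuine
repeat/intron categories, and secondary-structure realism beyond the
package's energy model. Passing tests therefore demonstrate algorithmic
correctness and exact bookkeeping on idealised reads — not robustness to
the measurement noise of real libraries.

A note on calibration versus realism: the Audic–Claverie statistic is
exact under Poisson sampling, and the null-calibration test (5,000 null
features at depth 10^6) confirms ≤2 % of nulls at `P ≤ 0.01`. With
biological overdispersion (`count_noise` > 0) and deep counts, however,
the exact test becomes sharply anti-conservative — in the default
simulation most non-planted miRNAs also reach significance. This mirrors
the behaviour of replicate-free exact tests on real pooled libraries and
is intentional: the package reproduces the historical method, it does not
fix it. Analysts with replicates should use a dispersion-aware model
instead.

# Problem sizes and runtime choices

Defaults were chosen so that the full pipeline (2 × 100,000 reads) runs in
seconds and the complete verification — including the exhaustive
enumeration sweep over all ≤12-nt sequences — in a few minutes on one
core. The test fixture uses 2 × 10,000 reads, which keeps every planted
feature comfortably above the discovery support threshold.

# Known limitations

* No replicate-aware inference (see above); the statistic is the
  historical two-library exact test.
* The energy model is a qualitative surrogate for a full thermodynamic
  nearest-neighbour parameterisation; absolute energies (and hence the
  −20 kcal/mol screen) are engine-dependent.
* Annotation matches references exactly or with small tolerance; there is
  no genome mapping, repeat library, or Rfam model scanning.
* Target prediction is ungapped and ignores site accessibility and
  3′UTR annotation (the whole transcript is scanned).
* GO enrichment ignores term hierarchy.
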