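---
title: "Methods: score-based tRNA modification detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: score-based tRNA modification detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnamod)
```

This vignette is the package's account of its methods: the statistics it
computes, the conventions and defaults it fixes where upstream descriptions
leave room, and what its simulation-based tests do and do not establish
about real data.

## Inputs and coordinates

The unit of analysis is an adapter-flanked mature tRNA: the reference
presented to the aligner is `adapter5 + body + adapter3`, because library
preparation ligates splint adapters to both tRNA ends. Adapter sequences
are experiment-specific configuration; the package never assumes them (the
simulator ships arbitrary fixed ones so fixtures are self-contained). All
reported positions are 1-based and inclusive on the tRNA *body*; internal
full-sequence coordinates are 0-based half-open. Sequences are accepted in
RNA or DNA alphabet and stored internally as DNA (U → T); single-base
columns of outputs report RNA. Annotation positions like `"20.1"` denote
bases inserted relative to canonical tRNA numbering; they are carried as
opaque labels and excluded from coordinate arithmetic, since computing
canonical numbering from an alignment is out of scope.

## Alignment and the three-rule filter

Reads are aligned all-against-all to the references with an affine-gap
local aligner (Smith–Waterman–Gotoh, implemented in C++). A gap of length
$L$ scores $g_{open} + (L-1)\,g_{ext}$. The default scheme is match $+2$,
mismatch $-1$, gap open $-2$, gap extend $-1$; the minimum alignment score
(AS) cutoff of 50 is scheme-relative, so both are exposed together. Because
an optimal local alignment is generally not unique, tie-breaking is fixed —
best cell with smallest reference end, then smallest read end; traceback
prefers the diagonal — so outputs are bit-reproducible.

Filtering applies three rules in order: (i) per read, keep only the
alignment(s) tied at that read's maximal AS (ties on several references are
retained on all of them and flagged, since a multi-mapping tRNA read has no
single home); (ii) drop alignments with AS < 50; (iii) keep only
*full-length* alignments. Full length is not defined upstream; here it
means the alignment's reference span covers every body position, with a
configurable tolerance of uncovered bases at each end (default 0). The
rationale is that downstream per-position statistics need uniform body
coverage, and truncated nanopore tRNA reads would otherwise bias 5'
positions. Direct-RNA reads are single-stranded, so only forward-orientation
alignments are meaningful and reads are aligned as given.

## Score extraction

Modification callers emit, per read, a score $\lfloor 255\,p\rfloor$ at
each position basecalled as the model's canonical base, withholding scores
below the 5% emission threshold ($\lfloor 255 \times 0.05\rfloor = 12$).
Scores travel in SAM MM/ML base-modification tags; the decoder resolves MM
skip counts against canonical-base occurrences in sequencing orientation
and honors both `?` and `.` skip semantics (the encoder writes `?`,
matching caller behavior: an unaddressed base carries no information, and
withheld sub-threshold scores are represented by absence).

Projection onto the reference keeps **matched positions only**: a
mismatched basecall has no prediction score for the reference canonical
base, and insertions/deletions have no reference home. Each site therefore
tracks two counts: `n_matched` (filtered reads with a sequence match at the
position) and `n_scored` (those with an emitted score), with
`n_scored ≤ n_matched`.

## De novo Ψ calling

The per-site fraction statistic is
$f = \#\{\text{scores} > 204\} / N$ with $204 = 255 \times 80\%$ and a
strictly-greater comparison. The denominator $N$ is ambiguous upstream
("all reads"); the package's default is **all matched reads**, counting
matched-but-unscored reads as unmodified — justified because a withheld
score is by construction below 5% probability. The alternative
(`denominator = "scored"`) is exposed because both readings are defensible;
the choice materially changes fractions when many scores are sub-threshold.

A site is called Ψ when $f \ge 0.2$; the boundary is inclusive (upstream
wording does not fix strictness, so the convention is documented and
configurable). The 0.2 operating point is chosen from the threshold curve:
the percentage of annotated vs non-annotated U sites exceeding each
candidate cutoff, both non-increasing in the cutoff. A per-site minimum of
20 matched reads (configurable) guards fractions against tiny denominators;
upstream is silent at the per-site level, and 20 bounds the binomial
standard error of $f$ at ≤ 0.11. ROC AUC uses the midrank Mann–Whitney
statistic, identical to the exhaustive pairwise comparison with ties
counting one half.

## Off-label detection with symmetric KL divergence

Per-site emitted scores (support [12, 255]) are binned into 10 equal-width
half-open bins spanning $[11, 256)$ (width 24.5). Smoothing adds a
pseudocount of 1 to every bin before normalization:
$p_i = (c_i + 1)/(n + 10)$. Two sites are compared with
$D_{KL}(P\|Q) + D_{KL}(Q\|P)$ in natural-log units.

Three numerical choices are the package's own, flagged for sensitivity
analysis because upstream does not state them:

* **Zero bins.** KL is undefined when $Q(x) = 0$; the +1 pseudocount is the
  minimal standard fix and keeps the statistic finite. Tests verify that as
  the pseudocount shrinks (1 → 0.1 → 0.01) the statistic converges to the
  unsmoothed value whenever all bins are occupied.
* **Log base.** Natural log; any other base rescales all values uniformly
  and does not affect rankings.
* **Coverage gate.** The minimum coverage of 100 is applied per tRNA per
  sample, using filtered full-length read counts, plus at least one emitted
  score per site in both samples. Histograms use emitted scores only
  (`n_scored`), since the stated support excludes sub-threshold absences.

Min–max normalization for display is grouped per model across the compared
tRNA set by default (comparable panels across models), with per-tRNA
grouping available. Model integration assigns each body position the
divergence of the caller matching its canonical base (U→Ψ, A→m6A, C→m5C);
G positions stay empty because no G-targeting model exists.

## Error-score outliers

An external error-profiling tool supplies one score per position; the
package applies Tukey's fences: outliers strictly exceed
$Q_3 + k\,\mathrm{IQR}$ with $k = 1.5$, quartiles by linear interpolation
(`stats::quantile` type 7 — the estimator is not specified upstream, so the
common default is used and exposed). Reported calls additionally require
score ≥ 10, a floor calibrated on non-U basecalling-error outliers. The
fence population defaults to all positions of all tRNAs in the comparison
(`scope = "global"`); a per-base-identity scope is offered because the
floor's calibration is base-dependent. The external statistic itself is not
reimplemented; `error_score_from_alignments()` is a clearly non-equivalent
internal stand-in (arcsine-stabilized per-site error-rate difference
between samples) provided so the outlier caller is testable end to end.

## Signal extraction

The basecaller's move table assigns each basecalled nucleotide a contiguous
signal segment whose length is a multiple of the model stride (6).
Segments of aligned positions only (matches and mismatches) are kept;
each is reduced to six values at indices $\lfloor iL/6 \rfloor$,
$i = 0..5$ — exactly one value per $L/6$ block, which is why
endpoint-inclusive spacing was rejected. To overlay two samples, the
vertical shift is the per-tRNA median over common positions of the
difference in per-position median signal, computed as sample A (wt) minus
sample B (mutant) and added to the mutant for display; the sign convention
is fixed by explicit argument roles and recorded with the output, since
"difference" alone is ambiguous. Signal units pass through untransformed;
re-segmentation of reads lacking a move table is out of scope. Signals are
exchanged via a plain TSV sidecar (read → signal array + move vector).

## The simulator

The simulator emulates every upstream input under one seed: random
adapter-flanked references; reads with independent per-base substitutions
(default 2%), indels (1%, split between insertion and deletion) and
5'-truncation (10%, guaranteeing a full-length-filter failure); per-read
score tracks; and stride-6 signals with Gaussian noise around per-base
levels. Score mixtures are discretized Betas: unmodified Beta(1, 20)
(low mode), on-label modified Beta(20, 1) (high mode), off-label
"abnormal" 0.5 Beta(4, 4) + 0.5 Beta(8, 2) (broad mid-range). These shapes
reproduce the qualitative low/high/abnormal score-distribution patterns of
real callers and are not fitted to data. Neighbor interference couples
sites within a read: when a read is modified at an interfering site, scores
at the configured offset positions are redrawn from an interference
distribution, emulating bulky modifications that confuse the caller at
adjacent uridines.

What the simulator does **not** emulate: sequence-context-dependent caller
accuracy, correlated errors (homopolymer slips, systematic miscalls around
modified bases other than the modeled interference), partial-modification
bimodality beyond what a stoichiometry parameter induces, pore-physics
signal structure, and real k-mer level tables. Passing tests therefore
demonstrate the *statistical machinery* — recovery of known mixtures,
ranking of perturbed sites, correctness of each transform — not caller
accuracy on real tRNA.

## Test and verification sizes

The test suite and acceptance script run at desk scale, sizes chosen so the
relevant standard errors are small relative to the tested margins: oracle
equivalence of the aligner on 1000 random pairs ≤ 12 nt against an
exhaustive pure-R dynamic program; Tukey fences against a sort-based
quantile oracle (1000 cases); ROC AUC against the pairwise oracle (≤ 8
sites, tie-prone integer scores); KL against direct summation on random
simplexes. Stoichiometry recovery uses 500 reads at π = 0.5 with a
3-standard-error band around the analytic mixture expectation
$\pi(1-F_1) + (1-\pi)(1-F_0)$ evaluated at score > 204 ⇔ p ≥ 205/255.
Off-label detection uses 100 seeded wt-vs-knockout replicates at 500
reads/sample on a 70-nt tRNA, requiring the modified site to rank first on
its tRNA in ≥ 95% of replicates. The neighbor-interference check places the
site at position 34 in a U-rich window and requires elevation at 34 ± 1 but
not beyond ± 2.

## Known limitations

* The AS ≥ 50 cutoff is inherited as a default; its calibration is not
  reproduced here and it should be revisited for scoring schemes other than
  the default.
* The coverage gate (100 per tRNA) makes low-expression tRNAs invisible to
  the KL comparison by design; there is no partial-coverage fallback.
* The symmetric KL statistic has no significance calibration — records are
  ranked, min–max normalized for display, and interpreted relative to the
  same tRNA's background, not tested against a null.
* Bimodality at partially modified sites is visible in the histograms but
  no formal partial-modification test is provided.
* Multi-reference (tied) reads contribute to every tied reference by
  default, which double-counts them in per-tRNA coverage; a configuration
  switch drops them instead.
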