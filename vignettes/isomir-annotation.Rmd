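---
title: "Sequence-level isomiR annotation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-level isomiR annotation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`casmir` annotates every unique small RNA sequence with a complete isomiR
classification and carries that annotation through filtering, composition
profiling and differential expression. This vignette explains the models
and procedures, the tunable parameters and their defaults, what the
built-in simulator does and does not emulate, and the design choices made
where more than one reasonable construction existed.

## 1. The classification model

Every sequence assigned to a canonical mature miRNA receives exactly one of
five classes — `canonical`, `iso5p`, `iso3p`, `polymorphic`, `mixed` — and
the assignment is total: class counts always sum to the number of
sequences (a sixth bucket, `unclassified`, holds sequences whose unaligned
end overhang exceeds a cap and which are reported but excluded from
class-fraction denominators).

The class is a function of three feature groups extracted from a local
alignment of the sequence against its canonical form:

* **5′ end change**: deletion (canonical bases missing), addition (query
  bases appended), or variation (terminal canonical bases replaced by
  other bases, possibly more of them — variation may lengthen a sequence).
* **3′ end change**: same subtypes.
* **internal edits**: substitutions, deletions or insertions strictly
  between the first and last canonical positions, reported on 1-based
  canonical coordinates so that position histograms are directly
  comparable across sequences of one mature.

One feature group present means `iso5p`, `iso3p` or `polymorphic`; two or
more mean `mixed`; none means `canonical` (and the sequence is literally
identical to the reference, which is asserted).

**Addition vs variation.** Both produce a query longer than its aligned
region, so a decision rule is needed; we resolve by canonical end
coverage. If the canonical is fully covered at that end, the overhang is
an addition. If canonical bases are *also* unaligned at that end, the
overhang replaces them: variation. A substituted terminal base with no
length change appears as a one-base overhang on each side (the local
aligner trims terminal mismatches) and is therefore a variation, which
matches the definition of a non-template change of the end nucleotide.

**Template vs non-template additions.** Appended bases are compared with
the precursor bases immediately flanking the mature placement — upstream
for 5′ additions, downstream for 3′ additions — in *every* placement of
that mature (a mature can sit in several hairpins, or twice in one). An
exact flank match in any placement makes the addition `template`;
otherwise, including when the mature has no placement at all or the flank
runs off the hairpin end, it is `nontemplate`. This any-placement rule
makes template calls monotone in the placement set. Template form cannot
prove biogenesis: a template addition may still have been added
enzymatically; the dichotomy only says what sequence evidence allows.

## 2. Alignment

Both assignment and feature extraction use the same affine-gap
Smith–Waterman local alignment, implemented in C++ with a full traceback:

* match +1, mismatch −3 (blastn-short-like), gap open 5, gap extend 2
  (a gap of length *k* costs 5 + 2*k*), forward strand only;
* deterministic tie-breaking: the first maximal cell in row-major order
  ends the alignment, and the traceback prefers diagonal over up (query
  base consumed) over left (canonical base consumed);
* assignment is seeded by exact 13-mers. Because miRNA-sized sequences
  are short, each seeded candidate gets a *complete* DP, so seeded
  results equal exhaustive Smith–Waterman whenever any seed exists —
  a property the test suite checks against an independent plain-R DP
  oracle on a thousand random pairs.

Word size 13 and the gap penalties follow the established short-miRNA
alignment convention; match/mismatch weights are configurable because
only the word size and gap costs are fixed by that convention. The score
floor for a reported hit defaults to 13, the score of a perfect seed, to
bound spurious assignments. Ties among equal-scoring matures resolve by
smallest total unaligned end offset, then fewest mismatches+gaps, then
lexicographic ID — fully deterministic, no hash-order dependence. Each
sequence is counted under exactly one canonical; fractional multi-mapping
would break read-count conservation, which downstream roll-ups rely on.

The **end-overhang cap** (default 6 nt per end) guards the taxonomy:
typical isomiR end offsets are ≤ 3 nt, and a sequence needing a longer
overhang is more plausibly a degradation product or chimera than an
isomiR, so it is reported as `unclassified` rather than forced into a
class.

## 3. Preprocessing

* **Adapter trimming** finds the leftmost position where a prefix of the
  adapter (length ≥ 8) matches the read exactly through to the read's
  end; full internal adapter occurrences match too. No mismatch is
  tolerated by default (configurable to 1): without a published error
  model, exactness is the reproducible choice. Untrimmed reads are kept —
  real inserts shorter than the read length always contain adapter, and
  anything that survives untrimmed is removed by the ≤ 25 nt filter.
* **Collapsing** aggregates identical sequences within and across samples.
  Reads containing N are discarded: the sequence string is the primary
  key, and N would fragment counts of the same molecule.
* **Quality flagging**: a (sequence, sample) pair is low-quality when *no*
  supporting read in that sample has all bases at Q ≥ 30, and a sequence
  is removed when flagged in more than 10 samples. The per-read "entirely
  ≥ Q30" reading is the most conservative definition that still removes
  sequencing-artifact variants; the threshold is also accepted as a
  fraction of samples, since an absolute count of 10 is only meaningful
  relative to a cohort's size (it presumes a cohort of roughly 80
  libraries).
* **Length filter**: 17–25 nt inclusive, the typical mature miRNA range.

Both filters are order-independent per-sequence predicates (the suite
checks idempotence and commutation).

## 4. Quantification and composition

Counts are scaled to reads per million *trimmed* reads of their sample.
Some small RNA workflows additionally apply proprietary cross-sample
smoothing normalizations; `casmir` makes no attempt to imitate any of
them. The default is scale-only, with a clearly labelled optional
median-of-ratios step (each sample divided by the median ratio of its
nonzero values to the row geometric mean) for users who want a
composition correction between libraries.

The abundance/prevalence filter keeps rows with all-sample mean strictly
above 5 (computed on the normalized scale, since the criterion follows
normalization) that are present — normalized value > 0 — in at least 50%
of the samples of at least one phenotype group.

Composition profiles are read-weighted fractions, each map normalized over
its own denominator: class fractions over all classified miRNA reads; the
addition/deletion/variation split over 3′-isomiR reads; the template
fraction over 3′-addition reads; added-string spectra over all and over
non-template 3′ additions; polymorphic position and substitution spectra
over read-weighted internal-edit incidences. Mixed-class reads count once,
under `mixed`, and enter none of the single-class denominators — the
taxonomy is mutually exclusive and the denominators respect that.
Per-mature most-abundant-form statistics (top sequence, its class, and its
read ratio to the canonical) expose miRNAs whose dominant form is an
isomiR. Per-miRNA roll-ups sum all sequences of a mature and conserve
totals exactly; they are the quantity comparable to name-level
quantifiers.

## 5. Differential expression

* **Fold change**: log-link Poisson GLM on a group indicator, fitted by
  IRLS (`stats::glm`), quasi-likelihood dispersion = Pearson χ²/(n−2)
  inflating the Wald standard error, two-sided *p* from *t* with n−2 df —
  standard quasi-Poisson practice; the two-group MLE makes the fitted
  fold change exactly the ratio of group means. Normalized values are
  rounded for the likelihood by default; supplying log-total offsets and
  raw counts is the statistically cleaner supported alternative. A group
  of all zeros yields a signed-infinite fold change with a fallback *p*
  from adding ½ to each group total, flagged `zero_group`.
* **AUC**: Mann–Whitney with ties ½, oriented as P(case > control), with
  DeLong's structural-component variance and a two-sided normal test
  against 0.5. Perfect separation gives a zero variance estimate, so a
  floor of 1/(4·n·m) applies before testing.
* **Flags**: up iff AUC > 0.8 and P < .01; down iff AUC < 0.2 and
  P < .01 — strict inequalities, raw (uncorrected) p-values, because that
  is the decision rule the workflow is built around; a Benjamini–Hochberg
  column is emitted for reference but does not drive flags. Which p-value
  feeds the flag (quasi-Poisson or DeLong) is configurable, default
  quasi-Poisson, as the printed decision rule is ambiguous between them.
* **Power**: the sample-size rationale (20 per group to detect AUC 0.75
  over 0.5 at one-sided α = 0.05 with 80% power) is checked by binormal
  Monte-Carlo simulation: controls standard normal, cases shifted by
  √2·Φ⁻¹(AUC). The suite requires empirical power ≥ 0.80 at 2000
  replicates; it lands near 0.90.

## 6. What the simulator emulates — and what it does not

`sim_config()` defaults are the study conditions the analysis assumes:
three pathology groups (normal/adenoma/CRC) of 20 samples each; matures of
20–23 nt embedded at known offsets in 80 nt hairpins with ≥ 3 nt flanks so
template and non-template additions can be planted deliberately; 13-mer
uniqueness across matures so canonical assignment is unambiguous;
per-mature abundances lognormal around 200 reads with negative-binomial
(size 5) sampling noise — deliberately overdispersed so the quasi-Poisson
adjustment is actually exercised; and an event spectrum mirroring the
composition reported for colorectal tissue (canonical 31% of miRNA reads;
3′ isomiRs 41.4% — i.e. 60% of the 69% non-canonical; additions 66% of 3′
forms, 60% of them template; added nucleotides weighted C 43% / U 27% /
A 12% / G 18%; 5′ isomiRs 2%; polymorphic 1%; mixed the remainder).
Reads are emitted insert + full adapter, padded with random bases to 50
cycles, at uniform Q40 with an optional Q29 spike-in for quality-filter
tests.

Two generator constraints keep planted truths unambiguous, which is the
generator's job (ambiguous events are excluded, not guessed at):

* planted internal substitutions keep an intact 13-mer of the parent
  mature, since a sequence without any seed is unreachable by the
  word-size-13 assignment the workflow prescribes;
* planted internal substitutions stay ≥ 5 nt from the 5′ end and ≥ 4 nt
  from the 3′ end: closer to an end, the +1/−3 scoring makes a single
  substitution *identical in evidence* to a terminal variation, so such a
  sequence collides with a different single-event description. (This is
  also consistent with observed biology: polymorphic changes concentrate
  away from the termini.)

Not emulated: ligation bias, FFPE degradation profiles, sequencing-error
spectra (a uniform substitution rate is available but defaults to 0),
UMI structure, paired ends. Passing end-to-end tests therefore shows the
*logic* is correct on data matching the model's assumptions; it does not
certify performance on platform-biased real libraries.

## 7. Numerical and formatting choices

* Coordinates are 0-based half-open internally, 1-based only in reports.
* RNA is converted to DNA (U→T) once at load time; all comparisons happen
  in DNA space because sequencer reads are DNA.
* The annotation label
  (`mature|class|5p:…|3p:…|int:…`) is a lossless grammar; `parse_label()`
  inverts `make_label()` exactly, and the mirGFF3 writer stores it in the
  `UID` attribute so that write∘read is the identity on annotation
  content, while the `Variant` attribute carries the community
  vocabulary (`iso_5p`, `iso_3p`, `iso_add3p`, `iso_5p_var`,
  `iso_3p_var`, `iso_snv`), a deliberately lossy projection.
* Composition fraction maps sum to 1 within 1e−9 of floating-point error
  over their own denominators, or are empty when the denominator is zero.
* Test problem sizes: the taxonomy totality suite runs on 10,000 planted
  events (1000 matures × 10 event types); the alignment oracle on 1000
  random pairs; the statistics oracles on 1000 random group pairs plus a
  2000-row null calibration; end-to-end recovery on 40 matures × 8
  samples. These sizes give tight binomial error on every rate checked
  while keeping the default suite around two minutes.

## 8. Known limitations

* No genome-wide mapping: sequences that do not seed against the mature
  database are `unassigned`, not rescued by a genome aligner, and novel
  miRNA discovery is out of scope.
* The biogenesis of a template addition is undecidable from sequence;
  `casmir` reports sequence evidence only.
* No covariate adjustment or paired designs in differential expression —
  the model is strictly two-group.
* Mixed-type isomiRs are reported as one class; their full sub-features
  are preserved in the label but not sub-typed in composition tables.
* Cross-sample normalization is per-million scaling (optionally
  median-of-ratios) only; no smoothing-based correction is provided
  (see §4).
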