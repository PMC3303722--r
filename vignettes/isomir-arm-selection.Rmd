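---
title: "Methods: isomiR quantification, arm selection and distribution comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR quantification, arm selection and distribution comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirarm)
```

## The problem

A pre-miRNA hairpin can yield a mature miRNA from its 5p arm, its 3p arm,
or both, and each mature miRNA is sequenced as a population of length and
position variants (isomiRs). Two questions drive this package, both asked
of a *pair* of small-RNA libraries (the motivating design is one normal and
one tumor gastric tissue from the same patient):

1. Does the **arm-selection preference** — the 5p:3p expression ratio of a
   hairpin — differ between the two libraries, and does it contradict the
   reference database's major/minor annotation?
2. Does the **isomiR distribution pattern** of a mature miRNA differ
   between the libraries, beyond what sampling noise explains?

Everything upstream (read collapsing, exact mapping with 3'-trim rescue,
offset-window isomiR assignment, opposite-arm detection, addition-fragment
bookkeeping) exists to produce the count tables these two questions are
asked of.

## Pipeline model and assumptions

**Read preprocessing.** Reads are adapter-trimmed (exact prefix overlap of
at least 6 nt anchored at the 3' end; a read without adapter evidence is
discarded as non-clean), kept if 18-25 nt (the mature-miRNA length
envelope), collapsed to unique reads, and unique reads seen fewer than
twice are dropped. Filtering is length-first, then count, so counts are
tallied over length-passed reads. Pre-collapsed two-column input bypasses
adapter handling but still passes the filters.

**Mapping.** A read must match a hairpin *exactly* — no mismatches
anywhere. Exactness limits paralog ambiguity without scoring heuristics.
The one systematic source of terminal mismatches, 3' non-templated
nucleotide addition, is handled by iterative trim-rescue: if the
full-length read hits nothing, its 3'-terminal base is removed and matching
retried, down to 18 nt; trimming stops at the first length with a hit
anywhere. The removed suffix is recorded as the addition fragment. Two
consequences worth stating plainly:

- trimming engages only for otherwise unmappable reads, so a templated
  extension (an appended base that happens to match the hairpin) is never
  trimmed and is indistinguishable from a genuine template read;
- the trimmed fragment is an *operational* addition call, not an editing
  classification — terminal modification (e.g. C-to-U) and addition of U
  can produce the same read, and this pipeline does not attempt to separate
  them.

A read hitting several loci contributes its full count to each by default
(`split_multihits = TRUE` divides by the number of loci). Reads map to the
given strand only, as small-RNA protocols are stranded.

**isomiR assignment.** A mapped read is an isomiR of a mature annotation on
the same hairpin iff its start offset is within ±2 nt and its end offset
within ±5 nt of the annotated span. The 5' end is held tighter because it
defines the seed; the 3' end is looser because additions and imprecise
processing concentrate there. Offsets are signed as read coordinate minus
mature coordinate. When one read satisfies two annotations' windows, the
smaller |start offset| wins (ties: smaller |end offset|, then 5p), with a
warning — overlapping mature annotations on one arm are rare and usually a
curation artifact.

**Arm assignment and opposite-arm detection.** The database never states
which arm a located mature sits on, so the package derives it: a span whose
midpoint is strictly upstream of the hairpin midpoint, (length+1)/2, is 5p,
else 3p. A span centered exactly on the midpoint is called 3p by convention
and flagged with a warning, since the call carries no biological content.
On hairpins annotated on one arm only, unassigned reads falling on the
opposite arm are clustered per library; the most abundant read's span
(ties: higher count, then smaller start, then smaller end) defines a
detected annotation if it has at least 2 reads, and remaining unassigned
reads re-enter assignment against it. Detection runs per library and is
cross-tabulated (exclusive to A / exclusive to B / shared); for
re-assignment the two libraries' detections of the same arm are
consolidated to the span whose defining read has the larger count. The
most-abundant-read convention for the detected reference span is a choice,
not a datum: with no database entry there is no canonical form, and the
modal read is the least arbitrary anchor.

**Arm-selection ratios.** Per hairpin, 5p and 3p expression are the sums of
their isomiR counts; Ratio_N53p = N5p/N3p and Ratio_T53p = T5p/T3p within
each library, and the fold change between libraries is
max(ratio)/min(ratio) — symmetric in the libraries and always ≥ 1. Ratios
use raw within-library counts deliberately: any monotone per-library
scaling cancels inside a within-library ratio, so between-library
normalization cannot change them. A hairpin is examined only when all four
arm counts are ≥ 10 (ratio estimates below that are dominated by shot
noise) and called significant when the fold change exceeds 3 — an
empirical screening threshold, not a test statistic. Ratios are computed at
full precision; reporting rounds half-up to 4 decimals (ratios) and 2
(fold changes).

**Between-library normalization.** Expression levels of shared matures are
regressed, library B on library A, by ordinary least squares on the log10
scale. Log scale is the package's choice: counts span four orders of
magnitude, and a linear-scale intercept of order 0.1 against totals of
order 10^7 would be meaningless; `scale = "linear"` is available. Zeros are
excluded from the fit (no pseudocounts) and map to zero on application.
After fitting, regressing B on the normalized values should give a slope
near 1; a slope outside [0.9, 1.1] despite R² ≥ 0.8 triggers a warning.
Normalization is reported separately and feeds no ratio arithmetic (see
above).

**Categorical KS comparison.** For one mature miRNA, the isomiR types are
the union of observed (start, end) offset pairs in either library, ordered
ascending by start then end offset — the natural 5'→3' reading — and
numbered 1..K. D is the maximum absolute difference of the two cumulative
relative-abundance vectors along that order. Because the axis is
categorical, the order matters: a different order can give a different D,
so the canonical order is fixed, documented, and tested for determinism.
The p-value uses the asymptotic Kolmogorov tail
Q(λ) = 2·Σ_{j≥1} (−1)^{j−1} e^{−2j²λ²} at
λ = (√n_e + 0.12 + 0.11/√n_e)·D with n_e = n_a·n_b/(n_a+n_b), where n_a,
n_b are total read counts — reads are the sample units, which is the only
reading under which a 1000-read eligibility floor makes sense. A miRNA is
eligible when it has strictly more than 8 types and strictly more than
1000 reads in each library; significance is a raw p < 0.001 with no
multiple-testing correction by default (`bonferroni = TRUE` adjusts).

Known caveat: with n in the thousands, the asymptotic KS treats multinomial
count vectors as if they were continuous samples, which is anticonservative
— tiny distributional wobbles can reach p < 0.001. The screen should be
read as a ranking device with an arbitrary-but-fixed cutoff, not as a
calibrated test. An exact permutation p-value is a clean extension point
(`ks_pvalue` is the single place to swap).

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| read length window | 18-25 | nt | mature miRNA length envelope |
| unique-read min count | 2 | reads | singleton reads are unreliable |
| adapter min overlap | 6 | nt | chance 3'-suffix match ~4^-6 |
| min post-trim length | 18 | nt | shorter cores match by chance |
| start / end offset windows | 2 / 5 | nt | seed fidelity vs 3' heterogeneity |
| arm-ratio count filter | 10 | reads/arm | ratio stability |
| fold-change threshold | 3 | — | empirical screening criterion |
| KS eligibility | >8 types, >1000 reads | — | pattern needs support |
| KS significance | p < 0.001 | — | raw, uncorrected |
| normalization scale | log10 | — | counts span decades |

## The synthetic-data generator

No sequencing data accompanies the motivating study, so the generator is a
first-class module: it emulates the *structure* of such data with known
ground truth, making every pipeline stage testable.

It draws random hairpins (uniform A/C/G/U, 80-110 nt), plants one 21-nt
mature span per arm, and per library splits each hairpin's depth between
arms at the configured 5p/3p ratio, draws (start, end) offsets from a
distribution concentrated on the reference form, and appends 3' fragments:
86% of reads carry none, and the 14% that do follow the empirical spectrum
observed in the normal gastric library (A 50.93%, U 30.72%, AA 3.39%, UA
2.28%, UU 2.16%, AU 1.53%, G 1.40%, AAA 1.07% of addition events), with the
unprinted 6.5% remainder filled by three synthetic minor fragments (UUU,
AG, GU).

Three constructions make ground truth exactly recoverable:

- **No shared 18-mers.** Hairpins are rejected until no 18-mer occurs twice
  anywhere in the reference, so every read has a unique mapping locus and
  brute-force oracle comparisons are exact.
- **A C-tract under every reachable 3' position.** Template bases at every
  position an isomiR 3' end or appended fragment base can occupy are set to
  C, and no default fragment starts with C, so an appended fragment can
  never be read as a templated extension: trim-rescue recovers exactly the
  planted fragment. (For user configs with C-starting fragments the
  generator falls back to per-base mismatch correction, which distorts the
  realized spectrum — the documentation says so, and it mirrors the real
  ambiguity that template-matching additions are invisible.)
- **Fixed 21-nt matures.** With the default offset support, every read core
  is 18-22 nt and every read with a ≤3-nt fragment stays ≤25 nt, so the
  length filters drop nothing and conservation checks are exact. This is a
  simulation convenience; real matures vary 18-25 nt.

What the generator does **not** emulate: sequencing error, quality scores,
base-composition and ligation biases, paralog families (excluded by
design), non-miRNA background reads, and biological isomiR structure beyond
an offset distribution. Passing recovery tests therefore demonstrates
algorithmic correctness — bookkeeping, windows, conservation, estimator
behavior under multinomial sampling — not robustness to real-data
artifacts.

One analysis-settings note: generator-recovery runs use `min_count = 1`.
The count ≥ 2 filter is a noise filter for real data; on simulated data it
preferentially removes singleton unique reads of rare fragment/offset
combinations and would bias the recovered spectra for reasons unrelated to
the estimators under test.

## Numerical choices

- The Kolmogorov series is summed to 100 terms, ample for any λ ≥ 0.001;
  below that λ the p-value is 1 by continuity. Results are clamped to
  [0, 1].
- Rounding for report tables is half away from zero (base `round()` is
  half-to-even), applied only at format time; all comparisons use full
  precision.
- Zero-denominator arm ratios are reported as infinite, excluded from
  significance, and the hairpin fails the count filter anyway.
- Degenerate inputs error early: a mature equal to its whole hairpin (arm
  undefined), annotations outside the hairpin, empty type tables, fewer
  than 3 shared matures for normalization, infeasible simulator configs.
- The simulator saves and restores the caller's RNG state; a fixed seed
  gives byte-identical output files.

## Problem sizes used in tests and scripts

The bundled analyses and tests run at sizes chosen to put sampling error
well inside the tolerances they assert: 20 hairpins at 18,000
reads/hairpin/library (~50,000 addition events, so a 3σ multinomial bound
on the largest fragment share is ~0.6 percentage points) for spectrum
recovery; 5 hairpins at 20,000 reads/hairpin for fold-change recovery
(truth 4.0, 3σ ≈ [3.0, 5.3]); 50 null + 10 shifted miRNAs at 5,000
reads/side for the KS screen; 200 matures with σ = 0.2 log-noise for
normalization recovery (slope SE ≈ 0.015).

## Known limitations

- The categorical KS p-value is anticonservative at read-level n (above).
- Fold-change screening has no error model; 3-fold is a convention.
- Exact-match mapping drops any read with an internal sequencing error or
  internal editing site; such reads are simply unmapped.
- Detected opposite-arm annotations depend on the modal-read convention;
  a different convention shifts offsets by a constant per arm but does not
  change counts.
- With `split_multihits = FALSE` (default), paralog multi-hits double-count
  reads at the locus level; conservation is therefore checked at the
  unique-read level.
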