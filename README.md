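# isomirarm

Quantify isomiRs and miRNA arm-selection from paired small-RNA sequencing
libraries, and test whether arm preference or isomiR distribution patterns
differ between the two libraries (the motivating design: one normal and one
tumor gastric tissue from the same patient).

The package is organised as an analysis workflow: all computation lives in
the package functions (`R/`), the numbered scripts under `analysis/` are
thin narrative drivers, and a synthetic paired-library generator with full
ground truth stands in for sequencing data, making every stage testable.

## What it computes

- **Read preprocessing** — 3' adapter trimming (exact overlap ≥ 6 nt),
  18-25 nt length filter, collapsing to unique reads, count ≥ 2 filter.
- **Exact mapping with 3'-trim rescue** — reads map to pre-miRNA hairpins
  with *no* mismatches; an unmappable read has its 3' bases removed one by
  one (down to 18 nt) until it maps, and the removed suffix is recorded as
  a 3' non-templated **addition fragment**.
- **isomiR assignment** — a mapped read is an isomiR of a mature miRNA when
  its start offset is within ±2 nt and its end offset within ±5 nt of the
  annotated span; expression of a miRNA is the sum of its isomiR counts.
- **Opposite-arm detection** — on hairpins annotated on one arm only,
  clustered unassigned reads on the other arm define newly detected mature
  miRNAs, cross-tabulated between libraries.
- **Arm-selection ratios** — per hairpin, the within-library 5p/3p ratios
  `Ratio_N53p = N5p/N3p` and `Ratio_T53p = T5p/T3p`, and their fold change
  `max(ratio)/min(ratio)`; hairpins with all four arm counts ≥ 10 and fold
  change > 3 are flagged, plus major-arm calls against the database
  annotation and between-library arm switches.
- **Categorical two-sample KS comparison** — per miRNA, isomiR types
  (offset pairs, ordered 5'→3') form a categorical axis;
  `D = max_k |CDF_A(k) − CDF_B(k)|` over cumulative relative abundances,
  with the asymptotic Kolmogorov p-value at effective size
  `n_e = n_A n_B/(n_A+n_B)`; miRNAs with > 8 types and > 1000 reads per
  library are screened at p < 0.001.
- **Between-library normalization** — OLS of log10 expression, library B on
  library A, with a post-normalization identity check.

## Worked example

The package ships the published per-hairpin arm-count tables of the gastric
study as plain TSV (`gastric_reference()`), and recomputes every derived
column from the raw counts:

```r
library(isomirarm)
tab <- gastric_reference("arm_ratio")
fmt <- format_arm_ratios(arm_ratios(tab))
fmt[fmt$premirna_id == "hsa-mir-423",
    c("N5p", "N3p", "ratio_a", "T5p", "T3p", "ratio_b", "fold_change")]
#>     N5p  N3p ratio_a  T5p  T3p ratio_b fold_change
#> 4 20920 8945  2.3387 1708 6266  0.2726        8.58
```

hsa-mir-423 is 5p-dominant in the normal library (ratio 2.34) but
3p-dominant in the tumor library (ratio 0.27), an 8.58-fold change in arm
preference — one of the arm-switching hairpins. Running
`Rscript analysis/01_reference_tables.R` reproduces all 10 printed ratio
pairs and fold changes, all 22 annotation-exchange labels (e.g.
hsa-mir-1307 → "N", hsa-mir-1303 → "T") and all 5 tissue-switch calls.

A full simulated run (`analysis/02` … `analysis/06`) generates a paired
dataset with planted arm ratios and the empirical addition spectrum, maps
it end to end, and prints, e.g.:

```
library A: 11 fragment kinds, 21,436 added reads (13.5% of mapped)
  fragment count   pct
1        A 11267 52.56
2        U  6888 32.13
...
KS screen: 40 miRNAs, 40 eligible, 0 significant at p < 0.001
```

— the addition rate and spectrum recover the generating values (14%; A
50.93%, U 30.72%, …), and the KS screen is quiet because both libraries
share one generating isomiR distribution.

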