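# sefunnel

Super-enhancer dynamics and *cis*-acting lncRNA prioritization for
ordered tumour-progression series.

Breast-cancer progression models such as the MCF10A isogenic series
(normal → atypical hyperplasia → ductal carcinoma in situ → invasive
carcinoma) let epigenomic changes be ordered along disease stages.
sefunnel implements, as a tested and reusable R package, the analysis
core such studies run on H3K27ac ChIP-seq and SE-lncRNA expression data:

* **Rank-ordering super-enhancer calling** from peak + signal tables:
  TSS-proximal peak exclusion, peak stitching, depth normalization, and
  the hockey-stick threshold. On the rank–signal curve with both axes
  min–max scaled to [0, 1], the cutoff is the signal y* at the first
  point where the curve's slope exceeds 1 (the slope-1 tangent point);
  regions with signal > y* are super-enhancers.
* **Stage-wise dynamics**: classification of super-enhancers as
  *acquired* (SE at stage k, no ≥1 bp overlap with any earlier stage's
  SEs), *lost* (baseline SE with no overlap at a later stage) or
  *retained* (acquired and present through the final stage), plus
  patient-cohort representation counts ("an SE in m of n patients").
* **A cis-candidate funnel** narrowing an SE-lncRNA expression screen:
  |log2 FC| ≥ log2 2 between first and last stage → neighbor genes
  within 50 kb that co-change → membership in a patient lncRNA atlas →
  Pearson |r| ≥ 0.5 across patients, with unmeasured or uncorrelated
  pairs re-tested by normal-to-tumour trend concordance → union with an
  annotated |FC| ≥ 10 branch.
* **qPCR analysis**: ΔΔCt fold changes (fold = 2^−ΔΔCt with multi-gene
  reference averaging), nuclear/cytoplasmic localization calls from
  fraction Ct ratios, one-way ANOVA with Tukey HSD, Student t-tests.
* **Seeded synthetic-data generators** for every input, with planted
  ground truth (SE clusters on acquisition/loss schedules, true cis
  pairs among targeted decoy classes, planted qPCR fold changes and
  fraction splits) so every stage of the pipeline has recovery tests.

Everything is tibble-first: functions take data frames and return
tibbles, results have `tidy()`/`glance()`/`autoplot()` methods, and all
coordinates are 0-based half-open (BED convention).

## Worked example

The synthetic generators make a self-contained example; on real data the
same calls take peak/signal tables read with `read_bed()` /
`read_bedgraph()`.

```r
library(sefunnel)

cfg <- synth_config(seed = 1)
cs  <- gen_chipseq_series(cfg)

calls <- call_super_enhancers(cs$peaks$DCIS, cs$genes)
calls
#> <se_calls> 416 stitched regions, 19 super-enhancers (signal cutoff 4.579)
#> # A tibble: 416 x 7
#>    chrom   start     end n_constituents signal  rank is_super
#>  1 chr1   150000  157100              8   409.     1 TRUE
#>  2 chr1  1550000 1557300              8   407.     2 TRUE
#>  ...
```

The DCIS stage yields 416 stitched enhancer regions of which 19 exceed
the hockey-stick cutoff (signal 4.58): the planted high-signal clusters
plus a few decoys from the exponential tail. `autoplot(calls)` draws the
rank–signal curve with the cutoff.

```r
series <- lapply(cs$peaks, function(p) se_regions(call_super_enhancers(p, cs$genes)))
dplyr::count(classify_se_dynamics(series), stage, status)
#> # A tibble: 8 x 3
#>   stage status       n
#> 1 AT1   acquired     5
#> 2 AT1   lost         2
#> 3 AT1   retained     3
#> 4 CA1   lost         8
#> 5 CA1   retained     2
#> 6 DCIS  acquired     5
#> 7 DCIS  lost         5
#> 8 DCIS  retained     2
```

Eight regions first become super-enhancers at AT1 (three of them stay
through CA1 and are *retained*), and eight baseline super-enhancers are
gone by CA1 — matching the generator's planted schedule exactly.

```r
ex  <- gen_expression(cfg)
rep <- run_cascade(ex$lnc_table, ex$mrna_table, ex$annotation,
                   ex$annotated_ids, ex$patient_matrix, ex$patient_direction)
tidy(rep)
#> # A tibble: 8 x 3
#>   step             n_lncrnas n_pairs
#> 1 input                  212      NA
#> 2 differential            92      NA
#> 3 paired                  58      58
#> 4 annotated               38      38
#> 5 correlated               6       6
#> 6 trend_concordant         2       2
#> 7 top_differential         4      NA
#> 8 shortlist               12      NA
```

Of 212 lncRNAs, 92 are differential, 58 have a co-changing neighbor
within 50 kb, 38 are atlas-annotated, 6 correlate with their neighbor
across patients and 2 more are rescued by trend concordance; with the 4
extreme responders the shortlist has 12 candidates — exactly the 8
planted cis pairs plus the 4 planted extremes (`autoplot(rep)` draws the
funnel).

```r
q <- gen_qpcr(cfg)
delta_delta_ct(q$ct, "TGT1", q$reference_genes, "CA1", "MCF10A")
#> # A tibble: 1 x 7
#>   gene_id condition control delta_delta_ct fold_change low_confidence ...
#> 1 TGT1    CA1       MCF10A           -1.01        2.01 FALSE
```

The planted two-fold induction is recovered as 2.01 from triplicate
wells with 0.05-cycle noise.

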