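# penlaws

Quantitative analysis of three motor laws of handwriting from
timestamped pen trajectories, aimed at the early, objective screening of
handwriting difficulties (dysgraphia) on consumer tablets — including at
the preliteracy stage, where symbol drawing stands in for word writing.

The three laws, and the statistics the package computes for them:

- **Isochrony** — bigger gestures are executed at proportionally higher
  speed, so movement duration stays roughly constant.  Measured as the
  mean execution speed per trial (border-trimmed, 10-Hz low-pass
  filtered discrete speed), compared across the five instruction
  modalities (*spontaneous, big, small, fast, slow*) with a Friedman
  test and Bonferroni-adjusted Wilcoxon post hocs.
- **Homothety** — the fraction of total execution time devoted to each
  element of a word or symbol sequence is invariant to overall size and
  speed.  Letters of a cursive word are segmented at the lowest point
  between letters; symbols of a sequence at pen lifts.  Per-element
  fraction times are compared across modalities (Friedman); *no* effect
  supports the law.
- **Speed–accuracy tradeoff (steering law)** — movement time grows
  linearly with the index of difficulty of a constrained path:

  ```
  ID = A / W          (amplitude over tunnel width)
  MT = a + b · ID     (per-subject OLS regression)
  IP = 1 / b          (index of performance, significant fits only)
  ```

  with the paper-and-pencil conventions: `A` is the perimeter (symbols)
  or path length (words) measured along the tunnel center; trials with
  more than 40% of the trace outside the borders are excluded; MT is
  measured on the central section only (the middle lap of a twice-steered
  symbol, or between the first and last letter-gate crossings of a word).

Because no child recordings are distributed, the package ships a
seedable synthetic cohort generator (`generate_cohort()`) that emulates
50-Hz tablet recordings of both games with configurable adherence to
each law (isochrony exponent, fraction-time templates, steering
intercept/slope, tremor, programmed border excursions).  Every analysis
stage is validated against this generator's ground truth.

## Worked example

```r
library(penlaws)

session <- generate_cohort(
  default_cohort_config(n_primary = 10, n_kindergarten = 10,
                        tunnel_reps = c(1, 1, 1, 1, 1)),
  seed = 42)
result <- run_analysis(session)
result
#> <cohort_result>
#>   trials: input=750, analysed=750, excluded=0, invalid=0
#>   compliance (big vs small length): p=9.57e-05
#>   isochrony primary:word_mele: p=4.33e-08
#>   isochrony primary:circle: p=4.33e-08
#>   ...
#>   isochrony kindergarten:sequence: p=4.33e-08
#>   homothety: 0/10 elements with a modality effect
#>   steering: 60 fits, 60 significant
```

Reading this: the cohort complies with the instructions (big traces are
longer than small ones, p < .001); every group × item speed comparison
shows the modality effect isochrony predicts; no fraction-time element
shows a modality effect (homothety holds); and every per-subject
steering regression is significant.  Drilling in:

```r
result$isochrony[["primary:circle"]]$posthoc   # big > small etc.
#>        cond1 cond2 median_diff   raw_p adjusted_p significant
#>  spontaneous   big       -64.4 0.00195     0.0195        TRUE
#>          big small        94.1 0.00195     0.0195        TRUE
#>          big  fast        33.9 0.00195     0.0195        TRUE
#>          big  slow        90.0 0.00195     0.0195        TRUE
#>  ...

head(subset(result$steering$fits, item == "square"), 4)
#>            subject_id   group     a      b    R2   RMSE        p   IP global_MT
#> P01:square        P01 primary 0.832 0.0835 0.963 0.1865 0.003012 12.0      2.33
#> P02:square        P02 primary 0.740 0.0857 0.930 0.2697 0.008055 11.7      2.82
#> P03:square        P03 primary 0.982 0.0717 0.996 0.0547 0.000125 14.0      2.24
#> P04:square        P04 primary 0.531 0.0827 0.983 0.1230 0.000913 12.1      1.90
```

Each row is one subject's steering law on one item: intercept `a` (s),
slope `b` (s per ID unit), fit quality (`R2`, `RMSE`), significance `p`,
index of performance `IP = 1/b`, and the median movement time across all
difficulty levels (`global_MT`, s).  The minimal R² at which a fit with
12 residual degrees of freedom is significant at the 5% level is
`critical_r2(12, 0.05)` = 0.28.

`render_report(result, "results/")` writes the tables (CSV) and a JSON
summary; `write_session()` / `read_session()` round-trip sessions
through a documented CSV or JSON format.

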