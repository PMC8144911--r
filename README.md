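# microresil

Resilience and changepoint analysis of longitudinal microbiome time series.

`microresil` is for microbiome researchers who run short, densely sampled
intervention studies — a defined bacterial community in gnotobiotic mice, a
dietary perturbation, fecal sampling every day or two — and want to answer
three questions from the resulting 16S count tables:

1. **How far does the community move from its own baseline, and does it
   come back?** Per-mouse Bray–Curtis distance-to-baseline trajectories
   with per-day means, standard errors and paired significance tests.
2. **When does each taxon change, and does the change revert?** Exact
   least-squares mean-shift segmentation of every taxon's relative-abundance
   series, with automatic selection of the number of segments, classified
   into response/recovery calls per mouse and for the across-mouse mean.
3. **Which taxa change significantly between the pre, treatment and post
   windows?** A 2-of-3 consensus combiner over differential-abundance
   verdicts.

## The model at the core

A taxon's series $y_1,\dots,y_n$ is modelled as piecewise-constant in mean.
For a given segment count $K$, the fit minimizes the within-segment sum of
squares

$$J(K) \;=\; \min_{\tau_1 < \dots < \tau_{K-1}} \sum_{k=1}^{K}
\sum_{t=\tau_{k-1}}^{\tau_k - 1} \left(y_t - \bar y_k\right)^2,$$

solved exactly by dynamic programming ($O(Kn^2)$, Bellman recursion over
prefix sums). The number of segments is chosen from the elbow curve of
$J(K)$: curvature is approximated by the central second difference
$D_2(K) = J(K{-}1) - 2J(K) + J(K{+}1)$ and $K_{opt}$ is its maximizer over
$K \in [2, K_{max}{-}1]$. Each changepoint is then classified against the
pre-treatment (first-segment) mean $m_1$: a **response** moves away from
$m_1$, a **recovery** moves back toward it, giving the familiar
"n/m (↑)" table cells. Community-level resilience uses
$d(x,y) = \sum_i|x_i-y_i| / \sum_i(x_i+y_i)$ (Bray–Curtis) against each
mouse's own baseline-day sample.

Because real study data of this kind are rarely deposited, the package
ships a compositional simulator (`simulate_study()`): logistic-normal noise
on log abundances, negative-binomial read depths, multinomial counts, and
planted early-transient / late-transient / persistent / null response
templates with full ground truth — a first-class, tested module used to
validate every downstream stage.

## Worked example

Simulate the default study — 6 mice, 25 taxa dominated by a
*B. ovatus*-like colonizer at 80% relative abundance, days 9–37 with
treatment on days 14–23 — then run the full analysis:

```r
library(microresil)

cfg <- synthetic_config(seed = 42)
sim <- simulate_study(cfg)
ab  <- to_relative(filter_min_reads(sim$counts, threshold = 4000))

traj <- baseline_distance_trajectory(ab, sim$metadata, cfg$design)
subset(traj$summary, day %in% c(9, 11, 15, 25, 37))
#>    day n   mean     sem  p_value
#>      9 6 0.0000 0.00000 3.69e-05
#>     11 6 0.0316 0.00379 2.05e-01
#>     15 6 0.0957 0.00543 1.57e-04
#>     25 6 0.0885 0.00434 7.49e-06
#>     37 6 0.0565 0.00943 5.05e-02
```

The community sits at distance 0 from baseline by construction on day 9,
is displaced during treatment (day 15, mean 0.096) and again after
treatment offset (day 25), and relaxes back toward baseline by day 37 —
the bimodal resilience signature this analysis is designed to expose.

```r
rep <- response_report(ab, sim$metadata, cfg$design)
rep$table[rep$table$taxon %in% c("Escherichia_coli", "Klebsiella_oxytoca",
                                 "Akkermansia_muciniphila",
                                 "Ruminococcus_bromii"), ]
#>                    taxon      m1      m2      m3      m4      m5      m6    Mean
#>         Escherichia_coli 1/1 (↑) 1/1 (↑) 1/1 (↑) 1/1 (↑) 1/1 (↑) 1/1 (↑) 1/1 (↑)
#>       Klebsiella_oxytoca 1/0 (↑) 1/0 (↑) 1/0 (↑) 1/0 (↑) 1/0 (↑) 1/0 (↑) 1/0 (↑)
#>  Akkermansia_muciniphila 1/1 (↑) 1/1 (↑) 1/1 (↑) 1/1 (↑) 1/1 (↑) 1/1 (↑) 1/1 (↑)
#>      Ruminococcus_bromii     0/0     0/0     0/0     0/0     0/0     0/0     0/0
```

Each cell reads `n_response/n_recovery (direction)`: the planted early
transient (*E. coli*) responds and recovers in every mouse, the persistent
riser (*K. oxytoca*) responds without recovery, the late transient
(*A. muciniphila*) responds after treatment offset and recovers, and an
unperturbed taxon stays at `0/0`.

The consensus layer combines three external differential-abundance verdicts
per taxon and phase pair (`consensus_calls(..., verdicts = read_verdicts(path))`);
without external verdicts it runs a clearly labelled paired-t stand-in.
`run_pipeline()` wires the whole workflow from TSV inputs to TSV/JSON
artifacts in one call.

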