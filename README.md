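# gepnetcea

Cost-effectiveness of starting somatostatin analogues (SSAs) immediately at
diagnosis of metastatic gastroenteropancreatic neuroendocrine tumours
(GEP-NETs) versus delaying them until first disease progression.

SSAs (octreotide, lanreotide) control tumour growth and symptoms but cost
about $4000 per monthly injection, indefinitely. `gepnetcea` implements a
Markov cohort state-transition model of the two timing strategies — **SSA**
(treat at diagnosis) and **DELAY** (observe, treat at progression) — with
peptide receptor radionuclide therapy (PRRT) as common salvage therapy after
progression in both arms. It is written for health-economics and
decision-modelling audiences: the full analysis (base case, tornado,
threshold price, probabilistic sensitivity analysis) is scriptable and
reproducible from a parameter file and a life table.

## The model in brief

A cohort starts at age 60 and moves monthly through health states
(stable untreated, stable on SSA, SSA stopped for complications, progressed
on delayed SSA, a 4-cycle PRRT tunnel, post-PRRT follow-up, and two
absorbing death states, NET vs other causes) until death or age 100.
Disease transitions derive from published medians under an exponential
assumption,

```
p_cycle = 1 - 0.5^(1 / median_months),
```

background mortality comes from a period life table
(`q_month = 1 - (1 - q_year)^(1/12)`), and competing exits within a cycle
are combined by sequential conditioning in a fixed clinical order (a
constant-rate apportionment alternative is built in). Rewards per cycle are
a cost (2020 US$) and a utility weight; QALYs are half-cycle corrected and,
like costs, discounted at 3%/year via `(1+r)^(-t/12)`. Strategies are
compared on the efficiency frontier:

```
ICER = (C_SSA - C_DELAY) / (Q_SSA - Q_DELAY),   NMB = λ·Q - C,  λ = $100,000/QALY.
```

One-way sensitivity analysis re-runs the model over each parameter's range
(tornado); a threshold analysis root-finds the SSA price meeting the
willingness-to-pay; the PSA draws all parameters simultaneously (gamma for
costs, beta for utilities and probabilities) and yields a cost-effectiveness
acceptability curve. An individual-level microsimulation of the identical
model serves as an internal validation oracle. See the methods vignette
(`vignettes/gepnet-cea-methods.Rmd`) for every convention and its
rationale.

## Worked example

```r
library(gepnetcea)

params <- gepnet_parameters()      # all base-case values
lt     <- default_life_table()     # bundled synthetic Gompertz-Makeham table
run_base_case(params, lt)
#> <cea_result>
#>   SSA   cost $594384 | LY 4.348 | QALY 2.867
#>   DELAY cost $426327 | LY 3.740 | QALY 2.440
#>   incremental (SSA vs DELAY): cost $168057 | LY 0.608 | QALY 0.427
#>   ICER $393597/QALY - NOT cost-effective at WTP $100000/QALY
```

Immediate SSA buys 0.61 undiscounted life-years (4.35 vs 3.74) and 0.43
discounted QALYs, at $168,057 extra discounted cost — about $394,000 per
QALY, far above the $100,000 willingness-to-pay threshold, so delaying SSA
remains the cost-effective strategy. Most deaths are tumour-related in both
arms (92.9% vs 94.0%):

```r
run_strategy(params, "SSA", lt)
#> <strategy_outcome> SSA   cost $594384 | LY 4.348 | QALY 2.867 | NET deaths 92.9%
run_strategy(params, "DELAY", lt)
#> <strategy_outcome> DELAY cost $426327 | LY 3.740 | QALY 2.440 | NET deaths 94.0%
```

The tornado shows the SSA price dominating the uncertainty, and the
threshold analysis gives the price at which immediate SSA would become
cost-effective:

```r
tor <- one_way_dsa(params, lt)
head(tor[, c("parameter", "icer_low", "icer_high", "width")], 3)
#>                   parameter icer_low icer_high  width
#> 1            cost_ssa_month   241961    696870 454908
#> 2                  u_on_ssa   542507    308829 233678
#> 3 median_progression_on_ssa   488969    316800 172169

threshold_price(params, lt, wtp = 1e5)
#> [1] 131.4658
```

At half to double the current price the ICER spans roughly $242k–$697k —
never below the threshold; the monthly price would have to fall to about
$131 (from $4121) to meet $100,000/QALY.

Report-style outputs (traces, results tables, tornado/PSA/CEAC CSVs with
provenance headers) are written by `cmd_run()`, `cmd_tornado()`,
`cmd_threshold()` and `cmd_psa()` on a `run_config()`, or from a shell via
the bundled front-end:

```sh
inst/cli/gepnet-cea run --out results/ --set cost_ssa_month=3000
```

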