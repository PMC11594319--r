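# targnet

Target-anchored weighted correlation networks for questionnaire cohorts.

`targnet` is for epidemiologists and psychometric-network researchers who
want to ask, of a cross-sectional questionnaire cohort: *which variables
are most influential with respect to one designated outcome?* The package
was built around depression symptomatology — the Beck Depression
Inventory score as the target, with mood states (POMS), physical activity
(IPAQ), sleep profile (PSQI, Epworth) and macronutrient intake as
candidate influences — but the machinery is generic: any numeric column
of a scored table can be the target.

## The method

Given a scored cohort, the pipeline:

1. **Screens** every variable pair for correlation, using Pearson's *r*
   when both variables pass Shapiro–Wilk normality at `alpha_norm` and
   Spearman's *ρ* otherwise, keeping pairs with two-sided *p* < `alpha`
   as edges.
2. **Anchors** the graph at the target: hop distances are computed by
   BFS, each edge gets order = min(endpoint hops) + 1, and its weight is
   attenuated geometrically with distance from the target,

   *w* = |*r*| × 0.5^(order − 1),

   so direct edges keep their correlation magnitude, second-degree edges
   keep 0.500 of it, third- and fourth-degree edges 0.250 and 0.125.
   Variables unreachable from the target drop out of the network.
3. **Ranks** nodes by eigenvector centrality — the principal eigenvector
   of the attenuated-weight adjacency, computed by power iteration — so a
   variable scores highly when it is connected, directly or through
   influential intermediaries, to the target's neighbourhood.

The analysis is rebuilt independently within strata (all participants,
each sex, and age bands G1 18–28, G2 29–39, G3 40–50, G4 ≥51), plus
descriptive tables, Mann–Whitney sex comparisons, Kruskal–Wallis age
comparisons with Dunn–Bonferroni post hocs, and Cronbach's alpha.

Because participant-level data for the motivating study design are not
distributable, the package includes a seedable Gaussian-copula cohort
generator (`default_spec()`, `generate_cohort()`) reproducing the study
conditions: n = 411, 78.3% female, age mix 241:70:60:40 across the four
bands, published marginal moments, female–male contrasts on the mood
block, and planted correlations (target–sleep quality 0.52, sleep
quality–carbohydrates 0.13). `backfill_items()` emits raw item responses
that re-score exactly, for end-to-end testing through the scoring layer.

## Worked example

```r
library(targnet)

cohort <- generate_cohort(default_spec(), seed = 1)   # 411 synthetic participants
fit <- build_targeted_network(cohort, target = "beck")
fit$network
#> Targeted correlation network: target 'beck'
#>   17 nodes, 43 edges (orders 1..4)
#>   dropped (unreachable): age
fit$centrality
#> Eigenvector centrality (17 nodes, 21 iterations)
#>              beck               tmd        depression         hostility
#>            0.4761            0.4195            0.3333            0.3307
#>         confusion           tension           fatigue             vigor
#>            0.3299            0.3253            0.3226            0.2091
#>     sleep_quality physical_activity     sleep_latency     carbohydrates
#>            0.1162            0.0263            0.0081            0.0075
#>    sleep_duration        drowsiness            energy               fat
#>            0.0070            0.0052            0.0047            0.0009
#>          proteins
#>            0.0008
```

Reading this: the mood block (total mood disturbance and the five
negative domains) is most central to the depression score, sleep quality
is the strongest non-psychological influence, and nutrition variables sit
at the periphery — they connect to the target only through sleep quality
and each other, so the hop-distance attenuation keeps their influence
small. `age` correlated significantly with nothing in this draw and was
dropped. The strongest edges confirm the anchoring:

```r
head(fit$network$edges[order(-fit$network$edges$weight), ], 3)
#>   var_a         var_b         r   method order    weight
#> 7  beck           tmd 0.5490539 spearman     1 0.5490539
#> 8  beck sleep_quality 0.5314499 spearman     1 0.5314499
#> 6  beck     confusion 0.4581807 spearman     1 0.4581807
```

The full stratified study, with per-stratum edge lists, GraphML,
centrality CSV/JSON, comparison tables, a bar-chart figure and a run log:

```r
run_full_study("study_out", spec = default_spec(), seed = 1)
```

or from a shell, `Rscript inst/scripts/run_study.R --out study_out
--seed 1` (use `--input your_cohort.csv` for real data, either raw item
responses per `raw_schema()` or a pre-scored table named per
`analysis_variables()`).

See the vignette (`vignettes/targeted-networks.Rmd`) for the model's
assumptions, the generator's design and its limitations.

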