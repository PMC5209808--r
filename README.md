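# priogap

Multi-criteria prioritisation of infectious animal diseases and gap analysis
of disease control tools (diagnostics, vaccines, pharmaceuticals), for
epidemiologists, animal-health economists and research funders who need a
transparent, reproducible way to turn expert scores into rankings and
research-gap flags.

## The model

Diseases are scored by expert panels on a *closed weighted scoring system*.
A model is a set of criteria; each criterion has `I` levels (sub-criteria)
scored on an integer scale with maximum `X`, and every level carries the
weighting coefficient

```
W = 100 / (X * I)
```

so each criterion's maximum weighted total is exactly 100 and all criteria
enter the overall score with equal weight. The package ships two reference
models:

* **Prioritisation** — six criteria (disease knowledge; impact on animal
  health and welfare; impact on public health; impact on wider society;
  impact on trade; control tools). The first five use a 0..4 scale; control
  tools use −2..+2 so missing tools *raise* a disease's priority. The
  overall score is the unrounded sum of the six weighted totals, bounded in
  [−100, 600].
* **Gap analysis** — three control-tool areas (diagnostics 12 levels,
  vaccines 11, pharmaceuticals 11) on −2..+2; area totals are rounded to
  integers and a positive total flags a research gap. When no product exists
  at all, an availability rule overrides the whole area (`gap_totals()`
  offers both published readings of the rule).

Around the scoring core the package provides expert-panel aggregation to
consensus sheets with dissent (knowledge-gap) records, competition rankings
(overall, per category, per criterion, per gap area), re-weighting
sensitivity analysis with Kendall tau-b concordance, a seeded synthetic-study
generator for parameter-recovery testing, packaged reference tables of a
published 52-disease EU prioritisation exercise, CSV/JSON I/O, and a thin
command-line wrapper (`inst/cli/priogap.R`).

## Worked example

Simulate a small elicitation study, aggregate each panel to a consensus
sheet, and rank:

```r
library(priogap)

model <- default_prioritisation_model()
cfg   <- generator_config(n_diseases = 8, seed = 42)
study <- generate_study(cfg, model, default_gap_model())

agg    <- lapply(study$prioritisation, function(p) aggregate_panel(p, model))
totals <- lapply(agg, function(a) disease_total(a$consensus, model))
rank_diseases(totals)
#> <ranking_table: scope overall, 8 entries>
#>  rank disease_id disease_name    score
#>     1       d006  Disease 006 350.0000
#>     2       d007  Disease 007 329.1667
#>     3       d001  Disease 001 272.9167
#>     4       d004  Disease 004 254.5833
#>     5       d008  Disease 008 244.5833
#>     6       d003  Disease 003 183.7500
#>     7       d005  Disease 005 179.5833
#>     8       d002  Disease 002 173.3333
```

Scores are weighted sums over 29 sub-criterion scores; e.g. 350.0 means the
disease averaged 58% of the attainable range across the six equally weighted
criteria. Where experts disagreed by more than the dissent threshold the
aggregation records it (here 61 sub-criterion disagreements across the 8
panels):

```r
head(do.call(rbind, lapply(agg, `[[`, "dissent")), 1)
#>   disease_id         criterion   sub_criterion                expert_scores range consensus_value
#> 1       d001 Disease knowledge Speed of spread 2,2,2,3,3,3,3,3,3,3,3,3,4,4     2               3
```

The packaged reference ranking reproduces the published table — 52 diseases,
Nipah virus first with 464 of a possible 600:

```r
head(as.data.frame(rank_diseases(fixture_totals(load_fixture("table4_overall")))), 5)
#>   rank                 disease_id               disease_name score
#> 1    1                nipah_virus                Nipah virus   464
#> 2    2 peste_des_petits_ruminants Peste des petits ruminants   385
#> 3    3        african_swine_fever        African swine fever   373
#> 4    4          rift_valley_fever          Rift valley fever   365
#> 5    5        bovine_tuberculosis        Bovine tuberculosis   359
```

How robust is a ranking to a stakeholder who ignores trade impact entirely?

```r
sc <- default_weight_scheme(model)
sc$weights[["Impact on trade"]] <- 0
rank_concordance(rank_diseases(totals),
                 rank_diseases(reweight(lapply(agg, `[[`, "consensus"), model, sc)))
#> [1] 0.9092412
```

A tau-b of 0.91 means dropping the trade criterion reverses only a few
percent of the pairwise orderings in this small study.

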