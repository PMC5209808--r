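---
title: "Weighted multi-criteria disease prioritisation and control-tool gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted multi-criteria disease prioritisation and control-tool gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priogap)
```

## The scoring model

`priogap` implements a *closed weighted scoring system* for prioritising
infectious animal diseases. A model is an ordered set of criteria; each
criterion groups several scored items ("levels" or sub-criteria) and carries a
single per-level weighting coefficient

$$W = \frac{100}{X \cdot I}$$

where $X$ is the maximum score of the criterion's scale and $I$ the number of
levels. This normalisation guarantees that every criterion's maximum weighted
total is exactly 100, so all criteria enter the overall score with equal
weight regardless of how many levels they contain or which scale they use.
The guarantee is enforced structurally: `criterion_spec()` always computes the
coefficient itself, `validate_model()` re-checks
$|W \cdot X \cdot I - 100| \le 10^{-9}$, and the JSON serialisation never
stores coefficients at all — they are recomputed on load.

The default **prioritisation model** (`default_prioritisation_model()`) has
six criteria — disease knowledge (10 levels), impact on animal health and
welfare (3), impact on public health (6), impact on wider society (3), impact
on trade (4) and control tools (3). The first five use the 0..4 scale; the
control-tools criterion uses −2..+2, oriented so that *missing* tools add to a
disease's priority and effective existing tools subtract from it. The overall
score is the unrounded sum of the six weighted criterion totals and is
therefore bounded in $[-100, 600]$.

The default **gap-analysis model** (`default_gap_model()`) scores three
control-tool areas — diagnostics (12 levels), vaccines (11) and
pharmaceuticals (11) — each on −2..+2, where +2 marks an important research
gap and −2 adequate current tools. Area totals are rounded to integers
(halves away from zero); a positive total flags a gap.

### The availability override

The first level of each gap area is product availability. When no product
exists at all (flag `"none"`, not even in development), the whole area is
overridden. The published rule fixes a "maximum score of 20" for the whole
criterion; the published score table, however, shows an apparent ceiling of
40 that the rule alone does not explain. Both readings are therefore
implemented as explicit modes of `gap_totals()`:

* `raw_cap` (default): the raw score sum is set to 20 and then weighted —
  the literal reading. For vaccines this yields $20 \cdot 100/22 = 90.9
  \rightarrow 91$.
* `display_cap`: the final area value is set to a configured cap, default 40,
  matching the observed table ceiling.

The mode is an argument (and is logged by the command-line wrapper) because
the per-sub-criterion data needed to decide between them empirically were
never published.

## Rounding conventions

The reference tables print the same coefficient inconsistently (100/24
appears as both 4.16 and 4.17, and 100/6 as 16.66). Internal consistency
was preferred over reproducing two mutually contradictory renderings:
coefficients are stored at full precision and *displayed* at two decimals
with halves rounded away from zero (`display_weight()`), giving 4.17 and
16.67. The same half-away-from-zero rule (`round_half_away()`) is used for
integer gap totals and for even-panel consensus medians, so a single
convention governs every rounding site in the package. `round_half_away()`
adds a $10^{-9}$ guard before truncating so that rationals such as
$100/22 \cdot 20$ stored a hair below an exact half round as intended; all
quantities rounded in this package are ratios of small integers, for which
the guard is exact.

## Expert-panel aggregation

Panels of experts score each disease; the elicitation design asks for at
least four experts jointly covering diagnostic, epidemiological, industry and
economic expertise (`panel_scores()` computes this coverage flag, and
`panel_coverage_summary()` reports it across a study). `aggregate_panel()`
reduces a panel to a consensus sheet:

* **Consensus statistic: the median.** The reference process records only
  that groups "reached a consensus"; the median reproduces unanimous panels
  exactly, is robust to a single outlying expert, and stays within the range
  of the observed scores.
* **Even panels** produce half-valued medians; these are rounded away from
  zero by default — toward the more extreme judgement (higher priority, or
  deeper gap), the conservative direction for a prioritisation exercise. The
  alternative (`half = "toward_zero"`) is available and documented because
  the choice is a convention, not a fact about the data.
* **Dissent is recorded, not erased.** Whenever the spread of expert scores
  on a sub-criterion exceeds `dissent_threshold`, a dissent record (scores,
  range, consensus value) is emitted alongside the consensus: failure to
  converge is itself a knowledge gap worth reporting. The default threshold
  of 1 treats adjacent scores (2 vs 3) as agreement; a gap is flagged only
  for a range of 2 or more. The reference process does not state what value
  was recorded when consensus failed, so both a consensus value and the
  dissent record are produced rather than guessing.
* Availability flags are aggregated by majority with ties resolved toward
  the more severe level (`none` > `in_development` > `available`), so a
  split panel never hides a missing product.

## Rankings and sensitivity analysis

`rank_diseases()` and `rank_gaps()` use competition ranking: tied scores
share a rank and the next rank is skipped (1, 2, 2, 4). Ties are listed
alphabetically by disease name in byte order, which is deterministic across
locales. The published tables order a few tied diseases non-alphabetically;
since tied entries share a rank, the two presentations carry identical
rank information and the alphabetical convention is simply this package's
deterministic choice of print order.

Because the overall score is a weighted sum, different stakeholders may
prefer different weightings. `reweight()` recomputes totals under a
`weight_scheme()` (criterion → weight, replacing the per-level
coefficients), and `rank_concordance()` quantifies how much a re-weighting
perturbs the ordering using Kendall's $\tau_b$ — chosen over Spearman's
$\rho$ because sensitivity questions here are about pairwise order
reversals, and $\tau_b$'s tie correction matches the integer, tie-rich
scores. The computation delegates to `stats::cor(method = "kendall")`; the
test suite pins it against an exhaustive concordant/discordant pair count
on small instances. Scaling all weights by a positive constant provably
leaves every ranking unchanged ($\tau_b = 1$ against baseline).

## The synthetic-study generator

No raw per-expert score sheets were ever deposited for the reference
exercise, so the package ships a generator (`generate_study()`) that
emulates the study's *structure* and makes every pipeline stage testable:

* 52 diseases split 18 / 15 / 19 across epizootic, food-producing and
  zoonotic categories — the column sizes of the published per-category
  ranking — via deterministic largest-remainder allocation;
* one latent integer score per sub-criterion, uniform over the scale,
  shifted by category effects and clamped. The default effect (+2 on the
  public-health criterion for zoonoses) reproduces the qualitative pattern
  that zoonoses dominate the public-health dimension;
* panel sizes Poisson-distributed around 7 (the reported average), floored
  at `panel_size_min` (default 1; a panel needs at least one expert — the
  reference study itself had panels of three or fewer for 9 of 52
  diseases);
* per-expert sheets equal to the latent sheet plus Gaussian noise rounded
  to an integer and clamped to the scale. The noise level (default sd 0.5)
  is *illustrative*: true inter-expert disagreement was never reported, so
  no default can claim to be estimated;
* gap areas flagged `"none"` with probability 0.1 (remaining mass split
  evenly between `"available"` and `"in_development"`).

Latent scores are integers because the elicitation instrument is
integer-valued. All draws for disease $i$ come from a substream seeded by an
integer hash of `(seed, i)`, so a study is bit-reproducible and extending the
disease list never perturbs earlier diseases' draws. Expert roles are
assigned cyclically through the five role labels, so any panel of four or
more meets the coverage minimum — the generator models the *structured
recruitment* of panels, not the recruitment failures that left 17% of the
reference panels under-covered.

`recovery_report()` closes the loop: it compares aggregated consensus sheets
against the latent truth (exact-match fraction per sub-criterion, mean
absolute error, top-$k$ ranking overlap). With zero noise recovery is exact
by construction; with noise, mean absolute error shrinks as panels grow —
the aggregation benefit the consensus design relies on. The test suite
checks this over 20 replicate seeds at panel sizes 3 vs 7, the zoonosis
effect at 300 diseases with one seed, and oracle equivalence of the scoring
engine against a naively coded summation on 1,000 random sheets; these sizes
keep the default suite comfortably fast while leaving the Monte-Carlo
comparisons well away from their decision boundaries.

What passing these tests does *not* show: that real expert panels behave
like clamped-Gaussian perturbations of a latent truth, that real
sub-criterion scores are uniform, or that the published overall scores can
be recovered — their sub-criterion decomposition exists only on the
project's website and is deliberately not modelled (`fixture` tables store
the printed integers as given).

## Packaged reference tables

`load_fixture()` exposes the published structures: the two model definitions,
the 52-disease overall ranking (top score 464, Nipah virus), the same 52
diseases ranked within category, and the 30-disease gap-score table (top 10
per category). Fixtures are transcribed data guarded by MD5 checksums and
structural invariants (52 entries; the category table partitions the same
diseases with identical scores; 10 gap rows per category); they are never
regenerated at run time. Name variants between the printed tables (e.g.
"Coccidiosis" vs "Poultry coccidiosis") are normalised to one canonical
spelling so `disease_id`s join across fixtures. Whether the printed overall
integers are rounded weighted sums or exact values cannot be determined from
the printed record; the fixtures store them as given and the prioritisation
engine itself never rounds.

## Degenerate inputs and error behaviour

Incomplete sheets fail validation — there is no imputation, because the
reference panels scored every criterion. Unknown categories, roles and
availability flags are rejected at parse time (closed enumerations).
Validation problems raise classed conditions (`priogap_validation_error`,
`priogap_invalid_argument`, `priogap_io_error`) that the command-line
wrapper maps to exit codes 2 / 2 / 3. `validate_model()` is the exception by
design: it *returns* violations so a user can inspect a broken model without
try/catch scaffolding. File writers stage to a temporary file and rename, so
a failed write never leaves a partial file, and identical inputs always
produce byte-identical CSV/JSON output.

## Known limitations

* The published overall scores cannot be recomputed from first principles
  (no public sub-criterion data); correctness of the engine rests on the
  normalisation guarantee, the extreme-value identities and the
  property-based oracle tests instead.
* Only one weight per criterion is supported — the reference design weights
  at the level/criterion granularity, and per-sub-criterion weights are out
  of scope.
* The consensus process itself (meetings, moderation, re-scoring) is not
  modelled; the median-plus-dissent aggregation is a reproducible stand-in
  for an inherently social procedure.
* Stakeholder-derived weight estimation (e.g. conjoint analysis) is not
  implemented; `weight_scheme()` expects the weights to be given.
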