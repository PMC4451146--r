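---
title: "Ancestral paternal age, mutation load and fitness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral paternal age, mutation load and fitness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmama)
```

## The scientific question

De novo point mutations in the human germline accumulate with the father's
age — roughly 20 extra point mutations per additional decade, about a
one-third increase between paternal ages 30 and 40 — and are transmitted to
descendants with Mendelian halving: an individual mutation is as likely to
have been acquired from the father as from the two grandfathers combined, or
from the four great-grandfathers combined. A mutational burden therefore
builds up over *several* ancestral generations, and looking only at a
father's age misses most of it.

This package implements the statistic that captures that burden, the
machinery to relate it to fitness outcomes in multi-generation pedigree data,
the deterministic load calculus that converts observed fitness declines into
per-generation mutational load, and a forward-time pedigree simulator that
provides data with the assumed causal structure (historical church-record
pedigrees of this kind are not publicly deposited).

## The WMAMA statistic

For a focal individual (proband), the weighted mean age of male ancestors is

$$m = \frac{\sum_{i=1}^{N} a_i r_i}{\sum_{i=1}^{N} r_i},$$

where $a_i$ is the age at which male ancestor $i$ fathered the next
individual in the proband's lineage and $r_i$ is the coefficient of
relationship: 0.5 for the father, 0.25 for each grandfather, 0.125 for each
great-grandfather. Unknown ancestors simply drop out of both sums, so the
statistic renormalizes over whatever is known. With all seven male ancestors
known the weights sum to $\sum r_i = 0.5 + 2(0.25) + 4(0.125) = 1.5$.

```{r}
ped <- read_pedigree(system.file("extdata", "synthetic_pedigree_4gen.tsv",
                                 package = "wmama"))
anc <- collect_male_ancestors(ped, "g4_18")
compute_wmama(anc)
```

Eligibility follows the convention of church-record pedigree analyses: a
proband enters analysis
cohorts only if the father's and both grandfathers' ages are known;
great-grandfathers are optional (0--4 known), and the renormalization
handles the varying weight sum. Ages are computed from birth years;
fractional years are honoured when present, and integer-year data carry a
documented ±1-year quantization.

Because the variance contributed by an ancestral generation halves each
generation back (twice as many ancestors, each with half the weight), the
information about the proband's mutation count is expected in the ratio
1 : 0.5 : 0.25 across fathers, grandfathers and great-grandfathers. Dropping
the father's age therefore forfeits $1/1.75 \approx 57\%$ of the signal when
all six older ancestors are known, and $1/1.5 \approx 67\%$ (printed
truncated as 66%) when only grandfathers are:

```{r}
expected_signal_shares(c(1, 2, 3))$father_loss
expected_signal_shares(c(1, 2))$father_loss
```

This is the generation-weight approximation, not an empirical variance
decomposition — a deliberate design choice mirroring the argument it
implements.

## The mutational-load calculus

The per-generation reduction in mean fitness from newly arising deleterious
mutations under relaxed selection is $\Delta_R = U \bar{hs}$, with $U$ the
diploid deleterious mutation rate and $\bar{hs}$ the mean heterozygous
selection coefficient. $U = 2 \mu L f$ from the per-site rate $\mu$, the
sites considered $L$ and the deleterious fraction $f$:

```{r}
deleterious_rate(1.2e-8, 3e7, 0.75)   # amino-acid-changing: U = 0.54
deleterious_rate(1.2e-8, 3.2e9, 0.05) # 5% of the genome functional: U = 3.84
load_reduction(0.54, c(0.029, 0.058)) # coding-only bracket
load_reduction(3.84, c(0.029, 0.058)) # genome-wide bracket
```

A cumulative fitness decline observed over three ancestral generations,
divided equally among them, gives a per-generation decline $\delta$; with
the load at paternal age 40 assumed $4/3$ of that at 30 (the one-third
increase in mutation count), the system $\Delta_{40} = \tfrac{4}{3}
\Delta_{30}$, $\Delta_{40} - \Delta_{30} = \delta$ yields the age-specific
loads. A useful closed-form check: with 3 generations and ratio $4/3$,
$\Delta_{30}$ equals the cumulative decline itself.

```{r}
load_from_age_effect(0.04)        # ~0.12 at age 30, ~0.16 at age 40
fitness_decline_load(0.001)       # lower credible bound
fitness_decline_load(0.254)       # upper credible bound
```

One caveat is intentional: dividing a 4% per-generation decline by the ~1
extra deleterious mutation separating paternal ages 30 and 40 gives an
implied $\bar{hs} = 0.04$, not the widely quoted 0.12; `implied_mean_hs()`
computes the plain ratio and its documentation spells out the alternative
reading ($0.04 / \tfrac{1}{3} = 0.12$) that reproduces the larger figure.
We do not silently adopt either.

## The synthetic pedigree generator

`simulate_population()` produces a strictly monogamous, discrete-generation
population in which the assumed mutational mechanism is the generative
truth, plus a per-individual truth table for validating every downstream
step. The design:

* **Mutations.** A child receives de novo deleterious mutations
  Poisson-distributed with mean $(\lambda_{\mathrm{ref}} + \beta(a - 30))
  f_{\mathrm{del}}$ for paternal age $a$ (defaults: $\lambda_{\mathrm{ref}}
  = 60$ point mutations at age 30, $\beta = 2$ per year, $f_{\mathrm{del}} =
  0.05$), a maternal age-independent mean of $15 f_{\mathrm{del}}$, and a
  binomial half of each parent's own count (one draw per meiosis).
* **Selection.** Survival to age 15 is $s_0 (1-hs)^k$ for total deleterious
  count $k$ (defaults $s_0 = 0.62$, $hs = 0.04$), shifted on the logit scale
  by nuisance covariates (parish intercepts, social class, twin status,
  maternal age) drawn once per run. Non-survivors never marry or reproduce,
  so selection purges load each generation. The multiplicative form is the
  standard load model and matches $\Delta_R = U\bar{hs}$ to first order; no
  particular functional form is implied by the load calculus itself.
* **Demography.** Founder couples are mutation-free with birth years near
  1700; paternal ages at each birth are truncated-normal (mean 33, sd 6, on
  [18, 60]); wives must be within a fertile window of 16--45 and both
  parents alive at each birth; survivors marry within parish at ages ~19--24
  with probability 0.85 and completed families average 7 births. Twin births
  (1.5%) and emigration (2%) provide the covariate and censoring structure
  the eligibility filters need. A hook
  (`female_marriage_wmama_slope`) adds a female-specific marriage penalty per
  WMAMA year, off by default, so the marriage analysis has a recoverable
  truth when enabled.
* **Reproducibility.** One master seed set at entry drives the whole run;
  identical configurations reproduce byte-identical pedigrees and truth
  tables. Per-stage reseeding was considered and dropped: generations are
  simulated as single vectorised blocks, so stage boundaries are not
  meaningful replay points.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: genealogical record errors, extra-pair paternity
(treated as zero; <1% in comparable record-linkage studies), social
transmission of mortality risk, overlapping generations and remarriage, and
a population at mutation--selection equilibrium. The last point matters. At
the default parameters the equilibrium load would be $\bar{k} = U/hs \approx
94$, implying survival near 1%, so no viable equilibrium exists; founders
start mutation-free as specified and the population is in a transient in
which load grows by roughly $U$ per generation. Two consequences are
documented here deliberately:

1. Realized child mortality is ~55% rather than the ~40% of the historical
   population, because the configured baseline $s_0 = 0.62$ sits on top of a
   growing mutation burden.
2. The mutation count correlates with calendar time, and the monogamous,
   fertile-window-constrained demography ties birth years together
   (correlation between a father's and a grandfather's ages at fathering is
   about −0.15). Both effects attenuate the regression of the mutation count
   on WMAMA from its naive value of $2 f_{\mathrm{del}} \beta \sum r_i =
   0.3$ per year to roughly 0.1--0.2, and the fitted survival-on-WMAMA logit
   slope to about −0.01, noticeably weaker than the ~−0.036 scale reported in
   historical-population analyses. The package's power-calibration check reflects this
   honestly: under the default effect size the fitted slope is negative in
   roughly three-quarters of seeds, not 95%.

## The association analyses

Four fitness components are analysed, each on a cohort assembled by
`build_cohort()` under the eligibility filters (born before 1900;
father and both grandfathers' ages known; social class known — the father's
for survival/longevity/marriage, one's own for breeding success;
outcome-specific follow-up rules; attrition audited per filter):

| outcome | family | notes |
|---|---|---|
| `survival15` | binomial-logit | excludes pre-15 emigrants |
| `longevity` | Poisson-log | years lived past 15, survivors with known death |
| `marriage` | binomial-logit | followed to 45 (f) / 50 (m); fit sexes separately |
| `lbs` | Poisson-log | children born; ever-married survivors to 45/50 |

Analyses of this kind are classically fitted as Bayesian generalized linear
mixed models with random intercepts for maternal identity and birth year.
This package deliberately replaces that machinery with maximum-likelihood GLMs plus
cluster-robust standard errors on maternal identity and stratified
permutation tests — the inferential target (sign and size of the exposure
coefficient with family clustering respected) is preserved without MCMC, and
birth year can enter as 25-year fixed bins (`"birth_year_bin"`), a standard
discretization for historical cohorts. Model pruning (`backward_prune()`) follows the usual reporting convention:
iteratively drop non-exposure fixed effects whose 95% interval covers zero,
never the exposure, and retain maternal age if it was significant before the
exposure entered. A person-year logistic hazard (`discrete_time_hazard()`)
stands in for the mixed-effects Cox model — for annual records and small
per-year hazards the two agree to first order — and AIC replaces DIC for
interaction screening.

Numerical and degenerate-input choices: Wald intervals use the normal
quantile on robust standard errors; rank-deficient designs and
non-convergence are hard errors naming the offending terms; binomial factor
levels in which the outcome never varies (e.g. a parish where everyone
marries) are dropped with a warning rather than fitted to ±∞; quartile cut
points use linear-interpolation empirical quantiles with ties assigned to
the lower quartile; permutation p-values use the add-one estimator
$(1 + \#\{|\beta^\*| \ge |\hat\beta|\})/(B + 1)$ with exposure permuted
within parish strata.

`translate_effect()` converts a fitted binomial coefficient into the
headline quantity "percent decline in outcome probability between WMAMA 30
and 40": inverse-link predictions at the two exposure values with covariates
at a reference profile (reference factor levels, numeric covariates at their
cohort mean — the original prediction profile is unstated, so ours is
explicit), reporting the absolute and the relative decline. Both are
reported because a quoted "13.5% decline" is ambiguous between the two
conventions: quartile means falling from 62% to 52% survival, for example,
are ~10 points absolute but ~16% relative.

## Problem sizes and calibration conditions

All empirical checks are seed-reproducible and sized as the package's own
study conditions: eligible analysis rows come to roughly 6.8× the number of
founder couples in a five-generation run, so null-calibration runs use 300
founder couples (≈2,000 rows, 100 seeds, hs = 0) and effect-size runs use
600 (≈4,000 rows, 100 seeds, hs = 0.04). Monte-Carlo checks of the mutation
laws use 10,000 draws; the WMAMA engine is checked against a brute-force
weighted mean on 1,000 random ancestor sets; the 13.5%-decline recovery uses
direct logistic cohorts of 4,000 over 100 seeds.

## Known limitations

* The load calculus is deterministic point arithmetic; no uncertainty
  propagation.
* No imputation of missing ancestor ages; unknown ancestors renormalize out.
* The simulator tracks mutation counts, not sites; no linkage, epistasis or
  epigenetic inheritance.
* Discrete generations with within-generation age variation; no remarriage
  or overlapping cohorts, and the pedigree schema does not distinguish
  birth parish from residence parish, so an exclusion of
  probands born outside their parish of residence cannot be expressed.
* Bayesian posterior summaries (posterior modes, HPD intervals) are out of
  scope; the ML + permutation machinery answers the same qualitative
  questions.
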