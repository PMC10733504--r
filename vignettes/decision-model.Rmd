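---
title: "The deafness screening decision model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The deafness screening decision model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deafscreenCEA)
```

## The decision problem

Most congenital deafness with a genetic cause in East Asian populations
traces to autosomal-recessive mutations in *GJB2* and *SLC26A4*. A
pre-pregnancy carrier screening programme tests women planning pregnancy
and — only when the woman carries at least one pathogenic allele — their
partners (two-step, or cascade, screening). The couple's joint genotype
places the family in one of four risk categories:

| category | genotypes | Mendelian deaf-birth risk |
|---|---|---|
| high | bi-allelic × bi-allelic | ~1 |
| medium-high | bi-allelic × mono-allelic | 1/2 |
| medium-low | mono-allelic × mono-allelic | 1/4 |
| low | either spouse negative | 0.001 |

High-risk couples receive counselling and choose between natural birth and
not having children. Medium-risk couples face a four-way choice: ART with
preimplantation genetic testing (PGT), amniocentesis (with a Mendelian
fetal diagnosis and, on a positive result, a birth/terminate decision),
natural birth, or no children. The comparator ("status quo") is no
screening and no intervention: every couple gives birth naturally at its
category's Mendelian risk.

The package represents each strategy as its own probability tree
(`build_screening_tree()`, `build_status_quo_tree()`) rather than as a
single tree with a root decision node; the two-row strategy table and the
probabilistic sensitivity analysis both re-evaluate strategies
independently, so keeping them separate simplifies every downstream step.

## Payoff models

Each terminal node carries four payoffs simultaneously — `cost`,
`eff_deaf`, `eff_healthy`, `eff_utility` — and the three published payoff
models select which effect is compared:

1. **deaf** — effect 1 for a deaf birth, 0 otherwise; screening *averts*
   deaf births, so the incremental effect is negative and the result is
   presented as cost per deaf birth averted, `|ΔC/ΔE|`.
2. **healthy** — effect 1 for a healthy birth; a conventional signed ICER
   `ΔC/ΔE`.
3. **utility** — effect in lifetime QALYs (22.1 healthy, 20.1 deaf, 0 for
   no birth); costs additionally include the born individual's discounted
   lifetime medical expenditure minus lifetime income, so birth leaves have
   large negative net costs.

Path costs accumulate exactly what happened on the path: one 64.20 USD
screen per tested person, ART+PGT (11,940.30 + 28.70 productivity loss) or
amniocentesis (2,686.60 + 14.40) where chosen, and the reproductive cost
651.00 on every path that ends in a birth (including ART births).
Termination after a positive amniocentesis carries no further cost — no
such cost appears among the model inputs. Childless leaves carry zero
utility and no lifetime financials; this convention is what makes the
published population-utility result reproducible, and its ethical weight
belongs to the policy discussion, not to the package.

A `cea_comparison` keeps the strict dominance taxonomy (`alt_dominated`
iff ΔC > 0 and ΔE < 0, `alt_dominant` iff the reverse, `tradeoff_icer`
otherwise) *and* always reports `|ΔC/ΔE|`, because the published results
use both presentations for the same comparison (a "dominated" tag in the
strategy table, a cost-per-case-averted in the abstract).

## Economic derivations

Lifetime quantities are annual amounts times a discounted lifetime factor.
The national life table behind the published factor is not part of the
model inputs, so the factor is a first-class calibrated parameter,
`u.lifetime_factor = 115622/5243 ≈ 22.0527` — the ratio of the published
lifetime income of a healthy individual to the 2021 annual disposable
income. This single factor reproduces every published lifetime value to
within 0.1% and, with the 0.91 deafness utility weight, the 22.1/20.1
lifetime QALY pair after rounding. Users with an explicit survival horizon
can instead call `discounted_lifetime_factor(rate, horizon, timing)`;
neither pure annuity form yields 22.05 at a plausible integer horizon,
which is why the calibrated ratio is the default rather than a derived
value. The deaf QALY defaults to the *printed* 20.1 rather than the
unrounded 22.1 × 0.91 = 20.111, because the published utility table was
evidently computed with the rounded constant; `derive_deaf_qaly()` exposes
both.

One input inconsistency is worth recording: the 2021 disabled disposable
income is published as \$2,992.70, but projecting the stated 2018 base at
the stated 7.56%/yr growth gives ≈\$2,539.70. The lifetime value 65,996
derives from the printed figure, and the printed figure wins — the package
treats published lifetime values as the model inputs and does not attempt
to re-derive them.

The willingness-to-pay threshold is three times the 2021 GDP per capita
for a whole discounted life: `derive_wtp(12086, 3, 22.1)` = 801,302 USD.

## Sensitivity apparatus

**One-way (tornado).** Each scalar input moves over a provenance-based
span — ±20% for survey-derived values, ±10% for literature, expert and
Mendelian values (both configurable). After any perturbation the siblings
of a sum-to-one block (genotype triples, the high-risk pair, the
medium-risk four-way choice, the post-amniocentesis pair) are rescaled
proportionally, so every probability block stays on the simplex; spans
that would push a probability outside [0, 1] are clipped with a warning.
Perturbing the deafness utility weight re-derives the deaf QALY, since the
model consumes the derived value.

**ART-uptake threshold.** The uptake `u` of ART with PGT among medium-risk
couples is swept over [0, 1]. Two reallocation rules are provided, because
the published break-even cannot be reproduced exactly under either and the
rule actually used is unstated: `none_absorbing` (default) holds
amniocentesis and natural birth at base and lets the no-children mass
absorb the change, clipping at zero with a proportional fallback once that
mass is exhausted (at u ≈ 0.234); `proportional` rescales all three
non-ART choices. The break-even where incremental healthy births cross
zero is found by bisection (`uniroot`, tolerance 1e-6): ≈17.1% under
none-absorbing and ≈15.9% under proportional, bracketing the published
17.4% within the documented rule ambiguity.

**Probabilistic (PSA).** Per draw, both trees are rebuilt from a sampled
parameter set and (ΔC, ΔE) recorded. Sampled components follow the
published design: the three key intervention costs (screening test,
ART+PGT, amniocentesis) are gamma-distributed; the reproductive-decision
probabilities are beta (binary pairs, complementary) or Dirichlet (the
four-way medium-risk choice); the deafness utility weight is beta.
Genotype prevalences are held fixed — they are observed data, not
modelling assumptions. Distribution spread is not published, so the
package defaults to a coefficient of variation of 0.2 for costs and 0.1
for probabilities/utilities, fitted by method of moments (gamma:
shape = 1/cv²; beta: matched mean and sd; Dirichlet: concentration chosen
so the largest component has the target cv). All are configurable through
`psa_spec()`, and cv = 0 degenerates every draw to the base case exactly —
a property the test suite exploits. Acceptance uses net monetary benefit
(`wtp·ΔE − ΔC ≥ 0`), which stays well defined when a draw lands on
ΔE = 0. The (ΔE, ΔC) cloud is summarised by its mean, covariance and the
χ²(2)-quantile 95% ellipse.

## The synthetic cohort

`generate_cohort()` draws individual-level couples with independent
multinomial genotypes per spouse — deliberately mirroring the analytic
model's product-of-marginals joint distribution (no assortative mating, no
same-gene matching adjustment; a `concordance` factor is available in the
tree builders but defaults to 1, which reproduces the published joint
probabilities). `two_step_screen()` enforces the cascade: husbands are
tested iff the wife is positive, and the male-genotype summary is
estimated on the tested subset, as in the study population (the study
recruited 6,200 women and 540 partners with 100% partner compliance).
`simulate_families()` then samples each family's decisions and outcome
with exactly the costs the tree assigns to that path, giving an end-to-end
Monte Carlo oracle: its outcome fractions and mean cost converge to the
tree rollback, and the tests assert agreement within three standard errors
at 200,000 families.

What the generator does *not* emulate: per-mutation allele structure (the
45-variant panel is collapsed to carrier status), location strata,
sequencing error (genotyping is treated as error-free, as in the analytic
model), repeat pregnancies and multiple gestations. Passing tests
therefore validate the internal consistency of the decision model, not the
field accuracy of the screening assay.

The wife genotype frequencies used analytically (0.0050/0.1572/0.8378) are
the screening-table values; the study-population table rounds the
mono-allelic share slightly differently (15.4%). The analytic model uses
the former, the cohort emulation accepts either; the two are not
reconciled in the source material.

## Numerical choices

- Probability-block and outcome-mass conservation is checked to 1e-9;
  payoff arithmetic is double precision, and the exhaustive
  path-enumeration oracle must agree with rollback to 1e-12 relative.
- Branch order is part of the tree definition; the tree microsimulation
  samples by inverse CDF over the depth-first path distribution, so a seed
  identifies the same sample on any platform.
- The reconstructed screening-arm expected cost is 816.85 USD against the
  published 817.60 (< 0.1%); the residual is documented rather than
  chased, and it propagates to ICERs that sit within 1% of the published
  values. The husband's screen is charged at the full 64.20 per-person
  cost, only when the wife is positive.
- The high-risk natural deaf-birth probability is not among the published
  branch probabilities; it defaults to 0.999, symmetric with the
  confirmed-positive birth outcome rows, and reproduces the published
  0.0073/0.0022 effectiveness pair at the printed precision.
- `run_psa()` at its default 10,000 draws evaluates in well under a minute
  per payoff model; the test suite runs the full three-model PSA, a
  200,000-path microsimulation and a 200,000-family cohort validation as
  its standard problem sizes.

## Known limitations

No Markov extension (deafness severity progressing over time), no
screening test sensitivity/specificity, no two-way sensitivity surfaces or
value-of-information analysis, no currency or inflation engine, and no
plotting: every analysis writes plain tables from which the standard
figures (tornado, threshold curve, CEAC, ICE scatter with ellipse) are one
call away in any plotting layer.
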