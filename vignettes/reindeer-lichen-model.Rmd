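---
title: "An age- and sex-structured bioeconomic model of reindeer husbandry under variable winters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An age- and sex-structured bioeconomic model of reindeer husbandry under variable winters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system and the questions

Semi-domesticated reindeer in Fennoscandia live off winter pastures whose
key resource is ground lichen. Winters differ: snow depth, hardness and
icing determine how large an area a reindeer can crater through per day and
how much energy cratering and movement cost. Difficult winters depress calf
production and survival; they also protect the pasture, because animals
that dig less also consume and trample less lichen. A herding district
decides each autumn how many animals of each age and sex to slaughter, and
(optionally) how much supplementary feed to deliver over the coming winter.

`poroeco` implements a district-level bioeconomic model of this system and
the three experiment families built on it:

1. deterministic dynamic optimization under constant average winters,
   converging to an economically optimal steady state;
2. single easy/difficult-winter perturbation experiments with optimal
   re-adaptation; and
3. certainty-equivalence feedback optimization over stochastic winter
   sequences, with ensemble averaging, with or without feeding.

All quantities are normalized to a hypothetical district with 1000 ha of
winter lichen pasture in old or mature pine forest (high lichen regrowth).

## Model structure

### State and annual cycle

The state is the autumn winter stock: 17 female age classes (calf, 1, ...,
16+) and 13 male classes (calf, 1, ..., 12+), plus the shared lichen
biomass $x$ (kg/ha). One model year runs autumn to autumn:

* **Winter energy budget.** The winter (200 days) is split into four
  sub-periods. In each, the crater energy density is the sum of a lichen
  term $\lambda(x) = c_L\, x^2/(x + k_u)$ (the $x/(x+k_u)$ factor is the
  accessibility of thin lichen mats) and a constant term $\omega$ for
  other cratered food (dwarf shrubs, hays, sedges). An animal can crater
  up to $\tau$ times its nominal daily area (34, 30 or 26 m$^2$/day for
  easy, normal and difficult winters), so at high biomass a reduced
  cratering area is fully compensated by longer cratering time, while at
  low biomass intake is area-limited. The covered fraction of needs is a
  smooth minimum of potential/need with width `cov_smooth`; the width is a
  physiological statement, not a numerical trick — even when the *mean*
  crater potential equals the need, within-winter variability leaves
  deficit days. Needs scale metabolically with body mass
  ($\propto m^{0.75}$, adult female $\approx 18$ MJ/day) and carry the
  winter-type multiplier 0.94/1.00/1.06. The herd's consumption plus
  wastage is removed from $x$ *within* the winter, so late-winter coverage
  is below early-winter coverage: winter stress is density-dependent.
* **Condition responses.** Accumulated deficits convert to relative weight
  loss $\rho$ via the tissue-energy constant (20 MJ/kg), linear to 25% of
  spring mass and saturating smoothly at 60% (animals reduce expenditure;
  losses are physiologically bounded). Fecundity responds as
  $\exp(-(\rho/s)^q)$ — flat for small, routine losses, with a long gentle
  tail — and survival as a normalized logistic cliff near the
  physiological limit: moderate losses suppress reproduction long before
  they kill adults. Surplus intake yields a small capped gain with no
  reproductive benefit (the "normal upper limit").
* **Reproduction.** Births follow a smoothed modified harmonic-mean mating
  system: the per-female mating probability is
  $\min(1,\, 2z/(1+z))$ with $z =$ harem size $\times$ effective males /
  breeding females, so it vanishes without males and saturates when males
  are abundant. Calves born in spring survive to the autumn round-up with
  probability 0.80.
* **Pasture.** Removal is consumption plus wastage; wastage rises with
  biomass (lush mats are trampled and dug up) and scales with
  $(\text{area}/30)^{2.2}$ — hard snow protects lichen from both
  consumption and wastage. Regrowth is logistic,
  $x' = x + r\,x(1 - x/K)$ with $r = 0.2$, $K = 3000$ kg/ha.
* **Round-up and cash flow.** Slaughter happens at the autumn round-up.
  Revenue is carcass mass (calves fetch a price premium) plus a
  per-animal subsidy on the new winter stock; costs are herding costs on
  the wintered stock, per-animal slaughter costs and feed at EUR 0.4/kg
  delivered. Flows are discounted with the first year undiscounted (the
  model year begins in autumn when slaughter revenue accrues).

### Decision form: escapement targets

The optimizers work with *escapement* policies: a kept-animal target per
class, everything above the target slaughtered. This is equivalent to
slaughter fractions at a steady state but self-stabilizing off it (a poor
calf crop automatically reduces slaughter, a rich one increases it), which
both matches how districts manage winter stocks and removes the
boom-and-bust artifacts that fixed proportional-harvest policies produce
in a grazing system. User-facing functions accept both forms.

### Optimization

The deterministic problem frees per-class decisions for the first
`t_trans` (10) years and a single stationary decision applied to the end
of a 150-year horizon; inside the objective the stationary policy is
additionally rolled 250 years further and the tail is valued from the mean
net revenue of the final 30 years, with a quadratic penalty on terminal
lichen drift (a stationarity terminal condition). Both guards exist for
the same reason: with slow pasture dynamics, a policy can look stationary
for a century while mining the resource, and the truncated objective must
see that. The problem is solved by L-BFGS-B over the box-constrained
decision vector with objective and forward-difference gradient evaluated
in compiled code, plus one jittered restart.

Feedback (certainty-equivalence) solutions re-optimize every year: the
next 3 years of per-class decisions are freed, the steady-state policy
continues for 60 more, the tail is a stationary continuation, and all
future winters are set to the expected winter type (the current winter is
known — feeding responds to conditions as they emerge). Only the
first-year decision is applied; the realized winter advances the true
state. Warm starts from the previous year keep each inner solve around a
tenth of a second.

Because the full model cannot be solved by backward induction (30
continuous state dimensions), the solver *strategy* is validated on a
reduced instance — one aggregated animal stock plus lichen — against an
exhaustive dynamic-programming oracle on a dense grid; the package tests
require agreement within 1%.

## Calibration

The parameterization was calibrated once, in this order, and then frozen:

1. **Diet structure.** $c_L$, $\omega$ so that more than 80% of winter
   energy comes from lichen above 1000 kg/ha while other cratered food
   dominates below 300 kg/ha.
2. **Winter-type responses.** The fecundity-response scale and shape so
   that the canonical reference herd at 500 kg/ha produces a 52% calf
   percentage in a normal winter and 30% under difficult-winter
   conditions (26 m$^2$/day, +6% energy need). The +-6% energy multiplier
   itself reproduces the published cratering-expenditure arithmetic: net
   hourly costs of 1.2–1.5 vs 2.3–2.9 kJ/kg/h for 8 h at an 18 MJ/day
   need give about a 6% increase for a 105-kg adult
   (`energy_need_increase()`).
3. **Economic scale.** Prices, subsidy and costs (calf carcass EUR
   6.5/kg, adult 5.35/kg, subsidy EUR 35/animal, herding EUR 12/animal-yr,
   slaughter EUR 6/animal) so that the optimal steady state at 0% interest
   yields annual net revenues near EUR 32,000 per 1000 ha with lichen
   biomass above 1000 kg/ha, more than 95% of male calves and about 60% of
   female calves slaughtered, and the steady-state biomass strictly
   decreasing in the interest rate.

The calf-price premium over adult meat is what makes intensive calf
slaughter optimal; reproductive senescence from age 10 concentrates female
culling around ages 9–12; and the harem size (20) makes the optimizer keep
males near the minimum that still saturates the mating probability.

## What the synthetic winter generator emulates

`generate_winter_sequence()` draws i.i.d. winter types from stated
probabilities (baseline 10/80/10; variants 20/60/20 and 40/20/40) with a
private, seeded RNG stream; ensemble replicates use seeds
`seed + 1 .. seed + reps`. Serial dependence between winters (cascading
effects of a previous season) is deliberately not modelled.
`simulate_coded_reports()` builds coded annual-report tables — one row per
district and herding year with 0/1 difficulty flags — from per-district
target counts, so that report-style summaries
(`tabulate_report_frequencies()`) are exactly recoverable; it is a
synthetic stand-in for archival district reports, not a model of them.

Passing tests on these inputs show that the *decision problem* responds to
winter variability as the calibrated model implies; they cannot show that
real districts face i.i.d. winters, and none of the archival content
analysis is reproduced here.

## Numerical choices

Kinks are smoothed (softplus/smooth-min) so the compiled objective is
differentiable: coverage saturation (width 0.07 in units of need),
escapement keep rule (width 0.1 animals), mating-probability cap and feed
uptake (width 0.01). The R reference implementation (`year_step()`) and
the compiled simulator use identical formulas; tests assert agreement to
1e-10. Fixed seeds make every experiment bit-reproducible on one machine.
Ties between a steady state and a small cycle around it are resolved by
cycle-averaging the final window of the extension.

Problem sizes in the shipped tests and acceptance script: deterministic
solves use the full 150-year horizon with the 250-year stationary
extension; perturbation experiments use 40 adaptation years; ensembles are
run at 10 replicates of 50 years (the full-scale experiment, 50 x 100, is
a few times slower and produces the same qualitative ordering).

## Known limitations

* Single pasture type, no spatial structure, no pasture rotation, no
  arboreal lichen, no predation; extreme ice-locked winters are outside
  the modelled range.
* The two winter-type anchors (52%/30% at 500 kg/ha) pin the
  condition response tightly in the biomass region where the 3% optimum
  rests. As a consequence the model's single difficult winter at that
  steady state costs a larger share of the first year's revenue than the
  published experiments suggest, and the escapement-buffered herd holds
  its winter stock roughly constant through a difficult year instead of
  shrinking slightly. The signs, the later-year recovery pattern, the
  asymmetry between difficult and easy winters, and the frequency scaling
  of stochastic losses all reproduce; `scripts/acceptance.R` prints the
  magnitudes this build actually attains.
* Within-year weather detail (snow-depth trajectories, icing events) is
  reduced to three categorical winter types with fixed physical effects.
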