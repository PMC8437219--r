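---
title: "Modelling colorectal cancer screening under selective and sporadic adherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling colorectal cancer screening under selective and sporadic adherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The question the model answers

Screening programs usually report adherence as a single number — the share
of the eligible population up to date with screening. That number hides the
longitudinal pattern behind it: 50% of people attending *every* annual FIT
round and 100% of people attending *every second* round are both "50%
adherence", but they expose very different sets of people to a first
screen. This package simulates both patterns over a lifelong horizon and
compares the cumulative colorectal cancer (CRC) cases, CRC deaths and
years of potential life lost (YPLL) they prevent.

## Natural history

The cohort model tracks occupancy fractions over these health states:

* lesion-free,
* non-advanced adenoma,
* advanced adenoma,
* preclinical (asymptomatic, undiagnosed) CRC,
* clinical (diagnosed) CRC, split by mode of detection (screen vs symptom)
  and years since diagnosis 0–14,
* dead of CRC, dead of other causes (both absorbing).

Annual transition probabilities between consecutive lesion states are
age-band- and sex-specific; the preclinical-to-clinical transition is the
reciprocal of the mean preclinical sojourn time and books a
symptom-detected diagnosis. Only *diagnosed* cancer carries CRC-specific
excess mortality; preclinical cancer can only die of other causes. That is
a deliberate simplification: a cancer that would kill before ever being
diagnosed is not observable as a CRC death in registry-type data, and
making preclinical disease lethal would require a diagnosis-at-death
pathway the model does not represent.

Propagation is by expected values (a deterministic cohort), not by
individual-level Monte Carlo. The expectations are identical; the cohort
form removes sampling noise from every comparison, makes runs byte-identical,
and keeps a 50-year two-sex scenario grid in the low seconds. A seeded
microsimulation would only matter for questions about variance, which the
package does not address.

### Within-year event order

A simulated year applies, in this fixed order:

1. the screening event, if one is scheduled at the current age;
2. lesion progression (non-cascading: each unit of mass advances at most
   one state per year), with years-since-diagnosis advancing for diagnosed
   cancer;
3. CRC-specific death by mode of detection and years since diagnosis;
4. other-cause death for every alive state.

No convention of this kind is canonical; what matters for reproducibility
is that one is fixed and documented. Screening-before-progression means a
test offered at age *a* sees the state the person brings *into* their
*a*-th year, which matches how screening visits actually precede the year
of risk they protect. Competing risks are applied multiplicatively in the
stated order rather than as jointly exponential rates; with annual cycles
and probabilities of the magnitudes used here the difference is far below
every tolerance in the test suite, and the multiplicative form keeps mass
conservation exact to machine precision. There is no half-cycle
correction: cycles are annual and outcomes are defined as cumulative counts
after whole years.

### Diagnosed-cancer mortality

Excess mortality after diagnosis depends on mode of detection
(screen-detected disease has the milder schedule) and fades with time since
diagnosis; after 14 years survivors carry no excess risk. The cap is a
pragmatic horizon for how long mode-of-detection survival differences are
empirically supported; it is configurable per parameter set (`ysd_cap`).

## Screening tests

Colonoscopy detects, per lesion state, `participation × sensitivity × mass`;
detected adenomas are removed (their mass returns to lesion-free),
detected preclinical cancer becomes screen-detected clinical cancer at
years-since-diagnosis 0. FIT positives — per-state sensitivity for
lesion-bearing participants, `1 − specificity` for lesion-free ones — all
receive a diagnostic colonoscopy, so FIT detection is the product
`sens_FIT × sens_colonoscopy` and false positives cost a colonoscopy
without changing state. A useful identity follows: FIT with a perfectly
sensitive stool stage and specificity 1 is *exactly* a colonoscopy round,
which the tests exploit.

Two simplifications are worth flagging. People with diagnosed cancer leave
the screening-eligible pool (standard program practice). And after
polypectomy, people simply re-enter the lesion-free state on their
scenario's ordinary offer schedule — there is no separate surveillance
track with shortened intervals. This overstates slightly the protection of
re-entry for sporadic attendees and is the model's main fidelity gap.

## Adherence patterns

For a strategy offering ages *A* (annual FIT 50–75, i.e. 26 offers;
colonoscopy at 50/60/70):

* `selective_adherence(p)` is the two-cohort mixture: weight *p* fully
  adherent, weight *1 − p* never screened. Every cumulative outcome is
  therefore *exactly* `p × (full adherence) + (1 − p) × (no screening)` —
  a structural linearity the test suite verifies to 1e-10 across random
  parameter sets.
* `sporadic_adherence(S)` sends the whole population to the offers in
  `S ⊆ A`. The `sporadic_every(strategy, k)` constructor anchors at the
  first offered age (50, 50+k, …): the first offer is where the incremental
  yield is largest, and anchoring there makes schedules nested and
  comparable across k.

Both have adherence level `p` resp. `|S|/|A|`. For display grids the
package pairs `selective(1/k)` with `every k years`, the conventional
presentation; for monotonicity analyses it pairs `selective(|S|/|A|)` with
the sporadic schedule so that the two arms of a pair sit at *identical*
levels. The distinction matters because `|S| = ⌈26/k⌉` moves in discrete
jumps: between k = 8 and k = 9 the sporadic arm loses a whole test while
`1/k` declines only smoothly, which can locally depress the
sporadic/selective ratio even though the ratio rises cleanly whenever the
level itself falls. The acceptance checks therefore assert monotone growth
of the ratios across distinct levels, not across raw k.

## Outcomes

Per scenario and per 100,000 starting population over 50 years: cumulative
CRC cases (screen- plus symptom-detected), cumulative CRC deaths, and YPLL
— each CRC death weighted by the remaining life expectancy at the integer
age of death (life expectancy at exact mid-year age would shift every
weight by under half a year, well inside the uncertainty of any life
table). Reductions are `100 × (baseline − scenario)/baseline` with a
zero baseline defined as zero reduction. Sporadic/selective ratios are
computed on unrounded prevented counts; rounding (whole percent,
one-decimal ratios) is applied only in `format_outcome_table()` for
display.

## Parameters and their defaults

Parameter sets are plain TSV tables plus a manifest; age bands are
half-open `[lo, hi)` so boundary ages resolve unambiguously, and ages past
the last band (80+) reuse the last band's rates — transition evidence for
the oldest ages is thin everywhere, and holding the last band constant is
explicit and conservative. The `variant` argument of `load_param_set()`
implements the sensitivity-analysis swap of every prevalence and
transition rate to its lower or upper 95% limit.

The synthetic generator (`synth_spec()` / `generate_param_set()`) emulates
the *structure* of registry-derived inputs, not any registry's numbers:

| quantity | default | why |
|---|---|---|
| non-advanced adenoma prevalence, men | 17% at 50 → 32% at 75 | colonoscopy-study magnitudes; rises with age |
| advanced adenoma prevalence, men | 3% → 7% | an order below non-advanced |
| preclinical CRC prevalence, men | 0.2% → 0.7% | rare but non-zero at 50 |
| female factor | 0.72 | women develop neoplasms later and less often |
| adenoma onset / progression rates | 1.3–3.2% per year, rising with age | keeps lifetime risk realistic |
| preclinical→clinical rate | 0.22 per year | mean sojourn ≈ 4.5 years |
| FIT sensitivity (non-adv/adv/preclinical) | 0.10 / 0.25 / 0.75 | stool tests barely see adenomas |
| FIT specificity | 0.96 | typical quantitative FIT cutoff |
| colonoscopy sensitivity | 0.75 / 0.95 / 0.98 | rises along the lesion sequence |
| all-cause mortality | Gompertz, sex-specific | life-table shape; life expectancy derived from the same curve for consistency |
| CRC excess mortality | 0.16·e^(−0.25·ysd), screen-detected × 0.45 | earlier detection is less lethal; excess fades |

The defaults were set so the implied no-screening lifetime CRC risk lands
in the commonly cited 3–7% band (the test suite recomputes this by running
the engine), and so screening effects are large enough that ordering
properties are tested far from numerical noise. Per-band jitter (±5%,
seeded) makes distinct seeds give distinct but structurally identical
sets; monotone age trends are re-imposed after jittering.

What the generator does **not** emulate: CRC stage at diagnosis, adenoma
multiplicity and location, surveillance after polypectomy, test-performance
heterogeneity, and correlated parameter uncertainty (CI bounds are
independent symmetric bands). Passing tests on synthetic sets therefore
demonstrate the *mechanics* — conservation, linearity, dominance,
direction and rough magnitude of pattern effects — not calibrated
predictions for any real population.

Four degenerate sets (`degenerate_sets()`) pin the engine analytically:
`null` (no lesions ever), `deterministic-chain` (unit transition rates, no
death — diagnosis timing is forced exactly), `perfect-test`, and
`useless-test` (screening provably a no-op).

## Numerical behaviour

* Mass is conserved to 1e-12 at every step of every run (tested).
* An age-independent chain reproduces the explicit one-year transition
  matrix raised to the n-th power to 1e-10 over 50 years (tested against a
  matrix built independently of the engine).
* Stored parameter files round-trip bit-exactly (`%.17g`).
* Degenerate inputs: participation 0, sensitivity 0, or an empty pattern
  reduce exactly to the no-screening run; a zero baseline yields zero
  reduction; a selective arm that prevents nothing flags its ratios `NA`
  rather than dividing by zero.

## Problem sizes

The reference analyses propagate one cohort per sex for 50 annual cycles
(ages 50–100; the early-start variant 45–100) with at most two weighted
sub-cohorts per scenario; the full two-sex comparison grid is 34 scenario
pairs. These sizes make the complete test suite and the scenario grid a
matter of seconds to a few minutes on a single core, which is why the
package runs everything deterministically rather than sampling.

## Known limitations

Beyond the generator's scope above: no stage-specific treatment effects,
no screening-related harms or costs, no behavioural adherence dynamics
(drop-out, late entry as processes — only the two idealized patterns), and
transition rates beyond the last age band are held constant. The two pure
adherence patterns are deliberate extremes; real populations mix them, and
the package's comparisons bound, rather than estimate, the effect of that
mix.
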