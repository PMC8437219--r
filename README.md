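# crcscreen

Deterministic multistate (Markov) cohort simulation of colorectal cancer
(CRC) screening, built to quantify how *longitudinal adherence patterns* —
not just the overall adherence level — drive a screening program's
long-term efficacy.

The package is for epidemiologists and screening-program modellers who want
to compare, at identical overall adherence levels:

* **selective adherence** — a fraction *p* of the population attends every
  offered screen, the rest never attend; and
* **sporadic adherence** — the entire population attends, but only a subset
  of the offered rounds.

## The model

A cohort of previously unscreened 50-year-olds (100,000 per sex) is
propagated in annual cycles through the adenoma–carcinoma sequence

```
no lesion → non-advanced adenoma → advanced adenoma → preclinical CRC → clinical CRC
```

with age- and sex-specific annual transition probabilities, other-cause
mortality from a life table, and — once cancer is diagnosed — excess CRC
mortality that depends on the *mode of detection* (screen-detected vs
symptom-detected) and years since diagnosis. Screening interrupts the
natural history: colonoscopy removes detected adenomas and converts
detected preclinical cancer to screen-detected clinical cancer; a positive
fecal immunochemical test (FIT) triggers a diagnostic colonoscopy, so FIT
detection follows the two-stage product rule
`sens_FIT(state) × sens_colonoscopy(state)`.

Propagation is by expected state-occupancy fractions (a cohort model), so
every run is deterministic and exactly reproducible.

For a strategy with offered ages *A* (annual FIT 50–75; colonoscopy at
50/60/70), the overall adherence level is

```
level = (people screened / people invited) × (tests used / tests offered)
```

so `selective(p)` has level *p* and `sporadic(S ⊆ A)` has level `|S|/|A|`.
Outcomes per scenario are cumulative CRC cases, CRC deaths and years of
potential life lost (YPLL = Σ deaths(age) × remaining life expectancy(age))
over 50 years, their percentage reductions against the matched no-screening
baseline, and the sporadic/selective ratios of *prevented* (baseline −
scenario) outcomes at matched levels.

Parameter sets live in plain tab-separated tables plus a YAML manifest
(`inst/extdata/synthetic-params/` ships a synthetic example), with optional
95%-CI columns used by the sensitivity analyses. `generate_param_set()`
creates structurally realistic synthetic sets from a seed.

## Worked example

```r
library(crcscreen)

params <- generate_param_set(synth_spec(seed = 1))
fit <- strategy_fit_annual()                      # annual FIT, ages 50-75

sel <- run_scenario(scenario_config("male", fit, selective_adherence(0.5)), params)
spo <- run_scenario(scenario_config("male", fit, sporadic_every(fit, 2)), params)
sel
#> <crc_outcome> male, start age 50, horizon 50 y (selective 50%)
#>   per 100,000: 3846 CRC cases, 1639 CRC deaths, 20724 YPLL
#>   reduction vs no screening: 38% / 42% / 42% (cases/deaths/YPLL)
spo
#> <crc_outcome> male, start age 50, horizon 50 y (sporadic at ages 50,52,54,56,58,60,62,64,66,68,70,72,74)
#>   per 100,000: 2461 CRC cases, 800 CRC deaths, 10153 YPLL
#>   reduction vs no screening: 60% / 72% / 72% (cases/deaths/YPLL)

compare_patterns(sel, spo)
#> <crc_comparison> sporadic vs selective adherence
#>   adherence level: selective 50%, sporadic 50%
#>   prevented (selective): 2359 cases, 1193 deaths, 14947 YPLL
#>   prevented (sporadic):  3744 cases, 2032 deaths, 25517 YPLL
#>   ratios sporadic/selective: 1.6 / 1.7 / 1.7
```

Both scenarios sit at a 50% adherence level, yet the sporadic pattern —
everyone screened every second year — prevents about 1.7 times more CRC
deaths than having half the population perfectly adherent: first-time
screens carry most of the preventive effect, and the sporadic pattern gives
everybody at least one.

`reproduce_tables(params)` runs the full matched grid (ten FIT levels and
the colonoscopy one-/two-age sporadic variants, both sexes);
`run_sensitivity_suite()` re-runs a scenario at the lower/upper 95% limits
of prevalences and transition rates and with screening starting at 45.
`exec/crcscreen` wraps all of this for the shell
(`generate-params`, `simulate`, `tables`, `sensitivity`).

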