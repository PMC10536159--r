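# faersignal

Disproportionality signal detection for FAERS-style spontaneous adverse
event reports, for pharmacovigilance analysts and methodologists who
want the complete screening pipeline — ingestion, deduplication, term
aggregation, four estimators with their decision rules, and a
ground-truth simulator — as tested, scriptable R functions rather than
ad-hoc SQL.

## What it computes

Spontaneous-report databases have no population denominator, so safety
screening asks whether a drug–event pair is reported *disproportionately*
often. For each pair the package builds the 2×2 table

|              | target event | other events |
|--------------|:------------:|:------------:|
| target drug  | a            | c            |
| other drugs  | b            | d            |

over (deduplicated case, distinct term) units and computes, with
`N = a+b+c+d`:

- **ROR** `= ad/(bc)`, 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
  signal if the lower bound > 1 and `a ≥ 3`
- **PRR** `= (a/(a+b))/(c/(c+d))`, analogous Wald CI and rule
- **BCPNN IC** `= log2(aN/((a+b)(a+c)))`; signal if `IC − 2SD > 0`,
  with `+`/`++`/`+++` strength bands at 1.5 and 3
- **EBGM-style ratio** `= aN/((a+c)(a+b))` with Wald interval; signal
  if `EBGM05 > 2`
- Pearson chi-square (Yates-corrected by default)

A pair is an **ADR** under the consensus rule only when all four
algorithms fire at once. IC and the EBGM-style ratio share one closed
form, so `IC = log2(EBGM)` exactly — an identity the test suite checks
on computed tables and on published value pairs.

The package also provides: FAERS quarterly ASCII IO (`$`-delimited
DEMO/DRUG/REAC/OUTC with dialect options), case deduplication (max
caseversion, then latest date, then max primaryid), PT→SOC aggregation
through any user-supplied hierarchy table (MedDRA is licensed and never
ships), Table-1-style demographic summaries, EBGM-ranked screens at PT
and SOC level with AE/ADR cascade counts, a reverse drug-by-event
screen with combination-product exclusion, and a seeded synthetic
generator with injected associations of known strength θ.

## Worked example

Simulate a 20,000-case quarter with one injected association
(θ = 5 between the target drug and `PT40`), then screen:

```r
library(faersignal)

cfg <- sim_config(
  n_cases  = 20000,
  injected = data.frame(drug = "EPIRUBICIN", pt = "PT40", theta = 5),
  seed     = 1)
dir <- tempfile("quarter")
pv_simulate(cfg, dir)                     # writes demo/drug/reac/outc + truth

sc <- pv_screen(dir, synonyms = "epirubicin", level = "pt")
head(format_signal_table(sc), 3)
#>   term  a              ROR              PRR  chi2           IC        EBGM band
#> 1 PT40 69 4.88 (3.43-6.94) 2.75 (2.35-3.23) 93.16  1.45 (1.22) 2.73 (1.92)    +
#> 2 PT29 50 1.33 (0.97-1.84) 1.25 (0.98-1.59)  2.80 0.32 (-0.03) 1.25 (0.91)    -
#> 3 PT38 19 1.27 (0.75-2.12) 1.20 (0.81-1.78)  0.57 0.26 (-0.31) 1.20 (0.72)    -
attr(sc, "cascade")
#>         n_terms       n_ror_prr n_ror_prr_bcpnn     n_consensus
#>              40               1               1               0
```

The injected pair leads the EBGM ranking with `a = 69` exposed cases
and ROR 4.88 (the Wald CI covers the true θ = 5); it is the only term
passing the ROR and PRR thresholds, and no term passes all four rules
in this draw (its EBGM05 of 1.92 sits just under the 2 cutoff — the
EBGM rule is the most stringent, which is why screens rank by it). The
background terms sit at ROR ≈ 1 with `-` bands, as a null should.

The descriptive summary of the same cohort
(`pv_describe(dir, synonyms = "epirubicin")`) reports 4,028 exposed
cases, 65.44% female / 12.56% male / 22.00% unknown, matching the
generator's configured marginals. The reverse direction —
`pv_reverse(dir, "PT40")` — lists every primary-suspect drug on `PT40`
cases with its own 2×2 statistics, excluding `\`-separated combination
products.

A command-line front end over the same functions is in
`inst/scripts/faersignal-cli.R`
(`simulate` / `describe` / `screen` / `reverse` subcommands).

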