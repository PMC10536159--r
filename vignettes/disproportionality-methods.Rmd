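---
title: "Disproportionality signal detection on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(data.table)
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting
System (FAERS) collect millions of drug/adverse-event reports but have no
denominator: there is no population at risk, only reports. The standard
way to screen such data for safety signals is *disproportionality
analysis*: for each drug–event pair, ask whether the event is reported
together with the drug more often than the overall reporting pattern
would predict under independence. `faersignal` implements the full
screening pipeline for this design — quarterly ASCII ingestion, case
deduplication, MedDRA-style term aggregation, four disproportionality
estimators with their decision rules, ranked screens in both directions
(events for one drug; drugs for one event), and a synthetic-data
generator with known ground truth so that every stage can be validated
without downloading the multi-gigabyte FAERS extract.

## The 2×2 table and its counting unit

Everything rests on a contingency table for one target drug and one
event term:

|              | target event | other events |
|--------------|:------------:|:------------:|
| target drug  | a            | c            |
| other drugs  | b            | d            |

The counting unit is the *(deduplicated case, distinct term at level)*
pair. At the preferred-term (PT) level a case contributes one unit per
distinct PT it reports; at the system-organ-class (SOC) level one unit
per distinct SOC after mapping, so a case never counts twice toward the
same SOC through two of its PTs. With this unit, `a` is exactly the
"case numbers" a publication table reports for a term, and the margins
`a+c` (all units from exposed cases) and `a+b` (all units carrying the
event) are well defined.

## The four estimators

With `N = a+b+c+d`:

* **ROR** (reporting odds ratio): `ad/(bc)`, with Wald interval
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`. Signal rule: lower 95% bound
  > 1 and `a ≥ 3`.
* **PRR** (proportional reporting ratio):
  `(a/(a+b)) / (c/(c+d))`, interval
  `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`. Same rule.
* **BCPNN information component**: `IC = log2(aN/((a+b)(a+c)))`, the
  log2 observed/expected ratio, with lower bound `IC − 2√V(IC)`. Signal
  rule: `IC−2SD > 0`, with strength bands `+` on `(0, 1.5]`, `++` on
  `(1.5, 3]`, `+++` above 3.
* **EBGM-style ratio**: `aN/((a+c)(a+b))` with the same Wald standard
  error as the ROR; `EBGM05` is the lower bound and the rule is
  `EBGM05 > 2`.

A pair is reported as an *ADR* (the consensus rule) only when all four
rules fire simultaneously. Because IC and the EBGM-style ratio share the
same closed form, `IC = log2(EBGM)` holds exactly for every table — a
useful internal consistency check that published screen tables of this
design also obey, and which the test suite asserts both on computed
tables and on published value pairs.

Note that the quantity printed here as EBGM is the *unshrunk*
observed/expected ratio with a Wald-style interval. The empirical-Bayes
geometric mean of the MGPS literature proper is the posterior mean under
a two-gamma mixture prior; fitting that mixture is deliberately out of
scope, because the unshrunk form is what the four-rule screens of this
design actually compute (it is the only form consistent with the
`IC = log2(EBGM)` identity those tables exhibit).

### The IC variance

The BCPNN literature defines `IC−2SD = E(IC) − 2√V(IC)` but the variance
is convention-dependent. The default here is the delta-method variance
of the log2 observed/expected ratio,

`V(IC) = (1/ln 2)² · (1/a − 1/(a+b) − 1/(a+c) + 1/N)`,

which is fast, transparent, and numerically close to the Bayesian
variants at the cell sizes where screens operate. A configuration switch
(`ic_variance = "bate"`) selects instead the classic gamma/Dirichlet
moment approximation (priors α₁ = β₁ = 1, α = β = 2, γ₁₁ = 1), which is
more conservative for very small `a`. The IC *point* estimate is the
closed form in both cases, preserving the identity above.

### Chi-square

Publication tables of this design print a chi-square per term without
stating the variant. The package computes the Pearson 2×2 chi-square in
closed form with the Yates continuity correction on by default (the
MHRA convention that pairs PRR with a corrected chi-square);
`yates = FALSE` gives the uncorrected statistic. Both variants are
cross-checked against `stats::chisq.test` in the test suite.

### Zero cells and other degenerate inputs

All four estimators are undefined when any cell is zero. The default
policy (`zero_policy = "correct"`) adds 0.5 to *every* cell of an
affected table only — leaving clean tables untouched — and flags the row
`continuity_corrected`, so screens stay total while marking affected
rows. `zero_policy = "strict"` propagates `NA` instead, and `NA`
statistics always classify as non-signals. Reported cell counts are
always the original integers. Degenerate margins give `NA` chi-square;
ties in the EBGM ranking break by `a` descending and then term name, so
output order is deterministic.

## Deduplication

FAERS cases are resubmitted as follow-ups sharing a `caseid`. The
deduplication rule is the FDA-recommended one: keep the highest
`caseversion`, break ties by latest receipt date (`fda_dt`), then by
highest `primaryid`. Records with a missing date sort before any dated
record — an arbitrary but fixed choice. The operation is idempotent and
the kept record's DRUG/REAC/OUTC rows are joined by its `primaryid`.

## The descriptive summary

The cohort summary tallies exposed cases by sex, age bin, country and
the four serious outcomes (death, disability, hospitalization,
life-threatening; FAERS codes DE/DS/HO/LT — codes CA/RI/OT are counted
internally but excluded from this block). Age bins are left-closed
(`[0,20), [20,30), …, [80,∞)`), so an age of exactly 80 lands in `≥80`.
FAERS ages arrive with unit codes and are converted to years (DEC ×10,
YR ×1, MON ÷12, WK ÷52.18, DY ÷365.25, HR ÷8766). Outcome categories
are not mutually exclusive, and all percentages use the number of
exposed cases as denominator.

Exposure matching is a case-insensitive word-boundary substring match of
configured synonyms against the free-text drug name, because FAERS drug
names carry salts and brand names ("EPIRUBICIN HYDROCHLORIDE"); the
role filter defaults to primary suspect (`PS`) only.

## The synthetic generator and what it does (not) emulate

`sim_config()` / `generate_reports()` draw a reporting system in which
the estimand of the screen is known by construction:

* one target drug, present as primary suspect on 20% of cases by
  default, plus 20 background drugs (marginals 0.12 down to 0.01) and a
  rare combination product named with the `\` ingredient separator;
* 40 PTs with baseline per-case probabilities falling geometrically
  from 0.08 to 0.002, each assigned to one of 10 synthetic organ
  classes;
* *injected associations*: for a configured (drug, PT, θ), the odds of
  that PT are multiplied by θ on cases where the drug is primary
  suspect. Because the injection acts on the conditional odds given
  exposure, the reporting odds ratio of the pair targets θ directly;
* demographics and outcomes drawn from marginals chosen to resemble a
  published oncology-drug cohort (female-dominant sex split, age mass
  between 40 and 70 with ~29% unknown, top reporting countries
  CN/IT/FR/GB/DE, hospitalization ~33% as the leading serious outcome);
* receipt dates uniform over the 2014Q1–2023Q1 window, `caseid`s of
  seven digits with `primaryid = caseid·10 + caseversion`.

Cases that draw no reaction are redrawn from their own probability row
(zero-truncation by rejection). Conditioning on "at least one PT"
rescales every PT probability of a case by the same factor, so the 2×2
odds structure — and hence the injected θ — is unaffected; this is why
recovery simulations reproduce θ to within Monte-Carlo error rather
than a diluted value.

Default sizes are the package's study conditions: 20,000 cases for
calibration runs and 50,000 for recovery runs, 200 and 100 replicates
respectively in the acceptance suite — large enough that the nominal
2.5% one-sided false-flag rate of `ror_lo > 1` and 95% interval
coverage are measured with small Monte-Carlo error, while a full suite
run stays within ordinary desktop patience.

The generator emulates the *file layout and statistical skeleton* of
FAERS, not its content: there is no drug-name misspelling, no duplicate
patients across caseids, no time trend in reporting, no real MedDRA
(the toy hierarchy assigns PTs to synthetic SOCs uniformly), and
background PT probabilities are independent across terms. Passing
calibration and recovery tests therefore demonstrates that the
*machinery* is correct and well-calibrated under its stated model — not
that any particular real-world screen is free of confounding,
stratification effects, or dictionary-version artifacts.

`inject_duplicates()` creates the condition deduplication must undo: a
seeded fraction of cases gets an extra, strictly older caseversion
(earlier date, lower primaryid, one reaction fewer when possible) while
the chosen original is bumped one version up, so the duplicate must
always lose. Distinct-caseid count is unchanged and rate 0 is the
identity.

Randomness uses one root seed from which per-stage streams (drugs,
events, demographics, dates) are derived, so each stage is
independently reproducible and written quarters are byte-identical
across reruns.

## The reverse screen

Given one event term, the reverse screen enumerates the normalized drug
names appearing as primary suspect on cases reporting it, excludes
combination products (names containing `\`) by default — a single-drug
attribution cannot be made for them — and computes each drug's full 2×2
statistics and decisions for that event against all other drugs. The
target drug's row in a reverse screen equals its forward table for the
same event, which the tests assert.

## Design choices that were genuinely open

* **Dedup tie-breaks** beyond caseversion are not standardized in
  publications; latest date then highest primaryid is deterministic and
  matches FDA guidance.
* **Windowing** is applied on `fda_dt` after parsing, not at read time,
  so fixtures need not carry realistic dates.
* **Counting unit** (case, distinct term at level) was chosen over
  raw reaction rows so that `a` matches published "case numbers" and
  SOC-level margins stay consistent.
* **No multiplicity adjustment**: screens apply fixed per-term
  thresholds, as this family of analyses does; an FDR layer would
  change the published semantics.
* **Unmapped PTs** at SOC level aggregate into an explicit
  `"(unmapped)"` row and a counter — they are never silently dropped.
* **Percentages** print at 2 decimals and report tables at 2 decimals,
  while machine-readable outputs keep full precision.

## Known limitations

Real FAERS quarters carry many more tables (therapy dates, indications,
report sources) and a licensed MedDRA with multi-axial PTs; both are out
of scope, as are stratified or time-scan methods and the two-gamma MGPS
posterior. The Wald intervals used by all four estimators are
asymptotic: at very small cells they are conservative in places and
anticonservative in others, which is visible as a null false-flag rate
slightly below 2.5% for the rarest terms.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(
  n_cases = 20000,
  injected = data.frame(drug = "EPIRUBICIN", pt = "PT40", theta = 5),
  seed = 1)
dir <- tempfile("quarter")
pv_simulate(cfg, dir)
pv_describe(dir, synonyms = "epirubicin")
sc <- pv_screen(dir, synonyms = "epirubicin", level = "pt")
head(format_signal_table(sc))
pv_reverse(dir, "PT40")
```
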