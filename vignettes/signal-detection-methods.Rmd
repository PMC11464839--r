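---
title: "Disproportionality signal detection: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event report databases (FAERS and its peers) collect
individual case safety reports (ICSRs): one submission describing a patient,
the drugs they took, the adverse events observed (coded as MedDRA preferred
terms, PTs), and the clinical outcomes. Because there is no denominator of
exposed patients, association mining works by *disproportionality*: for a
drug--event pair, compare how often the pair is reported against how often
each member is reported with anything else. pvsignal implements this for
case definitions given as PT term sets — its bundled definition covers
congenital anomalies of the external ear (microtia, anotia, accessory
auricle, and seven related PTs) — together with the ingest, filtering and
descriptive machinery around it, a published-table consistency validator,
and a synthetic report generator that makes every stage testable without
database access.

## The 2×2 model and its statistics

For one drug and one event term set over a universe of $n$ reports:

|                | event         | other events |
|----------------|---------------|--------------|
| **drug**       | $a$           | $c$          |
| **other drugs**| $b$           | $d$          |

Each report falls in exactly one cell, whatever the number of mentions. The
two frequentist measures and the association test are

$$\mathrm{ROR} = \frac{ad}{bc},\qquad
  \mathrm{PRR} = \frac{a(c+d)}{c(a+b)},\qquad
  \chi^2 = \frac{(ad-bc)^2\,(a+b+c+d)}{(a+b)(c+d)(a+c)(b+d)} .$$

Wald 95% intervals are computed on the log scale with standard errors
$\sqrt{1/a+1/b+1/c+1/d}$ for the ROR and
$\sqrt{1/a+1/c-1/(a+b)-1/(c+d)}$ for the PRR. The PRR interval form is a
design choice: published tables in this field print PRR intervals without
stating a variance formula, and no downstream decision in this package
depends on the exact variant. The $\chi^2$ is the plain Pearson statistic;
no Yates correction.

The identity $\mathrm{ROR}/\mathrm{PRR} = (1 - c/(c+d))/(1 - a/(a+b))$
explains why the two measures nearly coincide in practice: both event shares
are tiny in a large database. The package's property tests assert exactly
this two-sided limit.

Three criteria sets are evaluated per drug (all gated on $a \ge$ `min_a`,
default 3):

* **ROR rule** — lower 95% ROR bound $> 1$;
* **PRR rule** — $\mathrm{PRR} \ge 2$ and $\chi^2 \ge 4$;
* **headline rule** (`signal`) — lower 95% PRR bound $> 1$.

Zero cells make the ratios undefined. The Haldane–Anscombe $+0.5$ correction
is available but off by default; `signal_table()` uses `correction = "auto"`,
correcting only the drugs whose table contains a zero cell so that every
other drug's statistics stay exact. With `min_a = 3`, corrected tables can
never reach the case-count gate at $a = 0$, so the correction affects
ranking display, not signal calls. No multiple-testing adjustment is
applied — standard for this kind of hypothesis-generating screen, and a
known limitation: with hundreds of drugs, a 2.5% per-drug false-positive
rate still yields false leads.

## Case definition and filters

Event matching is by case-folded PT name, with PT codes accepted as an
alternative key when both sides carry one. Names are authoritative because
published code transcriptions are unreliable (the bundled term set has two
entries whose codes are recorded as missing for exactly that reason).

The default filters mirror a direct-report analysis: universe = reports of
type `direct` (submitted straight to the regulator, less prone to
manufacturer-channel confounding), exposure = drugs in role
`primary_suspect`. Both are configurable (`filter_config()`). The
seriousness switch (`require_outcome_serious`) demands at least one recorded
outcome code; it is off by default since every code in the schema already
denotes a serious outcome. Drug names are normalized to generics through a
bundled static synonym map; names with no mapping are dropped and logged,
mirroring the manual-elimination step used when a name cannot be resolved in
a drug dictionary. The counting unit is the ICSR; case-version deduplication
(`deduplicate_cases()`) exists but is off the default path.

Descriptive summaries use half-open age bands `<1`, `[1,4)`, `[4,10)`,
`>=10` (resolving the ambiguity of overlapping printed band labels),
type-7 linear-interpolation quantiles (R's default; none is ever stated in
published tables), and treat negative drug-start-to-event gaps as missing
data-entry artifacts, with a warning.

## Inverting published rows

Published top-signal tables print, per drug, only $a$, ROR, PRR and the
intervals — not $b$, $c$, $d$. Given the database size $N$, the two rational
equations

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad \mathrm{PRR} = \frac{a(c+d)}{c(a+b)},
\qquad d = N - a - b - c$$

identify the latent cells: the PRR equation gives
$c(b) = a(N-a-b)/(\mathrm{PRR}(a+b))$, the ROR/PRR ratio gives
$d(b) = (\mathrm{ROR}/\mathrm{PRR})\,b(N-a-b)/(a+b)$, and the closure
$a+b+c+d=N$ becomes a one-dimensional root problem in $b$, solved with
safeguarded bracketed root-finding (Brent, tolerance $10^{-12}$). Cells are
solved as positive reals — printed statistics carry two decimals, so integer
recovery is ill-posed; nearest integers are reported alongside. A row with
$\mathrm{ROR} \le \mathrm{PRR}$ admits no positive solution and is returned
as a non-converged diagnostic rather than an error.

`consistency_report()` then predicts $\chi^2$ and the ROR CI from the
recovered cells and compares them with the printed values. Agreement within
1% is the attainable bound given two-decimal rounding of the inputs. On the
bundled transcription of a published top-50 table ($N = 20{,}754{,}281$),
the four rows used for validation (primidone, methimazole, the 15-case
nevirapine row, telbivudine) reproduce $\chi^2$ and both ROR CI bounds
within a fraction of a percent, while several large-count rows (valproic
acid, mycophenolate mofetil, lamotrigine) are internally inconsistent — the
valproic acid row's printed $\chi^2$ is more than 10× smaller than its own
ROR/PRR imply. The package reports the discrepancy; it does not attempt to
resolve which of the printed numbers is wrong.

```{r inversion}
rep <- consistency_report()
rep[rep$name %in% c("primidone", "valproic acid"),
    c("name", "a", "b", "c", "pred_chi2", "chi2_rel_err", "consistent")]
```

## The synthetic generator

`generate_reports()` draws a FAERS-like database from `sim_params()`:

* one primary-suspect drug per report from the drug marginal (an implicit
  background agent absorbs the unassigned probability mass; optional
  concomitant mentions exercise the role filter);
* events independent per PT given the drug: probability `background_prob`,
  multiplied by `rate_ratio` (capped at 1) for injected signal pairs. This
  risk-ratio parameterization means the empirical ROR approximates the
  injected rate ratio only while the event is rare;
* demographics from stratum mixes; the defaults emulate a congenital-anomaly
  case profile: 85% infants under 1 year with a lognormal older tail,
  weight lognormal around a 2.75 kg median, onset gap lognormal around a
  273-day median (first-trimester exposure surfacing at birth), outcome mix
  led by congenital anomaly, country and reporter mixes concentrated on a
  few countries plus a large "other" mass, and a small direct-report share
  (6%) as in real spontaneous-reporting systems;
* reports that draw no event receive a designated fallback PT, so every
  generated ICSR is well-formed; expectations for the fallback PT itself are
  therefore understated, and `expected_table()` documents that bias.

Everything derives from a single integer seed through R's Mersenne-Twister
stream, drawn in a fixed vectorized order and restored afterwards, so
identical parameters give byte-identical written files across runs and
platforms. `expected_table()` provides closed-form expected cells, and
`recovery_experiment()` measures operating characteristics (sensitivity on
injected pairs, false-positive rate on named null pairs) with exact binomial
intervals.

What the generator does *not* model — and hence what passing tests cannot
certify about real data: drug co-prescription structure, report-level event
correlations, duplicate submissions beyond case versioning, reporting waves
over calendar time, and channel-dependent reporting biases. The simulation
validates the *statistical machinery*, not the epidemiology of any real
database.

## Problem sizes and numerical choices

The shipped tests and the acceptance script size their simulations to be
informative yet quick: formula oracles on 20,000 random tables with cells in
1..50 (exact in double precision, far below $2^{53}$); null calibration at
5,000 reports per replicate with expected $a = 5$ (400–1,000 replicates);
sensitivity at 20,000 reports with an injected rate ratio of 50 and expected
$a = 20$ (50 replicates). Under the null, the headline rule is nominally a
one-sided 2.5% test; its Wald interval is slightly anti-conservative at
small expected counts, which is why calibration is asserted against the 5%
operating bound rather than the exact nominal point. Ranking breaks ties by
case count, then name, so output is permutation-invariant; all statistics
are carried at full precision and only rounded in written artifacts.

## Running a study

```{r study, eval = FALSE}
cfg <- validate_config("study.yaml")   # inputs, dialect, termset, filters...
manifest <- run_study(cfg)             # tables + logs + manifest.json
```

`run_study()` writes the descriptive tables, the yearly series, the ranked
signal table (top 50 by ROR by default), quarantine/drop logs and a JSON
manifest of counts at every stage; the manifest counts are non-increasing
along the filter chain, and a run that ends with zero cases exits with
status `"no cases"` rather than an error.
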