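---
title: "Methods: property conventions and the selection funnel in pepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: property conventions and the selection funnel in pepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscan)
```

## What the package models

`pepscan` implements the desk half of an in silico directed-evolution screen
for short antimicrobial/anticancer peptides. Starting from a template — in
the worked example shipped with the package, the low-complexity,
threonine-rich *Anabas testudineus* mucus peptide AtMP1 — the screen
enumerates every single-residue substitution variant, computes a
physicochemical property panel per variant, ingests per-peptide scores from
external machine-learning predictors, and pushes everything through a staged
filter funnel (antimicrobial status, net-charge window, hydrophobicity
window, anticancer score) ending in a ranked top-k selection.

The external predictors are deliberately **not** reimplemented: their value
lies in trained weights we have no access to. The package consumes their
exported score tables (or synthetic stand-ins with the same statistical
shape), which keeps the artifact self-contained and honest about what is
reproducible offline.

## The substitution scan

`single_substitution_library()` generates variants in scan order (position
ascending, alphabet order within a position). With self-substitutions
excluded — the default, since substituting a residue with itself merely
duplicates the template — the library size is exactly
$\sum_i \left(|A| - [x_i \in A]\right)$ for alphabet $A$, i.e.
$L \times (|A| - 1)$ when the alphabet contains every template residue. A
24-mer over the standard 20 yields 456 variants; the 26-mer AtMP1 template
yields 494. The package reports whatever the enumeration actually produces
and asserts the formula against a brute-force oracle; it does not hard-code
any expected library size.

Two alphabets ship: `standard20`, the default, and `paper18`, which omits
isoleucine and valine — some published screens enumerate an 18-letter list
while describing it as twenty, and the reduced alphabet makes such
fidelity experiments possible.

## Net charge: three conventions, on purpose

Screening reports mix charge conventions freely, and the same peptide can
legitimately be printed with two different "net charges". `pepscan`
therefore makes the convention explicit and first-class:

* **`quarter_ph7`** — fixed contributions K/R $+1$, D/E $-1$, H $+0.25$,
  termini cancelling. The $+0.25$ is the Henderson–Hasselbalch histidine
  protonated fraction near pH 7 (side-chain p$K_a \approx 6.5$) rounded to
  quarters. This convention reproduces all ten net charges in the shipped
  candidate table (`atmp_candidates()`), e.g. $+1.25$ for ATMP6
  (one His, one Arg).
* **`anticp_integer`** — K/R $+1$, D/E $-1$, H $+0.5$, no terminal
  contributions. This reproduces the charges printed alongside the
  anticancer classifier scores ($+0.50$ / $+1.50$ for ATMP5/ATMP6).
* **Henderson–Hasselbalch** (`net_charge_hh()`) — the continuous model
  $Q(\mathrm{pH}) = \sum_{\mathrm{basic}} (1+10^{\mathrm{pH}-pK_a})^{-1}
  - \sum_{\mathrm{acidic}} (1+10^{pK_a-\mathrm{pH}})^{-1}$
  over both termini and all ionizable side chains.

The cascade defaults to `quarter_ph7` because that is the convention of the
candidate table the funnel operates on; the panel computes all three so a
report can never silently switch conventions.

## The calibrated pKa set and the isoelectric point

$Q(\mathrm{pH})$ is strictly decreasing, so the isoelectric point is the
unique root, found by bisection over $(0, 14)$ to a configurable tolerance
(default $10^{-4}$ pH units; one bisection costs ~17 charge evaluations, so
this is never a bottleneck). For a peptide with no ionizable side chains the
root has the closed form $(pK_{a,N} + pK_{a,C})/2$, which the tests use as
an exact oracle.

No single published pKa set is canonical, and the source screens never name
theirs. The package's default `"calibrated"` set is

| group | N-term | C-term | D | E | C | Y | H | K | R |
|-------|-------:|-------:|----:|----:|----:|----:|----:|----:|----:|
| p$K_a$ | 7.7 | 3.55 | 4.05 | 4.45 | 9.0 | 10.0 | 6.5 | 10.0 | 12.48 |

chosen as the set that simultaneously lands the reported isoelectric points
of both reference candidates (ATMP5 $\approx 7.09$, ATMP6 $\approx 10.11$).
The terminal and acidic values follow the Bjellqvist tradition; histidine at
6.5 matches the quarter-convention rationale above; arginine takes the
Lehninger value 12.48 — with the more common 12.0 the Arg-bearing
candidate's pI lands near 9.86, a quarter of a pH unit low, so 12.48 is the
deliberate calibration choice here. `"emboss"` and `"lehninger"` sets are
registered under their own names for comparison; none of the sets is ever
mutated in place (the registry is immutable).

## Hydrophobicity and the other panel properties

* **GRAVY** is the mean Kyte–Doolittle hydropathy; it reproduces the
  reported $-0.76$ / $-0.63$ for ATMP6/ATMP5 exactly at two decimals.
* **Hydrophobic percent** counts residues in a designated hydrophobic set
  and rounds **half-up** to an integer percent (printed tables round 12.5%
  to 13%; base R's banker's rounding would give 12%). The default set
  {A, C, F, I, L, M, V, W} — glycine and proline excluded — is the only
  standard choice consistent with the reported 13% for both reference
  candidates (3 alanines / 24 residues = 12.5% → 13%).
* **Hydrophilicity** defaults to the Hopp–Woods scale but is configurable.
  The hydrophobicity/hydrophilicity columns printed next to the anticancer
  scores in the source screen (−0.11/−0.19 and 0.06/0.16) are reproduced by
  no standard scale we tested (Kyte–Doolittle, Eisenberg, Hopp–Woods); the
  classifier's internal scales are undocumented. These two columns are
  therefore computed under named, configurable scales and never asserted
  against the printed values.
* **Molecular weight** sums standard average residue masses plus one water
  (18.0153 Da). The printed MWs of the source screen's toxicity table are
  internally inconsistent with their printed sequences (the ATMP5 value is
  ~35 Da below any mass-table evaluation, and the two candidates are
  ordered against the Tyr/Arg residue-mass difference), so molecular weight
  is reported but never asserted against those values.
* **Instability index** is the Guruprasad weighted sum over adjacent
  residue pairs, $(10/L)\sum_i \mathrm{DIWV}(x_i, x_{i+1})$, using the
  published 400-entry dipeptide weight table shipped as plain text.
* **Aliphatic index** is $100(f_A + 2.9 f_V + 3.9 (f_I + f_L))$.

## The selection funnel

`run_cascade()` applies four conjunctive filters in a configurable order
(default: antimicrobial call, charge, hydrophobicity, anticancer), keeping
per-stage bookkeeping with the invariant *input = kept + excluded* at every
stage. Because the filters are conjunctive, permuting the stage order
changes per-stage counts but never the surviving set — a property the tests
assert under random permutations.

Two threshold decisions were genuinely open and are worth recording:

* **"Favourable net charge"** is operationalised as $0 < Q \le +9$: the
  source narrative excludes "negative or extremely low" charges and quotes
  an optimal window of $+0.0$ to $+9$, but prints no cut-off for
  "extremely low", so the default lower edge is exactly 0, exclusive (a
  config flag makes it inclusive).
* **The hydrophobicity minimum** is evaluated on the *rounded* integer
  percent with an inclusive ≥13 comparison, because the candidates the
  source screen actually carried forward themselves show 13% (12.5%
  unrounded) — under a strict >13 rule the screen would have discarded its
  own selections. The quoted textbook optimum of 17–50% ships as the
  `"paper-optimal"` preset; the default is `"paper-selected"` ([13, 50]).

Peptides missing the score a stage needs are excluded at that stage and
logged as *unscored* — a defined degradation rather than an error, so a
partial score table (or none at all) still yields a valid, empty-able
result. The anticancer threshold comparison is inclusive (score ≥ 0.5
passes), matching the phrasing that peptides *below* 0.5 fail. Survivors
are ranked by anticancer score descending, then net charge descending, then
id — a deterministic total order.

The source screen's full-library funnel counts (212/69/48 exclusions from a
428-member library) depend on unexported web-server outputs and on an
enumeration count that no consistent (length, alphabet) pair reaches
(24×19 = 456, 26×19 = 494); reproducing those counts is explicitly out of
scope. What the package reproduces is the *shape* of the funnel and, for
the ten-candidate worked example with reported scores, the exact selection:
{ATMP6, ATMP5}, ATMP6 first (0.59 > 0.57).

## The synthetic generator

`generate_library()` / `generate_scores()` emulate the statistical structure
the cascade assumes, so every stage is testable offline:

* sequences drawn residue-by-residue from a composition bias, by default
  threonine-rich (T 0.60, P 0.10, A 0.10, the remaining 17 residues sharing
  0.20) — mimicking a substitution library over a Thr-rich template, where
  23 of 24 positions keep template-like composition and one is randomised;
* antimicrobial calls Bernoulli(0.505), the non-antimicrobial attrition of
  roughly half observed in the reference screen ((428−212)/428 ≈ 0.505);
* anticancer scores Beta(2, 10), putting ≈0.6% of mass at or above the 0.5
  classification threshold — in a 456-member library that is 2–3 expected
  hits, the "few candidates" regime of the reference funnel;
* toxic flags at rate 0.05 and allergen flags at 0.5 (the two reference
  candidates split on allergenicity between predictors).

All randomness flows through the spec's mandatory seed via a local RNG
scope, so generation is reproducible and never perturbs the caller's RNG.
What the generator does **not** emulate: real AMP sequence space, predictor
score correlations with sequence composition, and position-specific
substitution effects. Passing the end-to-end parameter-recovery test
(funnel survival fractions within 3 binomial standard errors of the
generator's rates at n = 10,000) therefore validates the pipeline's
bookkeeping and thresholds, not any biological claim.

## Numerical choices and problem sizes

Fixed-contribution charges are sums of quarters, hence exact in floating
point. Reported CSVs format charges, scale means and pI to two decimals and
fractions to four, matching table precision; rounding for percentages is
half-up. Degenerate inputs are defined: a length-1 peptide has no
instability index (it requires a dipeptide), an empty library produces an
all-zero funnel and an empty ranking with exit status 0, and ties in the
final ranking break lexicographically by id.

The test suite runs the recovery and invariant checks at n = 10,000
synthetic peptides and 250–456-member libraries elsewhere; every printed
reference value re-derives in well under a second.
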