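---
title: "Mining occupational chemical coexposures from measurement databases"
author: "coexminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining occupational chemical coexposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexminer)
```

## The problem

Occupational exposure databases (OEDBs) such as COLCHIC, SCOLA, IMIS or
MEGA accumulate hundreds of thousands of personal air measurements, each
tied to one chemical agent, an industrial sector, an occupation, a task
and a sampling date. Workers, however, are rarely exposed to one agent at
a time: a single process (paint spraying, arc welding, degreasing) emits
a characteristic *mixture*. Because campaigns measure one agent per
sample, mixtures are never observed directly — they must be
reconstructed by pooling measurements that plausibly describe the same
exposure circumstances.

`coexminer` implements that reconstruction as a market-basket analysis.
Measurements are pooled into **work situations** (WS): unique
combinations of industrial sector, occupation, task and calendar year.
Each WS becomes a *transaction* whose *items* are the agents detected at
least once above their limit of quantification (LOQ) within it.
Frequent-itemset and association-rule mining then describe which agent
combinations recur across the working population.

## The model and its metrics

For an itemset $I$ (a set of agents) over a transaction database of $N$
work situations,

$$\mathrm{support}(I) = \frac{|\{\,t : I \subseteq t\,\}|}{N},$$

the proportion of WS containing every agent of $I$. Two denominator
universes are supported, because both are meaningful: **all** WS, and
the **multi**-agent WS (those with at least two detected agents), which
is the natural universe for coexposure prevalences. The numerator is
always the exact containment count; only the divisor changes.

For a rule $A \to C$ with disjoint non-empty itemsets $A$, $C$:

* $\mathrm{support}(A \to C) = \mathrm{support}(A \cup C)$,
* $\mathrm{confidence}(A \to C) =
  \dfrac{n(A \cup C)}{n(A)}$ — the proportion of WS exposed to $A$ that
  are also exposed to $C$ (a ratio of counts, independent of the
  denominator universe),
* $\mathrm{lift}(A \to C) =
  \dfrac{\mathrm{support}(A \cup C)}
        {\mathrm{support}(A)\,\mathrm{support}(C)}$ — 1 under
  independence, above 1 for positive dependence; symmetric in $A$ and
  $C$.

The *complementary rule* $C \to A$ shares support and lift but not
confidence; report tables carry both confidences.

```{r toy}
rec <- data.frame(
    agent_id = c("asbestos", "lead", "wood dust",
                 "benzene", "ethanol", "lead",
                 "asbestos", "chromium", "lead"),
    sector = "S1", occupation = "O1",
    task = c("T1", "T1", "T2", "T3", "T3", "T3", "T4", "T4", "T4"),
    year = 2015L, source = "A")
db <- buildTransactions(rec)
itemsetSupport(db, c("asbestos", "lead"), "all")
ruleConfidence(db, "lead", "asbestos")   # 2 of the 3 lead WS
ruleLift(db, "lead", "asbestos", "all")  # exact 4/3
```

A note on display conventions: worked examples in the field often
present lift as the already-rounded confidence divided by the
consequent's support (0.67 / 0.5 = 1.34), while the exact ratio here is
4/3 = 1.333…. `ruleLift()` is always exact; `liftRoundedConvention()`
reproduces the two-step display, and the formatted report layer rounds
half-up (percentages to 1 decimal; lift to 2 decimals below 10, 1 above)
while machine-readable outputs keep full precision.

## From records to transactions

`readRecords()` validates each row and returns rejects with reasons
rather than dropping them. `flagDetected()` is the single point where
censoring is decided: a record is detected when its concentration is
*strictly above* its LOQ. The strict boundary takes "above the LOQ"
literally; it is configurable (`boundary = "inclusive"`) for sensitivity
analyses. Detection status is all that matters downstream — no
concentration magnitudes, no comparison with exposure limits, and no
attempt to distinguish "true zeros" from trace-level presence, which the
available descriptors cannot support.

`applyInclusionFilters()` applies, in a fixed audited order: the study
window on calendar year (2010–2019 by default), catalog and
per-(agent, source) exclusions, the detected-only restriction, then
removal of agents with fewer than 100 detected records. Design choices
worth stating:

* the minimum-count filter operates on the corpus pooled over sources,
  after the detected-only restriction, so "100 quantified samples" means
  100 detected records in the combined database;
* records missing any descriptor are rejected (reason
  `missing_descriptor`) rather than pooled into an "unknown" stratum — a
  WS is defined by the complete 4-tuple, and a partial key would create
  artificial mixtures;
* duplicate samples are counted as stored; no deduplication is applied
  before the count.

`buildTransactions()` then groups by the 4-tuple. Single-agent WS are
*kept* in the database: which denominator a statistic uses is decided at
analysis time, not at construction time.

## The miner

`mineItemsets()` is a depth-first Eclat: each agent carries the sorted
list of transaction ids containing it, and the search extends a prefix
itemset by intersecting id lists, pruning on the anti-monotone support
bound. This fits the data shape — the agent universe is small (about a
hundred agents) while transactions number in the tens of thousands — and
yields the exact WS count for every reported itemset. The effective
absolute threshold is

$$\max\big(\lceil s_{\min} \cdot N \rceil,\; n_{\min}\big)$$

with $s_{\min}$ the fractional support (default 0.1%) and $n_{\min}$ an
absolute floor. The ceiling is computed with a $10^{-9}$ guard so that
decimal fractions that are not binary-representable still give the
intended integer (0.001 × 5000 is 5, not 6). Ties in all rankings break
by descending WS count, then ascending itemset length, then
lexicographic items — determinism is required for byte-stable reports,
and every pipeline output is reproducible file-for-file.

`mineRules()` enumerates, for every frequent itemset of size ≥ 2, all
ordered bipartitions into antecedent and consequent. Both sides of an
emitted rule are themselves frequent (anti-monotonicity), so marginal
supports are never zero and lift is always defined. Multi-agent
consequents are supported; `maxConsequent = 1` reproduces the
single-consequent convention of published tables. The confidence floor
(default 10%) applies to the rule's own confidence only; the
complementary confidence is always carried.

## Subanalyses

* `restrictToCarcinogens()` intersects transactions with the
  catalog-flagged carcinogens and recomputes the multi-agent universe,
  so restricted supports are relative to WS exposed to ≥ 2 carcinogens.
  The denominator is always recomputed from data, never supplied as a
  constant. Carcinogen status is purely an input-catalog flag.
* `stratifiedMining()` analyses sectors or tasks with at least 100
  multi-agent WS (the qualification deliberately counts WS exposed to
  ≥ 2 agents, not all WS) and applies the support floor
  max(⌈0.1% · n⌉, 10 WS) within each stratum, with n the stratum's
  denominator count.
* `cooccurrenceMatrix()` tabulates pairwise WS counts. Entries below the
  display floor (default 10 WS) are *masked* as missing in exports, not
  zeroed — a sub-floor pair is undisclosed, not absent. Dominant pairs
  can be excluded via a configuration list rather than hard-coded names.

## The synthetic generator and what it shows

The source databases are not public, so validation rests on a generator
(`generateCorpus()`) that emulates the record structure with known
ground truth. Each WS draws a **process profile** — a set of agents with
per-agent emission probabilities, plus sector/task code pools — and each
emitted (WS, agent) produces $1 + \mathrm{Poisson}(\lambda)$ records,
each censored below its LOQ independently with probability $c$. The
WS-level detection probability is therefore
$d = 1 - c\,e^{-\lambda (1 - c)}$, and the expected support of an
itemset is the profile-weighted mixture of products of emission × $d$
over its members (`expectedSupport()`), which the tests compare against
mined supports using binomial standard errors.

Default conditions of the reference corpus: 5,000 WS, 8 profiles over 28
agents, $c = 0.48$ (matching the typical share of below-LOQ results in
OEDB extracts), $\lambda = 2$ (mean 3 records per emitted agent, so the
100-record filter is exercisable), years 2010–2019, two sources mixed
72/28. The profile weights and emission probabilities were fixed from
the closed-form expectations so that six planted mixtures sit clearly
above the 0.1% support threshold and the two low-weight profiles sit at
or below it, giving the recovery tests both power and a level check.
Occupation tokens are unique per WS — they index the workplace — which
guarantees a one-to-one map between planted WS and transaction keys;
sector and task pools still overlap across profiles as in real data.

What the generator does *not* emulate: real nomenclatures (codes are
opaque tokens, as in the pipeline itself), temporal drift within the
study window, correlated censoring across agents measured on one
sampling medium, and the highly skewed agent frequency distribution of
real OEDBs. Passing recovery tests therefore shows the machinery is
correct under the stated sampling model, not that any particular real
mixture prevalence is unbiased — in real extracts, absence of a
measurement never implies absence of exposure, and WS pooling inherits
whatever reporting biases the source databases carry.

## Problem sizes and numerical choices

The test suite runs the full oracle-equivalence check (exhaustive subset
and bipartition enumeration) on 100 random databases of up to 8 agents
and 60 transactions, the recovery check on the 5,000-WS reference
corpus, and the independence-null calibration on 200 replicates of
400 WS with six independently emitted agents — sizes chosen so the
whole suite completes in well under a minute while keeping at least
3 binomial standard errors of resolution on every stochastic claim.
Degenerate inputs are defined, not special-cased: an empty record set
yields a valid empty database; the support of the empty itemset is an
error (it is never used); rules with an empty-support antecedent are
never emitted.

## Limitations

Confidence is inflated toward ubiquitous consequents; lift is unstable
for rare marginals — both classical caveats apply and are the reason
report tables carry all three metrics plus the complementary
confidence. The miner enumerates all frequent itemsets without
closed/maximal condensation, which is exact but can be large at very low
thresholds on dense data. No inferential statistics are attached to the
descriptive tables, by design.
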