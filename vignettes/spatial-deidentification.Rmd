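---
title: "Bounded-risk spatial de-identification by linear programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded-risk spatial de-identification by linear programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deidlp)
```

## The problem

Disclosing patient locations at fine spatial resolution (postal codes, ZIP
codes, census blocks) is valuable for spatial epidemiology but risky for
privacy: a location combined with public records can re-identify
individuals, and regulatory regimes such as the HIPAA Expert Determination
route require a demonstration that the re-identification risk is *very
small* — in practice a threshold $\epsilon$ somewhere in $[0.05, 0.3]$, with
$0.2$ a common working value.

`deidlp` implements a *geomasking* approach with a provable guarantee:
instead of aggregating areas or jittering coordinates heuristically, it
computes a **transition probability matrix** $P_{ij}$ — the probability that
a patient truly living in area $i$ is *reported* in area $j$ — by solving a
linear program that minimizes the information loss subject to an explicit
bound on the re-identification probability. Patients are then relocated by
multinomial draws from their row of $P$.

## The model

Let $A$ be the set of areas, $n_i$ the population of area $i$,
$N = \sum_i n_i$, $d_{ij}$ the great-circle distance between centroids,
$s$ the number of patients, and $B_i \subseteq A$ the allowed destination
set of origin $i$. The decision variables are $P_{ij} \ge 0$ for
$j \in B_i$. The LP is

$$
\min \sum_{i \in A} \sum_{j \in B_i} \frac{n_i}{N}\, d_{ij}\, P_{ij}
\quad\text{s.t.}\quad
\sum_{j \in B_i} P_{ij} = 1 \;\; \forall i,
\qquad
\sum_{k:\, j \in B_k} \frac{n_k}{N} P_{kj} \;-\; \nu_i\, P_{ij} \;\ge\; 0
\;\; \forall i,\, j \in B_i .
$$

The objective is the *expected displacement* of a random patient, in meters.
The risk inequality bounds the posterior probability that a record disclosed
at $j$ belongs to a specific individual:

$$
r_{ij} \;=\; \min\!\Big(\frac{s}{n_i},\, 1\Big)\,
\frac{n_i P_{ij}}{\sum_k n_k P_{kj}} \;\le\; \epsilon .
$$

Two variants of the coefficient $\nu_i$ are supported:

* **classic** (`variant = "wcmb"`): $\nu = s/(N\epsilon)$ for every origin.
  This implicitly assumes every area could host all $s$ patients; when many
  areas have $n_i < s$ (a median population of 10 against a cohort of
  hundreds is typical for urban postal codes) the program is infeasible for
  any practical $\epsilon$, or only "solves" at $\epsilon > 1$, a bound with
  no protective meaning.
* **revised** (`variant = "revised"`, the default):
  $\nu_i = \min(s, n_i)/(N\epsilon)$. At most $n_i$ of the $s$ patients can
  truly originate from area $i$, so the per-origin cap is both sufficient
  for the bound above and much weaker for small areas — the program stays
  feasible on geographies dominated by small areas.

Since $\min(s, n_i) \le s$, every revised constraint is implied by the
classic one: the revised feasible region contains the classic one, and the
revised optimum can never be worse. Both facts are asserted by the test
suite.

### Redundancy pruning

Rearranging the risk constraint of origin $i$ so that every other
coefficient is non-negative leaves the coefficient
$g(n_i) = n_i/N - \nu_i$ on $P_{ij}$ itself. Piecewise,

$$
g(n_i) = \begin{cases}
\dfrac{n_i}{N}\Big(1 - \dfrac{1}{\epsilon}\Big), & n_i \le s,\\[6pt]
\dfrac{1}{N}\Big(n_i - \dfrac{s}{\epsilon}\Big), & n_i > s ,
\end{cases}
$$

continuous at $n_i = s$, minimized there at $(s/N)(1 - 1/\epsilon)$ for
$\epsilon < 1$, and crossing zero at $n_i = s/\epsilon$. When
$g(n_i) \ge 0$, i.e. $n_i \ge s/\epsilon$, all coefficients of the
constraint are non-negative and the constraint can be dropped without
changing the model. `build_lp(prune = TRUE)` (the default) drops those rows
and records the pruned origins; the suite verifies that pruned and unpruned
programs agree in status and objective to $10^{-6}$ relative. For
$\epsilon \ge 1$ the revised constraints are all vacuous, but the shared
pruning rule $n_i \epsilon \ge s$ is applied to both variants; it is
conservative (never removes a binding constraint) and keeps the two
variants' bookkeeping identical.

One reduction worth noting: with unit populations everywhere
($n_i = 1$), the classic constraint rearranges to
$P_{ij} \le (\epsilon/s) \sum_k P_{kj}$ — the per-pair cap scaled by the
column sum. (The column sum does not reduce further: columns of $P$ are not
stochastic.) The suite tests this exact rearranged form.

### Nearest-$k$ sparsification

A full formulation has $|A|^2$ variables and $|A|(1 + |A|)$ constraints —
at the scale of a real city (11,740 postal codes) that is 137.8 million
variables, far beyond what is useful. `nearest_neighbors()` restricts each
origin to its $k$ nearest areas, self included: the origin is trivially its
own nearest area at distance zero, keeping self-transition available, and
counting it toward $k$ reproduces the canonical sizes
$|A| \cdot k$ variables and $|A|(1 + k)$ constraints (117,400 / 129,140 at
$k = 10$; 352,200 / 363,940 at $k = 30$ for $|A| = 11{,}740$ — the
constraint formula value, which this implementation follows). Non-negativity
is treated as a variable bound, not a counted constraint. Under
sparsification the column sum in the risk constraint ranges only over
origins $k$ whose neighbor set contains $j$; the remaining $P_{kj}$ do not
exist as variables, which is the only consistent sparse reading.

Ties at equal distance are broken by ascending area id, so neighbor maps
are deterministic and invariant to input row order. Distances use the
Haversine formula on a sphere of radius 6,371,000 m (mean Earth radius);
ellipsoidal corrections are deliberately ignored — sub-0.5% distance error
is irrelevant against kilometer-scale displacement objectives.

## Solving

`solve_lp()` is a solver-agnostic contract: it takes the sparse `lp_spec`,
returns a status (`optimal`, `infeasible`, `unbounded`,
`numeric_failure`), the entries of $P$, and the objective *recomputed from
the returned solution* (required to agree with the solver's report to
$10^{-6}$ relative). Infeasibility is a reported outcome, never an
exception — diagnosing where the classic model breaks down is a primary use
of the package.

Two backends are provided:

* `"highs"` (default): the HiGHS solver via a `python`/SciPy subprocess,
  exchanging the problem as plain-text triplets. Suitable for
  hundreds of thousands of variables; the solve path (interior point with
  crossover, so a basic optimal solution is returned) is single-threaded
  and deterministic for a fixed input. Interior point is used because these
  risk systems are nearly degenerate: on infeasible instances dual simplex
  can spend many minutes failing to prove infeasibility that interior
  point certifies in seconds.
* `"dense"`: a self-contained dense two-phase simplex with Bland's rule,
  written in R. It is slow (small instances only, capped at 2,000
  variables) but has no external dependencies and serves as an independent
  cross-check: the suite requires both backends to agree on small random
  instances to $10^{-6}$ relative.

Only the objective is contract-bound. Degenerate optima are common in
transportation-like LPs, so two runs (or two backends) may return different
$P$ with identical expected displacement.

Numerical cleanup on return: entries in $[-10^{-6}, 10^{-6})$ are set to
zero and rows renormalized to exact unit sums. Tiny positive entries are
solver dust — they carry on the order of $10^{-13}$ expected patients, but
a risk ratio of dust over dust evaluates to 1 and would spuriously fail the
audit. Rows off unit sum by more than $10^{-4}$, or entries below
$-10^{-6}$, are treated as a numeric failure rather than repaired.

## The audit

`audit()` recomputes $r_{ij}$ for every matrix entry from first principles
— populations, $s$, and the entries of $P$ — rather than trusting LP
feasibility, so solver tolerance violations and pruning bugs are caught
independently. The report passes iff the maximum over all audited pairs is
at most $\epsilon + 10^{-6}$. Destinations receiving no transition mass are
skipped and listed rather than scored: a $0/0$ ratio describes a location
no record is ever disclosed at, which poses no risk and would otherwise
poison the maximum.

## Relocation

`relocate()` draws, for each origin $i$ holding $s_i$ patients, destination
counts from Multinomial$(s_i, \{P_{ij}\})$, then assigns them to that
origin's patients after a uniform shuffle — patients are exchangeable, and
no attribute other than origin influences the assignment. Determinism is
taken seriously: a single root seed spawns one substream per origin, keyed
by a hash of the area id, so adding or removing one origin's patients never
perturbs another origin's draws, and the caller's RNG state is saved and
restored around the call.

## The synthetic city

No real postal-code table ships with the package, so `generate_city()`
produces fixture geographies with the structure that makes this problem
hard:

* a dense **urban core** (70% of areas by default) drawn uniformly in the
  central 12% of the bounding box, with populations
  $1 + \lfloor \mathrm{LogNormal}(\log 16,\, 0.9) \rfloor$;
* a sparse **rural periphery** (the rest) spread over the whole box with
  populations $1 + \mathrm{Poisson}(1.5)$, mostly 1–5 people.

The defaults were calibrated once so the overall median population is
about 10 with a long right tail, matching the small-area regime of real
urban postal geographies (the mixture median sits at the urban
distribution's 28.6th percentile, which pins the urban log-normal median
near 16). The two-stratum layout matters: in a spatially *uniform* city
with the same population distribution, every origin's nearest-$k$
neighborhood pools enough population that the classic model remains
feasible at $\epsilon = 1$. It is the rural pockets — clusters of
tiny-population areas whose combined $k$-neighborhood holds far fewer
people than the patient cohort — that make the classic model infeasible for
every $\epsilon \le 1$, exactly the failure mode observed on real city
data. A useful feasibility heuristic falls out of summing each origin's
risk constraints: the population reachable around every origin must be at
least $s/\epsilon$.

`sample_patients()` draws the cohort uniformly from the person universe
(without replacement), so origin counts follow the population-weighted
multivariate hypergeometric law and no origin can contribute more patients
than it has residents.

What the generator does **not** emulate: real postal-code adjacency and
road geometry, spatially correlated population sizes beyond the two strata,
multiple urban centers, and any patient-level attributes (age, sex,
visit dates). Passing tests therefore demonstrate the model's mathematical
behavior in the small-area regime, not performance on any particular real
geography.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to finish in minutes
on one core: dual-backend equivalence on 5–8-area instances; pruning
equivalence and variant ordering on 100-area single-cluster cities; a
5-point $\epsilon$ sweep (1.0 down to 0.3) on a 200-area city at $k = 10$,
each optimum re-audited; and the headline contrast on a 1000-area
two-stratum city with $s = 224$ and $k = 30$, where the classic model is
verified infeasible at $\epsilon = 1$ (risk constraints only tighten as
$\epsilon$ falls, so this covers all $\epsilon \le 1$) while the revised
model solves and passes the audit at $\epsilon = 0.2$. Multinomial
relocation is checked against its analytic mean over 10,000 replicate
draws.

## A worked example

```{r example, eval = FALSE}
city <- generate_city(city_spec(n_areas = 1000, seed = 101))
nm   <- nearest_neighbors(city, 30)

# the classic model cannot de-identify this geography ...
solve_lp(build_lp(deid_problem(city, nm, s = 224, epsilon = 1, "wcmb")))$status
#> [1] "infeasible"

# ... the revised model can, at the working threshold
pr <- deid_problem(city, nm, s = 224, epsilon = 0.2, "revised")
tm <- solve_lp(build_lp(pr))
tm$objective_m          # expected displacement, meters
audit(tm, pr)$max_risk  # <= 0.2 + 1e-6

pts   <- sample_patients(city, 224, seed = 13)
moved <- relocate(pts, tm, seed = 14)
```

## Known limitations

* The destination universe equals the origin universe ($B = A$,
  sparsified). Distinct disclosure universes are not supported.
* Transition probabilities are continuous; no integer post-processing of
  relocated counts is attempted.
* The audit bounds the location-linkage risk defined above; it is not a
  linkage-attack simulation and says nothing about quasi-identifiers other
  than location.
* The dense backend is intentionally small-scale; national-scale instances
  would need decomposition techniques out of scope here.
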