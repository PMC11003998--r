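---
title: "Bacterial-foraging optimization and two-slice DBN structure learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bacterial-foraging optimization and two-slice DBN structure learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfodbn)
```

## The model

A dynamic Bayesian network over discrete variables $X_1,\dots,X_n$ observed
at time slices $0,\dots,T$ is specified here as a *two-slice* network
$(B_0, B_\to)$: an initial DAG $B_0$ over the $n$ slice-0 variables and a
transition graph $B_\to$ over $2n$ slice-labelled nodes (slice $t$ followed
by slice $t{+}1$).  Three assumptions make this representation exact: the
process is first-order Markov, the transition structure and its conditional
probabilities are time-invariant, and within a slice the dependencies form a
DAG.  The joint factorizes as

$$P(X_0,\dots,X_T) \;=\; P_{B_0}(X_0)\prod_{t=0}^{T-1} P_{B_\to}(X_{t+1}\mid X_t).$$

Temporal validity constrains $B_\to$: no edge may point into a slice-$t$
node, and the subgraph induced on the slice-$t{+}1$ nodes must be acyclic.
Intra-slice edges among the $t{+}1$ nodes are permitted and learned freely;
they are not forced to equal $B_0$, since $B_\to$ is defined with its own
structure over both slices.

## The score

Structure quality is measured by the K2 Bayesian–Dirichlet marginal
likelihood.  For one node $i$ with $r_i$ states and $q_i$ parent
configurations, with counts $N_{ijk}$ (configuration $j$, child state $k$)
and $N_{ij}=\sum_k N_{ijk}$, the log family score is

$$\sum_{j=1}^{q_i}\Big[\log (r_i-1)! \;-\; \log (N_{ij}+r_i-1)! \;+\;
  \sum_{k=1}^{r_i} \log N_{ijk}!\Big],$$

computed through `lgamma` (exact for integer counts at double precision; no
Stirling approximation).  The dynamic score of a 2T-BN is the sum of two
independent static K2 scores:

* $K2_0$: the families of $B_0$ counted on the **first slice** of every
  sequence;
* $K2_\to$: the families of the slice-$t{+}1$ nodes of $B_\to$ counted on
  the **stacked transition records** — every adjacent slice pair
  $(x_t, x_{t+1})$ of every sequence contributes one $2n$-column record, so
  a sequence of length $L$ contributes $L-1$ of them.

Printed intermediate forms of this derivation mix the two products with
inconsistent indices; the implementation follows the final additive form,
which is the one a decomposable scorer can cache: the score is a sum over
node families, an edge change touches exactly one (or, for a reversal, two)
family terms, and a per-dataset cache keyed by (segment, node, parent tuple)
returns bit-identical values to fresh computation.

## The continuous optimizer

`bfo_optimize()` minimizes a box-constrained objective with a colony of $S$
bacteria through four activities per generation.

**Chaotic initialization.** Positions are seeded from the logistic–sine
hybrid map $a_{i+1}=r a_i(1-a_i)$, $b_{i+1}=(4-r)\sin(\pi b_i)/4$,
$x_{i+1}=(a_{i+1}+b_{i+1}) \bmod 1$, mapped onto the box as
$lb + x(ub-lb)$.  A practical caveat discovered during development: at the
default $r=0.86$ the logistic component contracts to 0 and the sine
component settles near a short cycle, so the *transient* of the map — not
its asymptotic behaviour — carries the diversity.  The stream seeds
$a_0,b_0$ are drawn from the run RNG.

**Chemotaxis.** Each bacterium picks a target uniformly from its peers with
strictly better fitness (plus the current best; for the best bacterium the
set is itself) and proposes
$$x' = x + r \circ (SF - I \circ x),$$
with per-dimension $r\sim U(0,1)$ and $I\in\{1,2\}$, clipped to the box.
The move is kept only on strict improvement; ties keep the old position.
On improvement the *same step vector* is re-applied (swimming) up to $N_s$
times while fitness keeps improving.  Directional persistence is the classic
foraging swim and is load-bearing: with a fresh random step per swim the
search cannot follow curved, ill-conditioned valleys (the Kowalik function
stalls an order of magnitude above its minimum), while the repeated-step
swim performs an implicit line search and reaches it.  The classic
attraction–repulsion potential $J_{cc}$ is available (`swarm_params()`)
for comparison runs but is off by default: the peer-target move replaces
that group-communication mechanism.

**Reproduction.** Health is the running sum of each bacterium's fitness
after every swim round of the generation; bacteria that stop swimming
re-add their unchanged fitness, so every individual accumulates the same
number of terms and the ranking is comparable.  The healthier half (lower
accumulated objective under minimization) is copied unchanged; each
lower-half bacterium is, with probability $pc$, replaced by a two-point
crossover of itself with its rank-matched elite.  Cut points are drawn
uniformly without replacement from the $D{+}1$ coordinate boundaries; two
cut points are the minimal multi-point choice.

**Adaptive elimination–dispersal.** The dispersal probability of an
individual with score $f_i$ given historical extremes is

$$P \;=\; \frac{|f_{\min}| + |(f_{\max}-f_i)\,P_{prev}|}
               {|f_{\min}| + |(f_{\max}-f_{\min})\,P_{prev}|},$$

clamped to $[0,1]$, with $P=P_{prev}$ returned when the denominator is 0.
The formula is oriented so that the *numerically smallest* score means the
*worst* individual ($P=1$ exactly there): the minimizer therefore feeds it
negated objective values, and the structure learner feeds it log-score
health values directly.  Because $|f_{\min}|$ typically dominates both
numerator and denominator, these probabilities sit well above 0.5 for most
of a run; applying them independently to every individual at every
generation would re-randomize most of the colony and destroy the
contraction that produces machine-precision optima.  The per-generation
event therefore selects **one** bacterium uniformly at random and disperses
it with its adaptive probability (re-drawn from the chaotic stream); the
whole-colony form remains available as `eliminate_disperse()`.

Defaults follow the study settings: $S=60$, $T=1000$, $r=0.86$,
$P_{ed}=0.8$, $pc=0.2$; the loop-shape parameters not fixed there are
$N_c=1$ chemotaxis sweep per generation, swim cap $N_s=4$, reproduction and
dispersal every generation, making $T$ the single budget knob.

## The structure learner

`dbn_learn()` runs the same four-activity framework over candidate 2T-BNs,
maximizing the dynamic K2 score.

* **Encoding.** A graph is serialized row-wise: the $n-1$ off-diagonal
  entries of each row joined by `|` (so the three-node DAG with edges
  $1\to2$, $1\to3$, $2\to3$ is `11|01|00`).  A candidate's crossover genome
  is the concatenated $B_0$ and $B_\to$ bit vector.
* **Initialization.** Each candidate draws a random topological order and
  includes each backward edge when a chaotic value, convolved with a
  uniform draw modulo 1, falls below `p_edge` (default 0.25).  The
  convolution makes the inclusion probability exactly `p_edge` while the
  chaotic stream still drives the draws — thresholding the raw stream is
  degenerate at $r=0.86$ (see above).  Temporal validity and the parent cap
  hold by construction.
* **Chemotaxis.** The continuous move has no printed discrete counterpart,
  so the minimal faithful analogue is used: adopt $I\in\{1,2\}$ randomly
  chosen edge differences from a better-scoring target through the three
  validity-checked operations *add*, *remove*, *reverse* (invalid proposals
  are skipped, each with a distinct rejection code), keep the proposal only
  if the score strictly increases, and repeat toward the same target up to
  $N_s$ times while improving.
* **Health and reproduction.** A candidate's health is its $K2_0$ term plus
  the $K2_\to$ term of every accepted step since the last reproduction
  (higher is healthier).  Reproduction crosses each lower-half candidate
  with its rank-matched elite on the bit genome; offspring are repaired by
  a fixed row-major scan that drops any bit whose edge would violate
  acyclicity, bidirectionality, the temporal rule or the parent cap —
  deterministic repair was chosen over randomized repair for
  reproducibility.
* **Dispersal.** Every candidate's probability is updated from the
  historical health extremes (the candidate at the historical minimum gets
  probability 1) and dispersed candidates are re-initialized; the current
  best candidate is immune, so the reported optimum never regresses.
  Unlike the continuous loop, dispersal here tests every candidate: the
  discrete search benefits from aggressive restarts because fresh
  candidates climbing toward the retained best explore its neighbourhood.

The `max_parents` cap (default 4) bounds the $q_i$ blow-up of the score and
is the only structural prior.  A V-structure orientation step is sometimes
mentioned alongside searches of this family; no such rule is defined beyond
the three edge operations, and none is implemented.

## The synthetic-data generator

`forward_sample()` draws sequences ancestrally: slice 0 from the $B_0$
CPTs in topological order, each later slice from the $B_\to$ CPTs
conditioned on the previous slice.  `toy_network()` provides the canonical
three-node fixture (the `11|01|00` / `00110|00011|00001|00010|00001|00000`
pair) with `make_fixture_cpts()`: every child copies its *first* parent
with probability 0.9 and every root's success probability is drawn
uniformly from $[0.3, 0.7]$, deterministically given a seed.  These CPTs
are fixture choices, not estimates.

Two consequences matter for interpreting tests.  First, only
designated-parent edges carry signal: an edge whose child ignores it in the
CPT is statistically absent, and the score-optimal structure correctly
prunes it, so recovery is judged as SHD $\le 1$ rather than exact equality.
Second, K2 is not score-equivalent: with near-symmetric roots the optimum
can orient an edge against the generating direction (on the three-node
fixture at 3000 sequences the exhaustive optimum sits at SHD 1 from the
generating $B_0$).  The scoring *consistency* property is therefore
demonstrated on a single-edge fixture with an asymmetric root
($P=0.3$), where the generating structure genuinely is the exhaustive
argmax.  What passing tests show is recovery of identifiable structure from
clean, stationary, fully observed binary sequences; they do not speak to
hidden variables, non-stationarity, missing data, or cardinalities beyond
those sampled.

## Evaluation

`shd()` counts, over unordered node pairs, edges present in exactly one
graph plus pairs oriented oppositely, each at cost 1 (reversal is a single
operation).  `shd_2tbn()` reports the $B_0$ and $B_\to$ components and
their sum — the aggregation over the pair is a package convention, stated
because reported distances elsewhere do not always say which graphs they
cover.  `summarize_runs()` reports best/worst/mean and the $n-1$ sample
standard deviation, flagging single-run summaries.

## Numerical and degenerate-input choices

* Log-factorials via `lgamma(n + 1)`; empty data scores exactly 0.
* Chemotaxis ties (equal fitness/score) keep the incumbent.
* Out-of-bound continuous candidates are clipped to the nearest bound.
* `dispersal_probability()` returns the previous probability when its
  denominator is exactly 0 (e.g. $f_{\min}=0$ with $P_{prev}=0$); when
  $|f_{\min}|$ is tiny but nonzero the probabilities hug 1, which users
  should expect with scores near zero.
* Length-1 sequences contribute no transition records and a dataset of
  them has a zero transition score term.
* Node order for encodings is the declared node-name order; indices are
  1-based throughout the R interface.

## Problem sizes used by the test suite

The suite validates the optimizer at the full study settings ($S=60$,
$T=1000$) with 10 seeds per benchmark function, and the structure learner
at `pop_size = 20`, `generations = 100` — sizes at which the 200-record
score-optimality check and the 3000-sequence recovery check each run in a
couple of seconds per seed while leaving their success criteria
(≥95/100 and ≥90/100 seeded runs) comfortably met.  Table-scale settings
($S=60$) remain the learner's defaults for real use.  The published
dynamic benchmark networks (2T-Asia, 2T-alarm) are distributed separately;
the CLI accepts them through the JSON network container, and the
acceptance suite exercises that harness path on a synthetic stand-in.

## Known limitations

* First-order, time-invariant transitions only; no higher-lag networks.
* Complete data only — no missing values, no hidden variables.
* Structure learning only: CPT estimation beyond sufficient-statistic
  counting and probabilistic inference are out of scope.
* The discrete chemotaxis move is this package's analogue of the continuous
  one, chosen as the minimal peer-guided move; other discretizations are
  defensible.
* Runtime grows with $q_i$; the parent cap is a hard guard, not a prior
  over structures.
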