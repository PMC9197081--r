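---
title: "Learning and evolution between strategy spaces of different memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning and evolution between strategy spaces of different memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdyn)
```

## The model

Two players repeatedly play a symmetric 2×2 game. In the donation game a
cooperator pays a cost $c$ to give the co-player a benefit $b$, so the focal
payoff vector over round outcomes $(CC, CD, DC, DD)$ is
$\Pi_1 = (b-c, -c, b, 0)$ and the co-player's is $\Pi_2 = (b-c, b, -c, 0)$.
We set $b = 1$ throughout, so $c$ is the cost-to-benefit ratio. The package
also supports arbitrary $(R, S, T, P)$ games and the two-parameter family
$(1, u, v, 0)$ with $u \in [-1, 1]$, $v \in [0, 2]$, whose quadrants are the
four fundamental social dilemmas (`classify_game()`).

Each player is restricted to a strategy space: unconditional (U, one
cooperation probability), reactive (R, a pair $(p, q)$ conditioning on the
co-player's last move), memory-1 (M, $(p_{CC}, p_{CD}, p_{DC}, p_{DD})$), or
memory-2 (M2, 16 entries over the last two rounds). The spaces are nested,
$U \subset R \subset M \subset M2$, and `embed()` realizes the inclusions;
embedding never changes payoffs, which is tested property-style.

A note on the reactive space: it is the set of memory-1 strategies with
$p_{CC} = p_{DC}$ and $p_{CD} = p_{DD}$ — the player conditions only on the
co-player's last move. (Printed definitions of this space sometimes contain
an inconsistent index; the form used here is the one consistent with
Tit-for-Tat, $p_{XC} = 1, p_{XD} = 0$, and Generous Tit-for-Tat,
$p_{XD} = 1 - c/b$.)

### Exact payoffs

For a memory-1 (or embedded smaller) pair the repeated game is a Markov
chain over the four round outcomes; with memory-2 players it is the
16-state chain over the last two rounds, indexed lexicographically by
(own move at $t-2$, own move at $t-1$, co's move at $t-2$, co's move at
$t-1$) with $C < D$. Everywhere the state order is (CC, CD, DC, DD) with
the first letter the focal player's move. Payoffs are
$\pi_1 = v \cdot \Pi_1$, $\pi_2 = v \cdot \Pi_2$ with $v$ the invariant
distribution.

Numerical choices:

* **Implementation errors.** Every strategy entry $x$ is perturbed to
  $(1-\varepsilon)x + \varepsilon(1-x)$ before the chain is built
  (`engine_config()`, default $\varepsilon = 10^{-6}$). This guarantees a
  primitive chain — deterministic pairs like Tit-for-Tat vs Tit-for-Tat
  otherwise have no unique invariant distribution — while moving payoffs by
  $O(\varepsilon)$ only (there is an explicit $\varepsilon$-continuity
  test). The underlying studies state only that errors are "rare"; $10^{-6}$
  was chosen once as a value small enough to be payoff-neutral at the third
  decimal and is not tuned.
* **Stationary solve.** $vP = v$, $\sum v = 1$ is solved as a bordered
  linear system (one balance equation replaced by the normalization row)
  with partial pivoting; at $4\times4$ / $16\times16$ scale this is exact
  and needs no eigen-iteration. A residual above `solver_tol` ($10^{-12}$)
  or a singular system is reported as a degenerate chain rather than
  silently patched.
* **Two payoff routes.** The Press–Dyson determinant ratio is exposed
  (`press_dyson_payoffs()`) and is the fast route for memory-1 pairs; the
  stationary solve covers memory-2 and non-generic pairs (zero determinant
  denominators are reported distinctly so callers can fall back). The two
  routes agree below $10^{-9}$ over $10^4$ random pairs in the test suite —
  this dual-route check is the package's core numerical oracle.

### Introspection dynamics

Learning is modelled as introspection dynamics: starting from random
strategies, in each step one of the two players (picked uniformly) draws a
candidate from its own space and switches with the Fermi probability
$\varrho = 1/(1 + e^{-\beta(\pi' - \pi)})$, where $\beta \ge 0$ is the
selection strength. The reported quantity is the time average
$\bar\pi = \frac{1}{T}\sum_{t=1}^{T} \pi(t)$, taken from $t = 1$ with no
burn-in discarded — exactly as the reference averages in the literature are
defined. The initial transient is negligible at the run lengths used, and
the short-run mean stabilizes within roughly ten steps (tested).

The inner loop is compiled (Rcpp). Payoffs of the current pair are cached
and recomputed only when a strategy actually changes, so each step costs one
stationary solve for the candidate; a $10^6$-step run takes a fraction of a
second, which is what makes replicate tournaments and parameter scans
practical on a single CPU.

Candidate sampling schemes (`sample_strategy()`):

* `uniform` (baseline): i.i.d. Uniform(0, 1) entries;
* `arcsine`: i.i.d. Beta(1/2, 1/2), favouring extreme entries;
* `same_complexity_avg` / `same_complexity_extreme`: four base values are
  drawn regardless of the space, and lower-memory strategies are built by
  averaging pairs (resp. keeping the value farthest from 1/2, ties keeping
  the earlier draw — a measure-zero event fixed for determinism). These
  schemes decouple memory capacity from the size of the sampled strategy
  set; they are defined for U, R and M only, since the underlying
  construction has no memory-2 analogue.

Model extensions, both isolated behind `learner_config()` switches:

* **Imitation** (probability $\alpha$): the revising player adopts the
  co-player's strategy, accepted with the same Fermi rule applied to the
  *current* payoff difference $\pi_{co} - \pi_{self}$. Whether the
  acceptance should be Fermi or unconditional is not pinned down by the
  source material; the Fermi variant was chosen for consistency with the
  baseline update and sits behind the single `alpha` switch. Lower-memory
  observers cannot copy verbatim; they adopt the in-space strategy that best
  matches the imitated player's observable behaviour
  (`infer_effective_strategy()`): the stationary cooperation rate for U, and
  effective $(p, q)$ conditioned on the co-player's last move under the
  invariant distribution for R, with a fallback to the overall cooperation
  rate when a conditioning event has stationary mass below $10^{-9}$.
* **Active search**: candidates are redrawn until one is accepted, capped at
  `search_cap` (default $10^3$) draws per step to prevent non-termination
  near-optimal strategies at strong selection; hitting the cap leaves the
  step a no-op.

### Tournaments and the supergame

`run_tournament()` fills the matrix $\bar\pi_{S_i S_j}$ over ordered space
pairs (self pairings included; the two players of a self pairing are
exchangeable and both are averaged). Per-run seeds derive from the master
seed by a counter scheme, so cells are independent and reproducible.
`measures()` computes the four success measures: pairwise wins (a tie, per
the defining "≥", credits both spaces — so wins can sum to more than the
number of pairings), score, self payoff, and combined score (= score + self
payoff, an identity tested exactly).

The supergame treats whole spaces as traits of an infinite well-mixed
population with frequencies $x$, fitness $f = A x$, and replicator dynamics
$\dot x_i = x_i (f_i - \bar f)$. Implementation notes:

* Integration uses `deSolve::lsoda` at tolerance $10^{-9}$; boundary
  attractors cause harmless negative undershoot, which is clipped and
  renormalized after integration. Faces of the simplex are invariant, and a
  frequency starting at exactly zero is kept at exactly zero.
* Nash equilibria are found by support enumeration (at most 7 supports for
  three spaces): equal-payoff linear systems per support, feasibility and
  invasion checks, stability via the eigenvalues of the replicator Jacobian
  projected onto the simplex tangent space (computed by central
  differences; zero real parts are flagged degenerate, not guessed).
* "Globally stable" claims in scan outputs are numerical certificates —
  convergence checks from interior meshes — not symbolic proofs.
* The Nash tolerance defaults to $10^{-9}$ for exactly known matrices, but
  scans derived from stochastic tournaments use roughly two standard errors
  of the tournament entries, to avoid classifying sampling noise as ties.

A **memory dilemma** is detected (`detect_dilemma()`) when the space with
the largest self payoff is not a pure Nash equilibrium of the supergame:
*classic* if that space is the most complex present, *reverse* if it is a
strictly simpler space; *weak* variants apply when the best-self space is
Nash but other stable states coexist.

## Study conditions and problem sizes

The reference results in the literature use single runs of $T = 10^9$ steps. The
package's tests and the acceptance script reproduce them at
$T = 10^6$ with 10 independent replicates per pairing — the same total
information budget per matrix entry up to a factor, chosen so a full
three-space tournament takes seconds rather than hours. At this scale the
c = 0.2, β = 100 pairwise payoffs land within ±0.005 of the printed
three-decimal values, comfortably inside the ±0.02–0.03 bands the scaled-down
comparison warrants. Scan functions default to coarse grids
(cost step 0.05, 5×5 in $(u, v)$) with short runs; production-scale scans
(step 0.005, $10^9$ steps) are a matter of arguments, not code.

## What the generator does and does not emulate

All inputs are synthetic by construction — the model *is* the data
generator. The simulations capture: exact long-run payoffs (no sampling
error at the game layer), the stochasticity of the learning process, and
the deterministic replicator limit of an infinite population. They do not
capture: finite repeated games or discounting (everything is the
infinitely-iterated limit), finite-population drift at the supergame level,
memory-3 or larger spaces (the package only counts them:
`n_deterministic_strategies(3)` = $2^{64}$, far beyond systematic search),
or complexity *costs* — larger memory is never penalized directly, so any
disadvantage of memory in the results is structural, arising from how hard
it is to sample extreme strategies in a larger space.

## Known limitations

* Tournament entries are Monte-Carlo averages; their standard errors shrink
  as $1/\sqrt{\text{reps} \cdot T}$, and classification near bifurcation
  points inherits that noise. The scan functions expose the Nash tolerance
  for this reason.
* The memory-2 space supports uniform and arcsine sampling only (see
  above).
* Mixed Nash equilibria are enumerated for the supports of the spaces
  supplied (designed for the 3–4 space setting, not large matrices).
* JSON round-trips of results are accurate to ~16 significant digits
  (the serializer's maximum), which is full double precision for all
  practical purposes but not bit-for-bit.
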