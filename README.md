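# memdyn

Direct reciprocity — cooperation sustained by repeated interaction — is
usually studied under the assumption that everyone draws strategies from the
same space. `memdyn` is an R package for the asymmetric case: two players in
an infinitely repeated 2×2 game who are restricted to *different* strategy
spaces, distinguished by the memory capacity they require:

* **U** — unconditional strategies: one cooperation probability;
* **R** — reactive strategies: a pair (p, q), responding to the co-player's
  last move;
* **M** — memory-1 strategies: (p_CC, p_CD, p_DC, p_DD), responding to both
  players' last moves;
* **M2** — memory-2 strategies: 16 entries over the last two rounds.

The package answers three nested questions, each with its own layer:

1. **Game layer** — exact long-run payoffs of a fixed strategy pair. The
   repeated game is a Markov chain over round outcomes (CC, CD, DC, DD);
   payoffs are π₁ = v·Π₁, π₂ = v·Π₂ where v is the chain's invariant
   distribution and Π₁ = (R, S, T, P) the one-shot payoff vector. For the
   donation game (cost c, benefit b), Π₁ = (b−c, −c, b, 0). Two routes are
   implemented: a stationary linear solve (`payoffs()`) and the
   Press–Dyson determinant formula π₁ = D(p, q, Π₁)/D(p, q, 1)
   (`press_dyson_payoffs()`); they agree to 1e−9 on generic pairs. A small
   implementation-error rate ε (default 1e−6) keeps the chain primitive.
2. **Learning layer** — *introspection dynamics*: in each step one player is
   picked at random, draws a candidate strategy from its own space, and
   switches with the Fermi probability 1/(1 + e^(−β Δπ)), where β is the
   selection strength. `introspection_run()` returns time-averaged payoffs
   and cooperation rates (a compiled core makes 10⁶–10⁸ steps cheap);
   `run_tournament()` assembles the space-vs-space pairwise-average matrix
   and `measures()` the wins / score / self-payoff / combined-score summary.
   Model extensions: arcsine and same-complexity candidate sampling,
   imitation with probability α (with effective-strategy inference for
   lower-memory observers), and active search.
3. **Evolution layer** — replicator dynamics ẋᵢ = xᵢ(fᵢ − f̄) on the simplex
   of strategy-space frequencies, with the tournament matrix as the
   "supergame" payoff matrix: classification of pairwise dynamics
   (dominance / bistability / coexistence), Nash equilibria by support
   enumeration, trajectory integration, and detection of **memory
   dilemmas** — situations where the space with the highest self payoff is
   invadable, so evolution settles on a strategy space that is worse for
   everyone. `bifurcation_scan()` and `game_space_scan()` sweep the
   cooperation cost and the (u, v) plane of 2×2 games
   ((R, S, T, P) = (1, u, v, 0), covering prisoner's dilemma, snowdrift,
   stag hunt and harmony games).

## Worked example

```r
library(memdyn)

g <- make_donation_game(b = 1, c = 0.2)

# one learning run: memory-1 vs unconditional, strong selection
run <- introspection_run(learner_config("M", beta = 100),
                         learner_config("U", beta = 100),
                         g, T = 1e5, seed = 1)
glance(run)
#>   space_1 space_2 avg_payoff_1 avg_payoff_2 avg_coop_1 avg_coop_2      T  seed
#> 1 M       U              0.241        0.173      0.230      0.287 100000     1
```

The memory-1 player ends up earning ~0.24 per round against the
unconditional player's ~0.17: with cheap cooperation and strong selection,
more memory pays in this pairing. A full tournament shows the twist — the
reactive space beats the memory-1 space:

```r
tr <- run_tournament(c("M", "R", "U"), g, beta = 100, T = 1e5, reps = 3, seed = 1)
tr$pair_payoffs
#>       M     R     U
#> M 0.475 0.376 0.241
#> R 0.402 0.384 0.250
#> U 0.176 0.137 0.041
measures(tr)
#>   space  wins score self_payoff combined
#> 1 M         1 0.617      0.475     1.09
#> 2 R         2 0.652      0.384     1.04
#> 3 U         0 0.313      0.0407    0.353
```

M has the best self payoff (two memory-1 players learn to cooperate via
win-stay lose-shift-like strategies) but R wins both of its pairwise
competitions. Feeding a costly-cooperation, weak-selection supergame matrix
into the evolution layer exposes the dilemma:

```r
sg <- supergame_matrix(matrix(c(0.154, 0.106, 0.047,
                                0.184, 0.140, 0.099,
                                0.187, 0.121, 0.066),
                              3, 3, byrow = TRUE), c("M", "R", "U"))
detect_dilemma(sg)$dilemma
#> [1] "classic"
detect_dilemma(sg)$witness
#> [1] "pi(U,M) = 0.187 > pi(M,M) = 0.154"
tail(integrate_replicator(rep(1/3, 3), sg, t_end = 2000), 1)[-1]
#> M ~ 0, R > 0.999, U ~ 0
```

The population converges to reactive players even though a monomorphic
memory-1 population would earn more — a classic memory dilemma.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/memdyn.R payoff --p 1,0,0,1 --q 1,0 --b 1 --c 0.3 --json
Rscript inst/cli/memdyn.R tournament --spaces M,R,U --c 0.2 --beta 100 \
    --steps 1e6 --reps 10 --seed 1 --out results/
Rscript inst/cli/memdyn.R scan-cost --beta 10 --c-min 0.05 --c-max 0.95 --step 0.05
```

Strategies are comma-separated probability lists (length 1/2/4/16 implies
the space). Every output directory receives the resolved configuration, so
runs are reproducible from their outputs alone.

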