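#' Payoff engine configuration
#'
#' @param epsilon Implementation-error probability in `[0, 0.5)`. Applied to
#'   every strategy entry before the round-outcome chain is built; a positive
#'   value guarantees a primitive chain and hence a unique invariant
#'   distribution. Defaults to `1e-6`, which perturbs payoffs by a comparable
#'   order of magnitude only.
#' @param solver_tol Residual tolerance for the stationary linear solve.
#' @return An `memdyn_engine` list.
#' @export
engine_config <- function(epsilon = 1e-6, solver_tol = 1e-12) {
  stopifnot(epsilon >= 0, epsilon < 0.5, solver_tol > 0)
  structure(list(epsilon = epsilon, solver_tol = solver_tol),
            class = "memdyn_engine")
}

# embed a pair of strategies into their common chain family (M or M2)
common_family <- function(p, q) {
  p <- as_strategy(p); q <- as_strategy(q)
  target <- if (strategy_space(p)$complexity_rank == 4L ||
                strategy_space(q)$complexity_rank == 4L) "M2" else "M"
  list(p = embed(p, target), q = embed(q, target),
       n_states = if (target == "M2") 16L else 4L)
}

#' Transition matrix of the round-outcome Markov chain
#'
#' For two memory-1 strategies `p` and `q` the state of the chain is the
#' round outcome (CC, CD, DC, DD), first letter the focal player's action.
#' The probability of moving from state `ij` to state `kl` is the product of
#' player 1 choosing `k` (conditioning on history `ij` from its own
#' perspective) and player 2 choosing `l` (conditioning on `ji`). Memory-2
#' pairs use the analogous 16-state chain over the last two rounds.
#'
#' Lower-memory strategies are embedded first; both arguments must end up in
#' the same chain family.
#'
#' @param p,q Strategies (any spaces; embedded to the larger family).
#' @return A row-stochastic matrix (4 x 4 or 16 x 16) with named states.
#' @examples
#' transition_matrix(strategy(c(1, 0, 0, 1)), strategy(c(1, 0)))
#' @export
transition_matrix <- function(p, q) {
  fam <- common_family(p, q)
  pv <- unclass(fam$p); qv <- unclass(fam$q)
  if (fam$n_states == 4L) {
    m <- matrix(0, 4L, 4L)
    states <- expand.grid(co = 0:1, own = 0:1)[, 2:1]  # CC, CD, DC, DD
    for (s in 1:4) {
      i <- states$own[s]; j <- states$co[s]
      pc <- pv[m1_index(i, j)]   # player 1 conditions on (own, co)
      qc <- qv[m1_index(j, i)]   # player 2 sees the state from its side
      m[s, ] <- c(pc * qc, pc * (1 - qc), (1 - pc) * qc, (1 - pc) * (1 - qc))
    }
    dimnames(m) <- list(c("CC", "CD", "DC", "DD"), c("CC", "CD", "DC", "DD"))
    return(m)
  }
  m <- matrix(0, 16L, 16L)
  for (o2 in 0:1) for (o1 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
    s <- m2_index(o2, o1, c2, c1)
    pc <- pv[m2_index(o2, o1, c2, c1)]
    qc <- qv[m2_index(c2, c1, o2, o1)]
    for (a in 0:1) for (b in 0:1) {
      pr <- (if (a == 0) pc else 1 - pc) * (if (b == 0) qc else 1 - qc)
      m[s, m2_index(o1, a, c1, b)] <- pr
    }
  }
  lab <- c("C", "D")
  nm <- character(16L)
  for (o2 in 0:1) for (o1 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
    nm[m2_index(o2, o1, c2, c1)] <-
      paste0(lab[o2 + 1], lab[o1 + 1], "|", lab[c2 + 1], lab[c1 + 1])
  }
  dimnames(m) <- list(nm, nm)
  m
}

#' Invariant distribution of a stochastic matrix
#'
#' Solves `v %*% Tm = v` with `sum(v) = 1` as a bordered linear system: one
#' balance equation is replaced by the normalization constraint. For the
#' 4- and 16-state chains arising here this is an exact-scale direct solve.
#'
#' @param Tm Row-stochastic square matrix.
#' @param tol Residual tolerance; a solve whose residual exceeds it (or a
#'   singular system, possible for deterministic strategies at `epsilon = 0`)
#'   is reported as a degenerate chain.
#' @return Numeric probability vector over the chain states.
#' @export
invariant_distribution <- function(Tm, tol = 1e-12) {
  n <- nrow(Tm)
  stopifnot(ncol(Tm) == n)
  A <- t(Tm) - diag(n)
  A[n, ] <- 1
  rhs <- c(rep(0, n - 1L), 1)
  v <- tryCatch(solve(A, rhs), error = function(e) {
    stop("degenerate chain: stationary distribution is not unique ",
         "(use epsilon > 0)", call. = FALSE)
  })
  if (max(abs(v %*% Tm - v)) > max(tol, 1e-9) || any(v < -1e-9)) {
    stop("degenerate chain: stationary solve failed the balance check",
         call. = FALSE)
  }
  v <- pmax(v, 0)
  v / sum(v)
  }

# stationary distribution for a strategy pair under implementation errors
pair_invariant <- function(p, q, engine = engine_config()) {
  fam <- common_family(p, q)
  pe <- apply_error(fam$p, engine$epsilon)
  qe <- apply_error(fam$q, engine$epsilon)
  invariant_distribution(transition_matrix(pe, qe), engine$solver_tol)
}

# marginals of v over the last-round outcome, focal perspective
last_round_marginals <- function(v) {
  if (length(v) == 4L) return(v)
  out <- numeric(4L)
  for (o2 in 0:1) for (o1 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
    out[m1_index(o1, c1)] <- out[m1_index(o1, c1)] +
      v[m2_index(o2, o1, c2, c1)]
  }
  out
}

#' Long-run payoffs of a strategy pair
#'
#' Payoffs in the infinitely repeated game are computed from the invariant
#' distribution `v` of the round-outcome chain: `pi1 = v . Pi1` and
#' `pi2 = v . Pi2`. Strategies from different spaces are embedded into a
#' common family first, and implementation errors (`engine$epsilon`) are
#' applied before the chain is built.
#'
#' @param p,q Strategies for player 1 and player 2.
#' @param g Game spec.
#' @param engine [engine_config()].
#' @return Named numeric vector `c(pi1 = , pi2 = )`.
#' @examples
#' g <- make_donation_game(b = 1, c = 0.5)
#' payoffs(strategy(1), strategy(0), g)  # ALLC vs ALLD: (-c, b)
#' @export
payoffs <- function(p, q, g, engine = engine_config()) {
  v <- pair_invariant(p, q, engine)
  m <- unname(last_round_marginals(v))
  c(pi1 = sum(m * g$Pi1), pi2 = sum(m * g$Pi2))
}

#' Payoffs via the Press-Dyson determinant formula
#'
#' For two memory-1 strategies the long-run payoff can be written as a ratio
#' of two 4 x 4 determinants, `pi1 = D(p, q, Pi1) / D(p, q, 1)`, avoiding the
#' stationary solve. The formula applies to generic strategy pairs; when the
#' denominator vanishes (non-generic pairs) the function signals a distinct
#' condition so callers can fall back on [payoffs()].
#'
#' @inheritParams payoffs
#' @return Named numeric vector `c(pi1 = , pi2 = )`.
#' @examples
#' g <- make_donation_game(b = 1, c = 0.4)
#' press_dyson_payoffs(strategy(rep(0.5, 4)), strategy(rep(0.5, 4)), g)
#' @export
press_dyson_payoffs <- function(p, q, g) {
  p <- as_strategy(p); q <- as_strategy(q)
  if (strategy_space(p)$complexity_rank == 4L ||
      strategy_space(q)$complexity_rank == 4L) {
    stop("the determinant formula applies to memory-1 (or smaller) pairs",
         call. = FALSE)
  }
  pv <- unclass(embed(p, "M")); qv <- unclass(embed(q, "M"))
  D <- function(f) {
    det(cbind(
      c(-1 + pv[1] * qv[1], pv[2] * qv[3], pv[3] * qv[2], pv[4] * qv[4]),
      c(-1 + pv[1], -1 + pv[2], pv[3], pv[4]),
      c(-1 + qv[1], qv[3], -1 + qv[2], qv[4]),
      f))
  }
  denom <- D(rep(1, 4))
  if (abs(denom) < 1e-14) {
    stop("zero determinant denominator: non-generic pair, fall back on the ",
         "stationary solve", call. = FALSE)
  }
  c(pi1 = D(g$Pi1) / denom, pi2 = D(g$Pi2) / denom)
}

#' Long-run cooperation rates of a strategy pair
#'
#' Marginals of the invariant distribution: player 1 cooperates with
#' probability `v_CC + v_CD`, player 2 with `v_CC + v_DC`.
#'
#' @inheritParams payoffs
#' @return Named numeric vector `c(rho1 = , rho2 = )`.
#' @export
cooperation_rates <- function(p, q, engine = engine_config()) {
  m <- unname(last_round_marginals(pair_invariant(p, q, engine)))
  c(rho1 = m[1] + m[2], rho2 = m[1] + m[3])
}
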