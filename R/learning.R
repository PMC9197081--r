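scheme_levels <- c("uniform", "arcsine", "same_complexity_avg",
                   "same_complexity_extreme")

scheme_code <- function(scheme) {
  scheme <- match.arg(scheme, scheme_levels)
  match(scheme, scheme_levels) - 1L
}

#' Sample a random strategy
#'
#' Candidate generation for the learning process. Four schemes are supported:
#'
#' * `uniform` — every entry i.i.d. Uniform(0, 1) (the baseline).
#' * `arcsine` — every entry i.i.d. arcsine (Beta(1/2, 1/2)), putting more
#'   weight on extreme cooperation probabilities.
#' * `same_complexity_avg` — four uniform base values are drawn regardless of
#'   the space; memory-1 keeps the raw draws, reactive strategies average
#'   pairs (`(p1+p2)/2`, `(p3+p4)/2`), unconditional strategies average all
#'   four. This equalizes the sampled complexity across spaces while pulling
#'   low-memory strategies toward 1/2.
#' * `same_complexity_extreme` — four uniform base values; lower-memory
#'   strategies keep, per component, the value farthest from 1/2 (ties keep
#'   the earlier draw), biasing them toward extreme behaviour.
#'
#' The same-complexity schemes are defined for the U, R and M spaces only.
#'
#' @param space Space label or [space_tag()].
#' @param scheme Sampling scheme (see above).
#' @return A [strategy()] in the requested space.
#' @export
sample_strategy <- function(space, scheme = "uniform") {
  if (!inherits(space, "memdyn_space")) space <- space_tag(space)
  scheme <- match.arg(scheme, scheme_levels)
  d <- space$dimension
  if (scheme == "uniform") return(strategy(runif(d), space$label))
  if (scheme == "arcsine") return(strategy(rbeta(d, 0.5, 0.5), space$label))
  if (d > 4L) {
    stop("same-complexity sampling is defined for the U, R and M spaces only",
         call. = FALSE)
  }
  z <- runif(4)
  pick_extreme <- function(x) x[which.max(abs(x - 0.5))]
  entries <- if (scheme == "same_complexity_avg") {
    switch(space$label,
           M = z,
           R = c(mean(z[1:2]), mean(z[3:4])),
           U = mean(z))
  } else {
    switch(space$label,
           M = z,
           R = c(pick_extreme(z[1:2]), pick_extreme(z[3:4])),
           U = pick_extreme(z))
  }
  strategy(entries, space$label)
}

#' Fermi acceptance probability
#'
#' Probability that a revising player switches to a candidate strategy:
#' `1 / (1 + exp(-beta * (pi_new - pi_old)))`. At `beta = 0` every switch is
#' a coin flip (neutral drift); as `beta` grows, only payoff improvements are
#' accepted. Overflow-safe for large `|beta * delta|`.
#'
#' @param pi_new,pi_old Candidate and current payoffs.
#' @param beta Selection strength, `>= 0`.
#' @return Acceptance probability in `(0, 1)`.
#' @examples
#' acceptance_probability(0.4, 0.3, beta = 100)
#' @export
acceptance_probability <- function(pi_new, pi_old, beta) {
  stopifnot(beta >= 0)
  x <- beta * (pi_new - pi_old)
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

#' Learner configuration
#'
#' Bundles one player's constraints in the learning process: the strategy
#' space explored, the candidate-sampling scheme, the selection strength of
#' the Fermi rule, and the optional model extensions (imitation with
#' probability `alpha`, and active search, where a player redraws candidates
#' until one is accepted, capped at `search_cap` draws per step).
#'
#' @param space Space label (`"U"`, `"R"`, `"M"`, `"M2"`).
#' @param beta Selection strength, `>= 0`.
#' @param scheme Sampling scheme, see [sample_strategy()].
#' @param alpha Imitation probability in `[0, 1]`; `0` is the baseline
#'   introspection process.
#' @param active_search If `TRUE`, candidates are redrawn until accepted
#'   (or `search_cap` is reached, in which case the step is a no-op).
#' @param search_cap Maximum candidate draws per active-search step.
#' @return An `memdyn_learner` list.
#' @export
learner_config <- function(space, beta = 100, scheme = "uniform",
                           alpha = 0, active_search = FALSE,
                           search_cap = 1000L) {
  if (!inherits(space, "memdyn_space")) space <- space_tag(space)
  scheme <- match.arg(scheme, scheme_levels)
  stopifnot(beta >= 0, alpha >= 0, alpha <= 1, search_cap >= 1)
  if (space$dimension > 4L && scheme %in% scheme_levels[3:4]) {
    stop("same-complexity sampling is defined for the U, R and M spaces only",
         call. = FALSE)
  }
  structure(list(space = space, beta = beta, scheme = scheme, alpha = alpha,
                 active_search = active_search,
                 search_cap = as.integer(search_cap)),
            class = "memdyn_learner")
}

#' Run introspection dynamics between two players
#'
#' Two players with fixed (possibly different) strategy spaces start from
#' random strategies. In each of `T` steps one player is picked uniformly at
#' random and revises its strategy: a candidate is drawn from the player's
#' space (or, with probability `alpha`, imitated from the co-player), its
#' payoff against the co-player's current strategy is computed exactly from
#' the round-outcome Markov chain, and the switch is accepted with the Fermi
#' probability [acceptance_probability()]. Payoffs and cooperation rates of
#' both players are recorded after every step; the reported averages run over
#' `t = 1..T` with no burn-in discarded.
#'
#' @param cfg1,cfg2 [learner_config()]s for the two players.
#' @param g Game spec.
#' @param T Number of elementary steps.
#' @param engine [engine_config()].
#' @param seed Optional integer seed (set before sampling the initial
#'   strategies).
#' @param init1,init2 Optional initial strategies (default: sampled from the
#'   player's scheme).
#' @return An `memdyn_run` object; see [tidy()] / [glance()] for tabular
#'   access. Fields: `avg_payoff_1/2`, `avg_coop_1/2`, `accept_1/2` (accepted
#'   switches), `final_1/2` (final strategies), `T`, `seed`.
#' @examples
#' g <- make_donation_game(b = 1, c = 0.2)
#' run <- introspection_run(learner_config("M"), learner_config("U"),
#'                          g, T = 1000, seed = 1)
#' glance(run)
#' @export
introspection_run <- function(cfg1, cfg2, g, T,
                              engine = engine_config(), seed = NULL,
                              init1 = NULL, init2 = NULL) {
  stopifnot(inherits(cfg1, "memdyn_learner"), inherits(cfg2, "memdyn_learner"),
            inherits(g, "memdyn_game"), T >= 1)
  if (!is.null(seed)) set.seed(seed)
  as_init <- function(x, cfg) {
    if (is.null(x)) return(numeric(0))
    x <- as_strategy(x)
    stopifnot(attr(x, "space") == cfg$space$label)
    unclass(x)
  }
  res <- cpp_introspection_run(
    cfg1$space$dimension, cfg2$space$dimension,
    scheme_code(cfg1$scheme), scheme_code(cfg2$scheme),
    g$Pi1, cfg1$beta, cfg2$beta, cfg1$alpha, cfg2$alpha,
    cfg1$active_search, cfg2$active_search,
    max(cfg1$search_cap, cfg2$search_cap),
    engine$epsilon, as.numeric(T),
    as_init(init1, cfg1), as_init(init2, cfg2))
  structure(
    list(avg_payoff_1 = res$avg_payoff_1, avg_payoff_2 = res$avg_payoff_2,
         avg_coop_1 = res$avg_coop_1, avg_coop_2 = res$avg_coop_2,
         accept_1 = res$accept_1, accept_2 = res$accept_2,
         final_1 = strategy(res$final_1, cfg1$space$label),
         final_2 = strategy(res$final_2, cfg2$space$label),
         T = T, seed = seed,
         space_1 = cfg1$space$label, space_2 = cfg2$space$label,
         game = g),
    class = "memdyn_run")
}

#' @export
print.memdyn_run <- function(x, ...) {
  cat(sprintf("<introspection run %s vs %s, T = %g>\n", x$space_1, x$space_2, x$T))
  cat(sprintf("  avg payoffs: %.4f / %.4f   avg coop: %.4f / %.4f\n",
              x$avg_payoff_1, x$avg_payoff_2, x$avg_coop_1, x$avg_coop_2))
  invisible(x)
}

#' @rdname introspection_run
#' @param x An `memdyn_run` object.
#' @param ... Unused.
#' @export
tidy.memdyn_run <- function(x, ...) {
  tibble::tibble(
    player = c(1L, 2L),
    space = c(x$space_1, x$space_2),
    avg_payoff = c(x$avg_payoff_1, x$avg_payoff_2),
    avg_coop = c(x$avg_coop_1, x$avg_coop_2),
    accepted = c(x$accept_1, x$accept_2))
}

#' @rdname introspection_run
#' @export
glance.memdyn_run <- function(x, ...) {
  tibble::tibble(
    space_1 = x$space_1, space_2 = x$space_2,
    avg_payoff_1 = x$avg_payoff_1, avg_payoff_2 = x$avg_payoff_2,
    avg_coop_1 = x$avg_coop_1, avg_coop_2 = x$avg_coop_2,
    T = x$T, seed = x$seed %||% NA_integer_)
}

#' Infer the in-space strategy closest to an observed player
#'
#' When a lower-memory player imitates a higher-memory co-player, it adopts
#' the strategy in its own space that best matches the imitated player's
#' observable behaviour: an unconditional observer takes the imitated
#' player's stationary cooperation rate; a reactive observer takes effective
#' cooperation probabilities conditioned on the co-player's last move under
#' the invariant distribution of the (imitated, opponent) pair. Observers
#' with equal or larger memory copy the strategy verbatim (embedded).
#'
#' @param observer_space Space label of the imitating player.
#' @param imitated Strategy of the player being imitated.
#' @param opponent The imitated player's current co-player (i.e. the observer
#'   itself, in the learning process).
#' @param engine [engine_config()].
#' @return A strategy in `observer_space`.
#' @export
infer_effective_strategy <- function(observer_space, imitated, opponent,
                                     engine = engine_config()) {
  if (!inherits(observer_space, "memdyn_space")) {
    observer_space <- space_tag(observer_space)
  }
  imitated <- as_strategy(imitated); opponent <- as_strategy(opponent)
  if (observer_space$complexity_rank >= strategy_space(imitated)$complexity_rank) {
    return(embed(imitated, observer_space))
  }
  # invariant distribution with the imitated player as the focal player
  v <- pair_invariant(imitated, opponent, engine)
  m <- last_round_marginals(v)
  coop_rate <- m[1] + m[2]
  if (observer_space$label == "U") return(strategy(coop_rate))
  if (observer_space$label == "R") {
    fam <- common_family(imitated, opponent)
    s <- unclass(fam$p)
    if (fam$n_states == 4L) {
      mass_c <- v[1] + v[3]; mass_d <- v[2] + v[4]
      num_c <- v[1] * s[1] + v[3] * s[3]
      num_d <- v[2] * s[2] + v[4] * s[4]
    } else {
      idx <- seq_len(16L)  # lowest bit of the state index is the co-player's last move
      is_c <- (idx - 1L) %% 2L == 0L
      mass_c <- sum(v[is_c]); mass_d <- sum(v[!is_c])
      num_c <- sum(v[is_c] * s[is_c]); num_d <- sum(v[!is_c] * s[!is_c])
    }
    p_eff <- if (mass_c > 1e-9) num_c / mass_c else coop_rate
    q_eff <- if (mass_d > 1e-9) num_d / mass_d else coop_rate
    return(strategy(c(p_eff, q_eff)))
  }
  # observer M, imitated M2
  s <- unclass(imitated)
  out <- numeric(4L)
  for (o1 in 0:1) for (c1 in 0:1) {
    idx <- vapply(0:3, function(k) {
      o2 <- k %/% 2L; c2 <- k %% 2L
      m2_index(o2, o1, c2, c1)
    }, integer(1))
    mass <- sum(v[idx])
    out[m1_index(o1, c1)] <- if (mass > 1e-9) sum(v[idx] * s[idx]) / mass else coop_rate
  }
  strategy(out, "M")
}

#' Distribution of cooperation rates after short learning
#'
#' Samples `n_samples` fresh strategy pairs from the two spaces, runs
#' `t_steps` of introspection dynamics for each, records both players'
#' long-run cooperation rates, and bins them. Densities are renormalized so
#' each curve integrates to one. With `t_steps = 0` this is the distribution
#' of cooperation rates of randomly sampled pairs.
#'
#' @param space1,space2 Space labels of the two players.
#' @param g Game spec.
#' @param beta Selection strength.
#' @param t_steps Learning steps per sampled pair.
#' @param n_samples Number of sampled pairs.
#' @param bin_width Bin width (must divide 1).
#' @param engine [engine_config()].
#' @param scheme Sampling scheme for both players.
#' @return A tibble with columns `bin_mid`, `density_1`, `density_2`.
#' @export
coop_rate_distribution <- function(space1, space2, g, beta, t_steps,
                                   n_samples, bin_width = 0.02,
                                   engine = engine_config(),
                                   scheme = "uniform") {
  stopifnot(abs(1 / bin_width - round(1 / bin_width)) < 1e-9)
  s1 <- space_tag(space1); s2 <- space_tag(space2)
  rho <- cpp_coop_samples(as.integer(n_samples), s1$dimension, s2$dimension,
                          scheme_code(scheme), scheme_code(scheme),
                          g$Pi1, beta, engine$epsilon, as.integer(t_steps))
  breaks <- seq(0, 1, by = bin_width)
  bin_density <- function(x) {
    h <- graphics::hist(pmin(pmax(x, 0), 1), breaks = breaks, plot = FALSE)
    h$density
  }
  tibble::tibble(
    bin_mid = breaks[-1] - bin_width / 2,
    density_1 = bin_density(rho[, 1]),
    density_2 = bin_density(rho[, 2]))
}

#' @rdname coop_rate_distribution
#' @param object A tibble from `coop_rate_distribution()`.
#' @param ... Unused.
#' @export
plot_coop_distribution <- function(object, ...) {
  long <- tidyr::pivot_longer(object, dplyr::starts_with("density"),
                              names_to = "player", names_prefix = "density_",
                              values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_mid, y = .data$density,
                                     colour = .data$player)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cooperation rate", y = "density", colour = "player") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
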