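#' Run a space-versus-space tournament
#'
#' For every ordered pair of strategy spaces (including self pairings) the
#' introspection dynamics is simulated `reps` times for `T` steps each, and
#' the time-averaged payoff of the space-`i` player against the space-`j`
#' player is averaged over replicates. The result is the pairwise-average
#' matrix that feeds the success measures ([measures()]) and the supergame
#' between strategy spaces ([supergame()]).
#'
#' Per-run seeds are derived from `seed` by a counter scheme,
#' `(seed + 7919 * counter) mod (2^31 - 1)`, so every cell replicate uses an
#' independent, reproducible stream.
#'
#' @param spaces Character vector of space labels (default `c("M","R","U")`,
#'   the row/column order of the result).
#' @param g Game spec.
#' @param beta Selection strength (both players).
#' @param T Steps per run.
#' @param reps Independent replicates per pairing.
#' @param engine [engine_config()].
#' @param scheme Sampling scheme for all players.
#' @param seed Master seed.
#' @return An `memdyn_tournament` object with fields `spaces`,
#'   `pair_payoffs` (matrix, entry (i, j) = average payoff of space i against
#'   space j), `pair_coop` (matching cooperation rates), `se` (standard
#'   errors over replicates) and `params`.
#' @examples
#' g <- make_donation_game(b = 1, c = 0.2)
#' tr <- run_tournament(c("R", "U"), g, beta = 100, T = 2000, reps = 2, seed = 1)
#' tidy(tr)
#' @export
run_tournament <- function(spaces = c("M", "R", "U"), g, beta, T, reps = 10,
                           engine = engine_config(), scheme = "uniform",
                           seed = NULL) {
  stopifnot(reps >= 1, length(spaces) >= 1)
  k <- length(spaces)
  pay <- coop <- se <- matrix(NA_real_, k, k, dimnames = list(spaces, spaces))
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    if (is.null(seed)) NULL
    else (as.integer(seed) + 7919L * counter) %% 2147483647L
  }
  for (i in seq_len(k)) {
    for (j in i:k) {
      cfg_i <- learner_config(spaces[i], beta = beta, scheme = scheme)
      cfg_j <- learner_config(spaces[j], beta = beta, scheme = scheme)
      pij <- pji <- cij <- cji <- numeric(reps)
      for (r in seq_len(reps)) {
        run <- introspection_run(cfg_i, cfg_j, g, T = T, engine = engine,
                                 seed = next_seed())
        pij[r] <- run$avg_payoff_1; pji[r] <- run$avg_payoff_2
        cij[r] <- run$avg_coop_1; cji[r] <- run$avg_coop_2
      }
      if (i == j) {
        # self-play: the two players are exchangeable
        pay[i, i] <- mean(c(pij, pji)); coop[i, i] <- mean(c(cij, cji))
        se[i, i] <- stats::sd(c(pij, pji)) / sqrt(2 * reps)
      } else {
        pay[i, j] <- mean(pij); pay[j, i] <- mean(pji)
        coop[i, j] <- mean(cij); coop[j, i] <- mean(cji)
        se[i, j] <- stats::sd(pij) / sqrt(reps)
        se[j, i] <- stats::sd(pji) / sqrt(reps)
      }
    }
  }
  structure(
    list(spaces = spaces, pair_payoffs = pay, pair_coop = coop, se = se,
         params = list(g = g, beta = beta, T = T, reps = reps,
                       scheme = scheme, seed = seed,
                       epsilon = engine$epsilon)),
    class = "memdyn_tournament")
}

#' @export
print.memdyn_tournament <- function(x, ...) {
  cat(sprintf("<tournament %s: beta = %g, T = %g, reps = %d>\n",
              paste(x$spaces, collapse = "/"), x$params$beta, x$params$T,
              x$params$reps))
  print(round(x$pair_payoffs, 3))
  invisible(x)
}

#' @rdname run_tournament
#' @param x An `memdyn_tournament` object.
#' @param ... Unused.
#' @export
tidy.memdyn_tournament <- function(x, ...) {
  k <- length(x$spaces)
  grid <- expand.grid(space = x$spaces, opponent = x$spaces,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    space = grid$space, opponent = grid$opponent,
    avg_payoff = as.vector(x$pair_payoffs),
    avg_coop = as.vector(x$pair_coop),
    se = as.vector(x$se))
}

#' Tournament success measures
#'
#' Computes the four measures of a strategy space's success from a complete
#' pairwise-average matrix: the number of pairwise wins (a tie credits both
#' spaces), the score (payoff summed over the other spaces), the self payoff
#' (diagonal entry), and the combined score (score plus self payoff).
#'
#' @param tr An `memdyn_tournament` object, or a square named matrix of
#'   pairwise averages.
#' @return A tibble with one row per space and columns `space`, `wins`,
#'   `score`, `self_payoff`, `combined`; the attribute `"ranking"` holds the
#'   descending ranking string per measure.
#' @examples
#' A <- matrix(c(0.154, 0.106, 0.047,
#'               0.184, 0.140, 0.099,
#'               0.187, 0.121, 0.066),
#'             3, 3, byrow = TRUE, dimnames = list(c("M","R","U"), c("M","R","U")))
#' measures(A)
#' @export
measures <- function(tr) {
  A <- if (inherits(tr, "memdyn_tournament")) tr$pair_payoffs else as.matrix(tr)
  stopifnot(nrow(A) == ncol(A), !anyNA(A))
  spaces <- rownames(A) %||% paste0("S", seq_len(nrow(A)))
  k <- nrow(A)
  wins <- score <- numeric(k)
  for (i in seq_len(k)) {
    others <- setdiff(seq_len(k), i)
    wins[i] <- sum(A[i, others] >= A[others, i])
    score[i] <- sum(A[i, others])
  }
  self <- unname(diag(A))
  out <- tibble::tibble(space = spaces, wins = wins, score = score,
                        self_payoff = self, combined = score + self)
  rank_str <- function(v) paste(spaces[order(v, decreasing = TRUE)],
                                collapse = ", ")
  attr(out, "ranking") <- c(wins = rank_str(wins), score = rank_str(score),
                            self_payoff = rank_str(self),
                            combined = rank_str(score + self))
  out
}

#' @rdname run_tournament
#' @param object An `memdyn_tournament` object.
#' @export
autoplot.memdyn_tournament <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$opponent, y = .data$space,
                                  fill = .data$avg_payoff)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$avg_payoff))) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "opponent space", y = "focal space",
                  fill = "avg payoff") +
    ggplot2::theme_minimal()
}
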