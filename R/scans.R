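#' Bifurcation scan over the cooperation cost
#'
#' For each cost on the grid, a full tournament between the given spaces is
#' simulated, the supergame assembled, and the replicator dynamics
#' classified, along with the average self-play cooperation rate of each
#' space (the monomorphic-population cooperation level). The defaults keep
#' the grid coarse and the runs short; pass a finer `step` and larger
#' `T`/`reps` for production scans.
#'
#' @param c_min,c_max,step Cost grid (donation game, `b = 1`).
#' @param beta Selection strength.
#' @param spaces Spaces in complexity order (most complex first).
#' @param T,reps,scheme,engine,seed Tournament settings, see
#'   [run_tournament()].
#' @param nash_tol Nash tolerance; defaults to twice the largest standard
#'   error of the tournament matrix, to avoid classifying noise-level ties.
#' @return A tibble, one row per cost: dilemma label, best-self space,
#'   stable states, pairwise classifications, and per-space self-play
#'   cooperation rates (`coop_<space>` columns, flagged stable/unstable via
#'   `stable_<space>`).
#' @export
bifurcation_scan <- function(c_min = 0.05, c_max = 0.95, step = 0.05,
                             beta = 10, spaces = c("M", "R", "U"),
                             T = 1e5, reps = 2, scheme = "uniform",
                             engine = engine_config(), seed = NULL,
                             nash_tol = NULL) {
  stopifnot(step > 0)
  costs <- seq(c_min, c_max, by = step)
  counter <- 0L
  rows <- purrr::map(costs, function(cc) {
    counter <<- counter + 1L
    s <- if (is.null(seed)) NULL else
      (as.integer(seed) + 104729L * counter) %% 2147483647L
    tr <- run_tournament(spaces, make_donation_game(b = 1, c = cc),
                         beta = beta, T = T, reps = reps, engine = engine,
                         scheme = scheme, seed = s)
    tol <- nash_tol %||% max(2 * max(tr$se, na.rm = TRUE), 1e-9)
    rep_ <- dynamics_report(supergame(tr), complexity = spaces, tol = tol)
    pure_stable <- rep_$stable_states$support[!grepl("\\+", rep_$stable_states$support)]
    row <- tibble::tibble(
      cost = cc, beta = beta, dilemma = rep_$dilemma,
      best_self = rep_$best_self,
      stable_states = paste(rep_$stable_states$support, collapse = "; "),
      pairwise = paste(names(rep_$pairwise), unlist(rep_$pairwise),
                       sep = ": ", collapse = "; "))
    for (sp in spaces) {
      row[[paste0("coop_", sp)]] <- tr$pair_coop[sp, sp]
      row[[paste0("stable_", sp)]] <- sp %in% pure_stable
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Scan the space of two by two games
#'
#' Repeats the tournament-plus-replicator analysis over a grid of games
#' `(R, S, T, P) = (1, u, v, 0)` with `u` in `[-1, 1]` and `v` in `[0, 2]`,
#' covering the four fundamental social dilemmas. For each cell it reports
#' the game class, the Nash set of the supergame, the space with the highest
#' self payoff, and the memory-dilemma label.
#'
#' @param n_u,n_v Grid resolution in `u` and `v`.
#' @param beta Selection strength.
#' @inheritParams bifurcation_scan
#' @return A tibble, one row per grid cell.
#' @export
game_space_scan <- function(n_u = 5, n_v = 5, beta = 100,
                            spaces = c("M", "R", "U"),
                            T = 1e5, reps = 2, scheme = "uniform",
                            engine = engine_config(), seed = NULL,
                            nash_tol = NULL) {
  grid <- expand.grid(u = seq(-1, 1, length.out = n_u),
                      v = seq(0, 2, length.out = n_v))
  counter <- 0L
  rows <- purrr::pmap(grid, function(u, v) {
    counter <<- counter + 1L
    s <- if (is.null(seed)) NULL else
      (as.integer(seed) + 104729L * counter) %% 2147483647L
    g <- game_from_uv(u, v)
    tr <- run_tournament(spaces, g, beta = beta, T = T, reps = reps,
                         engine = engine, scheme = scheme, seed = s)
    tol <- nash_tol %||% max(2 * max(tr$se, na.rm = TRUE), 1e-9)
    rep_ <- dynamics_report(supergame(tr), complexity = spaces, tol = tol)
    tibble::tibble(
      u = u, v = v, game_class = classify_game(g),
      nash = paste(rep_$nash$support, collapse = "; "),
      stable_states = paste(rep_$stable_states$support, collapse = "; "),
      best_self = rep_$best_self, dilemma = rep_$dilemma)
  })
  dplyr::bind_rows(rows)
}

#' @rdname game_space_scan
#' @param object A tibble from `game_space_scan()`.
#' @param fill Which label to colour cells by: `"dilemma"`, `"best_self"` or
#'   `"nash"`.
#' @param ... Unused.
#' @export
plot_game_space_scan <- function(object, fill = c("dilemma", "best_self", "nash"),
                                 ...) {
  fill <- match.arg(fill)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$v, y = .data$u,
                                       fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::theme_minimal()
}
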