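#' One-shot game specifications
#'
#' A game spec stores the focal player's payoffs in a symmetric two by two
#' game: `R` for mutual cooperation, `S` for cooperating against a defector,
#' `T` for defecting against a cooperator, and `P` for mutual defection.
#' The payoff vectors over round outcomes (CC, CD, DC, DD) are
#' `Pi1 = (R, S, T, P)` for the focal player and `Pi2 = (R, T, S, P)` for the
#' co-player.
#'
#' `make_donation_game()` builds the donation game, where a cooperating
#' player pays a cost `c` to confer a benefit `b`, so
#' `(R, S, T, P) = (b - c, -c, b, 0)`. `game_from_uv()` builds the
#' two-parameter family `(R, S, T, P) = (1, u, v, 0)` with `u` in `[-1, 1]`
#' and `v` in `[0, 2]`, which tiles the four fundamental social dilemmas
#' into quadrants (prisoner's dilemma lower-right, snowdrift upper-right,
#' harmony upper-left, stag hunt lower-left, taking `u` as the vertical and
#' `v` as the horizontal axis).
#'
#' @param R,S,T,P Focal payoffs for outcomes CC, CD, DC, DD.
#' @param b,c Benefit and cost of cooperation. `c` may be negative
#'   (cooperation individually profitable) or exceed `b` (inefficient
#'   cooperation).
#' @param u,v Parameters of the `(1, u, v, 0)` family.
#' @return A `memdyn_game` list with fields `R`, `S`, `T`, `P`, `Pi1`, `Pi2`
#'   and, where applicable, `b`, `c` or `u`, `v`.
#' @examples
#' make_donation_game(b = 1, c = 0.3)
#' game_from_uv(u = -0.5, v = 1.5)  # a prisoner's dilemma
#' @name game_spec
NULL

new_game <- function(R, S, T, P, b = NULL, c = NULL, u = NULL, v = NULL) {
  structure(
    list(R = R, S = S, T = T, P = P,
         Pi1 = c(R, S, T, P), Pi2 = c(R, T, S, P),
         b = b, c = c, u = u, v = v),
    class = "memdyn_game"
  )
}

#' @rdname game_spec
#' @export
make_game <- function(R, S, T, P) new_game(R, S, T, P)

#' @rdname game_spec
#' @export
make_donation_game <- function(b = 1, c) {
  new_game(R = b - c, S = -c, T = b, P = 0, b = b, c = c)
}

#' @rdname game_spec
#' @export
game_from_uv <- function(u, v) {
  stopifnot(u >= -1, u <= 1, v >= 0, v <= 2)
  new_game(R = 1, S = u, T = v, P = 0, u = u, v = v)
}

#' @export
print.memdyn_game <- function(x, ...) {
  cat(sprintf("<game (R,S,T,P) = (%s)> class %s\n",
              paste(format(c(x$R, x$S, x$T, x$P), digits = 4), collapse = ", "),
              classify_game(x)))
  invisible(x)
}

#' Classify a two by two game
#'
#' Orders the one-shot payoffs to identify the social dilemma: prisoner's
#' dilemma (`PD`: T > R and P > S), snowdrift (`SG`: T > R and S > P),
#' stag hunt (`SH`: R > T and P > S) or harmony (`HG`: R > T and S > P).
#' Games with ties in either ordering are flagged `degenerate`.
#'
#' @param g A game spec from [make_donation_game()], [game_from_uv()] or
#'   [make_game()].
#' @return A single string: `"PD"`, `"SG"`, `"SH"`, `"HG"` or `"degenerate"`.
#' @examples
#' classify_game(make_donation_game(b = 1, c = 0.3))  # "PD"
#' @export
classify_game <- function(g) {
  stopifnot(inherits(g, "memdyn_game"))
  if (g$T == g$R || g$S == g$P) return("degenerate")
  greed <- g$T > g$R   # temptation to defect against a cooperator
  fear <- g$P > g$S    # defection safer against a defector
  if (greed && fear) "PD"
  else if (greed && !fear) "SG"
  else if (!greed && fear) "SH"
  else "HG"
}
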