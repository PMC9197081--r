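#' Strategy spaces
#'
#' Players in the repeated game are restricted to one of four nested strategy
#' spaces, distinguished by the memory capacity they require:
#'
#' * `"U"` — unconditional strategies: a single cooperation probability,
#'   independent of the history.
#' * `"R"` — reactive strategies: a pair `(p, q)` of cooperation
#'   probabilities after the co-player cooperated (`p`) or defected (`q`).
#' * `"M"` — memory-1 strategies: a vector `(p_CC, p_CD, p_DC, p_DD)`
#'   conditioning on both players' previous actions; the first index is the
#'   focal player's own previous action, the second the co-player's.
#' * `"M2"` — memory-2 strategies: 16 entries indexed lexicographically by
#'   (own move at t-2, own move at t-1, co's move at t-2, co's move at t-1)
#'   with C before D.
#'
#' The spaces are nested: U is contained in R is contained in M is contained
#' in M2, so any low-memory strategy can be [embedded][embed] into a larger
#' space without changing behaviour.
#'
#' @param label One of `"U"`, `"R"`, `"M"`, `"M2"`.
#' @return `space_tag()` returns a list with elements `label`, `dimension`
#'   (1, 2, 4 or 16) and `complexity_rank` (1 to 4, increasing with memory).
#' @examples
#' space_tag("R")
#' @export
space_tag <- function(label) {
  label <- match.arg(label, c("U", "R", "M", "M2"))
  dims <- c(U = 1L, R = 2L, M = 4L, M2 = 16L)
  ranks <- c(U = 1L, R = 2L, M = 3L, M2 = 4L)
  structure(
    list(label = label, dimension = dims[[label]],
         complexity_rank = ranks[[label]]),
    class = "memdyn_space"
  )
}

#' @export
print.memdyn_space <- function(x, ...) {
  cat(sprintf("<strategy space %s: dim %d, rank %d>\n",
              x$label, x$dimension, x$complexity_rank))
  invisible(x)
}

space_from_length <- function(n) {
  switch(as.character(n),
         "1" = "U", "2" = "R", "4" = "M", "16" = "M2",
         stop("strategy length must be 1, 2, 4 or 16, got ", n, call. = FALSE))
}

#' Construct a strategy
#'
#' A strategy is a vector of cooperation probabilities tagged with its
#' strategy space. When `space` is omitted it is inferred from the length of
#' `entries` (1 = unconditional, 2 = reactive, 4 = memory-1, 16 = memory-2).
#'
#' @param entries Numeric vector of cooperation probabilities in `[0, 1]`.
#' @param space Optional space label (`"U"`, `"R"`, `"M"`, `"M2"`); must be
#'   consistent with `length(entries)`.
#' @return A `memdyn_strategy` object (numeric vector with a space attribute).
#' @examples
#' strategy(c(1, 0))          # Tit-for-Tat, reactive
#' strategy(c(1, 0, 0, 1))    # win-stay lose-shift, memory-1
#' @export
strategy <- function(entries, space = NULL) {
  entries <- as.numeric(entries)
  if (anyNA(entries) || any(entries < 0) || any(entries > 1)) {
    stop("strategy entries must be probabilities in [0, 1]", call. = FALSE)
  }
  label <- space_from_length(length(entries))
  if (!is.null(space)) {
    if (inherits(space, "memdyn_space")) space <- space$label
    if (!identical(space, label)) {
      stop("entries of length ", length(entries),
           " are inconsistent with space ", space, call. = FALSE)
    }
  }
  structure(entries, space = label, class = "memdyn_strategy")
}

#' @export
print.memdyn_strategy <- function(x, ...) {
  cat(sprintf("<%s strategy> %s\n", attr(x, "space"),
              paste(format(unclass(x), digits = 4), collapse = ", ")))
  invisible(x)
}

as_strategy <- function(x) {
  if (inherits(x, "memdyn_strategy")) x else strategy(x)
}

strategy_space <- function(s) space_tag(attr(as_strategy(s), "space"))

# memory-1 index for (own, co) moves coded C=0, D=1
m1_index <- function(own, co) 2L * own + co + 1L

# memory-2 index for (own t-2, own t-1, co t-2, co t-1) coded C=0, D=1
m2_index <- function(o2, o1, c2, c1) 8L * o2 + 4L * o1 + 2L * c2 + c1 + 1L

#' Embed a strategy into a larger space
#'
#' The spaces are nested, so every unconditional strategy is also reactive,
#' every reactive strategy is memory-1, and every memory-1 strategy is
#' memory-2. Embedding replicates entries so that the embedded strategy
#' induces identical behaviour against any opponent: payoffs and the
#' invariant distribution of the round-outcome chain are unchanged.
#'
#' @param s A [strategy()] (or bare numeric vector).
#' @param target Target space label or [space_tag()]; must have complexity
#'   rank at least that of `s`'s space.
#' @return A strategy in the target space.
#' @examples
#' embed(strategy(0.3), "M")          # (0.3, 0.3, 0.3, 0.3)
#' embed(strategy(c(1, 0)), "M")      # TFT as memory-1: (1, 0, 1, 0)
#' @export
embed <- function(s, target) {
  s <- as_strategy(s)
  from <- strategy_space(s)
  if (!inherits(target, "memdyn_space")) target <- space_tag(target)
  if (target$complexity_rank < from$complexity_rank) {
    stop("cannot embed a ", from$label, " strategy into the lower-complexity space ",
         target$label, call. = FALSE)
  }
  v <- unclass(s)
  attributes(v) <- NULL
  # U -> R -> M by replication; M -> M2 by ignoring the older round
  if (from$label == "U" && target$complexity_rank >= 2L) v <- rep(v, 2L)
  if (length(v) == 2L && target$complexity_rank >= 3L) {
    # reactive (p, q): condition only on co-player's last move
    v <- c(v[1L], v[2L], v[1L], v[2L])
  }
  if (length(v) == 4L && target$complexity_rank >= 4L) {
    v16 <- numeric(16L)
    for (o2 in 0:1) for (o1 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
      v16[m2_index(o2, o1, c2, c1)] <- v[m1_index(o1, c1)]
    }
    v <- v16
  }
  strategy(v, target$label)
}

#' Apply implementation errors to a strategy
#'
#' With probability `epsilon` an intended action is flipped, so each
#' cooperation probability `x` becomes `(1 - epsilon) * x + epsilon * (1 - x)`.
#' A positive error rate keeps every entry inside `(0, 1)` and thereby makes
#' the round-outcome Markov chain primitive, guaranteeing a unique invariant
#' distribution.
#'
#' @param s A [strategy()].
#' @param epsilon Error probability in `[0, 0.5)`.
#' @return The perturbed strategy, with entries in `[epsilon, 1 - epsilon]`.
#' @examples
#' apply_error(strategy(c(1, 0, 0, 1)), 0.01)
#' @export
apply_error <- function(s, epsilon) {
  s <- as_strategy(s)
  stopifnot(epsilon >= 0, epsilon < 0.5)
  strategy((1 - epsilon) * unclass(s) + epsilon * (1 - unclass(s)),
           attr(s, "space"))
}

#' Number of deterministic memory-n strategies
#'
#' A deterministic memory-`n` strategy assigns C or D to each of the
#' `4^n` possible histories of the last `n` rounds, so there are
#' `2^(4^n)` such strategies: 16 for memory-1, 65536 for memory-2, and
#' about 1.8e19 for memory-3 — which is why a systematic sweep of spaces
#' beyond memory-2 is out of reach.
#'
#' @param memory Memory length `n >= 1`.
#' @return The count as a double (exact up to `memory = 3` within double
#'   precision).
#' @examples
#' n_deterministic_strategies(3)  # 2^64
#' @export
n_deterministic_strategies <- function(memory) {
  stopifnot(memory >= 1)
  2^(4^memory)
}
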