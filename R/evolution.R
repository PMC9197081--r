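#' Supergame payoff matrix between strategy spaces
#'
#' In the long-run dynamics, whole strategy spaces are the evolving traits:
#' the payoff of a player committed to space `i` against one committed to
#' space `j` is the learning-process time average `pair_payoffs[i, j]` of a
#' tournament. `supergame()` extracts that matrix from a tournament result;
#' `supergame_matrix()` wraps an explicitly given matrix (e.g. one printed in
#' a results table).
#'
#' @param tr An `memdyn_tournament`.
#' @param A Square numeric matrix, entry (i, j) the payoff of space i
#'   against space j.
#' @param spaces Character labels of the rows/columns, ordered from most to
#'   least complex where applicable.
#' @return An `memdyn_supergame` object.
#' @examples
#' eq7 <- supergame_matrix(matrix(c(0.154, 0.106, 0.047,
#'                                  0.184, 0.140, 0.099,
#'                                  0.187, 0.121, 0.066),
#'                                3, 3, byrow = TRUE), c("M", "R", "U"))
#' @export
supergame_matrix <- function(A, spaces = rownames(A)) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), all(is.finite(A)))
  if (is.null(spaces)) spaces <- paste0("S", seq_len(nrow(A)))
  dimnames(A) <- list(spaces, spaces)
  structure(list(spaces = spaces, A = A), class = "memdyn_supergame")
}

#' @rdname supergame_matrix
#' @export
supergame <- function(tr) {
  stopifnot(inherits(tr, "memdyn_tournament"))
  supergame_matrix(tr$pair_payoffs, tr$spaces)
}

#' @export
print.memdyn_supergame <- function(x, ...) {
  cat("<supergame matrix>\n")
  print(round(x$A, 3))
  invisible(x)
}

as_supergame <- function(x) {
  if (inherits(x, "memdyn_supergame")) x
  else if (inherits(x, "memdyn_tournament")) supergame(x)
  else supergame_matrix(x)
}

check_simplex <- function(x, k) {
  stopifnot(length(x) == k, all(x >= -1e-12), abs(sum(x) - 1) < 1e-9)
  pmax(x, 0) / sum(pmax(x, 0))
}

#' Fitness of strategy spaces in a mixed population
#'
#' With population frequencies `x` over the spaces, the fitness of space `i`
#' is `f_i = (A x)_i` and the mean fitness is `fbar = x . f`.
#'
#' @param x Frequency vector on the simplex.
#' @param sg Supergame (matrix, tournament or `memdyn_supergame`).
#' @return List with `f` (named fitness vector) and `fbar`.
#' @export
fitness <- function(x, sg) {
  sg <- as_supergame(sg)
  x <- check_simplex(x, nrow(sg$A))
  f <- drop(sg$A %*% x)
  list(f = setNames(f, sg$spaces), fbar = sum(x * f))
}

#' Replicator right-hand side
#'
#' The replicator equation on the simplex: `dx_i/dt = x_i (f_i - fbar)`.
#' Components sum to zero (the simplex is invariant) and every vertex is a
#' rest point.
#'
#' @inheritParams fitness
#' @return Named vector of rates of change.
#' @export
replicator_rhs <- function(x, sg) {
  sg <- as_supergame(sg)
  x <- check_simplex(x, nrow(sg$A))
  ft <- fitness(x, sg)
  setNames(x * (ft$f - ft$fbar), sg$spaces)
}

#' Integrate the replicator dynamics
#'
#' Solves the replicator ODE from `x0` with an adaptive integrator
#' (`deSolve::lsoda`, relative and absolute tolerance `tol`). After
#' integration, tiny negative undershoots near boundary attractors are
#' clipped to zero and each state is renormalized. Faces of the simplex are
#' invariant: spaces starting at frequency zero stay at zero.
#'
#' @param x0 Initial frequencies on the simplex.
#' @param sg Supergame.
#' @param t_end Final time.
#' @param n_steps Number of reported time points.
#' @param tol Integrator tolerance.
#' @return A tibble with a `time` column and one frequency column per space.
#' @examples
#' eq7 <- supergame_matrix(matrix(c(0.154, 0.106, 0.047,
#'                                  0.184, 0.140, 0.099,
#'                                  0.187, 0.121, 0.066),
#'                                3, 3, byrow = TRUE), c("M", "R", "U"))
#' traj <- integrate_replicator(rep(1/3, 3), eq7, t_end = 2000)
#' tail(traj, 1)  # converges to the reactive vertex
#' @export
integrate_replicator <- function(x0, sg, t_end = 1e4, n_steps = 200,
                                 tol = 1e-9) {
  sg <- as_supergame(sg)
  x0 <- check_simplex(x0, nrow(sg$A))
  rhs <- function(t, x, parms) list(x * drop(parms %*% x) - x * sum(x * (parms %*% x)))
  times <- seq(0, t_end, length.out = n_steps + 1)
  sol <- deSolve::lsoda(y = x0, times = times, func = rhs, parms = sg$A,
                        rtol = tol, atol = tol)
  states <- pmax(sol[, -1, drop = FALSE], 0)
  states <- states / rowSums(states)
  # faces are invariant: frequencies starting at zero stay exactly zero
  states[, x0 == 0] <- 0
  states <- states / rowSums(states)
  out <- tibble::as_tibble(as.data.frame(states))
  names(out) <- sg$spaces
  dplyr::bind_cols(tibble::tibble(time = sol[, 1]), out)
}

#' Classify two-space replicator dynamics
#'
#' For two spaces A and B with pairwise averages `a` (A vs A), `b_off`
#' (A vs B), `c_off` (B vs A) and `d` (B vs B), the replicator dynamics on
#' the edge has three generic outcomes: dominance of one space, bistability
#' (both vertices stable, unstable interior threshold), or coexistence
#' (stable interior mixture). Ties are flagged degenerate.
#'
#' @param a,b_off,c_off,d Pairwise average payoffs.
#' @return List with `class` (one of `"A_dominates"`, `"B_dominates"`,
#'   `"bistability"`, `"coexistence"`, `"degenerate"`) and `x_star`, the
#'   interior rest point (frequency of A) where one exists.
#' @examples
#' classify_pairwise(0.154, 0.106, 0.184, 0.140)  # R dominates M
#' @export
classify_pairwise <- function(a, b_off, c_off, d) {
  if (a == c_off || b_off == d) {
    return(list(class = "degenerate", x_star = NA_real_))
  }
  interior <- (d - b_off) / (a - b_off - c_off + d)
  if (a > c_off && b_off > d) list(class = "A_dominates", x_star = NA_real_)
  else if (a < c_off && b_off < d) list(class = "B_dominates", x_star = NA_real_)
  else if (a > c_off && b_off < d) list(class = "bistability", x_star = interior)
  else list(class = "coexistence", x_star = interior)
}

# replicator Jacobian at x, numerically, projected on the simplex tangent space
replicator_stability <- function(x, A) {
  k <- length(x)
  h <- 1e-7
  J <- matrix(0, k, k)
  rhs <- function(y) y * drop(A %*% y) - y * sum(y * (A %*% y))
  for (j in seq_len(k)) {
    e <- rep(0, k); e[j] <- h
    J[, j] <- (rhs(x + e) - rhs(x - e)) / (2 * h)
  }
  # orthonormal basis of the tangent space {sum v = 0}
  B <- qr.Q(qr(cbind(rep(1, k), diag(k))))[, 2:k, drop = FALSE]
  ev <- eigen(t(B) %*% J %*% B, only.values = TRUE)$values
  re <- max(Re(ev))
  if (abs(re) < 1e-7) "degenerate" else if (re < 0) "stable" else "unstable"
}

#' Nash equilibria of a supergame
#'
#' Pure equilibria are found by the best-response condition
#' `A[i, i] >= A[j, i] - tol` for all `j`; mixed equilibria by support
#' enumeration (equal-payoff linear systems per support, feasibility
#' checked). Each equilibrium is labelled stable, unstable or degenerate via
#' the eigenvalues of the replicator Jacobian projected on the simplex
#' tangent space.
#'
#' @param sg Supergame.
#' @param tol Tolerance for the equilibrium inequalities. Use about two
#'   standard errors when the matrix comes from stochastic tournaments.
#' @return A tibble with columns `support`, one frequency column per space,
#'   and `stability`.
#' @export
find_nash <- function(sg, tol = 1e-9) {
  sg <- as_supergame(sg)
  A <- sg$A
  k <- nrow(A)
  res <- list()
  supports <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(k, m, simplify = FALSE)
  }), recursive = FALSE)
  for (sup in supports) {
    m <- length(sup)
    if (m == 1L) {
      i <- sup
      if (all(A[, i] <= A[i, i] + tol)) {
        x <- rep(0, k); x[i] <- 1
        res[[length(res) + 1]] <- list(x = x, support = sup)
      }
      next
    }
    # equal payoffs on the support, frequencies sum to one
    As <- A[sup, sup, drop = FALSE]
    M <- rbind(cbind(As[-1, , drop = FALSE] - matrix(As[1, ], m - 1, m, byrow = TRUE)),
               rep(1, m))
    rhs <- c(rep(0, m - 1), 1)
    xs <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(xs) || any(xs < tol)) next
    x <- rep(0, k); x[sup] <- xs
    pay_sup <- drop(A[sup[1], , drop = FALSE] %*% x)
    pay_all <- drop(A %*% x)
    if (any(pay_all > pay_sup + max(tol, 1e-9))) next
    res[[length(res) + 1]] <- list(x = x, support = sup)
  }
  if (length(res) == 0) {
    out <- tibble::tibble(support = character(0))
    for (s in sg$spaces) out[[s]] <- numeric(0)
    out$stability <- character(0)
    return(out)
  }
  rows <- purrr::map(res, function(r) {
    row <- tibble::tibble(support = paste(sg$spaces[r$support], collapse = "+"))
    for (i in seq_len(k)) row[[sg$spaces[i]]] <- r$x[i]
    row$stability <- replicator_stability(r$x, A)
    row
  })
  dplyr::bind_rows(rows)
}

#' Detect a memory dilemma
#'
#' A memory dilemma arises when the strategy space with the largest self
#' payoff is not a (pure) Nash equilibrium of the supergame, i.e. it can be
#' invaded by a different space. The dilemma is *classic* when that space is
#' the most complex one present, *reverse* when it is a strictly less
#' complex space. The *weak* variants apply when the best-self space is a
#' Nash equilibrium but other stable states coexist (bistability).
#'
#' @param sg Supergame; row/column order must follow the complexity order
#'   given in `complexity`.
#' @param complexity Character vector of the space labels ordered from most
#'   to least complex (default: the supergame's own order, which for
#'   `c("M", "R", "U")` is most complex first).
#' @param tol Tolerance passed to [find_nash()].
#' @return List with `dilemma` (`"none"`, `"classic"`, `"reverse"`,
#'   `"weak_classic"`, `"weak_reverse"` or `"degenerate"`), `best_self`,
#'   `nash` (the [find_nash()] table) and `witness` (the inequality chain
#'   certifying invasion, where applicable).
#' @examples
#' eq7 <- supergame_matrix(matrix(c(0.154, 0.106, 0.047,
#'                                  0.184, 0.140, 0.099,
#'                                  0.187, 0.121, 0.066),
#'                                3, 3, byrow = TRUE), c("M", "R", "U"))
#' detect_dilemma(eq7)$dilemma  # "classic"
#' @export
detect_dilemma <- function(sg, complexity = NULL, tol = 1e-9) {
  sg <- as_supergame(sg)
  A <- sg$A
  spaces <- sg$spaces
  if (is.null(complexity)) complexity <- spaces
  stopifnot(setequal(complexity, spaces))
  self <- diag(A)
  if (any(duplicated(self))) {
    return(list(dilemma = "degenerate", best_self = NA_character_,
                nash = find_nash(sg, tol), witness = NULL))
  }
  best <- spaces[which.max(self)]
  nash <- find_nash(sg, tol)
  pure_nash <- nash$support[!grepl("\\+", nash$support)]
  stable_states <- nash[nash$stability == "stable", , drop = FALSE]
  best_is_nash <- best %in% pure_nash
  most_complex <- complexity[1]
  kind <- if (best == most_complex) "classic" else "reverse"
  witness <- NULL
  if (!best_is_nash) {
    b <- which(spaces == best)
    invader <- which.max(A[, b])
    witness <- sprintf("pi(%s,%s) = %.6g > pi(%s,%s) = %.6g",
                       spaces[invader], best, A[invader, b],
                       best, best, A[b, b])
    dilemma <- kind
  } else if (nrow(stable_states) > 1) {
    dilemma <- paste0("weak_", kind)
  } else {
    dilemma <- "none"
  }
  list(dilemma = dilemma, best_self = best, nash = nash, witness = witness)
}

#' Full dynamics report for a supergame
#'
#' Combines the pairwise edge classifications, the Nash equilibria with
#' stability labels, the set of stable states, and the memory-dilemma
#' classification into one object.
#'
#' @inheritParams detect_dilemma
#' @return An `memdyn_dynamics_report` list with fields `pairwise`,
#'   `nash`, `stable_states`, `dilemma`, `best_self`.
#' @export
dynamics_report <- function(sg, complexity = NULL, tol = 1e-9) {
  sg <- as_supergame(sg)
  spaces <- sg$spaces
  k <- length(spaces)
  pw <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    cl <- classify_pairwise(sg$A[i, i], sg$A[i, j], sg$A[j, i], sg$A[j, j])
    lab <- switch(cl$class,
                  A_dominates = paste0("dominance(", spaces[i], ")"),
                  B_dominates = paste0("dominance(", spaces[j], ")"),
                  bistability = sprintf("bistability(x*=%.3f)", cl$x_star),
                  coexistence = sprintf("coexistence(x*=%.3f)", cl$x_star),
                  "degenerate")
    pw[[paste(spaces[i], spaces[j], sep = "-")]] <- lab
  }
  dd <- detect_dilemma(sg, complexity, tol)
  structure(
    list(pairwise = pw, nash = dd$nash,
         stable_states = dd$nash[dd$nash$stability == "stable", , drop = FALSE],
         dilemma = dd$dilemma, best_self = dd$best_self,
         witness = dd$witness),
    class = "memdyn_dynamics_report")
}

#' @export
print.memdyn_dynamics_report <- function(x, ...) {
  cat("<dynamics report>\n")
  for (nm in names(x$pairwise)) cat(" ", nm, ":", x$pairwise[[nm]], "\n")
  cat("  dilemma:", x$dilemma, "(best self payoff:", x$best_self, ")\n")
  if (!is.null(x$witness)) cat("  witness:", x$witness, "\n")
  print(x$nash)
  invisible(x)
}

#' @rdname integrate_replicator
#' @param object A trajectory tibble from `integrate_replicator()`.
#' @param ... Unused.
#' @export
plot_replicator_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"time", names_to = "space",
                              values_to = "frequency")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$frequency,
                                     colour = .data$space)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
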