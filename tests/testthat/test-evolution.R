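test_that("fitness is the matrix product with the population state", {
  sg <- printed_supergame()
  ft <- fitness(c(1, 0, 0), sg)
  expect_equal(unname(ft$f["M"]), sg$A["M", "M"])
  expect_equal(ft$fbar, sg$A["M", "M"])

  ftc <- fitness(c(0.2, 0.3, 0.5), supergame_matrix(matrix(2, 3, 3)))
  expect_equal(unname(ftc$f), rep(2, 3))
  expect_equal(ftc$fbar, 2)

  # at the barycenter of the printed matrix the reactive space is favoured
  ftb <- fitness(rep(1 / 3, 3), sg)
  expect_gt(ftb$f[["R"]] - ftb$fbar, 0)
})

test_that("replicator rhs is tangent to the simplex and zero at vertices", {
  sg <- printed_supergame()
  for (i in 1:3) {
    x <- rep(0, 3); x[i] <- 1
    expect_equal(unname(replicator_rhs(x, sg)), rep(0, 3))
  }
  set.seed(141)
  for (k in 1:1000) {
    x <- runif(3); x <- x / sum(x)
    A <- matrix(rnorm(9), 3, 3)
    expect_lt(abs(sum(replicator_rhs(x, supergame_matrix(A)))), 1e-12)
  }
  rhs <- replicator_rhs(rep(1 / 3, 3), sg)
  expect_gt(rhs[["R"]], 0)
  expect_lt(rhs[["M"]], 0)
})

test_that("column translations of the payoff matrix leave the dynamics unchanged", {
  set.seed(151)
  A <- matrix(rnorm(9), 3, 3)
  B <- A
  B[, 2] <- B[, 2] + 3.7
  for (k in 1:50) {
    x <- runif(3); x <- x / sum(x)
    expect_equal(unname(replicator_rhs(x, supergame_matrix(A))),
                 unname(replicator_rhs(x, supergame_matrix(B))),
                 tolerance = 1e-9)
  }
})

test_that("replicator trajectories stay on the simplex and keep faces invariant", {
  sg <- printed_supergame()
  traj <- integrate_replicator(rep(1 / 3, 3), sg, t_end = 2000)
  expect_lt(max(abs(rowSums(traj[, -1]) - 1)), 1e-9)
  expect_true(all(traj[, -1] >= 0))
  # the printed matrix drives the population to the reactive vertex
  expect_gt(traj$R[nrow(traj)], 0.999)

  # vertices are rest points
  tv <- integrate_replicator(c(0, 1, 0), sg, t_end = 100)
  expect_equal(unname(as.matrix(tv[nrow(tv), -1])), matrix(c(0, 1, 0), 1))

  # a space absent initially never appears
  tf <- integrate_replicator(c(0.5, 0, 0.5), sg, t_end = 500)
  expect_true(all(tf$R == 0))
})

test_that("two-space coexistence converges to the interior equilibrium", {
  # a < c and b > d: stable mixture at x* = (d - b) / (a - b - c + d)
  a <- 1; b_off <- 2; c_off <- 1.5; d <- 1
  xstar <- (d - b_off) / (a - b_off - c_off + d)
  sg <- supergame_matrix(matrix(c(a, b_off, c_off, d), 2, 2, byrow = TRUE),
                         c("A", "B"))
  traj <- integrate_replicator(c(0.9, 0.1), sg, t_end = 500)
  expect_equal(traj$A[nrow(traj)], xstar, tolerance = 1e-6)
  expect_equal(classify_pairwise(a, b_off, c_off, d),
               list(class = "coexistence", x_star = xstar))
})

test_that("pairwise classification covers all generic cases and ties", {
  cl <- classify_pairwise(0.154, 0.106, 0.184, 0.140)  # printed M-R block
  expect_equal(cl$class, "B_dominates")
  cl <- classify_pairwise(2, 0, 1, 1)
  expect_equal(cl$class, "bistability")
  expect_equal(cl$x_star, 0.5)
  expect_equal(classify_pairwise(1, 1, 1, 1)$class, "degenerate")
  expect_equal(classify_pairwise(2, 2, 1, 1)$class, "A_dominates")
})

test_that("pairwise classes agree with the sign of the edge dynamics", {
  set.seed(161)
  for (k in 1:50) {
    A <- matrix(runif(4), 2, 2)
    cl <- classify_pairwise(A[1, 1], A[1, 2], A[2, 1], A[2, 2])
    if (cl$class == "degenerate") next
    xs <- seq(0.05, 0.95, length.out = 10)
    d1 <- vapply(xs, function(x) {
      replicator_rhs(c(x, 1 - x), supergame_matrix(A))[1]
    }, numeric(1))
    if (cl$class == "A_dominates") expect_true(all(d1 > 0))
    if (cl$class == "B_dominates") expect_true(all(d1 < 0))
    if (cl$class %in% c("bistability", "coexistence") &&
        cl$x_star > min(xs) && cl$x_star < max(xs)) {
      below <- d1[xs < cl$x_star]
      above <- d1[xs > cl$x_star]
      expect_true(sign(below[1]) != sign(above[length(above)]))
    }
  }
})

test_that("Nash equilibria match brute-force best-response checks", {
  sg <- printed_supergame()
  nash <- find_nash(sg)
  expect_equal(nash$support, "R")
  expect_equal(nash$stability, "stable")

  id3 <- supergame_matrix(diag(3), c("a", "b", "c"))
  nash_id <- find_nash(id3)
  pure <- nash_id[!grepl("\\+", nash_id$support), ]
  expect_setequal(pure$support, c("a", "b", "c"))
  expect_true(all(pure$stability == "stable"))

  # a coexistence pair with a dominated third space: one stable mixture on
  # the edge, verified against a grid of invaders
  A <- matrix(c(1, 2, 3,
                1.5, 1, 3,
                0, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nashm <- find_nash(supergame_matrix(A))
  mixed <- nashm[grepl("\\+", nashm$support), ]
  expect_equal(mixed$support, "A+B")
  x <- unlist(mixed[, c("A", "B", "C")])
  payoff_against <- drop(A %*% x)
  grid <- seq(0, 1, by = 0.01)
  # no pure or mixed invader on the grid improves on the equilibrium payoff
  best <- max(payoff_against)
  expect_lte(best, sum(x * payoff_against) + 1e-9)

  # pure-equilibrium set agrees with exhaustive best-response checks
  set.seed(171)
  for (k in 1:20) {
    B <- matrix(runif(9), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
    nb <- find_nash(supergame_matrix(B))
    pure <- setdiff(nb$support[!grepl("\\+", nb$support)], NA)
    expected <- c("a", "b", "c")[vapply(1:3, function(i) {
      all(B[, i] <= B[i, i] + 1e-9)
    }, logical(1))]
    expect_setequal(pure, expected)
  }
})

test_that("memory dilemmas are detected from the supergame structure", {
  sg <- printed_supergame()
  dd <- detect_dilemma(sg)
  expect_equal(dd$dilemma, "classic")
  expect_equal(dd$best_self, "M")
  # the invasion chain behind the dilemma holds with the printed entries
  A <- sg$A
  expect_true(A["R", "M"] > A["M", "M"] && A["M", "M"] > A["R", "R"])
  # the strongest invader of the memory-1 population certifies the dilemma
  expect_match(dd$witness, "0.154")

  # diagonally dominant: best self payoff is the unique Nash, no dilemma
  none <- supergame_matrix(matrix(c(3, 0, 0,
                                    0, 2, 0,
                                    2.9, 1.9, 1), 3, 3, byrow = TRUE),
                           c("M", "R", "U"))
  expect_equal(detect_dilemma(none)$dilemma, "weak_classic")
  none2 <- supergame_matrix(matrix(c(3, 2.5, 2.5,
                                     2.9, 2, 1.9,
                                     2.9, 1.9, 1), 3, 3, byrow = TRUE),
                            c("M", "R", "U"))
  expect_equal(detect_dilemma(none2)$dilemma, "none")

  # reverse dilemma: the simplest space has the best self payoff but the
  # most complex space is the unique Nash equilibrium
  rev_sg <- supergame_matrix(matrix(c(2, 0, 3,
                                      1, 1, 0,
                                      1, 0, 2.5), 3, 3, byrow = TRUE),
                             c("M", "R", "U"))
  expect_equal(detect_dilemma(rev_sg)$dilemma, "reverse")

  # ties in self payoffs are flagged
  tie <- supergame_matrix(diag(c(1, 1, 2)), c("M", "R", "U"))
  expect_equal(detect_dilemma(tie)$dilemma, "degenerate")
})

test_that("dynamics reports assemble the pieces coherently", {
  rep_ <- dynamics_report(printed_supergame())
  expect_equal(rep_$dilemma, "classic")
  expect_equal(rep_$pairwise[["M-R"]], "dominance(R)")
  expect_equal(rep_$pairwise[["M-U"]], "dominance(U)")
  expect_equal(rep_$pairwise[["R-U"]], "dominance(R)")
  expect_equal(rep_$stable_states$support, "R")
})
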