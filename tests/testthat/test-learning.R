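test_that("Fermi acceptance has the closed form and its symmetries", {
  expect_equal(acceptance_probability(0.7, 0.7, 10), 0.5)
  expect_equal(acceptance_probability(1, -1, 0), 0.5)
  expect_equal(acceptance_probability(0.1, 0, 100), 1 / (1 + exp(-10)))
  # rho(delta) + rho(-delta) = 1
  d <- seq(-2, 2, by = 0.25)
  expect_equal(acceptance_probability(d, 0, 5) + acceptance_probability(-d, 0, 5),
               rep(1, length(d)))
  # monotone in delta, overflow-safe at extreme selection
  expect_true(all(diff(acceptance_probability(d, 0, 3)) > 0))
  expect_equal(acceptance_probability(1, 0, 1e6), 1)
  expect_equal(acceptance_probability(-1, 0, 1e6), 0)
  expect_error(acceptance_probability(1, 0, -1))
})

test_that("sampling schemes produce in-space strategies with stated rules", {
  set.seed(91)
  for (scheme in c("uniform", "arcsine")) {
    for (sp in c("U", "R", "M", "M2")) {
      s <- sample_strategy(sp, scheme)
      expect_equal(length(unclass(s)), space_tag(sp)$dimension)
      expect_true(all(unclass(s) >= 0 & unclass(s) <= 1))
    }
  }
  # arcsine is symmetric around 1/2 with higher variance than uniform
  x <- rbeta(1e5, 0.5, 0.5)
  expect_equal(mean(x), 0.5, tolerance = 0.01)
  draws <- replicate(2e4, unclass(sample_strategy("U", "arcsine")))
  expect_equal(mean(draws), 0.5, tolerance = 0.02)
  expect_gt(var(draws), 1 / 12)

  # same-complexity averaging / extreme-biasing on pinned base draws
  local({
    set.seed(1)
    z <- runif(4)  # reference draws
    set.seed(1)
    avg <- sample_strategy("U", "same_complexity_avg")
    expect_equal(unclass(avg), mean(z), ignore_attr = TRUE)
    set.seed(1)
    ext <- sample_strategy("U", "same_complexity_extreme")
    expect_equal(unclass(ext), z[which.max(abs(z - 0.5))], ignore_attr = TRUE)
    set.seed(1)
    r2 <- sample_strategy("R", "same_complexity_avg")
    expect_equal(unclass(r2), c(mean(z[1:2]), mean(z[3:4])), ignore_attr = TRUE)
  })
  expect_error(sample_strategy("M2", "same_complexity_avg"), "U, R and M")
})

test_that("runs are reproducible given a seed and propagate settings", {
  g <- make_donation_game(1, 0.2)
  r1 <- introspection_run(learner_config("M"), learner_config("R"), g,
                          T = 2000, seed = 5)
  r2 <- introspection_run(learner_config("M"), learner_config("R"), g,
                          T = 2000, seed = 5)
  expect_identical(glance(r1), glance(r2))
  expect_identical(unclass(r1$final_1), unclass(r2$final_1))
  r3 <- introspection_run(learner_config("M"), learner_config("R"), g,
                          T = 2000, seed = 6)
  expect_false(identical(r1$avg_payoff_1, r3$avg_payoff_1))
  expect_equal(tidy(r1)$space, c("M", "R"))
})

test_that("neutral selection recovers the uniform-random-pair expectation", {
  # at beta = 0 every candidate is accepted with probability 1/2, so the
  # time average equals the mean payoff of uniformly drawn strategy pairs
  g <- make_donation_game(1, 0.2)
  set.seed(101)
  mc <- replicate(4000, {
    unname(payoffs(random_strategy("M"), random_strategy("U"), g)[1])
  })
  run <- introspection_run(learner_config("M", beta = 0),
                           learner_config("U", beta = 0),
                           g, T = 1e5, seed = 13)
  se <- sd(mc) / sqrt(length(mc))
  # the run average autocorrelates, so allow a generous multiple
  expect_lt(abs(run$avg_payoff_1 - mean(mc)), 30 * se)
})

test_that("effective-strategy inference reduces to the stationary marginals", {
  eng <- engine_config(1e-4)
  # idempotent on in-space strategies
  r <- strategy(c(0.8, 0.2))
  expect_equal(unclass(infer_effective_strategy("R", r, random_strategy("M"), eng)),
               c(0.8, 0.2), tolerance = 1e-9, ignore_attr = TRUE)
  u <- strategy(0.4)
  expect_equal(unclass(infer_effective_strategy("U", u, random_strategy("M"), eng)),
               0.4, tolerance = 1e-9, ignore_attr = TRUE)
  # equal-or-higher-memory observers copy verbatim (embedded)
  expect_equal(unclass(infer_effective_strategy("M", r, u, eng)),
               c(0.8, 0.2, 0.8, 0.2), ignore_attr = TRUE)
  # WSLS against ALLD alternates, so the unconditional reading is ~1/2
  got <- infer_effective_strategy("U", WSLS(), ALLD(), eng)
  v <- invariant_distribution(transition_matrix(apply_error(WSLS(), 1e-4),
                                                apply_error(embed(ALLD(), "M"), 1e-4)))
  expect_equal(unclass(got), unname(v[1] + v[2]), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unclass(got), 0.5, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("cooperation-rate distributions are proper densities", {
  g <- make_donation_game(1, 0.5)
  set.seed(111)
  d0 <- coop_rate_distribution("U", "U", g, beta = 10, t_steps = 0,
                               n_samples = 2e4, bin_width = 0.02)
  expect_equal(sum(d0$density_1) * 0.02, 1, tolerance = 1e-9)
  expect_equal(sum(d0$density_2) * 0.02, 1, tolerance = 1e-9)
  # unconditional sampling at t = 0 is flat
  expect_lt(max(abs(d0$density_1 - 1)), 0.25)
})

test_that("lower-memory spaces start with more extreme cooperation rates", {
  g <- make_donation_game(1, 0.5)
  set.seed(121)
  vars <- vapply(c("U", "R", "M"), function(sp) {
    d <- coop_rate_distribution(sp, sp, g, beta = 10, t_steps = 0,
                                n_samples = 2e4)
    sum(d$density_1 * 0.02 * (d$bin_mid - sum(d$density_1 * 0.02 * d$bin_mid))^2)
  }, numeric(1))
  expect_gt(vars[["U"]], vars[["R"]])
  expect_gt(vars[["R"]], vars[["M"]])
})

test_that("short-run payoff averages stabilize within about ten steps", {
  g <- make_donation_game(1, 0.5)
  avg_at <- function(T, seeds) {
    mean(vapply(seeds, function(s) {
      introspection_run(learner_config("M", beta = 10),
                        learner_config("R", beta = 10), g,
                        T = T, seed = s)$avg_payoff_1
    }, numeric(1)))
  }
  m10 <- avg_at(10, 1:400)
  m100 <- avg_at(100, 1:400)
  expect_lt(abs(m10 - m100), 0.05)
})

test_that("model extensions run and shift results in the documented direction", {
  g <- make_donation_game(1, 0.5)
  # same-complexity averaging removes the lower-memory advantage
  pay <- function(scheme, seeds) {
    out <- vapply(seeds, function(s) {
      r <- introspection_run(learner_config("M", beta = 100, scheme = scheme),
                            learner_config("U", beta = 100, scheme = scheme),
                            g, T = 2e4, seed = s)
      c(r$avg_payoff_1, r$avg_payoff_2)
    }, numeric(2))
    rowMeans(out)
  }
  base <- pay("uniform", 1:6)
  avg <- pay("same_complexity_avg", 1:6)
  expect_gt(avg[1], avg[2])   # memory-1 beats unconditional
  expect_lt(base[1], base[2]) # baseline at c = 0.5 reverses the ranking

  # imitation and active search run and return finite results
  r_im <- introspection_run(learner_config("M", beta = 100, alpha = 0.05),
                            learner_config("U", beta = 100, alpha = 0.05),
                            g, T = 5000, seed = 3)
  expect_true(is.finite(r_im$avg_payoff_1))
  r_as <- introspection_run(learner_config("M", beta = 100, active_search = TRUE,
                                           search_cap = 50),
                            learner_config("U", beta = 100), g,
                            T = 2000, seed = 3)
  expect_true(is.finite(r_as$avg_payoff_1))
  expect_gte(r_as$accept_1, r_im$accept_1 * 0)  # counts are tracked
})

test_that("memory-2 players compete through the 16-state chain", {
  g <- make_donation_game(1, 0.5)
  r <- introspection_run(learner_config("M", beta = 10),
                         learner_config("M2", beta = 10), g,
                         T = 3000, seed = 9)
  expect_true(all(is.finite(c(r$avg_payoff_1, r$avg_payoff_2))))
  expect_equal(attr(r$final_2, "space"), "M2")
})
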