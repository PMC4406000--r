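test_that("payoff arithmetic matches hand-computed cases", {
  cfg2 <- game_config(multiplier = 2)
  expect_equal(round_payoffs(rep(20, 4), cfg2), rep(40, 4))
  expect_equal(round_payoffs(rep(0, 4), cfg2), rep(20, 4))
  cfg16 <- game_config(multiplier = 1.6)
  expect_equal(round_payoffs(c(20, 0, 0, 0), cfg16), c(8, 28, 28, 28))
  expect_error(round_payoffs(c(21, 0, 0, 0), cfg2), class = "twinpgg_error")
  expect_error(round_payoffs(rep(1, 3), cfg2), class = "twinpgg_error")
})

test_that("payoffs conserve total surplus and are dominance-consistent", {
  cfg <- game_config(multiplier = 1.6)
  set.seed(11)
  for (i in 1:50) {
    m <- matrix(runif(40, 0, 20), 10, 4)
    pay <- round_payoffs(m, cfg)
    expect_equal(rowSums(pay),
                 4 * cfg$endowment + (cfg$multiplier - 1) * rowSums(m),
                 tolerance = 1e-12)
  }
  # holding others fixed, payoff strictly decreases in own contribution
  others <- c(5, 10, 15)
  own <- seq(0, 20, by = 5)
  pays <- vapply(own, function(c1) round_payoffs(c(c1, others), cfg)[1], numeric(1))
  expect_true(all(diff(pays) < 0))
})

test_that("conditional responses round half-up and clamp to the schedule domain", {
  ident <- tiny_population(n = 1, sched = 0:20)
  expect_equal(conditional_response(ident, 13.333), 13)
  expect_equal(conditional_response(ident, 13.5), 14)
  expect_equal(conditional_response(ident, 13.5, rounding = "half_even"), 14)
  expect_equal(conditional_response(ident, 12.5, rounding = "half_even"), 12)
  expect_equal(conditional_response(ident, 7), 7)

  s1 <- tiny_population(n = 1, sched = 0:20, dialect = "study1")
  # below the elicited domain: clamps to level 1
  expect_equal(conditional_response(s1, 0.333), 1)
  expect_error(conditional_response(ident, 25), class = "twinpgg_error")
})

test_that("one-shot simulation of identical free riders pays the endowment in both roles", {
  pop <- tiny_population(n = 4, uc = 0, sched = rep(0, 21))
  sim <- simulate_one_shot(pop, n_groups = 200, seed = 5)
  expect_equal(sim$mean_uncond, rep(20, 4))
  expect_equal(sim$mean_cond, rep(20, 4))
  expect_equal(sim$total_payoff, rep(40, 4))
})

test_that("role counts follow the binomial sampling distribution", {
  pop <- make_fixture("cc75_fr25", n = 40)
  n_groups <- 20000
  sim <- simulate_one_shot(pop, n_groups = n_groups, seed = 13)
  N <- nrow(pop)
  exp_c <- n_groups / N
  exp_u <- 3 * n_groups / N
  sd_c <- sqrt(n_groups * (1 / N) * (1 - 1 / N))
  sd_u <- sqrt(n_groups * (3 / N) * (1 - 3 / N))
  expect_true(all(abs(sim$n_cond - exp_c) < 4 * sd_c))
  expect_true(all(abs(sim$n_uncond - exp_u) < 4 * sd_u))
  expect_equal(sum(sim$n_cond), n_groups)
  expect_equal(sum(sim$n_uncond), 3 * n_groups)
})

test_that("simulations are seed-deterministic", {
  pop <- make_fixture("eightperson_oracle")
  a <- simulate_one_shot(pop, n_groups = 3000, seed = 42)
  b <- simulate_one_shot(pop, n_groups = 3000, seed = 42)
  expect_identical(a, b)
  c1 <- simulate_iterated(pop, iterations = 5, n_groups = 2000, seed = 42)
  c2 <- simulate_iterated(pop, iterations = 5, n_groups = 2000, seed = 42)
  expect_identical(c1, c2)
  d <- simulate_one_shot(pop, n_groups = 3000, seed = 43)
  expect_false(identical(a$mean_uncond, d$mean_uncond))

  # a simulation plan carries the same settings
  p <- simulate_one_shot(pop, plan = simulation_plan(3000, 1, seed = 42))
  expect_identical(a, p)
  expect_error(simulate_one_shot(pop, plan = simulation_plan(10, 2, seed = 1)),
               class = "twinpgg_error")
})

test_that("iterated homogeneous populations sit at their fixed points", {
  cc <- make_fixture("homogeneous_cc", n = 8)
  sim <- simulate_iterated(cc, game_config(multiplier = 2), iterations = 6,
                           n_groups = 500, seed = 3)
  expect_equal(sim$mean_payoff_per_round, rep(40, 8))

  fr <- tiny_population(n = 8, uc = 0, sched = rep(0, 21))
  sim0 <- simulate_iterated(fr, game_config(multiplier = 2), iterations = 6,
                            n_groups = 500, seed = 3)
  expect_equal(sim0$mean_payoff_per_round, rep(20, 8))
})

test_that("the 3-cooperators-1-free-rider group follows the hand trace", {
  pop <- make_fixture("fixed_cc3_fr1")
  tr <- play_group(pop, game_config(multiplier = 2), iterations = 2)
  r1 <- tr[tr$round == 1, ]
  expect_equal(r1$contribution, c(20, 20, 20, 0))
  expect_equal(r1$payoff, c(30, 30, 30, 50))
  r2 <- tr[tr$round == 2, ]
  # cooperators respond to (20 + 20 + 0)/3 = 13.33 -> level 13
  expect_equal(r2$contribution, c(13, 13, 13, 0))
  expect_equal(r2$payoff, c(26.5, 26.5, 26.5, 39.5))
  means <- tapply(tr$payoff, tr$individual_id, mean)
  expect_equal(as.numeric(means[r1$individual_id]), c(28.25, 28.25, 28.25, 44.75))
})

test_that("iterated rounds conserve total surplus exactly", {
  pop <- make_fixture("eightperson_oracle")[1:4, ]
  cfg <- game_config(multiplier = 1.6)
  tr <- play_group(pop, cfg, iterations = 10)
  by_round <- split(tr, tr$round)
  for (r in by_round) {
    expect_equal(sum(r$payoff),
                 4 * cfg$endowment + (cfg$multiplier - 1) * sum(r$contribution),
                 tolerance = 1e-9)
  }
})

test_that("exhaustive enumeration is exact for one group and symmetric for clones", {
  pop4 <- make_fixture("fixed_cc3_fr1")
  ex <- exhaustive_one_shot(pop4, game_config(multiplier = 2))
  # single subset; four role assignments. As unconditional member, a
  # cooperator earns its average over the assignments where it plays uc.
  sim <- simulate_one_shot(pop4, game_config(multiplier = 2),
                           n_groups = 40000, seed = 1)
  expect_equal(sim$mean_uncond, ex$mean_uncond, tolerance = 0.05)
  expect_equal(sim$mean_cond, ex$mean_cond, tolerance = 0.05)

  clones <- tiny_population(n = 6, uc = 10, sched = rep(10, 21))
  exc <- exhaustive_one_shot(clones)
  expect_equal(length(unique(round(exc$mean_uncond, 12))), 1)
  expect_equal(length(unique(round(exc$mean_cond, 12))), 1)

  big <- make_fixture("cc75_fr25", n = 16)
  expect_error(exhaustive_one_shot(big), "N <= 12", class = "twinpgg_error")
})

test_that("Monte Carlo one-shot converges to the enumeration oracle", {
  pop <- make_fixture("eightperson_oracle")
  ex <- exhaustive_one_shot(pop)
  sim <- simulate_one_shot(pop, n_groups = 60000, seed = 17)
  expect_true(all(abs(sim$mean_uncond - ex$mean_uncond) < 3 * sim$se_uncond))
  expect_true(all(abs(sim$mean_cond - ex$mean_cond) < 3 * sim$se_cond))
})

test_that("a cooperator/free-rider mixture flips the payoff-cooperativeness correlation", {
  pop <- make_fixture("cc75_fr25", n = 60)
  coop <- rowMeans(as.matrix(pop[paste0("c", 0:20)]))
  one <- simulate_one_shot(pop, game_config(multiplier = 2),
                           n_groups = 20000, seed = 21)
  expect_lt(spearman_rho(coop, one$total_payoff), 0)
  many <- simulate_iterated(pop, game_config(multiplier = 2), iterations = 50,
                            n_groups = 20000, seed = 22)
  expect_gt(spearman_rho(coop, many$mean_payoff_per_round), 0)
})
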