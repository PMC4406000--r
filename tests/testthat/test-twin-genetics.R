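test_that("double-entry ICC matches its closed form and handles edge patterns", {
  # identical co-twins
  same <- tibble::tibble(zygosity = "MZ", x1 = c(1, 4, 2, 8, 5), x2 = c(1, 4, 2, 8, 5))
  icc <- intraclass_correlation(same, ci = "none")
  expect_equal(icc$icc, 1)

  # perfect anticorrelation centred at zero
  anti <- tibble::tibble(zygosity = "MZ", x1 = c(-3, 1, 5, -2), x2 = c(3, -1, -5, 2))
  expect_equal(intraclass_correlation(anti, ci = "none")$icc, -1)

  # 6-pair fixture against the brute-force oracle
  set.seed(3)
  fix <- tibble::tibble(zygosity = "DZ", x1 = rnorm(6, 5, 2), x2 = rnorm(6, 5, 2))
  expect_equal(intraclass_correlation(fix, ci = "none")$icc,
               brute_double_entry(fix$x1, fix$x2))

  expect_error(
    intraclass_correlation(tibble::tibble(zygosity = "MZ", x1 = 1:2, x2 = 2:1)),
    "3 pairs", class = "twinpgg_error"
  )
  flat <- tibble::tibble(zygosity = "MZ", x1 = rep(2, 5), x2 = rep(2, 5))
  expect_error(intraclass_correlation(flat, ci = "none"), "Zero variance",
               class = "twinpgg_error")
})

test_that("bootstrap intervals bracket the estimate and the ANOVA estimator agrees", {
  pairs <- simulate_ace_pairs(80, 0, a2 = 0.5, c2 = 0.1, e2 = 0.4, seed = 4)
  de <- intraclass_correlation(pairs, R = 500, seed = 2)
  expect_true(de$conf.low < de$icc && de$icc < de$conf.high)
  an <- intraclass_correlation(pairs, method = "anova", ci = "none")
  expect_equal(an$icc, de$icc, tolerance = 0.05)
})

test_that("the Gelman-Rubin statistic follows its documented formula", {
  # identical chains: B = 0, statistic sqrt((n-1)/n)
  x <- rnorm(50)
  expect_equal(gelman_rubin(list(x, x)), sqrt(49 / 50))

  # hand-computed fixture: W = 5/3, B = 2, V = 1.75
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(2, 3, 4, 5))),
               sqrt(1.75 / (5 / 3)))

  # iid chains from one distribution converge
  set.seed(6)
  chains <- replicate(3, rnorm(1000), simplify = FALSE)
  expect_lt(gelman_rubin(chains), 1.1)

  expect_error(gelman_rubin(list(rep(1, 5), rep(1, 5))), "Degenerate",
               class = "twinpgg_error")
  expect_error(gelman_rubin(list(1:3)), class = "twinpgg_error")
  expect_error(gelman_rubin(list(1:3, 1:4)), class = "twinpgg_error")
})

test_that("the ACE sampler recovers generating shares and satisfies invariants", {
  pairs <- simulate_ace_pairs(400, 400, a2 = 0.4, c2 = 0.2, e2 = 0.4,
                              mu = 5, total_var = 25, seed = 31)
  fit <- fit_ace(pairs, reduced_ace_spec(), seed = 9)
  est <- setNames(fit$summary$estimate, fit$summary$term)
  # tolerance covers data-level sampling error of the shares at 400 pairs
  # per class (SE ~ 0.09), not just posterior uncertainty
  expect_lt(abs(est["a2"] - 0.4), 0.15)
  expect_lt(abs(est["c2"] - 0.2), 0.15)
  expect_lt(abs(est["e2"] - 0.4), 0.1)
  expect_lt(abs(est["mu"] - 5), 0.5)
  expect_true(all(fit$rhat < 1.1))

  # shares sum to one draw-wise and summaries sit inside their intervals
  expect_equal(fit$draws$a2 + fit$draws$c2 + fit$draws$e2,
               rep(1, nrow(fit$draws)))
  expect_true(all(fit$summary$conf.low <= fit$summary$estimate &
                    fit$summary$estimate <= fit$summary$conf.high))

  # retained draw bookkeeping: chains x (iterations - burnin) / thin
  expect_equal(nrow(fit$draws), 3 * (4000 - 1000) / 5)

  # seed determinism
  fit2 <- fit_ace(pairs, reduced_ace_spec(), seed = 9)
  expect_identical(fit$draws, fit2$draws)

  # broom-style accessors
  expect_named(tidy(fit), c("term", "estimate", "conf.low", "conf.high", "rhat"))
  expect_true(glance(fit)$converged)
})

test_that("independent scores yield a null ACE decomposition", {
  set.seed(12)
  null_pairs <- tibble::tibble(
    zygosity = rep(c("MZ", "DZ"), each = 200),
    x1 = rnorm(400), x2 = rnorm(400)
  )
  fit <- fit_ace(null_pairs, reduced_ace_spec(), seed = 2)
  est <- setNames(fit$summary$estimate, fit$summary$term)
  expect_lt(est["a2"], 0.15)
  expect_lt(est["c2"], 0.15)
  expect_gt(est["e2"], 0.7)
})

test_that("the posterior mean heritability tracks Falconer's approximation", {
  pairs <- simulate_ace_pairs(400, 400, a2 = 0.4, c2 = 0.2, e2 = 0.4,
                              mu = 5, total_var = 25, seed = 31)
  fit <- fit_ace(pairs, reduced_ace_spec(), seed = 9)
  icc <- intraclass_correlation(pairs, ci = "none")
  falconer <- 2 * (icc$icc[icc$zygosity == "MZ"] - icc$icc[icc$zygosity == "DZ"])
  a2 <- fit$summary$estimate[fit$summary$term == "a2"]
  expect_lt(abs(a2 - falconer), 0.1)
})

test_that("single-zygosity data are refused as unidentified", {
  mz_only <- simulate_ace_pairs(50, 0, a2 = 0.4, c2 = 0.2, e2 = 0.4, seed = 1)
  expect_error(fit_ace(mz_only, reduced_ace_spec()), "not separately identified",
               class = "twinpgg_error")
})

test_that("model-implied co-twin covariances hold in generated data", {
  pairs <- simulate_ace_pairs(2000, 2000, a2 = 0.6, c2 = 0.2, e2 = 0.2, seed = 14)
  mz <- pairs[pairs$zygosity == "MZ", ]
  dz <- pairs[pairs$zygosity == "DZ", ]
  expect_equal(cov(mz$x1, mz$x2), 0.8, tolerance = 0.06)
  expect_equal(cov(dz$x1, dz$x2), 0.5, tolerance = 0.06)
  expect_equal(var(c(pairs$x1, pairs$x2)), 1, tolerance = 0.06)
})

test_that("posterior chaining produces truncated-normal priors that still recover", {
  pairs1 <- simulate_ace_pairs(300, 300, a2 = 0.4, c2 = 0.2, e2 = 0.4,
                               mu = 5, total_var = 25, seed = 41)
  fit1 <- fit_ace(pairs1, reduced_ace_spec(), seed = 3)
  chained <- posterior_to_priors(fit1, iterations = 4000, burnin = 1000, thin = 5)
  expect_false(is.null(chained$informative))
  expect_equal(chained$informative$a, c(mean(fit1$draws$sigma2_a),
                                        var(fit1$draws$sigma2_a)))
  expect_equal(chained$informative$mu, c(mean(fit1$draws$mu),
                                         var(fit1$draws$mu)))

  # refit on fresh data from the same truth still recovers the shares
  pairs2 <- simulate_ace_pairs(300, 300, a2 = 0.4, c2 = 0.2, e2 = 0.4,
                               mu = 5, total_var = 25, seed = 42)
  fit2 <- fit_ace(pairs2, chained, seed = 4)
  est <- setNames(fit2$summary$estimate, fit2$summary$term)
  expect_lt(abs(est["a2"] - 0.4), 0.1)
  expect_lt(abs(est["c2"] - 0.2), 0.1)
  expect_lt(abs(est["e2"] - 0.4), 0.1)

  # a degenerate posterior still yields valid (floored) priors
  fake <- fit1
  fake$draws$sigma2_a <- rep(2, nrow(fake$draws))
  spec_fake <- posterior_to_priors(fake)
  expect_equal(spec_fake$informative$a, c(2, 1e-6))
})

test_that("the SD-scale prior interpretation runs and stays proper", {
  pairs <- simulate_ace_pairs(100, 100, a2 = 0.4, c2 = 0.2, e2 = 0.4,
                              mu = 5, total_var = 25, seed = 51)
  spec <- ace_model_spec(iterations = 2000, burnin = 500, thin = 5,
                         prior_scale = "sd")
  fit <- fit_ace(pairs, spec, seed = 5)
  expect_true(all(fit$draws$sigma2_a >= 0 & fit$draws$sigma2_a <= 2 * 50^2))
  expect_equal(fit$draws$a2 + fit$draws$c2 + fit$draws$e2, rep(1, nrow(fit$draws)))
})

test_that("doubling retained draws moves posterior means less than the MC error", {
  pairs <- simulate_ace_pairs(200, 200, a2 = 0.4, c2 = 0.2, e2 = 0.4,
                              mu = 5, total_var = 25, seed = 61)
  short <- fit_ace(pairs, reduced_ace_spec(iterations = 3000), seed = 6)
  long <- fit_ace(pairs, reduced_ace_spec(iterations = 6000), seed = 6)
  for (p in c("a2", "c2", "e2")) {
    mc_se <- sd(short$draws[[p]]) / sqrt(length(unique(short$draws$chain)) * 10)
    d <- abs(mean(short$draws[[p]]) - mean(long$draws[[p]]))
    expect_lt(d, 6 * mc_se)
  }
})
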