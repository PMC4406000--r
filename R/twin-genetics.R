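# Classical twin statistics: within-pair intraclass correlations and the
# Bayesian ACE variance-components model.
#
# Model: the observed score of individual i in family j is
#   Y_ij = mu + A1_j + A2_ij + C_j + E_ij
# where the two half-additive components A1 and A2 have equal variance
# (sigma2_A / 2 each). MZ co-twins share both halves, DZ co-twins share only
# A1, so the additive covariance in MZ pairs is twice that in DZ pairs; C is
# shared within pair and E is individual-specific. Marginally, a pair's
# scores are bivariate normal with common variance
#   v = sigma2_A + sigma2_C + sigma2_E
# and covariance sigma2_A + sigma2_C (MZ) or sigma2_A/2 + sigma2_C (DZ).
# The sampler works on this exact marginal likelihood (the latent effects
# are integrated out analytically): component-wise random-walk Metropolis
# for the three variances with a conjugate Gibbs update for mu.

#' Pair co-twin scores for genetic analysis
#'
#' Joins a per-individual score column into one row per complete twin pair.
#'
#' @param scores A tibble with `individual_id`, `pair_id`, `zygosity`, and
#'   the score column (e.g. output of [compute_scores()] or a simulation
#'   result joined with twin metadata).
#' @param score Name of the score column (string or bare name).
#' @return A tibble: `pair_id`, `zygosity`, `x1`, `x2` (complete pairs only).
#' @export
pair_scores <- function(scores, score) {
  score <- rlang::as_name(rlang::enquo(score))
  assert_data_frame(scores, c("individual_id", "pair_id", "zygosity", score), "scores")
  scores |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(
      zygosity = .data$zygosity[1],
      x1 = .data[[score]][1],
      x2 = .data[[score]][2],
      .groups = "drop"
    )
}

#' Within-pair intraclass correlation
#'
#' Default estimator is the double-entry Pearson correlation: each pair is
#' entered twice in both orders, symmetrising twin order. An ANOVA-based
#' one-way ICC is available as an alternative. Intervals are bootstrap
#' percentile intervals over pairs.
#'
#' @param paired A [pair_scores()] table (`zygosity`, `x1`, `x2`).
#' @param method `"double_entry"` (default) or `"anova"`.
#' @param ci `"bootstrap"` (default) or `"none"`.
#' @param R Bootstrap replicates.
#' @param conf Interval coverage (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return A tibble with one row per zygosity class: `zygosity`, `n_pairs`,
#'   `icc`, `conf.low`, `conf.high`.
#' @export
intraclass_correlation <- function(paired, method = c("double_entry", "anova"),
                                   ci = c("bootstrap", "none"), R = 2000,
                                   conf = 0.95, seed = 1) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  assert_data_frame(paired, c("zygosity", "x1", "x2"), "paired")
  if (!all(is.finite(paired$x1)) || !all(is.finite(paired$x2))) {
    stop_twinpgg("All paired scores must be finite.")
  }
  est_one <- function(x1, x2) {
    if (method == "double_entry") {
      if (var(c(x1, x2)) == 0) stop_twinpgg("Zero variance: ICC undefined.")
      cor(c(x1, x2), c(x2, x1))
    } else {
      # One-way ANOVA ICC(1) with k = 2 members per pair.
      y <- c(x1, x2)
      g <- factor(rep(seq_along(x1), 2))
      if (var(y) == 0) stop_twinpgg("Zero variance: ICC undefined.")
      ms <- anova(lm(y ~ g))[["Mean Sq"]]
      (ms[1] - ms[2]) / (ms[1] + ms[2])
    }
  }
  set.seed(seed)
  dplyr::bind_rows(lapply(split(paired, paired$zygosity), function(d) {
    n <- nrow(d)
    if (n < 3) stop_twinpgg("At least 3 pairs per zygosity class are required.")
    est <- est_one(d$x1, d$x2)
    lo <- hi <- NA_real_
    if (ci == "bootstrap") {
      boot <- vapply(seq_len(R), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        tryCatch(est_one(d$x1[i], d$x2[i]), error = function(e) NA_real_)
      }, numeric(1))
      qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
      lo <- unname(qs[1]); hi <- unname(qs[2])
    }
    tibble::tibble(zygosity = d$zygosity[1], n_pairs = n, icc = est,
                   conf.low = lo, conf.high = hi)
  }))
}

#' ACE model specification: priors and MCMC settings
#'
#' Non-informative default: uniform priors on the variance components --
#' `U(0, a_half_max)` on each half-additive component variance (hence
#' `U(0, 2 * a_half_max)` on the total additive variance), `U(0, c_max)` and
#' `U(0, e_max)` on the shared and non-shared variances -- and a
#' `N(mu_mean, mu_var)` prior on the population mean. Under
#' `prior_scale = "sd"` the same bounds are read as bounds on standard
#' deviations and `mu_var` as a standard deviation.
#'
#' Alternatively, `informative` supplies normal priors per component
#' (truncated at zero for variances), as produced by
#' [posterior_to_priors()] for chained analyses.
#'
#' @param a_half_max,c_max,e_max Uniform prior upper bounds.
#' @param mu_mean,mu_var Normal prior on the population mean.
#' @param informative Optional named list with elements `a`, `c`, `e`, `mu`,
#'   each `c(mean, var)` of a normal prior (variances truncated at 0).
#' @param chains Number of MCMC chains (>= 2, for convergence diagnostics).
#' @param iterations Iterations per chain.
#' @param thin Thinning interval (applied after burn-in removal).
#' @param burnin Burn-in iterations discarded before thinning.
#' @param prior_scale `"variance"` (default) or `"sd"`: the scale on which
#'   the uniform bounds and `mu_var` are interpreted.
#' @return An object of class `ace_spec`.
#' @export
ace_model_spec <- function(a_half_max = 50, c_max = 100, e_max = 100,
                           mu_mean = 0, mu_var = 100, informative = NULL,
                           chains = 3, iterations = 100000, thin = 100,
                           burnin = 10000,
                           prior_scale = c("variance", "sd")) {
  prior_scale <- match.arg(prior_scale)
  if (chains < 2) stop_twinpgg("At least 2 chains are required for Gelman-Rubin diagnostics.")
  if (burnin >= iterations) stop_twinpgg("`burnin` must be smaller than `iterations`.")
  bounds <- c(a_half_max, c_max, e_max, mu_var)
  if (any(!is.finite(bounds)) || any(bounds <= 0)) {
    stop_twinpgg("Prior bounds and `mu_var` must be positive and finite.")
  }
  if (!is.null(informative)) {
    need <- c("a", "c", "e", "mu")
    if (!all(need %in% names(informative))) {
      stop_twinpgg("`informative` must name components a, c, e, mu.")
    }
    ok <- vapply(informative[need], function(p) {
      length(p) == 2 && all(is.finite(p)) && p[2] > 0
    }, logical(1))
    if (!all(ok)) stop_twinpgg("Each informative prior must be c(mean, var) with var > 0.")
  }
  structure(
    list(a_half_max = a_half_max, c_max = c_max, e_max = e_max,
         mu_mean = mu_mean, mu_var = mu_var, informative = informative,
         chains = as.integer(chains), iterations = as.integer(iterations),
         thin = as.integer(thin), burnin = as.integer(burnin),
         prior_scale = prior_scale),
    class = "ace_spec"
  )
}

#' @export
print.ace_spec <- function(x, ...) {
  kind <- if (is.null(x$informative)) "non-informative (uniform variances)" else "informative (normal)"
  cat(sprintf("<ace_spec> %s priors, %d chains x %d iterations (burn-in %d, thin %d)\n",
              kind, x$chains, x$iterations, x$burnin, x$thin))
  invisible(x)
}

# Effective support / prior evaluation on the variance scale.
.ace_bounds <- function(spec) {
  if (spec$prior_scale == "variance") {
    list(s2a_max = 2 * spec$a_half_max, s2c_max = spec$c_max,
         s2e_max = spec$e_max, mu_var = spec$mu_var)
  } else {
    # Bounds on SDs: half-component sd < a_half_max means
    # sigma2_A = 2 * sd^2 < 2 * a_half_max^2; mu_var given as an SD.
    list(s2a_max = 2 * spec$a_half_max^2, s2c_max = spec$c_max^2,
         s2e_max = spec$e_max^2, mu_var = spec$mu_var^2)
  }
}

# Log prior for one variance component on the variance scale.
.lp_var <- function(x, upper, inf_prior) {
  if (x < 0) return(-Inf)
  if (is.null(inf_prior)) {
    if (x > upper) -Inf else 0
  } else {
    stats::dnorm(x, inf_prior[1], sqrt(inf_prior[2]), log = TRUE)
  }
}

# Marginal bivariate-normal log likelihood over both zygosity classes,
# written with sufficient statistics so each evaluation is O(1):
# for a class with n pairs, S11 = sum(d1^2 + d2^2) and S12 = sum(d1 d2)
# with d = y - mu expand in mu via the precomputed sums below.
.ace_loglik <- function(s2a, s2c, s2e, mu, st) {
  v <- s2a + s2c + s2e
  ll <- 0
  for (cl in c("mz", "dz")) {
    s <- st[[cl]]
    cc <- if (cl == "mz") s2a + s2c else s2a / 2 + s2c
    det <- v * v - cc * cc
    if (det <= 0 || v <= 0) return(-Inf)
    S11 <- s$sYY - 2 * mu * s$sY + 2 * s$n * mu^2
    S12 <- s$sP - mu * s$sY + s$n * mu^2
    ll <- ll - s$n * log(det) / 2 - (v * S11 - 2 * cc * S12) / (2 * det)
  }
  ll
}

.ace_suffstats <- function(y) {
  list(n = nrow(y), sY = sum(y), sYY = sum(y^2), sP = sum(y[, 1] * y[, 2]))
}

.run_ace_chain <- function(st, b, spec, chain_seed) {
  set.seed(chain_seed)
  inf <- spec$informative
  n_tot <- 2 * (st$mz$n + st$dz$n)
  y_mean <- st$mz$sY + st$dz$sY
  y_mean <- y_mean / n_tot
  y_var <- (st$mz$sYY + st$dz$sYY) / n_tot - y_mean^2

  # Overdispersed initial values inside the support.
  init_var <- function(upper, p) min(y_var * p, 0.9 * upper)
  u <- runif(3, 0.15, 0.6)
  s2a <- init_var(b$s2a_max, u[1])
  s2c <- init_var(b$s2c_max, u[2])
  s2e <- max(init_var(b$s2e_max, u[3]), 1e-6)
  mu <- y_mean + rnorm(1, 0, sqrt(y_var / n_tot) * 3)

  scales <- rep(max(y_var, 1e-3) * 0.2, 3)
  acc <- integer(3)
  n_keep <- (spec$iterations - spec$burnin) %/% spec$thin
  draws <- matrix(NA_real_, n_keep, 4,
                  dimnames = list(NULL, c("sigma2_a", "sigma2_c", "sigma2_e", "mu")))
  kept <- 0L
  ll <- .ace_loglik(s2a, s2c, s2e, mu, st)
  lp <- .lp_var(s2a, b$s2a_max, inf$a) + .lp_var(s2c, b$s2c_max, inf$c) +
    .lp_var(s2e, b$s2e_max, inf$e)

  for (it in seq_len(spec$iterations)) {
    cur <- c(s2a, s2c, s2e)
    for (k in 1:3) {
      prop <- cur
      prop[k] <- cur[k] + rnorm(1, 0, scales[k])
      lp_prop <- .lp_var(prop[1], b$s2a_max, inf$a) +
        .lp_var(prop[2], b$s2c_max, inf$c) +
        .lp_var(prop[3], b$s2e_max, inf$e)
      if (is.finite(lp_prop)) {
        ll_prop <- .ace_loglik(prop[1], prop[2], prop[3], mu, st)
        if (is.finite(ll_prop) &&
            log(runif(1)) < (ll_prop + lp_prop) - (ll + lp)) {
          cur <- prop; ll <- ll_prop; lp <- lp_prop
          acc[k] <- acc[k] + 1L
        }
      }
    }
    s2a <- cur[1]; s2c <- cur[2]; s2e <- cur[3]

    # Conjugate Gibbs update for mu given the variance components.
    v <- s2a + s2c + s2e
    cmz <- s2a + s2c
    cdz <- s2a / 2 + s2c
    mu_prior <- if (is.null(inf)) c(spec$mu_mean, b$mu_var) else inf$mu
    prec <- 1 / mu_prior[2] + 2 * st$mz$n / (v + cmz) + 2 * st$dz$n / (v + cdz)
    mean_post <- (mu_prior[1] / mu_prior[2] +
                    st$mz$sY / (v + cmz) + st$dz$sY / (v + cdz)) / prec
    mu <- rnorm(1, mean_post, sqrt(1 / prec))
    ll <- .ace_loglik(s2a, s2c, s2e, mu, st)

    # Adapt proposal scales during burn-in only (target ~ 35% acceptance).
    if (it <= spec$burnin && it %% 100L == 0L) {
      rate <- acc / 100
      scales <- scales * exp(rate - 0.35)
      scales <- pmax(scales, 1e-8)
      acc[] <- 0L
    }
    if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- c(s2a, s2c, s2e, mu)
    }
  }
  draws
}

#' Fit the Bayesian ACE model by MCMC
#'
#' Decomposes the variance of a paired twin score into additive-genetic (A),
#' shared-environment (C), and non-shared-environment (E) components using
#' the MZ/DZ covariance structure (see the model description in
#' the package vignette). Returns posterior draws of the raw variances, the
#' per-draw standardized shares \eqn{a^2, c^2, e^2} (which sum to 1),
#' posterior means with 95\% central credible intervals, and the
#' Gelman-Rubin statistic per parameter. Non-convergence (any G-R >= 1.1)
#' is reported as a flagged result via a warning, never silently.
#'
#' @param paired A [pair_scores()] table containing both MZ and DZ pairs.
#' @param spec An [ace_model_spec()].
#' @param seed Integer seed; chain seeds are derived deterministically.
#' @return An object of class `ace_fit` with elements `draws` (tibble:
#'   `chain`, `draw`, `sigma2_a`, `sigma2_c`, `sigma2_e`, `mu`, `a2`, `c2`,
#'   `e2`), `summary`, `rhat`, `converged`, `n_mz`, `n_dz`, `spec`.
#' @examples
#' pairs <- simulate_ace_pairs(60, 60, a2 = 0.4, c2 = 0.2, e2 = 0.4, seed = 2)
#' spec <- ace_model_spec(iterations = 2000, burnin = 500, thin = 5)
#' fit <- fit_ace(pairs, spec, seed = 1)
#' tidy(fit)
#' @export
fit_ace <- function(paired, spec = ace_model_spec(), seed = 1) {
  assert_data_frame(paired, c("zygosity", "x1", "x2"), "paired")
  if (!inherits(spec, "ace_spec")) stop_twinpgg("`spec` must be an ace_model_spec().")
  y <- as.matrix(paired[, c("x1", "x2")])
  storage.mode(y) <- "double"
  if (any(!is.finite(y))) stop_twinpgg("All paired scores must be finite.")
  mz <- y[paired$zygosity == "MZ", , drop = FALSE]
  dz <- y[paired$zygosity == "DZ", , drop = FALSE]
  if (nrow(mz) == 0 || nrow(dz) == 0) {
    stop_twinpgg(paste(
      "Both MZ and DZ pairs are required: with a single zygosity class the",
      "additive and shared components are not separately identified."
    ))
  }
  st <- list(mz = .ace_suffstats(mz), dz = .ace_suffstats(dz))
  b <- .ace_bounds(spec)

  chains <- lapply(seq_len(spec$chains), function(ch) {
    .run_ace_chain(st, b, spec, derive_seed(seed, ch))
  })

  rhat <- vapply(colnames(chains[[1]]), function(p) {
    gelman_rubin(lapply(chains, function(m) m[, p]))
  }, numeric(1))

  draws <- purrr::map_dfr(seq_along(chains), function(ch) {
    m <- tibble::as_tibble(chains[[ch]])
    tot <- m$sigma2_a + m$sigma2_c + m$sigma2_e
    dplyr::mutate(m,
      chain = ch, draw = dplyr::row_number(), .before = 1
    ) |>
      dplyr::mutate(a2 = .data$sigma2_a / tot, c2 = .data$sigma2_c / tot,
                    e2 = .data$sigma2_e / tot)
  })

  terms <- c("a2", "c2", "e2", "sigma2_a", "sigma2_c", "sigma2_e", "mu")
  summary <- purrr::map_dfr(terms, function(p) {
    x <- draws[[p]]
    tibble::tibble(
      term = p, estimate = mean(x),
      conf.low = unname(quantile(x, 0.025)),
      conf.high = unname(quantile(x, 0.975)),
      rhat = if (p %in% names(rhat)) unname(rhat[p]) else NA_real_
    )
  })

  converged <- all(rhat < 1.1)
  if (!converged) {
    warn(sprintf(
      "ACE fit flagged: Gelman-Rubin >= 1.1 for %s.",
      paste(names(rhat)[rhat >= 1.1], collapse = ", ")
    ), class = "twinpgg_nonconvergence")
  }
  structure(
    list(draws = draws, summary = summary, rhat = rhat, converged = converged,
         n_mz = nrow(mz), n_dz = nrow(dz), spec = spec, seed = seed),
    class = "ace_fit"
  )
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf(
    "<ace_fit> %d MZ + %d DZ pairs, %d retained draws (%d chains)%s\n",
    x$n_mz, x$n_dz, nrow(x$draws), x$spec$chains,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  sh <- x$summary[x$summary$term %in% c("a2", "c2", "e2"), ]
  for (i in seq_len(nrow(sh))) {
    cat(sprintf("  %s = %.3f [%.3f, %.3f]\n", sh$term[i], sh$estimate[i],
                sh$conf.low[i], sh$conf.high[i]))
  }
  cat(sprintf("  max Gelman-Rubin: %.4f\n", max(x$rhat)))
  invisible(x)
}

#' @rdname fit_ace
#' @param x,object An `ace_fit`.
#' @param ... Unused.
#' @export
tidy.ace_fit <- function(x, ...) x$summary

#' @rdname fit_ace
#' @export
glance.ace_fit <- function(x, ...) {
  tibble::tibble(
    n_mz = x$n_mz, n_dz = x$n_dz, n_draws = nrow(x$draws),
    chains = x$spec$chains, max_rhat = max(x$rhat), converged = x$converged
  )
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For m chains of length n with within-chain variance mean W and
#' between-chain variance B = n * var(chain means), the pooled variance
#' estimate is V = (n-1)/n * W + B/n and the statistic is sqrt(V / W).
#' Values near 1 indicate convergence; identical chains give
#' sqrt((n-1)/n) < 1.
#'
#' @param chains A list of >= 2 equal-length numeric vectors, or a matrix
#'   with one chain per column.
#' @return The potential scale reduction factor (a single number).
#' @examples
#' gelman_rubin(list(c(1, 2, 3, 4), c(2, 3, 4, 5)))
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2) {
    stop_twinpgg("At least 2 chains are required.")
  }
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 2) {
    stop_twinpgg("Chains must have equal length >= 2.")
  }
  W <- mean(vapply(chains, var, numeric(1)))
  if (W == 0) stop_twinpgg("Degenerate chains: zero within-chain variance.")
  B <- n * var(vapply(chains, mean, numeric(1)))
  V <- (n - 1) / n * W + B / n
  sqrt(V / W)
}

#' Turn an ACE posterior into informative priors
#'
#' Builds an informative [ace_model_spec()] whose normal priors are centred
#' at the posterior means of the variance components (and population mean)
#' with the corresponding posterior variances, truncated at zero for the
#' variance components. Used to chain an analysis of one sample into the
#' next.
#'
#' @param fit An `ace_fit`.
#' @param var_floor Minimum prior variance (guards degenerate posteriors).
#' @param ... MCMC settings forwarded to [ace_model_spec()] (`chains`,
#'   `iterations`, `thin`, `burnin`).
#' @return An informative `ace_spec`.
#' @export
posterior_to_priors <- function(fit, var_floor = 1e-6, ...) {
  if (!inherits(fit, "ace_fit")) stop_twinpgg("`fit` must be an ace_fit.")
  d <- fit$draws
  mkp <- function(x) c(mean(x), max(var(x), var_floor))
  ace_model_spec(
    informative = list(
      a = mkp(d$sigma2_a), c = mkp(d$sigma2_c),
      e = mkp(d$sigma2_e), mu = mkp(d$mu)
    ),
    ...
  )
}

#' Simulate paired twin scores from the ACE model
#'
#' Generates continuous co-twin scores with the exact covariance structure
#' the ACE model assumes: MZ co-twin correlation `a2 + c2`, DZ co-twin
#' correlation `a2/2 + c2` (the additive component is split into two
#' equal-variance halves, of which DZ pairs share one).
#'
#' @param n_mz,n_dz Numbers of MZ and DZ pairs.
#' @param a2,c2,e2 Standardized variance shares (must sum to 1).
#' @param mu Population mean.
#' @param total_var Total phenotypic variance.
#' @param seed Integer RNG seed.
#' @return A [pair_scores()]-shaped tibble.
#' @export
simulate_ace_pairs <- function(n_mz, n_dz, a2, c2, e2, mu = 0, total_var = 1,
                               seed = 1) {
  if (abs(a2 + c2 + e2 - 1) > 1e-8 || any(c(a2, c2, e2) < 0)) {
    stop_twinpgg("Shares a2, c2, e2 must be nonnegative and sum to 1.")
  }
  set.seed(seed)
  gen <- function(n, zyg) {
    if (n == 0) return(NULL)
    sa <- sqrt(a2 * total_var / 2)
    a1 <- rnorm(n, 0, sa)                      # shared by both zygosities
    a2_shared <- rnorm(n, 0, sa)               # shared half 2 (MZ only)
    cc <- rnorm(n, 0, sqrt(c2 * total_var))
    mk <- function(member) {
      a2_i <- if (zyg == "MZ") a2_shared else rnorm(n, 0, sa)
      mu + a1 + a2_i + cc + rnorm(n, 0, sqrt(e2 * total_var))
    }
    tibble::tibble(
      pair_id = sprintf("%s%05d", tolower(zyg), seq_len(n)),
      zygosity = zyg, x1 = mk(1), x2 = mk(2)
    )
  }
  dplyr::bind_rows(gen(n_mz, "MZ"), gen(n_dz, "DZ"))
}
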