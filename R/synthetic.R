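# Synthetic twin populations with known latent ACE structure mapped onto
# strategy-method schedules, so that every downstream stage (scores, ICC,
# ACE fits, simulations) can be validated against ground truth.
#
# Three jointly independent latent traits, each with its own ACE share
# triple, drive an individual's strategy:
#   * baseline  - contribution level at others'-average 0 (points scale),
#   * slope     - graded conditionality deviation (standard-normal scale),
#   * liability - standard-normal strategy-type liability with two
#                 thresholds: individuals above qnorm(1 - fr_prevalence)
#                 register an all-zero schedule and uc = 0 (strict free
#                 riders); individuals below qnorm(cc_prevalence) are
#                 near-perfect conditional cooperators (slope centred on 1
#                 point per level); the rest are weakly conditional
#                 intermediates.
# Strategy-method samples show exactly this discrete mixture: roughly a
# quarter strict free riders, over forty percent conditional cooperators
# who track others' average nearly one-for-one, and a remainder of flat or
# weakly conditional responders. Non-free-riders register
# c_k = clip(round(baseline + slope_i * k + noise)) and uc analogously at a
# fixed reference level (the contribution they expect from others).
# Clipping to [0, endowment] and integer rounding happen after noise
# addition; the resulting attenuation of twin correlations is accepted.

#' Configuration for the synthetic twin-population generator
#'
#' Defaults emulate the marginal structure observed in web-based
#' strategy-method experiments: about a quarter of participants strict free
#' riders, over forty percent near-perfect conditional cooperators, a
#' remainder of weakly conditional responders; per-level mean contributions
#' rising roughly linearly from ~1 to ~10 points over levels 0-20, and
#' per-level SDs rising with the level (driven by the strategy-type mixture
#' plus slope heterogeneity).
#'
#' @param n_mz,n_dz Complete pair counts per zygosity.
#' @param shares Named list of `c(a2, c2, e2)` triples (each summing to 1)
#'   for `baseline`, `slope`, `liability`.
#' @param baseline_mean,baseline_sd Baseline contribution (points at
#'   others'-average 0) of the intermediate type, as a linear map of the
#'   latent baseline trait.
#' @param cc_baseline_mean,cc_baseline_sd Baseline contribution of the
#'   conditional-cooperator type (near zero: matchers contribute what
#'   others contribute).
#' @param slope_mean,slope_sd Conditionality slope (points per level) of the
#'   intermediate type, as a linear map of the latent slope trait.
#' @param cc_slope_mean,cc_slope_sd Conditionality slope of the
#'   conditional-cooperator type (centred on matching, 1 point per level).
#' @param fr_prevalence Target strict free-rider prevalence in `[0, 1]`.
#' @param cc_prevalence Target conditional-cooperator prevalence;
#'   `fr_prevalence + cc_prevalence` must not exceed 1.
#' @param noise_sd SD of per-decision registration noise (points).
#' @param endowment Endowment (schedule values clipped to `[0, endowment]`).
#' @param dialect Schedule dialect of the emitted table.
#' @param uc_reference_level Others'-average level at which the unconditional
#'   decision is generated (default 10, the mid-scale expectation).
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mz = 500, n_dz = 500,
                             shares = list(
                               baseline = c(0.20, 0.10, 0.70),
                               slope = c(0.25, 0.10, 0.65),
                               liability = c(0.20, 0.10, 0.70)
                             ),
                             baseline_mean = 3, baseline_sd = 2.5,
                             cc_baseline_mean = 0, cc_baseline_sd = 0.5,
                             slope_mean = 0.25, slope_sd = 0.2,
                             cc_slope_mean = 1, cc_slope_sd = 0.1,
                             fr_prevalence = 0.248, cc_prevalence = 0.436,
                             noise_sd = 2, endowment = 20,
                             dialect = c("study2", "study1"),
                             uc_reference_level = 10, seed = 1) {
  dialect <- match.arg(dialect)
  need <- c("baseline", "slope", "liability")
  if (!all(need %in% names(shares))) {
    stop_twinpgg("`shares` must name baseline, slope, liability.")
  }
  for (nm in need) {
    s <- shares[[nm]]
    if (length(s) != 3 || any(s < 0) || abs(sum(s) - 1) > 1e-8) {
      stop_twinpgg(sprintf(
        "`shares$%s` must be a nonnegative triple (a2, c2, e2) summing to 1.", nm
      ))
    }
  }
  if (fr_prevalence < 0 || fr_prevalence > 1) {
    stop_twinpgg("`fr_prevalence` must lie in [0, 1].")
  }
  if (cc_prevalence < 0 || fr_prevalence + cc_prevalence > 1) {
    stop_twinpgg("`cc_prevalence` must be >= 0 with fr_prevalence + cc_prevalence <= 1.")
  }
  structure(
    list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz), shares = shares,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         cc_baseline_mean = cc_baseline_mean, cc_baseline_sd = cc_baseline_sd,
         slope_mean = slope_mean, slope_sd = slope_sd,
         cc_slope_mean = cc_slope_mean, cc_slope_sd = cc_slope_sd,
         fr_prevalence = fr_prevalence, cc_prevalence = cc_prevalence,
         noise_sd = noise_sd, endowment = endowment, dialect = dialect,
         uc_reference_level = uc_reference_level, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Standard-normal latent values for n_mz + n_dz pairs with the exact
# half-additive-component construction the ACE model assumes: MZ co-twins
# share both halves, DZ co-twins share one.
.latent_trait <- function(n_mz, n_dz, a2, c2, e2) {
  gen <- function(n, mz) {
    sa <- sqrt(a2 / 2)
    a1 <- rnorm(n, 0, sa)
    a2h <- rnorm(n, 0, sa)
    cc <- rnorm(n, 0, sqrt(c2))
    one <- function() {
      a2_i <- if (mz) a2h else rnorm(n, 0, sa)
      a1 + a2_i + cc + rnorm(n, 0, sqrt(e2))
    }
    cbind(one(), one())
  }
  rbind(gen(n_mz, TRUE), gen(n_dz, FALSE))
}

#' Generate a synthetic twin population of strategy profiles
#'
#' By construction, each latent trait's co-twin correlation is `a2 + c2` in
#' MZ pairs and `a2/2 + c2` in DZ pairs. The liability trait assigns the
#' discrete strategy types: free riders (above the upper threshold)
#' register all-zero schedules; conditional cooperators (below the lower
#' threshold) track others' average with a slope centred on 1;
#' intermediates respond weakly. Non-free-riders map baseline + slope
#' linearly onto the schedule with per-decision noise, rounded to integers
#' and clipped to the endowment.
#'
#' @param config A [synthetic_config()].
#' @return A list with `profiles` (validated population tibble) and `truth`
#'   (tibble of per-individual latent trait values `z_baseline`, `z_slope`,
#'   `liability` on the standard-normal scale, the mapped `baseline` and
#'   `slope`, `strategy_type`, `free_rider`) plus the generating `config`.
#' @examples
#' pop <- generate_twin_population(synthetic_config(n_mz = 50, n_dz = 50))
#' summarize_population(pop$profiles)
#' @export
generate_twin_population <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    stop_twinpgg("`config` must be a synthetic_config().")
  }
  set.seed(config$seed)
  n_pairs <- config$n_mz + config$n_dz
  n <- 2L * n_pairs
  sh <- config$shares
  z_base <- .latent_trait(config$n_mz, config$n_dz,
                          sh$baseline[1], sh$baseline[2], sh$baseline[3])
  z_slope <- .latent_trait(config$n_mz, config$n_dz,
                           sh$slope[1], sh$slope[2], sh$slope[3])
  z_liab <- .latent_trait(config$n_mz, config$n_dz,
                          sh$liability[1], sh$liability[2], sh$liability[3])

  liability <- as.vector(z_liab)
  fr <- liability > qnorm(1 - config$fr_prevalence)
  cc <- liability < qnorm(config$cc_prevalence)
  # One latent baseline trait and one latent conditionality trait, each
  # mapped linearly within strategy type: conditional cooperators vary
  # tightly around pure matching (baseline 0, slope 1), intermediates
  # around a flat-ish weakly conditional profile.
  baseline <- ifelse(cc,
                     config$cc_baseline_mean + config$cc_baseline_sd * as.vector(z_base),
                     config$baseline_mean + config$baseline_sd * as.vector(z_base))
  slope <- ifelse(cc,
                  config$cc_slope_mean + config$cc_slope_sd * as.vector(z_slope),
                  config$slope_mean + config$slope_sd * as.vector(z_slope))

  pair_id <- sprintf("pair%05d", rep(seq_len(n_pairs), 2))
  zyg <- rep(rep(c("MZ", "DZ"), c(config$n_mz, config$n_dz)), 2)
  member <- rep(1:2, each = n_pairs)
  individual_id <- sprintf("%s_%d", pair_id, member)

  lv <- schedule_levels(config$dialect)
  E <- config$endowment
  clipint <- function(x) pmin(pmax(floor(x + 0.5), 0), E)
  sched <- matrix(0L, n, 21)
  for (k in lv) {
    sched[, k + 1L] <- clipint(baseline + slope * k + rnorm(n, 0, config$noise_sd))
  }
  uc <- clipint(baseline + slope * config$uc_reference_level +
                  rnorm(n, 0, config$noise_sd))
  sched[fr, ] <- 0L
  uc[fr] <- 0L

  profiles <- tibble::tibble(
    individual_id = individual_id, pair_id = pair_id, zygosity = zyg,
    uc = as.integer(uc)
  )
  for (k in 0:20) {
    profiles[[paste0("c", k)]] <- if (k %in% lv) as.integer(sched[, k + 1L]) else NA_integer_
  }
  profiles <- validate_population(profiles, endowment = E, dialect = config$dialect)

  truth <- tibble::tibble(
    individual_id = individual_id, pair_id = pair_id, zygosity = zyg,
    z_baseline = as.vector(z_base), z_slope = as.vector(z_slope),
    liability = liability,
    baseline = baseline, slope = slope,
    strategy_type = ifelse(fr, "free_rider",
                           ifelse(cc, "conditional_cooperator", "intermediate")),
    free_rider = fr
  )
  list(profiles = profiles, truth = truth, config = config)
}

#' Small deterministic fixture populations
#'
#' Named, seed-free populations used throughout the test suites:
#' \describe{
#'   \item{`"homogeneous_cc"`}{`n` identical perfect conditional cooperators
#'     (`uc = 20`, `c_k = k`).}
#'   \item{`"eightperson_oracle"`}{Eight fixed mixed profiles (free riders,
#'     perfect and imperfect conditional cooperators, a flat contributor,
#'     an anti-conditional profile), small enough for
#'     [exhaustive_one_shot()].}
#'   \item{`"cc75_fr25"`}{`n` profiles, 75\% near-perfect conditional
#'     cooperators with deterministic variation in `uc` and schedule offset,
#'     25\% strict free riders.}
#'   \item{`"fixed_cc3_fr1"`}{Three perfect conditional cooperators plus one
#'     free rider (the hand-traceable iterated fixture).}
#' }
#'
#' @param name Fixture name.
#' @param n Population size where applicable.
#' @return A validated population tibble (Study-2 dialect).
#' @export
make_fixture <- function(name = c("homogeneous_cc", "eightperson_oracle",
                                  "cc75_fr25", "fixed_cc3_fr1"),
                         n = NULL) {
  name <- match.arg(name)
  mk <- function(uc, sched_rows) {
    n_i <- length(uc)
    prof <- tibble::tibble(
      individual_id = sprintf("%s_%03d", name, seq_len(n_i)),
      pair_id = sprintf("%s_p%03d", name, ceiling(seq_len(n_i) / 2)),
      zygosity = rep("MZ", n_i),
      uc = as.integer(uc)
    )
    for (k in 0:20) prof[[paste0("c", k)]] <- as.integer(sched_rows[, k + 1L])
    validate_population(prof)
  }
  lv <- 0:20
  perfect_cc <- lv
  free_rider <- rep(0L, 21)
  switch(name,
    homogeneous_cc = {
      n <- n %||% 8
      mk(rep(20L, n), matrix(perfect_cc, n, 21, byrow = TRUE))
    },
    eightperson_oracle = {
      rows <- rbind(
        free_rider,                      # strict free rider
        free_rider,                      # strict free rider
        perfect_cc,                      # perfect conditional cooperator
        perfect_cc,                      # perfect conditional cooperator
        rep(10L, 21),                    # flat mid contributor
        pmin(lv, 20 - lv) * 2L,          # hump-shaped responder
        floor(lv / 2),                   # half-slope cooperator
        20L - lv                         # anti-conditional profile
      )
      mk(c(0L, 0L, 20L, 17L, 10L, 8L, 5L, 15L), rows)
    },
    cc75_fr25 = {
      n <- n %||% 400
      n_cc <- round(0.75 * n)
      uc <- integer(n)
      rows <- matrix(0L, n, 21)
      for (i in seq_len(n_cc)) {
        offset <- (i %% 3) - 1          # -1, 0, 1 cycling
        rows[i, ] <- pmin(pmax(lv + offset, 0), 20)
        uc[i] <- 14 + (i %% 7)
      }
      mk(uc, rows)
    },
    fixed_cc3_fr1 = {
      mk(c(20L, 20L, 20L, 0L),
         rbind(perfect_cc, perfect_cc, perfect_cc, free_rider))
    }
  )
}
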