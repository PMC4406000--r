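# Public goods game payoff arithmetic, conditional-response lookup, and
# Monte Carlo simulation of one-shot and iterated four-player games over
# groups sampled from a strategy population, plus an exhaustive-enumeration
# oracle for small populations.

#' Per-round public goods payoffs
#'
#' For contributions \eqn{c_1,\dots,c_n} the payoff of member \eqn{i} is
#' \deqn{E - c_i + m \sum_j c_j / n,}
#' i.e. the endowment kept plus an equal share of the multiplied aggregate
#' contribution. Total payoffs therefore satisfy the conservation identity
#' \eqn{\sum_i \pi_i = nE + (m-1)\sum_i c_i}.
#'
#' @param contributions Numeric vector (one group) or matrix (groups in
#'   rows) of contributions in `[0, endowment]`; the number of members must
#'   equal `config$group_size`.
#' @param config A [game_config()].
#' @return Payoffs with the same shape as `contributions`.
#' @examples
#' round_payoffs(c(20, 0, 0, 0), game_config(multiplier = 1.6))
#' @export
round_payoffs <- function(contributions, config = game_config()) {
  if (!inherits(config, "pgg_config")) stop_twinpgg("`config` must be a pgg_config.")
  vec <- is.null(dim(contributions))
  m <- if (vec) matrix(contributions, nrow = 1) else as.matrix(contributions)
  if (ncol(m) != config$group_size) {
    stop_twinpgg(sprintf(
      "Expected %d contributions per group, got %d.", config$group_size, ncol(m)
    ))
  }
  if (any(m < 0 | m > config$endowment)) {
    stop_twinpgg(sprintf("Contributions must lie in [0, %g].", config$endowment))
  }
  pay <- config$endowment - m +
    config$multiplier * rowSums(m) / config$group_size
  if (vec) drop(pay) else pay
}

# Vectorised schedule lookup: rows of a 0..20-indexed schedule matrix,
# continuous others'-averages rounded to a level and clamped to the
# elicited domain.
.lookup_response <- function(sched, rows, others_average, dialect, rounding) {
  lev <- apply_rounding(others_average, rounding)
  lev <- pmin(pmax(lev, min(schedule_levels(dialect))), 20)
  sched[cbind(rows, lev + 1L)]
}

#' Conditional contribution at an observed others' average
#'
#' Rounds the others' average contribution to an integer schedule level
#' (half-up by default), clamps it to the profile's elicited domain
#' (Study-1 schedules start at level 1), and returns the registered
#' conditional decision at that level.
#'
#' @param profiles A validated population table.
#' @param others_average Numeric vector of others' average contributions in
#'   `[0, endowment]`, recycled against the rows of `profiles`.
#' @param rounding `"half_up"` (default) or `"half_even"`.
#' @return Numeric vector of contributions, one per profile row.
#' @export
conditional_response <- function(profiles, others_average,
                                 rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  assert_data_frame(profiles, POP_COLS, "profiles")
  dialect <- pgg_dialect(profiles)
  n <- nrow(profiles)
  others_average <- rep_len(others_average, n)
  if (any(others_average < 0 | others_average > 20)) {
    stop_twinpgg("`others_average` must lie in [0, endowment].")
  }
  sched <- schedule_matrix(profiles, dialect)
  .lookup_response(sched, seq_len(n), others_average, dialect, rounding)
}

#' Simulation plan
#'
#' @param n_groups Number of sampled groups (>= 1).
#' @param iterations Rounds per game (1 = one-shot).
#' @param seed Integer RNG seed.
#' @param rounding Rounding rule for others'-average schedule lookup.
#' @return A `simulation_plan` list.
#' @export
simulation_plan <- function(n_groups, iterations = 1, seed = 1,
                            rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  if (n_groups < 1 || iterations < 1) {
    stop_twinpgg("`n_groups` and `iterations` must be >= 1.")
  }
  structure(
    list(n_groups = as.integer(n_groups), iterations = as.integer(iterations),
         seed = as.integer(seed), rounding = rounding),
    class = "simulation_plan"
  )
}

# n_groups x 4 matrix of distinct individual indices, uniform over ordered
# distinct 4-tuples (so every column, in particular the responder column,
# is marginally uniform over group members).
.sample_groups <- function(n_groups, N) {
  if (N < 8) {
    return(t(vapply(seq_len(n_groups), function(i) sample.int(N, 4L), integer(4))))
  }
  idx <- matrix(sample.int(N, 4L * n_groups, replace = TRUE), n_groups, 4L)
  repeat {
    dup <- idx[, 1] == idx[, 2] | idx[, 1] == idx[, 3] | idx[, 1] == idx[, 4] |
      idx[, 2] == idx[, 3] | idx[, 2] == idx[, 4] | idx[, 3] == idx[, 4]
    bad <- which(dup)
    if (!length(bad)) break
    idx[bad, ] <- matrix(sample.int(N, 4L * length(bad), replace = TRUE),
                         length(bad), 4L)
  }
  idx
}

# Accumulate per-individual sums of `values` indexed by `ids` into an
# N-vector.
.accumulate <- function(values, ids, N) {
  rs <- rowsum(values, ids)
  out <- numeric(N)
  out[as.integer(rownames(rs))] <- rs
  out
}

#' Monte Carlo one-shot simulation with unconditional/conditional roles
#'
#' Repeatedly samples four distinct individuals; one is the conditional
#' decision maker, the other three contribute their unconditional decisions.
#' The conditional member contributes their registered decision at the
#' (rounded) average unconditional contribution of the other three. Payoffs
#' follow [round_payoffs()]. Per individual, role counts and role-wise mean
#' payoffs (with Monte Carlo standard errors) are accumulated; the total
#' estimated payoff is the sum of the two role-wise means.
#'
#' @param profiles A validated population table (>= 4 individuals).
#' @param config A [game_config()].
#' @param n_groups Number of sampled groups.
#' @param seed Integer RNG seed (simulation is reproducible given the seed).
#' @param rounding Rounding rule for the others'-average lookup.
#' @param plan Optional [simulation_plan()]; when supplied it overrides
#'   `n_groups`, `iterations`, `seed` and `rounding`.
#' @return A tibble with one row per individual: `individual_id`,
#'   `n_uncond`, `n_cond`, `mean_uncond`, `se_uncond`, `mean_cond`,
#'   `se_cond`, `total_payoff`.
#' @examples
#' pop <- make_fixture("eightperson_oracle")
#' simulate_one_shot(pop, game_config(), n_groups = 1000, seed = 7)
#' @export
simulate_one_shot <- function(profiles, config = game_config(),
                              n_groups = 250000, seed = 1,
                              rounding = c("half_up", "half_even"),
                              plan = NULL) {
  if (!is.null(plan)) {
    if (!inherits(plan, "simulation_plan")) stop_twinpgg("`plan` must be a simulation_plan.")
    if (plan$iterations != 1) stop_twinpgg("One-shot plans must have iterations = 1.")
    n_groups <- plan$n_groups; seed <- plan$seed; rounding <- plan$rounding
  }
  rounding <- match.arg(rounding)
  assert_data_frame(profiles, POP_COLS, "profiles")
  N <- nrow(profiles)
  if (N < config$group_size) {
    stop_twinpgg("Population smaller than the group size.")
  }
  if (config$group_size != 4) {
    stop_twinpgg("Monte Carlo simulations support four-member groups only.")
  }
  dialect <- pgg_dialect(profiles)
  uc <- as.numeric(profiles$uc)
  sched <- schedule_matrix(profiles, dialect)
  set.seed(seed)
  idx <- .sample_groups(n_groups, N)
  # Column 4 is the conditional decision maker; the ordered tuple is
  # uniform, so this is equivalent to drawing the role at random.
  resp <- idx[, 4]
  uc_mat <- matrix(uc[idx[, 1:3]], n_groups, 3)
  avg <- rowMeans(uc_mat)
  c_resp <- .lookup_response(sched, resp, avg, dialect, rounding)
  total <- rowSums(uc_mat) + c_resp
  share <- config$multiplier * total / config$group_size
  pay_u <- config$endowment - uc_mat + share      # n_groups x 3
  pay_c <- config$endowment - c_resp + share

  ids_u <- as.vector(idx[, 1:3])
  pays_u <- as.vector(pay_u)
  n_u <- tabulate(ids_u, N)
  n_c <- tabulate(resp, N)
  sum_u <- .accumulate(pays_u, ids_u, N)
  sum_c <- .accumulate(pay_c, resp, N)
  ss_u <- .accumulate(pays_u^2, ids_u, N)
  ss_c <- .accumulate(pay_c^2, resp, N)

  mean_u <- ifelse(n_u > 0, sum_u / n_u, NA_real_)
  mean_c <- ifelse(n_c > 0, sum_c / n_c, NA_real_)
  var_u <- ifelse(n_u > 1, (ss_u - n_u * mean_u^2) / (n_u - 1), NA_real_)
  var_c <- ifelse(n_c > 1, (ss_c - n_c * mean_c^2) / (n_c - 1), NA_real_)

  tibble::tibble(
    individual_id = profiles$individual_id,
    n_uncond = n_u,
    n_cond = n_c,
    mean_uncond = mean_u,
    se_uncond = sqrt(pmax(var_u, 0) / n_u),
    mean_cond = mean_c,
    se_cond = sqrt(pmax(var_c, 0) / n_c),
    total_payoff = mean_u + mean_c
  )
}

# Core iterated-game engine over a fixed index matrix. Round 1 plays the
# unconditional decisions; from round 2 on, every member responds to the
# other three members' previous-round average via their schedule. Returns
# per-individual membership counts and an N x iterations matrix of summed
# payoffs per round.
.iterated_engine <- function(uc, sched, dialect, idx, config, iterations, rounding) {
  n_g <- nrow(idx)
  N <- length(uc)
  ids <- as.vector(idx)
  counts <- tabulate(ids, N)
  C <- matrix(uc[idx], n_g, 4)
  round_sums <- matrix(0, N, iterations)
  min_lev <- min(schedule_levels(dialect))
  for (t in seq_len(iterations)) {
    if (t > 1) {
      avg <- (rowSums(C) - C) / 3
      lev <- apply_rounding(avg, rounding)
      lev <- pmin(pmax(lev, min_lev), 20)
      C <- matrix(sched[cbind(ids, as.vector(lev) + 1L)], n_g, 4)
    }
    pay <- config$endowment - C +
      config$multiplier * rowSums(C) / config$group_size
    round_sums[, t] <- .accumulate(as.vector(pay), ids, N)
  }
  list(counts = counts, round_sums = round_sums)
}

#' Monte Carlo iterated-game simulation
#'
#' Samples groups of four and plays a fixed number of rounds. In round 1
#' every member contributes their unconditional decision; in later rounds
#' every member is a conditional responder to the other three members'
#' average contribution in the preceding round (memory-1 play, fresh
#' endowment every round). The reported quantity per individual is the mean
#' payoff per round, averaged over group memberships.
#'
#' @inheritParams simulate_one_shot
#' @param iterations Number of rounds (>= 2).
#' @param n_groups Number of sampled groups.
#' @return A tibble per individual: `individual_id`, `iterations`,
#'   `n_memberships`, `mean_payoff_per_round`.
#' @export
simulate_iterated <- function(profiles, config = game_config(), iterations,
                              n_groups = 100000, seed = 1,
                              rounding = c("half_up", "half_even"),
                              plan = NULL) {
  if (!is.null(plan)) {
    if (!inherits(plan, "simulation_plan")) stop_twinpgg("`plan` must be a simulation_plan.")
    iterations <- plan$iterations; n_groups <- plan$n_groups
    seed <- plan$seed; rounding <- plan$rounding
  }
  rounding <- match.arg(rounding)
  assert_data_frame(profiles, POP_COLS, "profiles")
  if (iterations < 2) stop_twinpgg("`iterations` must be >= 2 (use simulate_one_shot for 1).")
  N <- nrow(profiles)
  if (N < config$group_size) stop_twinpgg("Population smaller than the group size.")
  if (config$group_size != 4) {
    stop_twinpgg("Monte Carlo simulations support four-member groups only.")
  }
  dialect <- pgg_dialect(profiles)
  set.seed(seed)
  idx <- .sample_groups(n_groups, N)
  eng <- .iterated_engine(as.numeric(profiles$uc),
                          schedule_matrix(profiles, dialect),
                          dialect, idx, config, iterations, rounding)
  tibble::tibble(
    individual_id = profiles$individual_id,
    iterations = as.integer(iterations),
    n_memberships = eng$counts,
    mean_payoff_per_round = ifelse(
      eng$counts > 0,
      rowSums(eng$round_sums) / (iterations * eng$counts),
      NA_real_
    )
  )
}

#' Play one fixed group for a given number of rounds
#'
#' Deterministic trace of the iterated dynamics for a single group of
#' exactly `group_size` profiles: round 1 plays the unconditional decisions,
#' later rounds the memory-1 conditional responses. Useful for hand-checked
#' fixtures and conservation checks.
#'
#' @inheritParams simulate_one_shot
#' @param iterations Number of rounds (>= 1).
#' @return A tibble: `round`, `individual_id`, `contribution`, `payoff`.
#' @examples
#' pop <- make_fixture("fixed_cc3_fr1")
#' play_group(pop, game_config(), iterations = 2)
#' @export
play_group <- function(profiles, config = game_config(), iterations = 1,
                       rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  assert_data_frame(profiles, POP_COLS, "profiles")
  if (nrow(profiles) != config$group_size) {
    stop_twinpgg(sprintf("`profiles` must contain exactly %d rows.", config$group_size))
  }
  dialect <- pgg_dialect(profiles)
  sched <- schedule_matrix(profiles, dialect)
  C <- as.numeric(profiles$uc)
  min_lev <- min(schedule_levels(dialect))
  out <- vector("list", iterations)
  for (t in seq_len(iterations)) {
    if (t > 1) {
      avg <- (sum(C) - C) / (config$group_size - 1)
      lev <- pmin(pmax(apply_rounding(avg, rounding), min_lev), 20)
      C <- sched[cbind(seq_along(C), lev + 1L)]
    }
    out[[t]] <- tibble::tibble(
      round = t,
      individual_id = profiles$individual_id,
      contribution = C,
      payoff = config$endowment - C +
        config$multiplier * sum(C) / config$group_size
    )
  }
  dplyr::bind_rows(out)
}

#' Exact expected one-shot payoffs by exhaustive enumeration
#'
#' Enumerates every 4-subset of the population and every responder
#' assignment (all equally likely under the sampling scheme of
#' [simulate_one_shot()]) and returns the exact role-wise expected payoffs.
#' Guarded to populations of at most 12 individuals.
#'
#' @inheritParams simulate_one_shot
#' @return A tibble per individual: `individual_id`, `mean_uncond`,
#'   `mean_cond`, `total_payoff`.
#' @export
exhaustive_one_shot <- function(profiles, config = game_config(),
                                rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  assert_data_frame(profiles, POP_COLS, "profiles")
  N <- nrow(profiles)
  if (N < config$group_size) stop_twinpgg("Population smaller than the group size.")
  if (N > 12) stop_twinpgg("Exhaustive enumeration is limited to N <= 12.")
  dialect <- pgg_dialect(profiles)
  uc <- as.numeric(profiles$uc)
  sched <- schedule_matrix(profiles, dialect)
  subsets <- combn(N, config$group_size)
  sum_u <- sum_c <- numeric(N)
  n_u <- n_c <- integer(N)
  for (s in seq_len(ncol(subsets))) {
    grp <- subsets[, s]
    for (r in seq_along(grp)) {
      others <- grp[-r]
      avg <- mean(uc[others])
      cr <- .lookup_response(sched, grp[r], avg, dialect, rounding)
      contrib <- c(uc[others], cr)
      share <- config$multiplier * sum(contrib) / config$group_size
      sum_u[others] <- sum_u[others] + config$endowment - uc[others] + share
      n_u[others] <- n_u[others] + 1L
      sum_c[grp[r]] <- sum_c[grp[r]] + config$endowment - cr + share
      n_c[grp[r]] <- n_c[grp[r]] + 1L
    }
  }
  tibble::tibble(
    individual_id = profiles$individual_id,
    mean_uncond = sum_u / n_u,
    mean_cond = sum_c / n_c,
    total_payoff = sum_u / n_u + sum_c / n_c
  )
}
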