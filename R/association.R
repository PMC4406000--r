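# Rank-based association between decision scores and simulated payoffs:
# Spearman correlations, partial Spearman correlations via residualised
# ranks, and cumulative-round correlation curves.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive their average rank, which
#' matters here: strategy-score distributions are tie-heavy, e.g. the
#' all-zero free riders).
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_twinpgg("`x` and `y` must have equal length >= 3.")
  }
  if (var(rank(x)) == 0 || var(rank(y)) == 0) {
    stop_twinpgg("Zero rank variance: Spearman correlation undefined.")
  }
  cor(x, y, method = "spearman")
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all variables (mid-ranks), removes the least-squares
#' projection on the controls (with intercept) from both `x` and `y`, and
#' correlates the residuals. With no controls this reduces exactly to
#' [spearman_rho()].
#'
#' @param x,y Equal-length numeric vectors.
#' @param controls Optional data frame / matrix of control variables.
#' @return The partial rank correlation.
#' @export
partial_spearman <- function(x, y, controls = NULL) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_twinpgg("`x` and `y` must have equal length >= 3.")
  }
  if (is.null(controls) || NCOL(controls) == 0) {
    return(spearman_rho(x, y))
  }
  z <- as.matrix(as.data.frame(controls))
  if (nrow(z) != length(x)) stop_twinpgg("`controls` must have one row per observation.")
  rz <- apply(z, 2, rank)
  X <- cbind(1, rz)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop_twinpgg("Collinear controls: partial correlation not estimable.")
  }
  res <- function(v) qr.resid(qr_x, rank(v))
  rx <- res(x); ry <- res(y)
  if (var(rx) == 0 || var(ry) == 0) {
    stop_twinpgg("Zero residual variance: partial correlation undefined.")
  }
  cor(rx, ry)
}

#' Spearman correlations between two score tables on matched individuals
#'
#' Joins two per-individual score tables by id (e.g. repeat participants of
#' two experiments) and returns the full cross-correlation matrix of the
#' named score columns in tidy form.
#'
#' @param scores_x,scores_y Tibbles with `individual_id` and score columns.
#' @param by Join column (default `"individual_id"`).
#' @return A tibble: `score_x`, `score_y`, `n`, `rho`.
#' @export
cross_spearman <- function(scores_x, scores_y, by = "individual_id") {
  assert_data_frame(scores_x, by, "scores_x")
  assert_data_frame(scores_y, by, "scores_y")
  merged <- dplyr::inner_join(scores_x, scores_y, by = by,
                              suffix = c("_x", "_y"))
  meta <- c(by, "pair_id", "zygosity", "pair_id_x", "pair_id_y",
            "zygosity_x", "zygosity_y")
  num_x <- setdiff(names(scores_x), meta)
  num_y <- setdiff(names(scores_y), meta)
  num_x <- num_x[vapply(scores_x[num_x], is.numeric, logical(1))]
  num_y <- num_y[vapply(scores_y[num_y], is.numeric, logical(1))]
  col_of <- function(base, side) {
    nm <- if (base %in% names(merged)) base else paste0(base, side)
    merged[[nm]]
  }
  tidyr::expand_grid(score_x = num_x, score_y = num_y) |>
    dplyr::mutate(
      n = nrow(merged),
      rho = purrr::map2_dbl(.data$score_x, .data$score_y, function(a, b) {
        spearman_rho(col_of(a, "_x"), col_of(b, "_y"))
      })
    )
}

#' Cumulative score-payoff correlation curves over iterated play
#'
#' Runs one iterated simulation to `max_iterations` rounds and, for every
#' round k, correlates each decision score with the cumulative mean payoff
#' per round through round k (Spearman), together with the partial Spearman
#' correlation controlling for the remaining scores. Reproduces, for any
#' population, the qualitative pattern in which cooperativeness is costly
#' over few rounds but profitable over many.
#'
#' Individuals never sampled into a group are dropped (with a warning).
#' Degenerate correlations (zero rank variance, e.g. in a homogeneous
#' population) are flagged as `NA` with a warning, never silently emitted.
#'
#' @param profiles A validated population table.
#' @param scores Per-individual score table ([compute_scores()] output);
#'   all numeric columns except `uc`-metadata are treated as scores.
#' @param config A [game_config()].
#' @param max_iterations Longest horizon (curve length).
#' @param n_groups Number of sampled groups.
#' @param seed Integer RNG seed (shares group sampling with
#'   [simulate_iterated()] at the same seed).
#' @param rounding Rounding rule for schedule lookup.
#' @return A tibble of class `pgg_curves`: `round`, `score`, `rho`,
#'   `partial_rho`.
#' @export
payoff_curves <- function(profiles, scores, config = game_config(),
                          max_iterations = 100, n_groups = 100000, seed = 1,
                          rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  assert_data_frame(profiles, POP_COLS, "profiles")
  assert_data_frame(scores, "individual_id", "scores")
  if (config$group_size != 4) {
    stop_twinpgg("Monte Carlo simulations support four-member groups only.")
  }
  N <- nrow(profiles)
  if (N < 4) stop_twinpgg("Population smaller than the group size.")
  dialect <- pgg_dialect(profiles)
  set.seed(seed)
  idx <- .sample_groups(n_groups, N)
  eng <- .iterated_engine(as.numeric(profiles$uc),
                          schedule_matrix(profiles, dialect),
                          dialect, idx, config, max_iterations, rounding)

  keep <- eng$counts > 0
  if (!all(keep)) {
    warn(sprintf("%d individual(s) never sampled; dropped from curves.",
                 sum(!keep)))
  }
  cum <- t(apply(eng$round_sums[keep, , drop = FALSE], 1, cumsum))
  cum <- cum / (eng$counts[keep] %o% seq_len(max_iterations))

  score_cols <- setdiff(names(scores), c("individual_id", "pair_id", "zygosity"))
  score_cols <- score_cols[vapply(scores[score_cols], is.numeric, logical(1))]
  if (!length(score_cols)) stop_twinpgg("`scores` has no numeric score columns.")
  sm <- scores[match(profiles$individual_id[keep], scores$individual_id),
               score_cols, drop = FALSE]
  if (anyNA(sm)) stop_twinpgg("`scores` must cover every individual in `profiles`.")
  sm <- as.matrix(sm)

  pay_ranks <- apply(cum, 2, rank)
  degenerate <- FALSE
  out <- purrr::map_dfr(score_cols, function(sc) {
    xr <- rank(sm[, sc])
    ctrl <- sm[, setdiff(score_cols, sc), drop = FALSE]
    rho <- partial <- rep(NA_real_, max_iterations)
    if (var(xr) > 0) {
      ok <- apply(pay_ranks, 2, var) > 0
      rho[ok] <- suppressWarnings(cor(xr, pay_ranks[, ok, drop = FALSE]))[1, ]
      if (ncol(ctrl) > 0) {
        X <- cbind(1, apply(ctrl, 2, rank))
        qr_x <- qr(X)
        if (qr_x$rank == ncol(X)) {
          xres <- qr.resid(qr_x, xr)
          yres <- qr.resid(qr_x, pay_ranks)
          okp <- ok & apply(yres, 2, var) > 0
          if (var(xres) > 0) {
            partial[okp] <- suppressWarnings(cor(xres, yres[, okp, drop = FALSE]))[1, ]
          }
        }
      } else {
        partial <- rho
      }
    }
    if (anyNA(rho)) degenerate <<- TRUE
    tibble::tibble(round = seq_len(max_iterations), score = sc,
                   rho = rho, partial_rho = partial)
  })
  if (degenerate) {
    warn("Degenerate (zero-variance) correlations flagged as NA.",
         class = "twinpgg_degenerate")
  }
  class(out) <- c("pgg_curves", class(out))
  out
}
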