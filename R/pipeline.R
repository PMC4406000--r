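# End-to-end orchestration: population -> decision summaries and trend
# regressions -> composite scores -> ICC table -> ACE posteriors per score
# (optionally chained) -> one-shot and iterated payoff simulations ->
# score-payoff correlations and ACE on payoffs -> cumulative correlation
# curves. Every stage draws its RNG seed deterministically from the single
# run seed (derive_seed(seed, stage_offset)), so stages can be rerun in
# isolation and a rerun with the same configuration is numerically
# identical.

#' Configuration for a full analysis run
#'
#' @param population A validated population tibble, or `NULL` to generate
#'   one from `synthetic`.
#' @param synthetic A [synthetic_config()] (used when `population` is NULL).
#' @param config A [game_config()].
#' @param bands A [band_spec()] preset name or object.
#' @param ace_spec An [ace_model_spec()] (reduced settings are a sensible
#'   default for desk-scale runs).
#' @param oneshot_groups Groups for the one-shot simulation.
#' @param iteration_ladder Strictly increasing iteration counts for the
#'   iterated simulations.
#' @param iterated_groups Groups per iterated simulation.
#' @param curve_iterations Longest horizon for the correlation curves
#'   (0 disables the curve stage).
#' @param chained Also refit each score with informative priors chained from
#'   its own non-informative posterior?
#' @param out_dir Optional directory for delimited output tables and the
#'   run manifest.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(population = NULL, synthetic = synthetic_config(),
                       config = game_config(), bands = NULL,
                       ace_spec = ace_model_spec(iterations = 10000,
                                                 burnin = 1000, thin = 10),
                       oneshot_groups = 250000,
                       iteration_ladder = c(2, 5, 10, 20, 50, 100),
                       iterated_groups = 100000, curve_iterations = 100,
                       chained = FALSE, out_dir = NULL, seed = 1) {
  if (any(diff(iteration_ladder) <= 0) || any(iteration_ladder < 2)) {
    stop_twinpgg("`iteration_ladder` must be strictly increasing integers >= 2.")
  }
  structure(
    list(population = population, synthetic = synthetic, config = config,
         bands = bands, ace_spec = ace_spec,
         oneshot_groups = as.integer(oneshot_groups),
         iteration_ladder = as.integer(iteration_ladder),
         iterated_groups = as.integer(iterated_groups),
         curve_iterations = as.integer(curve_iterations),
         chained = isTRUE(chained), out_dir = out_dir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# Stage seed offsets (documented part of the reproducibility contract).
.STAGE_OFFSETS <- c(generate = 101, icc = 223, ace = 311, oneshot = 401,
                    iterated = 503, curves = 601)

.fit_ace_safely <- function(paired, spec, seed) {
  withCallingHandlers(
    fit_ace(paired, spec, seed = seed),
    twinpgg_nonconvergence = function(w) invokeRestart("muffleWarning")
  )
}

#' Run the full three-part analysis on one population
#'
#' Executes, in order: decision summary and trend regressions, composite
#' scores, intraclass correlations, ACE fits per score (plus an optional
#' chained-prior refit), the one-shot simulation with role-wise payoffs and
#' score-payoff Spearman correlations, the iterated-game ladder with ACE
#' fits on payoff per round, and the cumulative correlation curves. A
#' manifest records configuration, seeds, versions, and per-stage wall
#' times. Any stage failure aborts with the stage name; partial outputs
#' written so far are retained and the manifest marks the run incomplete.
#'
#' @param rc A [run_config()].
#' @return A `pgg_bundle` list: `population`, `decision_summary`, `trends`,
#'   `scores`, `icc`, `ace` (tibble of per-score share estimates),
#'   `ace_fits`, `oneshot`, `oneshot_summary`, `score_payoff_rho`,
#'   `iterated`, `iterated_ace`, `curves`, `manifest`.
#' @export
run_study <- function(rc = run_config()) {
  if (!inherits(rc, "run_config")) stop_twinpgg("`rc` must be a run_config().")
  bundle <- list()
  manifest <- list(
    seed = rc$seed,
    package_version = as.character(utils::packageVersion("twinpgg")),
    r_version = as.character(getRversion()),
    stage_offsets = .STAGE_OFFSETS,
    complete = FALSE,
    stages = list()
  )
  out_dir <- rc$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, tab) {
    if (!is.null(out_dir) && is.data.frame(tab)) {
      readr::write_tsv(tab, file.path(out_dir, paste0(name, ".tsv")),
                       progress = FALSE)
    }
  }
  write_manifest <- function() {
    if (is.null(out_dir)) return(invisible())
    lines <- c(
      sprintf("seed: %d", manifest$seed),
      sprintf("package_version: %s", manifest$package_version),
      sprintf("r_version: %s", manifest$r_version),
      sprintf("complete: %s", tolower(as.character(manifest$complete))),
      sprintf("stage_offset_%s: %d", names(.STAGE_OFFSETS), .STAGE_OFFSETS),
      vapply(names(manifest$stages), function(s) {
        sprintf("stage_%s_seconds: %.3f", s, manifest$stages[[s]])
      }, "")
    )
    writeLines(lines, file.path(out_dir, "manifest.txt"))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    result <- tryCatch(expr, error = function(e) {
      manifest$complete <<- FALSE
      write_manifest()
      stop_twinpgg(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$stages[[name]] <<- proc.time()[["elapsed"]] - t0
    result
  }

  # Population ------------------------------------------------------------
  profiles <- stage("population", {
    if (!is.null(rc$population)) {
      validate_population(rc$population, endowment = rc$config$endowment)
    } else {
      sc <- rc$synthetic
      sc$seed <- derive_seed(rc$seed, .STAGE_OFFSETS[["generate"]])
      generate_twin_population(sc)$profiles
    }
  })
  bundle$population <- profiles
  emit("population", profiles)

  dialect <- pgg_dialect(profiles)
  bands <- rc$bands %||% band_spec(dialect)
  if (is.character(bands)) bands <- band_spec(bands)

  # Decisions --------------------------------------------------------------
  bundle$decision_summary <- stage("decision_summary", summarize_population(profiles))
  emit("decision_summary", bundle$decision_summary)
  bundle$trends <- stage("trends", tryCatch(
    trend_regressions(bundle$decision_summary),
    # degenerate (e.g. homogeneous) populations: flagged, not fatal
    twinpgg_error = function(e) tibble::tibble(
      statistic = c("mean", "sd"), slope = NA_real_, intercept = NA_real_,
      standardized_slope = NA_real_, r_squared = NA_real_
    )
  ))
  emit("trends", bundle$trends)
  bundle$scores <- stage("scores", compute_scores(profiles, bands))
  emit("scores", bundle$scores)
  score_cols <- c("uc", names(bands$bands))

  # Twin statistics ---------------------------------------------------------
  icc_seed <- derive_seed(rc$seed, .STAGE_OFFSETS[["icc"]])
  bundle$icc <- stage("icc", purrr::map_dfr(score_cols, function(sc) {
    paired <- pair_scores(bundle$scores, !!sc)
    tryCatch(
      dplyr::mutate(
        intraclass_correlation(paired, seed = icc_seed),
        score = sc, .before = 1
      ),
      twinpgg_error = function(e) tibble::tibble(
        score = sc, zygosity = NA_character_, n_pairs = NA_integer_,
        icc = NA_real_, conf.low = NA_real_, conf.high = NA_real_
      )
    )
  }))
  emit("icc", bundle$icc)

  ace_seed <- derive_seed(rc$seed, .STAGE_OFFSETS[["ace"]])
  bundle$ace_fits <- stage("ace", {
    fits <- purrr::map(score_cols, function(sc) {
      paired <- pair_scores(bundle$scores, !!sc)
      # Degenerate scores (e.g. a homogeneous population) are flagged by
      # an empty fit slot rather than aborting the run.
      fit <- tryCatch(.fit_ace_safely(paired, rc$ace_spec, seed = ace_seed),
                      twinpgg_error = function(e) NULL)
      if (is.null(fit)) return(list())
      if (rc$chained) {
        chained_spec <- posterior_to_priors(
          fit,
          chains = rc$ace_spec$chains, iterations = rc$ace_spec$iterations,
          thin = rc$ace_spec$thin, burnin = rc$ace_spec$burnin
        )
        list(noninformative = fit,
             chained = .fit_ace_safely(paired, chained_spec, seed = ace_seed + 1L))
      } else {
        list(noninformative = fit)
      }
    })
    setNames(fits, score_cols)
  })
  bundle$ace <- purrr::map_dfr(score_cols, function(sc) {
    purrr::map_dfr(names(bundle$ace_fits[[sc]]), function(kind) {
      dplyr::mutate(tidy(bundle$ace_fits[[sc]][[kind]]),
                    score = sc, priors = kind, .before = 1)
    })
  })
  emit("ace", bundle$ace)

  # Simulations -------------------------------------------------------------
  oneshot_seed <- derive_seed(rc$seed, .STAGE_OFFSETS[["oneshot"]])
  bundle$oneshot <- stage("oneshot", simulate_one_shot(
    profiles, rc$config, n_groups = rc$oneshot_groups, seed = oneshot_seed
  ))
  emit("oneshot", bundle$oneshot)
  bundle$oneshot_summary <- tibble::tibble(
    role = c("uncond", "cond"),
    mean = c(mean(bundle$oneshot$mean_uncond, na.rm = TRUE),
             mean(bundle$oneshot$mean_cond, na.rm = TRUE)),
    sd = c(sd(bundle$oneshot$mean_uncond), sd(bundle$oneshot$mean_cond))
  )
  emit("oneshot_summary", bundle$oneshot_summary)

  scores_only <- bundle$scores[c("individual_id", score_cols)]
  rho_of <- function(payoff) {
    purrr::map_dfr(score_cols, function(sc) {
      tibble::tibble(score = sc, rho = tryCatch(
        spearman_rho(scores_only[[sc]], payoff),
        twinpgg_error = function(e) NA_real_
      ))
    })
  }
  bundle$score_payoff_rho <- dplyr::bind_rows(
    dplyr::mutate(rho_of(bundle$oneshot$mean_uncond), payoff = "uncond", .before = 1),
    dplyr::mutate(rho_of(bundle$oneshot$mean_cond), payoff = "cond", .before = 1)
  )

  iter_seed0 <- derive_seed(rc$seed, .STAGE_OFFSETS[["iterated"]])
  iterated <- stage("iterated", purrr::map(
    seq_along(rc$iteration_ladder), function(i) {
      simulate_iterated(profiles, rc$config,
                        iterations = rc$iteration_ladder[i],
                        n_groups = rc$iterated_groups,
                        seed = iter_seed0 + i)
    }
  ))
  bundle$iterated <- dplyr::bind_rows(iterated)
  emit("iterated", bundle$iterated)
  bundle$score_payoff_rho <- dplyr::bind_rows(
    bundle$score_payoff_rho,
    purrr::map_dfr(iterated, function(sim) {
      dplyr::mutate(rho_of(sim$mean_payoff_per_round),
                    payoff = sprintf("it%d", sim$iterations[1]), .before = 1)
    })
  )
  emit("score_payoff_rho", bundle$score_payoff_rho)

  bundle$iterated_ace <- stage("iterated_ace", purrr::map_dfr(
    c(list(NULL), iterated), function(sim) {
      if (is.null(sim)) {
        payoff <- bundle$oneshot$total_payoff
        label <- "oneshot_total"
      } else {
        payoff <- sim$mean_payoff_per_round
        label <- sprintf("it%d", sim$iterations[1])
      }
      dat <- dplyr::mutate(bundle$scores[c("individual_id", "pair_id", "zygosity")],
                           payoff = payoff)
      paired <- pair_scores(dat, payoff)
      fit <- tryCatch(.fit_ace_safely(paired, rc$ace_spec, seed = ace_seed + 7L),
                      twinpgg_error = function(e) NULL)
      if (is.null(fit)) return(tibble::tibble())
      dplyr::mutate(tidy(fit), payoff = label, .before = 1)
    }
  ))
  emit("iterated_ace", bundle$iterated_ace)

  if (rc$curve_iterations >= 2) {
    curve_seed <- derive_seed(rc$seed, .STAGE_OFFSETS[["curves"]])
    bundle$curves <- stage("curves", suppressWarnings(payoff_curves(
      profiles, scores_only, rc$config,
      max_iterations = rc$curve_iterations,
      n_groups = rc$iterated_groups, seed = curve_seed
    )))
    emit("curves", bundle$curves)
  }

  manifest$complete <- TRUE
  bundle$manifest <- manifest
  write_manifest()
  class(bundle) <- "pgg_bundle"
  bundle
}

#' @export
print.pgg_bundle <- function(x, ...) {
  cat(sprintf(
    "<pgg_bundle> %d individuals; stages: %s\n",
    nrow(x$population),
    paste(names(x$manifest$stages), collapse = ", ")
  ))
  invisible(x)
}
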